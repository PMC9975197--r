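test_that("hierarchical_partitions builds nested, deterministic trees", {
  # K = 2: the only possible tree
  pa2 <- hierarchical_partitions(rand_corr(2, seed = 1))
  expect_equal(pa2$assignments[[2]], c(1L, 2L))
  expect_equal(pa2$assignments[[1]], c(1L, 1L))

  # block-diagonal similarity: the 2-cluster cut recovers the two blocks
  Rb <- matrix(0, 4, 4); Rb[1:2, 1:2] <- 0.9; Rb[3:4, 3:4] <- 0.9; diag(Rb) <- 1
  pab <- hierarchical_partitions(Rb)
  expect_true(same_partition(pab$assignments[[2]], c(1, 1, 2, 2)))

  # fully tied distances: deterministic, identical across calls
  p1 <- hierarchical_partitions(diag(3))
  p2 <- hierarchical_partitions(diag(3))
  expect_identical(p1, p2)
  # lexicographic tie-break merges (1,2) first
  expect_equal(p1$assignments[[2]], c(1L, 1L, 2L))

  # K = 1 trivial partition
  expect_equal(hierarchical_partitions(matrix(1, 1, 1))$assignments[[1]], 1L)

  # nested refinement across random matrices and linkages
  for (s in 1:5) {
    R <- rand_corr(9, seed = 100 + s)
    for (lk in c("average", "single", "complete")) {
      pa <- hierarchical_partitions(R, lk)
      for (L in 2:9) {
        fine <- pa$assignments[[L]]; coarse <- pa$assignments[[L - 1]]
        expect_equal(length(unique(paste(fine, coarse))), L)
        expect_equal(sort(unique(fine)), 1:L)
      }
    }
  }
})

test_that("partitions agree with stats::hclust/cutree on tie-free inputs", {
  for (s in 1:10) {
    K <- 3 + (s %% 8)
    R <- rand_corr(K, seed = 200 + s)
    pa <- hierarchical_partitions(R, "average")
    hc <- stats::hclust(stats::as.dist(1 - R), method = "average")
    for (L in 1:K)
      expect_true(same_partition(pa$assignments[[L]], stats::cutree(hc, k = L)))
  }
})

test_that("clc_statistic matches an explicit dense-algebra evaluation", {
  R3 <- matrix(0.5, 3, 3); diag(R3) <- 1
  z3 <- c(1, 2, 3)
  B <- cbind(c(1, 1, 0), c(0, 0, 1))
  # independent route: explicit inversions
  W <- t(B) %*% solve(R3)
  oracle <- drop(t(W %*% z3) %*% solve(W %*% R3 %*% t(W)) %*% (W %*% z3))
  got <- clc_statistic(z3, R3, B)
  expect_equal(got$statistic, oracle, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$pvalue, stats::pchisq(oracle, 2, lower.tail = FALSE))

  # single all-ones column, R = I: (1'Z)^2 / K
  expect_equal(clc_statistic(c(1, 1), diag(2), matrix(1, 2, 1))$statistic, 2)

  expect_error(clc_statistic(z3, R3, cbind(c(1, 1, 0), c(1, 0, 1))),
               "membership")
})

test_that("L=K collapses to Wald and L=1 to Hom on random PD matrices", {
  worst_wald <- 0; worst_hom <- 0
  for (s in 1:100) {
    K <- 2 + (s %% 7)
    R <- rand_corr(K, seed = 300 + s)
    z <- sclc:::with_seed(400 + s, stats::rnorm(K))
    pa <- hierarchical_partitions(R)
    tK <- clc_statistic(z, R, membership_matrix(pa, K))$statistic
    t1 <- clc_statistic(z, R, membership_matrix(pa, 1))$statistic
    wald <- wald_test(z, R)$statistic
    hom <- hom_test(z, R)$statistic
    worst_wald <- max(worst_wald, abs(tK - wald) / wald)
    worst_hom <- max(worst_hom, abs(t1 - hom) / max(hom, 1e-12))
  }
  expect_lt(worst_wald, 1e-8)
  expect_lt(worst_hom, 1e-8)
})

test_that("clc_statistic is invariant to column permutations of B", {
  R <- rand_corr(6, seed = 17)
  z <- sclc:::with_seed(18, stats::rnorm(6))
  pa <- hierarchical_partitions(R)
  B <- membership_matrix(pa, 3)
  base <- clc_statistic(z, R, B)$statistic
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(3, 2, 1)))
    expect_equal(clc_statistic(z, R, B[, perm])$statistic, base,
                 tolerance = 1e-12)
})

test_that("cauchy_combination matches its closed forms and stays stable", {
  expect_equal(cauchy_combination(c(0.5, 0.5))$pvalue, 0.5, tolerance = 1e-12)
  # single p-value round trip
  expect_equal(cauchy_combination(0.05)$pvalue, 0.05, tolerance = 1e-10)
  expect_equal(cauchy_combination(0.999)$pvalue, 0.999, tolerance = 1e-9)
  # extreme tail: T ~ 1/(3 pi p), combined p ~ 3p
  out <- cauchy_combination(c(1e-300, 0.5, 0.5))
  expect_equal(out$pvalue, 3e-300, tolerance = 0.01)
  expect_error(cauchy_combination(c(0.2, 1)), "strictly")
  expect_error(cauchy_combination(c(0, 0.2)), "strictly")
})

test_that("decreasing any single p_L strictly decreases the combined p", {
  set.seed(21)
  for (rep in 1:5) {
    p <- runif(8, 0.01, 0.99)
    base <- cauchy_combination(p)$pvalue
    for (i in seq_along(p)) {
      p2 <- p; p2[i] <- p2[i] * 0.5
      expect_lt(cauchy_combination(p2)$pvalue, base)
    }
  }
})

test_that("sclc_test handles the degenerate and null-centred cases", {
  # K = 1: the pipeline reduces to the single-trait chi-square p-value
  r1 <- sclc_test(1.7, matrix(1, 1, 1))
  expect_equal(r1$pvalue, stats::pchisq(1.7^2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # Z = 0: every statistic is 0, every p_L is at the clamp, combined p >= 0.5
  r0 <- sclc_test(c(0, 0), diag(2))
  expect_gte(r0$pvalue, 0.5)
  expect_equal(unname(r0$detail$stat_per_L), c(0, 0))
})

test_that("sclc_scan equals the per-SNP loop and reuses the clustering", {
  R <- rand_corr(7, seed = 31)
  Z <- sclc:::with_seed(32, matrix(stats::rnorm(7 * 50), 7, 50))
  colnames(Z) <- paste0("rs", 1:50)
  sclc:::reset_counters()
  scan <- sclc_scan(Z, R)
  expect_equal(sclc:::get_counter("hierarchical_partitions"), 1L)
  for (i in c(1, 17, 50)) {
    single <- sclc_test(Z[, i], R)
    expect_equal(scan$sclc_p[i], single$pvalue, tolerance = 1e-12)
    expect_equal(scan$sclc_stat[i], single$statistic, tolerance = 1e-12)
  }
  # empty scan
  empty <- sclc_scan(Z[, 0, drop = FALSE], R)
  expect_equal(nrow(empty), 0)
  # per-cluster emission carries K columns of per-L p-values
  pc <- sclc_scan(Z[, 1:3, drop = FALSE], R, per_cluster = TRUE)
  expect_true(all(paste0("sclc_p_L", 1:7) %in% names(pc)))
})

test_that("sCLC null tail calibration holds for small and large K", {
  # ACAT-style combinations are conservative mid-range but tail-calibrated;
  # assert the tail rates the type-I tables actually report
  for (K in c(5, 40)) {
    R <- if (K == 40) ar1_block_R(40, 0.1) else rand_corr(5, seed = 99)
    eng <- sclc:::sclc_engine(as.matrix(R))
    Z <- t(simulate_z(0, R, 1e4, seed = 7))
    p <- eng$pfun(Z)$pvalue
    for (al in c(0.05, 0.01)) {
      se <- sqrt(al * (1 - al) / 1e4)
      expect_lt(abs(mean(p < al) - al), 4 * se)
    }
  }
})
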