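test_that("weighted chi-square tail oracle matches closed forms", {
  # chi2_2 survival: exp(-q/2)
  expect_equal(as.numeric(weighted_chisq_pvalue(c(1, 1), 2)), exp(-1),
               tolerance = 1e-8)
  # chi2_1 quantile
  expect_equal(as.numeric(weighted_chisq_pvalue(1, 3.841459)), 0.05,
               tolerance = 1e-6)
  expect_equal(as.numeric(weighted_chisq_pvalue(c(2, 0.5), 0)), 1)
  expect_error(weighted_chisq_pvalue(c(1, -1), 2), "positive")
  # scaled single chi-square
  expect_equal(as.numeric(weighted_chisq_pvalue(2.5, 7)),
               stats::pchisq(7 / 2.5, 1, lower.tail = FALSE), tolerance = 1e-8)
  # achieved error bound is reported
  expect_lt(attr(weighted_chisq_pvalue(c(3, 1, 0.5), 5), "abs_error"), 1e-8)
})

test_that("SSU reduces to the chi-square law at R = I", {
  cf <- sclc:::.ssu_coefs(diag(6))
  expect_equal(cf$a, 1); expect_equal(cf$b, 0); expect_equal(cf$d, 6)
  r <- ssu_test(c(1, 1), diag(2))
  expect_equal(r$statistic, 2)
  expect_equal(r$pvalue, exp(-1), tolerance = 1e-12)
  # negative moment-matched argument pins p at 1
  rneg <- ssu_test(c(0, 0), rand_corr(4, seed = 3))
  expect_equal(rneg$pvalue, 1)
})

test_that("SSU effective degrees of freedom shrink with high correlation", {
  Req <- matrix(0.9, 8, 8); diag(Req) <- 1
  expect_lt(sclc:::.ssu_coefs(Req)$d, 8)
  expect_lt(sclc:::.ssu_coefs(Req)$d, 2)   # strongly dominated by the top eigenvalue
})

test_that("Hom collapses antisymmetric effects and ignores the cohort size", {
  r <- hom_test(c(1, 1), diag(2))
  expect_equal(r$statistic, 2)
  expect_equal(r$pvalue, stats::pchisq(2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # opposite-sign effects are invisible
  expect_equal(hom_test(c(1, -1), diag(2))$statistic, 0)
  expect_equal(hom_test(c(1, -1), diag(2))$pvalue, 1)
  # with one cohort the sample-size weights cancel
  z <- c(0.4, -1.2, 2.2); R <- rand_corr(3, seed = 5)
  expect_equal(hom_test(z, R, n = 10)$statistic,
               hom_test(z, R, n = 1000)$statistic)
  expect_equal(hom_test(z, R, weights = rep(7, 3))$statistic,
               hom_test(z, R)$statistic, tolerance = 1e-12)
})

test_that("Wald equals its spectral form and handles the null point", {
  r <- wald_test(c(1, 1), diag(2))
  expect_equal(r$statistic, 2)
  expect_equal(r$pvalue, exp(-1), tolerance = 1e-12)
  expect_equal(wald_test(c(0, 0, 0), rand_corr(3, seed = 7))$pvalue, 1)
  for (s in 1:10) {
    K <- 3 + s %% 5
    R <- rand_corr(K, seed = 500 + s)
    z <- sclc:::with_seed(600 + s, stats::rnorm(K))
    ev <- eigen(R, symmetric = TRUE)
    spectral <- sum((t(ev$vectors) %*% z)^2 / ev$values)
    expect_equal(wald_test(z, R)$statistic, spectral, tolerance = 1e-10)
  }
})

test_that("PCFisher combines per-component p-values on the Fisher scale", {
  # R = I: the statistic is the Fisher combination of two-sided normal p's
  z <- c(1.3, -0.4, 2.1)
  r <- pcfisher_test(z, diag(3))
  fisher <- -2 * sum(log(2 * stats::pnorm(-abs(z))))
  expect_equal(r$statistic, fisher, tolerance = 1e-10)
  expect_equal(r$pvalue, stats::pchisq(fisher, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(pcfisher_test(c(0, 0), diag(2))$pvalue, 1)

  # independent spectral oracle on a random matrix
  R <- rand_corr(3, seed = 11)
  z3 <- c(0.7, -1.1, 0.2)
  ev <- eigen(R, symmetric = TRUE)
  pm <- 2 * stats::pnorm(-abs(t(ev$vectors) %*% z3) / sqrt(ev$values))
  expect_equal(pcfisher_test(z3, R)$statistic, -2 * sum(log(pm)),
               tolerance = 1e-10)
})

test_that("MAT truncation keeps the right spectral dimension", {
  # sigma = (4, 2, 1, 0.05): gamma = 30 keeps 3 (4/0.05 = 80 > 30, 4/1 <= 30)
  U <- sclc:::with_seed(13, qr.Q(qr(matrix(stats::rnorm(16), 4))))
  S <- U %*% diag(c(4, 2, 1, 0.05)) %*% t(U)
  z <- sclc:::with_seed(14, stats::rnorm(4))
  expect_equal(mat_test(z, S, 30)$detail$m, 3L)
  expect_equal(mat_test(z, S, 100)$detail$m, 4L)
  # gamma = 1 keeps the top singular value's multiplicity, never the empty set
  expect_equal(mat_test(z, S, 1)$detail$m, 1L)
  expect_equal(mat_test(z, diag(4), 1)$detail$m, 4L)   # all-ones spectrum
  # full pseudoinverse equals the Wald statistic
  R <- rand_corr(5, seed = 15)
  z5 <- sclc:::with_seed(16, stats::rnorm(5))
  expect_equal(mat_test(z5, R, 1e6)$statistic, wald_test(z5, R)$statistic,
               tolerance = 1e-10)
  expect_error(mat_test(z5, R, 0.5), "gamma")
})

test_that("aMAT collapses to min-p when all MAT tests coincide", {
  z <- c(1, 2, 0.5, 1)
  r <- amat_test(z, diag(4))
  expect_equal(r$pvalue, r$statistic, tolerance = 1e-12)
  expect_equal(unname(r$detail$m_per_gamma), rep(4L, 4))
})

test_that("aMAT p-value respects the Frechet/Bonferroni envelope", {
  R <- ar1_block_R(40, 0.1)
  set.seed(44)
  for (i in 1:15) {
    z <- stats::rnorm(40) * sample(c(0.5, 1, 2.5), 1)
    r <- amat_test(z, R)
    mp <- min(r$detail$p_per_gamma)
    expect_gte(r$pvalue, mp - 1e-12)
    expect_lte(r$pvalue, 4 * mp + 1e-12)
  }
})

test_that("all tests sit at p = 1 for Z = 0 and respect phenotype permutations", {
  R <- rand_corr(6, seed = 19)
  z0 <- rep(0, 6)
  expect_equal(hom_test(z0, R)$pvalue, 1)
  expect_equal(wald_test(z0, R)$pvalue, 1)
  expect_equal(ssu_test(z0, R)$pvalue, 1)
  expect_equal(pcfisher_test(z0, R)$pvalue, 1)
  expect_gte(amat_test(z0, R)$pvalue, 1 - 1e-9)

  z <- sclc:::with_seed(20, stats::rnorm(6))
  perm <- c(3, 6, 1, 5, 2, 4)
  Rp <- R[perm, perm]; zp <- z[perm]
  expect_equal(ssu_test(zp, Rp)$pvalue, ssu_test(z, R)$pvalue, tolerance = 1e-9)
  expect_equal(hom_test(zp, Rp)$pvalue, hom_test(z, R)$pvalue, tolerance = 1e-9)
  expect_equal(wald_test(zp, Rp)$pvalue, wald_test(z, R)$pvalue, tolerance = 1e-9)
  expect_equal(pcfisher_test(zp, Rp)$pvalue, pcfisher_test(z, R)$pvalue,
               tolerance = 1e-9)
  expect_equal(sclc_test(zp, Rp)$pvalue, sclc_test(z, R)$pvalue, tolerance = 1e-9)
})

test_that("null calibration of the competing tests at moderate alpha", {
  for (K in c(5, 40)) {
    R <- if (K == 40) ar1_block_R(40, 0.1) else rand_corr(5, seed = 23)
    rep <- type1_study(R, methods = c("hom", "wald", "amat", "pcfisher"),
                       alphas = 0.05, n_reps = 1e4, seed = 3)
    se <- sqrt(0.05 * 0.95 / 1e4)
    for (m in rownames(rep$rejections))
      expect_lt(abs(rep$rejections[m, 1] - 0.05), 4 * se)
  }
})

test_that("run_tests emits one stat/p column pair per method in order", {
  R <- rand_corr(5, seed = 29)
  Z <- sclc:::with_seed(30, matrix(stats::rnorm(5 * 8), 5, 8))
  colnames(Z) <- paste0("s", 1:8)
  res <- run_tests(Z, R, methods = c("sclc", "wald"))
  expect_identical(names(res), c("snp", "sclc_stat", "sclc_p",
                                 "wald_stat", "wald_p"))
  expect_equal(res$wald_p[3], wald_test(Z[, 3], R)$pvalue, tolerance = 1e-12)
})
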