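# Simulation study: type-I error and power of the six tests under
# multivariate-normal Z scores, the block AR(1) correlation structure, the
# four effect-size scenarios, and LDSC-structured summary-statistic
# fixtures with a known true intercept matrix.

#' Block AR(1) phenotype correlation matrix
#'
#' Block-diagonal matrix of four equal AR(1) blocks: blocks 1 and 3 have
#' entries rho^|s-k|, blocks 2 and 4 have entries (-rho)^|s-k| (an AR(1)
#' process with negative parameter; taking "-rho^|s-k|" literally would put
#' -1 on the diagonal, which is not a correlation matrix). Positive
#' definiteness is verified. The simulation default is rho = 0.1.
#'
#' @param K number of phenotypes, divisible by 4.
#' @param rho AR(1) parameter, |rho| < 1.
#' @return A `correlation_matrix`.
#' @export
#' @examples
#' ar1_block_R(8, 0.1)
ar1_block_R <- function(K, rho = 0.1) {
  if (K %% 4 != 0) stop2("K must be divisible by 4")
  if (abs(rho) >= 1) stop2("|rho| must be < 1")
  kb <- K / 4
  lag <- abs(outer(seq_len(kb), seq_len(kb), "-"))
  pos <- rho^lag
  neg <- (-rho)^lag
  R <- matrix(0, K, K)
  for (b in 1:4) {
    idx <- ((b - 1) * kb + 1):(b * kb)
    R[idx, idx] <- if (b %% 2 == 1) pos else neg
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop2("block AR(1) matrix not positive definite")  # unreachable for |rho|<1
  correlation_matrix(R, paste0("pheno", seq_len(K)))
}

#' Effect-size vector for the four simulation scenarios
#'
#' Scenario 1: a same-direction ramp beta*(1/K, 2/K, ..., 1).
#' Scenario 2: half the phenotypes unaffected, half at beta (same
#' direction). Scenario 3 (k = K/5): 2k zeros, 2k at beta, then an
#' opposite-direction ramp -(2 beta/(k+1))*(1..k). Scenario 4 (k = K/14,
#' sparse): 13k zeros then the ramp (2 beta/(k+1))*(1..k).
#'
#' @param scenario 1, 2, 3 or 4.
#' @param K number of phenotypes (scenario 2: even; 3: divisible by 5;
#'   4: divisible by 14).
#' @param beta effect-size scale.
#' @return Numeric vector of length K.
#' @export
#' @examples
#' scenario_mu(3, K = 10, beta = 1)
scenario_mu <- function(scenario, K, beta) {
  if (!scenario %in% 1:4) stop2("scenario must be 1, 2, 3 or 4")
  switch(as.character(scenario),
    "1" = beta * seq_len(K) / K,
    "2" = {
      if (K %% 2 != 0) stop2("scenario 2 requires even K")
      c(rep(0, K / 2), rep(beta, K / 2))
    },
    "3" = {
      if (K %% 5 != 0) stop2("scenario 3 requires K divisible by 5")
      k <- K / 5
      c(rep(0, 2 * k), rep(beta, 2 * k), -(2 * beta / (k + 1)) * seq_len(k))
    },
    "4" = {
      if (K %% 14 != 0) stop2("scenario 4 requires K divisible by 14")
      k <- K / 14
      c(rep(0, 13 * k), (2 * beta / (k + 1)) * seq_len(k))
    })
}

#' Synthetic "empirical-like" phenotype correlation matrix
#'
#' A stand-in for the sample correlation matrix of a large set of related
#' phenotypes (such as disease codes within one ICD chapter): phenotypes
#' fall into clusters whose within-cluster correlation varies from cluster
#' to cluster and decays with within-cluster distance (graded similarity,
#' as between disease codes of one sub-chapter), plus a weak
#' between-cluster correlation; the released matrix is the sample
#' correlation of seeded multivariate-normal draws. The defaults mirror
#' mostly-rare binary disease phenotypes scored on a cohort of hundreds of
#' thousands: pairwise correlations are predominantly weak and
#' heterogeneous, the matrix is well conditioned, no two dissimilarities
#' are exactly tied (unlike the tie-degenerate block AR(1) structure), and
#' at the default `n_samples` the sampling noise is far below the spacing
#' of the correlation values, so the hierarchical tree is determined by the
#' structure rather than by noise.
#'
#' @param K number of phenotypes (divisible by `n_clusters`).
#' @param n_clusters number of phenotype clusters.
#' @param within within-cluster correlation range; clusters get base
#'   levels evenly spaced across it.
#' @param decay per-step geometric decay of correlation inside a cluster.
#' @param between correlation across clusters.
#' @param n_samples number of normal draws the sample correlation is
#'   computed from (controls the estimation-noise level).
#' @param seed RNG seed.
#' @return A `correlation_matrix`.
#' @export
synthetic_empirical_R <- function(K = 70, n_clusters = 7,
                                  within = c(0.15, 0.5), decay = 0.9,
                                  between = 0.02, n_samples = 3e5, seed = 1) {
  if (K %% n_clusters != 0) stop2("K must be divisible by n_clusters")
  size <- K / n_clusters
  base <- seq(within[1], within[2], length.out = n_clusters)
  S0 <- matrix(between, K, K)
  lag <- abs(outer(seq_len(size), seq_len(size), "-"))
  for (b in seq_len(n_clusters)) {
    idx <- ((b - 1) * size + 1):(b * size)
    S0[idx, idx] <- base[b] * decay^lag
  }
  diag(S0) <- 1
  S0 <- normalize_and_repair(S0)    # guard PD for extreme parameter choices
  X <- simulate_z(0, S0, n_samples, seed = seed)
  normalize_and_repair(stats::cor(X), provenance = "specified")
}

#' Draw Z score vectors from N(mu, R)
#'
#' @param mu mean vector (length K).
#' @param R correlation matrix.
#' @param n_reps number of replicates.
#' @param seed optional seed.
#' @return n_reps x K matrix of Z scores.
#' @export
simulate_z <- function(mu, R, n_reps, seed = NULL) {
  R <- as.matrix(R)
  K <- nrow(R)
  if (length(mu) == 1) mu <- rep(mu, K)
  if (length(mu) != K) stop2("length(mu) must match dim(R)")
  ch <- chol_safe(R)
  with_seed(seed, {
    E <- matrix(stats::rnorm(n_reps * K), n_reps, K)
    sweep(E %*% ch, 2, mu, "+")
  })
}

new_simulation_report <- function(rejections, se, alphas, n_reps, seed,
                                  provenance, mu = NULL) {
  structure(list(rejections = rejections, se = se, alphas = alphas,
                 n_reps = n_reps, seed = seed, provenance = provenance,
                 mu = mu),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat("simulation_report: n_reps =", format(x$n_reps, big.mark = ","),
      ", seed =", x$seed, ", R:", x$provenance, "\n")
  print(signif(x$rejections, 4))
  invisible(x)
}

# shared Monte-Carlo driver: proportion of p-values below each alpha,
# generated in chunks to bound memory
.mc_study <- function(R, mu, methods, alphas, n_reps, seed,
                      linkage = "average", amat_null_draws = 1e5,
                      chunk = 25000L, R_test = NULL) {
  R <- as.matrix(R)
  K <- nrow(R)
  if (length(mu) == 1) mu <- rep(mu, K)
  # Z scores are generated under R; the tests may use a different matrix
  # (e.g. a noise-perturbed estimate), as in robustness studies
  engines <- method_engines(as.matrix(R_test %||% R), methods, linkage = linkage,
                            amat_null_draws = amat_null_draws,
                            amat_seed = (seed * 7 + 11) %% .Machine$integer.max)
  ch <- chol_safe(R)
  counts <- matrix(0, length(engines), length(alphas),
                   dimnames = list(names(engines), paste0("alpha_", alphas)))
  with_seed(seed, {
    done <- 0L
    while (done < n_reps) {
      m <- min(chunk, n_reps - done)
      Z <- crossprod(ch, matrix(stats::rnorm(K * m), K, m)) + mu
      for (nm in names(engines)) {
        p <- engines[[nm]](Z)$p
        for (a in seq_along(alphas))
          counts[nm, a] <- counts[nm, a] + sum(p < alphas[a])
      }
      done <- done + m
    }
  })
  prop <- counts / n_reps
  se <- sqrt(prop * (1 - prop) / n_reps)
  list(prop = prop, se = se)
}

#' Type-I error study
#'
#' Proportion of null replicates (mu = 0) rejected at each significance
#' level, per method, with binomial standard errors.
#'
#' @param R phenotype correlation matrix used as the null covariance.
#' @param methods subset of c("sclc", "ssu", "hom", "wald", "amat",
#'   "pcfisher").
#' @param alphas significance levels.
#' @param n_reps number of null replicates.
#' @param seed RNG seed (reports are bit-reproducible under it).
#' @param linkage linkage for sCLC.
#' @param amat_null_draws copula-estimation draws for aMAT.
#' @param R_test optional matrix used by the tests in place of R (Z scores
#'   are still generated under R), e.g. a [perturb_R()] output.
#' @return A `simulation_report`.
#' @export
type1_study <- function(R, methods = c("sclc", "ssu", "hom", "wald", "amat",
                                       "pcfisher"),
                        alphas = 1e-3, n_reps = 1e5, seed = 1,
                        linkage = "average", amat_null_draws = 1e5,
                        R_test = NULL) {
  if (n_reps < 10 / min(alphas))
    warning("n_reps < 10/min(alphas): rejection-rate estimates will be noisy",
            call. = FALSE)
  out <- .mc_study(R, 0, methods, alphas, n_reps, seed, linkage,
                   amat_null_draws, R_test = R_test)
  new_simulation_report(out$prop, out$se, alphas, n_reps, seed,
                        attr(R, "provenance") %||% "specified")
}

#' Power study
#'
#' Rejection proportion at a single significance level under an alternative
#' mean vector mu, per method.
#'
#' @param R phenotype correlation matrix.
#' @param mu effect-size vector (see [scenario_mu()]).
#' @param methods subset of the six methods.
#' @param alpha significance level (default the genome-wide 5e-8).
#' @param n_reps number of replicates.
#' @param seed RNG seed.
#' @param linkage linkage for sCLC.
#' @param amat_null_draws copula-estimation draws for aMAT.
#' @param R_test optional matrix used by the tests in place of R (Z scores
#'   are still generated under R), e.g. a [perturb_R()] output.
#' @return A `simulation_report`.
#' @export
power_study <- function(R, mu, methods = c("sclc", "ssu", "hom", "wald",
                                           "amat", "pcfisher"),
                        alpha = 5e-8, n_reps = 1e4, seed = 1,
                        linkage = "average", amat_null_draws = 1e5,
                        R_test = NULL) {
  out <- .mc_study(R, mu, methods, alpha, n_reps, seed, linkage,
                   amat_null_draws, R_test = R_test)
  new_simulation_report(out$prop, out$se, alpha, n_reps, seed,
                        attr(R, "provenance") %||% "specified", mu = mu)
}

#' LDSC-structured synthetic summary statistics
#'
#' Generates per-SNP LD scores and Z score vectors following the LD score
#' regression model: Z_j ~ N(0, R0 + l_j * genetic_cov) independently
#' across SNPs, so the regression of pairwise Z products on LD scores has
#' intercept matrix R0 (the phenotypic correlation) and slope matrix
#' genetic_cov by construction. The slope-implied heritability proxy of
#' phenotype k is genetic_cov[k,k] * M / n_samples.
#'
#' @param M number of SNPs.
#' @param K number of phenotypes.
#' @param R0 true K x K phenotype correlation matrix (the intercepts).
#' @param genetic_cov K x K PSD slope matrix; 0 (default) gives pure-noise
#'   phenotypes with heritability 0.
#' @param ldscore_law function(M) drawing M LD scores; default 1 + a
#'   gamma(shape 2, scale 20) draw, emulating the long-tailed LD score
#'   distribution of common variants.
#' @param n_samples GWAS sample size written to the N column.
#' @param seed RNG seed.
#' @return list(tables = named list of `sumstats_table`, ldscores =
#'   `ldscore_table`, true_R = R0).
#' @export
ldsc_fixture <- function(M, K, R0, genetic_cov = NULL, ldscore_law = NULL,
                         n_samples = 10000, seed = 1) {
  R0 <- as.matrix(R0)
  stopifnot(nrow(R0) == K)
  if (is.null(genetic_cov)) genetic_cov <- matrix(0, K, K)
  genetic_cov <- as.matrix(genetic_cov)
  if (is.null(ldscore_law))
    ldscore_law <- function(m) 1 + stats::rgamma(m, shape = 2, scale = 20)
  with_seed(seed, {
    l <- ldscore_law(M)
    lmax <- max(l)
    if (min(eigen(R0 + lmax * genetic_cov, symmetric = TRUE,
                  only.values = TRUE)$values) <= 0)
      stop2("R0 + l * genetic_cov not positive definite at the largest LD score")
    # Z = A'eps + sqrt(l) C'eta gives cov R0 + l * genetic_cov
    A <- chol(R0)
    Z <- crossprod(A, matrix(stats::rnorm(K * M), K, M))
    if (any(genetic_cov != 0)) {
      Cg <- chol(genetic_cov + 1e-12 * diag(K))
      H <- crossprod(Cg, matrix(stats::rnorm(K * M), K, M))
      Z <- Z + H * rep(sqrt(l), each = K)
    }
    snp <- paste0("rs", seq_len(M))
    ids <- rownames(R0) %||% paste0("pheno", seq_len(K))
    tables <- lapply(seq_len(K), function(k) {
      structure(data.frame(snp = snp, chrom = "1", pos = seq_len(M),
                           a1 = "A", a2 = "G", z = Z[k, ],
                           beta = NA_real_, se = NA_real_,
                           pvalue = NA_real_, n = n_samples,
                           stringsAsFactors = FALSE),
                class = c("sumstats_table", "data.frame"))
    })
    names(tables) <- ids
    ldscores <- structure(data.frame(snp = snp, ldscore = l,
                                     stringsAsFactors = FALSE),
                          class = c("ldscore_table", "data.frame"))
    list(tables = tables, ldscores = ldscores, true_R = R0)
  })
}

#' Write a fixture to summary-statistics and LD score files
#'
#' @param fixture output of [ldsc_fixture()].
#' @param dir output directory (created if missing).
#' @return Invisibly, a list of the written paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (id in names(fixture$tables)) {
    t <- fixture$tables[[id]]
    out <- data.frame(SNP = t$snp, CHR = t$chrom, BP = t$pos,
                      A1 = t$a1, A2 = t$a2, Z = t$z, N = t$n)
    p <- file.path(dir, paste0(id, ".sumstats"))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[id]] <- p
  }
  lp <- file.path(dir, "fixture.l2.ldscore")
  utils::write.table(data.frame(CHR = "1", SNP = fixture$ldscores$snp,
                                BP = seq_len(nrow(fixture$ldscores)),
                                L2 = fixture$ldscores$ldscore),
                     lp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$ldscores <- lp
  invisible(paths)
}
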