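# Comparison tests for multi-phenotype association from summary statistics:
# SSU, Hom, Wald, PCFisher, MAT/aMAT, plus an exact weighted-chi-square
# tail oracle (Imhof integration) used to validate the SSU approximation.
#
# All tests consume a K-vector of Z scores and the K x K phenotype
# correlation matrix R, and share the `sclc_result` contract.

# ---- exact weighted chi-square tail (Imhof) --------------------------------

#' Exact upper tail of a weighted sum of 1-df chi-squares
#'
#' P(sum w_i X_i > q) with X_i iid chi-square(1), by Imhof's numerical
#' inversion of the characteristic function, falling back to Ruben's exact
#' chi-square mixture series (all coefficients non-negative, so the
#' truncation error is bounded by the unassigned mass) when the oscillatory
#' quadrature cannot certify the requested accuracy. Serves as the exact
#' oracle for the moment-matched SSU null approximation.
#'
#' @param weights positive weights.
#' @param q evaluation point.
#' @param abs_tol target absolute error (default 1e-8).
#' @return The upper-tail probability in [0, 1]; attribute `abs_error`
#'   carries the achieved error bound, attribute `method` the route taken.
#' @export
#' @examples
#' weighted_chisq_pvalue(c(1, 1), 2)   # exp(-1)
weighted_chisq_pvalue <- function(weights, q, abs_tol = 1e-8) {
  if (any(weights <= 0)) stop2("weights must be positive")
  if (q <= 0) return(structure(1, abs_error = 0, method = "exact"))
  theta <- function(u)
    0.5 * colSums(atan(outer(weights, u))) - 0.5 * q * u
  rho <- function(u)
    exp(0.25 * colSums(log1p(outer(weights^2, u^2))))
  integrand <- function(u) {
    out <- sin(theta(u)) / (u * rho(u))
    out[u == 0] <- 0.5 * (sum(weights) - q)   # limit u -> 0
    out
  }
  int <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-12, abs.tol = abs_tol / 10,
                     subdivisions = 2000L, stop.on.error = FALSE),
    error = function(e) NULL)
  if (!is.null(int) && int$message == "OK" && int$abs.error / pi <= abs_tol) {
    p <- min(max(0.5 + int$value / pi, 0), 1)
    return(structure(p, abs_error = int$abs.error / pi, method = "imhof"))
  }
  .ruben_upper(weights, q, abs_tol)
}

# Ruben (1962) series: P(sum w_i chi2_1 > q) = sum_n c_n P(chi2_{K+2n} > q/beta)
# with beta = min(w); the c_n are a probability mass, so the truncation
# error is bounded by 1 - sum(c_n).
.ruben_upper <- function(weights, q, abs_tol = 1e-8, max_terms = 200000L) {
  K <- length(weights)
  beta <- min(weights)
  r <- 1 - beta / weights                    # all in [0, 1)
  c0 <- exp(0.5 * sum(log(beta / weights)))
  total_c <- c0
  p <- c0 * stats::pchisq(q / beta, df = K, lower.tail = FALSE)
  cs <- c0
  g <- numeric(0)
  r_pow <- r
  n <- 0L
  while (1 - total_c > abs_tol / 2 && n < max_terms) {
    n <- n + 1L
    g[n] <- sum(r_pow); r_pow <- r_pow * r
    cn <- sum(g[1:n] * cs[n:1]) / (2 * n)
    cs[n + 1L] <- cn
    total_c <- total_c + cn
    p <- p + cn * stats::pchisq(q / beta, df = K + 2 * n, lower.tail = FALSE)
  }
  if (1 - total_c > abs_tol / 2)
    stop2("weighted chi-square tail did not converge (achieved error bound ",
          signif(1 - total_c, 3), "); weight ratio too extreme")
  structure(min(max(p, 0), 1), abs_error = 1 - total_c, method = "ruben")
}

# ---- SSU -------------------------------------------------------------------

# moment-matched a*chi2_d + b null approximation from the eigenvalues of R
.ssu_coefs <- function(R) {
  ci <- eigen(as.matrix(R), symmetric = TRUE, only.values = TRUE)$values
  s1 <- sum(ci); s2 <- sum(ci^2); s3 <- sum(ci^3)
  list(a = s3 / s2, b = s1 - s2^2 / s3, d = s2^3 / s3^2)
}

.engine_ssu <- function(R) {
  cf <- .ssu_coefs(R)
  function(Zmat) {
    Tv <- .colSums(Zmat^2, nrow(Zmat), ncol(Zmat))
    x <- (Tv - cf$b) / cf$a
    p <- stats::pchisq(x, df = cf$d, lower.tail = FALSE)
    p[x < 0] <- 1
    list(stat = Tv, p = p)
  }
}

#' SSU test (sum of squared Z scores)
#'
#' T = Z'Z, with the null -- a mixture of chi-squares weighted by the
#' eigenvalues c_i of R -- approximated by a*chi2_d + b with
#' a = sum(c^3)/sum(c^2), b = sum(c) - sum(c^2)^2/sum(c^3),
#' d = sum(c^2)^3/sum(c^3)^2. The effective degrees of freedom d can fall
#' well below K for highly correlated phenotypes.
#'
#' @param z Z score vector of length K.
#' @param R phenotype correlation matrix.
#' @return An `sclc_result` (detail: a, b, d).
#' @export
ssu_test <- function(z, R) {
  cf <- .ssu_coefs(R)
  out <- .engine_ssu(R)(matrix(z, ncol = 1))
  new_test_result("SSU", out$stat, out$p, detail = cf)
}

# ---- Hom -------------------------------------------------------------------

.engine_hom <- function(R, weights = NULL) {
  K <- nrow(as.matrix(R))
  vinv_e <- if (is.null(weights)) rep(1, K) else 1 / weights
  u <- solve(as.matrix(R), vinv_e)        # R^{-1} V^{-1} e
  denom <- sum(vinv_e * u)                # e' V^{-1} R^{-1} V^{-1} e
  function(Zmat) {
    s <- drop(crossprod(u, Zmat))
    Tv <- s^2 / denom
    list(stat = Tv, p = stats::pchisq(Tv, df = 1, lower.tail = FALSE))
  }
}

#' Hom test (homogeneous-effect linear combination)
#'
#' The optimally weighted single linear combination of Z scores under a
#' homogeneous-effect alternative:
#' S = (e'(RV)^{-1}Z)^2 / (e'(VRV)^{-1}e) ~ chi-square(1), with V a diagonal
#' weight matrix. For a single cohort (J = 1, the setting evaluated here)
#' the sample-size weights cancel and S = (e'R^{-1}Z)^2 / (e'R^{-1}e).
#' Effects of opposite signs cancel inside the combination, which is why
#' Hom loses essentially all power under sign-heterogeneous alternatives.
#'
#' @param z Z score vector of length K.
#' @param R phenotype correlation matrix.
#' @param n sample size(s); with one cohort the statistic does not depend
#'   on them (kept for interface compatibility).
#' @param weights optional diagonal of V (e.g. sqrt of per-cohort sample
#'   sizes for J > 1 stacked statistics); default all-ones.
#' @return An `sclc_result`.
#' @export
hom_test <- function(z, R, n = NULL, weights = NULL) {
  out <- .engine_hom(R, weights)(matrix(z, ncol = 1))
  new_test_result("Hom", out$stat, out$p, detail = list(df = 1))
}

# ---- Wald ------------------------------------------------------------------

.engine_wald <- function(R) {
  ch <- chol_safe(as.matrix(R))
  K <- nrow(as.matrix(R))
  function(Zmat) {
    y <- backsolve(ch, Zmat, transpose = TRUE)
    Tv <- .colSums(y^2, K, ncol(Zmat))
    list(stat = Tv, p = stats::pchisq(Tv, df = K, lower.tail = FALSE))
  }
}

#' Wald test
#'
#' T = Z' R^{-1} Z ~ chi-square(K); equivalently the sum over principal
#' components of PC_m^2 / lambda_m.
#'
#' @param z Z score vector of length K.
#' @param R phenotype correlation matrix (invertible).
#' @return An `sclc_result`.
#' @export
wald_test <- function(z, R) {
  out <- .engine_wald(R)(matrix(z, ncol = 1))
  new_test_result("Wald", out$stat, out$p,
                  detail = list(df = nrow(as.matrix(R))))
}

# ---- PCFisher --------------------------------------------------------------

.engine_pcfisher <- function(R) {
  ev <- eigen(as.matrix(R), symmetric = TRUE)
  if (any(ev$values <= 0)) stop2("PCFisher requires positive eigenvalues")
  K <- length(ev$values)
  Ut <- t(ev$vectors)
  inv_sd <- 1 / sqrt(ev$values)
  function(Zmat) {
    xs <- (Ut %*% Zmat) * inv_sd         # standardised PCs, N(0,1) under null
    logp <- log(2) + stats::pnorm(-abs(xs), log.p = TRUE)  # two-sided, log scale
    Tv <- -2 * .colSums(logp, K, ncol(Zmat))
    list(stat = Tv, p = stats::pchisq(Tv, df = 2 * K, lower.tail = FALSE))
  }
}

#' PCFisher test
#'
#' Fisher combination of the p-values of all K independent principal
#' components of R: PC_m = u_m'Z ~ N(0, lambda_m) under the null, p_m the
#' two-sided normal p-value of PC_m / sqrt(lambda_m), and
#' -2 sum log p_m ~ chi-square(2K). Weights the low-variance components
#' heavily, which favours effects orthogonal to the leading PCs.
#'
#' @param z Z score vector of length K.
#' @param R phenotype correlation matrix with positive eigenvalues.
#' @return An `sclc_result`.
#' @export
pcfisher_test <- function(z, R) {
  out <- .engine_pcfisher(R)(matrix(z, ncol = 1))
  new_test_result("PCFisher", out$stat, out$p,
                  detail = list(df = 2 * nrow(as.matrix(R))))
}

# ---- MAT / aMAT ------------------------------------------------------------

# number of leading singular values kept at truncation ratio gamma:
# the largest m with sigma_1 / sigma_m <= gamma (<=, so gamma = 1 keeps the
# top singular value's multiplicity rather than nothing)
.mat_m <- function(sigma, gamma) {
  m <- max(which(sigma[1] / sigma <= gamma + 1e-12))
  max(m, 1L)
}

.engine_mat_all <- function(R, gammas) {
  ev <- eigen(as.matrix(R), symmetric = TRUE)
  sigma <- pmax(ev$values, 0)
  Ut <- t(ev$vectors)
  ms <- vapply(gammas, function(g) .mat_m(sigma, g), integer(1))
  inv_sd <- 1 / sqrt(sigma[seq_len(max(ms))])
  list(ms = ms, sigma = sigma,
       pfun = function(Zmat) {
         xs <- (Ut[seq_len(max(ms)), , drop = FALSE] %*% Zmat) * inv_sd
         cums <- apply(xs^2, 2, cumsum)
         if (max(ms) == 1) cums <- matrix(cums, nrow = 1)
         stats <- cums[ms, , drop = FALSE]         # one row per gamma
         ps <- stats
         for (g in seq_along(ms))
           ps[g, ] <- stats::pchisq(stats[g, ], df = ms[g], lower.tail = FALSE)
         list(stat = stats, p = ps)
       })
}

#' MAT test with a fixed truncation ratio
#'
#' T = Z' R+_gamma Z, where R+_gamma is the pseudoinverse of R truncated to
#' the m leading singular values with sigma_1/sigma_m <= gamma. Under the
#' null T is exactly chi-square with m degrees of freedom (the truncated
#' pseudoinverse projects onto the kept m-dimensional eigenspace).
#'
#' @param z Z score vector of length K.
#' @param R phenotype correlation matrix.
#' @param gamma truncation ratio, >= 1.
#' @return An `sclc_result` (detail: m, sigma).
#' @export
mat_test <- function(z, R, gamma) {
  if (gamma < 1) stop2("gamma must be >= 1")
  eng <- .engine_mat_all(R, gamma)
  out <- eng$pfun(matrix(z, ncol = 1))
  new_test_result(paste0("MAT(", gamma, ")"), drop(out$stat), drop(out$p),
                  detail = list(m = eng$ms[1], sigma = eng$sigma))
}

# ---- Gaussian-copula tail for the minimum of dependent p-values ------------

# Genz-style sequential quasi-Monte Carlo for one term of the disjoint
# decomposition P(Y_1 >= b, Y_2 < b, ..., Y_d < b), Y ~ N(0, C). The tail
# coordinate comes first so its (possibly tiny) probability factors out and
# the QMC error stays relative to the term's magnitude.
.orthant_term <- function(b, C, n_pts = 512L, n_shifts = 8L) {
  d <- nrow(C)
  f1 <- stats::pnorm(b, lower.tail = FALSE)
  if (d == 1) return(f1)
  Lc <- t(chol(C))
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47)
  w0 <- outer(seq_len(n_pts), sqrt(primes[seq_len(d - 1)]))
  shifts <- outer(seq_len(n_shifts) * exp(1), sqrt(primes[15 - seq_len(d - 1)]))
  est <- numeric(n_shifts)
  for (s in seq_len(n_shifts)) {
    w <- (w0 + matrix(shifts[s, ], n_pts, d - 1, byrow = TRUE)) %% 1
    # coordinate 1 on [b, Inf): y1 from the upper tail, computed in the
    # lower-tail parametrisation to keep precision when f1 is tiny
    y <- matrix(0, n_pts, d)
    y[, 1] <- -stats::qnorm(pmax((1 - w[, 1]) * f1, 5e-324))
    f <- rep(f1, n_pts)
    for (i in 2:d) {
      u <- (b - y[, seq_len(i - 1), drop = FALSE] %*% Lc[i, seq_len(i - 1)]) / Lc[i, i]
      ei <- stats::pnorm(u)
      f <- f * ei
      if (i < d)
        y[, i] <- stats::qnorm(pmin(pmax(w[, i] * ei, 5e-324), 1 - 1e-16))
    }
    est[s] <- mean(f)
  }
  mean(est)
}

# P(min_g p_g <= t) when (p_1..p_G) are uniform with Gaussian copula C:
# disjoint decomposition over which component is the first to cross.
.minp_tail <- function(t, C) {
  G <- nrow(C)
  if (t <= 0) return(0)
  if (t >= 1) return(1)
  b <- stats::qnorm(t, lower.tail = FALSE)
  total <- 0
  for (i in seq_len(G)) {
    idx <- c(i, seq_len(i - 1))
    total <- total + .orthant_term(b, C[idx, idx, drop = FALSE])
  }
  min(max(total, t), min(G * t, 1))      # Frechet / Bonferroni envelope
}

# Correlation of the probit-transformed MAT p-values under the null,
# estimated once per R from seeded chi-square partial-sum simulations.
.amat_copula <- function(ms_unique, null_draws, seed) {
  G <- length(ms_unique)
  with_seed(seed, {
    Y <- matrix(0, null_draws, G)
    acc <- stats::rchisq(null_draws, df = ms_unique[1])
    Y[, 1] <- stats::qnorm(stats::pchisq(acc, ms_unique[1], lower.tail = FALSE),
                           lower.tail = FALSE)
    for (g in seq_len(G - 1) + 1) {
      acc <- acc + stats::rchisq(null_draws, df = ms_unique[g] - ms_unique[g - 1])
      Y[, g] <- stats::qnorm(stats::pchisq(acc, ms_unique[g], lower.tail = FALSE),
                             lower.tail = FALSE)
    }
    C <- stats::cor(Y)
    # guard against a (numerically) non-PD estimate
    ev <- eigen(C, symmetric = TRUE)
    if (min(ev$values) < 1e-10) {
      lam <- pmax(ev$values, 1e-10)
      C <- ev$vectors %*% (lam * t(ev$vectors))
      s <- 1 / sqrt(diag(C)); C <- C * tcrossprod(s); diag(C) <- 1
    }
    C
  })
}

.engine_amat <- function(R, gammas = c(1, 10, 30, 50), null_draws = 1e5,
                         seed = 20230228, grid_pts = 80L) {
  mats <- .engine_mat_all(R, gammas)
  uniq <- sort(unique(mats$ms))
  G <- length(uniq)
  if (G > 1) {
    C <- .amat_copula(uniq, null_draws, seed)
    # precompute P(min p <= t) on a log-spaced grid; interpolate in log-log.
    # log f is essentially linear in log t deep in the tail (f ~ G t), so the
    # deep-tail knots can be sparse, but the bend near moderate t needs dense
    # coverage
    lt <- c(seq(log(1e-320), log(1e-5), length.out = grid_pts %/% 3),
            seq(log(2e-5), log(0.99), length.out = grid_pts))
    lf <- vapply(lt, function(x) log(.minp_tail(exp(x), C)), numeric(1))
    interp <- stats::splinefun(lt, lf, method = "hyman")
    tailfun <- function(t) {
      out <- exp(interp(log(pmin(pmax(t, 1e-320), 0.99))))
      out[t >= 0.99] <- vapply(t[t >= 0.99], .minp_tail, numeric(1), C = C)
      pmin(pmax(out, t), pmin(G * t, 1))
    }
  } else {
    C <- matrix(1, 1, 1)
    tailfun <- identity
  }
  list(ms = mats$ms, ms_unique = uniq, copula = C,
       pfun = function(Zmat) {
         mp <- mats$pfun(Zmat)
         keep <- match(uniq, mats$ms)
         minp <- do.call(pmin, lapply(keep, function(g) mp$p[g, ]))
         list(stat = minp, p = tailfun(minp), per_gamma = mp$p)
       })
}

#' aMAT: adaptive MAT over a grid of truncation ratios
#'
#' Computes the MAT p-value for every gamma in `gammas`, takes their minimum
#' as the adaptive statistic, and converts it to a p-value through a
#' Gaussian copula: the correlation among the probit-transformed MAT
#' p-values is estimated once per R from seeded null simulations, and the
#' minimum's tail probability under that multivariate normal is evaluated
#' by a quasi-Monte Carlo routine with a tail-stable decomposition. MAT
#' tests made identical by equal truncation dimensions collapse before the
#' copula step, so the perfectly dependent limit returns min p exactly.
#'
#' @param z Z score vector of length K.
#' @param R phenotype correlation matrix.
#' @param gammas truncation ratios (default the standard grid 1, 10, 30, 50).
#' @param null_draws null simulations for the copula correlation estimate.
#' @param seed seed for the copula estimate.
#' @return An `sclc_result` (statistic = min p; detail: per-gamma p-values,
#'   truncation dimensions, copula correlation).
#' @export
amat_test <- function(z, R, gammas = c(1, 10, 30, 50), null_draws = 1e5,
                      seed = 20230228) {
  if (length(gammas) == 0) stop2("gammas must be non-empty")
  eng <- .engine_amat(R, gammas, null_draws, seed)
  out <- eng$pfun(matrix(z, ncol = 1))
  new_test_result("aMAT", out$stat, out$p,
                  detail = list(p_per_gamma = drop(out$per_gamma),
                                gammas = gammas, m_per_gamma = eng$ms,
                                copula = eng$copula))
}

# ---- batch engines shared with the simulation module -----------------------

# named list of vectorised p-value engines for a fixed R; each element is a
# function(Zmat) returning list(stat, p)
method_engines <- function(R, methods = c("sclc", "ssu", "hom", "wald",
                                          "amat", "pcfisher"),
                           linkage = "average",
                           amat_gammas = c(1, 10, 30, 50),
                           amat_null_draws = 1e5, amat_seed = 20230228) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  for (m in methods) {
    out[[m]] <- switch(m,
      sclc = local({
        eng <- sclc_engine(R, linkage = linkage)
        function(Zmat) {
          r <- eng$pfun(Zmat)
          list(stat = r$statistic, p = r$pvalue)
        }
      }),
      ssu = .engine_ssu(R),
      hom = .engine_hom(R),
      wald = .engine_wald(R),
      pcfisher = .engine_pcfisher(R),
      amat = local({
        eng <- .engine_amat(R, amat_gammas, amat_null_draws, amat_seed)
        function(Zmat) {
          r <- eng$pfun(Zmat)
          list(stat = r$stat, p = r$p)
        }
      }))
  }
  out
}

#' Run a set of association tests across a Z score matrix
#'
#' Applies any subset of the six tests to every SNP of a Z matrix, with all
#' R-dependent factors computed once.
#'
#' @param z a `z_matrix` or plain K x M matrix.
#' @param R phenotype correlation matrix.
#' @param methods subset of c("sclc", "ssu", "hom", "wald", "amat",
#'   "pcfisher").
#' @param linkage linkage for the sCLC clustering.
#' @param amat_null_draws,amat_seed copula-estimation controls for aMAT.
#' @return A data.frame: `snp` plus a `<method>_stat`, `<method>_p` column
#'   pair per method, in the order requested.
#' @export
run_tests <- function(z, R, methods = c("sclc", "ssu", "hom", "wald",
                                        "amat", "pcfisher"),
                      linkage = "average",
                      amat_null_draws = 1e5, amat_seed = 20230228) {
  Zmat <- if (inherits(z, "z_matrix")) z$z else as.matrix(z)
  snps <- colnames(Zmat) %||% as.character(seq_len(ncol(Zmat)))
  engines <- method_engines(R, methods, linkage = linkage,
                            amat_null_draws = amat_null_draws,
                            amat_seed = amat_seed)
  res <- data.frame(snp = snps, stringsAsFactors = FALSE)
  for (m in names(engines)) {
    r <- engines[[m]](Zmat)
    res[[paste0(m, "_stat")]] <- drop(r$stat)
    res[[paste0(m, "_p")]] <- drop(r$p)
  }
  res
}
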