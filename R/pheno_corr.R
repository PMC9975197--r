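# Phenotype correlation matrix from LD score regression intercepts.
#
# For a pair of phenotypes s, k the expected product of per-SNP Z scores is
#   E(Z_sj Z_kj) = G_g * l_j + rho_sk,
# where l_j is SNP j's LD score, the slope G_g carries the genetic
# covariance and the intercept rho_sk is the phenotypic correlation
# (including confounding-induced correlation such as sample overlap).
# Regressing the products on the LD scores across all SNPs and keeping the
# intercept therefore estimates rho_sk; the univariate regression of Z^2 on
# l_j (s == k) gives the diagonal.

#' Construct a phenotype correlation matrix object
#'
#' @param values K x K symmetric numeric matrix with unit diagonal.
#' @param phenotype_ids optional phenotype names (defaults to dimnames).
#' @param provenance one of "specified", "ldsc", "perturbed".
#' @return The matrix with class `correlation_matrix` and a `provenance`
#'   attribute.
#' @export
correlation_matrix <- function(values,
                               phenotype_ids = rownames(values),
                               provenance = c("specified", "ldsc", "perturbed")) {
  provenance <- match.arg(provenance)
  values <- check_symmetric(values, tol = 1e-12, what = "correlation matrix")
  if (max(abs(diag(values) - 1)) > 1e-8)
    stop2("correlation matrix must have unit diagonal")
  if (is.null(phenotype_ids)) phenotype_ids <- paste0("pheno", seq_len(nrow(values)))
  dimnames(values) <- list(phenotype_ids, phenotype_ids)
  structure(values, provenance = provenance,
            class = c("correlation_matrix", "matrix", "array"))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("correlation_matrix (", nrow(x), " phenotypes, provenance: ",
      attr(x, "provenance") %||% "specified", ")\n", sep = "")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' LD score regression for one phenotype pair
#'
#' Ordinary least squares of per-SNP Z score products on LD scores with an
#' intercept. The intercept estimates the phenotypic correlation (or, on the
#' diagonal, 1 plus confounding inflation); the slope carries the genetic
#' (co)variance signal.
#'
#' @param products numeric vector of Z score products (Z_s * Z_k per SNP).
#' @param ldscores numeric vector of LD scores, same length, not all equal.
#' @param weights optional regression weights (inverse-variance style);
#'   default unweighted.
#' @param max_zsq optional cap: SNPs whose product exceeds this value are
#'   excluded before the fit (default off).
#' @return A list of class `ldsc_fit`: `intercept`, `slope`, `n_snps`.
#' @export
ldsc_regression <- function(products, ldscores, weights = NULL, max_zsq = NULL) {
  if (length(products) != length(ldscores)) stop2("length mismatch")
  if (!is.null(max_zsq)) {
    keep <- abs(products) <= max_zsq
    products <- products[keep]; ldscores <- ldscores[keep]
    if (!is.null(weights)) weights <- weights[keep]
  }
  M <- length(products)
  if (M < 3) stop2("need at least 3 SNPs for LD score regression")
  if (stats::sd(ldscores) == 0)
    stop2("degenerate design: constant LD scores, slope unidentifiable")
  if (is.null(weights)) {
    fit <- stats::lm.fit(cbind(1, ldscores), products)
  } else {
    fit <- stats::lm.wfit(cbind(1, ldscores), products, w = weights)
  }
  structure(list(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 n_snps = M),
            class = "ldsc_fit")
}

#' Rescale and repair a raw matrix into a valid correlation matrix
#'
#' Symmetrises (average of the matrix and its transpose, tolerating only
#' round-off asymmetry), rescales to unit diagonal by D^(-1/2) raw D^(-1/2),
#' and -- if the smallest eigenvalue falls below `psd_floor` -- clips the
#' spectrum at `psd_floor` and re-normalises to unit diagonal. Idempotent.
#'
#' @param raw K x K matrix with positive diagonal.
#' @param psd_floor smallest admissible eigenvalue (default 1e-8).
#' @param provenance passed to [correlation_matrix()].
#' @return A `correlation_matrix`.
#' @export
normalize_and_repair <- function(raw, psd_floor = 1e-8,
                                 provenance = "specified") {
  raw <- check_symmetric(raw, tol = 1e-8, what = "input matrix")
  d <- diag(raw)
  if (any(d <= 0)) stop2("non-positive diagonal entry; cannot normalise")
  s <- 1 / sqrt(d)
  R <- raw * tcrossprod(s)
  diag(R) <- 1
  # re-normalising after a clip can push the smallest eigenvalue slightly
  # back under the floor, so iterate; converges in a handful of passes
  for (i in 1:50) {
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) >= psd_floor) break
    lam <- pmax(ev$values, psd_floor)
    R <- ev$vectors %*% (lam * t(ev$vectors))
    R <- (R + t(R)) / 2
    s <- 1 / sqrt(diag(R))
    R <- R * tcrossprod(s)
    diag(R) <- 1
  }
  correlation_matrix(R, rownames(raw), provenance = provenance)
}

#' Estimate the phenotype correlation matrix from Z scores and LD scores
#'
#' Runs the univariate LD score regression (Z^2 on l) for every phenotype
#' and the bivariate regression (Z_s Z_k on l) for every pair. Univariate
#' intercepts estimate the diagonal, bivariate intercepts the off-diagonal
#' entries. Phenotypes whose slope-implied heritability falls outside
#' `h2_bounds` are excluded before assembly ("out of bounds"); the assembled
#' matrix is passed through [normalize_and_repair()].
#'
#' The heritability proxy is `slope * M / n_mean` when a mean sample size is
#' available for the phenotype and the raw slope otherwise.
#'
#' @param z a `z_matrix` from [align_z_matrix()], aligned to LD scores, or a
#'   plain K x M matrix (then `ldscores` must be supplied).
#' @param ldscores numeric vector of LD scores per SNP; defaults to the
#'   scores carried by `z`.
#' @param n_mean optional per-phenotype mean sample sizes (defaults to those
#'   carried by `z`).
#' @param h2_bounds admissible heritability interval (default `c(0, 1)`,
#'   the parameter space).
#' @param h2_margin sampling-noise allowance beyond `h2_bounds` (default
#'   0.05): a point estimate may legitimately fall slightly outside the
#'   parameter space, so only estimates beyond the margin count as out of
#'   bounds.
#' @param psd_floor passed to [normalize_and_repair()].
#' @param weights,max_zsq passed to [ldsc_regression()].
#' @return A list: `R` (`correlation_matrix`, provenance "ldsc"),
#'   `excluded` (phenotype ids failing the heritability filter),
#'   `intercepts_raw` (K x K matrix of raw intercepts, diagonal included),
#'   `h2` (per-phenotype heritability proxies).
#' @export
estimate_R <- function(z, ldscores = NULL, n_mean = NULL,
                       h2_bounds = c(0, 1), h2_margin = 0.05,
                       psd_floor = 1e-8, weights = NULL, max_zsq = NULL) {
  if (inherits(z, "z_matrix")) {
    Z <- z$z
    ldscores <- ldscores %||% z$ldscores
    n_mean <- n_mean %||% z$n_mean
  } else {
    Z <- as.matrix(z)
  }
  if (is.null(ldscores)) stop2("LD scores required to estimate R")
  K <- nrow(Z); M <- ncol(Z)
  if (K < 2) stop2("need at least 2 phenotypes")
  if (length(ldscores) != M) stop2("LD scores not aligned to Z matrix")
  ids <- rownames(Z) %||% paste0("pheno", seq_len(K))
  if (is.null(n_mean)) n_mean <- rep(NA_real_, K)

  # univariate fits: heritability filter + raw diagonal intercepts
  h2 <- numeric(K); diag_int <- numeric(K)
  for (k in seq_len(K)) {
    fit <- ldsc_regression(Z[k, ]^2, ldscores, weights = weights,
                           max_zsq = max_zsq)
    diag_int[k] <- fit$intercept
    h2[k] <- if (is.finite(n_mean[k])) fit$slope * M / n_mean[k] else fit$slope
  }
  names(h2) <- ids
  bad <- h2 < h2_bounds[1] - h2_margin | h2 > h2_bounds[2] + h2_margin
  # a non-positive univariate intercept cannot scale a correlation matrix;
  # treat such phenotypes as pathological and exclude them too
  if (any(diag_int <= 0 & !bad)) {
    warning("non-positive univariate LDSC intercept for ",
            paste(ids[diag_int <= 0 & !bad], collapse = ", "),
            "; phenotype(s) excluded", call. = FALSE)
    bad <- bad | diag_int <= 0
  }
  excluded <- ids[bad]
  keep <- which(!bad)
  if (length(keep) < 2)
    stop2("fewer than 2 phenotypes survive the heritability-bounds filter")

  raw <- matrix(NA_real_, K, K, dimnames = list(ids, ids))
  diag(raw) <- diag_int
  for (s in keep) for (k in keep) if (s < k) {
    fit <- ldsc_regression(Z[s, ] * Z[k, ], ldscores, weights = weights,
                           max_zsq = max_zsq)
    raw[s, k] <- raw[k, s] <- fit$intercept
  }
  intercepts_raw <- raw
  sub <- raw[keep, keep, drop = FALSE]
  # the released matrix is a correlation matrix: raw univariate intercepts
  # (1 + confounding inflation) only set the scale of the diagonal
  R <- normalize_and_repair(sub, psd_floor = psd_floor, provenance = "ldsc")
  list(R = R, excluded = excluded, intercepts_raw = intercepts_raw, h2 = h2)
}

#' Perturb a correlation matrix with white noise
#'
#' Adds independent N(0, delta) noise to every strict upper-triangle entry,
#' mirrors to the lower triangle, keeps the unit diagonal, and repairs the
#' result into a valid correlation matrix. Emulates estimation error of an
#' LDSC-estimated matrix in robustness studies.
#'
#' @param R a `correlation_matrix` (or plain symmetric matrix).
#' @param delta noise variance, >= 0; `delta = 0` returns the input.
#' @param seed optional seed for reproducibility.
#' @return A `correlation_matrix` with provenance "perturbed".
#' @export
perturb_R <- function(R, delta, seed = NULL) {
  if (delta < 0) stop2("delta must be >= 0")
  R <- as.matrix(R)
  if (delta == 0)
    return(correlation_matrix(R, rownames(R), provenance = "perturbed"))
  K <- nrow(R)
  up <- upper.tri(R)
  noise <- with_seed(seed, stats::rnorm(sum(up), mean = 0, sd = sqrt(delta)))
  out <- R
  out[up] <- out[up] + noise
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- 1
  normalize_and_repair(out, provenance = "perturbed")
}

#' Write / read a correlation matrix as delimited text
#'
#' Square matrix with a header row and a leading column of phenotype ids.
#' @param R a `correlation_matrix`.
#' @param path file path.
#' @return `write_correlation` returns the path invisibly; `read_correlation`
#'   a `correlation_matrix`.
#' @export
write_correlation <- function(R, path) {
  df <- data.frame(phenotype = rownames(R), as.data.frame(unclass(R)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation
#' @export
read_correlation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  m <- (m + t(m)) / 2   # absorb round-off from text serialisation
  correlation_matrix(m, ids)
}
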