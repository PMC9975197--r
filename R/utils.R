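# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so library calls never disturb
#' user-level reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Cholesky factor with a shrinkage fallback
#'
#' Returns the upper-triangular factor of `R`; if the factorization fails
#' (numerically singular input, e.g. duplicated phenotypes) the matrix is
#' shrunk towards the identity, (1-eps) R + eps I, and a warning is issued.
#' A genome scan must not crash on a near-singular correlation matrix.
#' @noRd
chol_safe <- function(R, eps = 1e-6) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    warning("correlation matrix numerically singular; applying shrinkage (1-",
            eps, ")*R + ", eps, "*I", call. = FALSE)
    K <- nrow(R)
    ch <- chol((1 - eps) * R + eps * diag(K))
  }
  ch
}

#' log(sum(exp(x))) without overflow
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop2 <- function(...) stop(..., call. = FALSE)

#' Check a square numeric matrix is (numerically) symmetric
#' @noRd
check_symmetric <- function(x, tol = 1e-8, what = "matrix") {
  if (!is.matrix(x) || nrow(x) != ncol(x) || !is.numeric(x))
    stop2(what, " must be a square numeric matrix")
  if (max(abs(x - t(x))) > tol)
    stop2(what, " is not symmetric (max |x - t(x)| > ", tol, ")")
  (x + t(x)) / 2
}
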