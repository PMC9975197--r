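# The sCLC test.
#
# Phenotypes are clustered hierarchically on the dissimilarity 1 - R. For
# every number of clusters L = 1..K the cluster membership matrix B (K x L)
# defines the linear combinations W = B' R^{-1}, and the quadratic form
#   T_CLC^L = (W Z)' (W R W')^{-1} (W Z)
# is chi-square with L degrees of freedom under the null. The K p-values
# p_L are aggregated with the Cauchy combination
#   T_sCLC = (1/K) sum_L tan((0.5 - p_L) pi),
# whose null tail is approximately standard Cauchy, so the combined p-value
# is 0.5 - arctan(T_sCLC)/pi.

new_test_result <- function(method, statistic, pvalue, detail = list()) {
  structure(list(method = method, statistic = statistic,
                 pvalue = pvalue, detail = detail),
            class = "sclc_result")
}

#' @export
print.sclc_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %s\n", x$method, x$statistic,
              .format_p(x$pvalue)))
  invisible(x)
}

# call counter used to assert that expensive set-up (clustering) is not
# recomputed inside a scan
.sclc_counters <- new.env(parent = emptyenv())
.count <- function(what) {
  cur <- get0(what, envir = .sclc_counters, ifnotfound = 0L)
  assign(what, cur + 1L, envir = .sclc_counters)
  invisible(NULL)
}
reset_counters <- function() {
  rm(list = ls(.sclc_counters), envir = .sclc_counters)
  invisible(NULL)
}
get_counter <- function(what) get0(what, envir = .sclc_counters, ifnotfound = 0L)

#' Nested hierarchical partitions of phenotypes
#'
#' Agglomerative clustering of the K phenotypes on the dissimilarity
#' D = 1 - R (entrywise, zero diagonal; negative correlations give
#' dissimilarities in (1, 2], used as-is). Starting from singletons, the
#' pair of clusters at the smallest linkage distance is merged until one
#' cluster remains, yielding one nested partition for every cluster count
#' L = 1..K. Among equal-distance merges the pair with the
#' lexicographically smallest (minimum member index, second minimum member
#' index) is chosen, making the tree deterministic across platforms.
#'
#' @param R a `correlation_matrix` or plain symmetric matrix.
#' @param linkage "average" (UPGMA, default), "single" or "complete".
#' @return An object of class `clc_partitions`: list with `K`, `linkage`,
#'   `assignments` (for each L, an integer vector of cluster labels 1..L,
#'   clusters numbered by smallest member index) and `heights` (merge
#'   distances).
#' @export
hierarchical_partitions <- function(R, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  .count("hierarchical_partitions")
  R <- as.matrix(R)
  K <- nrow(R)
  assignments <- vector("list", K)
  assignments[[K]] <- seq_len(K)
  if (K == 1) {
    return(structure(list(K = 1L, linkage = linkage,
                          assignments = assignments, heights = numeric()),
                     class = "clc_partitions"))
  }
  D <- 1 - R
  diag(D) <- 0

  members <- as.list(seq_len(K))      # active clusters, each a member set
  mins <- seq_len(K)                  # smallest member index per cluster
  d <- D                              # linkage distances between active clusters
  heights <- numeric(K - 1)
  current <- seq_len(K)               # cluster slot per phenotype

  for (step in seq_len(K - 1)) {
    n <- length(members)
    dm <- d; dm[!upper.tri(dm)] <- Inf
    best <- min(dm)
    cand <- which(dm <= best + 1e-12, arr.ind = TRUE)
    # lexicographic tie-break on (min member index, other min member index)
    key1 <- pmin(mins[cand[, 1]], mins[cand[, 2]])
    key2 <- pmax(mins[cand[, 1]], mins[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    heights[step] <- d[i, j]

    ni <- length(members[[i]]); nj <- length(members[[j]])
    new_d <- switch(linkage,
      average  = (ni * d[i, ] + nj * d[j, ]) / (ni + nj),
      single   = pmin(d[i, ], d[j, ]),
      complete = pmax(d[i, ], d[j, ]))
    members[[i]] <- c(members[[i]], members[[j]])
    mins[i] <- min(mins[i], mins[j])
    d[i, ] <- d[, i] <- new_d
    d[i, i] <- 0
    members <- members[-j]; mins <- mins[-j]
    d <- d[-j, -j, drop = FALSE]

    L <- n - 1L
    lab <- integer(K)
    ord <- order(vapply(members, min, integer(1)))   # number by smallest member
    for (l in seq_along(ord)) lab[members[[ord[l]]]] <- l
    assignments[[L]] <- lab
  }
  structure(list(K = as.integer(K), linkage = linkage,
                 assignments = assignments, heights = heights),
            class = "clc_partitions")
}

#' Membership matrix B for one partition
#'
#' @param partitions a `clc_partitions` object.
#' @param L number of clusters.
#' @return K x L binary matrix with exactly one 1 per row; columns ordered
#'   by smallest member index.
#' @export
membership_matrix <- function(partitions, L) {
  lab <- partitions$assignments[[L]]
  B <- matrix(0, partitions$K, L)
  B[cbind(seq_len(partitions$K), lab)] <- 1
  B
}

#' @export
print.clc_partitions <- function(x, ...) {
  cat("clc_partitions: K =", x$K, ", linkage =", x$linkage, "\n")
  invisible(x)
}

#' CLC chi-square statistic for one partition
#'
#' Computes T = (WZ)'(WRW')^{-1}(WZ) with W = B'R^{-1} and its chi-square
#' upper-tail p-value on L degrees of freedom (L = number of clusters).
#' The tail is evaluated in log space so small p-values keep relative
#' accuracy.
#'
#' @param z numeric Z score vector of length K.
#' @param R phenotype correlation matrix (positive definite after repair).
#' @param B K x L binary membership matrix (one 1 per row).
#' @return list(statistic, pvalue, df).
#' @export
clc_statistic <- function(z, R, B) {
  R <- as.matrix(R)
  B <- as.matrix(B)
  K <- length(z); L <- ncol(B)
  stopifnot(nrow(B) == K, nrow(R) == K)
  if (any(rowSums(B) != 1) || any(!B %in% c(0, 1)))
    stop2("B must be a binary membership matrix with one 1 per row")
  ch <- chol_safe(R)
  Rinv_z <- backsolve(ch, backsolve(ch, z, transpose = TRUE))
  wz <- drop(crossprod(B, Rinv_z))                 # W Z
  Rinv_B <- backsolve(ch, backsolve(ch, B, transpose = TRUE))
  A <- crossprod(B, Rinv_B)                        # W R W' = B' R^{-1} B
  chA <- tryCatch(chol(A), error = function(e)
    stop2("degenerate clustering: WRW' numerically singular"))
  stat <- sum(backsolve(chA, wz, transpose = TRUE)^2)
  p <- stats::pchisq(stat, df = L, lower.tail = FALSE)
  list(statistic = stat, pvalue = p, df = L)
}

# ACAT-style stabilised Cauchy transform of a p-value matrix (rows = tests,
# cols = replicates). Returns statistic, pvalue and -log10 p per column,
# with the extreme tail handled in log space.
.cauchy_combine_mat <- function(P) {
  Kn <- nrow(P); M <- ncol(P)
  P <- pmin(pmax(P, 5e-324), 1 - 1e-16)
  small <- P < 1e-15
  terms <- matrix(0, Kn, M)
  terms[!small] <- tanpi(0.5 - P[!small])
  terms[small] <- 1 / (P[small] * pi)              # may overflow to Inf
  Tstat <- colMeans(terms)
  pvalue <- stats::pcauchy(Tstat, lower.tail = FALSE)
  neglog10 <- -log10(pmax(pvalue, 5e-324))
  # columns whose mean overflowed, or whose tail underflows double precision:
  # recover -log10 p from the log of the dominant terms, p ~ 1/(pi T)
  fix <- which(!is.finite(Tstat) | pvalue < 1e-300)
  for (m in fix) {
    lt <- ifelse(small[, m], -log(P[, m]) - log(pi),
                 log(pmax(terms[, m], 0)))
    lt <- lt[is.finite(lt) & terms[, m] > 0]
    if (length(lt) == 0) next
    logT <- logsumexp(lt) - log(Kn)
    logp <- -log(pi) - logT
    pvalue[m] <- max(exp(logp), 5e-324)
    neglog10[m] <- (log(pi) + logT) / log(10)
    Tstat[m] <- exp(logT)
  }
  pvalue <- pmin(pmax(pvalue, 5e-324), 1)
  list(statistic = Tstat, pvalue = pvalue, neglog10p = neglog10)
}

#' Cauchy combination of dependent p-values
#'
#' T = (1/K) sum tan((0.5 - p) pi); the combined p-value is the standard
#' Cauchy upper tail 0.5 - arctan(T)/pi. For p below 1e-15 the transform is
#' replaced by its asymptote 1/(p pi), and p-values at 1 are clamped to
#' 1 - 1e-16, the standard ACAT stabilisation preserving the Cauchy tail.
#'
#' @param pvalues vector of p-values in (0, 1).
#' @return list(statistic, pvalue, neglog10p).
#' @export
#' @examples
#' cauchy_combination(c(0.5, 0.5))   # p = 0.5
cauchy_combination <- function(pvalues) {
  if (length(pvalues) == 0) stop2("no p-values to combine")
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues >= 1))
    stop2("input p-values must lie strictly in (0, 1)")
  out <- .cauchy_combine_mat(matrix(pvalues, ncol = 1))
  list(statistic = out$statistic, pvalue = out$pvalue,
       neglog10p = out$neglog10p)
}

# Precompute everything that depends only on R: partitions, the Cholesky
# factor of R, and per-L factors of B'R^{-1}B. Returns a batch evaluator.
sclc_engine <- function(R, linkage = "average", partitions = NULL) {
  R <- as.matrix(R)
  K <- nrow(R)
  if (is.null(partitions)) partitions <- hierarchical_partitions(R, linkage)
  stopifnot(partitions$K == K)
  ch <- chol_safe(R)
  factors <- vector("list", K)
  for (L in seq_len(K)) {
    B <- membership_matrix(partitions, L)
    Rinv_B <- backsolve(ch, backsolve(ch, B, transpose = TRUE))
    A <- crossprod(B, Rinv_B)
    factors[[L]] <- list(group = partitions$assignments[[L]],
                         chA = chol(A))
  }
  pfun <- function(Zmat) {
    Zmat <- as.matrix(Zmat)
    M <- ncol(Zmat)
    Q <- backsolve(ch, backsolve(ch, Zmat, transpose = TRUE))  # R^{-1} Z
    P <- matrix(NA_real_, K, M)
    stats_L <- matrix(NA_real_, K, M)
    for (L in seq_len(K)) {
      f <- factors[[L]]
      WZ <- rowsum(Q, group = f$group, reorder = TRUE)         # B' R^{-1} Z
      y <- backsolve(f$chA, WZ, transpose = TRUE)
      tl <- .colSums(y^2, L, M)
      stats_L[L, ] <- tl
      P[L, ] <- stats::pchisq(tl, df = L, lower.tail = FALSE)
    }
    comb <- .cauchy_combine_mat(P)
    list(statistic = comb$statistic, pvalue = comb$pvalue,
         neglog10p = comb$neglog10p, p_per_L = P, stat_per_L = stats_L)
  }
  list(partitions = partitions, pfun = pfun, chol = ch)
}

#' The sCLC test for one SNP
#'
#' Computes the CLC chi-square p-value for every cluster count L = 1..K of
#' the hierarchical tree of `R` and combines them with the Cauchy
#' combination.
#'
#' @param z Z score vector of length K.
#' @param R phenotype correlation matrix.
#' @param partitions optional precomputed [hierarchical_partitions()];
#'   computed from `R` when NULL.
#' @param linkage linkage used when computing partitions.
#' @return An object of class `sclc_result`; `detail` carries the per-L
#'   p-values and statistics, the partitions, and -log10 p.
#' @export
sclc_test <- function(z, R, partitions = NULL, linkage = "average") {
  R <- as.matrix(R)
  if (length(z) != nrow(R)) stop2("length(z) must match dim(R)")
  eng <- sclc_engine(R, linkage = linkage, partitions = partitions)
  out <- eng$pfun(matrix(z, ncol = 1))
  new_test_result("sCLC", out$statistic, out$pvalue,
                  detail = list(p_per_L = drop(out$p_per_L),
                                stat_per_L = drop(out$stat_per_L),
                                neglog10p = out$neglog10p,
                                partitions = eng$partitions))
}

#' Genome scan with the sCLC test
#'
#' Runs [sclc_test()] across all SNPs of a Z score matrix. The clustering,
#' the Cholesky factor of R and the per-partition quadratic-form factors
#' are computed once and reused, so the scan is equivalent to (and much
#' faster than) a per-SNP loop.
#'
#' @param z a `z_matrix` or a plain K x M matrix (phenotypes x SNPs).
#' @param R phenotype correlation matrix.
#' @param linkage linkage for the clustering.
#' @param per_cluster if TRUE, per-L p-value columns are included.
#' @return A data.frame with columns `snp`, `sclc_stat`, `sclc_p`,
#'   `sclc_neglog10p` (and `sclc_p_L<\ell>` when `per_cluster`).
#' @export
sclc_scan <- function(z, R, linkage = "average", per_cluster = FALSE) {
  Zmat <- if (inherits(z, "z_matrix")) z$z else as.matrix(z)
  if (nrow(Zmat) != nrow(as.matrix(R)))
    stop2("row count of z must equal the dimension of R")
  snps <- colnames(Zmat) %||% as.character(seq_len(ncol(Zmat)))
  if (ncol(Zmat) == 0)
    return(data.frame(snp = character(), sclc_stat = numeric(),
                      sclc_p = numeric(), sclc_neglog10p = numeric()))
  eng <- sclc_engine(R, linkage = linkage)
  out <- eng$pfun(Zmat)
  res <- data.frame(snp = snps, sclc_stat = out$statistic,
                    sclc_p = out$pvalue, sclc_neglog10p = out$neglog10p,
                    stringsAsFactors = FALSE)
  if (per_cluster) {
    pl <- t(out$p_per_L)
    colnames(pl) <- paste0("sclc_p_L", seq_len(nrow(out$p_per_L)))
    res <- cbind(res, as.data.frame(pl))
  }
  rownames(res) <- NULL
  res
}
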