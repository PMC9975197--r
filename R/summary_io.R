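# Reading, writing and transforming GWAS summary statistics.
#
# The native file dialect is LDSC-style delimited text with a header of
# SNP CHR BP A1 A2 Z N; any other header is handled through a column-name
# mapping (`sumstats_dialect()`). LD scores follow the `.l2.ldscore` dialect
# (CHR SNP BP L2). Both readers are gzip-transparent.

#' Column-name mapping for summary-statistic files
#'
#' Describes how the columns of a delimited summary-statistics file map onto
#' the fields used by the package. The default matches the LDSC sumstats
#' convention (`SNP CHR BP A1 A2 Z N`), with `BETA`/`SE`/`P` recognised when
#' present. Set an entry to `NA` to declare the column absent.
#'
#' @param snp,chrom,pos,a1,a2,z,beta,se,pvalue,n,log10p column names in the
#'   file header for, respectively: SNP identifier, chromosome, 1-based
#'   position, effect allele, other allele, Z score, effect estimate, its
#'   standard error, p-value, sample size, and log10 p-value (for p-values
#'   that underflow double precision).
#' @return A named list of class `sumstats_dialect`.
#' @export
#' @examples
#' sumstats_dialect(pvalue = "PVAL", n = NA)
sumstats_dialect <- function(snp = "SNP", chrom = "CHR", pos = "BP",
                             a1 = "A1", a2 = "A2", z = "Z",
                             beta = "BETA", se = "SE", pvalue = "P",
                             n = "N", log10p = NA) {
  structure(list(snp = snp, chrom = chrom, pos = pos, a1 = a1, a2 = a2,
                 z = z, beta = beta, se = se, pvalue = pvalue, n = n,
                 log10p = log10p),
            class = "sumstats_dialect")
}

# convert a character column to numeric, reporting the 1-based file line of
# the first malformed entry (header is line 1)
.parse_numeric <- function(x, col, what = "field") {
  miss <- is.na(x) | x == "" | x == "NA" | x == "."
  out <- suppressWarnings(as.numeric(x))
  bad <- !miss & is.na(out)
  if (any(bad))
    stop2("malformed numeric ", what, " in column '", col, "' at file line ",
          which(bad)[1] + 1L, ": '", x[which(bad)[1]], "'")
  out
}

#' Read a GWAS summary-statistics file
#'
#' Reads a delimited (optionally gzipped) per-phenotype summary-statistics
#' file. Each record must carry a Z score or a (beta, se) pair; Z is derived
#' as beta/se when absent. Malformed numeric fields are rejected with the
#' offending line number; duplicated SNP identifiers are an error.
#'
#' @param path path to the file.
#' @param dialect a [sumstats_dialect()] mapping header names to fields.
#' @return A data.frame of class `sumstats_table` with columns `snp`,
#'   `chrom`, `pos`, `a1`, `a2`, `z`, `beta`, `se`, `pvalue`, `n` (absent
#'   source columns give `NA` columns).
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect()) {
  if (!file.exists(path)) stop2("summary-statistics file not found: ", path)
  raw <- data.table::fread(path, header = TRUE, colClasses = "character",
                           data.table = FALSE, showProgress = FALSE)
  if (nrow(raw) == 0) stop2("empty summary-statistics file: ", path)
  hdr <- names(raw)
  get_col <- function(field) {
    nm <- dialect[[field]]
    if (is.null(nm) || is.na(nm) || !(nm %in% hdr)) return(NULL)
    raw[[nm]]
  }
  snp <- get_col("snp")
  if (is.null(snp))
    stop2("mandatory SNP id column '", dialect$snp, "' missing in ", path)
  if (anyDuplicated(snp))
    stop2("duplicated SNP id in ", path, ": ", snp[duplicated(snp)][1])

  num_or_na <- function(field) {
    x <- get_col(field)
    if (is.null(x)) return(rep(NA_real_, length(snp)))
    .parse_numeric(x, dialect[[field]], field)
  }
  chr_or_na <- function(field) {
    x <- get_col(field)
    if (is.null(x)) rep(NA_character_, length(snp)) else x
  }

  tab <- data.frame(snp = snp,
                    chrom = chr_or_na("chrom"),
                    pos = num_or_na("pos"),
                    a1 = toupper(chr_or_na("a1")),
                    a2 = toupper(chr_or_na("a2")),
                    z = num_or_na("z"),
                    beta = num_or_na("beta"),
                    se = num_or_na("se"),
                    pvalue = num_or_na("pvalue"),
                    n = num_or_na("n"),
                    stringsAsFactors = FALSE)
  log10p <- get_col("log10p")
  if (!is.null(log10p)) tab$log10p <- .parse_numeric(log10p, dialect$log10p, "log10p")

  has_z <- !is.na(tab$z)
  has_bse <- !is.na(tab$beta) & !is.na(tab$se)
  if (any(!has_z & !has_bse))
    stop2("record without Z and without beta/se at file line ",
          which(!has_z & !has_bse)[1] + 1L, " in ", path)
  if (any(has_bse & tab$se <= 0))
    stop2("non-positive standard error at file line ",
          which(has_bse & tab$se <= 0)[1] + 1L, " in ", path)
  if (any(!is.na(tab$pvalue) & (tab$pvalue <= 0 | tab$pvalue > 1)))
    stop2("p-value outside (0, 1] at file line ",
          which(!is.na(tab$pvalue) & (tab$pvalue <= 0 | tab$pvalue > 1))[1] + 1L)
  class(tab) <- c("sumstats_table", "data.frame")
  tab
}

#' Read an LD score file
#'
#' Reads a delimited LD score file in the `.l2.ldscore` dialect
#' (columns `CHR SNP BP L2`), gzip-transparent.
#'
#' @param path path to the file.
#' @param snp_col,ldscore_col header names of the SNP id and LD score columns.
#' @return A data.frame of class `ldscore_table` with columns `snp`, `ldscore`.
#' @export
read_ldscores <- function(path, snp_col = "SNP", ldscore_col = "L2") {
  if (!file.exists(path)) stop2("LD score file not found: ", path)
  raw <- data.table::fread(path, header = TRUE, colClasses = "character",
                           data.table = FALSE, showProgress = FALSE)
  if (!all(c(snp_col, ldscore_col) %in% names(raw)))
    stop2("LD score file must have columns '", snp_col, "' and '",
          ldscore_col, "'")
  snp <- raw[[snp_col]]
  if (anyDuplicated(snp))
    stop2("duplicated SNP id in LD score file: ", snp[duplicated(snp)][1])
  l2 <- .parse_numeric(raw[[ldscore_col]], ldscore_col, "LD score")
  if (any(!is.finite(l2))) stop2("non-finite LD score in ", path)
  structure(data.frame(snp = snp, ldscore = l2, stringsAsFactors = FALSE),
            class = c("ldscore_table", "data.frame"))
}

#' Z score from an effect estimate and its standard error
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @return `beta / se`.
#' @export
#' @examples
#' z_from_beta(0.1, 0.05)  # 2
z_from_beta <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) stop2("invalid standard error: se must be > 0")
  beta / se
}

#' Signed Z score from a p-value (saddlepoint-adjusted score tests)
#'
#' Converts a two-sided p-value and the sign of the underlying score
#' statistic into an adjusted Z score, `sign * sqrt(q)` with `q` the upper-p
#' quantile of the 1-df chi-square distribution. Intended for score tests
#' whose p-values come from a saddlepoint approximation under extremely
#' unbalanced case-control ratios, where beta/se is badly calibrated.
#' For p-values that underflow double precision supply `log10p` instead.
#'
#' @param p two-sided p-value(s) in (0, 1]. Ignored where `log10p` is given.
#' @param sign sign(s) of the score statistic, -1 or +1.
#' @param log10p optional log10 p-value(s) (non-positive); used where not NA.
#' @return Adjusted Z score(s).
#' @export
#' @examples
#' adjusted_z(0.05, 1)          # 1.959964
#' adjusted_z(NA, -1, log10p = -300)
adjusted_z <- function(p, sign, log10p = NULL) {
  if (!all(sign %in% c(-1, 1))) stop2("sign must be -1 or +1")
  n <- max(length(p), length(sign), length(log10p %||% numeric()))
  p <- rep_len(p, n); sign <- rep_len(sign, n)
  use_log <- if (is.null(log10p)) rep(FALSE, n) else !is.na(rep_len(log10p, n))
  q <- numeric(n)
  if (any(!use_log)) {
    pp <- p[!use_log]
    if (any(is.na(pp) | pp <= 0 | pp > 1))
      stop2("p must lie in (0, 1]; for underflowed p-values supply log10p")
    q[!use_log] <- stats::qchisq(pp, df = 1, lower.tail = FALSE)
  }
  if (any(use_log)) {
    lp <- rep_len(log10p, n)[use_log] * log(10)
    if (any(lp > 0)) stop2("log10p must be <= 0")
    q[use_log] <- stats::qchisq(lp, df = 1, lower.tail = FALSE, log.p = TRUE)
  }
  sign * sqrt(q)
}

#' Score statistic for one SNP and one phenotype
#'
#' The score test numerator for individual-level data: the covariance-type
#' sum of centred phenotype values against genotype dosages,
#' sum((y - mean(y)) * g). Used when building fixtures from small
#' individual-level matrices.
#'
#' @param y phenotype vector (e.g. 0/1 case-control) of length N >= 2.
#' @param g genotype dosage vector of the same length.
#' @return The score statistic (a scalar).
#' @export
score_statistic <- function(y, g) {
  if (length(y) != length(g)) stop2("y and g must have equal length")
  if (length(y) < 2) stop2("need at least two observations")
  sum((y - mean(y)) * g)
}

# strand-ambiguous allele pair (A/T or C/G)?
.is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align several summary-statistic tables into a Z score matrix
#'
#' Restricts all tables (and the LD score table, if given) to their common
#' SNPs, harmonises alleles against the first table -- a swapped
#' effect/other allele pair flips the sign of Z, an incompatible pair drops
#' the SNP -- and assembles the K x M matrix of Z scores. Strand-ambiguous
#' SNPs (A/T, C/G) are kept but flagged in the report.
#'
#' @param tables named list of `sumstats_table`s, one per phenotype.
#' @param ldscores optional `ldscore_table`; the intersection is further
#'   restricted to its SNPs and the matching scores are attached.
#' @return An object of class `z_matrix`: list with `z` (K x M matrix,
#'   phenotypes x SNPs), `phenotypes`, `snps`, `ldscores` (aligned vector or
#'   NULL), `n_mean` (per-phenotype mean sample size, NA when absent) and
#'   `report` (counts of dropped/flipped/ambiguous SNPs).
#' @export
align_z_matrix <- function(tables, ldscores = NULL) {
  if (length(tables) < 1) stop2("need at least one summary-statistics table")
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("pheno", seq_along(tables))
  K <- length(tables)

  common <- Reduce(intersect, lapply(tables, function(t) t$snp))
  if (!is.null(ldscores)) common <- intersect(common, ldscores$snp)
  if (length(common) == 0) stop2("empty SNP intersection across tables")
  # keep the first table's SNP order
  common <- tables[[1]]$snp[tables[[1]]$snp %in% common]

  zcol <- function(tab) {
    z <- tab$z
    need <- is.na(z)
    z[need] <- tab$beta[need] / tab$se[need]
    z
  }

  ref <- tables[[1]][match(common, tables[[1]]$snp), ]
  have_alleles <- !any(is.na(ref$a1)) && !any(is.na(ref$a2))
  Z <- matrix(NA_real_, nrow = K, ncol = length(common),
              dimnames = list(names(tables), common))
  flips <- integer(K); names(flips) <- names(tables)
  drop_mask <- rep(FALSE, length(common))
  for (k in seq_len(K)) {
    tk <- tables[[k]][match(common, tables[[k]]$snp), ]
    zk <- zcol(tk)
    if (have_alleles && !any(is.na(tk$a1)) && !any(is.na(tk$a2))) {
      same <- tk$a1 == ref$a1 & tk$a2 == ref$a2
      swap <- tk$a1 == ref$a2 & tk$a2 == ref$a1
      zk[swap] <- -zk[swap]
      flips[k] <- sum(swap)
      drop_mask <- drop_mask | (!same & !swap)
    }
    Z[k, ] <- zk
  }
  ambiguous <- if (have_alleles) common[.is_ambiguous(ref$a1, ref$a2)] else character()
  keep <- !drop_mask
  if (!any(keep)) stop2("no SNP survives allele harmonisation")
  Z <- Z[, keep, drop = FALSE]
  snps <- common[keep]

  l2 <- NULL
  if (!is.null(ldscores)) l2 <- ldscores$ldscore[match(snps, ldscores$snp)]
  n_mean <- vapply(tables, function(t) mean(t$n, na.rm = TRUE), numeric(1))
  n_mean[is.nan(n_mean)] <- NA_real_

  structure(list(z = Z, phenotypes = names(tables), snps = snps,
                 ldscores = l2, n_mean = n_mean,
                 report = list(n_input = length(common),
                               n_dropped_incompatible = sum(drop_mask),
                               n_flipped = flips,
                               ambiguous_snps = ambiguous)),
            class = "z_matrix")
}

#' @export
print.z_matrix <- function(x, ...) {
  cat("z_matrix:", nrow(x$z), "phenotypes x", ncol(x$z), "SNPs\n")
  if (x$report$n_dropped_incompatible > 0)
    cat("  dropped (incompatible alleles):", x$report$n_dropped_incompatible, "\n")
  if (length(x$report$ambiguous_snps) > 0)
    cat("  flagged strand-ambiguous:", length(x$report$ambiguous_snps), "\n")
  invisible(x)
}

# p-value formatting contract: >= 6 significant digits, scientific below 1e-4
.format_p <- function(p) {
  out <- sprintf("%.6g", p)
  sci <- !is.na(p) & p > 0 & p < 1e-4
  out[sci] <- sprintf("%.6e", p[sci])
  out[is.na(p)] <- "NA"
  out
}

#' Write per-SNP test results to a delimited file
#'
#' One row per SNP, one (statistic, p) column pair per method, in a
#' deterministic column order. P-values carry at least six significant
#' digits and switch to scientific notation below 1e-4.
#'
#' @param results a data.frame as returned by [sclc_scan()]/[run_tests()]
#'   (column `snp` followed by `<method>_stat`, `<method>_p` pairs).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  pcols <- grep("_p$", names(out), value = TRUE)
  for (cc in pcols) out[[cc]] <- .format_p(results[[cc]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop2("cannot write results to ", path)
  invisible(path)
}
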