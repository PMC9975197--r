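# Shared test fixtures, all generated in code.

# random positive-definite correlation matrix (normalised Wishart, df = 2K
# unless stated: moderate, realistic conditioning)
rand_corr <- function(K, df = 2 * K, seed = NULL) {
  gen <- function() {
    A <- matrix(stats::rnorm(K * df), K, df)
    S <- tcrossprod(A)
    d <- 1 / sqrt(diag(S))
    S * tcrossprod(d)
  }
  if (is.null(seed)) gen() else sclc:::with_seed(seed, gen())
}

# minimal in-memory summary-statistics table
make_sumstats <- function(snp, z = NULL, beta = NULL, se = NULL,
                          a1 = "A", a2 = "G", n = 1000, chrom = "1",
                          pos = seq_along(snp)) {
  k <- length(snp)
  structure(
    data.frame(snp = snp, chrom = rep_len(chrom, k), pos = pos,
               a1 = rep_len(a1, k), a2 = rep_len(a2, k),
               z = if (is.null(z)) NA_real_ else z,
               beta = if (is.null(beta)) NA_real_ else beta,
               se = if (is.null(se)) NA_real_ else se,
               pvalue = NA_real_, n = rep_len(n, k),
               stringsAsFactors = FALSE),
    class = c("sumstats_table", "data.frame"))
}

# write a small sumstats file in the native dialect
write_sumstats_file <- function(path, snp, z, a1 = "A", a2 = "G", n = 1000) {
  df <- data.frame(SNP = snp, CHR = "1", BP = seq_along(snp),
                   A1 = a1, A2 = a2, Z = z, N = n)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# two partitions equal up to cluster relabelling?
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
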