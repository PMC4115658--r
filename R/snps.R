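# SNP list construction between strain pairs.
#
# SNP tables are (chrom, pos [1-based], base_a, base_b) where base_a is the
# allele of the first-named strain of the pair.

#' Derive a B/C SNP list from A/B and A/C lists
#'
#' For two lists that share strain A as reference: a position present only
#' in A/C is copied (B carries the A allele, so the record already reads
#' B-allele, C-allele); a position present only in A/B is inverted (swap,
#' so the B allele comes first and C carries the A allele); a position
#' present in both is excluded, since it reflects a difference between A
#' and both other strains. Records sharing a position but disagreeing on
#' the strain-A base are dropped with a warning.
#'
#' @param list_ab SNP `data.table` for strains A/B.
#' @param list_ac SNP `data.table` for strains A/C.
#' @return SNP `data.table` for strains B/C.
#' @export
derive_pair_snps <- function(list_ab, list_ac) {
  ab <- validate_snps(list_ab)
  ac <- validate_snps(list_ac)
  key <- function(x) paste(x$chrom, x$pos)
  kab <- key(ab); kac <- key(ac)
  shared <- intersect(kab, kac)
  if (length(shared)) {
    # consistency check: same position must report the same strain-A base
    a1 <- ab[kab %in% shared][order(chrom, pos)]
    a2 <- ac[kac %in% shared][order(chrom, pos)]
    bad <- a1$base_a != a2$base_a
    if (any(bad)) warning(sum(bad), " shared positions with inconsistent ",
                          "strain-A alleles; dropped")
  }
  only_ac <- ac[!kac %in% kab]                     # copied: (A=B allele, C)
  only_ab <- ab[!kab %in% kac]                     # inverted: (B, A=C allele)
  out <- rbind(
    only_ac[, .(chrom, pos, base_a, base_b)],
    only_ab[, .(chrom, pos, base_a = base_b, base_b = base_a)])
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Filter SNPs by control-library misclassification rate
#'
#' One-tailed exact binomial test per SNP of H0: underlying error rate
#' <= `max_error` (upper tail, P(X >= observed)); SNPs with p < `alpha`
#' are removed. SNPs with zero control coverage are retained (no evidence
#' against them).
#'
#' @param control_counts `data.table` with `chrom`, `pos`, `mis`
#'   (misclassified reads) and `total` control reads per SNP.
#' @param max_error Null acceptable error rate (default 0.05).
#' @param alpha Removal threshold on the upper-tail p-value (default 0.05).
#' @return `control_counts` with columns `p_err` and logical `keep`.
#' @export
filter_snps_by_error <- function(control_counts, max_error = 0.05,
                                 alpha = 0.05) {
  x <- data.table::as.data.table(control_counts)
  if (any(x$mis > x$total)) stop("misclassified exceeds total")
  if (any(x$total < 0)) stop("negative totals")
  x <- data.table::copy(x)
  # P(X >= mis | total, max_error); mis = 0 gives p = 1
  x[, p_err := pbinom(mis - 1L, total, max_error, lower.tail = FALSE)]
  x[, keep := total == 0L | p_err >= alpha]
  x[]
}
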