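#' Read an allele-count table
#'
#' Expects a TSV with columns `gene_id`, `mother`, `father`, `tissue`,
#' `replicate`, `maternal_reads`, `paternal_reads`.
#'
#' @param path File path.
#' @return A `data.table` of allele counts.
#' @export
read_allele_counts <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  need <- c("gene_id", "mother", "father", "tissue", "replicate",
            "maternal_reads", "paternal_reads")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("allele-count table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(x$maternal_reads < 0) || any(x$paternal_reads < 0))
    stop("negative read counts")
  x[]
}

#' Read a per-cytosine methylation report
#'
#' CX-report dialect: tab-separated `chrom`, 1-based `pos`, `strand`,
#' methylated count, unmethylated count, `context` (CG/CHG/CHH). Returns
#' counts as `meth` and `total` (= methylated + unmethylated).
#'
#' @param path File path.
#' @param sample_id Optional sample label attached as a column.
#' @return A `data.table` of cytosine records.
#' @export
read_cx_report <- function(path, sample_id = NULL) {
  x <- data.table::fread(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "pos", "strand",
                                       "count_meth", "count_unmeth",
                                       "context"))
  x[, `:=`(meth = count_meth, total = count_meth + count_unmeth,
           count_meth = NULL, count_unmeth = NULL)]
  bad <- setdiff(unique(x$context), CONTEXTS)
  if (length(bad)) stop("unknown context: ", paste(bad, collapse = ", "))
  if (!is.null(sample_id)) x[, sample_id := sample_id]
  x[]
}

#' Write cytosine records as a CX-style report
#' @param cyt Cytosine `data.table` (`chrom`, `pos`, `strand`, `meth`,
#'   `total`, `context`).
#' @param path Output path.
#' @export
write_cx_report <- function(cyt, path) {
  out <- data.table::data.table(chrom = cyt$chrom, pos = cyt$pos,
                                strand = cyt$strand, count_meth = cyt$meth,
                                count_unmeth = cyt$total - cyt$meth,
                                context = cyt$context)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a SNP list
#'
#' TSV with columns `chrom`, `pos` (1-based), `base_a`, `base_b`.
#' @param path File path.
#' @return A `data.table` of SNP records.
#' @export
read_snps <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  validate_snps(x)
}

validate_snps <- function(x) {
  x <- data.table::as.data.table(x)
  need <- c("chrom", "pos", "base_a", "base_b")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("SNP table missing columns: ",
                         paste(miss, collapse = ", "))
  ok <- x$base_a %in% c("A", "C", "G", "T") &
    x$base_b %in% c("A", "C", "G", "T") & x$base_a != x$base_b
  if (!all(ok)) stop(sum(!ok), " SNP records with invalid or equal alleles")
  x[]
}

#' Read a BED6 annotation into a feature table
#'
#' Internally features use 0-based half-open coordinates, as in BED.
#' The BED name field becomes `feature_id`; an optional 7th column (or a
#' `gene`/`TE` prefix of the name, e.g. `TE_...`) sets `feature_type`.
#'
#' @param path File path.
#' @return A `data.table` with `chrom`, `start`, `end`, `feature_id`,
#'   `strand`, `feature_type`.
#' @export
read_features_bed <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(x) < 6) stop("expected BED6 (6+ columns)")
  out <- data.table::data.table(chrom = as.character(x[[1]]),
                                start = as.integer(x[[2]]),
                                end = as.integer(x[[3]]),
                                feature_id = as.character(x[[4]]),
                                strand = as.character(x[[6]]))
  out[, feature_type := if (ncol(x) >= 7) as.character(x[[7]]) else
    data.table::fifelse(startsWith(feature_id, "TE"), "TE", "gene")]
  out[]
}

#' Write a feature table as BED6 (+ feature_type column)
#' @param features Feature `data.table`.
#' @param path Output path.
#' @export
write_features_bed <- function(features, path) {
  out <- data.table::data.table(features$chrom, features$start,
                                features$end, features$feature_id, 0L,
                                features$strand, features$feature_type)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write DMRs as BED6+ (score = -log10 q; extra columns diff, n_shared,
#' p_raw, q)
#' @param dmrs DMR `data.table`.
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- round(-log10(pmax(dmrs$q, 1e-300)), 3)
  out <- data.table::data.table(dmrs$chrom, dmrs$start, dmrs$end,
                                dmrs$context, score,
                                data.table::fifelse(dmrs$diff_meth >= 0,
                                                    "+", "-"),
                                dmrs$diff_meth, dmrs$n_shared, dmrs$p_raw,
                                dmrs$q)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a DMR-by-strain methylation score matrix
#'
#' TSV with first column `dmr_id` and one column per strain; `NA` marks a
#' missing score.
#' @param path File path.
#' @return Numeric matrix with DMR ids as rownames.
#' @export
read_score_matrix <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  m <- as.matrix(x[, -1])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a DMR-by-strain score matrix as TSV
#' @param mat Numeric matrix, DMR ids as rownames.
#' @param path Output path.
#' @export
write_score_matrix <- function(mat, path) {
  out <- data.table::data.table(dmr_id = rownames(mat))
  out <- cbind(out, data.table::as.data.table(mat))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
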