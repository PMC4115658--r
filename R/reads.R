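# Strain-of-origin read classification, deduplication and allele counting.
#
# Reads are abstract aligned records (chrom, 0-based start, strand,
# reference-oriented sequence); classification works from SNP votes.

#' Classify reads by strain of origin at SNP positions
#'
#' Each SNP covered by a read casts a vote: the read base at the SNP
#' position matched against the two strain alleles. All votes for one
#' strain assign the read; disagreeing votes mark it `conflict`; no votes
#' (no SNP covered, non-allele base, or all covered SNPs masked) leave it
#' `unassigned`. In bisulfite mode C/T SNPs are ignored for `+`-strand
#' reads and G/A SNPs for `-`-strand reads, because bisulfite conversion
#' makes them unreadable.
#'
#' @param reads Read `data.table` (`chrom`, `start` 0-based, `strand`,
#'   `sequence`, ...).
#' @param snps SNP `data.table` (`chrom`, `pos` 1-based, `base_a`,
#'   `base_b`).
#' @param bisulfite_mode Apply the bisulfite SNP masking rules.
#' @param labels Origin labels for the two strains, in SNP-column order.
#' @return The input with an `origin` column
#'   (`labels[1]`/`labels[2]`/`unassigned`/`conflict`).
#' @export
classify_reads <- function(reads, snps, bisulfite_mode = FALSE,
                           labels = c("strain_a", "strain_b")) {
  reads <- data.table::as.data.table(reads)
  snps <- validate_snps(snps)
  rd <- data.table::copy(reads)
  rd[, read_id := if ("read_id" %in% names(reads)) reads$read_id else
    sprintf("r%06d", .I)]
  rd[, `:=`(rstart = start + 1L, rend = start + nchar(sequence))]

  s <- snps[, .(chrom, pos, base_a, base_b)]
  data.table::setkey(s, chrom, pos)
  hits <- s[rd[, .(read_id, chrom, rstart, rend, strand, sequence,
                   start)],
            on = .(chrom, pos >= rstart, pos <= rend), nomatch = NULL,
            .(read_id, snp_pos = x.pos, base_a, base_b, strand, sequence,
              start)]
  if (nrow(hits)) {
    if (bisulfite_mode) {
      ct <- (hits$base_a == "C" & hits$base_b == "T") |
        (hits$base_a == "T" & hits$base_b == "C")
      ga <- (hits$base_a == "G" & hits$base_b == "A") |
        (hits$base_a == "A" & hits$base_b == "G")
      hits <- hits[!((strand == "+" & ct) | (strand == "-" & ga))]
    }
  }
  origin <- rep("unassigned", nrow(rd))
  names(origin) <- rd$read_id
  if (nrow(hits)) {
    hits[, base := substr(sequence, snp_pos - start, snp_pos - start)]
    hits[, vote := data.table::fcase(base == base_a, "a",
                                     base == base_b, "b",
                                     default = NA_character_)]
    hits <- hits[!is.na(vote)]
    if (nrow(hits)) {
      verdict <- hits[, .(v = if (data.table::uniqueN(vote) > 1L) "conflict"
                          else vote[1]), by = read_id]
      lab <- c(a = labels[1], b = labels[2], conflict = "conflict")
      origin[verdict$read_id] <- lab[verdict$v]
    }
  }
  out <- data.table::copy(reads)
  out[, origin := unname(origin)]
  out[]
}

#' Deduplicate reads mapping to the same position and strand
#'
#' Within each (chrom, start, strand) group exactly one read is kept:
#' the most prevalent identical sequence first, then the highest total
#' base quality, then the fewest mismatches, with a final deterministic
#' lexicographic tie-break on the sequence.
#'
#' @param reads Read `data.table` with `chrom`, `start`, `strand`,
#'   `sequence`, `quality_sum`, `mismatches`.
#' @return Deduplicated `data.table`, one row per group.
#' @export
deduplicate_reads <- function(reads) {
  x <- data.table::as.data.table(reads)
  if (!nrow(x)) return(x)
  x <- data.table::copy(x)
  x[, seq_count := .N, by = .(chrom, start, strand, sequence)]
  data.table::setorder(x, chrom, start, strand, -seq_count, -quality_sum,
                       mismatches, sequence)
  out <- x[, .SD[1L], by = .(chrom, start, strand)]
  out[, seq_count := NULL]
  out[]
}

#' Count maternal/paternal reads per gene
#'
#' Strict counting: a read contributes only if its full aligned interval
#' lies within exactly one feature extent. Reads with conflicting or no
#' SNP evidence are excluded. Origins are mapped to maternal/paternal via
#' the cross's mother and father strains.
#'
#' @param classified Classified read `data.table` (needs `origin`).
#' @param features Feature `data.table` (0-based half-open `start`, `end`).
#' @param mother,father Strain names of the cross (must match origin
#'   labels).
#' @param tissue,replicate Metadata carried into the output.
#' @return Allele-count `data.table`, one row per feature.
#' @export
count_alleles <- function(classified, features, mother, father,
                          tissue = "endosperm", replicate = 1L) {
  x <- data.table::as.data.table(classified)
  ft <- data.table::as.data.table(features)
  if (is.na(mother) || is.na(father))
    stop("cross metadata missing a strain")
  x <- x[origin %in% c(mother, father)]
  x[, `:=`(rstart = start, rend = start + nchar(sequence))]
  f <- ft[, .(feature_id, chrom, fstart = start, fend = end)]
  hits <- f[x[, .(idx = .I, chrom, rstart, rend, origin)],
            on = .(chrom, fstart <= rstart, fend >= rend), nomatch = NULL,
            .(idx, feature_id, origin)]
  hits <- hits[, if (.N == 1L) .SD, by = idx]   # exactly one containing gene
  cnt <- hits[, .(maternal_reads = sum(origin == mother),
                  paternal_reads = sum(origin == father)),
              by = feature_id]
  out <- merge(ft[, .(gene_id = feature_id)], cnt,
               by.x = "gene_id", by.y = "feature_id", all.x = TRUE)
  out[is.na(maternal_reads), maternal_reads := 0L]
  out[is.na(paternal_reads), paternal_reads := 0L]
  out[, `:=`(mother = mother, father = father, tissue = tissue,
             replicate = replicate)]
  data.table::setcolorder(out, c("gene_id", "mother", "father", "tissue",
                                 "replicate", "maternal_reads",
                                 "paternal_reads"))
  out[]
}

#' Maternal read fraction in genomic windows
#'
#' Assigns classified reads to windows by their start position and reports
#' the maternal fraction per window; windows with fewer than `min_reads`
#' classified reads get `NA`.
#'
#' @param classified Classified read `data.table` (needs `origin`,
#'   `chrom`, `start`).
#' @param windows Window `data.table` (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param mother,father Strain names of the cross.
#' @param min_reads Minimum classified reads per window (default 5).
#' @param library_size Optional total genome-aligned reads after
#'   structural-RNA subtraction; when given, an `rpm` column
#'   (reads per million) is added.
#' @return Windows with `maternal`, `paternal`, `n_reads`, `fraction`
#'   (and `rpm` when `library_size` is given).
#' @export
maternal_fraction_windows <- function(classified, windows, mother, father,
                                      min_reads = 5L,
                                      library_size = NULL) {
  x <- data.table::as.data.table(classified)[origin %in% c(mother, father)]
  w <- data.table::copy(data.table::as.data.table(windows))
  w[, window_id := .I]
  hits <- w[x[, .(chrom, rpos = start, origin)],
            on = .(chrom, start <= rpos, end > rpos), nomatch = NULL,
            .(window_id, origin)]
  cnt <- hits[, .(maternal = sum(origin == mother),
                  paternal = sum(origin == father)), by = window_id]
  out <- merge(w, cnt, by = "window_id", all.x = TRUE)
  out[is.na(maternal), `:=`(maternal = 0L, paternal = 0L)]
  out[, n_reads := maternal + paternal]
  out[, fraction := data.table::fifelse(n_reads >= min_reads,
                                        maternal / n_reads, NA_real_)]
  if (!is.null(library_size)) {
    if (library_size <= 0) stop("library_size must be positive")
    out[, rpm := n_reads / library_size * 1e6]
  }
  out[, window_id := NULL]
  out[]
}
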