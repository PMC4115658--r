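# Imprinted-gene calling from reciprocal-cross allele counts.
#
# Notation: m1/p1 are maternal/paternal informative reads in the
# A-female x B-male cross, m2/p2 in the reciprocal. In endosperm the
# non-imprinted expectation is a 2:1 maternal:paternal ratio (maternal
# fraction 2/3) because of genome dosage; in embryo it is 1:1.

round_half_up <- function(x) floor(x + 0.5)

#' Exact test for deviation from the dosage null in reciprocal crosses
#'
#' Default (`mode = "adjusted"`): maternal counts are halved (round half
#' up) to remove the 2:1 endosperm dosage, and the 2x2 table
#' strain-A/strain-B reads x cross direction is tested with the central
#' two-sided Fisher exact test. In cross 1 strain A is the mother (its
#' reads are `m1`, halved); in cross 2 strain A is the father (reads
#' `p2`). Embryo tissue uses raw counts (1:1 null). The optional
#' `"noncentral"` mode tests the raw table against a null odds ratio of 4
#' (endosperm) or 1 (embryo) via the noncentral hypergeometric
#' distribution.
#'
#' @param m1,p1 Maternal/paternal counts in cross A-female x B-male.
#' @param m2,p2 Counts in the reciprocal cross.
#' @param tissue `"endosperm"` or `"embryo"`.
#' @param mode `"adjusted"` or `"noncentral"`.
#' @return Two-sided exact p-value (vectorised over the counts).
#' @export
imprinting_test <- function(m1, p1, m2, p2, tissue = "endosperm",
                            mode = c("adjusted", "noncentral")) {
  mode <- match.arg(mode)
  tissue <- match.arg(tissue, c("endosperm", "embryo"))
  n <- length(m1)
  stopifnot(length(p1) == n, length(m2) == n, length(p2) == n)
  if (any(c(m1, p1, m2, p2) < 0)) stop("negative counts")
  mapply(function(m1, p1, m2, p2) {
    if (m1 + p1 + m2 + p2 == 0) stop("all four counts are zero")
    if (m1 + p1 == 0 || m2 + p2 == 0) return(NA_real_)
    if (mode == "adjusted") {
      if (tissue == "endosperm") {
        m1 <- round_half_up(m1 / 2)
        m2 <- round_half_up(m2 / 2)
      }
      # columns: strain-A reads, strain-B reads; rows: cross 1, cross 2
      tab <- matrix(c(m1, p2, p1, m2), 2L)
      fisher.test(tab)$p.value
    } else {
      or0 <- if (tissue == "endosperm") 4 else 1
      tab <- matrix(c(m1, p2, p1, m2), 2L)
      fisher.test(tab, or = or0)$p.value
    }
  }, m1, p1, m2, p2)
}

#' Imprinting factor: fold deviation from the dosage expectation
#'
#' Reconstruction of the published filter (the defining formula lives in
#' earlier work): the maternal imprinting factor is the smaller, over the
#' two cross directions, of ((m+1)/(p+1))/2 -- i.e. how many times the
#' maternal:paternal ratio exceeds the 2:1 dosage expectation; the
#' paternal factor is min over directions of 2*(p+1)/(m+1). A value of 1
#' sits exactly at the dosage expectation; calls require >= 2.
#'
#' @inheritParams imprinting_test
#' @param direction `"maternal"` or `"paternal"`.
#' @param tissue Tissue: the dosage expectation is 2 for endosperm and 1
#'   for embryo.
#' @return Numeric imprinting factor (vectorised).
#' @export
imprinting_factor <- function(m1, p1, m2, p2,
                              direction = c("maternal", "paternal"),
                              tissue = "endosperm") {
  direction <- match.arg(direction)
  dosage <- if (match.arg(tissue, c("endosperm", "embryo")) == "endosperm")
    2 else 1
  if (direction == "maternal")
    pmin(((m1 + 1) / (p1 + 1)) / dosage, ((m2 + 1) / (p2 + 1)) / dosage)
  else
    pmin(dosage * (p1 + 1) / (m1 + 1), dosage * (p2 + 1) / (m2 + 1))
}

#' Seed-coat expression filter
#'
#' Genes more than twofold higher expressed in the seed coat than in the
#' assayed tissue are suspected seed-coat contaminants. Compartment means
#' are averaged on the linear scale, then log2-transformed; genes with
#' log2(seed coat) - log2(tissue) < `max_diff` pass. Genes absent from
#' the table pass with a warning.
#'
#' @param gene_id Character vector of genes to test.
#' @param expression `data.table` with `gene_id`, `endosperm`, `embryo`,
#'   `seed_coat` linear-scale means.
#' @param tissue Which compartment to compare against the seed coat.
#' @param max_diff Log2 difference cutoff (default 1).
#' @return Logical vector: passes the filter.
#' @export
seedcoat_filter <- function(gene_id, expression, tissue = "endosperm",
                            max_diff = 1) {
  expression <- data.table::as.data.table(expression)
  if (any(expression[[tissue]] < 0, na.rm = TRUE) ||
      any(expression$seed_coat < 0, na.rm = TRUE))
    stop("negative expression values")
  i <- match(gene_id, expression$gene_id)
  if (anyNA(i))
    warning(sum(is.na(i)), " genes absent from the expression table pass ",
            "the seed-coat filter")
  d <- log2(expression$seed_coat[i]) - log2(expression[[tissue]][i])
  ifelse(is.na(i), TRUE, d < max_diff)
}

#' Call imprinted genes from reciprocal-cross allele counts
#'
#' Per reciprocal cross pair and biological replicate: the exact dosage
#' test ([imprinting_test()]) is BH-corrected across all assessable genes
#' of that replicate pair; genes need adjusted p < `alpha`, imprinting
#' factor >= `min_if`, the seed-coat filter, and the maternal-fraction
#' cutoffs in both directions (endosperm MEG >= 0.85 maternal, PEG >= 0.50
#' paternal; embryo MEG >= 0.70 maternal, PEG < 0.30 maternal). Endosperm
#' genes must be called in at least `min_replicate_calls` of the replicate
#' pairs; embryo calls use the single replicate pair.
#'
#' @param counts Allele-count `data.table` (see [read_allele_counts()]).
#' @param expression Tissue-expression table for the seed-coat filter
#'   (`NULL` skips the filter).
#' @param params [imprinting_params()].
#' @return `data.table` with one row per gene x cross pair: `gene_id`,
#'   `strain_a`, `strain_b`, `tissue`, `status` (MEG/PEG/none/
#'   not_assessable), `p_adj` (median over assessable replicates),
#'   `imprinting_factor`, pooled maternal fractions per direction,
#'   `replicates_called`, `replicates_assessable` and a compact
#'   `filter_trail`.
#' @export
call_imprinting <- function(counts, expression = NULL,
                            params = imprinting_params()) {
  x <- data.table::as.data.table(counts)
  x[, pair_id := paste(pmin(mother, father), pmax(mother, father),
                       sep = "|")]
  out <- x[, call_one_pair(.SD, .BY$tissue, expression, params),
           by = .(pair_id, tissue)]
  out[, c("strain_a", "strain_b") := data.table::tstrsplit(pair_id, "|",
                                                           fixed = TRUE)]
  out[, pair_id := NULL]
  data.table::setcolorder(out, c("gene_id", "strain_a", "strain_b",
                                 "tissue"))
  out[]
}

# one reciprocal cross pair (both directions, all replicates) of one tissue
call_one_pair <- function(sd, tis, expression, params) {
  a <- min(sd$mother[1], sd$father[1]); b <- max(sd$mother[1], sd$father[1])
  wide <- merge(
    sd[mother == a, .(gene_id, replicate, m1 = maternal_reads,
                      p1 = paternal_reads)],
    sd[mother == b, .(gene_id, replicate, m2 = maternal_reads,
                      p2 = paternal_reads)],
    by = c("gene_id", "replicate"))
  n_expected <- data.table::uniqueN(sd$replicate)
  if (data.table::uniqueN(wide$replicate) < n_expected)
    warning("fewer reciprocal replicate pairs than replicates; ",
            "proceeding with available pairs")

  wide[, assessable := (m1 + p1) > 0 & (m2 + p2) > 0]
  wide[, p_raw := NA_real_]
  wide[assessable == TRUE,
       p_raw := imprinting_test(m1, p1, m2, p2, tissue = tis,
                                mode = params$test_mode)]
  wide[, p_adj := NA_real_]
  wide[assessable == TRUE, p_adj := p.adjust(p_raw, "BH"), by = replicate]
  wide[, `:=`(if_mat = imprinting_factor(m1, p1, m2, p2, "maternal", tis),
              if_pat = imprinting_factor(m1, p1, m2, p2, "paternal", tis),
              f1 = data.table::fifelse(m1 + p1 > 0, m1 / (m1 + p1),
                                       NA_real_),
              f2 = data.table::fifelse(m2 + p2 > 0, m2 / (m2 + p2),
                                       NA_real_))]
  sc <- if (is.null(expression)) rep(TRUE, nrow(wide)) else
    seedcoat_filter(wide$gene_id, expression,
                    tissue = if (tis == "embryo") "embryo" else "endosperm",
                    max_diff = params$seedcoat_max_diff)
  wide[, seedcoat_ok := sc]

  if (tis == "endosperm") {
    meg_cut <- params$meg_cutoff_endosperm
    wide[, meg_rep := assessable & !is.na(p_adj) & p_adj < params$alpha &
           if_mat >= params$min_if & seedcoat_ok &
           f1 >= meg_cut & f2 >= meg_cut]
    wide[, peg_rep := assessable & !is.na(p_adj) & p_adj < params$alpha &
           if_pat >= params$min_if & seedcoat_ok &
           (1 - f1) >= params$peg_cutoff_endosperm &
           (1 - f2) >= params$peg_cutoff_endosperm]
    need <- params$min_replicate_calls
  } else {
    wide[, meg_rep := assessable & !is.na(p_adj) & p_adj < params$alpha &
           if_mat >= params$min_if & seedcoat_ok &
           f1 >= params$meg_cutoff_embryo & f2 >= params$meg_cutoff_embryo]
    wide[, peg_rep := assessable & !is.na(p_adj) & p_adj < params$alpha &
           if_pat >= params$min_if & seedcoat_ok &
           f1 < params$peg_cutoff_embryo & f2 < params$peg_cutoff_embryo]
    need <- 1L
  }

  trail <- wide[, .(trail = paste(sprintf(
    "rep%s:p%s,ifm%.2g,ifp%.2g,sc%s,f%.2f/%.2f",
    replicate,
    data.table::fifelse(is.na(p_adj), "NA",
                        data.table::fifelse(p_adj < params$alpha, "+", "-")),
    if_mat, if_pat, data.table::fifelse(seedcoat_ok, "+", "-"), f1, f2),
    collapse = ";")), by = gene_id]

  agg <- wide[, .(
    n_assessable = sum(assessable),
    n_meg = sum(meg_rep), n_peg = sum(peg_rep),
    p_adj = if (any(assessable)) stats::median(p_adj[assessable]) else
      NA_real_,
    if_mat = stats::median(if_mat), if_pat = stats::median(if_pat),
    f1 = sum(m1) / pmax(sum(m1) + sum(p1), 1L),
    f2 = sum(m2) / pmax(sum(m2) + sum(p2), 1L)), by = gene_id]
  agg[, status := data.table::fcase(
    n_assessable == 0L, "not_assessable",
    n_meg >= min(need, n_assessable) & n_meg > 0L & n_meg >= n_peg, "MEG",
    n_peg >= min(need, n_assessable) & n_peg > 0L & n_peg > n_meg, "PEG",
    default = "none")]
  agg[, imprinting_factor := data.table::fifelse(status == "PEG", if_pat,
                                                 if_mat)]
  out <- merge(agg, trail, by = "gene_id")
  out[, .(gene_id, status, p_adj, imprinting_factor,
          maternal_fraction_dir1 = f1, maternal_fraction_dir2 = f2,
          replicates_called = pmax(n_meg, n_peg),
          replicates_assessable = n_assessable, filter_trail = trail)]
}

#' Exact binomial test against the 2:3 maternal:total ratio
#'
#' Used to validate clone counts: under biallelic endosperm expression the
#' expected maternal:total ratio is 2:3.
#'
#' @param maternal Maternal clone count.
#' @param total Total clone count (>= 1).
#' @param direction `"less"` or `"greater"`: tail of the alternative.
#' @param p_null Null maternal proportion (default 2/3).
#' @return One-sided exact binomial p-value.
#' @export
binomial_validation <- function(maternal, total,
                                direction = c("less", "greater"),
                                p_null = 2 / 3) {
  direction <- match.arg(direction)
  if (any(total == 0)) stop("total must be >= 1")
  stopifnot(maternal >= 0, maternal <= total)
  if (direction == "less") pbinom(maternal, total, p_null)
  else pbinom(maternal - 1, total, p_null, lower.tail = FALSE)
}
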