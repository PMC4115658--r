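# Sliding-window weighted-methylation DMR calling.
#
# Cytosine positions are 1-based on input; windows and DMRs use 0-based
# half-open intervals (BED convention). Weighted methylation of a region
# is pooled methylated reads over pooled total reads across informative
# sites -- not the mean of per-site fractions.

# expand cytosines to (window, site) pairs on the sliding grid
assign_windows <- function(cyt, window, step) {
  k_max <- (cyt$pos - 1L) %/% step
  k_min <- pmax(0L, as.integer(ceiling((cyt$pos - window) / step)))
  n_win <- k_max - k_min + 1L
  idx <- rep(seq_len(nrow(cyt)), n_win)
  win <- unlist(lapply(seq_len(nrow(cyt)),
                       function(i) k_min[i]:k_max[i]), use.names = FALSE)
  out <- cyt[idx]
  out[, win_start := win * step]
  out
}

#' Weighted methylation in sliding windows
#'
#' Pools counts over the cytosines of one context with at least `min_cov`
#' reads inside each window of a sliding grid (default 300 nt, step 200,
#' i.e. adjacent windows share 100 nt). Windows without informative sites
#' are omitted.
#'
#' @param cyt Cytosine `data.table` (`chrom`, `pos` 1-based, `context`,
#'   `meth`, `total`).
#' @param context Context to evaluate (CG/CHG/CHH).
#' @param window,step,min_cov See [dmr_params()].
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open),
#'   `context`, `n_informative`, `sum_meth`, `sum_total`, `wmeth`.
#' @export
window_methylation <- function(cyt, context = "CG", window = 300L,
                               step = 200L, min_cov = 5L) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  ctx <- context
  x <- data.table::as.data.table(cyt)[context == ctx]
  # counts split over several records at one position pool identically;
  # aggregate before the coverage filter so the split is invisible
  x <- x[, .(meth = sum(meth), total = sum(total)),
         by = .(chrom, pos, context)][total >= min_cov]
  if (!nrow(x))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), context = character(),
                                  n_informative = integer(),
                                  sum_meth = integer(),
                                  sum_total = integer(), wmeth = numeric()))
  ex <- assign_windows(x, as.integer(window), as.integer(step))
  out <- ex[, .(n_informative = .N, sum_meth = sum(meth),
                sum_total = sum(total)), by = .(chrom, win_start)]
  out[, `:=`(start = win_start, end = win_start + as.integer(window),
             context = ctx, wmeth = sum_meth / sum_total,
             win_start = NULL)]
  data.table::setorder(out, chrom, start)
  data.table::setcolorder(out, c("chrom", "start", "end", "context",
                                 "n_informative", "sum_meth", "sum_total",
                                 "wmeth"))
  out[]
}

# two-sided Fisher p for vectors of 2x2 cell counts, memoised on identical
# tables (window comparisons repeat the same small tables often)
fisher_p_vec <- function(a, b, c, d) {
  key <- paste(a, b, c, d)
  u <- !duplicated(key)
  pu <- mapply(function(a, b, c, d)
    fisher.test(matrix(c(a, b, c, d), 2L))$p.value,
    a[u], b[u], c[u], d[u])
  unname(pu[match(key, key[u])])
}

#' Compare two samples' methylation in sliding windows and call DMRs
#'
#' Both samples are restricted to cytosine positions informative
#' (`total >= min_cov`) in BOTH samples; weighted methylation and pooled
#' counts are recomputed on that shared set, so the difference, the
#' minimum-site rule and the Fisher test all see the same sites. Per
#' window, `diff_meth = wmeth_a - wmeth_b` and a two-sided Fisher exact
#' test on the pooled (meth, unmeth) table; BH correction across all
#' tested windows of the comparison. A window is a DMR when
#' `q < q_cutoff`, `|diff_meth| >= min_diff[context]` and
#' `n_shared >= min_shared[context]` (CG/CHG: 0.35 and 3; CHH: 0.10 and
#' 10).
#'
#' @param cyt_a,cyt_b Cytosine `data.table`s for the two samples.
#' @param context Context (CG/CHG/CHH).
#' @param params [dmr_params()].
#' @return `data.table` of all tested windows with `diff_meth`,
#'   `n_shared`, `p_raw`, `q` and logical `is_dmr`.
#' @export
compare_windows <- function(cyt_a, cyt_b, context = "CG",
                            params = dmr_params()) {
  ctx <- context
  prep <- function(cyt) {
    x <- data.table::as.data.table(cyt)[context == ctx]
    x[, .(meth = sum(meth), total = sum(total)), by = .(chrom, pos)]
  }
  a <- prep(cyt_a)[total >= params$min_cov]
  b <- prep(cyt_b)[total >= params$min_cov]
  shared <- merge(a, b, by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    context = character(), n_shared = integer(), wmeth_a = numeric(),
    wmeth_b = numeric(), diff_meth = numeric(), p_raw = numeric(),
    q = numeric(), is_dmr = logical())
  if (!nrow(shared)) return(empty)
  shared[, context := ctx]
  ex <- assign_windows(shared, params$window, params$step)
  win <- ex[, .(n_shared = .N,
                meth_a = sum(meth_a), tot_a = sum(total_a),
                meth_b = sum(meth_b), tot_b = sum(total_b)),
            by = .(chrom, win_start)]
  win[, `:=`(wmeth_a = meth_a / tot_a, wmeth_b = meth_b / tot_b)]
  win[, diff_meth := wmeth_a - wmeth_b]
  win[, p_raw := fisher_p_vec(meth_a, tot_a - meth_a,
                              meth_b, tot_b - meth_b)]
  win[, q := p.adjust(p_raw, "BH")]
  win[, is_dmr := q < params$q_cutoff &
        abs(diff_meth) >= params$min_diff[[ctx]] &
        n_shared >= params$min_shared[[ctx]]]
  win[, `:=`(start = win_start, end = win_start + params$window,
             context = ctx, win_start = NULL, meth_a = NULL, tot_a = NULL,
             meth_b = NULL, tot_b = NULL)]
  data.table::setorder(win, chrom, start)
  data.table::setcolorder(win, c("chrom", "start", "end", "context",
                                 "n_shared", "wmeth_a", "wmeth_b",
                                 "diff_meth", "p_raw", "q", "is_dmr"))
  win[]
}

#' Merge overlapping or book-ended DMR windows
#'
#' Windows of the same context and difference direction that overlap or
#' are contiguous are unioned; the merged record carries the minimum q,
#' the maximum absolute difference (with its sign) and the total span.
#'
#' @param windows DMR window `data.table` (rows with `is_dmr = TRUE` of
#'   [compare_windows()], or any table with `chrom`, `start`, `end`,
#'   `context`, `diff_meth`, `q`, `n_shared`, `p_raw`).
#' @return Merged DMR `data.table`.
#' @export
merge_dmrs <- function(windows) {
  x <- data.table::as.data.table(windows)
  if ("is_dmr" %in% names(x)) x <- x[is_dmr == TRUE]
  if (!nrow(x))
    return(data.table::data.table(dmr_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  context = character(),
                                  direction = character(),
                                  diff_meth = numeric(), q = numeric(),
                                  n_shared = integer(), p_raw = numeric()))
  x[, direction := data.table::fifelse(diff_meth >= 0, "+", "-")]
  out <- x[, {
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start + 1L, end))
    red <- GenomicRanges::reduce(gr)            # merges book-ended runs
    ov <- GenomicRanges::findOverlaps(gr, red)
    grp <- S4Vectors::subjectHits(ov)
    dt <- data.table::data.table(grp = grp, diff_meth, q, n_shared, p_raw)
    agg <- dt[, .(diff_meth = diff_meth[which.max(abs(diff_meth))],
                  q = min(q), p_raw = min(p_raw),
                  n_shared = max(n_shared)), by = grp]
    data.table::data.table(
      start = GenomicRanges::start(red)[agg$grp] - 1L,
      end = GenomicRanges::end(red)[agg$grp],
      diff_meth = agg$diff_meth, q = agg$q, p_raw = agg$p_raw,
      n_shared = agg$n_shared)
  }, by = .(chrom, context, direction)]
  data.table::setorder(out, chrom, start)
  out[, dmr_id := sprintf("DMR%04d", .I)]
  data.table::setcolorder(out, c("dmr_id", "chrom", "start", "end",
                                 "context", "direction", "diff_meth", "q",
                                 "n_shared", "p_raw"))
  out[]
}

#' Annotate DMRs with overlapping features
#'
#' A DMR overlapping at least 1 bp of a feature is assigned to it (it may
#' hit several); DMRs hitting nothing are intergenic.
#'
#' @param dmrs DMR `data.table` (`dmr_id`, `chrom`, `start`, `end`).
#' @param features Feature `data.table` (`chrom`, `start`, `end`,
#'   `feature_id`, `feature_type`).
#' @return List with `hits` (`dmr_id`, `feature_id`, `feature_type`;
#'   intergenic DMRs have NA feature) and `summary` (distinct features
#'   per class plus intergenic DMR count).
#' @export
annotate_dmrs <- function(dmrs, features) {
  d <- data.table::as.data.table(dmrs)
  f <- data.table::as.data.table(features)
  gr_d <- GenomicRanges::GRanges(d$chrom,
                                 IRanges::IRanges(d$start + 1L, d$end))
  gr_f <- GenomicRanges::GRanges(f$chrom,
                                 IRanges::IRanges(f$start + 1L, f$end))
  ov <- GenomicRanges::findOverlaps(gr_d, gr_f)
  hits <- data.table::data.table(
    dmr_id = d$dmr_id[S4Vectors::queryHits(ov)],
    feature_id = f$feature_id[S4Vectors::subjectHits(ov)],
    feature_type = f$feature_type[S4Vectors::subjectHits(ov)])
  orphan <- setdiff(d$dmr_id, hits$dmr_id)
  if (length(orphan))
    hits <- rbind(hits, data.table::data.table(
      dmr_id = orphan, feature_id = NA_character_,
      feature_type = "intergenic"))
  smry <- hits[feature_type != "intergenic",
               .(n_features = data.table::uniqueN(feature_id)),
               by = feature_type]
  smry <- rbind(smry, data.table::data.table(
    feature_type = "intergenic", n_features = length(orphan)))
  list(hits = hits[order(dmr_id)], summary = smry)
}

#' Weighted methylation of an arbitrary region
#'
#' @param cyt Cytosine `data.table` of one sample.
#' @param chrom,start,end Region (0-based half-open).
#' @param context Context.
#' @param min_cov Minimum reads per informative site.
#' @return Pooled methylated/total fraction, or `NA` if the region has no
#'   informative site.
#' @export
region_wmeth <- function(cyt, chrom, start, end, context = "CG",
                         min_cov = 5L) {
  ch <- chrom; ctx <- context
  x <- data.table::as.data.table(cyt)
  x <- x[chrom == ch & context == ctx & pos > start & pos <= end &
           total >= min_cov]
  if (!nrow(x)) return(NA_real_)
  sum(x$meth) / sum(x$total)
}

#' Average methylation metaprofile over a feature set
#'
#' Fixed-width flank bins upstream and downstream plus a scaled gene body:
#' per feature, weighted methylation per bin; the profile is the mean over
#' features ignoring missing bins. Minus-strand features are
#' coordinate-reversed so the profile reads 5' to 3'.
#'
#' @param cyt Cytosine `data.table` of one sample.
#' @param features Stranded feature `data.table`.
#' @param context Context.
#' @param flank Flank size in bp (default 2000).
#' @param bin Flank bin width in bp (default 200).
#' @param body_bins Number of scaled body bins (default 20).
#' @param min_cov Minimum reads per informative site.
#' @return `data.table` with `bin` index, `zone`
#'   (upstream/body/downstream), `wmeth` (mean over features) and
#'   `n_features` contributing.
#' @export
metaprofile <- function(cyt, features, context = "CG", flank = 2000L,
                        bin = 200L, body_bins = 20L, min_cov = 5L) {
  ctx <- context
  x <- data.table::as.data.table(cyt)[context == ctx & total >= min_cov]
  f <- data.table::as.data.table(features)
  n_flank <- as.integer(flank / bin)
  n_bins <- 2L * n_flank + body_bins
  prof <- matrix(NA_real_, nrow(f), n_bins)
  for (i in seq_len(nrow(f))) {
    fe <- f[i]
    cc <- x[chrom == fe$chrom & pos > fe$start - flank &
              pos <= fe$end + flank]
    if (!nrow(cc)) next
    p0 <- cc$pos - 1L
    rel <- numeric(nrow(cc))
    up <- p0 < fe$start
    dn <- p0 >= fe$end
    body <- !up & !dn
    # map to [0, n_bins): flank bins absolute, body bins scaled
    rel[up] <- (p0[up] - (fe$start - flank)) / bin
    rel[body] <- n_flank + (p0[body] - fe$start) /
      (fe$end - fe$start) * body_bins
    rel[dn] <- n_flank + body_bins + (p0[dn] - fe$end) / bin
    b <- pmin(floor(rel), n_bins - 1L) + 1L
    if (identical(fe$strand, "-")) b <- n_bins + 1L - b
    agg <- data.table::data.table(b = b, meth = cc$meth, total = cc$total)[
      , .(w = sum(meth) / sum(total)), by = b]
    prof[i, agg$b] <- agg$w
  }
  data.table::data.table(
    bin = seq_len(n_bins),
    zone = rep(c("upstream", "body", "downstream"),
               c(n_flank, body_bins, n_flank)),
    wmeth = colMeans(prof, na.rm = TRUE),
    n_features = colSums(!is.na(prof)))
}

#' Compare per-feature methylation across strains
#'
#' Scales each strain's per-feature weighted methylation by the reference
#' strain's mean, tests for a strain effect by one-way ANOVA and reports
#' Tukey HSD pairwise differences at `alpha`.
#'
#' @param feature_meth `data.table` with `feature_id`, `strain`, `wmeth`.
#' @param ref_strain Reference strain for scaling (default first).
#' @param alpha Tukey HSD significance level (default 0.05).
#' @return List with `anova_p`, `pairs` (`pair`, `mean_rel_diff`,
#'   `p_adj`, `significant`) and the scaled long table.
#' @export
compare_strain_feature_methylation <- function(feature_meth,
                                               ref_strain = NULL,
                                               alpha = 0.05) {
  x <- data.table::as.data.table(feature_meth)
  x <- x[!is.na(wmeth)]
  if (data.table::uniqueN(x$strain) < 2L) stop("need at least 2 strains")
  if (any(x[, .N, by = strain]$N < 2L))
    stop("each strain needs at least 2 features")
  if (is.null(ref_strain)) ref_strain <- sort(unique(x$strain))[1]
  ref_mean <- x[strain == ref_strain, mean(wmeth)]
  if (is.na(ref_mean) || ref_mean == 0)
    stop("reference strain mean is zero or missing")
  x <- data.table::copy(x)
  x[, value := wmeth / ref_mean]
  fit <- aov(value ~ strain, data = x)
  an_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$strain
  pairs <- data.table::data.table(pair = rownames(tk),
                                  mean_rel_diff = tk[, "diff"],
                                  p_adj = tk[, "p adj"])
  pairs[, significant := p_adj < alpha]
  list(anova_p = an_p, pairs = pairs[], scaled = x[])
}
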