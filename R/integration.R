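# Gene-DMR association, enrichment and TE proximity.

#' Associate genes with DMRs within the gene body and 2 kb flanks
#'
#' A gene is associated with every DMR overlapping its body or its 2 kb
#' 5'/3' flanks (strand-aware). Body overlap takes precedence; otherwise
#' the relation is `upstream_2kb`/`downstream_2kb` with the distance from
#' the nearest gene end.
#'
#' @param genes Stranded feature `data.table` (0-based half-open).
#' @param dmrs DMR `data.table` (`dmr_id`, `chrom`, `start`, `end`).
#' @param flank Flank size in bp (default 2000).
#' @return `data.table` with `gene_id`, `dmr_id`, `relation`, `distance`.
#' @export
associate_genes_dmrs <- function(genes, dmrs, flank = 2000L) {
  g <- data.table::as.data.table(genes)
  d <- data.table::as.data.table(dmrs)
  empty <- data.table::data.table(gene_id = character(),
                                  dmr_id = character(),
                                  relation = character(),
                                  distance = integer())
  if (!nrow(g) || !nrow(d)) return(empty)
  gr_g <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(pmax(g$start + 1L - flank,
                                                       1L),
                                                  g$end + flank))
  gr_d <- GenomicRanges::GRanges(d$chrom,
                                 IRanges::IRanges(d$start + 1L, d$end))
  ov <- GenomicRanges::findOverlaps(gr_d, gr_g)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  ds <- d$start[qi]; de <- d$end[qi]
  gs <- g$start[si]; ge <- g$end[si]
  body <- ds < ge & de > gs
  left <- de <= gs            # DMR entirely left of the gene
  # strand-aware: left of a + gene is upstream, left of a - gene downstream
  minus <- g$strand[si] == "-"
  rel <- ifelse(body, "body",
                ifelse(xor(left, minus), "upstream_2kb", "downstream_2kb"))
  dist <- ifelse(body, 0L, ifelse(left, gs - de, ds - ge))
  data.table::data.table(gene_id = g$feature_id[si],
                         dmr_id = d$dmr_id[qi],
                         relation = rel, distance = as.integer(dist))
}

#' Fisher enrichment of an association among a gene set
#'
#' 2x2 Fisher exact test of query vs the rest of the background against
#' associated vs not.
#'
#' @param query_genes Character vector (subset of `background_genes`).
#' @param flagged Character vector of associated genes.
#' @param background_genes Character vector of assessable genes.
#' @return List with `p_value`, `fold` (query rate / background rate),
#'   `query_rate`, `background_rate` and the 2x2 `table`.
#' @export
enrichment_test <- function(query_genes, flagged, background_genes) {
  if (!length(background_genes)) stop("empty background")
  if (!length(query_genes)) stop("empty query set")
  if (!all(query_genes %in% background_genes))
    stop("query genes must be a subset of the background")
  q <- unique(query_genes); bg <- unique(background_genes)
  rest <- setdiff(bg, q)
  tab <- matrix(c(sum(q %in% flagged), sum(!q %in% flagged),
                  sum(rest %in% flagged), sum(!rest %in% flagged)), 2L,
                dimnames = list(c("associated", "not"),
                                c("query", "rest")))
  qr <- tab[1, 1] / length(q)
  br <- (tab[1, 1] + tab[1, 2]) / length(bg)
  list(p_value = fisher.test(tab)$p.value,
       fold = if (br > 0) qr / br else NA_real_,
       query_rate = qr, background_rate = br, table = tab)
}

#' Binary TE presence around genes in fixed bins
#'
#' 200-bp bins spanning 2 kb upstream, the first 1 kb of the gene body and
#' 2 kb downstream, oriented 5' to 3' per gene; a bin is 1 when any TE
#' overlaps it.
#'
#' @param genes Stranded feature `data.table`.
#' @param tes TE feature `data.table`.
#' @param flank Flank size (default 2000).
#' @param bin Bin width (default 200).
#' @param body_extent Bp of gene body binned from the 5' end (default
#'   1000).
#' @return Integer matrix genes x bins (0/1).
#' @export
te_proximity <- function(genes, tes, flank = 2000L, bin = 200L,
                         body_extent = 1000L) {
  g <- data.table::as.data.table(genes)
  t <- data.table::as.data.table(tes)
  n_flank <- as.integer(flank / bin)
  n_body <- as.integer(body_extent / bin)
  n_bins <- 2L * n_flank + n_body
  out <- matrix(0L, nrow(g), n_bins,
                dimnames = list(g$feature_id, NULL))
  if (!nrow(t)) return(out)
  for (i in seq_len(nrow(g))) {
    ge <- g[i]
    fwd <- !identical(ge$strand, "-")
    glen <- ge$end - ge$start
    for (k in seq_len(n_bins)) {
      if (k <= n_flank) {               # upstream of the 5' end
        off_lo <- (k - 1L - n_flank) * bin; off_hi <- off_lo + bin
      } else if (k <= n_flank + n_body) {  # into the body from the 5' end
        off_lo <- (k - 1L - n_flank) * bin
        off_hi <- min(off_lo + bin, glen)
        if (off_lo >= glen) next        # short gene: bin beyond the body
      } else {                          # past the 3' end
        j <- k - n_flank - n_body
        off_lo <- glen + (j - 1L) * bin; off_hi <- off_lo + bin
      }
      if (fwd) { lo <- ge$start + off_lo; hi <- ge$start + off_hi }
      else { lo <- ge$end - off_hi; hi <- ge$end - off_lo }
      hit <- t[chrom == ge$chrom & start < hi & end > lo]
      if (nrow(hit)) out[i, k] <- 1L
    }
  }
  out
}
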