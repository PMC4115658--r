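# Population methylation-variability classification of merged DMRs.

VARIABILITY_CLASSES <- c("very_low", "low", "not_bimodal",
                         "weakly_bimodal", "strongly_bimodal", "censored")

#' Score one merged DMR across strains
#'
#' Per strain, the weighted methylation over CG sites with at least
#' `min_cov` reads inside the DMR; strains with fewer than `min_sites`
#' qualifying sites get a missing score.
#'
#' @param dmr One-row `data.table` (`chrom`, `start`, `end`, 0-based
#'   half-open) or a list with those fields.
#' @param strain_cyt Named list of cytosine `data.table`s, one per strain.
#' @param min_sites Minimum qualifying CG sites per strain (default 5).
#' @param min_cov Minimum reads per site (default 5).
#' @param context Context to score (default CG).
#' @return Named numeric vector of per-strain scores (NA = missing).
#' @export
score_dmr <- function(dmr, strain_cyt, min_sites = 5L, min_cov = 5L,
                      context = "CG") {
  if (dmr$end <= dmr$start) stop("empty DMR interval")
  ctx <- context
  vapply(strain_cyt, function(cyt) {
    x <- data.table::as.data.table(cyt)
    x <- x[chrom == dmr$chrom & context == ctx & pos > dmr$start &
             pos <= dmr$end & total >= min_cov]
    if (nrow(x) < min_sites) return(NA_real_)
    sum(x$meth) / sum(x$total)
  }, numeric(1))
}

#' Classify the population variability of one DMR score vector
#'
#' Let R be the range of present scores and f the fraction of present
#' scores strictly inside the outer quarter-bands of the range
#' (score < min + 0.25 R or score > max - 0.25 R; scores exactly at a band
#' boundary count as middle). Classes:
#' \itemize{
#'   \item `censored`: more than `max_missing` strains missing (or fewer
#'     than 2 present);
#'   \item `very_low`: R < 0.2;
#'   \item `low`: 0.2 <= R < 0.4;
#'   \item `strongly_bimodal`: R > 0.7 and f >= 0.8;
#'   \item `weakly_bimodal`: (R > 0.7 and f >= 0.5) or
#'     (0.4 <= R <= 0.7 and f >= 0.8);
#'   \item `not_bimodal`: everything else.
#' }
#'
#' @param scores Numeric vector of per-strain scores in `[0, 1]`, NA =
#'   missing.
#' @param max_missing Maximum missing strains before censoring; default 70
#'   for a 140-strain population, otherwise `ceiling(n / 2)`.
#' @return List with `class`, `range`, `outer_fraction`, `n_present`.
#' @export
classify_variability <- function(scores, max_missing = NULL) {
  n <- length(scores)
  if (is.null(max_missing)) max_missing <- if (n == 140L) 70L else
    ceiling(n / 2)
  present <- scores[!is.na(scores)]
  n_missing <- n - length(present)
  if (length(present) && (min(present) < 0 || max(present) > 1))
    stop("scores must lie in [0, 1]")
  if (n_missing > max_missing || length(present) < 2L)
    return(list(class = "censored", range = NA_real_,
                outer_fraction = NA_real_,
                n_present = length(present)))
  lo <- min(present); hi <- max(present)
  R <- hi - lo
  f <- if (R == 0) 0 else
    mean(present < lo + 0.25 * R | present > hi - 0.25 * R)
  cls <- if (R < 0.2) "very_low"
  else if (R < 0.4) "low"
  else if (R > 0.7 && f >= 0.8) "strongly_bimodal"
  else if ((R > 0.7 && f >= 0.5) || (R >= 0.4 && R <= 0.7 && f >= 0.8))
    "weakly_bimodal"
  else "not_bimodal"
  list(class = cls, range = R, outer_fraction = f,
       n_present = length(present))
}

#' Classify all DMRs of a score matrix
#'
#' @param scores Matrix DMR x strain (rownames = DMR ids, NA = missing),
#'   e.g. from [simulate_population_matrix()] or [read_score_matrix()].
#' @param max_missing Passed to [classify_variability()].
#' @return List with `table` (`dmr_id`, `class`, `range`,
#'   `outer_fraction`, `n_present`) and `summary` (class fractions).
#' @export
classify_all <- function(scores, max_missing = NULL) {
  if (is.null(rownames(scores))) rownames(scores) <-
      sprintf("DMR%04d", seq_len(nrow(scores)))
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    cl <- classify_variability(scores[i, ], max_missing = max_missing)
    data.table::data.table(dmr_id = rownames(scores)[i], class = cl$class,
                           range = cl$range,
                           outer_fraction = cl$outer_fraction,
                           n_present = cl$n_present)
  })
  tab <- data.table::rbindlist(rows)
  if (!nrow(tab))
    return(list(table = tab,
                summary = data.table::data.table(class = character(),
                                                 n = integer(),
                                                 fraction = numeric())))
  smry <- tab[, .(n = .N), by = class][, fraction := n / sum(n)][]
  list(table = tab, summary = smry)
}
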