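#' Default parameters for imprinting calls
#'
#' Thresholds of the reciprocal-cross imprinting caller. The endosperm null
#' maternal proportion is 2/3, reflecting the 2:1 maternal:paternal genome
#' dosage of the triploid endosperm; the embryo null is 1/2.
#'
#' @param alpha Benjamini-Hochberg adjusted p-value cutoff (default 0.01).
#' @param min_if Minimum imprinting factor (default 2).
#' @param meg_cutoff_endosperm Minimum maternal read fraction, both cross
#'   directions, for an endosperm MEG (default 0.85).
#' @param peg_cutoff_endosperm Minimum paternal read fraction, both
#'   directions, for an endosperm PEG (default 0.50).
#' @param meg_cutoff_embryo Minimum maternal fraction for an embryo MEG
#'   (default 0.70).
#' @param peg_cutoff_embryo Maximum maternal fraction for an embryo PEG
#'   (default 0.30, strict).
#' @param min_replicate_calls Replicate pairs (of 3) in which a gene must be
#'   called to be reported for endosperm (default 2).
#' @param seedcoat_max_diff Maximum allowed log2 seed-coat minus tissue
#'   expression difference (default 1, i.e. less than twofold higher in seed
#'   coat).
#' @param test_mode `"adjusted"` (halve maternal counts, central Fisher) or
#'   `"noncentral"` (raw counts, null odds ratio 4 for endosperm).
#' @return Named list of parameters.
#' @export
imprinting_params <- function(alpha = 0.01,
                              min_if = 2,
                              meg_cutoff_endosperm = 0.85,
                              peg_cutoff_endosperm = 0.50,
                              meg_cutoff_embryo = 0.70,
                              peg_cutoff_embryo = 0.30,
                              min_replicate_calls = 2,
                              seedcoat_max_diff = 1,
                              test_mode = c("adjusted", "noncentral")) {
  test_mode <- match.arg(test_mode)
  list(alpha = alpha, min_if = min_if,
       meg_cutoff_endosperm = meg_cutoff_endosperm,
       peg_cutoff_endosperm = peg_cutoff_endosperm,
       meg_cutoff_embryo = meg_cutoff_embryo,
       peg_cutoff_embryo = peg_cutoff_embryo,
       min_replicate_calls = min_replicate_calls,
       seedcoat_max_diff = seedcoat_max_diff,
       test_mode = test_mode,
       null_maternal = c(endosperm = 2 / 3, embryo = 1 / 2))
}

#' Default parameters for DMR calling
#'
#' Sliding-window weighted-methylation comparison. Windows are 300 nt and
#' adjacent windows share 100 nt (step 200). A cytosine is informative at
#' `min_cov` reads. CG and CHG DMR windows need an absolute weighted
#' methylation difference of at least 0.35 over at least 3 shared
#' informative cytosines; CHH windows at least 0.10 over at least 10;
#' all at BH-adjusted p < 0.01.
#'
#' @param window Window size in nt.
#' @param step Window step in nt (300 - 100 overlap = 200).
#' @param min_cov Minimum reads per cytosine to be informative.
#' @param q_cutoff BH-adjusted p-value cutoff.
#' @param min_diff Named vector of minimum absolute weighted-methylation
#'   differences per context.
#' @param min_shared Named vector of minimum shared informative cytosines
#'   per context.
#' @return Named list of parameters.
#' @export
dmr_params <- function(window = 300L, step = 200L, min_cov = 5L,
                       q_cutoff = 0.01,
                       min_diff = c(CG = 0.35, CHG = 0.35, CHH = 0.10),
                       min_shared = c(CG = 3L, CHG = 3L, CHH = 10L)) {
  stopifnot(window > 0, step > 0, min_cov >= 1)
  list(window = as.integer(window), step = as.integer(step),
       min_cov = as.integer(min_cov), q_cutoff = q_cutoff,
       min_diff = min_diff, min_shared = min_shared)
}

CONTEXTS <- c("CG", "CHG", "CHH")
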