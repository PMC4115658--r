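# Strain-dependent (allele-specific) imprinting detection.
#
# Works on the reciprocal ratio plane: for each cross pair, the ratio
# x = (m+1)/(p+1) of direction 1 against the same ratio y of direction 2.
# Non-imprinted endosperm loci sit near the lines x = 2 and y = 2.

#' Parental bias factor b(g)
#'
#' `b = log2(maternal + 1) - log2(2 * paternal + 1)`; zero at the 2:1
#' endosperm dosage expectation (e.g. m = 200, p = 100), positive for
#' maternal bias, negative for paternal bias.
#'
#' @param m,p Maternal and paternal read counts.
#' @return Numeric bias factor (vectorised).
#' @export
bias_factor <- function(m, p) {
  stopifnot(all(m >= 0), all(p >= 0))
  log2(m + 1) - log2(2 * p + 1)
}

#' Standardize bias factors across loci
#'
#' `(b - mean(b)) / sd(b)` with the sample (n - 1) standard deviation.
#'
#' @param b Numeric vector of bias factors (>= 2 loci).
#' @return Standardized scores with mean 0 and sample sd 1.
#' @export
normalize_bias <- function(b) {
  if (length(b) < 2L) stop("need at least 2 loci")
  s <- sd(b)
  if (s == 0) stop("zero standard deviation of bias factors")
  (b - mean(b)) / s
}

#' Detect strain-dependent imprinting
#'
#' Replicates are summed per gene and cross direction. For each reciprocal
#' cross pair, loci with informative reads in both directions (and passing
#' the seed-coat filter) are plotted on the ratio plane; loci within
#' distance 1 of either no-imprinting line (|x - 2| <= 1 or |y - 2| <= 1)
#' are retained. Per direction, b(g) is standardized over the retained
#' loci; a locus is flagged "maternally biased only when strain S is the
#' mother" when its S-mother direction exceeds the 95th percentile of
#' b_norm while the opposite direction lies within distance 1 of its line
#' (paternal bias: below the 5th percentile, symmetric). Flags are
#' intersected across the two cross pairs sharing each (strain, role), and
#' then with the MEG (maternal) or PEG (paternal) calls of the third cross
#' pair, yielding patterns such as "PEG except when S is the male parent".
#'
#' @param counts Allele-count `data.table` (endosperm reciprocal crosses of
#'   three strains; replicates are summed).
#' @param calls Imprinting calls from [call_imprinting()] on the same
#'   counts (provides the per-pair MEG/PEG lists).
#' @param expression Optional tissue-expression table for the seed-coat
#'   filter.
#' @param params [imprinting_params()].
#' @param percentile Upper tail probability for the b_norm flag
#'   (default 0.95; lower tail uses 1 - percentile).
#' @return `data.table` with `gene_id`, `type` (MEG/PEG), `strain`, `role`
#'   (parental role at which the imprint is lost) and a human-readable
#'   `pattern`.
#' @export
detect_allele_specific <- function(counts, calls, expression = NULL,
                                   params = imprinting_params(),
                                   percentile = 0.95) {
  x <- data.table::as.data.table(counts)
  strains <- sort(unique(c(x$mother, x$father)))
  if (length(strains) != 3L)
    stop("allele-specific detection needs exactly three strains")
  pooled <- x[, .(m = sum(maternal_reads), p = sum(paternal_reads)),
              by = .(gene_id, mother, father)]
  # pooled counts indexed by direction
  getdir <- function(mo, fa) {
    r <- pooled[mother == mo & father == fa]
    if (!nrow(r)) stop("missing reciprocal direction ", mo, " x ", fa)
    r
  }

  pairs <- utils::combn(strains, 2, simplify = FALSE)
  flags <- list()
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    d1 <- getdir(a, b); d2 <- getdir(b, a)
    g <- merge(d1[, .(gene_id, m1 = m, p1 = p)],
               d2[, .(gene_id, m2 = m, p2 = p)], by = "gene_id")
    g <- g[(m1 + p1) > 0 & (m2 + p2) > 0]
    if (!is.null(expression))
      g <- g[seedcoat_filter(gene_id, expression,
                             max_diff = params$seedcoat_max_diff)]
    g[, `:=`(x = (m1 + 1) / (p1 + 1), y = (m2 + 1) / (p2 + 1))]
    g <- g[abs(x - 2) <= 1 | abs(y - 2) <= 1]
    if (nrow(g) < 20L) next
    g[, `:=`(z1 = normalize_bias(bias_factor(m1, p1)),
             z2 = normalize_bias(bias_factor(m2, p2)))]
    q_hi1 <- quantile(g$z1, percentile, names = FALSE)
    q_lo1 <- quantile(g$z1, 1 - percentile, names = FALSE)
    q_hi2 <- quantile(g$z2, percentile, names = FALSE)
    q_lo2 <- quantile(g$z2, 1 - percentile, names = FALSE)

    add_flag <- function(genes, strain, role, type) {
      if (!length(genes)) return()
      flags[[length(flags) + 1L]] <<- data.table::data.table(
        gene_id = genes, strain = strain, role = role, type = type,
        pair = paste(a, b, sep = "|"))
    }
    # direction 1: a is mother, b is father; on-line check on direction 2
    mat1 <- g[z1 > q_hi1 & abs(y - 2) <= 1, gene_id]
    pat1 <- g[z1 < q_lo1 & abs(y - 2) <= 1, gene_id]
    # direction 2: b is mother, a is father; on-line check on direction 1
    mat2 <- g[z2 > q_hi2 & abs(x - 2) <= 1, gene_id]
    pat2 <- g[z2 < q_lo2 & abs(x - 2) <= 1, gene_id]
    add_flag(mat1, a, "mother", "maternal")
    add_flag(mat1, b, "father", "maternal")
    add_flag(pat1, a, "mother", "paternal")
    add_flag(pat1, b, "father", "paternal")
    add_flag(mat2, b, "mother", "maternal")
    add_flag(mat2, a, "father", "maternal")
    add_flag(pat2, b, "mother", "paternal")
    add_flag(pat2, a, "father", "paternal")
  }
  empty <- data.table::data.table(gene_id = character(), type = character(),
                                  strain = character(), role = character(),
                                  pattern = character())
  if (!length(flags)) return(empty)
  fl <- data.table::rbindlist(flags)

  calls <- data.table::as.data.table(calls)
  calls[, pair := paste(pmin(strain_a, strain_b),
                        pmax(strain_a, strain_b), sep = "|")]
  out <- list()
  for (s in strains) {
    s_pairs <- vapply(pairs, function(p) s %in% p, logical(1))
    other_pair <- paste(pairs[[which(!s_pairs)]], collapse = "|")
    for (role_v in c("mother", "father")) {
      for (type_v in c("maternal", "paternal")) {
        sets <- lapply(which(s_pairs), function(i) {
          pid <- paste(pairs[[i]], collapse = "|")
          fl[strain == s & role == role_v & type == type_v & pair == pid,
             gene_id]
        })
        consistent <- Reduce(intersect, sets)
        if (!length(consistent)) next
        want <- if (type_v == "maternal") "MEG" else "PEG"
        imprinted <- calls[pair == other_pair & status == want, gene_id]
        hit <- intersect(consistent, imprinted)
        if (!length(hit)) next
        lost_role <- if (role_v == "mother") "father" else "mother"
        parent <- if (lost_role == "father") "male" else "female"
        out[[length(out) + 1L]] <- data.table::data.table(
          gene_id = hit, type = want, strain = s, role = lost_role,
          pattern = sprintf("%s except when %s is the %s parent",
                            want, s, parent))
      }
    }
  }
  if (!length(out)) return(empty)
  unique(data.table::rbindlist(out))
}
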