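# Independent oracles, deliberately written straight from first principles
# (enumeration / prose transliteration), never calling the package's own
# code paths.

# Two-sided Fisher exact p for the 2x2 table [[a, b], [c, d]] by full
# hypergeometric enumeration with the probability-summation rule (masses
# <= observed * (1 + 1e-7) are summed, the same tie rule R uses).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0L, c1 - r2):min(c1, r1)
  lp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(lp)
  p_obs <- exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(n, c1))
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Straight-line transliteration of the five-class variability rules.
variability_oracle <- function(scores, max_missing = 70L) {
  present <- scores[!is.na(scores)]
  if ((length(scores) - length(present)) > max_missing ||
      length(present) < 2) return("censored")
  R <- max(present) - min(present)
  if (R == 0) f <- 0 else {
    lo_band <- min(present) + 0.25 * R
    hi_band <- max(present) - 0.25 * R
    f <- sum(present < lo_band | present > hi_band) / length(present)
  }
  if (R < 0.2) return("very_low")
  if (R < 0.4) return("low")
  if (R > 0.7 && f >= 0.8) return("strongly_bimodal")
  if (R > 0.7 && f >= 0.5) return("weakly_bimodal")
  if (R >= 0.4 && R <= 0.7 && f >= 0.8) return("weakly_bimodal")
  "not_bimodal"
}

# Brute-force strict containment counting: a read counts for a feature iff
# its interval lies fully inside that feature and inside no other.
strict_count_oracle <- function(reads, features, mother, father) {
  res <- setNames(rep(0L, 2L * nrow(features)), NULL)
  mat <- setNames(integer(nrow(features)), features$feature_id)
  pat <- mat
  for (i in seq_len(nrow(reads))) {
    rs <- reads$start[i]; re <- rs + nchar(reads$sequence[i])
    inside <- which(features$chrom == reads$chrom[i] &
                      features$start <= rs & features$end >= re)
    if (length(inside) != 1L) next
    if (reads$origin[i] == mother)
      mat[inside] <- mat[inside] + 1L
    else if (reads$origin[i] == father)
      pat[inside] <- pat[inside] + 1L
  }
  list(maternal = mat, paternal = pat)
}

# Textbook Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

# Small helper: random 2x2 tables with all margins <= max_margin.
random_tables <- function(n, max_margin = 60L) {
  t(replicate(n, {
    repeat {
      a <- sample(0:max_margin, 1); b <- sample(0:(max_margin - a), 1)
      c <- sample(0:(max_margin - a), 1)
      d_max <- min(max_margin - b, max_margin - c)
      if (d_max >= 0) {
        d <- sample(0:d_max, 1)
        if (a + b + c + d > 0) return(c(a, b, c, d))
      }
    }
  }))
}
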