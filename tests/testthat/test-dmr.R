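# windowed weighted methylation and DMR calling

dt <- data.table::data.table

cx <- function(pos, meth, total, context = "CG", strand = "+",
               chrom = "chr1") {
  dt(chrom = chrom, pos = pos, strand = strand, context = context,
     meth = meth, total = total)
}

test_that("window_methylation pools counts (weighted, not per-site mean)", {
  w <- window_methylation(cx(50L, 5L, 10L), "CG")
  expect_equal(w$wmeth, 0.5)
  # (4/5, 1/20) -> 5/25 = 0.2, not the per-site mean 0.425
  w2 <- window_methylation(cx(c(50L, 60L), c(4L, 1L), c(5L, 20L)), "CG")
  expect_equal(w2[start == 0, wmeth], 0.2)
  # below-coverage site excluded
  w3 <- window_methylation(cx(c(50L, 60L), c(4L, 4L), c(4L, 10L)), "CG")
  expect_equal(w3[start == 0, n_informative], 1L)
  expect_equal(w3[start == 0, wmeth], 0.4)
  expect_error(window_methylation(cx(1L, 1L, 5L), "CG", window = 0),
               "positive")
})

test_that("windows tile with 100-nt overlap and positions land in the right
          windows", {
  # pos 250 (1-based) lies in [0,300) and [200,500)
  w <- window_methylation(cx(250L, 5L, 10L), "CG")
  expect_equal(sort(w$start), c(0L, 200L))
  expect_true(all(w$end - w$start == 300L))
  # pos 201 lies in [0,300) and [200,500); pos 200 only in [0,300)
  expect_equal(sort(window_methylation(cx(201L, 1L, 5L), "CG")$start),
               c(0L, 200L))
  expect_equal(window_methylation(cx(200L, 1L, 5L), "CG")$start, 0L)
})

test_that("wmeth is invariant to splitting a site's counts across records", {
  whole <- window_methylation(cx(c(50L, 80L), c(6L, 2L), c(10L, 10L)), "CG")
  split <- window_methylation(
    cx(c(50L, 50L, 80L), c(4L, 2L, 2L), c(7L, 3L, 10L)), "CG")
  expect_equal(split$wmeth, whole$wmeth)
  expect_equal(split$n_informative, whole$n_informative)
})

test_that("compare_windows restricts to shared informative sites and applies
          context thresholds", {
  # identical samples: diff 0, p 1, no DMR
  a <- cx(seq(10L, 290L, 40L), 5L, 10L)
  w <- compare_windows(a, a, "CG")
  expect_true(all(w$diff_meth == 0))
  expect_true(all(w$p_raw == 1))
  expect_false(any(w$is_dmr))

  # 3 shared CG sites, 30/30 vs 0/30 -> diff 1, q << 0.01 -> DMR
  b1 <- cx(c(50L, 100L, 150L), 10L, 10L)
  b2 <- cx(c(50L, 100L, 150L), 0L, 10L)
  w2 <- compare_windows(b1, b2, "CG")
  expect_true(w2[start == 0, is_dmr])
  expect_equal(w2[start == 0, diff_meth], 1.0)
  expect_equal(w2[start == 0, n_shared], 3L)
  expect_equal(w2[start == 0, p_raw], fisher_oracle(30, 0, 0, 30),
               tolerance = 1e-12)

  # a site informative in only one sample is excluded from the shared set
  b3 <- cx(c(50L, 100L, 150L), 10L, 10L)
  b4 <- rbind(cx(c(50L, 100L), 0L, 10L), cx(150L, 0L, 4L))
  w3 <- compare_windows(b3, b4, "CG")
  expect_equal(w3[start == 0, n_shared], 2L)
  expect_false(w3[start == 0, is_dmr])        # < 3 shared CG sites

  # CHH: diff 0.12 over 9 shared sites fails the 10-site rule
  pos9 <- seq(10L, 170L, 20L)
  c1 <- cx(pos9, 22L, 100L, context = "CHH")
  c2 <- cx(pos9, 10L, 100L, context = "CHH")
  w4 <- compare_windows(c1, c2, "CHH")
  expect_equal(w4[start == 0, n_shared], 9L)
  expect_equal(w4[start == 0, diff_meth], 0.12)
  expect_false(w4[start == 0, is_dmr])
  # same difference over 10 sites passes
  pos10 <- seq(10L, 190L, 20L)
  w5 <- compare_windows(cx(pos10, 22L, 100L, context = "CHH"),
                        cx(pos10, 10L, 100L, context = "CHH"), "CHH")
  expect_true(w5[start == 0, is_dmr])
})

test_that("compare_windows is antisymmetric", {
  set.seed(12)
  pos <- sort(sample(1:5000, 200))
  tot <- rpois(200, 12)
  a <- cx(pos, rbinom(200, tot, 0.6), tot)
  tot2 <- rpois(200, 12)
  b <- cx(pos, rbinom(200, tot2, 0.3), tot2)
  ab <- compare_windows(a, b, "CG")
  ba <- compare_windows(b, a, "CG")
  expect_equal(ab$diff_meth, -ba$diff_meth)
  expect_equal(ab$p_raw, ba$p_raw)
  expect_equal(ab$is_dmr, ba$is_dmr)
})

test_that("Fisher window p-values match enumeration for pooled counts", {
  set.seed(13)
  tabs <- random_tables(40, 60)
  for (i in seq_len(nrow(tabs))) {
    me_a <- tabs[i, 1]; un_a <- tabs[i, 2]
    me_b <- tabs[i, 3]; un_b <- tabs[i, 4]
    tot_a <- me_a + un_a; tot_b <- me_b + un_b
    if (tot_a == 0 || tot_b == 0) next
    w <- compare_windows(cx(50L, me_a, tot_a), cx(50L, me_b, tot_b), "CG",
                         params = dmr_params(min_cov = 1L))
    expect_equal(w$p_raw[1], fisher_oracle(me_a, un_a, me_b, un_b),
                 tolerance = 1e-12)
  }
})

test_that("merge_dmrs unions overlapping and book-ended windows per
          direction", {
  win <- dt(chrom = "chr1", start = c(0L, 200L, 600L),
            end = c(300L, 500L, 900L), context = "CG",
            diff_meth = c(0.5, 0.6, 0.4), q = c(1e-5, 1e-8, 1e-4),
            n_shared = c(5L, 6L, 4L), p_raw = c(1e-6, 1e-9, 1e-5),
            is_dmr = TRUE)
  m <- merge_dmrs(win)
  expect_equal(nrow(m), 2)
  expect_equal(m[start == 0, end], 500L)          # overlap union
  expect_equal(m[start == 0, q], 1e-8)
  expect_equal(m[start == 0, diff_meth], 0.6)     # max |diff| carried
  # book-ended windows merge
  win2 <- dt(chrom = "chr1", start = c(0L, 300L), end = c(300L, 600L),
             context = "CG", diff_meth = 0.5, q = 1e-5, n_shared = 3L,
             p_raw = 1e-6, is_dmr = TRUE)
  expect_equal(merge_dmrs(win2)[, .(start, end)], dt(start = 0L, end = 600L))
  # opposite directions never merge
  win3 <- dt(chrom = "chr1", start = c(0L, 200L), end = c(300L, 500L),
             context = "CG", diff_meth = c(0.5, -0.5), q = 1e-5,
             n_shared = 3L, p_raw = 1e-6, is_dmr = TRUE)
  expect_equal(nrow(merge_dmrs(win3)), 2)
  # disjoint windows stay separate
  win4 <- dt(chrom = "chr1", start = c(0L, 400L), end = c(300L, 700L),
             context = "CG", diff_meth = 0.5, q = 1e-5, n_shared = 3L,
             p_raw = 1e-6, is_dmr = TRUE)
  expect_equal(nrow(merge_dmrs(win4)), 2)
})

test_that("annotate_dmrs assigns by >= 1 bp overlap", {
  feats <- dt(chrom = "chr1", start = c(100L, 500L), end = c(400L, 800L),
              feature_id = c("geneX", "TE1"), strand = "+",
              feature_type = c("gene", "TE"))
  dmrs <- dt(dmr_id = c("d1", "d2", "d3"), chrom = "chr1",
             start = c(150L, 350L, 900L), end = c(250L, 550L, 950L))
  ann <- annotate_dmrs(dmrs, feats)
  expect_equal(ann$hits[dmr_id == "d1", feature_id], "geneX")
  expect_equal(sort(ann$hits[dmr_id == "d2", feature_id]),
               c("TE1", "geneX"))                 # spans the boundary
  expect_equal(ann$hits[dmr_id == "d3", feature_type], "intergenic")
  expect_equal(ann$summary[feature_type == "gene", n_features], 1L)
  expect_equal(ann$summary[feature_type == "intergenic", n_features], 1L)
})

test_that("region_wmeth pools informative sites of a region", {
  cyt <- cx(c(100L, 200L, 300L), c(10L, 0L, 7L), c(10L, 10L, 10L))
  expect_equal(region_wmeth(cyt, "chr1", 0L, 250L), 0.5)
  expect_equal(region_wmeth(cyt, "chr1", 250L, 400L), 0.7)
  low <- cx(c(100L, 200L), c(1L, 1L), c(3L, 4L))
  expect_true(is.na(region_wmeth(low, "chr1", 0L, 250L)))
})

test_that("metaprofile averages features and mirrors minus-strand genes", {
  # an asymmetric profile: methylated only upstream of the + gene
  up <- cx(seq(10L, 1990L, 50L), 9L, 10L)
  body <- cx(seq(2010L, 3990L, 50L), 0L, 10L)
  cyt <- rbind(up, body)
  plus <- dt(chrom = "chr1", start = 2000L, end = 4000L,
             feature_id = "g+", strand = "+", feature_type = "gene")
  minus <- dt(chrom = "chr1", start = 2000L, end = 4000L,
              feature_id = "g-", strand = "-", feature_type = "gene")
  p_plus <- metaprofile(cyt, plus, flank = 2000L, bin = 200L,
                        body_bins = 10L)
  p_minus <- metaprofile(cyt, minus, flank = 2000L, bin = 200L,
                         body_bins = 10L)
  expect_equal(p_plus$wmeth, rev(p_minus$wmeth))
  expect_true(all(p_plus[zone == "upstream", wmeth] == 0.9))
  expect_true(all(p_plus[zone == "body", wmeth] == 0))
  # two features average bin-wise
  two <- metaprofile(rbind(cyt, cyt), rbind(plus, plus),
                     flank = 2000L, bin = 200L, body_bins = 10L)
  expect_equal(two[zone == "upstream", wmeth], rep(0.9, 10))
})

test_that("strain comparison scales to the reference and runs Tukey HSD", {
  set.seed(14)
  base <- runif(40, 0.2, 0.8)
  fm <- rbind(dt(feature_id = sprintf("f%02d", 1:40), strain = "Col",
                 wmeth = base),
              dt(feature_id = sprintf("f%02d", 1:40), strain = "Cvi",
                 wmeth = base * 0.5))
  res <- compare_strain_feature_methylation(fm, ref_strain = "Col")
  expect_lt(res$anova_p, 1e-6)
  # Cvi at half the Col level: relative difference about -50% of the
  # Col mean
  expect_equal(res$pairs$mean_rel_diff,
               -0.5 * mean(base) / mean(base), tolerance = 0.02)
  expect_true(res$pairs$significant)
  # identical strains: no significant difference
  fm2 <- rbind(dt(feature_id = sprintf("f%02d", 1:40), strain = "Col",
                  wmeth = base),
               dt(feature_id = sprintf("f%02d", 1:40), strain = "Ler",
                  wmeth = base))
  res2 <- compare_strain_feature_methylation(fm2, ref_strain = "Col")
  expect_equal(res2$pairs$mean_rel_diff, 0, tolerance = 1e-12)
  expect_false(res2$pairs$significant)
  expect_error(compare_strain_feature_methylation(
    dt(feature_id = "f1", strain = c("a", "b"), wmeth = 0.5)),
    "at least 2 features")
})
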