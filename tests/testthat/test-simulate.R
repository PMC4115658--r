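# synthetic-data generator: determinism, planted truth, stated null

test_that("truth_config validates its inputs", {
  expect_error(truth_config(depth_mean = 0), "positive")
  expect_error(truth_config(n_genes = 10, n_meg = 20), "more special")
  expect_error(truth_config(as_role = "uncle"), "mother/father")
  cfg <- truth_config(seed = 1, n_genes = 50, n_meg = 5, n_peg = 3,
                      n_as_peg = 2, n_seedcoat = 1)
  # every gene has exactly one class and appears once in the truth table
  expect_equal(nrow(cfg$genes), 50)
  expect_false(anyDuplicated(cfg$genes$gene_id) > 0)
  expect_equal(sum(cfg$genes$class == "MEG"), 5)
  expect_equal(sum(cfg$genes$class == "allele_specific_PEG"), 2)
})

test_that("simulate_allele_counts is deterministic and emits truth once", {
  cfg <- truth_config(seed = 11, n_genes = 80, n_meg = 8, n_peg = 4,
                      n_as_peg = 2, n_seedcoat = 2, n_replicates = 2)
  s1 <- simulate_allele_counts(cfg)
  s2 <- simulate_allele_counts(cfg)
  expect_identical(s1, s2)
  expect_identical(sort(unique(s1$counts$gene_id)), sort(s1$truth$gene_id))
  # 3 pairs x 2 directions x 2 replicates
  expect_equal(nrow(s1$counts), 80 * 12)
  expect_true(all(s1$counts$maternal_reads >= 0))
})

test_that("biallelic endosperm maternal fraction converges to 2/3", {
  cfg <- truth_config(seed = 21, n_genes = 600, n_meg = 0, n_peg = 0,
                      n_as_peg = 0, n_seedcoat = 0, n_replicates = 1)
  s <- simulate_allele_counts(cfg)
  m <- sum(s$counts$maternal_reads)
  n <- m + sum(s$counts$paternal_reads)
  se <- sqrt((2 / 3) * (1 / 3) / n)
  expect_lt(abs(m / n - 2 / 3), 3 * se)
})

test_that("planted MEGs keep maternal fractions above 0.85 as often as the
          binomial tail predicts", {
  cfg <- truth_config(seed = 31, n_genes = 100, n_meg = 100, n_peg = 0,
                      n_as_peg = 0, n_seedcoat = 0, n_replicates = 3)
  s <- simulate_allele_counts(cfg)
  x <- s$counts
  frac <- x$maternal_reads / (x$maternal_reads + x$paternal_reads)
  # oracle: per-library P(X >= ceil(0.85 n)) at Binomial(n, 0.95) over the
  # realised depths; the observed count of passing libraries is a sum of
  # independent Bernoullis with exactly these probabilities
  n <- x$maternal_reads + x$paternal_reads
  k <- ceiling(0.85 * n - 1e-9)        # guard against 0.85*n FP jitter
  tail_p <- pbinom(k - 1, n, 0.95, lower.tail = FALSE)
  expect_gt(mean(tail_p), 0.95)        # stated world: cutoff holds whp
  obs <- sum(frac >= 0.85)
  expect_lt(abs(obs - sum(tail_p)), 3 * sqrt(sum(tail_p * (1 - tail_p))) + 1)
})

test_that("allele-specific PEG switches to biallelic only in the designated
          role", {
  cfg <- truth_config(seed = 41, n_genes = 10, n_meg = 0, n_peg = 0,
                      n_as_peg = 10, n_seedcoat = 0,
                      as_strain = "strainC", as_role = "father",
                      depth_mean = 5000, depth_dispersion = 0.01)
  s <- simulate_allele_counts(cfg)
  x <- s$counts[, .(f = sum(maternal_reads) /
                      sum(maternal_reads + paternal_reads)),
                by = .(father = father == "strainC")]
  # C as father: biallelic 2/3 maternal; otherwise PEG, 0.4 maternal
  expect_lt(abs(x[father == TRUE, f] - 2 / 3), 0.02)
  expect_lt(abs(x[father == FALSE, f] - 0.40), 0.02)
  expect_true(all(s$truth$class == "allele_specific_PEG"))
  expect_true(all(s$truth$as_strain == "strainC"))
  expect_true(all(s$truth$as_role == "father"))
})

test_that("methylome pair plants DMRs of the stated magnitude", {
  cfg <- truth_config(seed = 51, chrom_length = 3e5, n_dmrs = 4)
  anno <- simulate_annotation(cfg)
  m <- simulate_methylome_pair(cfg, anno)
  expect_identical(m, simulate_methylome_pair(cfg, anno))  # determinism
  expect_equal(nrow(m$truth), 4)
  for (i in seq_len(nrow(m$truth))) {
    tr <- m$truth[i]
    wa <- region_wmeth(m$sample_a, tr$chrom, tr$start, tr$end, "CG",
                       min_cov = 1)
    wb <- region_wmeth(m$sample_b, tr$chrom, tr$start, tr$end, "CG",
                       min_cov = 1)
    expect_lt(abs((wa - wb) - 0.5), 0.15)
    # each planted DMR carries the configured number of CG sites
    n_sites <- nrow(m$sample_a[context == "CG" & pos > tr$start &
                                 pos <= tr$end])
    expect_equal(n_sites, cfg$dmr_n_sites)
  }
  # background-only regions have difference ~0 in expectation
  bg_a <- m$sample_a[context == "CG" & pos <= min(m$truth$start)]
  bg_b <- m$sample_b[context == "CG" & pos <= min(m$truth$start)]
  expect_lt(abs(sum(bg_a$meth) / sum(bg_a$total) -
                  sum(bg_b$meth) / sum(bg_b$total)), 0.05)
})

test_that("overlapping planted DMRs with contradictory levels error", {
  cfg <- truth_config(seed = 52, chrom_length = 1e5)
  anno <- simulate_annotation(cfg)
  plan <- data.table::data.table(
    dmr_id = c("d1", "d2"), chrom = "chr1",
    start = c(1000L, 1100L), end = c(1300L, 1400L), context = "CG",
    level_a = c(0.9, 0.1), level_b = c(0.1, 0.9))
  expect_error(simulate_methylome_pair(cfg, anno, plan = plan),
               "overlapping planted DMRs")
  expect_error(simulate_methylome_pair(
    cfg, anno, plan = data.table::data.table(
      dmr_id = "d", chrom = "chr1", start = 99000L, end = 101000L,
      context = "CG", level_a = 0.9, level_b = 0.1)),
    "inside the simulated chromosome")
})

test_that("low-coverage sites are mostly below the 5-read rule, matching the
          Poisson tail", {
  cfg <- truth_config(seed = 53, chrom_length = 2e5, n_dmrs = 2,
                      coverage_lambda = 3)
  anno <- simulate_annotation(cfg)
  m <- simulate_methylome_pair(cfg, anno)
  frac_kept <- mean(m$sample_a$total >= 5)
  # P(X >= 5 | lambda = 3) = 0.1847368 (enumerated Poisson tail)
  tail5 <- 1 - sum(exp(-3) * 3^(0:4) / factorial(0:4))
  expect_equal(tail5, 0.1847368, tolerance = 1e-6)
  expect_lt(abs(frac_kept - tail5), 0.01)
})

test_that("population matrix realises each planted class and masks missing
          strains", {
  plan <- data.table::data.table(
    dmr_id = sprintf("d%02d", 1:6),
    class = c("very_low", "low", "not_bimodal", "weakly_bimodal",
              "strongly_bimodal", "very_low"),
    n_missing = c(0L, 0L, 0L, 0L, 0L, 75L))
  cfg <- truth_config(seed = 61, population_plan = plan)
  pm <- simulate_population_matrix(cfg)
  expect_identical(pm, simulate_population_matrix(cfg))
  expect_equal(dim(pm$scores), c(6L, 140L))
  expect_equal(sum(is.na(pm$scores[6, ])), 75)
  rng <- apply(pm$scores[1:5, ], 1, function(s) diff(range(s, na.rm = TRUE)))
  expect_lt(rng[1], 0.2)                       # very_low
  expect_true(rng[2] >= 0.2 && rng[2] < 0.4)   # low
  expect_gt(rng[4], 0.7)                       # weakly_bimodal
  expect_gt(rng[5], 0.7)                       # strongly_bimodal
  expect_error(simulate_population_matrix(
    truth_config(seed = 1, population_plan = data.table::data.table(
      dmr_id = "d", class = "sideways", n_missing = 0L))),
    "unknown variability class")
})

test_that("read simulator: origins recoverable, conflict rate matches
          2e(1-e)", {
  g <- simulate_strain_genomes(8000, 400, seed = 71)
  expect_equal(nchar(g$genomes[[1]]), 8000)
  expect_equal(nchar(g$genomes[[2]]), 8000)
  # genomes differ exactly at SNP positions
  a <- strsplit(g$genomes[[1]], "")[[1]]
  b <- strsplit(g$genomes[[2]], "")[[1]]
  expect_identical(which(a != b), as.integer(g$snps$pos))

  expect_error(simulate_reads(g$genomes, 10, read_length = 9000),
               "exceeds genome length")

  rd <- simulate_reads(g$genomes, 400, 60, error_rate = 0, seed = 72)
  expect_identical(rd, simulate_reads(g$genomes, 400, 60, error_rate = 0,
                                      seed = 72))
  cl <- classify_reads(rd, g$snps)
  assigned <- cl[origin %in% c("strain_a", "strain_b")]
  expect_true(all(assigned$origin == assigned$true_origin))
  expect_false(any(cl$origin == "conflict"))

  # with errors, conflicting reads appear at roughly 2 e (1 - e) among
  # 2-SNP reads
  rde <- simulate_reads(g$genomes, 4000, 60, error_rate = 0.01, seed = 73)
  cle <- classify_reads(rde, g$snps)
  n_snps_per_read <- sapply(seq_len(nrow(rde)), function(i)
    sum(g$snps$pos > rde$start[i] & g$snps$pos <= rde$start[i] + 60))
  two <- n_snps_per_read == 2
  expect_gt(sum(two), 200)
  rate <- mean(cle$origin[two] == "conflict")
  # one of the two bases erroneous (2 e (1 - e)) AND the error base equal
  # to the other strain's allele (1/3, errors drawn from the 3 non-ref
  # bases)
  expected <- 2 * 0.01 * (1 - 0.01) / 3
  expect_lt(abs(rate - expected), 3 * sqrt(expected / sum(two)) + 0.005)
})
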