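# Synthetic-data generator: every pipeline input with planted truth.
#
# Counts are generated directly at the "informative reads" level
# (post-classification); the read simulator exists separately to exercise
# the SNP classifier. Coordinates in emitted cytosine tables are 1-based
# (CX-report dialect); features/windows are 0-based half-open.

GENE_CLASSES <- c("biallelic", "MEG", "PEG", "allele_specific_MEG",
                  "allele_specific_PEG", "seedcoat_dominant")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# decouple RNG streams of the different generators
sub_seed <- function(seed, offset) (as.integer(seed) + offset) %% 2147483647L

#' Build a synthetic-truth configuration
#'
#' Defines the stated world for the synthetic generators: which genes are
#' imprinted and how strongly, the read-depth model, the cross design, the
#' planted DMRs and the planted population variability classes.
#'
#' Default effect sizes: MEGs express 95% maternally, PEGs 60% paternally;
#' biallelic endosperm genes follow the 2:1 dosage null (maternal fraction
#' 2/3; embryo 1/2). Allele-specific classes behave like their parent class
#' except in crosses where the designated strain holds the designated
#' parental role, where they revert to the biallelic fraction. Read depth
#' per gene x library is negative binomial (mean 300, dispersion 0.3).
#'
#' @param seed Integer RNG seed; identical configs give identical outputs.
#' @param n_genes Total number of genes.
#' @param n_meg,n_peg Numbers of planted MEGs / PEGs.
#' @param n_as_meg,n_as_peg Numbers of planted allele-specific MEGs / PEGs
#'   (designated strain `as_strain`, role `as_role`).
#' @param n_seedcoat Genes expressed predominantly in the seed coat (should
#'   be removed by the seed-coat filter).
#' @param as_strain,as_role Strain and parental role at which
#'   allele-specific genes lose their imprint (default third strain as
#'   father, i.e. "PEG except when strain C is the male parent").
#' @param meg_fraction Maternal read fraction of MEGs.
#' @param peg_paternal_fraction Paternal read fraction of PEGs.
#' @param depth_mean,depth_dispersion Negative-binomial depth model
#'   (variance = mu + dispersion * mu^2).
#' @param strains Ordered character vector of 3 strain names.
#' @param tissue Tissue of the default cross design.
#' @param n_replicates Biological replicates per reciprocal cross pair.
#' @param chrom_length Length of the single synthetic chromosome (bp).
#' @param n_dmrs Planted CG DMRs for the methylome pair.
#' @param dmr_magnitude Weighted-methylation difference of planted DMRs.
#' @param dmr_n_sites CG sites placed inside each planted DMR.
#' @param coverage_lambda Mean per-site read coverage (Poisson).
#' @param n_strains_population Pseudo-strains in the population matrix.
#' @param population_plan Optional `data.table` (`dmr_id`, `class`,
#'   `n_missing`) overriding the default planted class composition
#'   (40 very_low, 15 low, 14 not_bimodal, 15 weakly_bimodal,
#'   16 strongly_bimodal).
#' @param error_rate Per-base error rate of the read simulator.
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(seed = 1L,
                         n_genes = 2000L,
                         n_meg = 100L, n_peg = 50L,
                         n_as_meg = 0L, n_as_peg = 8L,
                         n_seedcoat = 20L,
                         as_strain = NULL, as_role = "father",
                         meg_fraction = 0.95,
                         peg_paternal_fraction = 0.60,
                         depth_mean = 300, depth_dispersion = 0.3,
                         strains = c("strainA", "strainB", "strainC"),
                         tissue = "endosperm",
                         n_replicates = 3L,
                         chrom_length = 2e6,
                         n_dmrs = 20L,
                         dmr_magnitude = 0.5,
                         dmr_n_sites = 10L,
                         coverage_lambda = 12,
                         n_strains_population = 140L,
                         population_plan = NULL,
                         error_rate = 0) {
  stopifnot(length(strains) == 3L, !anyDuplicated(strains))
  if (depth_mean <= 0) stop("depth model mean must be positive")
  stopifnot(meg_fraction >= 0, meg_fraction <= 1,
            peg_paternal_fraction >= 0, peg_paternal_fraction <= 1)
  if (!as_role %in% c("mother", "father")) stop("as_role must be mother/father")
  if (is.null(as_strain)) as_strain <- strains[3]
  n_special <- n_meg + n_peg + n_as_meg + n_as_peg + n_seedcoat
  if (n_special > n_genes) stop("more special genes than n_genes")

  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  cls <- rep("biallelic", n_genes)
  idx <- 0L
  take <- function(n) { out <- idx + seq_len(n); idx <<- idx + n; out }
  cls[take(n_meg)] <- "MEG"
  cls[take(n_peg)] <- "PEG"
  cls[take(n_as_meg)] <- "allele_specific_MEG"
  cls[take(n_as_peg)] <- "allele_specific_PEG"
  cls[take(n_seedcoat)] <- "seedcoat_dominant"
  genes <- data.table::data.table(gene_id = gene_id, class = cls)
  genes[, as_strain := data.table::fifelse(startsWith(class, "allele_specific"),
                                           as_strain, NA_character_)]
  genes[, as_role := data.table::fifelse(startsWith(class, "allele_specific"),
                                         as_role, NA_character_)]

  # reciprocal crosses: all unordered strain pairs, both directions
  pairs <- utils::combn(strains, 2, simplify = FALSE)
  crosses <- data.table::rbindlist(lapply(pairs, function(p)
    data.table::CJ(mother = p, father = p, replicate = seq_len(n_replicates)
    )[mother != father]))
  crosses[, tissue := tissue]

  maternal_fraction <- list(
    biallelic = c(endosperm = 2 / 3, embryo = 1 / 2, whole_seed = 1 / 2),
    MEG = c(endosperm = meg_fraction, embryo = meg_fraction,
            whole_seed = meg_fraction),
    PEG = c(endosperm = 1 - peg_paternal_fraction,
            embryo = 1 - peg_paternal_fraction,
            whole_seed = 1 - peg_paternal_fraction),
    seedcoat_dominant = c(endosperm = 2 / 3, embryo = 1 / 2,
                          whole_seed = 1 / 2))
  maternal_fraction$allele_specific_MEG <- maternal_fraction$MEG
  maternal_fraction$allele_specific_PEG <- maternal_fraction$PEG

  cfg <- structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    genes = genes, strains = strains, crosses = crosses,
    maternal_fraction = maternal_fraction,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    chrom_length = as.integer(chrom_length),
    n_dmrs = as.integer(n_dmrs), dmr_magnitude = dmr_magnitude,
    dmr_n_sites = as.integer(dmr_n_sites),
    coverage_lambda = coverage_lambda,
    n_strains_population = as.integer(n_strains_population),
    population_plan = population_plan,
    error_rate = error_rate), class = "truth_config")
  cfg
}

#' @export
print.truth_config <- function(x, ...) {
  cat("truth_config: ", x$n_genes, " genes, strains ",
      paste(x$strains, collapse = "/"), ", seed ", x$seed, "\n", sep = "")
  print(x$genes[, .N, by = class])
  invisible(x)
}

class_fraction <- function(class, tissue, mother, father, as_strain, as_role,
                           maternal_fraction) {
  f <- vapply(seq_along(class), function(i) {
    cl <- class[i]
    base <- maternal_fraction[[cl]][[tissue[i]]]
    if (startsWith(cl, "allele_specific")) {
      role_strain <- if (as_role[i] == "mother") mother[i] else father[i]
      if (identical(role_strain, as_strain[i]))
        base <- maternal_fraction[["biallelic"]][[tissue[i]]]
    }
    base
  }, numeric(1))
  f
}

#' Simulate allele-specific read counts for all crosses
#'
#' For each gene x cross x replicate, total informative reads are drawn from
#' the negative-binomial depth model and maternal reads binomially at the
#' gene class's maternal fraction for that tissue. Allele-specific classes
#' switch to the biallelic fraction only in crosses where the designated
#' strain holds the designated parental role.
#'
#' @param config A [truth_config()].
#' @return List with `counts` (allele-count `data.table`: `gene_id`,
#'   `mother`, `father`, `tissue`, `replicate`, `maternal_reads`,
#'   `paternal_reads`) and `truth` (`gene_id`, `class`, `as_strain`,
#'   `as_role`).
#' @export
simulate_allele_counts <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  bad <- setdiff(config$genes$class, GENE_CLASSES)
  if (length(bad)) stop("unknown gene class: ", paste(bad, collapse = ", "))
  crosses <- config$crosses
  genes <- config$genes
  with_seed(sub_seed(config$seed, 101L), {
    out <- data.table::rbindlist(lapply(seq_len(nrow(crosses)), function(i) {
      cr <- crosses[i]
      f <- class_fraction(genes$class, rep(cr$tissue, nrow(genes)),
                          rep(cr$mother, nrow(genes)),
                          rep(cr$father, nrow(genes)),
                          genes$as_strain, genes$as_role,
                          config$maternal_fraction)
      n <- rnbinom(nrow(genes), mu = config$depth_mean,
                   size = 1 / config$depth_dispersion)
      m <- rbinom(nrow(genes), n, f)
      data.table::data.table(gene_id = genes$gene_id, mother = cr$mother,
                             father = cr$father, tissue = cr$tissue,
                             replicate = cr$replicate,
                             maternal_reads = m, paternal_reads = n - m)
    }))
  })
  list(counts = out, truth = data.table::copy(genes))
}

#' Simulate a tissue-expression table for the seed-coat filter
#'
#' Linear-scale mean expression per compartment. `seedcoat_dominant` genes
#' are expressed fourfold higher in the seed coat than in endosperm/embryo
#' (log2 difference 2, failing the < 1 filter); all other genes have
#' near-equal compartment means.
#'
#' @param config A [truth_config()].
#' @return `data.table` with `gene_id`, `endosperm`, `embryo`, `seed_coat`.
#' @export
simulate_tissue_expression <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  g <- config$genes
  with_seed(sub_seed(config$seed, 202L), {
    base <- exp(rnorm(nrow(g), log(100), 0.5))
    noise <- function() exp(rnorm(nrow(g), 0, 0.05))
    sc_mult <- data.table::fifelse(g$class == "seedcoat_dominant", 4, 1)
    data.table::data.table(gene_id = g$gene_id,
                           endosperm = base * noise(),
                           embryo = base * noise(),
                           seed_coat = base * sc_mult * noise())
  })
}

#' Simulate a gene/TE annotation on the synthetic chromosome
#'
#' Alternating genes and TEs with intergenic gaps on one chromosome
#' (`chr1`), BED-style 0-based half-open coordinates, random strands.
#'
#' @param config A [truth_config()].
#' @param gene_length,te_length,gap Feature and gap sizes (bp).
#' @return Feature `data.table` (`chrom`, `start`, `end`, `feature_id`,
#'   `strand`, `feature_type`).
#' @export
simulate_annotation <- function(config, gene_length = 2000L,
                                te_length = 1000L, gap = 1500L) {
  stopifnot(inherits(config, "truth_config"))
  L <- config$chrom_length
  feats <- list(); pos <- gap; i_gene <- 0L; i_te <- 0L
  with_seed(sub_seed(config$seed, 303L), {
    repeat {
      len <- if ((i_gene + i_te) %% 2L == 0L) gene_length else te_length
      if (pos + len + gap > L) break
      if ((i_gene + i_te) %% 2L == 0L) {
        i_gene <- i_gene + 1L
        id <- sprintf("gene%04d", i_gene); type <- "gene"
      } else {
        i_te <- i_te + 1L
        id <- sprintf("TE%04d", i_te); type <- "TE"
      }
      feats[[length(feats) + 1L]] <- data.table::data.table(
        chrom = "chr1", start = pos, end = pos + len, feature_id = id,
        strand = sample(c("+", "-"), 1L), feature_type = type)
      pos <- pos + len + gap
    }
  })
  data.table::rbindlist(feats)
}

default_methylome_plan <- function(config, annotation) {
  # planted CG DMRs aligned to the 200-nt window grid so that one analysis
  # window coincides exactly with each DMR; placed in intergenic space
  L <- config$chrom_length
  n <- config$n_dmrs
  occupied <- annotation[, .(start, end)]
  starts <- integer(0); cand <- seq(2000L, L - 2000L, by = 200L)
  with_seed(sub_seed(config$seed, 404L), {
    cand <- sample(cand)
    for (s in cand) {
      if (length(starts) >= n) break
      e <- s + 300L
      if (any(occupied$start < e & occupied$end > s)) next
      if (length(starts) && any(abs(starts - s) < 900L)) next
      starts <- c(starts, s)
    }
  })
  if (length(starts) < n) stop("could not place all planted DMRs")
  starts <- sort(starts)
  hi <- 0.3 + config$dmr_magnitude
  data.table::data.table(dmr_id = sprintf("dmr%03d", seq_len(n)),
                         chrom = "chr1", start = starts, end = starts + 300L,
                         context = "CG", level_a = hi, level_b = 0.3)
}

# background methylation probability by context and overlapping feature type
background_level <- function(context, feature_type) {
  key <- paste(feature_type, context, sep = ".")
  lv <- c(TE.CG = 0.85, TE.CHG = 0.65, TE.CHH = 0.30,
          gene.CG = 0.25, gene.CHG = 0.03, gene.CHH = 0.02,
          intergenic.CG = 0.10, intergenic.CHG = 0.05,
          intergenic.CHH = 0.05)
  unname(lv[key])
}

#' Simulate a pair of methylomes with planted DMRs
#'
#' Places cytosines of each context along the synthetic chromosome,
#' assigns background methylation levels by overlapping feature type
#' (high CG/CHG in TEs, low CHG/CHH in genes), and inside each planted DMR
#' interval makes the two samples differ by the planted magnitude.
#' Per-site coverage is Poisson(`coverage_lambda`); methylated counts are
#' binomial. Both samples share cytosine positions (same genome).
#'
#' @param config A [truth_config()].
#' @param annotation Feature table from [simulate_annotation()].
#' @param plan Optional methylome plan (`dmr_id`, `chrom`, `start`, `end`,
#'   `context`, `level_a`, `level_b`); default plants `config$n_dmrs`
#'   CG DMRs of the configured magnitude in intergenic space.
#' @param site_density Named per-context cytosine density (sites per bp).
#' @return List with `sample_a`, `sample_b` (cytosine `data.table`s with
#'   1-based `pos`) and `truth` (the plan).
#' @export
simulate_methylome_pair <- function(config, annotation, plan = NULL,
                                    site_density = c(CG = 0.03, CHG = 0.03,
                                                     CHH = 0.08)) {
  stopifnot(inherits(config, "truth_config"))
  if (is.null(plan)) plan <- default_methylome_plan(config, annotation)
  if (any(plan$start >= plan$end) || any(plan$end > config$chrom_length))
    stop("planted DMR intervals must fall inside the simulated chromosome")
  # contradictory overlaps within a context are a configuration error
  p <- plan[order(context, start)]
  ov <- p[, any(start[-1] < head(end, -1)), by = context]$V1
  if (any(ov)) stop("overlapping planted DMRs with contradictory levels")
  L <- config$chrom_length

  with_seed(sub_seed(config$seed, 505L), {
    sites <- data.table::rbindlist(lapply(CONTEXTS, function(ctx) {
      n_bg <- rpois(1L, site_density[[ctx]] * L)
      pos <- sort(sample.int(L, min(n_bg, L)))
      data.table::data.table(chrom = "chr1", pos = pos, context = ctx)
    }))
    # drop background sites inside planted intervals, then place the
    # planted sites evenly so each DMR has a known informative-site count
    for (i in seq_len(nrow(plan))) {
      pl <- plan[i]
      sites <- sites[!(context == pl$context & pos > pl$start &
                         pos <= pl$end)]
      planted <- as.integer(round(seq(pl$start + 10L, pl$end - 10L,
                                      length.out = config$dmr_n_sites)))
      sites <- rbind(sites, data.table::data.table(
        chrom = pl$chrom, pos = planted, context = pl$context))
    }
    sites <- unique(sites, by = c("chrom", "pos", "context"))
    data.table::setorder(sites, chrom, pos)
    sites[, strand := sample(c("+", "-"), .N, replace = TRUE)]

    # background probability from overlapping feature
    sites[, feature_type := "intergenic"]
    for (i in seq_len(nrow(annotation))) {
      f <- annotation[i]
      sites[pos > f$start & pos <= f$end, feature_type := f$feature_type]
    }
    sites[, `:=`(prob_a = background_level(context, feature_type),
                 prob_b = background_level(context, feature_type))]
    for (i in seq_len(nrow(plan))) {
      pl <- plan[i]
      sites[context == pl$context & pos > pl$start & pos <= pl$end,
            `:=`(prob_a = pl$level_a, prob_b = pl$level_b)]
    }
    draw <- function(prob) {
      tot <- rpois(nrow(sites), config$coverage_lambda)
      me <- rbinom(nrow(sites), tot, prob)
      data.table::data.table(chrom = sites$chrom, pos = sites$pos,
                             strand = sites$strand, context = sites$context,
                             meth = me, total = tot)
    }
    list(sample_a = draw(sites$prob_a), sample_b = draw(sites$prob_b),
         truth = plan)
  })
}

default_population_plan <- function() {
  data.table::data.table(
    dmr_id = sprintf("mdmr%03d", 1:100),
    class = rep(c("very_low", "low", "not_bimodal", "weakly_bimodal",
                  "strongly_bimodal"), c(40L, 15L, 14L, 15L, 16L)),
    n_missing = 0L)
}

#' Simulate a DMR-by-strain population methylation matrix
#'
#' Draws per-strain methylation scores for each planted variability class.
#' Two anchor strains pin the score range exactly, so the planted class is
#' recovered deterministically by [classify_variability()]:
#' `very_low` scores span a 0.148 band, `low` a 0.25 band, `not_bimodal` a
#' unimodal 0.6 spread, `weakly_bimodal` a two-mode mixture with 64% of
#' strains in the outer quarter-bands, `strongly_bimodal` ~93%/7% modes at
#' the range extremes.
#'
#' @param config A [truth_config()]; uses `population_plan` (or the default
#'   100-DMR composition), `n_strains_population` and the seed.
#' @return List with `scores` (matrix DMR x strain, NA = missing) and
#'   `truth` (`dmr_id`, `class`, `n_missing`).
#' @export
simulate_population_matrix <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  plan <- config$population_plan
  if (is.null(plan)) plan <- default_population_plan()
  plan <- data.table::as.data.table(plan)
  if (!"n_missing" %in% names(plan)) plan[, n_missing := 0L]
  n <- config$n_strains_population
  if (n < 4L) stop("need at least 4 strains")
  strains <- sprintf("pstrain%03d", seq_len(n))

  gen_class <- function(class, n) {
    band <- function(center, hb) {
      s <- runif(n, center - hb, center + hb)
      s[1] <- center - hb; s[2] <- center + hb    # anchors pin the range
      s
    }
    switch(class,
      very_low = band(runif(1, 0.15, 0.85), 0.074),
      low = band(runif(1, 0.15, 0.85), 0.125),
      not_bimodal = band(runif(1, 0.35, 0.65), 0.30),
      weakly_bimodal = {
        n_mode <- round(0.643 * n); n_lo <- floor(n_mode / 2)
        s <- c(runif(n_lo, 0.08, 0.12), runif(n_mode - n_lo, 0.88, 0.92),
               runif(n - n_mode, 0.30, 0.70))
        s[1] <- 0.08; s[n_lo + 1] <- 0.92
        s
      },
      strongly_bimodal = {
        n_lo <- max(2L, round(0.07 * n))
        s <- c(runif(n_lo, 0.04, 0.08), runif(n - n_lo, 0.89, 0.93))
        s[1] <- 0.04; s[n_lo + 1] <- 0.93
        s
      },
      stop("unknown variability class: ", class))
  }

  with_seed(sub_seed(config$seed, 606L), {
    scores <- matrix(NA_real_, nrow(plan), n,
                     dimnames = list(plan$dmr_id, strains))
    for (i in seq_len(nrow(plan))) {
      s <- gen_class(plan$class[i], n)
      if (plan$n_missing[i] > 0L) {
        # mask non-anchor strains first so planted ranges survive masking
        pool <- if (plan$n_missing[i] <= n - 2L) 3:n else seq_len(n)
        s[sample(pool, plan$n_missing[i])] <- NA_real_
      }
      scores[i, ] <- s
    }
    list(scores = scores, truth = plan)
  })
}

#' Simulate a pair of strain genomes differing only at SNPs
#'
#' @param genome_length Genome length (bp), single chromosome `chr1`.
#' @param n_snps Number of SNP positions (uniformly placed).
#' @param seed RNG seed.
#' @param strains Two strain names.
#' @return List with `genomes` (named character vector of sequences) and
#'   `snps` (SNP `data.table`: `chrom`, 1-based `pos`, `base_a`, `base_b`).
#' @export
simulate_strain_genomes <- function(genome_length = 10000L, n_snps = 200L,
                                    seed = 1L,
                                    strains = c("strain_a", "strain_b")) {
  stopifnot(length(strains) == 2L, n_snps < genome_length)
  bases <- c("A", "C", "G", "T")
  with_seed(sub_seed(seed, 707L), {
    ref <- sample(bases, genome_length, replace = TRUE)
    pos <- sort(sample.int(genome_length, n_snps))
    alt <- vapply(ref[pos], function(b) sample(setdiff(bases, b), 1L),
                  character(1))
    alt_genome <- ref
    alt_genome[pos] <- alt
    genomes <- c(paste(ref, collapse = ""), paste(alt_genome, collapse = ""))
    names(genomes) <- strains
    list(genomes = genomes,
         snps = data.table::data.table(chrom = "chr1", pos = pos,
                                       base_a = unname(ref[pos]),
                                       base_b = unname(alt)))
  })
}

#' Simulate aligned reads of known strain origin
#'
#' Fixed-length reads sampled uniformly from one of two strain haplotypes
#' with independent per-base errors; sequences are reported in reference
#' orientation (as in an alignment), with the strand recorded.
#'
#' @param genomes Named character vector of 2 strain genome sequences.
#' @param n_reads Number of reads.
#' @param read_length Read length (bp).
#' @param error_rate Per-base error probability.
#' @param seed RNG seed.
#' @return `data.table` with `read_id`, `chrom`, 0-based `start`, `strand`,
#'   `sequence`, `mismatches` (planted errors), `quality_sum` and
#'   `true_origin` (a strain name).
#' @export
simulate_reads <- function(genomes, n_reads = 500L, read_length = 50L,
                           error_rate = 0, seed = 1L) {
  stopifnot(length(genomes) == 2L, !is.null(names(genomes)))
  glen <- unique(nchar(genomes))
  if (length(glen) != 1L) stop("strain genomes must have equal length")
  if (read_length > glen) stop("read length exceeds genome length")
  bases <- c("A", "C", "G", "T")
  with_seed(sub_seed(seed, 808L), {
    origin <- sample(names(genomes), n_reads, replace = TRUE)
    start <- sample.int(glen - read_length + 1L, n_reads,
                        replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- character(n_reads); nerr <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      s <- strsplit(substr(genomes[[origin[i]]], start[i] + 1L,
                           start[i] + read_length), "")[[1]]
      err <- which(runif(read_length) < error_rate)
      for (j in err) s[j] <- sample(setdiff(bases, s[j]), 1L)
      seqs[i] <- paste(s, collapse = "")
      nerr[i] <- length(err)
    }
    data.table::data.table(
      read_id = sprintf("read%05d", seq_len(n_reads)), chrom = "chr1",
      start = start, strand = strand, sequence = seqs, mismatches = nerr,
      quality_sum = round(rnorm(n_reads, 38 * read_length,
                                2 * sqrt(read_length))),
      true_origin = origin)
  })
}
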