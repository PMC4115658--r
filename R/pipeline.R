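# End-to-end orchestration of the synthetic pipeline.

#' Build a pipeline configuration
#'
#' Bundles the synthetic-truth configuration, thresholds and the output
#' directory. All randomness derives from `seed`, so two runs with the
#' same config produce identical outputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed.
#' @param truth A [truth_config()]; default built from `seed`.
#' @param imprinting [imprinting_params()].
#' @param dmr [dmr_params()].
#' @param max_missing Censoring threshold for variability classification.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, truth = NULL,
                            imprinting = imprinting_params(),
                            dmr = dmr_params(), max_missing = NULL) {
  if (is.null(truth)) truth <- truth_config(seed = seed)
  stopifnot(inherits(truth, "truth_config"))
  structure(list(out_dir = out_dir, seed = as.integer(seed), truth = truth,
                 imprinting = imprinting, dmr = dmr,
                 max_missing = max_missing),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic pipeline
#'
#' simulate -> call imprinting -> detect allele-specific imprinting ->
#' simulate methylomes -> call and merge DMRs -> annotate -> simulate the
#' population matrix -> classify variability -> associate genes with DMRs
#' and test enrichment. Writes all tables as TSV/BED under
#' `config$out_dir` plus a JSON manifest with seeds, thresholds and
#' per-stage record counts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  counts_of <- list()

  sim <- stage("simulate", simulate_allele_counts(config$truth))
  expr_tab <- stage("simulate", simulate_tissue_expression(config$truth))
  data.table::fwrite(sim$counts, out("allele_counts.tsv"), sep = "\t")
  data.table::fwrite(sim$truth, out("truth_genes.tsv"), sep = "\t")
  data.table::fwrite(expr_tab, out("expression.tsv"), sep = "\t")
  counts_of$allele_counts <- nrow(sim$counts)

  calls <- stage("call-imprinting",
                 call_imprinting(sim$counts, expr_tab,
                                 params = config$imprinting))
  data.table::fwrite(calls, out("imprinting_calls.tsv"), sep = "\t")
  counts_of$imprinting_calls <- nrow(calls)

  asi <- stage("call-allele-specific",
               detect_allele_specific(sim$counts, calls, expr_tab,
                                      params = config$imprinting))
  data.table::fwrite(asi, out("allele_specific.tsv"), sep = "\t")
  counts_of$allele_specific <- nrow(asi)

  anno <- stage("simulate", simulate_annotation(config$truth))
  write_features_bed(anno, out("annotation.bed"))
  meth <- stage("simulate",
                simulate_methylome_pair(config$truth, anno))
  write_cx_report(meth$sample_a, out("sample_a.cx.tsv"))
  write_cx_report(meth$sample_b, out("sample_b.cx.tsv"))
  data.table::fwrite(meth$truth, out("truth_dmrs.tsv"), sep = "\t")

  win <- stage("call-dmrs",
               compare_windows(meth$sample_a, meth$sample_b, "CG",
                               params = config$dmr))
  data.table::fwrite(win, out("dmr_windows.tsv"), sep = "\t")
  dmrs <- stage("call-dmrs", merge_dmrs(win))
  write_dmr_bed(dmrs, out("dmrs.bed"))
  counts_of$dmr_windows <- nrow(win)
  counts_of$dmrs <- nrow(dmrs)

  ann <- stage("annotate", annotate_dmrs(dmrs, anno))
  data.table::fwrite(ann$hits, out("dmr_annotation.tsv"), sep = "\t")

  popm <- stage("simulate", simulate_population_matrix(config$truth))
  write_score_matrix(popm$scores, out("population_matrix.tsv"))
  vari <- stage("classify-variability",
                classify_all(popm$scores, max_missing = config$max_missing))
  data.table::fwrite(vari$table, out("variability.tsv"), sep = "\t")
  counts_of$variability <- nrow(vari$table)

  assoc <- stage("associate",
                 associate_genes_dmrs(anno[feature_type == "gene"], dmrs))
  data.table::fwrite(assoc, out("gene_dmr_associations.tsv"), sep = "\t")
  counts_of$associations <- nrow(assoc)

  enr <- NULL
  megs <- calls[status == "MEG", unique(gene_id)]
  bg <- calls[status != "not_assessable", unique(gene_id)]
  flagged <- intersect(unique(assoc$gene_id), bg)
  if (length(megs) && length(flagged))
    enr <- stage("enrich", enrichment_test(megs, flagged, bg))
  if (!is.null(enr))
    jsonlite::write_json(list(p_value = enr$p_value, fold = enr$fold),
                         out("enrichment.json"), auto_unbox = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("imprintomics")),
    seed = config$seed,
    thresholds = list(imprinting = config$imprinting[
      c("alpha", "min_if", "meg_cutoff_endosperm", "peg_cutoff_endosperm")],
      dmr = config$dmr[c("window", "step", "min_cov", "q_cutoff")]),
    record_counts = counts_of,
    stages = c("simulate", "call-imprinting", "call-allele-specific",
               "call-dmrs", "annotate", "classify-variability",
               "associate"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  yaml::write_yaml(list(seed = config$seed,
                        n_genes = config$truth$n_genes,
                        strains = config$truth$strains),
                   out("config.yaml"))

  invisible(list(counts = sim$counts, truth = sim$truth,
                 expression = expr_tab, calls = calls,
                 allele_specific = asi, annotation = anno,
                 methylomes = meth, dmr_windows = win, dmrs = dmrs,
                 dmr_annotation = ann, population = popm,
                 variability = vari, associations = assoc,
                 enrichment = enr, manifest = manifest))
}
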