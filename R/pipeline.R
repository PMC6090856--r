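# End-to-end orchestration: sample QC -> mutation filters -> clonality ->
# expression gate -> peptide enumeration -> binding -> cohort statistics,
# with a funnel count at every stage and reproducible run metadata.

#' Pipeline run configuration
#'
#' All numeric thresholds default to the pipeline's canonical values:
#' panel-of-normals 1%, minimum depth 10X, purity floor 20%, ploidy ceiling
#' 6, expression floor 3 reads, clonal-call CCF threshold 0.95, binder
#' thresholds 50/500 nM.
#'
#' @param pon_max,min_depth mutation filter thresholds.
#' @param min_purity,max_ploidy sample QC thresholds.
#' @param min_expr_reads expression gate threshold.
#' @param clonal_ccf_min clonal-call threshold on the CCF credible interval.
#' @param strong_nm,weak_nm IC50 binder category thresholds (nM).
#' @param allele_mode `"panel"` (score every allele for every patient) or
#'   `"typed"` (each patient's typed alleles only).
#' @param predictor `"toy"` (built-in deterministic scorer) or `"external"`.
#' @param adapter_config adapter configuration for the external predictor.
#' @param class2_length,class1_lengths peptide window lengths.
#' @param grid_resolution CCF grid step.
#' @param allele_panel allele panel for `"panel"` mode and enrichment rows.
#' @param namespace seed namespace of the built-in scorer.
#' @param bias optional named per-allele score bias vector.
#' @return list of class `run_config`.
#' @export
run_config <- function(pon_max = 0.01, min_depth = 10, min_purity = 0.20,
                       max_ploidy = 6.0, min_expr_reads = 3,
                       clonal_ccf_min = 0.95, strong_nm = 50, weak_nm = 500,
                       allele_mode = c("panel", "typed"),
                       predictor = c("toy", "external"), adapter_config = NULL,
                       class2_length = 15L, class1_lengths = NULL,
                       grid_resolution = 0.01, allele_panel = drb1_panel(),
                       namespace = "clonepitope-v1", bias = NULL) {
  cfg <- list(pon_max = pon_max, min_depth = min_depth,
              min_purity = min_purity, max_ploidy = max_ploidy,
              min_expr_reads = min_expr_reads, clonal_ccf_min = clonal_ccf_min,
              strong_nm = strong_nm, weak_nm = weak_nm,
              allele_mode = match.arg(allele_mode),
              predictor = match.arg(predictor),
              adapter_config = adapter_config, class2_length = class2_length,
              class1_lengths = class1_lengths,
              grid_resolution = grid_resolution, allele_panel = allele_panel,
              namespace = namespace, bias = bias)
  thresholds <- c(cfg$pon_max, cfg$min_depth, cfg$min_purity, cfg$max_ploidy,
                  cfg$min_expr_reads, cfg$clonal_ccf_min, cfg$strong_nm,
                  cfg$weak_nm)
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  class(cfg) <- "run_config"
  cfg
}

# Stable hash of the configuration for output provenance.
config_hash <- function(config) {
  str_hash(paste(deparse(config[order(names(unclass(config)))]), collapse = ""))
}

read_inputs <- function(dir) {
  list(mutations = read_mutations(file.path(dir, "mutations.tsv"), dialect = "tsv"),
       samples = read_samples(file.path(dir, "samples.tsv")),
       segments = read_segments(file.path(dir, "segments.tsv")),
       expression = read_expression(file.path(dir, "expression.tsv")),
       proteome = read_fasta(file.path(dir, "proteome.fasta")),
       cds = if (file.exists(file.path(dir, "cds.fasta")))
         read_fasta(file.path(dir, "cds.fasta")) else NULL)
}

stage <- function(name, expr, log) {
  log(sprintf("stage %s", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes sample QC, mutation filtering, CCF/clonality, expression
#' gating, peptide window enumeration, binding prediction and cohort
#' statistics on an input bundle (a directory of the standard files or an
#' in-memory list as returned by [generate_cohort()]). When `out_dir` is
#' given, every intermediate table, a JSON run summary (the stage funnel
#' plus cohort totals and the configuration hash) and a plain-text log are
#' written there. With the built-in predictor the whole run is
#' deterministic: rerunning with the same inputs and configuration yields
#' an identical summary.
#'
#' @param inputs input directory path or in-memory bundle (list with
#'   `mutations`, `samples`, `segments`, `expression`, `proteome`,
#'   optionally `cds`).
#' @param out_dir optional output directory.
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `summary` (funnel counts, totals,
#'   config hash), `tables` (annotated mutations, candidates, calls,
#'   cohort summary) and `qc` (dropped samples).
#' @export
run_pipeline <- function(inputs, out_dir = NULL, config = run_config(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  if (is.character(inputs)) inputs <- stage("read_inputs", read_inputs(inputs), log)

  funnel <- c(samples_in = nrow(inputs$samples))
  samples <- stage("sample_qc", {
    s <- dedupe_samples(inputs$samples)
    qc_samples(s, config$min_purity, config$max_ploidy)
  }, log)
  funnel["samples_kept"] <- nrow(samples$kept)

  muts0 <- inputs$mutations[inputs$mutations$patient_id %in%
                              samples$kept$patient_id, , drop = FALSE]
  funnel["mutations_in"] <- nrow(muts0)
  freport <- stage("mutation_filters",
                   filter_mutations(muts0, config$pon_max, config$min_depth), log)
  funnel["mutations_filtered"] <- nrow(freport$kept)

  annotated <- stage("clonality",
                     annotate_clonality(freport$kept, samples$kept,
                                        inputs$segments,
                                        grid_resolution = config$grid_resolution,
                                        clonal_ccf_min = config$clonal_ccf_min),
                     log)
  clonal <- annotated[annotated$is_clonal, , drop = FALSE]
  funnel["mutations_clonal"] <- nrow(clonal)

  expressed <- stage("expression_gate", {
    if (is.null(inputs$expression)) stop("expression table missing")
    clonal[expression_gate(clonal, inputs$expression, config$min_expr_reads), ,
           drop = FALSE]
  }, log)
  funnel["mutations_expressed"] <- nrow(expressed)

  candidates <- stage("peptides",
                      build_candidates(expressed, inputs$proteome,
                                       cds = inputs$cds,
                                       class2_length = config$class2_length,
                                       class1_lengths = config$class1_lengths),
                      log)
  funnel["candidate_mutations"] <- length(unique(paste(
    candidates$patient_id, candidates$gene, candidates$protein_change)))
  funnel["candidate_peptides"] <- nrow(candidates)

  calls <- stage("binding", {
    if (config$predictor == "external") {
      run_external_predictor(candidates, config$allele_panel,
                             config$adapter_config)
    } else {
      score_candidates(candidates, config$allele_panel,
                       samples = samples$kept, mode = config$allele_mode,
                       namespace = config$namespace, bias = config$bias,
                       strong_nm = config$strong_nm, weak_nm = config$weak_nm)
    }
  }, log)
  funnel["binding_calls"] <- nrow(calls)

  summary_tables <- stage("stats",
                          cohort_summary(calls, expressed, samples$kept,
                                         config$allele_panel), log)

  summary <- list(funnel = as.list(funnel),
                  totals = summary_tables$totals,
                  removed_by = as.list(freport$removed_by),
                  per_category_counts = as.list(freport$per_category_counts),
                  allele_mode = config$allele_mode,
                  predictor = if (config$predictor == "toy") TOY_PREDICTOR_NAME
                              else "external",
                  config_hash = config_hash(config))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_filter_report(freport, file.path(out_dir, "mutations_filtered.tsv"),
                        file.path(out_dir, "filter_summary.json"))
    write_clonality(annotated, file.path(out_dir, "clonality.tsv"))
    write_tsv(candidates, file.path(out_dir, "peptide_candidates.tsv"))
    write_tsv(calls, file.path(out_dir, "binding_calls.tsv"))
    write_cohort_summary(summary_tables, out_dir)
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(sprintf("clonepitope %s", as.character(utils::packageVersion("clonepitope"))),
                 sprintf("config_hash %s", summary$config_hash),
                 sprintf("time %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                 log_lines),
               file.path(out_dir, "run.log"))
  }
  invisible(list(summary = summary,
                 tables = list(annotated = annotated, candidates = candidates,
                               calls = calls, cohort = summary_tables),
                 qc = samples$dropped))
}
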