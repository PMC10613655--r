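# One-call orchestration: preprocess -> differential -> association ->
# cross-reactivity -> enrichment, with a run manifest reconciling the
# counts at every stage.

#' Pipeline configuration
#'
#' Houses every tunable threshold of the pipeline with its conventional
#' default: replicate CV% cutoff 20, unadjusted significance level 0.05,
#' correlated-pair screen at r-squared 0.7, isoform homology screen at 50%
#' identity.
#'
#' @param cv_threshold replicate CV% cutoff.
#' @param floor linear net-intensity floor before log2.
#' @param alpha unadjusted p-value cutoff for differential calls.
#' @param r2_threshold squared-correlation cutoff for the pair screen.
#' @param isoform_identity_threshold percent-identity cutoff for the
#'   isoform screen.
#' @param loess_span,loess_iterations cyclic loess parameters.
#' @param psa_breadth_min minimum reactivity breadth for a PSA flag.
#' @param seed seed for the pipeline's stochastic steps (loess pair
#'   subsampling).
#' @param fg_col,bg_col GPR intensity column names.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cv_threshold = 20, floor = 1, alpha = 0.05,
                            r2_threshold = 0.7, isoform_identity_threshold = 50,
                            loess_span = 0.7, loess_iterations = 3,
                            psa_breadth_min = 0.25, seed = 1,
                            fg_col = "F532 Mean", bg_col = "B532 Mean") {
  cfg <- as.list(environment())
  stopifnot(cfg$cv_threshold > 0, cfg$floor > 0,
            cfg$alpha > 0, cfg$alpha <= 1,
            cfg$r2_threshold >= 0, cfg$r2_threshold <= 1,
            cfg$isoform_identity_threshold >= 0, cfg$isoform_identity_threshold <= 100,
            cfg$loess_span > 0, cfg$loess_span <= 1, cfg$loess_iterations >= 1,
            cfg$psa_breadth_min >= 0, cfg$psa_breadth_min <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a QC report as JSON
#' @param qc QC list from [preprocess_study()].
#' @param path output path.
#' @export
write_qc <- function(qc, path) {
  jsonlite::write_json(qc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_study_inputs <- function(gpr_dir, gal_path, meta_path, config) {
  gal <- read_gal(gal_path)
  metadata <- read_metadata(meta_path)
  gprs <- sort(list.files(gpr_dir, pattern = "\\.gpr$", full.names = TRUE))
  if (!length(gprs)) stop_sp("no .gpr files in ", gpr_dir)
  spots <- do.call(rbind, lapply(gprs, read_gpr, layout = gal,
                                 fg_col = config$fg_col, bg_col = config$bg_col))
  missing_md <- setdiff(unique(spots$sample_id), metadata$sample_id)
  if (length(missing_md)) {
    stop_sp("GPR sample(s) absent from metadata: ",
            paste(missing_md, collapse = ", "))
  }
  list(gal = gal, metadata = metadata, spots = spots)
}

#' Run the complete analysis
#'
#' Orchestrates preprocessing, differential testing, covariate
#' correlations, cross-reactivity adjudication (when a panel FASTA is
#' given) and set overrepresentation (when a GMT is given), writing
#' `matrix.tsv`, `qc.json`, `diff.tsv`, `assoc.tsv`, `xreact.json`,
#' `enrich.tsv` and `manifest.json` under `out_dir`.  Deterministic for a
#' fixed config and inputs.
#'
#' @param gpr_dir directory of per-sample `.gpr` files.
#' @param gal_path path to the GAL layout.
#' @param meta_path path to the metadata TSV.
#' @param out_dir output directory (created if needed).
#' @param fasta_path optional panel FASTA for the cross-reactivity check.
#' @param gmt_path optional GMT annotation file for enrichment.
#' @param config a [pipeline_config()].
#' @param timestamp include a `created` field in the manifest (disable for
#'   byte-identical reruns).
#' @return the manifest list, invisibly; all artifacts are on disk.
#' @export
run_all <- function(gpr_dir, gal_path, meta_path, out_dir,
                    fasta_path = NULL, gmt_path = NULL,
                    config = pipeline_config(), timestamp = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_sp("[", name, "] ", conditionMessage(e),
              " -- fix the stage's inputs and rerun")
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- stage("io", read_study_inputs(gpr_dir, gal_path, meta_path, config))

  pre <- stage("preprocess", preprocess_study(
    inputs$spots, inputs$metadata,
    floor = config$floor, cv_threshold = config$cv_threshold,
    psa_breadth_min = config$psa_breadth_min,
    loess_span = config$loess_span, loess_iterations = config$loess_iterations,
    seed = config$seed))
  write_matrix(pre$amat, file.path(out_dir, "matrix.tsv"))
  write_qc(pre$qc, file.path(out_dir, "qc.json"))

  diff_tab <- stage("differential", run_differential(
    pre$amat, inputs$metadata, alpha = config$alpha))
  utils::write.table(diff_tab, file.path(out_dir, "diff.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  assoc <- stage("association", {
    rbind(correlate_matrix(pre$amat, inputs$metadata, "age"),
          if (any(inputs$metadata$diagnosis == "case" & !is.na(inputs$metadata$ados2)))
            correlate_matrix(pre$amat, inputs$metadata, "ados2"))
  })
  utils::write.table(assoc, file.path(out_dir, "assoc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  significant <- diff_tab$antigen[diff_tab$call != "ns"]
  xreact <- NULL
  if (!is.null(fasta_path)) {
    xreact <- stage("crossreact", cross_react_report(
      pre$amat, significant, read_fasta(fasta_path),
      r2_threshold = config$r2_threshold,
      identity_threshold = config$isoform_identity_threshold))
    write_xreact(xreact, file.path(out_dir, "xreact.json"))
  }
  enrich <- NULL
  if (!is.null(gmt_path)) {
    enrich <- stage("enrichment", {
      background <- names(pre$amat$antigen_status)[pre$amat$antigen_status == "retained"]
      overrepresentation(intersect(significant, background),
                         read_gmt(gmt_path), background)
    })
    utils::write.table(enrich, file.path(out_dir, "enrich.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "seroprofiler",
    version = as.character(packageVersion("seroprofiler")),
    config = unclass(config),
    counts = c(pre$qc$counts, list(
      cv_flagged_groups = pre$qc$cv_flagged_groups,
      n_significant = length(significant),
      n_up = sum(diff_tab$call == "up"),
      n_down = sum(diff_tab$call == "down"),
      n_correlated_pairs = if (!is.null(xreact)) nrow(xreact$correlated_pairs) else NA,
      n_enriched_terms = if (!is.null(enrich)) nrow(enrich) else NA
    )),
    outputs = list.files(out_dir)
  )
  if (timestamp) manifest$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
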