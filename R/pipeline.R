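#' Run the multimodal early-response-prediction pipeline end to end
#'
#' Orchestrates the full analysis on a synthetic cohort with strict cohort
#' separation: the discovery cohort trains the RNA classifier (differential
#' expression for feature candidates, repeated stratified cross-validation
#' over the feature grid), the test cohort selects the best candidate and
#' tunes the multimodal uncertainty bands, and the validation cohort is
#' evaluated once with everything frozen. Validation truth labels are never
#' passed to the training or tuning stages. ctDNA is quantified and
#' dichotomized for every patient independently of the cohort split, as in
#' the clinical analysis.
#'
#' @param cfg A [sim_config()] describing the synthetic cohort.
#' @param fixed_composition Use the exact study composition (42 CB of 93)
#'   instead of Bernoulli draws; requires `cfg$n_patients == 93`.
#' @param rna_enabled When `FALSE`, the RNA and multimodal stages are
#'   skipped and the ctDNA-only predictions are evaluated.
#' @param candidate_floor Minimum number of candidate genes fed to the
#'   classifier; when the discovery DEG list is shorter, the top genes by
#'   p value are used instead (default 100).
#' @param outdir Optional directory; when given, stage outputs and the run
#'   manifest are written there as tab-separated/JSON files.
#' @return List with `patients`, `ctdna`, `dea`, `cv`, `selection`,
#'   `model`, `multimodal` (tuned config + grid), `evaluation` (test and
#'   validation metrics), and `manifest`.
#' @export
run_pipeline <- function(cfg = sim_config(), fixed_composition = TRUE,
                         rna_enabled = TRUE, candidate_floor = 100L,
                         outdir = NULL) {
  patients <- if (fixed_composition && cfg$n_patients == 93L) {
    simulate_cohort(cfg, n_cb = 42L)
  } else {
    simulate_cohort(cfg)
  }
  truth <- ifelse(patients$cb, "CB", "N-CB")
  names(truth) <- patients$patient_id

  ## --- ctDNA stage (full cohort) -------------------------------------
  assay <- simulate_ctdna_assay(patients, cfg)
  ctdna <- quantify_cohort_ctdna(assay)
  ctdna_perf <- confusion_metrics(
    ctdna$ctdna_label[match(patients$patient_id, ctdna$patient_id)], truth)

  result <- list(patients = patients, ctdna = ctdna,
                 ctdna_performance = ctdna_perf)

  if (!rna_enabled) {
    result$evaluation <- list(
      ctdna_only = TRUE,
      survival = stratify_survival(ctdna$ctdna_label, patients$pfs_months,
                                   patients$event))
    result$manifest <- pipeline_manifest(cfg, rna_enabled)
    if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
    return(result)
  }

  ## --- RNA stage: discovery ------------------------------------------
  expr <- simulate_expression(patients, cfg)
  counts <- filter_genes(expr$counts, groups = expr$samples$group)
  nf <- tmm_factors(counts)
  values <- transform_counts(counts, nf)

  disc <- expr$samples[expr$samples$cohort == "discovery", , drop = FALSE]
  dea_cb <- paired_dea(counts[, disc$sample_id, drop = FALSE], disc, "CB")
  degs <- dea_cb$gene[dea_cb$deg]
  candidates_genes <- if (length(degs) >= candidate_floor) degs else
    dea_cb$gene[seq_len(min(candidate_floor, nrow(dea_cb)))]

  feat <- feature_changes(values, expr$samples, candidates_genes)
  cohort_of <- patients$cohort[match(rownames(feat), patients$patient_id)]
  y_all <- patients$cb[match(rownames(feat), patients$patient_id)]

  X_disc <- feat[cohort_of == "discovery", , drop = FALSE]
  y_disc <- y_all[cohort_of == "discovery"]
  plan <- cv_plan(seed = stage_seed(cfg$seed, "cv"))
  cv <- cross_validate(X_disc, y_disc, plan)

  ## --- test cohort: model selection + band tuning --------------------
  test_ids <- rownames(feat)[cohort_of == "test"]
  X_test <- feat[test_ids, , drop = FALSE]
  pts_test <- patients[match(test_ids, patients$patient_id), ]
  sel <- select_best_model(cv$candidates, X_test, pts_test$cb,
                           pts_test$pfs_months, pts_test$event)
  model <- sel$model

  pred_table <- function(ids) {
    data.frame(
      patient_id = ids,
      ratio = ctdna$ratio[match(ids, ctdna$patient_id)],
      rna_prob = predict_proba(model, feat[ids, , drop = FALSE]),
      rna_label = classify(model, feat[ids, , drop = FALSE]),
      ctdna_label = ctdna$ctdna_label[match(ids, ctdna$patient_id)],
      stringsAsFactors = FALSE)
  }
  test_pred <- pred_table(test_ids)
  tuning <- grid_search_bands(test_pred, truth[test_ids])

  ## --- frozen evaluation on validation -------------------------------
  val_ids <- rownames(feat)[cohort_of == "validation"]
  val_pred <- pred_table(val_ids)
  pts_val <- patients[match(val_ids, patients$patient_id), ]
  val_mm <- apply_multimodal(tuning$config, val_pred, truth[val_ids],
                             pts_val$pfs_months, pts_val$event)
  evaluation <- list(
    test = list(
      rna = confusion_metrics(test_pred$rna_label, truth[test_ids]),
      rna_auc = roc_auc(1 - test_pred$rna_prob, truth[test_ids])$auc,
      ctdna = confusion_metrics(test_pred$ctdna_label, truth[test_ids]),
      multimodal = confusion_metrics(
        apply_arbitration(test_pred, tuning$config), truth[test_ids])),
    validation = list(
      rna = confusion_metrics(val_pred$rna_label, truth[val_ids]),
      rna_auc = roc_auc(1 - val_pred$rna_prob, truth[val_ids])$auc,
      ctdna = confusion_metrics(val_pred$ctdna_label, truth[val_ids]),
      multimodal = val_mm$performance,
      survival = val_mm$survival))

  result <- c(result, list(
    dea = dea_cb, candidate_genes = candidates_genes, cv = cv$cv,
    cv_summary = cv$summary, selection = sel$scores, winner = sel$winner,
    model = model, test_predictions = test_pred,
    validation_predictions = val_pred, multimodal = tuning,
    evaluation = evaluation,
    manifest = pipeline_manifest(cfg, rna_enabled)))
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

# Per-patient OT - BL change of normalized expression for selected genes.
feature_changes <- function(values, samples, genes) {
  pats <- intersect(samples$patient_id[samples$timepoint == "BL"],
                    samples$patient_id[samples$timepoint == "OT"])
  bl <- samples$sample_id[match(paste(pats, "BL"),
                                paste(samples$patient_id, samples$timepoint))]
  ot <- samples$sample_id[match(paste(pats, "OT"),
                                paste(samples$patient_id, samples$timepoint))]
  d <- t(values[genes, ot, drop = FALSE] - values[genes, bl, drop = FALSE])
  rownames(d) <- pats
  d
}

pipeline_manifest <- function(cfg, rna_enabled) {
  list(
    package_version = as.character(utils::packageVersion("erpredict")),
    r_version = R.version.string,
    seed = cfg$seed,
    rna_enabled = rna_enabled,
    parameters = list(
      independent_calling = list(min_reads = 5, min_vaf = 0.001),
      dependent_calling = list(min_reads = 3, control_fold = 20,
                               wbc_fold = 3),
      cnv_thresholds = list(loss = c(-0.3, -0.1), gain = c(0.3, 0.1),
                            maf = 0.6),
      copies_per_ng = 303,
      gene_filter = list(cpm_min = 1, cv_max = 100),
      cv = list(n_repeats = 10, n_folds = 3),
      feature_grid = c(10, 15, 20),
      prob_cutoff = 0.55,
      band_grids = list(ratio = c(0, 0.25, 0.5, 0.75, 1),
                        prob = c(0, 0.05, 0.1, 0.15, 0.2))),
    sim_config = unclass(cfg),
    timestamp = format(Sys.time(), tz = "UTC")
  )
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$ctdna, file.path(outdir, "ctdna_quant.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$test_predictions)) {
    utils::write.table(result$test_predictions,
                       file.path(outdir, "test_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$validation_predictions,
                       file.path(outdir, "validation_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$multimodal$grid,
                       file.path(outdir, "band_grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_spls_model(result$model, file.path(outdir, "rna_model.json"))
  }
  manifest <- result$manifest
  files <- list.files(outdir, full.names = TRUE)
  manifest$file_md5 <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
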