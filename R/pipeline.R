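#' End-to-end pipeline configuration
#'
#' Bundles every stage parameter of the generate - denoise - mask - metrics
#' - split - sample - train - predict - evaluate chain. All randomness
#' derives from `generator$seed` via a fixed counter scheme, so a rerun
#' from the same configuration is bit-reproducible.
#'
#' @param generator A `generator_config`.
#' @param mnf_k MNF components kept per core (default 20).
#' @param tissue_anchor_cm1 Tissue-mask anchor band (default 1650).
#' @param tissue_threshold Absorbance cutoff, or `NULL` for Otsu.
#' @param region_table A `region_table` (default: the 41-region table).
#' @param fractions Split fractions (model / validation / test).
#' @param n_folds Cross-validation folds available on the model set.
#' @param n_trees Forest size (default 50).
#' @param chosen_classes Class names scoring cores/patients
#'   (default Cancer).
#' @param score_mode `"fraction"` or `"count"` entity scores.
#' @param positive_group Patient-level ROC positive group.
#' @return A `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       mnf_k = 20L,
                       tissue_anchor_cm1 = 1650,
                       tissue_threshold = NULL,
                       region_table = default_region_table(),
                       fractions = c(model = 0.5, validation = 0.25,
                                     test = 0.25),
                       n_folds = 4L,
                       n_trees = 50L,
                       chosen_classes = "Cancer",
                       score_mode = "fraction",
                       positive_group = "cancer") {
  axis <- build_spectral_axis()
  if (mnf_k < 1 || mnf_k > length(axis$wavenumbers))
    stop("mnf_k outside [1, bands]", call. = FALSE)
  structure(list(generator = generator, mnf_k = as.integer(mnf_k),
                 tissue_anchor_cm1 = tissue_anchor_cm1,
                 tissue_threshold = tissue_threshold,
                 region_table = region_table, fractions = fractions,
                 n_folds = as.integer(n_folds),
                 n_trees = as.integer(n_trees),
                 chosen_classes = chosen_classes, score_mode = score_mode,
                 positive_group = positive_group),
            class = "run_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the cohort, denoises each array core-by-core with MNF, masks
#' tissue by thresholding the Amide I band, extracts metric vectors,
#' splits patients, draws a class- and array-balanced training sample,
#' trains the forest, predicts digital-staining images for every array, and
#' evaluates: per-class one-vs-rest pixel AUC on test-set annotated pixels,
#' plus core- and patient-level chosen-class ROC/AUC with the Youden-J
#' operating point.
#'
#' @param config A `run_config`.
#' @param outdir Optional directory; when given, stage outputs (cubes,
#'   labels, manifest, metric table, split plan, evaluation report and a
#'   run manifest with content hashes) are written there.
#' @param axis Spectral axis (default 3850-900 cm^-1, 765 points).
#' @param verbose Print stage progress.
#' @return An `eval_report`: `confusion`, `pixel_auc` (named per class),
#'   `pixel_roc` (list of `roc_result`), `core_roc`, `patient_roc`,
#'   `core_auc`, `patient_auc`, `youden`, `sensitivity_pct`, `n_patients`,
#'   `n_cores`, `split_plan`, `model`, `scores`, `predictions`, `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL,
                         axis = build_spectral_axis(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  gen <- config$generator
  seed <- gen$seed

  say("[generate] %d TMAs x %d cores (%s)", gen$n_tmas, gen$cores_per_tma,
      gen$definition_tag)
  cohort <- generate_cohort(gen, axis = axis)

  tables <- list()
  preds_shapes <- list()
  cubes_dn <- list()
  for (tid in names(cohort$tmas)) {
    sc <- cohort$tmas[[tid]]
    say("[denoise] %s: MNF k = %d, core-by-core", tid, config$mnf_k)
    dn <- mnf_denoise_per_core(sc$cube, sc$manifest, k = config$mnf_k)
    say("[mask] %s: anchor %g cm^-1", tid, config$tissue_anchor_cm1)
    mask <- tissue_mask(dn, anchor_cm1 = config$tissue_anchor_cm1,
                        threshold = config$tissue_threshold)
    say("[metrics] %s: %d masked pixels", tid, sum(mask))
    tables[[tid]] <- extract_metrics_image(dn, mask, sc$labels,
                                           sc$manifest,
                                           table = config$region_table)
    preds_shapes[[tid]] <- dim(sc$labels$labels)
    cubes_dn[[tid]] <- dn
  }
  combined <- do.call(rbind, lapply(tables, function(t) {
    class(t) <- "data.frame"; t
  }))
  rownames(combined) <- NULL
  class(combined) <- c("metric_table", "data.frame")
  attr(combined, "metric_names") <- attr(tables[[1]], "metric_names")

  say("[split] %d patients", nrow(cohort$manifest$patients))
  plan <- make_split_plan(cohort$manifest, fractions = config$fractions,
                          n_folds = config$n_folds,
                          seed = child_seed(seed, 101))
  say("[sample] balanced draw from model set")
  samp <- balanced_sample(combined, plan, seed = child_seed(seed, 102))
  say("[train] %d trees on %d rows (%d per class)", config$n_trees,
      nrow(samp$rows), samp$quota$per_class_n)
  model <- train_tissue_model(samp$rows, n_trees = config$n_trees,
                              seed = child_seed(seed, 103),
                              quota = samp$quota)

  say("[predict] posteriors for %d pixels", nrow(combined))
  posteriors <- predict_posteriors(model, combined)
  preds <- list()
  for (tid in names(tables)) {
    sel <- combined$tma_id == tid
    preds[[tid]] <- predict_image(model, combined[sel, , drop = FALSE],
                                  preds_shapes[[tid]],
                                  posteriors = posteriors[sel, ,
                                                          drop = FALSE])
  }

  say("[evaluate] test-set pixel / core / patient ROC")
  test_ids <- split_patients(plan, "test")
  test_sel <- combined$patient_id %in% test_ids & combined$label > 0L
  test_post <- posteriors[test_sel, , drop = FALSE]
  test_lab <- combined$label[test_sel]
  pixel_roc <- lapply(names(TISSUE_CLASSES), function(cls) {
    tryCatch(pixel_roc_auc(test_post, test_lab, cls),
             error = function(e) NULL)
  })
  names(pixel_roc) <- names(TISSUE_CLASSES)
  pixel_auc <- vapply(pixel_roc, function(r)
    if (is.null(r)) NA_real_ else r$auc, numeric(1))

  pred_lab <- max.col(test_post, ties.method = "first")
  confusion <- table(
    annotation = factor(names(TISSUE_CLASSES)[test_lab],
                        levels = names(TISSUE_CLASSES)),
    prediction = factor(names(TISSUE_CLASSES)[pred_lab],
                        levels = names(TISSUE_CLASSES)))

  scores <- cohort_scores(preds, cohort$manifest,
                          chosen_classes = config$chosen_classes,
                          mode = config$score_mode)
  test_cores <- scores$cores[scores$cores$patient_id %in% test_ids, ]
  test_pats <- scores$patients[scores$patients$patient_id %in% test_ids, ]
  core_path <- cohort$manifest$patients$pathology[
    match(test_cores$patient_id, cohort$manifest$patients$patient_id)]
  core_roc <- entity_roc_auc(test_cores$score, core_path,
                             positive_group = config$positive_group)
  patient_roc <- entity_roc_auc(test_pats$score, test_pats$pathology,
                                positive_group = config$positive_group)
  yj <- youden_point(patient_roc)

  report <- structure(list(
    confusion = unclass(confusion),
    pixel_auc = pixel_auc, pixel_roc = pixel_roc,
    core_roc = core_roc, core_auc = core_roc$auc,
    patient_roc = patient_roc, patient_auc = patient_roc$auc,
    youden = yj, sensitivity_pct = 100 * yj[["sensitivity"]],
    n_patients = nrow(test_pats), n_cores = nrow(test_cores),
    n_test_pixels = sum(test_sel),
    split_plan = plan, model = model, scores = scores,
    predictions = preds, manifest = cohort$manifest,
    quota = samp$quota), class = "eval_report")

  if (!is.null(outdir)) .write_run_artifacts(config, cohort, cubes_dn,
                                             combined, plan, report, outdir)
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report (test set):\n")
  cat(sprintf("  pixels: %d annotated; per-class AUC:\n", x$n_test_pixels))
  for (cls in names(x$pixel_auc))
    cat(sprintf("    %-13s %.4f\n", cls, x$pixel_auc[[cls]]))
  cat(sprintf("  cores:    n = %2d, AUC = %.4f\n", x$n_cores, x$core_auc))
  cat(sprintf("  patients: n = %2d, AUC = %.4f\n", x$n_patients,
              x$patient_auc))
  cat(sprintf("  Youden-J sensitivity = %.1f%% (specificity %.1f%%)\n",
              x$sensitivity_pct, 100 * x$youden[["specificity"]]))
  invisible(x)
}

.write_run_artifacts <- function(config, cohort, cubes_dn, combined, plan,
                                 report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tid in names(cohort$tmas)) {
    sc <- cohort$tmas[[tid]]
    p_cube <- file.path(outdir, paste0(tid, "_denoised.img"))
    write_cube(cubes_dn[[tid]], p_cube)
    p_lab <- file.path(outdir, paste0(tid, "_labels.png"))
    write_labels(sc$labels, p_lab)
    p_pred <- file.path(outdir, paste0(tid, "_prediction.png"))
    png::writePNG(render_prediction(report$predictions[[tid]]), p_pred)
    paths <- c(paths, p_cube, paste0(p_cube, ".hdr"), p_lab, p_pred)
  }
  p_man <- file.path(outdir, "manifest.json")
  write_manifest(cohort$manifest, p_man)
  p_met <- file.path(outdir, "metrics.csv")
  write_metric_table(combined, p_met)
  p_plan <- file.path(outdir, "split_plan.json")
  write_split_plan(plan, p_plan)
  p_eval <- file.path(outdir, "eval_report.json")
  jsonlite::write_json(list(
    pixel_auc = as.list(report$pixel_auc),
    core_auc = report$core_auc, patient_auc = report$patient_auc,
    sensitivity_pct = report$sensitivity_pct,
    confusion = report$confusion,
    n_patients = report$n_patients, n_cores = report$n_cores),
    p_eval, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p_man, p_met, p_plan, p_eval)
  hashes <- tools::md5sum(paths)
  names(hashes) <- basename(paths)
  jsonlite::write_json(list(
    parameters = list(
      seed = config$generator$seed, mnf_k = config$mnf_k,
      n_trees = config$n_trees, fractions = as.list(config$fractions),
      definition_tag = config$generator$definition_tag,
      noise_sd = config$generator$noise_sd,
      chosen_classes = config$chosen_classes,
      score_mode = config$score_mode),
    artifacts = as.list(hashes)),
    file.path(outdir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
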