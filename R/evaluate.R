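#' @title Pixel, core and patient level evaluation
#' @description Classifier quality is read at three granularities: per-pixel
#'   one-vs-rest ROC/AUC on the posterior of each class, and ROC/AUC on
#'   core- and patient-level scores defined as the content of a chosen
#'   class (e.g. Cancer) among the predicted tissue pixels of the entity.
#'   AUC uses the trapezoidal rule on the tie-grouped ROC, which equals the
#'   Mann-Whitney statistic under the midrank convention.
#' @name irhisto-evaluation
NULL

#' ROC curve and AUC of a score against binary labels
#'
#' Thresholds sweep the distinct score values from high to low; tied scores
#' move the operating point diagonally, so trapezoidal integration of the
#' curve reproduces the Mann-Whitney U statistic with midranks for ties.
#'
#' @param scores Numeric scores, larger = more positive-like.
#' @param positive Logical (or 0/1) labels, at least one of each.
#' @return A `roc_result`: `curve` (data frame `threshold`, `fpr`, `tpr`,
#'   first row (0,0) at +Inf) and `auc`.
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  if (anyNA(scores) || anyNA(positive))
    stop("scores/labels contain NA", call. = FALSE)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: need at least one positive and one negative",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positive[ord]
  # group ties: cumulative counts at each distinct threshold
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_group]
  fp <- cumsum(!p)[last_of_group]
  curve <- data.frame(threshold = c(Inf, s[last_of_group]),
                      fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  structure(list(curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d pos / %d neg)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' One-vs-rest pixel ROC/AUC for a class
#'
#' @param posteriors Matrix (pixels x classes) of posterior probabilities,
#'   columns named by class.
#' @param labels Integer vector of true class ids per pixel.
#' @param class Class name (e.g. `"Cancer"`).
#' @return A `roc_result` for the class posterior against membership.
#' @export
pixel_roc_auc <- function(posteriors, labels, class) {
  id <- TISSUE_CLASSES[[class]]
  if (is.null(id)) stop("unknown class: ", class, call. = FALSE)
  roc_auc(posteriors[, class], labels == id)
}

#' Chosen-class score of a core or patient footprint
#'
#' Counts the predicted-tissue pixels of the chosen class(es) within the
#' footprint; `mode = "fraction"` (default) divides by the tissue pixels in
#' the footprint, which is robust to entities contributing different
#' numbers of cores, `mode = "count"` returns the raw pixel count.
#'
#' @param pred A `prediction_image`.
#' @param footprint Logical matrix selecting the entity's pixels.
#' @param chosen_classes Character vector of class names (default Cancer).
#' @param mode `"fraction"` or `"count"`.
#' @return Scalar score; `NA` when the footprint has no tissue pixels
#'   (entity excluded upstream).
#' @export
entity_score <- function(pred, footprint, chosen_classes = "Cancer",
                         mode = c("fraction", "count")) {
  mode <- match.arg(mode)
  ids <- TISSUE_CLASSES[chosen_classes]
  cm <- pred$class_map[footprint]
  tissue <- sum(cm > 0L)
  hits <- sum(cm %in% ids)
  if (mode == "count") return(hits)
  if (tissue == 0L) return(NA_real_)
  hits / tissue
}

#' Core- and patient-level scores for a whole cohort
#'
#' @param preds Named list of `prediction_image`s, one per array (names are
#'   tma ids).
#' @param manifest Cohort `tma_manifest`.
#' @param chosen_classes Class names whose pixel content scores an entity.
#' @param mode `"fraction"` or `"count"` (see [entity_score()]).
#' @return List of data frames `cores` (`core_id`, `patient_id`, `score`)
#'   and `patients` (`patient_id`, `pathology`, `score`); patient scores
#'   aggregate all the patient's cores (pooled pixels for `"fraction"`,
#'   summed counts for `"count"`). Entities without tissue pixels are
#'   dropped.
#' @export
cohort_scores <- function(preds, manifest, chosen_classes = "Cancer",
                          mode = c("fraction", "count")) {
  mode <- match.arg(mode)
  ids <- TISSUE_CLASSES[chosen_classes]
  cores <- manifest$cores
  hits <- tissue <- numeric(nrow(cores))
  for (i in seq_len(nrow(cores))) {
    core <- cores[i, ]
    pred <- preds[[core$tma_id]]
    if (is.null(pred)) stop("no prediction for array ", core$tma_id,
                            call. = FALSE)
    fp <- core_footprint(core, nrow(pred$class_map), ncol(pred$class_map))
    cm <- pred$class_map[fp]
    tissue[i] <- sum(cm > 0L)
    hits[i] <- sum(cm %in% ids)
  }
  core_score <- if (mode == "count") hits else
    ifelse(tissue > 0, hits / tissue, NA_real_)
  core_df <- data.frame(core_id = cores$core_id,
                        patient_id = cores$patient_id,
                        score = core_score, stringsAsFactors = FALSE)
  agg <- function(pid) {
    j <- cores$patient_id == pid
    if (mode == "count") return(sum(hits[j]))
    if (sum(tissue[j]) == 0) return(NA_real_)
    sum(hits[j]) / sum(tissue[j])
  }
  pat <- manifest$patients
  pat_df <- data.frame(
    patient_id = pat$patient_id, pathology = pat$pathology,
    score = vapply(pat$patient_id, agg, numeric(1)),
    stringsAsFactors = FALSE)
  list(cores = core_df[!is.na(core_df$score), , drop = FALSE],
       patients = pat_df[!is.na(pat_df$score), , drop = FALSE])
}

#' ROC/AUC on core or patient scores
#'
#' @param scores Numeric entity scores.
#' @param pathology Character pathology per entity.
#' @param positive_group `"cancer"` (vs rest) or `"inflammation"` (vs
#'   benign; cancer entities are excluded).
#' @return A `roc_result`.
#' @export
entity_roc_auc <- function(scores, pathology,
                           positive_group = c("cancer", "inflammation")) {
  positive_group <- match.arg(positive_group)
  if (positive_group == "inflammation") {
    keep <- pathology %in% c("inflammation", "benign")
    scores <- scores[keep]; pathology <- pathology[keep]
  }
  roc_auc(scores, pathology == positive_group)
}

#' Confusion matrix over masked annotated pixels
#'
#' @param predicted Integer class map (rows x cols).
#' @param labels Integer annotation map (same shape; 0 = unannotated).
#' @param mask Logical matrix of pixels to count.
#' @return classes x classes integer matrix, rows = annotation, cols =
#'   prediction; row sums equal per-class annotated pixel counts within the
#'   mask.
#' @export
confusion_counts <- function(predicted, labels, mask) {
  stopifnot(identical(dim(predicted), dim(labels)),
            identical(dim(labels), dim(mask)))
  sel <- mask & labels > 0L
  lv <- factor(names(TISSUE_CLASSES)[labels[sel]],
               levels = names(TISSUE_CLASSES))
  pv <- factor(names(TISSUE_CLASSES)[ifelse(predicted[sel] > 0L,
                                            predicted[sel], NA)],
               levels = names(TISSUE_CLASSES))
  m <- table(annotation = lv, prediction = pv, useNA = "no")
  unclass(m)
}

#' Sensitivity/specificity at the Youden-J operating point
#'
#' Picks the ROC point maximizing TPR - FPR and reports the rates there.
#'
#' @param roc A `roc_result`.
#' @return Named numeric: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_point <- function(roc) {
  j <- roc$curve$tpr - roc$curve$fpr
  i <- which.max(j)
  c(threshold = roc$curve$threshold[i],
    sensitivity = roc$curve$tpr[i],
    specificity = 1 - roc$curve$fpr[i],
    youden_j = j[i])
}
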