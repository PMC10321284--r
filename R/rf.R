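#' @title Random-forest tissue classification
#' @description A 50-tree random forest on the 123 metric features
#'   discriminates the six tissue classes. Training data are class-balanced
#'   upstream ([balanced_sample()]); prediction paints every tissue pixel
#'   with its argmax class and keeps the full posterior stack for ROC
#'   analysis ("digital staining").
#' @name irhisto-rf
NULL

# fixed rendering palette; Benign is green by convention, the remaining
# colors are package-defined
CLASS_PALETTE <- c(Background = "#000000", Benign = "#2ca02c",
                   Cancer = "#d62728", Necrosis = "#8c564b",
                   Inflammation = "#9467bd", Fiber = "#ff7f0e",
                   Blood = "#e31a7f")

#' Train a tissue-class random forest
#'
#' @param rows A `metric_table` of training rows (balanced upstream; must
#'   contain >= 2 classes).
#' @param n_trees Number of trees (default 50).
#' @param seed Training seed (forest growth is deterministic under it).
#' @param quota Optional `sampling_quota` recorded with the model.
#' @return A `trained_model`: `forest`, `feature_names`, `class_table`,
#'   `n_trees`, `seed`, `training_quota` (if attached), and the out-of-bag
#'   error of the fit.
#' @export
train_tissue_model <- function(rows, n_trees = 50L, seed = 1L,
                               quota = NULL) {
  feats <- attr(rows, "metric_names") %||%
    setdiff(names(rows), c("tma_id", "core_id", "patient_id",
                           "row", "col", "label"))
  x <- as.matrix(rows[, feats, drop = FALSE])
  y <- factor(names(TISSUE_CLASSES)[rows$label],
              levels = names(TISSUE_CLASSES))
  y <- droplevels(y)
  if (nlevels(y) < 2L)
    stop("training data contain a single class", call. = FALSE)
  forest <- with_seed(seed,
    randomForest::randomForest(x, y, ntree = n_trees))
  structure(list(forest = forest, feature_names = feats,
                 class_table = default_class_table(),
                 n_trees = as.integer(n_trees), seed = seed,
                 training_quota = quota,
                 oob_error = mean(forest$err.rate[n_trees, "OOB"])),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model: %d trees, %d features, OOB error %.3f\n",
              x$n_trees, length(x$feature_names), x$oob_error))
  invisible(x)
}

#' Posterior class probabilities for metric-table rows
#'
#' @param model A `trained_model`.
#' @param table A `metric_table` whose metric columns match the model's
#'   feature descriptor.
#' @return Matrix (rows x classes) of posterior probabilities (vote
#'   fractions), columns in canonical class order.
#' @export
predict_posteriors <- function(model, table) {
  missing <- setdiff(model$feature_names, names(table))
  if (length(missing))
    stop("metric table lacks model features: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  x <- as.matrix(table[, model$feature_names, drop = FALSE])
  p <- stats::predict(model$forest, x, type = "prob")
  out <- matrix(0, nrow(x), length(TISSUE_CLASSES),
                dimnames = list(NULL, names(TISSUE_CLASSES)))
  out[, colnames(p)] <- p
  out
}

#' Predict a digital-staining image
#'
#' Assigns every pixel of the metric table its argmax posterior class and
#' assembles the per-class posterior maps; pixels outside the table (non-
#' tissue) stay class 0 with zero posteriors.
#'
#' @param model A `trained_model`.
#' @param table A `metric_table` with `row`/`col` provenance (0-based).
#' @param shape Integer `(rows, cols)` of the target image.
#' @param posteriors Optional precomputed posterior matrix for `table`'s
#'   rows (as returned by [predict_posteriors()]).
#' @return A `prediction_image`: `class_map` (rows x cols integer),
#'   `posteriors` (rows x cols x classes array), `palette`.
#' @export
predict_image <- function(model, table, shape, posteriors = NULL) {
  nr <- shape[1]; nc <- shape[2]
  class_map <- matrix(0L, nr, nc)
  post <- array(0, dim = c(nr, nc, length(TISSUE_CLASSES)),
                dimnames = list(NULL, NULL, names(TISSUE_CLASSES)))
  if (nrow(table)) {
    p <- posteriors %||% predict_posteriors(model, table)
    idx <- table$row + 1L + table$col * nr       # 0-based provenance
    pred <- max.col(p, ties.method = "first")
    class_map[idx] <- TISSUE_CLASSES[pred]
    for (j in seq_along(TISSUE_CLASSES)) {
      plane <- matrix(0, nr, nc)
      plane[idx] <- p[, j]
      post[, , j] <- plane
    }
  }
  structure(list(class_map = class_map, posteriors = post,
                 palette = CLASS_PALETTE),
            class = "prediction_image")
}

#' Render a prediction image to an RGB array
#' @param pred A `prediction_image`.
#' @return rows x cols x 3 numeric array in [0, 1], using the fixed class
#'   palette (Benign green).
#' @export
render_prediction <- function(pred) {
  ids <- pred$class_map + 1L                 # palette is 0-indexed by class
  rgb <- grDevices::col2rgb(CLASS_PALETTE) / 255
  out <- array(0, dim = c(dim(pred$class_map), 3))
  for (ch in 1:3)
    out[, , ch] <- matrix(rgb[ch, ids], nrow(pred$class_map))
  out
}
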