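#' @title Patient-level splitting and class-balanced sampling
#' @description Patients — not pixels or cores — are the unit of
#'   partitioning: a patient appearing on several arrays still receives a
#'   single assignment, so no patient's pixels can reach both a training and
#'   an evaluation set. Training draws are balanced twice over: every class
#'   contributes the same number of pixels (set by the scarcest class), and
#'   within a class the pixels are spread as evenly as the data allow across
#'   arrays.
#' @name irhisto-splits
NULL

#' Stratified patient split with cross-validation folds
#'
#' Randomly assigns every patient to the model, validation or test set,
#' stratified by pathology group so each group is represented in each set,
#' then deals the model-set patients into cross-validation folds balanced
#' to within one patient.
#'
#' @param manifest A `tma_manifest` (cohort-wide; overlapping patients
#'   appear once in its patient table).
#' @param fractions Named numeric `(model, validation, test)` summing to 1.
#' @param n_folds Cross-validation folds over model-set patients
#'   (default 4).
#' @param seed Seed for the assignment.
#' @return A `split_plan`: `assignments` (data frame `patient_id`,
#'   `pathology`, `set`), `cv_folds` (named integer vector for model-set
#'   patients), `fractions`, `seed`.
#' @export
make_split_plan <- function(manifest,
                            fractions = c(model = 0.5, validation = 0.25,
                                          test = 0.25),
                            n_folds = 4L, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1", call. = FALSE)
  stopifnot(all(c("model", "validation", "test") %in% names(fractions)))
  patients <- manifest$patients
  groups <- split(patients$patient_id, patients$pathology)
  if (any(lengths(groups) < 3L))
    stop("every pathology group needs >= 3 patients to populate ",
         "model, validation and test sets", call. = FALSE)
  with_seed(seed, {
    rows <- lapply(names(groups), function(g) {
      ids <- sample(groups[[g]])
      n <- length(ids)
      n_model <- max(1L, round(fractions[["model"]] * n))
      n_val <- max(1L, round(fractions[["validation"]] * n))
      if (n_model + n_val >= n) {             # keep >= 1 test patient
        n_val <- max(1L, n - n_model - 1L)
        n_model <- n - n_val - 1L
      }
      set <- rep("test", n)
      set[seq_len(n_model)] <- "model"
      set[n_model + seq_len(n_val)] <- "validation"
      data.frame(patient_id = ids, pathology = g, set = set,
                 stringsAsFactors = FALSE)
    })
    assignments <- do.call(rbind, rows)
    model_ids <- assignments$patient_id[assignments$set == "model"]
    if (length(model_ids) < n_folds)
      stop(sprintf("only %d model-set patients for %d CV folds",
                   length(model_ids), n_folds), call. = FALSE)
    # deal folds within pathology strata so folds stay balanced
    cv <- integer(0)
    offset <- 0L
    for (g in names(groups)) {
      ids <- assignments$patient_id[assignments$set == "model" &
                                      assignments$pathology == g]
      ids <- sample(ids)
      f <- ((seq_along(ids) - 1L + offset) %% n_folds) + 1L
      offset <- (offset + length(ids)) %% n_folds
      names(f) <- ids
      cv <- c(cv, f)
    }
  })
  structure(list(assignments = assignments, cv_folds = cv,
                 fractions = fractions, n_folds = as.integer(n_folds),
                 seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("split_plan:\n")
  print(table(x$assignments$pathology, x$assignments$set))
  invisible(x)
}

#' Patients of a split plan belonging to a set
#' @param plan A `split_plan`. @param set `"model"`, `"validation"` or
#'   `"test"`.
#' @return Character vector of patient ids.
#' @export
split_patients <- function(plan, set) {
  plan$assignments$patient_id[plan$assignments$set == set]
}

# even allocation of `target` picks over TMAs with availabilities `avail`
# (named by tma id, ascending order): every TMA starts at an equal quota;
# TMAs short of it contribute everything and the deficit is re-spread
# round-robin (ascending tma id) over TMAs with spare pixels
.allocate_quota <- function(avail, target) {
  tmas <- sort(names(avail))
  avail <- as.integer(avail[tmas])
  names(avail) <- tmas
  n_tma <- length(tmas)
  target <- as.integer(target)
  base <- target %/% n_tma
  alloc <- pmin(avail, base)
  # distribute floor-rounding remainder and shortage deficits one by one,
  # round-robin over arrays that still have spare pixels
  deficit <- target - sum(alloc)
  while (deficit > 0L) {
    spare <- tmas[avail - alloc > 0]
    if (!length(spare))
      stop("not enough pixels across TMAs to fill the quota", call. = FALSE)
    take <- spare[seq_len(min(length(spare), deficit))]
    alloc[take] <- alloc[take] + 1L
    deficit <- deficit - length(take)
  }
  alloc
}

#' Class- and TMA-balanced training sample
#'
#' Restricts the metric table to model-set patients (optionally one CV
#' fold's training patients), sets the per-class target to the scarcest
#' class's availability, allocates each class's target evenly over arrays
#' (arrays lacking pixels contribute all they have and the deficit is
#' evenly topped up from the others), and samples uniformly without
#' replacement within each (class, array) cell.
#'
#' @param table A `metric_table`.
#' @param plan A `split_plan`.
#' @param seed Sampling seed.
#' @param exclude_fold Optional CV fold index whose patients are held out.
#' @return List: `rows` (the sampled `metric_table` rows), `quota` (a
#'   `sampling_quota`: `per_class_n` and the class x tma allocation matrix).
#' @export
balanced_sample <- function(table, plan, seed = 1L, exclude_fold = NULL) {
  ids <- split_patients(plan, "model")
  if (!is.null(exclude_fold)) {
    held <- names(plan$cv_folds)[plan$cv_folds == exclude_fold]
    ids <- setdiff(ids, held)
  }
  tab <- table[table$patient_id %in% ids & table$label > 0L, , drop = FALSE]
  counts <- table(factor(tab$label, levels = TISSUE_CLASSES))
  if (any(counts == 0L))
    stop("class with zero pixels in the training pool: ",
         paste(names(TISSUE_CLASSES)[counts == 0], collapse = ", "),
         call. = FALSE)
  per_class_n <- min(counts)
  tma_ids <- sort(unique(tab$tma_id))
  alloc <- matrix(0L, length(TISSUE_CLASSES), length(tma_ids),
                  dimnames = list(names(TISSUE_CLASSES), tma_ids))
  picked <- with_seed(seed, {
    rows <- list()
    for (cls in names(TISSUE_CLASSES)) {
      id <- TISSUE_CLASSES[[cls]]
      avail <- vapply(tma_ids, function(t)
        sum(tab$label == id & tab$tma_id == t), integer(1))
      names(avail) <- tma_ids
      a <- .allocate_quota(avail, per_class_n)
      alloc[cls, names(a)] <- a
      for (t in tma_ids) {
        pool <- which(tab$label == id & tab$tma_id == t)
        rows[[paste(cls, t)]] <- pool[sample.int(length(pool))[seq_len(a[[t]])]]
      }
    }
    unlist(rows, use.names = FALSE)
  })
  out <- tab[picked, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("metric_table", "data.frame")
  list(rows = out,
       quota = structure(list(per_class_n = per_class_n,
                              per_tma_allocation = alloc),
                         class = "sampling_quota"))
}

#' Serialize / load a split plan as JSON
#' @param plan A `split_plan`. @param path JSON path.
#' @return `path` (writer) or a `split_plan` (reader).
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(
    list(assignments = plan$assignments,
         cv_folds = as.list(plan$cv_folds),
         fractions = as.list(plan$fractions),
         n_folds = plan$n_folds, seed = plan$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cv <- unlist(x$cv_folds)
  structure(list(assignments = as.data.frame(x$assignments),
                 cv_folds = vapply(cv, as.integer, integer(1)),
                 fractions = unlist(x$fractions),
                 n_folds = as.integer(x$n_folds), seed = x$seed),
            class = "split_plan")
}
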