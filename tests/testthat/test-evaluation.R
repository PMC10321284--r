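# exhaustive pairwise oracle: fraction of concordant (pos > neg) pairs plus
# half the ties — the Mann-Whitney reading of the AUC
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

test_that("AUC hits its boundary values on separated and degenerate scores", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE,
                                                FALSE))$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(TRUE, TRUE, FALSE,
                                                FALSE))$auc, 0)
  # constant scores: midrank convention gives exactly 0.5
  expect_equal(roc_auc(rep(0.4, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "undefined")
})

test_that("trapezoidal ROC AUC equals the pairwise Mann-Whitney oracle", {
  # fixed hand-listed case with ties
  s <- c(0.9, 0.8, 0.8, 0.6, 0.5, 0.5, 0.3, 0.1)
  l <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(s, l)$auc, oracle_auc(s, l), tolerance = 1e-12)
  # randomized property sweep, heavy ties included
  withr::with_seed(23, {
    for (i in 1:50) {
      n <- sample(5:40, 1)
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      l <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(l) || all(l)) next
      r <- roc_auc(s, l)
      expect_equal(r$auc, oracle_auc(s, l), tolerance = 1e-12)
      # complementing the labels mirrors the AUC
      expect_equal(roc_auc(s, !l)$auc, 1 - r$auc, tolerance = 1e-12)
      # curve is monotone in both coordinates
      expect_true(all(diff(r$curve$fpr) >= 0))
      expect_true(all(diff(r$curve$tpr) >= 0))
    }
  })
})

test_that("AUC agrees with an independent package implementation", {
  withr::with_seed(29, {
    s <- c(rnorm(30, 1), rnorm(25))
    l <- rep(c(TRUE, FALSE), c(30, 25))
  })
  ours <- roc_auc(s, l)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(response = l, predictor = s,
                                           quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("entity scores count chosen-class pixels over tissue", {
  pred <- structure(list(
    class_map = matrix(c(2L, 2L, 1L, 0L), 2, 2),
    posteriors = array(0, c(2, 2, 6))), class = "prediction_image")
  fp <- matrix(TRUE, 2, 2)
  expect_equal(entity_score(pred, fp, "Cancer"), 2 / 3)
  expect_equal(entity_score(pred, fp, "Cancer", mode = "count"), 2)
  expect_equal(entity_score(pred, fp, "Blood"), 0)
  all_cancer <- structure(list(class_map = matrix(2L, 3, 3)),
                          class = "prediction_image")
  expect_equal(entity_score(all_cancer, matrix(TRUE, 3, 3), "Cancer"), 1)
  none <- structure(list(class_map = matrix(0L, 2, 2)),
                    class = "prediction_image")
  expect_true(is.na(entity_score(none, matrix(TRUE, 2, 2), "Cancer")))
})

test_that("patient scores pool cores: 30% and 50% of equal areas give 40%", {
  # two 5x5 cores for one patient on one array: 30% and 50% cancer pixels
  cm <- matrix(0L, 9, 20)
  block <- function(frac) {
    v <- rep(1L, 25); v[seq_len(round(frac * 25))] <- 2L
    matrix(v, 5, 5)
  }
  cm[3:7, 3:7] <- block(0.28)     # 7 of 25 pixels
  cm[3:7, 13:17] <- block(0.52)   # 13 of 25 pixels
  pred <- structure(list(class_map = cm), class = "prediction_image")
  man <- tma_manifest(
    data.frame(core_id = c("c1", "c2"), tma_id = "TMA1",
               patient_id = "P01", center_row = 4, center_col = c(4, 14),
               radius_px = 2.9),
    data.frame(patient_id = "P01", pathology = "cancer"))
  sc <- cohort_scores(list(TMA1 = pred), man)
  expect_equal(sort(sc$cores$score), c(7, 13) / 25)
  expect_equal(sc$patients$score, (7 + 13) / 50)
})

test_that("entity ROC separates patient groups and honors the positive group", {
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.15)
  path <- c("cancer", "cancer", "cancer", "benign", "benign",
            "inflammation")
  r <- entity_roc_auc(scores, path, "cancer")
  expect_equal(r$auc, 1)
  expect_equal(r$auc, oracle_auc(scores, path == "cancer"),
               tolerance = 1e-12)
  # inflammation-vs-benign excludes cancer entities
  r2 <- entity_roc_auc(scores, path, "inflammation")
  expect_identical(r2$n_pos + r2$n_neg, 3L)
  expect_equal(r2$auc, oracle_auc(c(0.2, 0.1, 0.15),
                                  c(FALSE, FALSE, TRUE)),
               tolerance = 1e-12)
  # all-equal scores: tie convention
  expect_equal(entity_roc_auc(rep(1, 6), path, "cancer")$auc, 0.5)
})

test_that("confusion counts masked annotated pixels only", {
  lab <- matrix(c(1L, 2L, 2L, 0L), 2, 2)
  pred <- matrix(c(1L, 2L, 5L, 3L), 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, TRUE), 2, 2)
  cm <- confusion_counts(pred, lab, mask)
  expect_identical(sum(cm), 3L)                      # label 0 ignored
  expect_identical(cm["Benign", "Benign"], 1L)
  expect_identical(cm["Cancer", "Cancer"], 1L)
  expect_identical(cm["Cancer", "Fiber"], 1L)
  # row sums = annotated counts within the mask
  expect_identical(unname(rowSums(cm)[c("Benign", "Cancer")]), c(1, 2))
  expect_identical(sum(confusion_counts(pred, lab,
                                        matrix(FALSE, 2, 2))), 0L)
  ident <- confusion_counts(lab, lab, mask)
  expect_true(all(ident[row(ident) != col(ident)] == 0))
})

test_that("the Youden point maximizes TPR minus FPR", {
  s <- c(0.9, 0.85, 0.6, 0.55, 0.3, 0.2)
  l <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  y <- youden_point(roc_auc(s, l))
  expect_equal(y[["sensitivity"]], 1)
  expect_equal(y[["specificity"]], 1)
  expect_equal(y[["youden_j"]], 1)
  # overlapping scores: J < 1 but still the max over the curve
  s2 <- c(0.9, 0.5, 0.6, 0.55, 0.52, 0.2)
  r2 <- roc_auc(s2, l)
  y2 <- youden_point(r2)
  expect_equal(y2[["youden_j"]], max(r2$curve$tpr - r2$curve$fpr))
})
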