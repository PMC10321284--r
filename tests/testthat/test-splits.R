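# brute-force quota allocator: hand-checked expected allocations frozen from
# manual arithmetic (floor split, shortfall topped up one pixel at a time
# round-robin over arrays with spare pixels, ascending id order)
test_that("balanced allocation matches hand-computed shortage cases", {
  alloc <- function(avail, target)
    irhisto:::.allocate_quota(avail, target)
  # 10 available on array A, quota 50 over 3 arrays: A gives its 10, the
  # remaining 40 split evenly over B and C
  expect_identical(alloc(c(A = 10L, B = 100L, C = 100L), 50L),
                   c(A = 10L, B = 20L, C = 20L))
  expect_identical(alloc(c(A = 5L, B = 7L, C = 100L), 30L),
                   c(A = 5L, B = 7L, C = 18L))
  expect_identical(alloc(c(A = 0L, B = 40L, C = 40L), 60L),
                   c(A = 0L, B = 30L, C = 30L))
  expect_identical(alloc(c(A = 3L, B = 50L, C = 50L, D = 4L), 41L),
                   c(A = 3L, B = 17L, C = 17L, D = 4L))
  # sufficient case: equal thirds up to integer rounding
  even <- alloc(c(A = 40L, B = 40L, C = 40L), 31L)
  expect_identical(sum(even), 31L)
  expect_true(max(even) - min(even) <= 1L)
  expect_error(alloc(c(A = 10L, B = 10L, C = 10L), 40L), "not enough")
})

make_test_manifest <- function(n_per_group = c(benign = 5, inflammation = 4,
                                               cancer = 6)) {
  pats <- data.frame(
    patient_id = sprintf("P%02d", seq_len(sum(n_per_group))),
    pathology = rep(names(n_per_group), n_per_group),
    stringsAsFactors = FALSE)
  # two arrays; first two patients sit on both (overlap)
  cores <- do.call(rbind, lapply(seq_len(nrow(pats)), function(i) {
    tmas <- if (i <= 2) c("TMA1", "TMA2") else
      if (i %% 2 == 0) "TMA1" else "TMA2"
    data.frame(core_id = sprintf("%s_C%02d", tmas, i), tma_id = tmas,
               patient_id = pats$patient_id[i],
               center_row = 10, center_col = 10, radius_px = 3,
               stringsAsFactors = FALSE)
  }))
  tma_manifest(cores, pats)
}

test_that("split plans are deterministic, exhaustive and exclusive", {
  man <- make_test_manifest()
  p1 <- make_split_plan(man, seed = 7)
  p2 <- make_split_plan(man, seed = 7)
  expect_identical(p1$assignments, p2$assignments)
  expect_identical(p1$cv_folds, p2$cv_folds)
  expect_false(identical(p1$assignments,
                         make_split_plan(man, seed = 8)$assignments))
  a <- p1$assignments
  # every patient exactly once; overlapping patients get a single assignment
  expect_setequal(a$patient_id, man$patients$patient_id)
  expect_identical(anyDuplicated(a$patient_id), 0L)
  # every pathology group present in every set
  expect_true(all(table(a$pathology, a$set) >= 1))
  # folds balanced within one patient
  f <- table(p1$cv_folds)
  expect_lte(max(f) - min(f), 1)
  expect_setequal(names(p1$cv_folds), split_patients(p1, "model"))
})

test_that("no patient ever straddles two sets across 1000 seeded draws", {
  man <- make_test_manifest()
  for (s in seq_len(1000)) {
    a <- make_split_plan(man, seed = s)$assignments
    expect_identical(anyDuplicated(a$patient_id), 0L)
    expect_identical(sort(a$patient_id),
                     sort(man$patients$patient_id))
  }
})

test_that("a pathology group too small to stratify is a configuration error", {
  man <- make_test_manifest(c(benign = 5, inflammation = 2, cancer = 6))
  expect_error(make_split_plan(man), ">= 3 patients")
  man_ok <- make_test_manifest(c(benign = 3, inflammation = 3, cancer = 3))
  expect_error(make_split_plan(man_ok, n_folds = 8), "CV folds")
})

# synthetic metric table with controllable class/TMA counts
fake_metric_table <- function(counts, patient = "P01", seed = 3) {
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n[i]
    if (n == 0) return(NULL)
    data.frame(tma_id = counts$tma_id[i], core_id = "c",
               patient_id = counts$patient_id[i] %||% patient,
               row = seq_len(n), col = 1L, label = counts$label[i],
               m1 = withr::with_seed(seed + i, rnorm(n)), m2 = 0,
               stringsAsFactors = FALSE)
  }))
  class(rows) <- c("metric_table", "data.frame")
  attr(rows, "metric_names") <- c("m1", "m2")
  rows
}

test_that("balanced sampling equalizes classes and spreads arrays evenly", {
  counts <- expand.grid(tma_id = c("TMA1", "TMA2", "TMA3"),
                        label = 1:6, stringsAsFactors = FALSE)
  counts$n <- 200L
  counts$label <- as.integer(counts$label)
  counts$n[counts$label == 6] <- c(10L, 200L, 200L)  # Blood short on TMA1
  counts$patient_id <- "P01"
  tab <- fake_metric_table(counts)
  plan <- list(assignments = data.frame(patient_id = "P01",
                                        pathology = "cancer",
                                        set = "model"),
               cv_folds = c(P01 = 1L))
  class(plan) <- "split_plan"
  res <- balanced_sample(tab, plan, seed = 5)
  drawn <- table(res$rows$label)
  # every class drawn at the scarcest class's availability (Blood: 410)
  expect_true(all(drawn == res$quota$per_class_n))
  expect_identical(res$quota$per_class_n, 410L)
  # shortage class: TMA1 contributes all 10, deficit split over the others
  expect_identical(unname(res$quota$per_tma_allocation["Blood", ]),
                   c(10L, 200L, 200L))
  # abundant classes: even thirds (410 = 136+137+137 up to rotation)
  ben <- res$quota$per_tma_allocation["Benign", ]
  expect_identical(sum(ben), 410L)
  expect_lte(max(ben) - min(ben), 1L)
  # no replacement: all drawn rows unique
  expect_identical(anyDuplicated(res$rows[, c("tma_id", "label", "row")]), 0L)
})

test_that("a class with no pixels in the training pool is a clear error", {
  counts <- expand.grid(tma_id = c("TMA1", "TMA2"), label = 1:5,
                        stringsAsFactors = FALSE)
  counts$n <- 50L
  counts$label <- as.integer(counts$label)
  counts$patient_id <- "P01"
  tab <- fake_metric_table(counts)
  plan <- list(assignments = data.frame(patient_id = "P01",
                                        pathology = "cancer", set = "model"),
               cv_folds = c(P01 = 1L))
  class(plan) <- "split_plan"
  expect_error(balanced_sample(tab, plan, seed = 1), "Blood")
})

test_that("plans serialize to JSON and back", {
  man <- make_test_manifest()
  plan <- make_split_plan(man, seed = 4)
  p <- file.path(withr::local_tempdir(), "plan.json")
  write_split_plan(plan, p)
  back <- read_split_plan(p)
  expect_identical(back$assignments$set, plan$assignments$set)
  expect_identical(back$cv_folds[names(plan$cv_folds)], plan$cv_folds)
})
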