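#' Synthetic TMA generator configuration
#'
#' Describes the statistical conditions of a synthetic tissue-microarray
#' cohort: array and core geometry, patient cohort composition, optical
#' definition and noise model. Defaults are desk-scale: 3 arrays of 6 cores
#' of radius 24 px at SD sampling (~1800 tissue pixels per core), a cohort
#' of 15 patients (benign / inflammation / cancer mix) of whom 20% appear on
#' more than one array.
#'
#' @param n_tmas Number of arrays.
#' @param cores_per_tma Cores per array.
#' @param core_radius_px Core radius in SD pixels; at HD the radius is
#'   rescaled by the pixel-size ratio so the physical core size is unchanged.
#' @param n_patients Cohort size.
#' @param pathology_mix Named fractions for benign / inflammation / cancer.
#' @param overlap_fraction Fraction of patients whose cores appear on two or
#'   more arrays.
#' @param definition_tag `"SD"` (2.7 um pixels) or `"HD"` (1.1 um pixels).
#' @param noise_sd Additive Gaussian noise standard deviation (absorbance
#'   units) at SD.
#' @param hd_noise_multiplier Factor (> 1) applied to `noise_sd` for HD
#'   cubes; HD acquisitions are noisier than SD at matched measurement time.
#' @param amplitude_jitter_cv Per-pixel multiplicative amplitude jitter CV.
#' @param paraffin_residual_amplitude Amplitude of the residual paraffin
#'   band at 1462 cm^-1 left by incomplete deparaffinization.
#' @param background_offset Flat near-zero absorbance of non-tissue pixels.
#' @param seed Master seed for all generator randomness.
#' @return A `generator_config`.
#' @export
generator_config <- function(n_tmas = 3L, cores_per_tma = 6L,
                             core_radius_px = 24L, n_patients = 15L,
                             pathology_mix = c(benign = 1 / 3,
                                               inflammation = 4 / 15,
                                               cancer = 6 / 15),
                             overlap_fraction = 0.2,
                             definition_tag = c("SD", "HD"),
                             noise_sd = 0.008, hd_noise_multiplier = 2,
                             amplitude_jitter_cv = 0.05,
                             paraffin_residual_amplitude = 0.05,
                             background_offset = 0.08,
                             seed = 1L) {
  definition_tag <- match.arg(definition_tag)
  if (hd_noise_multiplier <= 1)
    stop("hd_noise_multiplier must exceed 1 (HD is noisier than SD)",
         call. = FALSE)
  pathology_mix <- pathology_mix / sum(pathology_mix)
  if (!all(c("benign", "inflammation", "cancer") %in% names(pathology_mix)))
    stop("pathology_mix must cover benign, inflammation, cancer",
         call. = FALSE)
  n_overlap <- round(overlap_fraction * n_patients)
  slots <- n_tmas * cores_per_tma
  if (n_patients + n_overlap > slots)
    stop(sprintf(
      "cohort needs %d core slots (patients + overlap) but arrays offer %d",
      n_patients + n_overlap, slots), call. = FALSE)
  structure(list(
    n_tmas = as.integer(n_tmas), cores_per_tma = as.integer(cores_per_tma),
    core_radius_px = core_radius_px, n_patients = as.integer(n_patients),
    pathology_mix = pathology_mix, overlap_fraction = overlap_fraction,
    definition_tag = definition_tag, noise_sd = noise_sd,
    hd_noise_multiplier = hd_noise_multiplier,
    amplitude_jitter_cv = amplitude_jitter_cv,
    paraffin_residual_amplitude = paraffin_residual_amplitude,
    background_offset = background_offset,
    seed = seed), class = "generator_config")
}

# effective additive noise sigma for the configured definition
effective_noise_sd <- function(config) {
  if (config$definition_tag == "HD")
    config$noise_sd * config$hd_noise_multiplier else config$noise_sd
}

# effective core radius in pixels for the configured definition
effective_radius_px <- function(config) {
  if (config$definition_tag == "HD")
    round(config$core_radius_px * 2.7 / 1.1) else config$core_radius_px
}

# pathology-conditional Voronoi region class tables; cancer cores are
# guaranteed to contain Cancer, Fiber, Necrosis, Inflammation and Blood so
# every class is represented in any split containing a cancer patient
.region_plan <- function(pathology) {
  switch(pathology,
    benign = list(n_regions = 5L, forced = "Benign",
                  freq = c(Benign = 0.72, Fiber = 0.18, Blood = 0.10)),
    inflammation = list(n_regions = 5L,
                        forced = c("Benign", "Inflammation"),
                        freq = c(Benign = 0.40, Inflammation = 0.40,
                                 Fiber = 0.12, Blood = 0.08)),
    cancer = list(n_regions = 8L,
                  forced = c("Cancer", "Fiber", "Necrosis",
                             "Inflammation", "Blood"),
                  freq = c(Cancer = 0.50, Fiber = 0.35, Necrosis = 0.05,
                           Inflammation = 0.05, Blood = 0.05)))
}

# assign patients to pathologies and cores to (patient, tma) slots;
# exactly n_overlap patients appear on >= 2 arrays
.plan_cohort <- function(config) {
  p <- config$n_patients
  counts <- floor(config$pathology_mix * p)
  while (sum(counts) < p)
    counts[which.max(config$pathology_mix * p - counts)] <-
      counts[which.max(config$pathology_mix * p - counts)] + 1L
  if (any(counts < 1L))
    stop("pathology mix must give every group at least one patient",
         call. = FALSE)
  pathology <- sample(rep(names(counts), counts))
  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(p)),
    pathology = pathology, stringsAsFactors = FALSE)

  n_overlap <- round(config$overlap_fraction * p)
  overlap_ids <- sample(patients$patient_id, n_overlap)
  capacity <- rep(config$cores_per_tma, config$n_tmas)
  assign_tma <- function(k) {
    # k arrays with most remaining capacity, random among ties
    ord <- order(capacity + runif(length(capacity)) * 1e-3,
                 decreasing = TRUE)
    ord[seq_len(k)]
  }
  rows <- list()
  for (pid in patients$patient_id) {
    k <- if (pid %in% overlap_ids) 2L else 1L
    tmas <- assign_tma(k)
    capacity[tmas] <- capacity[tmas] - 1L
    rows[[pid]] <- data.frame(patient_id = pid, tma = tmas)
  }
  # leftover slots become extra cores on arrays the patient already occupies
  # (keeps the overlap count exact)
  assign <- do.call(rbind, rows)
  while (any(capacity > 0L)) {
    tma <- which(capacity > 0L)[1]
    here <- assign$patient_id[assign$tma == tma]
    pid <- sample(here, 1L)
    assign <- rbind(assign, data.frame(patient_id = pid, tma = tma))
    capacity[tma] <- capacity[tma] - 1L
  }
  list(patients = patients, assign = assign, overlap_ids = overlap_ids)
}

# smooth random surface ~N(0,1): coarse Gaussian grid, bilinear upsampling;
# emulates slowly varying section thickness / density across a core
.smooth_unit_field <- function(nr, nc, coarse = 5L) {
  g <- matrix(rnorm((coarse + 1L)^2), coarse + 1L, coarse + 1L)
  lerp_rows <- function(m, n_out) {
    u <- seq(0, nrow(m) - 1L, length.out = n_out)
    i0 <- pmin(floor(u), nrow(m) - 2L)
    f <- u - i0
    m[i0 + 1L, , drop = FALSE] * (1 - f) + m[i0 + 2L, , drop = FALSE] * f
  }
  field <- t(lerp_rows(t(lerp_rows(g, nr)), nc))
  s <- stats::sd(field)
  if (s > 0) field / s else field
}

# lay out cores_per_tma disk footprints on a rectangular grid
.core_layout <- function(cores_per_tma, radius) {
  grid_rows <- floor(sqrt(cores_per_tma))
  grid_cols <- ceiling(cores_per_tma / grid_rows)
  gap <- max(8, round(radius / 2))
  cell <- 2 * radius + gap
  img_rows <- grid_rows * cell + gap
  img_cols <- grid_cols * cell + gap
  centers <- expand.grid(gr = seq_len(grid_rows), gc = seq_len(grid_cols))
  centers <- centers[seq_len(cores_per_tma), , drop = FALSE]
  list(
    img_rows = img_rows, img_cols = img_cols,
    center_row = gap + (centers$gr - 1) * cell + radius,
    center_col = gap + (centers$gc - 1) * cell + radius)
}

#' Generate one synthetic TMA scene
#'
#' Lays out the requested cores on a grid, partitions every core disk into
#' contiguous class regions by a random Voronoi tessellation (class
#' frequencies conditioned on the owning patient's pathology), and renders
#' every tissue pixel's spectrum as
#' `jitter * class band sum + baseline + paraffin residual + N(0, noise_sd)`.
#' Background pixels carry a flat near-zero absorbance plus the same noise.
#'
#' @param config A `generator_config`.
#' @param class_models List of six `class_spectrum_model`s (canonical order).
#' @param axis A `spectral_axis`.
#' @param core_table Data frame with one row per core to place:
#'   `core_id`, `patient_id`; patient pathologies come from `patients`.
#' @param patients Patient table (`patient_id`, `pathology`).
#' @param tma_id Array identifier string.
#' @param seed Seed for this scene's randomness.
#' @param keep_clean Also return the noise-free cube (signal + baseline +
#'   paraffin, no additive noise) for oracle comparisons.
#' @return List with `cube` (`hyper_cube`), `labels` (`label_image`),
#'   `manifest` (`tma_manifest` for this array), and `ground_truth` (list:
#'   per-core region records, per-pixel jitter draws, and optionally
#'   `clean`, the noise-free data array).
#' @export
generate_tma <- function(config, class_models, axis, core_table, patients,
                         tma_id, seed, keep_clean = FALSE) {
  stopifnot(length(class_models) == 6L)
  stopifnot(identical(names(class_models), names(TISSUE_CLASSES)))
  radius <- effective_radius_px(config)
  noise_sd <- effective_noise_sd(config)
  lay <- .core_layout(nrow(core_table), radius)
  nr <- lay$img_rows; nc <- lay$img_cols
  nb <- length(axis$wavenumbers)
  wn <- axis$wavenumbers

  curves <- vapply(class_models, model_curve, numeric(nb), axis = axis,
                   include_baseline = FALSE)      # nb x 6, bands only
  baseline <- class_models[[1]]$baseline
  base_curve <- baseline[1] + baseline[2] * (wn - 900)
  paraffin_curve <- exp(-((wn - 1462)^2) / (2 * 10^2))

  with_seed(seed, {
    slot_order <- sample(nrow(core_table))
    labels <- matrix(0L, nr, nc)
    jitter_map <- matrix(1, nr, nc)
    paraffin_map <- matrix(0, nr, nc)
    core_rows <- list()
    gt_cores <- list()
    for (i in seq_len(nrow(core_table))) {
      s <- slot_order[i]
      cr <- lay$center_row[s]; cc <- lay$center_col[s]
      pid <- core_table$patient_id[i]
      pathology <- patients$pathology[match(pid, patients$patient_id)]
      plan <- .region_plan(pathology)
      m <- plan$n_regions
      # Voronoi seeds in the unit disk (uniform by sqrt-radius)
      th <- runif(m, 0, 2 * pi); rr <- sqrt(runif(m))
      sy <- rr * cos(th); sx <- rr * sin(th)
      cls <- sample(names(plan$freq), m, replace = TRUE, prob = plan$freq)
      cls[seq_along(plan$forced)] <- plan$forced
      # pixels of this core, in unit-disk coordinates
      rows <- pmax(1L, cr - radius + 1L):pmin(nr, cr + radius + 1L)
      cols <- pmax(1L, cc - radius + 1L):pmin(nc, cc + radius + 1L)
      ry <- (rows - 1 - cr) / radius
      rx <- (cols - 1 - cc) / radius
      dy <- matrix(ry, length(rows), length(cols))
      dx <- matrix(rep(rx, each = length(rows)), length(rows), length(cols))
      inside <- dy^2 + dx^2 <= 1
      # nearest Voronoi seed per pixel
      d2 <- sapply(seq_len(m), function(j) (dy - sy[j])^2 + (dx - sx[j])^2)
      reg <- matrix(max.col(-d2, ties.method = "first"),
                    length(rows), length(cols))
      lab_patch <- labels[rows, cols]
      lab_patch[inside] <- TISSUE_CLASSES[cls[reg[inside]]]
      labels[rows, cols] <- lab_patch
      n_in <- sum(inside)
      jp <- jitter_map[rows, cols]
      jfield <- .smooth_unit_field(length(rows), length(cols))
      jp[inside] <- pmax(0, 1 + config$amplitude_jitter_cv * jfield[inside])
      jitter_map[rows, cols] <- jp
      # residual paraffin varies core-to-core (deparaffinization efficiency),
      # constant within a core
      pp <- paraffin_map[rows, cols]
      pp[inside] <- config$paraffin_residual_amplitude * runif(1, 0.5, 1.5)
      paraffin_map[rows, cols] <- pp
      core_rows[[i]] <- data.frame(
        core_id = sprintf("%s_C%02d", tma_id, i), tma_id = tma_id,
        patient_id = pid, center_row = cr, center_col = cc,
        radius_px = radius, stringsAsFactors = FALSE)
      gt_cores[[i]] <- list(core_id = core_rows[[i]]$core_id,
                            pathology = pathology,
                            region_classes = cls)
    }
    # render spectra: clean = jitter * class curve + baseline + paraffin
    npx <- nr * nc
    clean <- matrix(rep(base_curve, each = npx), npx, nb)
    labv <- as.vector(labels)
    tissue <- labv > 0L
    clean[tissue, ] <- clean[tissue, ] +
      as.vector(jitter_map)[tissue] * t(curves)[labv[tissue], ] +
      outer(as.vector(paraffin_map)[tissue], paraffin_curve)
    data <- clean + matrix(rnorm(npx * nb, 0, noise_sd), npx, nb)
    data[data < 0] <- 0                       # absorbance is non-negative
    cube_arr <- array(data, dim = c(nr, nc, nb))
  })

  manifest <- tma_manifest(do.call(rbind, core_rows), patients)
  gt <- list(cores = gt_cores, noise_sd = noise_sd,
             jitter = jitter_map, paraffin = paraffin_map)
  if (keep_clean) gt$clean <- array(clean, dim = c(nr, nc, nb))
  list(cube = hyper_cube(cube_arr, axis,
                         definition_tag = config$definition_tag),
       labels = label_image(labels),
       manifest = manifest,
       ground_truth = gt)
}

#' Generate a multi-array synthetic TMA cohort
#'
#' Builds the patient cohort (pathology mix, cross-array overlap), assigns
#' cores to arrays, and renders each array with [generate_tma()]. Exactly
#' `round(overlap_fraction * n_patients)` patients own cores on two or more
#' arrays.
#'
#' @inheritParams generate_tma
#' @return List with `tmas` (named list of per-array scenes as returned by
#'   [generate_tma()]), `manifest` (cohort-wide `tma_manifest`), and
#'   `overlap_ids` (patients present on >= 2 arrays).
#' @export
generate_cohort <- function(config, class_models = NULL,
                            axis = build_spectral_axis(),
                            keep_clean = FALSE) {
  if (is.null(class_models))
    class_models <- default_class_models(
      axis, amplitude_jitter_cv = config$amplitude_jitter_cv)
  plan <- with_seed(child_seed(config$seed, 0), .plan_cohort(config))
  tma_ids <- sprintf("TMA%d", seq_len(config$n_tmas))
  scenes <- list()
  all_cores <- list()
  for (t in seq_len(config$n_tmas)) {
    ct <- plan$assign[plan$assign$tma == t, , drop = FALSE]
    ct$core_id <- sprintf("%s_C%02d", tma_ids[t], seq_len(nrow(ct)))
    sc <- generate_tma(config, class_models, axis,
                       core_table = ct, patients = plan$patients,
                       tma_id = tma_ids[t],
                       seed = child_seed(config$seed, t),
                       keep_clean = keep_clean)
    scenes[[tma_ids[t]]] <- sc
    all_cores[[t]] <- sc$manifest$cores
  }
  list(tmas = scenes,
       manifest = tma_manifest(do.call(rbind, all_cores), plan$patients),
       overlap_ids = plan$overlap_ids,
       class_models = class_models)
}
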