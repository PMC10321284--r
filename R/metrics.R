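#' @title Spectral metric extraction
#' @description Every spectrum is reduced to "metrics": within each curated
#'   wavenumber region a local linear baseline (the chord through the
#'   region's endpoint values) is subtracted, then the band integral
#'   (trapezoidal), the maximum value and the center of gravity
#'   (intensity-weighted mean wavenumber) are computed and each is
#'   normalized by the corresponding value of the Amide I reference region.
#'   The default table emits 41 regions, i.e. 123 metrics per spectrum.
#' @name irhisto-metrics
NULL

#' Local linear baseline removal over a segment
#'
#' Subtracts the straight line through the first and last values of the
#' segment, so the corrected endpoints are exactly zero.
#'
#' @param y Numeric segment values (length >= 2).
#' @param wn Wavenumbers of the segment points (same length).
#' @return Corrected segment.
#' @export
local_baseline_correct <- function(y, wn) {
  m <- length(y)
  if (m < 2L) stop("baseline correction needs >= 2 points", call. = FALSE)
  if (length(wn) != m) stop("y and wn lengths differ", call. = FALSE)
  slope <- (y[m] - y[1]) / (wn[m] - wn[1])
  y - (y[1] + slope * (wn - wn[1]))
}

#' Integral, maximum and center of gravity of a corrected band
#'
#' @param y Baseline-corrected segment values.
#' @param wn Segment wavenumbers (descending grids give positive areas for
#'   positive bands because absolute spacings are used).
#' @return Named numeric: `integral` (trapezoidal area), `maximum`,
#'   `cog` (Sum(wn*y)/Sum(y)); `cog` is `NA` when the segment mass is <= 0.
#' @export
band_stats <- function(y, wn) {
  m <- length(y)
  dwn <- abs(diff(wn))
  integral <- sum((y[-m] + y[-1]) / 2 * dwn)
  mass <- sum(y)
  c(integral = integral, maximum = max(y),
    cog = if (mass > 0) sum(wn * y) / mass else NA_real_)
}

# region -> inclusive axis index range; nearest axis point at each endpoint
.region_indices <- function(axis, high, low) {
  i_hi <- band_index(axis, high)
  i_lo <- band_index(axis, low)
  seq(min(i_hi, i_lo), max(i_hi, i_lo))
}

#' Metric names emitted for a region table (region-major, metric-minor)
#' @param table A `region_table`.
#' @return Character vector of `<region>_{int,max,cog}` names.
#' @export
metric_names <- function(table = default_region_table()) {
  as.vector(t(outer(table$regions$name, c("int", "max", "cog"), paste,
                    sep = "_")))
}

# vectorized metric extraction on a spectra matrix (n x bands).
# returns list(values = n x 3R matrix, rejected = logical n, cog_undefined
# = count). Rejected rows (non-positive Amide I reference) are NA-filled.
.extract_metrics_matrix <- function(spectra, axis, table) {
  n <- nrow(spectra)
  wn <- axis$wavenumbers
  region_stats <- function(high, low) {
    idx <- .region_indices(axis, high, low)
    ws <- wn[idx]
    m <- length(idx)
    sub <- spectra[, idx, drop = FALSE]
    slope <- (sub[, m] - sub[, 1]) / (ws[m] - ws[1])
    corrected <- sub - (matrix(sub[, 1], n, m) + outer(slope, ws - ws[1]))
    dwn <- abs(diff(ws))
    w_trap <- c(dwn / 2, 0) + c(0, dwn / 2)
    integral <- as.vector(corrected %*% w_trap)
    maximum <- do.call(pmax, as.data.frame(corrected))
    mass <- rowSums(corrected)
    cog <- as.vector(corrected %*% ws) / mass
    cog[mass <= 0] <- NA_real_
    list(integral = integral, maximum = maximum, cog = cog)
  }
  ref <- region_stats(table$amide1_region[1], table$amide1_region[2])
  rejected <- !(ref$integral > 0 & ref$maximum > 0 &
                  !is.na(ref$cog) & ref$cog > 0)
  nr <- nrow(table$regions)
  values <- matrix(NA_real_, n, 3L * nr)
  cog_undefined <- 0L
  for (j in seq_len(nr)) {
    st <- region_stats(table$regions$high_cm1[j], table$regions$low_cm1[j])
    cog_undefined <- cog_undefined + sum(is.na(st$cog) & !rejected)
    st$cog[is.na(st$cog)] <- 0
    values[, 3 * j - 2] <- st$integral / ref$integral
    values[, 3 * j - 1] <- st$maximum / ref$maximum
    values[, 3 * j] <- st$cog / ref$cog
  }
  colnames(values) <- metric_names(table)
  values[rejected, ] <- NA_real_
  list(values = values, rejected = rejected, cog_undefined = cog_undefined)
}

#' Extract the metric vector of a single spectrum
#'
#' @param spectrum Numeric vector, one absorbance per axis point.
#' @param axis A `spectral_axis`.
#' @param table A `region_table` (default: the 41-region table).
#' @return Named numeric vector of `3 * nrow(regions)` metrics (123 for the
#'   default table), ordered region-major with the (integral, max, cog)
#'   triple per region, each normalized by the Amide I reference value.
#'   Errors if the spectrum fails Amide I quality control (non-positive
#'   reference integral, maximum or center of gravity).
#' @export
extract_metrics <- function(spectrum, axis, table = default_region_table()) {
  if (length(spectrum) != length(axis$wavenumbers))
    stop("spectrum length != axis length", call. = FALSE)
  res <- .extract_metrics_matrix(matrix(spectrum, 1), axis, table)
  if (res$rejected[1])
    stop("spectrum rejected: non-positive Amide I reference (QC flag)",
         call. = FALSE)
  v <- res$values[1, ]
  attr(v, "cog_undefined") <- res$cog_undefined
  v
}

#' Extract a metric table from a cube
#'
#' Computes one metric vector per masked pixel and attaches class label and
#' (tma, core, patient, row, col) provenance from the label image and
#' manifest. Pixels whose Amide I reference fails quality control are
#' excluded and counted; pixels outside every core footprint get sentinel
#' `"unassigned"` provenance.
#'
#' @param cube A `hyper_cube`.
#' @param mask Logical tissue mask.
#' @param labels A `label_image` (same spatial dims as the cube).
#' @param manifest A `tma_manifest` for this cube's array.
#' @param table A `region_table`.
#' @return A `metric_table`: data frame with provenance columns `tma_id`,
#'   `core_id`, `patient_id`, `row`, `col`, `label`, followed by the metric
#'   columns. Attributes `n_rejected` and `n_cog_undefined` carry QC counts.
#' @export
extract_metrics_image <- function(cube, mask, labels, manifest,
                                  table = default_region_table()) {
  check_cube_labels(cube, labels)
  nr <- dim(cube$data)[1]; nc <- dim(cube$data)[2]
  stopifnot(identical(dim(mask), dim(labels$labels)))
  nb <- dim(cube$data)[3]
  sel <- which(mask)
  prov <- data.frame(
    tma_id = rep("unassigned", length(sel)),
    core_id = rep("unassigned", length(sel)),
    patient_id = rep("unassigned", length(sel)),
    row = (sel - 1) %% nr, col = (sel - 1) %/% nr,   # 0-based coords
    label = labels$labels[sel], stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest$cores))) {
    core <- manifest$cores[i, ]
    inside <- (prov$row - core$center_row)^2 +
      (prov$col - core$center_col)^2 <= core$radius_px^2
    prov$tma_id[inside] <- core$tma_id
    prov$core_id[inside] <- core$core_id
    prov$patient_id[inside] <- core$patient_id
  }
  spectra <- matrix(cube$data, nr * nc, nb)[sel, , drop = FALSE]
  res <- .extract_metrics_matrix(spectra, cube$axis, table)
  keep <- !res$rejected
  out <- cbind(prov[keep, , drop = FALSE],
               as.data.frame(res$values[keep, , drop = FALSE]))
  rownames(out) <- NULL
  class(out) <- c("metric_table", "data.frame")
  attr(out, "n_rejected") <- sum(res$rejected)
  attr(out, "n_cog_undefined") <- res$cog_undefined
  attr(out, "metric_names") <- metric_names(table)
  out
}

#' Write / read a metric table as CSV
#' @param table A `metric_table`. @param path CSV path.
#' @return `path` (writer) or a `metric_table` (reader).
#' @export
write_metric_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("metric_table", "data.frame")
  attr(out, "metric_names") <-
    setdiff(names(out), c("tma_id", "core_id", "patient_id",
                          "row", "col", "label"))
  out
}
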