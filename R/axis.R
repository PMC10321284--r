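#' Spectral axis for FT-IR hyperspectral cubes
#'
#' A `spectral_axis` is the ordered wavenumber grid (cm^-1) shared by every
#' spectrum of a cube. The convention throughout the package is *descending*:
#' the first point is the highest wavenumber (e.g. 3850) and the last the
#' lowest (e.g. 900), matching how FT-IR instruments report absorbance.
#'
#' @param wavenumbers Numeric vector of band positions in cm^-1, strictly
#'   monotonic descending, evenly spaced.
#' @param resolution_cm1 Nominal spectral resolution in cm^-1.
#' @param zff Zero-filling factor (positive integer).
#' @return An object of class `spectral_axis`.
#' @export
spectral_axis <- function(wavenumbers, resolution_cm1 = NA_real_, zff = 1L) {
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 2L)
    stop("spectral_axis needs at least 2 points", call. = FALSE)
  d <- diff(wavenumbers)
  if (any(d >= 0))
    stop("spectral_axis must be strictly monotonic descending", call. = FALSE)
  rel <- abs(d - d[1]) / abs(d[1])
  if (any(rel > 1e-9))
    stop("spectral_axis spacing must be uniform (rel. tol 1e-9)", call. = FALSE)
  structure(
    list(wavenumbers = wavenumbers,
         resolution_cm1 = resolution_cm1,
         zff = as.integer(zff)),
    class = "spectral_axis")
}

# point counts that reproduce the acquisition conventions of known setups;
# keyed by "high_low_resolution_zff"
.axis_point_lookup <- c("3850_900_8_2" = 765L)

#' Build a spectral axis from acquisition parameters
#'
#' Constructs the evenly spaced descending wavenumber grid for a measurement
#' range, spectral resolution and zero-filling factor. For the default
#' acquisition (3850-900 cm^-1, 8 cm^-1 resolution, zero filling 2) the axis
#' has exactly 765 points, the count produced by the reference instrument
#' configuration; other parameter combinations use
#' `n = floor((high - low) * zff / resolution) + 1`. Both endpoints are
#' included, so the spacing is `(high - low) / (n - 1)`.
#'
#' @param high_cm1 Upper end of the range in cm^-1.
#' @param low_cm1 Lower end of the range in cm^-1.
#' @param resolution_cm1 Spectral resolution in cm^-1 (> 0).
#' @param zff Zero-filling factor (integer >= 1).
#' @return A `spectral_axis` descending from `high_cm1` to `low_cm1`.
#' @examples
#' ax <- build_spectral_axis()
#' length(ax$wavenumbers)  # 765
#' @export
build_spectral_axis <- function(high_cm1 = 3850, low_cm1 = 900,
                                resolution_cm1 = 8, zff = 2L) {
  if (!is.finite(high_cm1) || !is.finite(low_cm1) || high_cm1 <= low_cm1)
    stop("need high_cm1 > low_cm1", call. = FALSE)
  if (!is.finite(resolution_cm1) || resolution_cm1 <= 0)
    stop("resolution_cm1 must be positive", call. = FALSE)
  if (zff < 1) stop("zff must be >= 1", call. = FALSE)
  key <- paste(format(c(high_cm1, low_cm1, resolution_cm1), trim = TRUE,
                      scientific = FALSE, drop0trailing = TRUE),
               collapse = "_")
  key <- paste0(key, "_", as.integer(zff))
  n <- if (key %in% names(.axis_point_lookup)) {
    .axis_point_lookup[[key]]
  } else {
    as.integer(floor((high_cm1 - low_cm1) * zff / resolution_cm1)) + 1L
  }
  spectral_axis(seq(high_cm1, low_cm1, length.out = n),
                resolution_cm1 = resolution_cm1, zff = zff)
}

#' Index of the axis point nearest a requested wavenumber
#'
#' @param axis A `spectral_axis`.
#' @param cm1 Requested wavenumber(s) in cm^-1; must lie within the axis range.
#' @return Integer index (or vector of indices) into `axis$wavenumbers`.
#' @export
band_index <- function(axis, cm1) {
  wn <- axis$wavenumbers
  lo <- min(wn); hi <- max(wn)
  if (any(cm1 < lo - 1e-9) || any(cm1 > hi + 1e-9))
    stop(sprintf("wavenumber outside axis range [%g, %g]", lo, hi),
         call. = FALSE)
  vapply(cm1, function(x) which.min(abs(wn - x)), integer(1))
}

#' @export
print.spectral_axis <- function(x, ...) {
  wn <- x$wavenumbers
  cat(sprintf("spectral_axis: %d points, %g -> %g cm^-1 (spacing %.4f)\n",
              length(wn), wn[1], wn[length(wn)], wn[1] - wn[2]))
  invisible(x)
}
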