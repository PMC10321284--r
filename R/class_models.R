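#' Class spectrum model
#'
#' Parametric model of one tissue class's mean absorbance spectrum: a sum of
#' Gaussian bands on a linear baseline, with a per-pixel multiplicative
#' amplitude jitter. Band positions follow standard IR biospectroscopy
#' assignments (Amide I ~1650, Amide II ~1545, Amide A ~3290, Amide B ~3070,
#' CH stretches 3000-2800, nucleic-acid phosphate bands ~1240/1080,
#' glycogen ~1030); amplitudes per class are a synthetic invention chosen so
#' that classes differ chiefly in the Amide A/B (3550-3000 cm^-1) and
#' DNA/RNA (1300-1000 cm^-1) regions, as real pancreatic tissue classes do.
#'
#' @param class_name Tissue class name.
#' @param bands Data frame with columns `center_cm1`, `width_cm1` (Gaussian
#'   sigma), `amplitude` (>= 0).
#' @param baseline Numeric length-2: (offset, slope per cm^-1); the baseline
#'   value at wavenumber v is `offset + slope * (v - 900)`.
#' @param amplitude_jitter_cv Coefficient of variation of the per-pixel
#'   amplitude scaling.
#' @return A `class_spectrum_model`.
#' @export
class_spectrum_model <- function(class_name, bands,
                                 baseline = c(0.08, 0),
                                 amplitude_jitter_cv = 0.05) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("center_cm1", "width_cm1", "amplitude") %in% names(bands)))
  if (any(bands$amplitude < 0)) stop("band amplitudes must be >= 0",
                                     call. = FALSE)
  if (any(bands$width_cm1 <= 0)) stop("band widths must be > 0",
                                      call. = FALSE)
  structure(list(class_name = class_name, bands = bands,
                 baseline = baseline,
                 amplitude_jitter_cv = amplitude_jitter_cv),
            class = "class_spectrum_model")
}

#' Evaluate a model's noiseless curve on an axis
#'
#' @param model A `class_spectrum_model`.
#' @param axis A `spectral_axis`.
#' @param include_baseline Add the linear baseline term (default TRUE).
#' @return Numeric vector of absorbance, one value per axis point.
#' @export
model_curve <- function(model, axis, include_baseline = TRUE) {
  wn <- axis$wavenumbers
  y <- gaussian_band_sum(wn, model$bands)
  if (include_baseline)
    y <- y + model$baseline[1] + model$baseline[2] * (wn - 900)
  y
}

# sum of Gaussian components A * exp(-(v - c)^2 / (2 s^2)) over a grid
gaussian_band_sum <- function(wn, bands) {
  y <- numeric(length(wn))
  for (i in seq_len(nrow(bands))) {
    y <- y + bands$amplitude[i] *
      exp(-((wn - bands$center_cm1[i])^2) / (2 * bands$width_cm1[i]^2))
  }
  y
}

.band_row <- function(center, width, amp)
  data.frame(center_cm1 = center, width_cm1 = width, amplitude = amp)

#' Default six-class spectrum model table
#'
#' Returns synthetic band tables for Benign, Cancer, Necrosis, Inflammation,
#' Fiber and Blood. All classes share a dominant Amide I band near 1650
#' cm^-1 (the most intense tissue band) and an Amide II band near 1545
#' cm^-1; classes are separated by their Amide A/B amplitudes, their
#' nucleic-acid phosphate bands (Cancer and Inflammation elevated), a lipid
#' ester band for Necrosis, a collagen fingerprint multiplet for Fiber and a
#' heme-dominated profile for Blood. These tables are a documented synthetic
#' stand-in: no quantitative class-mean spectra are published for the tissue
#' they emulate.
#'
#' @param axis A `spectral_axis` covering 3850-900 cm^-1.
#' @param amplitude_jitter_cv Per-pixel amplitude jitter CV for every class.
#' @return Named list of six `class_spectrum_model` objects, in canonical
#'   class order (Benign, Cancer, Necrosis, Inflammation, Fiber, Blood).
#' @export
default_class_models <- function(axis = build_spectral_axis(),
                                 amplitude_jitter_cv = 0.05) {
  wn <- axis$wavenumbers
  if (min(wn) > 1000 || max(wn) < 3550)
    stop("axis must cover the 3550-1000 cm^-1 diagnostic regions",
         call. = FALSE)
  common <- function(amideA, amideB, ch3a, ch2a, ch2s, amideII,
                     coo, po2a, co, po2s, glyc) rbind(
    .band_row(3290, 70, amideA),   # Amide A (N-H stretch)
    .band_row(3070, 25, amideB),   # Amide B
    .band_row(2958, 12, ch3a),     # CH3 asym stretch
    .band_row(2925, 14, ch2a),     # CH2 asym stretch
    .band_row(2852, 10, ch2s),     # CH2 sym stretch
    .band_row(1652, 25, 1.00),     # Amide I, dominant in every class
    .band_row(1545, 22, amideII),  # Amide II
    .band_row(1400, 15, coo),      # COO- sym stretch
    .band_row(1240, 18, po2a),     # PO2- asym (nucleic acids)
    .band_row(1160, 12, co),       # C-O stretch
    .band_row(1080, 18, po2s),     # PO2- sym (nucleic acids)
    .band_row(1030, 14, glyc))     # glycogen C-O
  tables <- list(
    Benign = common(0.30, 0.10, 0.08, 0.12, 0.07, 0.50,
                    0.14, 0.10, 0.08, 0.14, 0.26),
    Cancer = common(0.48, 0.14, 0.07, 0.10, 0.06, 0.58,
                    0.15, 0.26, 0.10, 0.34, 0.06),
    Necrosis = rbind(
      common(0.14, 0.05, 0.12, 0.18, 0.12, 0.42,
             0.10, 0.05, 0.05, 0.08, 0.05),
      .band_row(1740, 14, 0.16)),  # lipid ester C=O
    Inflammation = rbind(
      common(0.30, 0.08, 0.06, 0.09, 0.05, 0.52,
             0.13, 0.40, 0.09, 0.46, 0.06),
      .band_row(968, 10, 0.10)),   # phosphorylated residues
    Fiber = rbind(
      common(0.56, 0.16, 0.07, 0.10, 0.06, 0.62,
             0.12, 0.12, 0.06, 0.10, 0.14),
      .band_row(1338, 12, 0.18),   # collagen CH2 wag
      .band_row(1282, 12, 0.16),   # collagen amide III
      .band_row(1204, 12, 0.20)),  # collagen C-O / hydroxyproline
    Blood = rbind(
      common(0.34, 0.12, 0.05, 0.08, 0.04, 0.78,
             0.20, 0.04, 0.04, 0.05, 0.04),
      .band_row(1585, 12, 0.18),   # heme ring mode shoulder
      .band_row(1370, 12, 0.12)))  # heme symmetric mode
  mapply(function(nm, tb)
    class_spectrum_model(nm, tb, amplitude_jitter_cv = amplitude_jitter_cv),
    names(tables), tables, SIMPLIFY = FALSE)
}
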