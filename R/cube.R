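#' Hyperspectral absorbance cube
#'
#' A `hyper_cube` wraps a 3-D array (rows x cols x bands) of unitless
#' absorbance values together with its `spectral_axis` and pixel-size
#' metadata. The `definition_tag` records the optical configuration:
#' `"SD"` (15x objective, 2.7 um projected pixel) or `"HD"` (36x objective,
#' 1.1 um projected pixel).
#'
#' @param data Numeric 3-D array, rows x cols x bands.
#' @param axis `spectral_axis` whose length equals `dim(data)[3]`.
#' @param pixel_size_um Projected pixel edge in micrometres. Defaults to the
#'   conventional value for `definition_tag` (SD = 2.7, HD = 1.1).
#' @param definition_tag `"SD"` or `"HD"`.
#' @return A `hyper_cube` object.
#' @export
hyper_cube <- function(data, axis, pixel_size_um = NULL,
                       definition_tag = c("SD", "HD")) {
  definition_tag <- match.arg(definition_tag)
  if (length(dim(data)) != 3L)
    stop("cube data must be rows x cols x bands", call. = FALSE)
  if (dim(data)[3] != length(axis$wavenumbers))
    stop(sprintf("bands dimension (%d) != axis length (%d)",
                 dim(data)[3], length(axis$wavenumbers)), call. = FALSE)
  if (!all(is.finite(data)))
    stop("cube contains non-finite absorbance values", call. = FALSE)
  if (is.null(pixel_size_um))
    pixel_size_um <- if (definition_tag == "SD") 2.7 else 1.1
  structure(
    list(data = data, axis = axis, pixel_size_um = pixel_size_um,
         definition_tag = definition_tag),
    class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hyper_cube: %d x %d pixels, %d bands, %s (%g um/px)\n",
              d[1], d[2], d[3], x$definition_tag, x$pixel_size_um))
  invisible(x)
}

# canonical class ids used everywhere: 0 is background / non-tissue
TISSUE_CLASSES <- c(Benign = 1L, Cancer = 2L, Necrosis = 3L,
                    Inflammation = 4L, Fiber = 5L, Blood = 6L)

#' Default class id table (0 = Background plus the six tissue classes)
#' @return Named integer vector mapping class name to integer id.
#' @export
default_class_table <- function() {
  c(Background = 0L, TISSUE_CLASSES)
}

#' Per-pixel class annotation image
#'
#' @param labels Integer matrix (rows x cols) of class ids; 0 is background.
#' @param class_table Named integer vector mapping class name to id; every
#'   nonzero id present in `labels` must appear in it.
#' @return A `label_image` object.
#' @export
label_image <- function(labels, class_table = default_class_table()) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  ids <- setdiff(unique(as.vector(labels)), 0L)
  if (!all(ids %in% class_table))
    stop("label image contains ids absent from class_table", call. = FALSE)
  structure(list(labels = labels, class_table = class_table),
            class = "label_image")
}

#' Tissue-microarray manifest
#'
#' Records the core layout of one or more TMAs and the patient-level
#' pathology annotations. Cores are closed disks in 0-based row/col pixel
#' coordinates; a patient may own cores on several arrays.
#'
#' @param cores Data frame with columns `core_id`, `tma_id`, `patient_id`,
#'   `center_row`, `center_col`, `radius_px`.
#' @param patients Data frame with columns `patient_id`, `pathology`
#'   (one of "benign", "inflammation", "cancer").
#' @return A `tma_manifest` object.
#' @export
tma_manifest <- function(cores, patients) {
  need <- c("core_id", "tma_id", "patient_id", "center_row", "center_col",
            "radius_px")
  if (!all(need %in% names(cores)))
    stop("cores must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(c("patient_id", "pathology") %in% names(patients)))
    stop("patients must have columns patient_id, pathology", call. = FALSE)
  if (anyDuplicated(patients$patient_id))
    stop("duplicated patient_id in patients table", call. = FALSE)
  bad <- setdiff(patients$pathology, c("benign", "inflammation", "cancer"))
  if (length(bad))
    stop("unknown pathology annotation: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(cores$patient_id %in% patients$patient_id))
    stop("cores reference patient_id absent from patients table",
         call. = FALSE)
  structure(list(cores = as.data.frame(cores, stringsAsFactors = FALSE),
                 patients = as.data.frame(patients, stringsAsFactors = FALSE)),
            class = "tma_manifest")
}

#' @export
print.tma_manifest <- function(x, ...) {
  cat(sprintf("tma_manifest: %d cores on %d array(s), %d patients\n",
              nrow(x$cores), length(unique(x$cores$tma_id)),
              nrow(x$patients)))
  invisible(x)
}

#' Logical footprint mask of one core (closed disk) on an image grid
#'
#' @param core One row of a manifest `cores` table.
#' @param nrow,ncol Image dimensions.
#' @return Logical matrix, TRUE inside the disk.
#' @export
core_footprint <- function(core, nrow, ncol) {
  r <- matrix(seq_len(nrow) - 1L, nrow, ncol)
  cc <- matrix(rep(seq_len(ncol) - 1L, each = nrow), nrow, ncol)
  (r - core$center_row)^2 + (cc - core$center_col)^2 <= core$radius_px^2
}

#' Threshold a cube into a tissue mask
#'
#' Marks as tissue every pixel whose absorbance at the band nearest
#' `anchor_cm1` exceeds `threshold`. The 1650 cm^-1 Amide I band is the
#' conventional anchor because it is the most intense tissue band; with
#' `threshold = NULL` an Otsu threshold is computed on that band image, which
#' is parameter-free and separates near-zero background from tissue.
#'
#' @param cube A `hyper_cube`.
#' @param anchor_cm1 Anchor wavenumber (default 1650).
#' @param threshold Absorbance cutoff, or `NULL` for Otsu's threshold.
#' @return Logical matrix with attributes `n_pixels` (retained count) and
#'   `threshold` (the value actually used).
#' @export
tissue_mask <- function(cube, anchor_cm1 = 1650, threshold = NULL) {
  b <- band_index(cube$axis, anchor_cm1)
  img <- cube$data[, , b]
  if (is.null(threshold)) {
    rg <- range(img)
    threshold <- if (diff(rg) <= 0) rg[1] else
      EBImage::otsu(img, range = rg, levels = 256L)
  }
  mask <- img > threshold
  attr(mask, "n_pixels") <- sum(mask)
  attr(mask, "threshold") <- threshold
  mask
}
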