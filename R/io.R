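#' @title ENVI cube, label image and manifest I/O
#' @description Readers and writers for the on-disk formats used by the
#'   pipeline: cubes as ENVI header + flat binary (BSQ or BIL interleave,
#'   64-bit IEEE doubles so round-trips are exact), label images as 8-bit
#'   grayscale PNG with a JSON sidecar holding the class table, manifests as
#'   JSON.
#' @name irhisto-io
NULL

#' Write a hyperspectral cube as ENVI header + binary
#'
#' @param cube A `hyper_cube`.
#' @param path Output path of the binary file; the header is written to
#'   `<path>.hdr`.
#' @param interleave `"bsq"` (band-sequential) or `"bil"` (band-interleaved
#'   by line).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, interleave = c("bsq", "bil")) {
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = cm-1",
    sprintf("pixel size um = %.10g", cube$pixel_size_um),
    sprintf("definition tag = %s", cube$definition_tag),
    if (is.finite(cube$axis$resolution_cm1))
      sprintf("resolution cm1 = %.10g", cube$axis$resolution_cm1),
    sprintf("zero filling factor = %d", cube$axis$zff),
    sprintf("wavelength = { %s }",
            paste(sprintf("%.10f", cube$axis$wavenumbers), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  # data array is rows x cols x bands; ENVI expects pixels row-major
  x <- aperm(cube$data, c(2, 1, 3))           # cols x rows x bands
  values <- if (interleave == "bsq") {
    as.vector(x)                              # band, then line, then sample
  } else {
    as.vector(aperm(x, c(1, 3, 2)))           # line, then band, then sample
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(values, con, size = 8, endian = "little")
  invisible(path)
}

.parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  txt <- paste(txt, collapse = "\n")
  # re-join brace-delimited multi-line values
  fields <- list()
  pat <- gregexpr("([a-zA-Z][a-zA-Z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                  txt, perl = TRUE)
  m <- regmatches(txt, pat)[[1]]
  for (kv in m) {
    eq <- regexpr("=", kv, fixed = TRUE)
    key <- tolower(trimws(substr(kv, 1, eq - 1)))
    val <- trimws(substr(kv, eq + 1, nchar(kv)))
    fields[[key]] <- val
  }
  fields
}

.require_hdr_field <- function(fields, key, path) {
  if (is.null(fields[[key]]))
    stop(sprintf("malformed ENVI header %s: missing field '%s'", path, key),
         call. = FALSE)
  fields[[key]]
}

#' Read a hyperspectral cube from ENVI header + binary
#'
#' @param path Path of the binary file (header expected at `<path>.hdr`).
#' @return A `hyper_cube`.
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path,
                                   call. = FALSE)
  if (!file.exists(path)) stop("missing ENVI binary: ", path, call. = FALSE)
  f <- .parse_envi_header(hdr_path)
  samples <- as.integer(.require_hdr_field(f, "samples", hdr_path))
  lines   <- as.integer(.require_hdr_field(f, "lines", hdr_path))
  bands   <- as.integer(.require_hdr_field(f, "bands", hdr_path))
  dtype   <- as.integer(.require_hdr_field(f, "data type", hdr_path))
  il      <- tolower(.require_hdr_field(f, "interleave", hdr_path))
  if (!dtype %in% c(4L, 5L))
    stop(sprintf("malformed ENVI header %s: unsupported data type %d",
                 hdr_path, dtype), call. = FALSE)
  if (!il %in% c("bsq", "bil"))
    stop(sprintf("malformed ENVI header %s: unsupported interleave '%s'",
                 hdr_path, il), call. = FALSE)
  wl_raw <- .require_hdr_field(f, "wavelength", hdr_path)
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1]])
  if (length(wl) != bands)
    stop(sprintf(
      "malformed ENVI header %s: field 'wavelength' has %d values, bands = %d",
      hdr_path, length(wl), bands), call. = FALSE)
  size <- if (dtype == 5L) 8L else 4L
  n <- samples * lines * bands
  con <- file(path, "rb")
  on.exit(close(con))
  values <- readBin(con, "double", n = n, size = size, endian = "little")
  if (length(values) != n)
    stop(sprintf("ENVI binary %s: expected %d values, found %d",
                 path, n, length(values)), call. = FALSE)
  x <- if (il == "bsq") {
    array(values, dim = c(samples, lines, bands))
  } else {
    aperm(array(values, dim = c(samples, bands, lines)), c(1, 3, 2))
  }
  axis <- spectral_axis(
    wl,
    resolution_cm1 = if (!is.null(f[["resolution cm1"]]))
      as.numeric(f[["resolution cm1"]]) else NA_real_,
    zff = if (!is.null(f[["zero filling factor"]]))
      as.integer(f[["zero filling factor"]]) else 1L)
  hyper_cube(aperm(x, c(2, 1, 3)), axis,
             pixel_size_um = if (!is.null(f[["pixel size um"]]))
               as.numeric(f[["pixel size um"]]) else NULL,
             definition_tag = if (!is.null(f[["definition tag"]]))
               f[["definition tag"]] else "SD")
}

#' Write / read a label image (8-bit grayscale PNG + JSON class table)
#'
#' @param lab A `label_image` (ids must fit 0..255).
#' @param path PNG output path; the class table goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(lab, path) {
  if (max(lab$labels) > 255L)
    stop("label ids exceed 8-bit PNG range", call. = FALSE)
  png::writePNG(lab$labels / 255, path)
  jsonlite::write_json(as.list(lab$class_table), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  labels <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  ct_path <- paste0(path, ".json")
  ct <- if (file.exists(ct_path)) {
    unlist(jsonlite::read_json(ct_path, simplifyVector = TRUE))
  } else default_class_table()
  label_image(labels, class_table = vapply(ct, as.integer, integer(1)))
}

#' Write / read a TMA manifest as JSON
#'
#' @param manifest A `tma_manifest`.
#' @param path JSON output path.
#' @return `path` (writer) or a `tma_manifest` (reader).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(
    list(cores = manifest$cores, patients = manifest$patients),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$cores) || is.null(x$patients))
    stop("malformed manifest JSON ", path,
         ": needs 'cores' and 'patients' fields", call. = FALSE)
  tma_manifest(x$cores, x$patients)
}

#' Check that a cube and a label image describe the same scene
#' @param cube A `hyper_cube`. @param lab A `label_image`.
#' @return TRUE invisibly; errors on mismatch naming the offending field.
#' @export
check_cube_labels <- function(cube, lab) {
  dc <- dim(cube$data); dl <- dim(lab$labels)
  if (dc[1] != dl[1] || dc[2] != dl[2])
    stop(sprintf(
      "dimension mismatch: cube %dx%d vs labels %dx%d (field: spatial dims)",
      dc[1], dc[2], dl[1], dl[2]), call. = FALSE)
  invisible(TRUE)
}
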