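#' Spectral region table for metric extraction
#'
#' @param regions Data frame with columns `name`, `high_cm1`, `low_cm1`
#'   (high > low), one row per emitted region.
#' @param amide1_region Length-2 numeric `(high, low)` of the Amide I
#'   reference region; its metrics normalize every emitted region and are
#'   not emitted themselves.
#' @return A `region_table`.
#' @export
region_table <- function(regions, amide1_region = c(1700, 1600)) {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "high_cm1", "low_cm1") %in% names(regions)))
  if (any(regions$high_cm1 <= regions$low_cm1))
    stop("every region needs high_cm1 > low_cm1", call. = FALSE)
  if (anyDuplicated(regions$name))
    stop("region names must be unique", call. = FALSE)
  if (amide1_region[1] <= amide1_region[2])
    stop("amide1_region needs high > low", call. = FALSE)
  structure(list(regions = regions, amide1_region = amide1_region),
            class = "region_table")
}

#' @export
print.region_table <- function(x, ...) {
  cat(sprintf(
    "region_table: %d emitted regions (%d metrics), Amide I ref %g-%g\n",
    nrow(x$regions), 3 * nrow(x$regions),
    x$amide1_region[1], x$amide1_region[2]))
  invisible(x)
}

#' Default 41-region table (123 metrics)
#'
#' A reconstruction of a spectroscopist-curated band list tiling the
#' standard IR biomarker windows: Amide A/B and their envelope
#' (3550-3000 cm^-1), CH stretches (3000-2800), the ester carbonyl, Amide II
#' sub-bands, and the fingerprint region 1450-910 including the DNA/RNA
#' phosphate windows (1300-1000). The paraffin-contaminated window around
#' 1462 cm^-1 is deliberately not covered. Amide I (1700-1600) is the
#' normalization reference and is not emitted, so the table yields
#' 41 regions x 3 metrics = 123 features per spectrum. The exact curated
#' list used with real instruments is not published; any user-supplied
#' table is accepted wherever this default is.
#'
#' @return A `region_table` with exactly 41 emitted regions.
#' @export
default_region_table <- function() {
  r <- function(name, high, low)
    data.frame(name = name, high_cm1 = high, low_cm1 = low,
               stringsAsFactors = FALSE)
  regions <- rbind(
    r("oh_nh_3550_3420", 3550, 3420),
    r("amideA_3420_3300", 3420, 3300),
    r("amideA_3300_3200", 3300, 3200),
    r("amideA_3200_3100", 3200, 3100),
    r("amideB_3100_3040", 3100, 3040),
    r("amideB_3040_3000", 3040, 3000),
    r("amideAB_full_3550_3000", 3550, 3000),
    r("ch3_asym_3000_2950", 3000, 2950),
    r("ch2_asym_2950_2900", 2950, 2900),
    r("ch_2900_2870", 2900, 2870),
    r("ch3_sym_2870_2840", 2870, 2840),
    r("ch2_sym_2840_2800", 2840, 2800),
    r("ch_full_3000_2800", 3000, 2800),
    r("ester_1780_1710", 1780, 1710),
    r("amideII_1600_1560", 1600, 1560),
    r("amideII_1560_1530", 1560, 1530),
    r("amideII_1530_1480", 1530, 1480),
    r("amideII_full_1600_1480", 1600, 1480),
    r("heme_1600_1570", 1600, 1570),
    r("ch3_def_1450_1420", 1450, 1420),
    r("coo_1420_1390", 1420, 1390),
    r("ch_bend_1390_1360", 1390, 1360),
    r("collagen_1360_1330", 1360, 1330),
    r("collagen_1330_1300", 1330, 1300),
    r("nucleic_1300_1270", 1300, 1270),
    r("amideIII_1270_1240", 1270, 1240),
    r("po2_asym_1240_1210", 1240, 1210),
    r("amideIII_1210_1180", 1210, 1180),
    r("co_1180_1150", 1180, 1150),
    r("co_1150_1120", 1150, 1120),
    r("co_1120_1090", 1120, 1090),
    r("po2_sym_1090_1060", 1090, 1060),
    r("carb_1060_1030", 1060, 1030),
    r("glycogen_1030_1000", 1030, 1000),
    r("carb_1000_970", 1000, 970),
    r("phos_970_940", 970, 940),
    r("ring_940_910", 940, 910),
    r("dna_rna_full_1300_1000", 1300, 1000),
    r("fingerprint_1440_1350", 1440, 1350),
    r("phos_full_1270_1180", 1270, 1180),
    r("carb_full_1060_970", 1060, 970))
  region_table(regions, amide1_region = c(1700, 1600))
}
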