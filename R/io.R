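#' Write a synthetic cell as a multi-page TIFF plus a JSON truth sidecar
#'
#' Page 1 holds the fluorescence image scaled to `[0, 1]` by the geometry's
#' bit depth (32-bit float samples); pages 2-4 hold the truth masks
#' (chromosome plate, whole cell, background) and page 5 the emulated
#' hand-drawn plate ROI, all as 0/1. The sidecar (`<prefix>.json`) records
#' the ground truth: true CER, expression, plate flag, seed, bit depth and
#' the generating profile name.
#'
#' @param cell A [generate_cell_image()] result.
#' @param prefix Output path prefix; writes `<prefix>.tif` and
#'   `<prefix>.json`.
#' @return Invisibly, the two paths written.
#' @export
write_synthetic_cell <- function(cell, prefix) {
  stopifnot(inherits(cell, "synthetic_cell"))
  tif <- paste0(prefix, ".tif"); js <- paste0(prefix, ".json")
  pages <- list(cell$fluor_image / cell$geometry$bit_depth,
                cell$chrom_mask_truth * 1,
                cell$cell_mask_truth * 1,
                cell$background_mask * 1,
                cell$chrom_roi * 1)
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(construct = cell$profile$name,
         true_cer = cell$true_cer,
         expression = cell$expression,
         plate_defined = cell$plate_defined,
         seed = cell$seed,
         bit_depth = cell$geometry$bit_depth,
         background_level = cell$geometry$background_level),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, js))
}

#' Read a synthetic cell written by [write_synthetic_cell()]
#'
#' @param prefix Path prefix used at write time.
#' @return A list shaped like a `synthetic_cell` (image rescaled back to
#'   intensity units, masks logical, truth metadata from the sidecar).
#'   Images round-trip through 32-bit float samples, so intensities agree
#'   with the generated cell to single precision.
#' @export
read_synthetic_cell <- function(prefix) {
  tif <- paste0(prefix, ".tif"); js <- paste0(prefix, ".json")
  pages <- tiff::readTIFF(tif, all = TRUE)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  structure(
    list(fluor_image = pages[[1]] * meta$bit_depth,
         chrom_mask_truth = pages[[2]] > 0.5,
         cell_mask_truth = pages[[3]] > 0.5,
         background_mask = pages[[4]] > 0.5,
         chrom_roi = pages[[5]] > 0.5,
         true_cer = meta$true_cer,
         expression = meta$expression,
         plate_defined = meta$plate_defined,
         seed = meta$seed,
         construct = meta$construct),
    class = "synthetic_cell_file")
}

#' Write a cohort manifest CSV
#'
#' One row per cell: `cell_id`, `construct`, `seed`, `true_cer`,
#' `expression`, `plate_defined`, and (if the cells were written to disk)
#' the TIFF path.
#'
#' @param cohort A [generate_cohort()] result.
#' @param path Output CSV path.
#' @param tiff_paths Optional character vector of per-cell TIFF paths.
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort_manifest <- function(cohort, path, tiff_paths = NA_character_) {
  df <- data.frame(
    cell_id = vapply(cohort, function(cl) sprintf("%s_seed%d",
                                                  cl$profile$name, cl$seed),
                     character(1)),
    construct = vapply(cohort, function(cl) cl$profile$name, character(1)),
    seed = vapply(cohort, `[[`, integer(1), "seed"),
    true_cer = vapply(cohort, `[[`, numeric(1), "true_cer"),
    expression = vapply(cohort, `[[`, numeric(1), "expression"),
    plate_defined = vapply(cohort, `[[`, logical(1), "plate_defined"),
    tiff = tiff_paths)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
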