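#' Localization profile of a reporter construct
#'
#' Describes where a construct concentrates in a metaphase cell as
#' dimensionless multipliers of the free cytoplasmic concentration, plus the
#' distribution of per-cell expression level. A multiplier of 1 means the
#' compartment holds reporter at the cytoplasmic concentration; the metaphase
#' plate multiplier above 1 models chromosome binding, below 1 exclusion from
#' the chromatin volume.
#'
#' @param name Construct label, e.g. `"WT_1-433"`.
#' @param chrom_enrich Concentration multiplier on the metaphase plate
#'   (>= 0).
#' @param spindle_enrich Multiplier in the spindle region (>= 0).
#' @param centrosome_enrich Peak multiplier at the two centrosome foci
#'   (>= 0).
#' @param expression_mean Mean per-cell reporter concentration, arbitrary
#'   intensity units (> 0).
#' @param expression_cv Coefficient of variation of per-cell expression
#'   (>= 0). The default 0.9 reproduces the broad over/under-expression
#'   spread of transient transfection and is calibrated, together with the
#'   default ill-defined-plate probability, so that 20-30% of cells in a
#'   cohort fall in the cannot-call category.
#'
#' @return An object of class `localization_profile`.
#' @seealso [calibrate_profile()] to solve `chrom_enrich` for a target CER.
#' @export
localization_profile <- function(name,
                                 chrom_enrich = 1,
                                 spindle_enrich = 1,
                                 centrosome_enrich = 1,
                                 expression_mean = 200,
                                 expression_cv = 0.9) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in c(chrom_enrich, spindle_enrich, centrosome_enrich,
              expression_mean, expression_cv)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("profile parameters must be finite, non-negative scalars")
    }
  }
  if (expression_mean <= 0) stop("expression_mean must be > 0")
  structure(
    list(name = name,
         chrom_enrich = chrom_enrich,
         spindle_enrich = spindle_enrich,
         centrosome_enrich = centrosome_enrich,
         expression_mean = expression_mean,
         expression_cv = expression_cv),
    class = "localization_profile")
}

#' Geometry of the synthetic metaphase cell
#'
#' Dimensions are in binned pixels at the scale of a 40X objective with a
#' 2x2-binned CCD (about 0.32 um per pixel), so the default 40 x 36 px cell
#' semi-axes correspond to a rounded mitotic cell of roughly 25 um diameter
#' and the 7 x 22 px plate to a metaphase plate about 4.5 x 14 um. The cell is
#' modelled as a dome: projected thickness t(x, y) = (1 - r^2)^thickness_power
#' over the elliptical footprint (r is the normalized elliptical radius), so
#' the metaphase plate sits in the thickest part of the cell and a uniformly
#' distributed fluorophore still reads CER > 1.
#'
#' @param image_shape Image size in pixels, `c(rows, cols)`.
#' @param cell_axes Semi-axes of the elliptical cell footprint,
#'   `c(row, col)` pixels.
#' @param plate_axes Semi-axes of the central metaphase-plate ellipse,
#'   `c(row, col)` pixels; the plate is tall (rows) and narrow (cols),
#'   perpendicular to the spindle axis which runs along columns.
#' @param thickness_power Exponent of the dome thickness profile (>= 0);
#'   0 gives a flat cell, 0.5 the projected thickness of a hemisphere.
#' @param background_level Camera offset, intensity units.
#' @param bit_depth Maximum representable intensity (default 12-bit, 4095).
#'
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(image_shape = c(128L, 128L),
                          cell_axes = c(36, 40),
                          plate_axes = c(22, 7),
                          thickness_power = 0.5,
                          background_level = 20,
                          bit_depth = 4095) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8),
            length(cell_axes) == 2L, all(cell_axes > 0),
            length(plate_axes) == 2L, all(plate_axes > 0),
            is.numeric(thickness_power), thickness_power >= 0,
            background_level >= 0, bit_depth > background_level)
  if (any(plate_axes >= cell_axes)) {
    stop("plate ellipse must lie strictly inside the cell ellipse")
  }
  if (any(image_shape / 2 - cell_axes < 10)) {
    stop("image must contain the cell plus a background margin of >= 10 px")
  }
  structure(
    list(image_shape = as.integer(image_shape),
         cell_axes = as.numeric(cell_axes),
         plate_axes = as.numeric(plate_axes),
         thickness_power = thickness_power,
         background_level = background_level,
         bit_depth = bit_depth),
    class = "cell_geometry")
}

#' Camera noise model
#'
#' Poisson shot noise on the expected photon count plus Gaussian read noise.
#' `photon_scale = Inf` together with `read_sd = 0` turns noise off and makes
#' the generator deterministic. Defaults describe a cooled interline CCD at
#' moderate gain: 4.6 photons per intensity unit (ADU) and a read noise of
#' 0.8 ADU (about 3.7 electrons). Read noise sets the 12-SD segmentation
#' threshold (background + 12 * read_sd), and the default keeps that
#' threshold far below the mean signal of the dimmest cell admitted by the
#' 50-500 QC window, which is what keeps the CER estimator calibrated at the
#' dim end of the window.
#'
#' @param photon_scale Expected photons per intensity unit (> 0, may be
#'   `Inf`).
#' @param read_sd Gaussian read-noise standard deviation, intensity units
#'   (>= 0).
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photon_scale = 4.6, read_sd = 0.8) {
  stopifnot(is.numeric(photon_scale), photon_scale > 0,
            is.numeric(read_sd), read_sd >= 0)
  structure(list(photon_scale = photon_scale, read_sd = read_sd),
            class = "noise_model")
}

#' Noise-free camera model
#'
#' Convenience constructor for the deterministic limit of [noise_model()].
#' @return A `noise_model` with infinite photon scale and zero read noise.
#' @export
no_noise <- function() noise_model(photon_scale = Inf, read_sd = 0)

# Per-pixel fields shared by the generator and the calibration algebra:
# thickness map, compartment masks and the enrichment-multiplier map.
# Returned multiplier excludes the plate override so calibration can treat
# chrom_enrich as the free variable.
compartment_fields <- function(profile, geometry) {
  nr <- geometry$image_shape[1]; nc <- geometry$image_shape[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  y <- matrix(seq_len(nr), nr, nc)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r2_cell <- ((y - cy) / geometry$cell_axes[1])^2 +
    ((x - cx) / geometry$cell_axes[2])^2
  r2_plate <- ((y - cy) / geometry$plate_axes[1])^2 +
    ((x - cx) / geometry$plate_axes[2])^2
  cell <- r2_cell < 1
  plate <- r2_plate < 1
  thickness <- matrix(0, nr, nc)
  thickness[cell] <- (1 - r2_cell[cell])^geometry$thickness_power

  # Spindle: barrel-shaped region spanning pole to pole along columns.
  spindle_axes <- c(0.45 * geometry$cell_axes[1], 0.80 * geometry$cell_axes[2])
  r2_spindle <- ((y - cy) / spindle_axes[1])^2 + ((x - cx) / spindle_axes[2])^2
  spindle <- r2_spindle < 1 & cell

  # Two centrosome foci at the spindle poles (Gaussian bumps, sigma 3 px).
  pole_dx <- 0.80 * geometry$cell_axes[2]
  sigma <- 3
  foci <- exp(-(((y - cy)^2 + (x - (cx - pole_dx))^2)) / (2 * sigma^2)) +
    exp(-(((y - cy)^2 + (x - (cx + pole_dx))^2)) / (2 * sigma^2))

  mult <- matrix(1, nr, nc)
  mult[spindle] <- profile$spindle_enrich
  mult <- mult + (profile$centrosome_enrich - 1) * foci
  mult[!cell] <- 0

  background <- r2_cell >= 1.44  # guard ring of ~20% of the cell radius

  list(thickness = thickness, mult_noplate = mult,
       cell = cell, plate = plate, spindle = spindle,
       background = background, r2_cell = r2_cell)
}

#' Solve the plate enrichment that yields a target ground-truth CER
#'
#' The noise-free CER of a synthetic cell is an analytic function of the
#' profile and geometry:
#' \deqn{CER(k) = \frac{k\,\bar t_{plate}}{\frac{1}{N_{cell}}(k S_{plate} + C)}}
#' where \eqn{k} is the plate multiplier, \eqn{S_{plate} = \sum_{plate} t},
#' \eqn{\bar t_{plate} = S_{plate}/N_{plate}} and \eqn{C = \sum_{cell
#' \setminus plate} t \cdot m} collects the spindle/centrosome/cytoplasm
#' contributions. This is inverted in closed form, so a profile can be
#' calibrated to any attainable target (the supremum as \eqn{k \to \infty} is
#' \eqn{N_{cell}\bar t_{plate}/S_{plate}}, about 9 for the default geometry).
#'
#' @param target_cer Desired noise-free ground-truth CER (> 0).
#' @param profile A [localization_profile()] whose spindle/centrosome/
#'   expression settings are kept; its `chrom_enrich` is replaced.
#' @param geometry A [cell_geometry()].
#' @return The input profile with `chrom_enrich` set so that the noise-free
#'   ground-truth CER equals `target_cer`.
#' @export
calibrate_profile <- function(target_cer, profile, geometry = cell_geometry()) {
  stopifnot(is.numeric(target_cer), target_cer > 0)
  f <- compartment_fields(profile, geometry)
  n_cell <- sum(f$cell)
  n_plate <- sum(f$plate)
  s_plate <- sum(f$thickness[f$plate])
  tbar_plate <- s_plate / n_plate
  off_plate <- f$cell & !f$plate
  C <- sum(f$thickness[off_plate] * f$mult_noplate[off_plate])
  denom <- n_cell * tbar_plate - target_cer * s_plate
  if (denom <= 0) {
    stop(sprintf("target CER %.3f exceeds the geometric maximum %.3f",
                 target_cer, n_cell * tbar_plate / s_plate))
  }
  k <- target_cer * C / denom
  profile$chrom_enrich <- k
  profile
}

#' Load a calibrated construct catalogue
#'
#' Reads a YAML catalogue of named localization profiles. Each entry gives a
#' `target_cer` (the mean CER the construct should show on noise-free
#' synthetic cells) plus optional spindle/centrosome multipliers and
#' expression settings; `chrom_enrich` is calibrated against `geometry` with
#' [calibrate_profile()]. The catalogue shipped in
#' `system.file("extdata", "constructs.yaml", package = "cerquant")` encodes
#' the published construct panel (full-length reporter fusion, free GFP, and
#' the N-terminal truncation/mutation series) via their reported mean CERs.
#'
#' @param path Path to the YAML catalogue (default: the shipped catalogue).
#' @param geometry A [cell_geometry()] used for calibration.
#' @return Named list of calibrated `localization_profile` objects.
#' @export
load_construct_catalogue <- function(path = system.file("extdata", "constructs.yaml",
                                                        package = "cerquant"),
                                     geometry = cell_geometry()) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$constructs)) stop("catalogue has no 'constructs' key")
  profs <- lapply(spec$constructs, function(cs) {
    p <- localization_profile(
      name = cs$name,
      spindle_enrich = cs$spindle_enrich %||% 1,
      centrosome_enrich = cs$centrosome_enrich %||% 1,
      expression_mean = cs$expression_mean %||% 200,
      expression_cv = cs$expression_cv %||% 0.9)
    calibrate_profile(cs$target_cer, p, geometry)
  })
  names(profs) <- vapply(profs, `[[`, character(1), "name")
  profs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
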