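#' Generate one synthetic metaphase-cell image with ground truth
#'
#' Builds the noise-free expected image
#' \deqn{E(x,y) = b + t(x,y)\, m(x,y)\, A,}
#' where \eqn{b} is the camera offset, \eqn{t} the dome thickness profile,
#' \eqn{m} the compartment enrichment multiplier (plate / spindle /
#' centrosomes / cytoplasm) and \eqn{A} the cell's expression level, then
#' applies Poisson shot noise and Gaussian read noise. Ground truth
#' (compartment masks and the analytic CER of the expected image) is carried
#' along, as is an emulated hand-drawn plate ROI: the truth plate ellipse
#' shrunk by a seeded 0-2 px erosion, mimicking an operator conservatively
#' tracing inside the chromosome mass seen in the DIC channel.
#'
#' @param profile A [localization_profile()].
#' @param geometry A [cell_geometry()].
#' @param noise A [noise_model()]; use [no_noise()] for the deterministic
#'   limit.
#' @param seed Integer RNG seed; the cell is fully reproducible given the
#'   same arguments and seed.
#' @param expression Per-cell expression level; defaults to
#'   `profile$expression_mean`. [generate_cohort()] passes lognormal draws.
#' @param plate_defined Logical flag recorded in the truth metadata: whether
#'   the metaphase plate would be judged well-defined in the DIC channel.
#'
#' @return An object of class `synthetic_cell`: list with `fluor_image`,
#'   `chrom_mask_truth`, `cell_mask_truth`, `background_mask`, `chrom_roi`,
#'   `true_cer`, `expression`, `plate_defined`, `seed`, and the generating
#'   `profile`/`geometry`/`noise`.
#' @export
generate_cell_image <- function(profile, geometry = cell_geometry(),
                                noise = noise_model(), seed = 1L,
                                expression = profile$expression_mean,
                                plate_defined = TRUE) {
  stopifnot(inherits(profile, "localization_profile"),
            inherits(geometry, "cell_geometry"),
            inherits(noise, "noise_model"),
            is.numeric(expression), expression > 0)
  f <- compartment_fields(profile, geometry)
  mult <- f$mult_noplate
  mult[f$plate] <- profile$chrom_enrich

  expected <- geometry$background_level + f$thickness * mult * expression
  if (max(expected) > geometry$bit_depth) {
    stop(sprintf(
      "saturation: expected intensity %.1f exceeds bit depth %d; lower the expression or enrichment",
      max(expected), geometry$bit_depth))
  }

  bg <- geometry$background_level
  true_cer <- (mean(expected[f$plate]) - bg) / (mean(expected[f$cell]) - bg)

  set.seed(seed)
  # Hand-ROI emulation: erode the truth plate ellipse by 0-2 px.
  erosion <- sample(0:2, 1L)
  roi_axes <- pmax(geometry$plate_axes - erosion, 1)
  nr <- geometry$image_shape[1]; nc <- geometry$image_shape[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  y <- matrix(seq_len(nr), nr, nc)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  chrom_roi <- ((y - cy) / roi_axes[1])^2 + ((x - cx) / roi_axes[2])^2 < 1

  img <- expected
  if (is.finite(noise$photon_scale)) {
    signal <- expected - bg
    img <- bg + rpois(length(signal), noise$photon_scale * signal) /
      noise$photon_scale
    dim(img) <- dim(expected)
  }
  if (noise$read_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, noise$read_sd), nrow(img))
  }
  img[img < 0] <- 0  # the camera reports non-negative counts

  structure(
    list(fluor_image = img,
         chrom_mask_truth = f$plate,
         cell_mask_truth = f$cell,
         background_mask = f$background,
         chrom_roi = chrom_roi,
         true_cer = true_cer,
         expression = expression,
         plate_defined = isTRUE(plate_defined),
         seed = as.integer(seed),
         profile = profile, geometry = geometry, noise = noise),
    class = "synthetic_cell")
}

#' @export
print.synthetic_cell <- function(x, ...) {
  cat(sprintf("synthetic metaphase cell [%s], %d x %d px\n",
              x$profile$name, nrow(x$fluor_image), ncol(x$fluor_image)))
  cat(sprintf("  expression %.1f, true CER %.4f, plate %s, seed %d\n",
              x$expression, x$true_cer,
              if (x$plate_defined) "defined" else "ill-defined", x$seed))
  invisible(x)
}

#' Generate a cohort of synthetic cells for one construct
#'
#' Draws independent per-cell expression levels from a lognormal with mean
#' `profile$expression_mean` and CV `profile$expression_cv` (a flat 100%-
#' efficiency stand-in for the spread of transient transfection), flags a
#' fraction of cells as lacking a well-defined metaphase plate, and generates
#' each cell with its own child seed. Expression draws are truncated at the
#' level where the brightest compartment would reach the camera bit depth
#' (with 10% noise headroom); the truncation point lies far above the
#' overexpression QC cut, so the cannot-call calibration is unaffected.
#'
#' @inheritParams generate_cell_image
#' @param n Number of cells (>= 1). Published cohorts used at least 8 cells
#'   per construct.
#' @param prob_ill_defined Probability that a cell's metaphase plate is
#'   flagged ill-defined (a human DIC judgment the generator draws as a
#'   Bernoulli truth flag). The default 0.18, with the default expression CV,
#'   yields the reported 20-30% cannot-call rate.
#' @return List of `n` [generate_cell_image()] results (class
#'   `synthetic_cohort`).
#' @export
generate_cohort <- function(profile, n, geometry = cell_geometry(),
                            noise = noise_model(), seed = 1L,
                            prob_ill_defined = 0.18) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be an integer >= 1")
  }
  n <- as.integer(n)
  set.seed(seed)
  cv <- profile$expression_cv
  if (cv > 0) {
    sdlog <- sqrt(log1p(cv^2))
    meanlog <- log(profile$expression_mean) - sdlog^2 / 2
    expr <- rlnorm(n, meanlog, sdlog)
  } else {
    expr <- rep(profile$expression_mean, n)
  }
  f <- compartment_fields(profile, geometry)
  mult <- f$mult_noplate
  mult[f$plate] <- profile$chrom_enrich
  peak <- max(f$thickness * mult)
  expr_max <- 0.9 * (geometry$bit_depth - geometry$background_level) / peak
  expr <- pmin(expr, expr_max)
  ill <- rbinom(n, 1L, prob_ill_defined) == 1L
  child_seeds <- sample.int(.Machine$integer.max, n)
  cells <- lapply(seq_len(n), function(i) {
    generate_cell_image(profile, geometry, noise, seed = child_seeds[i],
                        expression = expr[i], plate_defined = !ill[i])
  })
  structure(cells, class = c("synthetic_cohort", "list"))
}

#' Blot ground truth for one protein
#'
#' Parameters of the linear mixing model behind synthetic fractionation
#' densitometry: a protein with true chromosome-associated proportion `T`
#' fractionates into a chromosome pellet that also captures a proportion `c`
#' of the cytoplasmic material, so the observed chromosome band is
#' `total * (T + c (1 - T))` and the cytoplasmic band the remainder.
#'
#' @param true_fraction True chromosome-associated proportion, in `[0, 1]`.
#' @param contamination Proportion of cytoplasmic material pelleting with
#'   chromosomes, in `[0, 1]` (about 0.17 for tubulin in mitotic HeLa
#'   fractionations).
#' @param total_signal Total densitometry signal, arbitrary units (> 0).
#' @param noise_cv Multiplicative lognormal noise CV per band (>= 0).
#' @return An object of class `blot_truth`.
#' @export
blot_truth <- function(true_fraction, contamination = 0,
                       total_signal = 100, noise_cv = 0) {
  stopifnot(true_fraction >= 0, true_fraction <= 1,
            contamination >= 0, contamination <= 1,
            total_signal > 0, noise_cv >= 0)
  structure(list(true_fraction = true_fraction,
                 contamination = contamination,
                 total_signal = total_signal,
                 noise_cv = noise_cv),
            class = "blot_truth")
}

#' Generate synthetic fractionation-blot band intensities
#'
#' @param truth A [blot_truth()].
#' @param seed Integer RNG seed.
#' @param protein Protein label carried into the sample.
#' @return A [blot_sample()] with whole-cell (`wce`), chromosomal
#'   (`chr_band`) and cytoplasmic (`cyto_band`) band intensities; with
#'   `noise_cv = 0` the bands satisfy the mixing model exactly.
#' @export
generate_blot <- function(truth, seed = 1L, protein = "protein") {
  stopifnot(inherits(truth, "blot_truth"))
  T <- truth$true_fraction
  c0 <- truth$contamination
  chr <- truth$total_signal * (T + c0 * (1 - T))
  cyto <- truth$total_signal * (1 - T) * (1 - c0)
  wce <- truth$total_signal
  if (truth$noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log1p(truth$noise_cv^2))
    fac <- rlnorm(3, -sdlog^2 / 2, sdlog)  # mean-one multiplicative noise
    wce <- wce * fac[1]; chr <- chr * fac[2]; cyto <- cyto * fac[3]
  }
  blot_sample(protein = protein, wce = wce, chr_band = chr, cyto_band = cyto,
              truth = truth)
}
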