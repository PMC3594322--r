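#' Estimate background statistics from a masked region
#'
#' Arithmetic mean and population standard deviation (divisor `n`, not
#' `n - 1`: the masked pixels are the whole population of interest, and at
#' the >= 100 pixels expected here the difference is negligible) of the
#' pixels in `background_mask`.
#'
#' @param image Numeric matrix of fluorescence intensities.
#' @param background_mask Logical matrix, `TRUE` outside the cell.
#' @return An object of class `background_stats`: `mean`, `sd`, `n_pixels`.
#' @export
estimate_background <- function(image, background_mask) {
  stopifnot(is.matrix(image), identical(dim(image), dim(background_mask)))
  px <- image[background_mask]
  if (length(px) == 0L) stop("background mask is empty")
  if (length(px) < 100L) {
    warning(sprintf("only %d background pixels; statistics may be unreliable",
                    length(px)))
  }
  m <- mean(px)
  structure(list(mean = m,
                 sd = sqrt(mean((px - m)^2)),
                 n_pixels = length(px)),
            class = "background_stats")
}

#' Segment the whole cell by a 12-SD background threshold
#'
#' The whole-cell region is every pixel strictly above
#' `bg$mean + 12 * bg$sd`, reduced to its largest connected component (a
#' single cell is imaged per measurement; the component rule discards debris
#' and hot pixels). A warning is raised when a second component reaches half
#' the size of the largest, since the field then likely holds more than one
#' object.
#'
#' @param image Numeric intensity matrix.
#' @param bg A [estimate_background()] result.
#' @param k Number of background standard deviations defining the threshold
#'   (default 12, the published convention).
#' @return Logical cell mask.
#' @export
segment_whole_cell <- function(image, bg, k = 12) {
  stopifnot(inherits(bg, "background_stats"), is.finite(bg$sd))
  thr <- bg$mean + k * bg$sd
  mask <- image > thr
  if (!any(mask)) stop("no cell detected: entire image below threshold")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(lab)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) > 1L) {
    top2 <- sort(sizes, decreasing = TRUE)[1:2]
    if (top2[2] >= 0.5 * top2[1]) {
      warning("ambiguous segmentation: second component >= 50% of the largest")
    }
  }
  out <- matrix(lab == which.max(sizes), nrow(image), ncol(image))
  out
}

#' Mean intensity over a masked region
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical matrix of the same dimensions.
#' @return Arithmetic mean of the masked pixels.
#' @export
mean_intensity <- function(image, mask) {
  stopifnot(is.matrix(image), identical(dim(image), dim(mask)))
  if (!any(mask)) stop("mask is empty")
  mean(image[mask])
}

#' Chromosome enrichment ratio
#'
#' \deqn{CER = (\bar I_{chrom} - \bar I_{bg}) / (\bar I_{cell} - \bar I_{bg}).}
#' The same background mean subtracts from numerator and denominator; no
#' clamping is applied, so a chromosome mean below background yields a
#' negative ratio (with a warning) rather than a silent zero, preserving the
#' estimator's linearity for downstream statistics.
#'
#' @param chrom_mean Mean intensity of the metaphase-plate ROI.
#' @param cell_mean Mean intensity of the segmented whole cell.
#' @param bg_mean Background mean intensity.
#' @return The dimensionless ratio.
#' @export
compute_cer <- function(chrom_mean, cell_mean, bg_mean) {
  stopifnot(is.numeric(chrom_mean), is.numeric(cell_mean), is.numeric(bg_mean))
  if (cell_mean <= bg_mean) {
    stop("degenerate cell signal: whole-cell mean does not exceed background")
  }
  if (chrom_mean < bg_mean) {
    warning("chromosome mean below background; returning a negative ratio (possible over-subtraction)")
  }
  (chrom_mean - bg_mean) / (cell_mean - bg_mean)
}

#' Quantify one cell: background, segmentation, means, CER, QC
#'
#' Runs the full per-cell pipeline: [estimate_background()] on the
#' background mask, [segment_whole_cell()] at 12 background SDs,
#' [mean_intensity()] over the plate ROI and the segmented cell, then
#' [compute_cer()]. The chromosome region always comes from the supplied ROI
#' (the hand-drawn plate selection), never from the fluorescence threshold.
#' QC passes when the raw whole-cell mean lies in `qc_range`, endpoints
#' inclusive (the published window is 50-500).
#'
#' @param x A `synthetic_cell`, or a numeric image matrix (then `chrom_roi`
#'   and `background_mask` are required).
#' @param ... Passed to methods.
#' @return An object of class `cer_measurement`: `chrom_mean`, `cell_mean`,
#'   `background` ([estimate_background()] result), `cer`, `qc_pass`,
#'   `cell_id`, and the QC window used.
#' @export
quantify_cell <- function(x, ...) UseMethod("quantify_cell")

#' @rdname quantify_cell
#' @param chrom_roi Logical plate-ROI mask.
#' @param background_mask Logical background mask.
#' @param cell_id Identifier carried into the measurement.
#' @param qc_range Inclusive whole-cell mean intensity window, default
#'   `c(50, 500)`.
#' @export
quantify_cell.default <- function(x, chrom_roi, background_mask,
                                  cell_id = "cell", qc_range = c(50, 500),
                                  ...) {
  image <- x
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  bg <- stage("background", estimate_background(image, background_mask))
  cell_mask <- stage("segmentation", segment_whole_cell(image, bg))
  chrom_mean <- stage("chromosome mean", mean_intensity(image, chrom_roi))
  cell_mean <- stage("cell mean", mean_intensity(image, cell_mask))
  cer <- stage("cer", compute_cer(chrom_mean, cell_mean, bg$mean))
  structure(
    list(chrom_mean = chrom_mean,
         cell_mean = cell_mean,
         background = bg,
         cer = cer,
         qc_pass = cell_mean >= qc_range[1] & cell_mean <= qc_range[2],
         qc_range = qc_range,
         cell_id = cell_id,
         cell_mask = cell_mask),
    class = "cer_measurement")
}

#' @rdname quantify_cell
#' @param use_truth_roi Use the ground-truth plate mask instead of the
#'   emulated hand-drawn ROI (synthetic cells only).
#' @export
quantify_cell.synthetic_cell <- function(x, use_truth_roi = FALSE,
                                         cell_id = NULL,
                                         qc_range = c(50, 500), ...) {
  roi <- if (use_truth_roi) x$chrom_mask_truth else x$chrom_roi
  quantify_cell.default(x$fluor_image, chrom_roi = roi,
                        background_mask = x$background_mask,
                        cell_id = cell_id %||% sprintf("seed%d", x$seed),
                        qc_range = qc_range)
}

#' @export
print.cer_measurement <- function(x, ...) {
  cat(sprintf("CER measurement [%s]\n", x$cell_id))
  cat(sprintf("  chrom mean %.2f, cell mean %.2f, background %.2f (sd %.2f)\n",
              x$chrom_mean, x$cell_mean, x$background$mean, x$background$sd))
  cat(sprintf("  CER = %.4f, QC %s (window %g-%g)\n", x$cer,
              if (x$qc_pass) "pass" else "FAIL",
              x$qc_range[1], x$qc_range[2]))
  invisible(x)
}
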