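#' Densitometry record for one protein across fractionation lanes
#'
#' Band intensities from a subcellular fractionation immunoblot: whole-cell
#' extract (WCE), chromosome-enriched pellet (CHR) and cytoplasmic
#' supernatant (CYTO). Band quantification itself (lane profile to band
#' integral) is upstream of this package; the numbers arrive as inputs.
#'
#' @param protein Protein label.
#' @param wce Whole-cell extract band signal (arbitrary units).
#' @param chr_band Chromosomal-fraction band signal (>= 0).
#' @param cyto_band Cytoplasmic-fraction band signal (>= 0).
#' @param truth Optional [blot_truth()] in synthetic mode.
#' @return An object of class `blot_sample`.
#' @export
blot_sample <- function(protein, wce, chr_band, cyto_band, truth = NULL) {
  stopifnot(chr_band >= 0, cyto_band >= 0)
  if (chr_band + cyto_band <= 0) stop("chr_band + cyto_band must be > 0")
  structure(list(protein = protein, wce = wce, chr_band = chr_band,
                 cyto_band = cyto_band, truth = truth),
            class = "blot_sample")
}

#' Observed chromosome-associated percentage
#'
#' The percent of a protein in the chromosome-enriched fraction:
#' `100 * CHR / (CHR + CYTO)`.
#'
#' @param s A [blot_sample()].
#' @return Percentage in `[0, 100]`.
#' @export
chromosome_fraction <- function(s) {
  stopifnot(inherits(s, "blot_sample"))
  if (s$chr_band + s$cyto_band <= 0) stop("zero denominator: empty lanes")
  100 * s$chr_band / (s$chr_band + s$cyto_band)
}

#' Correct an observed chromosome fraction for cytoplasmic contamination
#'
#' The chromosome pellet captures a proportion `c` of cytoplasmic material
#' (measured with a pure-cytoplasm marker such as tubulin, about 17%), so
#' the observed fraction overstates true association. Two corrections are
#' reported:
#' \itemize{
#'   \item `proportional` (the default model):
#'     \eqn{T = 100 (f_{obs} - c)/(100 - c)}, the exact inverse of the
#'     linear mixing model \eqn{f_{obs} = T + c (1 - T)} under which
#'     contaminating cytoplasm pellets with the chromosomes;
#'   \item `subtraction`: the naive \eqn{f_{obs} - c}, reported alongside
#'     for comparison since published corrected ranges are consistent with
#'     either model.
#' }
#' A marker that is pure cytoplasm (\eqn{f_{obs} = c}) corrects to 0 under
#' both models.
#'
#' @param f_obs Observed chromosome fraction, percent.
#' @param contamination Contamination percentage `c`, `0 <= c < 100`.
#' @return List of class `contamination_correction` with elements
#'   `proportional`, `subtraction`, `f_obs`, `contamination`. Values below 0
#'   (f_obs < c) are clipped at 0 with a warning.
#' @export
correct_contamination <- function(f_obs, contamination) {
  stopifnot(is.numeric(f_obs), is.numeric(contamination),
            contamination >= 0, contamination < 100)
  prop <- 100 * (f_obs - contamination) / (100 - contamination)
  subt <- f_obs - contamination
  if (f_obs < contamination) {
    warning("observed fraction below contamination level; corrected value clipped at 0")
    prop <- pmax(prop, 0)
    subt <- pmax(subt, 0)
  }
  structure(list(proportional = prop, subtraction = subt,
                 f_obs = f_obs, contamination = contamination),
            class = "contamination_correction")
}

#' @export
print.contamination_correction <- function(x, ...) {
  cat(sprintf("observed %.1f%% with %.1f%% contamination\n", x$f_obs,
              x$contamination))
  cat(sprintf("  corrected: %.1f%% (proportional mixing) / %.1f%% (subtraction)\n",
              x$proportional, x$subtraction))
  invisible(x)
}

#' Relative abundance of a transgene vs the endogenous protein
#'
#' Ratio of whole-cell-extract band signals for the tagged transgene and its
#' endogenous counterpart.
#'
#' @param transgene_band,endogenous_band Band signals; `endogenous_band > 0`.
#' @return Dimensionless ratio.
#' @export
relative_abundance <- function(transgene_band, endogenous_band) {
  if (endogenous_band <= 0) stop("zero denominator: endogenous band must be > 0")
  transgene_band / endogenous_band
}
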