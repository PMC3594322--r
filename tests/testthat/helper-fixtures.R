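# Shared fixtures. A reduced geometry keeps most unit tests fast; tests of
# calibrated behaviour use the default geometry.

geom_small <- function(...) {
  cell_geometry(image_shape = c(96, 96), cell_axes = c(26, 28),
                plate_axes = c(16, 5), ...)
}

flat_geom <- function(...) {
  cell_geometry(image_shape = c(96, 96), cell_axes = c(26, 28),
                plate_axes = c(16, 5), thickness_power = 0, ...)
}

uniform_profile <- function(...) {
  localization_profile("uniform", chrom_enrich = 1, spindle_enrich = 1,
                       centrosome_enrich = 1, ...)
}

# Minimal cer_measurement for classifier tests.
fake_measurement <- function(cer, cell_mean = 150, qc_range = c(50, 500)) {
  structure(list(chrom_mean = NA_real_, cell_mean = cell_mean,
                 background = NULL, cer = cer,
                 qc_pass = cell_mean >= qc_range[1] & cell_mean <= qc_range[2],
                 qc_range = qc_range, cell_id = "fake"),
            class = "cer_measurement")
}

# Quantify a cohort and return eligible (QC-passing, plate-defined) CERs.
eligible_cers <- function(cohort) {
  ms <- suppressWarnings(lapply(cohort, quantify_cell))
  ok <- vapply(ms, function(m) isTRUE(m$qc_pass), logical(1)) &
    vapply(cohort, `[[`, logical(1), "plate_defined")
  vapply(ms[ok], `[[`, numeric(1), "cer")
}
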