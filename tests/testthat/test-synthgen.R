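test_that("flat uniform cell has ground-truth CER exactly 1", {
  cell <- generate_cell_image(uniform_profile(), flat_geom(), no_noise(),
                              seed = 1)
  expect_identical(cell$true_cer, 1)
})

test_that("dome thickness alone pushes a uniform fluorophore above CER 1", {
  cell <- generate_cell_image(uniform_profile(), geom_small(), no_noise(),
                              seed = 1)
  expect_gt(cell$true_cer, 1)
  # steeper domes concentrate more projected signal at the plate
  steeper <- generate_cell_image(uniform_profile(),
                                 geom_small(thickness_power = 1),
                                 no_noise(), seed = 1)
  expect_gt(steeper$true_cer, cell$true_cer)
})

test_that("ground-truth CER matches a per-pixel sum oracle", {
  prof <- localization_profile("enriched", chrom_enrich = 3)
  for (g in list(flat_geom(), geom_small())) {
    cell <- generate_cell_image(prof, g, no_noise(), seed = 3)
    expect_equal(
      cell$true_cer,
      oracle_cer(cell$fluor_image, cell$chrom_mask_truth,
                 cell$cell_mask_truth, g$background_level),
      tolerance = 1e-12)
  }
})

test_that("noise-free image equals the analytic expected image everywhere", {
  prof <- localization_profile("x", chrom_enrich = 2, spindle_enrich = 1.4,
                               centrosome_enrich = 2)
  g <- geom_small()
  cell <- generate_cell_image(prof, g, no_noise(), seed = 5, expression = 150)
  # independent reconstruction of the expected image from the documented model
  nr <- g$image_shape[1]; nc <- g$image_shape[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  expected <- matrix(g$background_level, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r2 <- ((i - cy) / g$cell_axes[1])^2 + ((j - cx) / g$cell_axes[2])^2
      if (r2 >= 1) next
      t <- (1 - r2)^g$thickness_power
      mult <- 1
      if (((i - cy) / (0.45 * g$cell_axes[1]))^2 +
          ((j - cx) / (0.80 * g$cell_axes[2]))^2 < 1) mult <- 1.4
      pole <- 0.80 * g$cell_axes[2]
      foci <- exp(-((i - cy)^2 + (j - (cx - pole))^2) / 18) +
        exp(-((i - cy)^2 + (j - (cx + pole))^2) / 18)
      mult <- mult + (2 - 1) * foci
      if (((i - cy) / g$plate_axes[1])^2 + ((j - cx) / g$plate_axes[2])^2 < 1) {
        mult <- 2
      }
      expected[i, j] <- g$background_level + t * mult * 150
    }
  }
  expect_equal(max(abs(cell$fluor_image - expected)), 0)
})

test_that("masks are mutually consistent and partition accounted pixels", {
  cell <- generate_cell_image(uniform_profile(), geom_small(), no_noise(),
                              seed = 2)
  expect_true(all(cell$cell_mask_truth[cell$chrom_mask_truth]))
  expect_true(all(cell$cell_mask_truth[cell$chrom_roi]))
  expect_false(any(cell$background_mask & cell$cell_mask_truth))
  n_chrom <- sum(cell$chrom_mask_truth)
  n_rest <- sum(cell$cell_mask_truth & !cell$chrom_mask_truth)
  n_bg <- sum(cell$background_mask)
  expect_identical(n_chrom + n_rest, sum(cell$cell_mask_truth))
  expect_gt(n_bg, 100)
})

test_that("generation is deterministic given the seed", {
  prof <- localization_profile("x", chrom_enrich = 2)
  a <- generate_cell_image(prof, geom_small(), noise_model(), seed = 11)
  b <- generate_cell_image(prof, geom_small(), noise_model(), seed = 11)
  expect_identical(a$fluor_image, b$fluor_image)
  expect_identical(a$chrom_roi, b$chrom_roi)
  ca <- generate_cohort(prof, 8, geom_small(), noise_model(), seed = 4)
  cb <- generate_cohort(prof, 8, geom_small(), noise_model(), seed = 4)
  for (i in 1:8) expect_identical(ca[[i]]$fluor_image, cb[[i]]$fluor_image)
  cc <- generate_cohort(prof, 8, geom_small(), noise_model(), seed = 5)
  expect_false(identical(ca[[1]]$fluor_image, cc[[1]]$fluor_image))
})

test_that("zero expression variability and no noise give identical cells", {
  prof <- localization_profile("x", chrom_enrich = 2, expression_cv = 0)
  co <- generate_cohort(prof, 6, geom_small(), no_noise(), seed = 9)
  cers <- vapply(co, `[[`, numeric(1), "true_cer")
  expect_true(all(cers == cers[1]))
  exprs <- vapply(co, `[[`, numeric(1), "expression")
  expect_true(all(exprs == prof$expression_mean))
})

test_that("QC-window tail fraction matches the lognormal closed form", {
  prof <- localization_profile("x", chrom_enrich = 1.5, expression_cv = 0.5,
                               expression_mean = 180)
  g <- geom_small()
  co <- generate_cohort(prof, 50, g, no_noise(), seed = 21,
                        prob_ill_defined = 0)
  cell_means <- vapply(co, function(cl) {
    mean_intensity(cl$fluor_image, cl$cell_mask_truth)
  }, numeric(1))
  observed <- mean(cell_means < 50 | cell_means > 500)
  # closed form: cell mean = bg + c * E with E lognormal; solve the E bounds
  c_fac <- (cell_means[1] - g$background_level) / co[[1]]$expression
  sdlog <- sqrt(log1p(0.5^2))
  meanlog <- log(180) - sdlog^2 / 2
  p_out <- plnorm((50 - g$background_level) / c_fac, meanlog, sdlog) +
    plnorm((500 - g$background_level) / c_fac, meanlog, sdlog,
           lower.tail = FALSE)
  expect_lt(abs(observed - p_out), 3 * sqrt(p_out * (1 - p_out) / 50) + 0.02)
})

test_that("ground-truth CER is monotone in compartment enrichment", {
  g <- geom_small()
  cer_at <- function(chrom, spindle) {
    generate_cell_image(
      localization_profile("x", chrom_enrich = chrom,
                           spindle_enrich = spindle),
      g, no_noise(), seed = 1)$true_cer
  }
  by_chrom <- vapply(c(0.5, 1, 1.5, 2, 3), cer_at, numeric(1), spindle = 1.3)
  expect_true(all(diff(by_chrom) > 0))
  by_spindle <- vapply(c(0.8, 1, 1.5, 2), function(s) cer_at(2, s), numeric(1))
  expect_true(all(diff(by_spindle) < 0))
})

test_that("generator refuses saturating and impossible geometries", {
  expect_error(
    generate_cell_image(localization_profile("x", chrom_enrich = 3),
                        geom_small(), no_noise(), seed = 1,
                        expression = 5000),
    "saturation")
  expect_error(cell_geometry(cell_axes = c(26, 28), plate_axes = c(27, 5)),
               "inside")
  expect_error(cell_geometry(image_shape = c(64, 64), cell_axes = c(26, 28),
                             plate_axes = c(16, 5)),
               "margin")
  expect_error(generate_cohort(uniform_profile(), 0, geom_small()),
               ">= 1")
})

test_that("profile calibration hits any attainable target CER", {
  g <- geom_small()
  for (target in c(1.0, 1.2, 1.37, 1.87, 2.45, 3.5)) {
    prof <- calibrate_profile(target, localization_profile("x"), g)
    cell <- generate_cell_image(prof, g, no_noise(), seed = 1)
    expect_equal(cell$true_cer, target, tolerance = 1e-12)
  }
  expect_error(calibrate_profile(50, localization_profile("x"), g),
               "geometric maximum")
})

test_that("shipped construct catalogue is calibrated to its target CERs", {
  g <- cell_geometry()
  profs <- load_construct_catalogue(geometry = g)
  expect_true(all(c("WT_1-433", "GFP", "WT_1-63") %in% names(profs)))
  targets <- c("WT_1-433" = 1.87, "GFP" = 1.37, "WT_1-63" = 2.45,
               "WT_1-110" = 2.34, "WT_1-166" = 2.14)
  for (nm in names(targets)) {
    cell <- generate_cell_image(profs[[nm]], g, no_noise(), seed = 1)
    expect_equal(cell$true_cer, targets[[nm]], tolerance = 1e-12)
  }
})

test_that("synthetic blots follow the linear mixing model", {
  # model identity at zero noise
  s <- generate_blot(blot_truth(0.5, 0, 100, 0))
  expect_equal(s$chr_band, 50)
  expect_equal(s$cyto_band, 50)
  # a pure-cytoplasm protein shows exactly the contamination level
  s <- generate_blot(blot_truth(0, 0.17, 100, 0))
  expect_equal(chromosome_fraction(s), 17)
  # noisy blots are reproducible by seed
  a <- generate_blot(blot_truth(0.4, 0.1, 100, 0.1), seed = 7)
  b <- generate_blot(blot_truth(0.4, 0.1, 100, 0.1), seed = 7)
  expect_identical(a$chr_band, b$chr_band)
  expect_error(blot_truth(1.2, 0), "true_fraction")
})
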