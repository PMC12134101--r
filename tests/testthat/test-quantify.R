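toy_channel_map <- function() {
  tibble::tibble(
    subclass = c("PC", "PC", "CE"),
    channel = c("[M+H]+", "[M+H-H2O]+", "[M+NH4]+"),
    fraction = c(0.8, 0.2, 1)
  )
}

test_that("channel summation collapses mapped channels and warns otherwise", {
  peaks <- tibble::tibble(
    sample_id = "S1",
    analyte = c("PC 34:1", "PC 34:1", "PC 34:1", "CE 18:2"),
    channel = c("[M+H]+", "[M+H-H2O]+", "[M+Na]+", "[M+NH4]+"),
    area = c(100, 20, 999, 50)
  )
  expect_warning(
    out <- sum_channels(peaks, toy_channel_map()),
    "unmapped"
  )
  expect_equal(out$area[out$analyte == "PC 34:1"], 120)
  expect_equal(out$area[out$analyte == "CE 18:2"], 50)
  # single-channel analyte passes through unchanged
  single <- sum_channels(peaks[4, ], toy_channel_map())
  expect_equal(single$area, 50)
  # a subclass with no channel entry at all is an error
  expect_error(
    sum_channels(
      tibble::tibble(
        sample_id = "S1", analyte = "TG 52:3",
        channel = "[M+NH4]+", area = 1
      ),
      toy_channel_map()
    ),
    class = "avl_channel_error"
  )
  expect_error(
    sum_channels(dplyr::mutate(peaks, area = -area), toy_channel_map()),
    class = "avl_schema_error"
  )
})

test_that("type II correction removes the M+2 of the d+1 neighbour", {
  # two-species toy: the correction must subtract exactly area * r2
  f <- lipid_formulas("PC 34:2")$formula[[1]]
  r2 <- m2_m0_ratio(f)
  o <- oracle_m012(f)
  expect_equal(r2, unname(o["M2"] / o["M0"]), tolerance = 1e-9)
  summed <- tibble::tibble(
    sample_id = "S1",
    analyte = c("PC 34:2", "PC 34:1"),
    subclass = "PC",
    area = c(1000, 1000)
  )
  out <- type2_correct(summed)
  expect_equal(out$area[out$analyte == "PC 34:2"], 1000)
  expect_equal(out$area[out$analyte == "PC 34:1"], 1000 - 1000 * r2)

  # single species in a subclass: idempotent
  one <- type2_correct(summed[1, ])
  expect_equal(one$area, 1000)
  expect_equal(type2_correct(one), one)

  # clipping at zero
  clipped <- type2_correct(tibble::tibble(
    sample_id = "S1", analyte = c("PC 34:2", "PC 34:1"),
    subclass = "PC", area = c(1e6, 1)
  ))
  expect_gte(min(clipped$area), 0)

  # cascade: correction runs from most unsaturated downwards
  tri <- type2_correct(tibble::tibble(
    sample_id = "S1",
    analyte = c("PC 34:3", "PC 34:2", "PC 34:1"),
    subclass = "PC", area = c(1000, 1000, 1000)
  ))
  f2 <- lipid_formulas("PC 34:3")$formula[[1]]
  a342 <- 1000 - 1000 * m2_m0_ratio(f2)
  expect_equal(tri$area[tri$analyte == "PC 34:2"], a342)
  expect_equal(
    tri$area[tri$analyte == "PC 34:1"],
    1000 - a342 * m2_m0_ratio(lipid_formulas("PC 34:2")$formula[[1]])
  )
})

test_that("single-point quantification has the stated algebraic structure", {
  istd <- av_istd_panel()
  metadata <- tibble::tibble(sample_id = "S1", tissue_mass_mg = 20)
  # analyte area == standard area, matched formulas: conc = spike / mass.
  # Use the standard's own composition as a synthetic analyte so the
  # type I factor reduces to the deuterium-purity ratio, which we supply.
  pc_istd <- istd[istd$serves_subclass == "PC", ]
  m0_a <- monoisotopic_fraction(lipid_formulas("PC 33:1")$formula[[1]])
  m0_i <- monoisotopic_fraction(pc_istd$formula[[1]], purity = pc_istd$purity)
  peaks <- tibble::tibble(
    sample_id = "S1",
    analyte = c("PC 33:1", pc_istd$standard_name),
    channel = "[M+H]+",
    area = c(100 * m0_a, 100 * m0_i)
  )
  cm <- tibble::tibble(subclass = "PC", channel = "[M+H]+", fraction = 1)
  conc <- quantify_areas(peaks, metadata, istd = pc_istd, channel_map = cm)
  expect_equal(conc$conc_pmol_mg, pc_istd$spiked_pmol / 20)

  # doubling tissue mass halves the concentration
  conc2 <- quantify_areas(
    peaks, dplyr::mutate(metadata, tissue_mass_mg = 40),
    istd = pc_istd, channel_map = cm
  )
  expect_equal(conc2$conc_pmol_mg, conc$conc_pmol_mg / 2)

  # linear in analyte area
  peaks3 <- peaks
  peaks3$area[1] <- peaks3$area[1] * 3
  conc3 <- quantify_areas(peaks3, metadata, istd = pc_istd, channel_map = cm)
  expect_equal(conc3$conc_pmol_mg, conc$conc_pmol_mg * 3)

  # missing standard for a class errors
  expect_error(
    quantify_areas(
      dplyr::mutate(peaks, analyte = c("CE 18:2", pc_istd$standard_name)),
      metadata,
      istd = pc_istd,
      channel_map = tibble::tibble(
        subclass = c("CE", "PC"), channel = "[M+H]+", fraction = 1
      )
    ),
    class = "avl_missing_istd"
  )
})

test_that("forward simulation then quantification recovers truth", {
  design <- av_study_design(n_male = 4, n_female = 3)
  sim <- simulate_av_study(design, seed = 11)
  conc <- sim$concentrations
  metadata <- unique(conc[, c(
    "sample_id", "patient", "sex", "morphology", "stage", "tissue_mass_mg"
  )])

  # zero measurement noise: identity to < 1e-6 relative error
  peaks <- simulate_peak_areas(
    conc,
    measurement = av_measurement_model(noise_cv = 0), seed = 12
  )
  hat <- quantify_areas(peaks, metadata)
  cmp <- dplyr::inner_join(
    conc, dplyr::select(hat, "lipid", "sample_id", est = "conc_pmol_mg"),
    by = c("lipid", "sample_id")
  )
  cmp <- cmp[!is.na(cmp$conc_pmol_mg), ]
  expect_gt(nrow(cmp), 9000)
  expect_lt(
    max(abs(cmp$est - cmp$conc_pmol_mg) / cmp$conc_pmol_mg), 1e-6
  )
  # simulated missing cells come back as NA, never as fake numbers
  miss <- dplyr::inner_join(
    conc[is.na(conc$conc_pmol_mg), c("lipid", "sample_id")],
    hat,
    by = c("lipid", "sample_id")
  )
  expect_true(all(is.na(miss$conc_pmol_mg)))

  # M+2 leakage: correction reduces bias versus leaving it on
  peaks_leak <- simulate_peak_areas(
    conc,
    measurement = av_measurement_model(
      noise_cv = 0, inject_isotopologues = TRUE
    ),
    seed = 12
  )
  hat_corr <- quantify_areas(peaks_leak, metadata, type2 = TRUE)
  hat_raw <- quantify_areas(peaks_leak, metadata, type2 = FALSE)
  err <- function(h) {
    j <- dplyr::inner_join(
      conc, dplyr::select(h, "lipid", "sample_id", est = "conc_pmol_mg"),
      by = c("lipid", "sample_id")
    )
    j <- j[!is.na(j$conc_pmol_mg), ]
    stats::median(abs(j$est - j$conc_pmol_mg) / j$conc_pmol_mg)
  }
  expect_lt(err(hat_corr), err(hat_raw))
  expect_lt(err(hat_corr), 1e-6)
})

test_that("calibration fitting reports linearity and trims saturation", {
  pts <- tibble::tibble(amount = rep(c(1, 2, 5, 10, 20, 50, 100), each = 3))
  pts$area <- 40 * pts$amount + 7
  fit <- fit_calibration(pts)
  expect_s3_class(fit, "av_calibration")
  expect_equal(fit$r_squared, 1.0)
  expect_equal(fit$linear_range, c(1, 100))
  expect_equal(tidy(fit)$estimate, c(7, 40), tolerance = 1e-9)

  # saturating top point gets excluded from the linear range
  sat <- pts
  sat$area[sat$amount == 100] <- 0.55 * (40 * 100 + 7)
  fit2 <- fit_calibration(sat, rel_tol = 0.05)
  expect_equal(fit2$linear_range[2], 50)
  expect_equal(fit2$linear_range[1], 1)

  expect_error(
    fit_calibration(tibble::tibble(amount = c(5, 5, 5), area = c(1, 2, 3))),
    class = "avl_insufficient_data"
  )
  expect_error(
    fit_calibration(tibble::tibble(amount = c(1, 2, 3), area = c(4, 4, 4))),
    class = "avl_degenerate_design"
  )
})

test_that("linearity screen flags inflated samples and nonlinear lipids", {
  # 6-point toy with one 10x inflated area; hand-check via rstudent
  d <- tibble::tibble(
    lipid = "PC 34:1",
    sample_id = paste0("S", 1:6),
    conc_pmol_mg = c(10, 20, 30, 40, 50, 60)
  )
  summed <- tibble::tibble(
    analyte = "PC 34:1",
    sample_id = paste0("S", 1:6),
    subclass = "PC",
    area = c(100, 200, 300, 400, 500, 600)
  )
  expect_equal(nrow(linearity_screen(d, summed)), 0)

  summed_bad <- summed
  summed_bad$area[4] <- 4000 # 10x inflated area for S4
  flags <- linearity_screen(d, summed_bad, r2_min = 0.99)
  expect_true("nonlinear" %in% flags$flag)
  # hand check: deleting S4 leaves the exact line area = 10 * conc, which
  # predicts 400 for S4 against an observed 4000 -- an unbounded
  # studentized deviation, so S4 (and only S4) must be flagged
  flagged <- flags$sample_id[flags$flag == "outlier_sample"]
  expect_setequal(flagged, "S4")

  expect_warning(
    linearity_screen(d[1:3, ], summed[1:3, ]),
    "skipped"
  )
})

test_that("recovery rate is the stated before/after mean ratio", {
  expect_equal(recovery_rate(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(recovery_rate(c(50, 60, 70), c(100, 120, 140)), 50)
  expect_error(recovery_rate(numeric(0), 1), class = "avl_insufficient_data")
  expect_error(recovery_rate(1, 0), class = "avl_zero_denominator")
})
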