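toy_conc <- function() {
  tidyr::crossing(
    tibble::tibble(
      lipid = c("CE 18:2", "CE 16:0", "PC 34:1", "LPC 18:1"),
      subclass = c("CE", "CE", "PC", "LPC")
    ),
    tibble::tibble(
      sample_id = c("a", "b"),
      stage = c("mildly_diseased", "fibrotic")
    )
  ) |>
    dplyr::mutate(conc_pmol_mg = dplyr::case_when(
      lipid == "CE 18:2" ~ 3,
      lipid == "CE 16:0" ~ 7,
      lipid == "PC 34:1" ~ 8,
      lipid == "LPC 18:1" ~ 2
    ))
}

test_that("class totals sum member species and partition into categories", {
  totals <- class_totals(toy_conc())
  expect_equal(
    totals$total_pmol_mg[totals$subclass == "CE" & totals$sample_id == "a"],
    10
  )
  cat_tot <- class_totals(toy_conc(), level = "category")
  expect_equal(
    sum(cat_tot$total_pmol_mg[cat_tot$sample_id == "a"]),
    sum(totals$total_pmol_mg[totals$sample_id == "a"])
  )
})

test_that("pooled mildly diseased class totals reproduce the reference lipidome", {
  # noise-free study: the generator's baseline panel carries the printed
  # class totals (CE 10.80, TG 1.65, PC 0.8, SM 0.76, etherPE 0.27 nmol/mg)
  eff <- av_stage_effects(species_cv = 0, patient_cv = 0, missing_rate = 0)
  sim <- simulate_av_study(effects = eff, seed = 3)
  md <- class_totals(
    dplyr::filter(sim$concentrations, stage == "mildly_diseased"),
    summarise_by = "stage"
  )
  got <- stats::setNames(md$mean_total_pmol_mg, md$subclass)
  expect_equal(unname(got["CE"]) / 1000, 10.80, tolerance = 0.02)
  expect_equal(unname(got["TG"]) / 1000, 1.65, tolerance = 0.02)
  expect_equal(unname(got["PC"]) / 1000, 0.80, tolerance = 0.01)
  expect_equal(unname(got["SM"]) / 1000, 0.76, tolerance = 0.01)
  expect_equal(unname(got["etherPE"]) / 1000, 0.27, tolerance = 0.01)
})

test_that("ratio metrics divide class totals and report stage folds", {
  rm <- ratio_metric(toy_conc(), "LPC_PC")
  expect_equal(tidy(rm)$ratio, c(0.25, 0.25))
  # identical samples across stages -> all fold changes 1
  expect_equal(rm$stage_summary$fold_change, c(1, 1), ignore_attr = TRUE)
  g <- glance(rm)
  expect_equal(g$fold_fibrotic, 1)

  zero_den <- dplyr::mutate(
    toy_conc(),
    conc_pmol_mg = ifelse(subclass == "PC" & sample_id == "b", 0, conc_pmol_mg)
  )
  expect_warning(ratio_metric(zero_den, "LPC_PC"), "zero")
})

test_that("planted ratio fold changes are recovered from a simulated cohort", {
  sim <- simulate_av_study(seed = 7)
  lpc <- glance(ratio_metric(sim$concentrations, "LPC_PC"))
  expect_equal(lpc$fold_fibrotic, 2.8, tolerance = 0.25)
  expect_equal(lpc$fold_calcific, 4.0, tolerance = 0.25)
  cer <- glance(ratio_metric(sim$concentrations, "Cer_SM"))
  expect_equal(cer$fold_fibrotic, 1.5, tolerance = 0.2)
  expect_equal(cer$fold_calcific, 1.8, tolerance = 0.2)
})

test_that("stage fold changes are mean ratios and scale invariant", {
  x <- toy_conc()
  doubled <- dplyr::mutate(
    x, conc_pmol_mg = ifelse(stage == "fibrotic", 2 * conc_pmol_mg, conc_pmol_mg)
  )
  fc <- stage_fold_changes(doubled, by = "subclass")
  expect_equal(
    fc$fold_change[fc$stage == "fibrotic"], rep(2, 3)
  )
  expect_equal(
    fc$fold_change[fc$stage == "mildly_diseased"], rep(1, 3)
  )
  rescaled <- dplyr::mutate(doubled, conc_pmol_mg = conc_pmol_mg * 17)
  fc2 <- stage_fold_changes(rescaled, by = "subclass")
  expect_equal(fc2$fold_change, fc$fold_change)

  tot <- stage_fold_changes(doubled, by = "total")
  expect_equal(tot$fold_change[tot$stage == "fibrotic"], 2)
})

test_that("welch t behaves at the null, under separation, and vs permutation", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  apart <- welch_t(c(1, 2, 3), c(101, 102, 103))
  expect_lt(apart$p_value, 1e-6)

  expect_error(welch_t(1, c(1, 2)), class = "avl_insufficient_data")

  # identical constant groups
  const <- welch_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(const$p_value, 1)

  # permutation oracle agreement on a 5+5 toy with comparable spreads
  x <- c(2.1, 3.4, 2.9, 3.8, 2.5)
  y <- c(4.0, 4.9, 4.4, 5.6, 3.9)
  p_w <- welch_t(x, y)$p_value
  p_perm <- oracle_permutation_p(x, y)
  expect_lt(abs(p_w - p_perm), 0.02)
})

test_that("one-way ANOVA detects planted stage effects and respects the null", {
  flat <- one_way_anova(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_lt(flat$statistic, 1e-12)
  expect_gt(flat$p_value, 0.999)

  expect_error(
    one_way_anova(1:4, c("a", "a", "a", "b")),
    class = "avl_insufficient_data"
  )

  # type-I error near nominal on a null study (quick check; the full
  # 10,000-lipid calibration lives in the acceptance suite)
  null <- null_study(n_lipids = 600, seed = 5)
  by_lipid <- anova_by_lipid(null)
  rate <- mean(by_lipid$p_value < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.08)

  # power at the generator's default effect sizes
  sim <- simulate_av_study(seed = 6)
  ce <- dplyr::filter(sim$concentrations, subclass == "CE")
  pw <- anova_by_lipid(ce)
  expect_gt(mean(pw$p_value < 0.05, na.rm = TRUE), 0.8)
})

test_that("welch p-values are uniform under the null", {
  null <- null_study(n_lipids = 1500, seed = 9)
  md_fib <- dplyr::filter(null, stage != "calcific")
  p <- dplyr::summarise(
    dplyr::group_by(md_fib, lipid),
    p = welch_t(
      conc_pmol_mg[stage == "fibrotic"],
      conc_pmol_mg[stage == "mildly_diseased"]
    )$p_value,
    .groups = "drop"
  )$p
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("volcano preparation applies the joint FC and p gate", {
  set.seed(2)
  mk <- function(lipid, a_vals, b_vals) {
    tibble::tibble(
      lipid = lipid, subclass = "PC",
      sample_id = paste0("s", seq_len(length(a_vals) + length(b_vals))),
      sex = rep(c("female", "male"), c(length(a_vals), length(b_vals))),
      conc_pmol_mg = c(a_vals, b_vals)
    )
  }
  conc <- dplyr::bind_rows(
    mk("PC 34:1", c(2.0, 2.1, 1.9, 2.0, 2.05), c(1.0, 1.05, 0.95, 1.0, 1.0)),
    mk("PC 34:2", c(1.2, 1.21, 1.19, 1.2, 1.2), c(1.0, 1.01, 0.99, 1.0, 1.0)),
    mk("PC 36:2", c(1.1, 2.2, 0.9, 1.6, 1.3), c(1.2, 1.9, 1.1, 1.5, 1.2))
  )
  v <- volcano_prep(conc, "sex", c("female", "male"))
  v1 <- v[v$lipid == "PC 34:1", ] # FC 2, tiny p -> significant
  expect_true(v1$significant)
  expect_equal(v1$fold_change, 2, tolerance = 0.05)
  v2 <- v[v$lipid == "PC 34:2", ] # FC 1.2, tiny p -> gated out by FC
  expect_lt(v2$p_value, 0.001)
  expect_false(v2$significant)
  v3 <- v[v$lipid == "PC 36:2", ] # FC ~1, large p -> not significant
  expect_false(v3$significant)

  # missing-majority exclusion: lipid absent in 3 of 5 female samples
  sparse <- mk("PC 38:4", c(1, NA, NA, NA, 1.1), c(1, 1, 1, 1.05, 0.95))
  v4 <- volcano_prep(dplyr::bind_rows(conc, sparse), "sex", c("female", "male"))
  expect_false("PC 38:4" %in% v4$lipid)
})

test_that("male-up lipids in the calcific stage are TG species", {
  sim <- simulate_av_study(seed = 13)
  v <- volcano_prep(
    sim$concentrations, "sex", c("male", "female"),
    within = list(stage = "calcific")
  )
  up_male <- v[v$direction == "up_in_male", ]
  expect_gt(nrow(up_male), 5)
  # the male-up signature is TG-dominated (sporadic false positives from
  # other classes are expected at the raw-p gate over ~450 lipids)
  expect_gt(mean(up_male$subclass == "TG"), 0.9)
  expect_true(any(up_male$subclass == "TG"))
})

test_that("heatmap preparation yields unit-scaled rows", {
  sim <- simulate_av_study(av_study_design(3, 3), seed = 4)
  m <- heatmap_prep(
    sim$concentrations,
    lipids = unique(sim$concentrations$lipid)[1:40]
  )
  expect_lt(max(abs(rowMeans(m))), 1e-12)
  expect_lt(max(abs(apply(m, 1, stats::sd) - 1)), 1e-12)

  # after log, multiplying a row by a positive constant only shifts its
  # mean: the scaled row is invariant
  x <- sim$concentrations[sim$concentrations$lipid %in% unique(sim$concentrations$lipid)[1:10], ]
  y <- dplyr::mutate(
    x,
    conc_pmol_mg = ifelse(lipid == lipid[1], conc_pmol_mg * 37, conc_pmol_mg)
  )
  m1 <- heatmap_prep(x)
  m2 <- heatmap_prep(y)
  # equality up to the additive log guard
  expect_equal(m1[x$lipid[1], ], m2[x$lipid[1], ], tolerance = 1e-3)

  const <- tibble::tibble(
    lipid = "CE 18:2", subclass = "CE",
    sample_id = c("a", "b", "c"), conc_pmol_mg = 5
  )
  expect_warning(
    heatmap_prep(dplyr::bind_rows(
      const,
      tibble::tibble(
        lipid = "CE 16:0", subclass = "CE",
        sample_id = c("a", "b", "c"), conc_pmol_mg = c(1, 2, 3)
      )
    )),
    "constant"
  )
})

test_that("distribution plot data sorts species within class and sums them", {
  conc <- tibble::tibble(
    lipid = c("CE 16:0", "CE 18:2"), subclass = "CE",
    sample_id = "a", stage = "mildly_diseased", conc_pmol_mg = c(1, 10)
  )
  d <- distribution_plot_data(conc)
  expect_equal(d$lipid, c("CE 18:2", "CE 16:0"))
  expect_equal(d$rank, c(1, 2))
  expect_equal(unique(d$class_total_pmol_mg), 11)

  # on the reference study the extreme species are the printed ones
  eff <- av_stage_effects(species_cv = 0, patient_cv = 0, missing_rate = 0)
  sim <- simulate_av_study(effects = eff, seed = 8)
  dd <- distribution_plot_data(
    sim$concentrations,
    within = list(stage = "mildly_diseased")
  )
  expect_equal(dd$lipid[which.max(dd$mean_pmol_mg)], "CE 18:2")
  expect_equal(dd$lipid[which.min(dd$mean_pmol_mg)], "SM 32:0;O3")
  expect_lte(max(dd$mean_pmol_mg), max(dd$class_total_pmol_mg))
})
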