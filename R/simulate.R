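# Ground-truthed synthetic aortic-valve lipidomics studies.
#
# The generator emulates the study conditions: ~480 quantified species over
# 28 subclasses spanning ~6 orders of magnitude, three dissected sections
# (mildly diseased, fibrotic, calcific) per patient, stage- and
# sex-specific multiplicative effects mirroring the cohort's headline fold
# changes, 0.16% missingness, and a forward measurement model (class
# response factors, isotopologue structure, internal-standard spikes) that
# the quantification module inverts.

.STAGES <- c("mildly_diseased", "fibrotic", "calcific")

# Baseline class totals (pmol/mg wet tissue) for mildly diseased tissue.
# The five largest match the printed reference class totals; the remainder
# are plausible for a lipoprotein-rich tissue.
.CLASS_BASELINES <- c(
  CE = 10800, TG = 1650, DG = 150, MG = 10, PC = 800, PE = 200,
  etherPE = 270, PS = 60, PI = 100, PG = 30, PA = 25, CL = 80,
  LPC = 40, LPE = 15, LPA = 2, LPI = 3, LPS = 2, SM = 760,
  Cer = 100, dhCer = 5, deoxyCer = 13.3, phytoCer = 7.5, sphdCer = 9,
  HexCer = 25, Hex2Cer = 10, GM3 = 15, ST = 2500, FA = 120
)

# Rank-share exponent of the within-class power-law concentration profile.
.CLASS_ALPHA <- c(CE = 1.68, SM = 1.9, TG = 1.3, PC = 1.4)
.DEFAULT_ALPHA <- 1.5

.CER_ACYLS <- tibble::tibble(
  acyl = c(
    "24:0", "24:1", "16:0", "22:0", "23:0", "18:0", "20:0", "25:0",
    "26:0", "26:1", "21:0", "19:0", "17:0", "14:0", "15:0", "18:1",
    "20:1", "22:1", "16:1", "28:0", "28:1", "27:0", "25:1", "23:1"
  ),
  weight = c(
    0.30, 0.21, 0.18, 0.08, 0.04, 0.04, 0.03, 0.02,
    0.02, 0.015, 0.01, 0.005, 0.005, 0.005, 0.004, 0.004,
    0.004, 0.004, 0.003, 0.002, 0.002, 0.002, 0.002, 0.002
  )
)

cer_family_species <- function(class_token, base, n) {
  ac <- .CER_ACYLS[seq_len(n), ]
  tibble::tibble(
    lipid = paste0(class_token, " ", base, "/", ac$acyl),
    share = ac$weight / sum(ac$weight)
  )
}

power_shares <- function(n, alpha) {
  s <- seq_len(n)^(-alpha)
  s / sum(s)
}

species_comp_names <- function(token, comps, alpha) {
  tibble::tibble(
    lipid = paste(token, comps),
    share = power_shares(length(comps), alpha)
  )
}

#' The synthetic 480-species aortic-valve lipid panel
#'
#' A deterministic panel of 480 lipid species over the 28-subclass
#' registry with baseline concentrations (pmol/mg wet tissue, mildly
#' diseased) following a within-class power-law rank profile. The panel
#' spans ~6 orders of magnitude; CE 18:2 is the most abundant species and
#' SM 32:0;O3 the least, and the five largest class totals match the
#' reference tissue lipidome. Ceramide-family species are chain-resolved
#' so that sphingolipid decomposition applies.
#'
#' @return Tibble with columns `lipid` (canonical shorthand), `subclass`,
#'   `category`, `baseline_pmol_mg`.
#' @export
#' @examples
#' av_lipid_panel()
av_lipid_panel <- function() {
  cls <- list(
    species_comp_names("CE", c(
      "18:2", "18:1", "16:0", "18:3", "20:4", "16:1", "18:0", "20:3",
      "22:6", "20:5", "17:1", "14:0", "15:0", "16:2", "17:0", "19:2",
      "20:2", "22:5", "22:4", "18:4", "20:1", "19:1", "22:3", "14:1", "24:4"
    ), .CLASS_ALPHA[["CE"]]),
    {
      grid <- expand.grid(db = 0:8, c = c(52, 54, 50, 56, 48, 58, 46, 44, 60))
      comps <- paste0(grid$c, ":", grid$db)[seq_len(75)]
      species_comp_names("TG", comps, .CLASS_ALPHA[["TG"]])
    },
    {
      grid <- expand.grid(db = 0:5, c = c(34, 36, 32, 38))
      species_comp_names("DG", paste0(grid$c, ":", grid$db), .DEFAULT_ALPHA)
    },
    species_comp_names("MG", c("18:1", "16:0", "18:2", "18:0"), .DEFAULT_ALPHA),
    {
      grid <- expand.grid(db = 0:6, c = c(34, 36, 32, 38, 30, 40, 31))
      comps <- paste0(grid$c, ":", grid$db)[seq_len(45)]
      species_comp_names("PC", comps, .CLASS_ALPHA[["PC"]])
    },
    {
      grid <- expand.grid(db = 0:6, c = c(36, 38, 34, 40))
      species_comp_names("PE", paste0(grid$c, ":", grid$db), .DEFAULT_ALPHA)
    },
    {
      grid <- expand.grid(db = 1:6, c = c(36, 38, 34, 40))
      comps <- c(
        paste0("P-", grid$c, ":", grid$db),
        paste0("O-", c(34, 36, 38, 40, 34, 36), ":", c(1, 2, 4, 6, 3, 5))
      )
      species_comp_names("PE", comps, .DEFAULT_ALPHA)
    },
    {
      grid <- expand.grid(db = 0:5, c = c(36, 38, 40))
      comps <- paste0(grid$c, ":", grid$db)[seq_len(12)]
      species_comp_names("PS", comps, .DEFAULT_ALPHA)
    },
    {
      grid <- expand.grid(db = 0:5, c = c(38, 36, 34))
      comps <- paste0(grid$c, ":", grid$db)[seq_len(12)]
      species_comp_names("PI", comps, .DEFAULT_ALPHA)
    },
    {
      grid <- expand.grid(db = 0:4, c = c(34, 36))
      species_comp_names("PG", paste0(grid$c, ":", grid$db), .DEFAULT_ALPHA)
    },
    {
      grid <- expand.grid(db = 0:4, c = c(34, 36))
      species_comp_names("PA", paste0(grid$c, ":", grid$db), .DEFAULT_ALPHA)
    },
    species_comp_names("CL", paste0(
      c(72, 70, 72, 68, 74, 70, 72, 68, 74, 66),
      ":", c(8, 7, 7, 6, 8, 6, 6, 5, 9, 4)
    ), .DEFAULT_ALPHA),
    species_comp_names("LPC", c(
      "16:0", "18:2", "18:1", "18:0", "20:4", "16:1", "22:6", "20:3",
      "17:0", "15:0", "18:3", "20:5", "14:0", "20:2", "22:5", "24:0"
    ), .DEFAULT_ALPHA),
    species_comp_names("LPE", c(
      "18:1", "16:0", "18:2", "18:0", "20:4", "22:6", "16:1", "20:3",
      "18:3", "22:5", "17:0", "20:5"
    ), .DEFAULT_ALPHA),
    species_comp_names("LPA", c("18:1", "16:0", "18:2", "18:0", "20:4", "22:6"), .DEFAULT_ALPHA),
    species_comp_names("LPI", c("18:0", "18:1", "20:4", "16:0", "18:2"), .DEFAULT_ALPHA),
    species_comp_names("LPS", c("18:1", "18:0", "16:0", "20:4", "22:6"), .DEFAULT_ALPHA),
    {
      comps <- c(
        "34:1;O2", "34:2;O2", "36:1;O2", "42:2;O2", "36:2;O2", "42:1;O2",
        "40:1;O2", "42:3;O2", "38:1;O2", "33:1;O2", "41:1;O2", "40:2;O2",
        "35:1;O2", "39:1;O2", "41:2;O2", "38:2;O2", "36:0;O2", "34:0;O2",
        "43:1;O2", "43:2;O2", "44:1;O2", "44:2;O2", "32:1;O2", "37:1;O2",
        "42:4;O2", "40:3;O2", "34:1;O3", "42:1;O3", "36:1;O3", "44:3;O2",
        "33:2;O2", "35:2;O2", "39:2;O2", "45:1;O2", "45:2;O2", "31:1;O2",
        "46:2;O2"
      )
      sm <- species_comp_names("SM", comps, .CLASS_ALPHA[["SM"]])
      # the least abundant species of the whole panel
      tail_share <- 4e-6
      sm$share <- sm$share * (1 - tail_share)
      dplyr::bind_rows(sm, tibble::tibble(lipid = "SM 32:0;O3", share = tail_share))
    },
    {
      main <- cer_family_species("Cer", "18:1;O2", 24)
      minor <- dplyr::bind_rows(
        cer_family_species("Cer", "16:1;O2", 3),
        cer_family_species("Cer", "20:1;O2", 3)
      )
      main$share <- main$share * 0.97
      minor$share <- minor$share / sum(minor$share) * 0.03
      dplyr::bind_rows(main, minor)
    },
    cer_family_species("dhCer", "18:0;O2", 10),
    cer_family_species("deoxyCer", "18:1;O", 8),
    cer_family_species("phytoCer", "18:0;O3", 10),
    cer_family_species("sphdCer", "18:2;O2", 8),
    cer_family_species("HexCer", "18:1;O2", 12),
    cer_family_species("Hex2Cer", "18:1;O2", 8),
    cer_family_species("GM3", "18:1;O2", 10),
    tibble::tibble(lipid = "ST 27:1;O", share = 1),
    species_comp_names("FA", c(
      "16:0", "18:1", "18:2", "18:0", "20:4", "22:6", "16:1", "14:0",
      "20:5", "18:3", "22:4", "17:0", "15:0", "20:3", "24:1", "22:5"
    ), .DEFAULT_ALPHA)
  )
  totals_by_block <- c(
    "CE", "TG", "DG", "MG", "PC", "PE", "etherPE", "PS", "PI", "PG",
    "PA", "CL", "LPC", "LPE", "LPA", "LPI", "LPS", "SM", "Cer", "dhCer",
    "deoxyCer", "phytoCer", "sphdCer", "HexCer", "Hex2Cer", "GM3", "ST", "FA"
  )
  panel <- dplyr::bind_rows(lapply(seq_along(cls), function(i) {
    block <- cls[[i]]
    block$baseline_pmol_mg <- block$share * .CLASS_BASELINES[[totals_by_block[i]]]
    block$share <- NULL
    block
  }))
  parsed <- parse_lipid_names(panel$lipid)
  panel$lipid <- parsed$lipid
  panel$subclass <- parsed$subclass
  panel$category <- parsed$category
  dplyr::select(
    tibble::as_tibble(panel),
    "lipid", "subclass", "category", "baseline_pmol_mg"
  )
}

#' Synthetic study design
#'
#' @param n_male,n_female patients per sex (default 11 + 10, three sections
#'   each, matching a 21-valve stage comparison).
#' @param morphology valve morphology for all patients (`"TAV"` or
#'   `"BAV"`); mixed designs can be built by row-binding two designs.
#' @param tissue_mass_mean,tissue_mass_sd wet tissue mass distribution (mg).
#' @return A list describing the design.
#' @export
av_study_design <- function(n_male = 11, n_female = 10, morphology = "TAV",
                            tissue_mass_mean = 20, tissue_mass_sd = 2) {
  stopifnot(n_male + n_female >= 1, tissue_mass_mean > 0)
  patients <- tibble::tibble(
    patient = sprintf("P%02d", seq_len(n_male + n_female)),
    sex = c(rep("male", n_male), rep("female", n_female)),
    morphology = morphology
  )
  list(
    patients = patients,
    stages = .STAGES,
    tissue_mass_mean = tissue_mass_mean,
    tissue_mass_sd = tissue_mass_sd
  )
}

#' Default stage and sex effect model
#'
#' Multiplicative per-subclass stage effects (relative to mildly diseased)
#' planted to mirror the cohort's headline trends: CE 2.7/2.3, free sterol
#' 2.6/3.0, SM 1.9/1.8, and class multipliers chosen so the lipoprotein
#' proxy ratios come out at LPC/PC 2.8/4.0, Cer/SM 1.5/1.8, SM/PC 1.6/1.8
#' and LPE/PE 1.7/1.8 in fibrotic/calcific tissue. Sex terms emulate the
#' cohort's dimorphism: higher male baseline CE/TG, a strong female CE
#' surge at the fibrotic stage, and a male-specific elevation of
#' polyunsaturated TG species in calcific tissue.
#'
#' @param species_cv residual log-normal coefficient of variation per
#'   measurement (default 0.4).
#' @param patient_cv log-normal CV of the patient random effect shared by
#'   a patient's three sections (default 0.25).
#' @param missing_rate missing-at-random cell probability (default 0.0016).
#' @return A list with elements `class_effects`, `sex_baseline`,
#'   `sex_stage`, `pufa_tg_male_calcific`, `species_cv`, `patient_cv`,
#'   `missing_rate`.
#' @export
av_stage_effects <- function(species_cv = 0.4, patient_cv = 0.25,
                             missing_rate = 0.0016) {
  class_effects <- tibble::tribble(
    ~subclass, ~fibrotic, ~calcific,
    "CE", 2.7, 2.3,
    "ST", 2.6, 3.0,
    "TG", 1.0, 1.0,
    "DG", 1.3, 1.25,
    "MG", 1.2, 1.2,
    "FA", 1.5, 1.4,
    "PC", 1.2, 1.0,
    "PE", 1.0, 1.0,
    "etherPE", 1.0, 0.95,
    "PS", 1.0, 1.0,
    "PI", 1.0, 1.0,
    "PG", 1.0, 1.0,
    "PA", 1.1, 1.1,
    "CL", 1.0, 0.9,
    "LPC", 3.36, 4.0,
    "LPE", 1.7, 1.8,
    "LPA", 1.5, 1.6,
    "LPI", 1.2, 1.2,
    "LPS", 1.2, 1.2,
    "SM", 1.9, 1.8,
    "Cer", 2.85, 3.24,
    "dhCer", 2.85, 3.24,
    "deoxyCer", 2.85, 3.24,
    "phytoCer", 2.85, 3.24,
    "sphdCer", 2.85, 3.24,
    "HexCer", 2.0, 1.9,
    "Hex2Cer", 2.0, 1.9,
    "GM3", 2.0, 1.9
  )
  sex_baseline <- tibble::tribble(
    ~subclass, ~sex, ~mult,
    "TG", "male", 1.33,
    "TG", "female", 0.61,
    "CE", "male", 1.1,
    "CE", "female", 0.9
  )
  sex_stage <- tibble::tribble(
    ~subclass, ~sex, ~stage, ~mult,
    "CE", "female", "fibrotic", 1.35,
    "CE", "male", "fibrotic", 0.82,
    "TG", "female", "calcific", 1.4
  )
  list(
    class_effects = class_effects,
    sex_baseline = sex_baseline,
    sex_stage = sex_stage,
    pufa_tg_male_calcific = 1.5,
    species_cv = species_cv,
    patient_cv = patient_cv,
    missing_rate = missing_rate
  )
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Simulate a ground-truthed concentration study
#'
#' Draws per-sample species concentrations as baseline x stage multiplier
#' x sex terms x shared patient log-normal factor x residual log-normal
#' noise, then applies missing-at-random cells. The returned truth record
#' contains every planted quantity the downstream estimators target.
#'
#' @param design study design from [av_study_design()].
#' @param effects effect model from [av_stage_effects()].
#' @param panel lipid panel tibble, see [av_lipid_panel()].
#' @param seed integer seed; generation is bit-reproducible per seed.
#' @return A list: `concentrations` (long tibble with one row per lipid x
#'   sample: metadata, `conc_pmol_mg`, NA where missing) and `truth`
#'   (list: `panel`, `effects`, `expected`, the noise-free expected
#'   concentration per lipid x stage x sex).
#' @export
simulate_av_study <- function(design = av_study_design(),
                              effects = av_stage_effects(),
                              panel = av_lipid_panel(),
                              seed = 1L) {
  samples <- tidyr::crossing(design$patients, stage = design$stages)
  samples$stage <- factor(samples$stage, levels = .STAGES)
  samples <- dplyr::arrange(samples, .data$patient, .data$stage)
  samples$sample_id <- paste0(samples$patient, "_", substr(samples$stage, 1, 3))

  # replicated null panels carry " #k" suffixes; strip for parsing
  parsed <- parse_lipid_names(sub(" #\\d+$", "", panel$lipid))
  pufa_tg <- panel$subclass == "TG" & parsed$total_double_bonds >= 6L

  withr::with_seed(seed, {
    samples$tissue_mass_mg <- pmax(
      stats::rnorm(nrow(samples), design$tissue_mass_mean, design$tissue_mass_sd),
      design$tissue_mass_mean / 4
    )
    patient_factor <- stats::setNames(
      stats::rlnorm(
        nrow(design$patients),
        meanlog = 0, sdlog = cv_to_sdlog(effects$patient_cv)
      ),
      design$patients$patient
    )

    grid <- tidyr::crossing(
      tibble::tibble(
        lipid = panel$lipid, subclass = panel$subclass,
        baseline = panel$baseline_pmol_mg, pufa_tg = pufa_tg
      ),
      samples
    )
    mult <- planted_multiplier(
      grid$subclass, as.character(grid$stage), grid$sex, grid$pufa_tg, effects
    )
    expected <- grid$baseline * mult
    sdlog <- cv_to_sdlog(effects$species_cv)
    conc <- expected * unname(patient_factor[grid$patient]) *
      stats::rlnorm(nrow(grid), meanlog = 0, sdlog = sdlog)
    missing <- stats::runif(nrow(grid)) < effects$missing_rate
    conc[missing] <- NA_real_
  })

  concentrations <- tibble::tibble(
    lipid = grid$lipid, subclass = grid$subclass,
    sample_id = grid$sample_id, patient = grid$patient, sex = grid$sex,
    morphology = grid$morphology, stage = as.character(grid$stage),
    tissue_mass_mg = grid$tissue_mass_mg, conc_pmol_mg = conc
  )
  truth_expected <- dplyr::distinct(tibble::tibble(
    lipid = grid$lipid, stage = as.character(grid$stage), sex = grid$sex,
    expected_pmol_mg = expected
  ))
  list(
    concentrations = concentrations,
    truth = list(panel = panel, effects = effects, expected = truth_expected)
  )
}

planted_multiplier <- function(subclass, stage, sex, pufa_tg, effects) {
  mult <- rep(1, length(subclass))
  ce <- effects$class_effects
  for (st in c("fibrotic", "calcific")) {
    idx <- match(subclass, ce$subclass)
    hit <- stage == st & !is.na(idx)
    mult[hit] <- mult[hit] * ce[[st]][idx[hit]]
  }
  for (r in seq_len(nrow(effects$sex_baseline))) {
    row <- effects$sex_baseline[r, ]
    hit <- subclass == row$subclass & sex == row$sex
    mult[hit] <- mult[hit] * row$mult
  }
  for (r in seq_len(nrow(effects$sex_stage))) {
    row <- effects$sex_stage[r, ]
    hit <- subclass == row$subclass & sex == row$sex & stage == row$stage
    mult[hit] <- mult[hit] * row$mult
  }
  hit <- pufa_tg & sex == "male" & stage == "calcific"
  mult[hit] <- mult[hit] * effects$pufa_tg_male_calcific
  mult
}

#' Simulate a null study for statistical calibration
#'
#' All stage and sex multipliers are forced to one. Sections are drawn
#' independently (no shared patient factor) so that the marginal null
#' behaviour of the unpaired tests is what is calibrated; the residual
#' dispersion absorbs the patient CV.
#'
#' @inheritParams simulate_av_study
#' @param n_lipids number of null lipids; the panel is recycled with
#'   suffixed names when more than 480 are requested.
#' @return A long concentration tibble as in [simulate_av_study()].
#' @export
null_study <- function(design = av_study_design(), n_lipids = NULL,
                       effects = av_stage_effects(), seed = 1L) {
  panel <- av_lipid_panel()
  if (!is.null(n_lipids)) {
    reps <- ceiling(n_lipids / nrow(panel))
    panel <- panel[rep(seq_len(nrow(panel)), reps)[seq_len(n_lipids)], ]
    panel$lipid <- make.unique(panel$lipid, sep = " #")
  }
  eff <- effects
  eff$class_effects$fibrotic <- 1
  eff$class_effects$calcific <- 1
  eff$sex_baseline <- eff$sex_baseline[0, ]
  eff$sex_stage <- eff$sex_stage[0, ]
  eff$pufa_tg_male_calcific <- 1
  # fold the patient effect into the residual: independent sections
  eff$species_cv <- sqrt(exp(
    log(1 + effects$species_cv^2) + log(1 + effects$patient_cv^2)
  ) - 1)
  eff$patient_cv <- 0
  eff$missing_rate <- 0
  sim <- simulate_av_study(design, eff, panel, seed = seed)
  sim$concentrations
}

#' Default internal-standard panel
#'
#' One class-matched standard per subclass: an exotic or deuterated
#' species, its label size, isotopic purity per position, and the spiked
#' amount (pmol per sample), set near the mid-range of the endogenous
#' class signal for a 20 mg sample.
#'
#' @param panel lipid panel used to scale spike amounts.
#' @param purity isotopic purity per deuterium position.
#' @return Tibble: `standard_name`, `serves_subclass`, `species`,
#'   `deuterium_count`, `purity`, `spiked_pmol`, `formula` (list-column).
#' @export
av_istd_panel <- function(panel = av_lipid_panel(), purity = 0.98) {
  class_totals <- dplyr::summarise(
    dplyr::group_by(panel, .data$subclass),
    total = sum(.data$baseline_pmol_mg), .groups = "drop"
  )
  species <- c(
    CE = "CE 18:1", TG = "TG 45:0", DG = "DG 31:1", MG = "MG 17:1",
    PC = "PC 15:0/18:1", PE = "PE 15:0/18:1", etherPE = "PE O-18:0/18:1",
    PS = "PS 15:0/18:1", PI = "PI 15:0/18:1", PG = "PG 15:0/18:1",
    PA = "PA 15:0/18:1", CL = "CL 56:0", LPC = "LPC 18:1", LPE = "LPE 18:1",
    LPA = "LPA 18:1", LPI = "LPI 18:1", LPS = "LPS 18:1",
    SM = "SM 18:1;O2/18:1", Cer = "Cer 18:1;O2/15:0",
    dhCer = "Cer 18:0;O2/15:0", deoxyCer = "Cer 18:1;O/15:0",
    phytoCer = "Cer 18:0;O3/15:0", sphdCer = "Cer 18:2;O2/15:0",
    HexCer = "HexCer 18:1;O2/15:0", Hex2Cer = "Hex2Cer 18:1;O2/15:0",
    GM3 = "GM3 18:1;O2/18:1", ST = "ST 27:1;O", FA = "FA 16:0"
  )
  out <- tibble::tibble(
    standard_name = paste0("ISTD ", names(species)),
    serves_subclass = names(species),
    species = unname(species),
    deuterium_count = 7L,
    purity = purity
  )
  out$spiked_pmol <- class_totals$total[
    match(out$serves_subclass, class_totals$subclass)
  ] * 20
  f <- lipid_formulas(out$species)$formula
  out$formula <- mapply(label_formula, f, out$deuterium_count, SIMPLIFY = FALSE)
  out
}

#' Default adduct/in-source-fragment channel map
#'
#' Which measured channels are summed per subclass before quantification.
#'
#' @return Tibble with columns `subclass`, `channel`, `fraction` (the
#'   share of the total class signal the generator places on the channel).
#' @export
av_channel_map <- function() {
  reg <- av_class_registry()
  nh4 <- c("CE", "TG", "DG", "MG", "ST")
  dplyr::bind_rows(lapply(reg$subclass, function(sc) {
    if (sc %in% nh4) {
      tibble::tibble(
        subclass = sc,
        channel = c("[M+NH4]+", "[M+H-H2O]+"),
        fraction = c(0.8, 0.2)
      )
    } else {
      tibble::tibble(
        subclass = sc,
        channel = c("[M+H]+", "[M+H-H2O]+"),
        fraction = c(0.9, 0.1)
      )
    }
  }))
}

#' Default measurement model
#'
#' @param noise_cv multiplicative log-normal measurement noise CV.
#' @param rf_cv spread of per-subclass response factors (log-normal).
#' @param inject_isotopologues add M+2 leakage from the species with one
#'   more double bond (same subclass and carbon number) onto each species'
#'   monoisotopic signal, the interference removed by type II correction.
#'   On by default so that the default forward model and the default
#'   quantification (type II on) are exact inverses.
#' @return A list of measurement parameters.
#' @export
av_measurement_model <- function(noise_cv = 0.2, rf_cv = 0.3,
                                 inject_isotopologues = TRUE) {
  list(
    noise_cv = noise_cv, rf_cv = rf_cv,
    inject_isotopologues = inject_isotopologues
  )
}

#' Simulate internal-standard-spiked peak areas
#'
#' Forward measurement model inverted by [quantify_areas()]: each
#' analyte's summed signal is concentration x tissue mass x class response
#' factor x monoisotopic fraction x noise, split over the class's
#' channels; standards are spiked at known pmol. Optionally injects M+2
#' isotopologue leakage between double-bond neighbours.
#'
#' @param concentrations long concentration tibble (NA cells are emitted
#'   as zero-area signals).
#' @param istd internal-standard panel, see [av_istd_panel()].
#' @param measurement measurement model, see [av_measurement_model()].
#' @param channel_map channel map, see [av_channel_map()].
#' @param seed integer seed.
#' @return A peak table tibble: `sample_id`, `analyte`, `channel`, `area`.
#' @export
simulate_peak_areas <- function(concentrations, istd = av_istd_panel(),
                                measurement = av_measurement_model(),
                                channel_map = av_channel_map(), seed = 1L) {
  missing_class <- setdiff(
    unique(concentrations$subclass), istd$serves_subclass
  )
  if (length(missing_class) > 0) {
    rlang::abort(
      paste0(
        "no internal standard covers subclass: ",
        paste(missing_class, collapse = ", ")
      ),
      class = "avl_uncovered_class"
    )
  }

  lipids <- unique(concentrations[, c("lipid", "subclass")])
  parsed <- lipid_formulas(lipids$lipid)
  lipids$m0 <- monoisotopic_fraction(parsed$formula)
  lipids$series <- homologous_series_key(parsed)
  lipids$double_bonds <- parsed$total_double_bonds
  lipids$m2 <- vapply(parsed$formula, m2_m0_ratio, numeric(1))

  samples <- unique(concentrations[, c("sample_id", "tissue_mass_mg")])

  withr::with_seed(seed, {
    rf <- stats::setNames(
      stats::rlnorm(
        length(unique(lipids$subclass)),
        meanlog = 0, sdlog = cv_to_sdlog(measurement$rf_cv)
      ),
      sort(unique(lipids$subclass))
    )

    # undetected (missing) cells are absent from the report, as in a real
    # transition export, and contribute no interference
    x <- dplyr::left_join(
      concentrations[!is.na(concentrations$conc_pmol_mg), ], lipids,
      by = c("lipid", "subclass")
    )
    sdlog <- cv_to_sdlog(measurement$noise_cv)
    noise <- if (measurement$noise_cv > 0) {
      stats::rlnorm(nrow(x), meanlog = 0, sdlog = sdlog)
    } else {
      rep(1, nrow(x))
    }
    x$area <- x$conc_pmol_mg * x$tissue_mass_mg * rf[x$subclass] * x$m0 * noise

    if (isTRUE(measurement$inject_isotopologues)) {
      key <- paste(x$sample_id, x$series, x$double_bonds + 1L)
      partner <- match(
        key, paste(x$sample_id, x$series, x$double_bonds)
      )
      leak <- ifelse(is.na(partner), 0, x$area[partner] * x$m2[partner])
      x$area <- x$area + leak
    }

    istd_noise <- if (measurement$noise_cv > 0) {
      stats::rlnorm(nrow(istd) * nrow(samples), meanlog = 0, sdlog = sdlog)
    } else {
      rep(1, nrow(istd) * nrow(samples))
    }
  })

  analyte_rows <- split_channels(
    tibble::tibble(
      sample_id = x$sample_id, analyte = x$lipid,
      subclass = x$subclass, area = x$area
    ),
    channel_map
  )

  istd_grid <- tidyr::crossing(
    istd[, c("standard_name", "serves_subclass", "spiked_pmol")],
    samples[, "sample_id"]
  )
  istd_grid <- dplyr::arrange(istd_grid, .data$standard_name, .data$sample_id)
  istd_m0 <- monoisotopic_fraction(istd$formula, purity = istd$purity[1])
  istd_grid$area <- istd_grid$spiked_pmol *
    rf[istd_grid$serves_subclass] *
    istd_m0[match(istd_grid$standard_name, istd$standard_name)] *
    istd_noise
  istd_rows <- split_channels(
    tibble::tibble(
      sample_id = istd_grid$sample_id, analyte = istd_grid$standard_name,
      subclass = istd_grid$serves_subclass, area = istd_grid$area
    ),
    channel_map
  )

  out <- dplyr::bind_rows(analyte_rows, istd_rows)
  dplyr::arrange(
    out[, c("sample_id", "analyte", "channel", "area")],
    .data$sample_id, .data$analyte, .data$channel
  )
}

split_channels <- function(rows, channel_map) {
  joined <- dplyr::inner_join(rows, channel_map,
    by = "subclass",
    relationship = "many-to-many"
  )
  joined$area <- joined$area * joined$fraction
  joined[, c("sample_id", "analyte", "channel", "area")]
}
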