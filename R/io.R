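# Readers, writers and the end-to-end pipeline runner. Plain TSV/CSV with
# documented headers are the interchange formats (matching the ecosystem
# of transition-report exports), YAML for configuration, JSON for the run
# manifest.

.STAGE_LEVELS <- c("mildly_diseased", "fibrotic", "calcific")

schema_abort <- function(...) {
  rlang::abort(paste0(...), class = "avl_schema_error")
}

require_cols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0) {
    schema_abort(what, " is missing columns: ", paste(miss, collapse = ", "))
  }
}

#' Read a transition-report style peak table
#'
#' CSV with columns `sample_id` (or `Replicate`), `analyte` (or
#' `Molecule`), `channel` (or `Precursor`/`Transition`), `area` (or
#' `Area`). Duplicate (sample, analyte, channel) rows and negative areas
#' are schema errors.
#'
#' @param path CSV file path.
#' @return Peak table tibble.
#' @export
read_peak_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  aliases <- c(
    Replicate = "sample_id", Molecule = "analyte", Precursor = "channel",
    Transition = "channel", Area = "area"
  )
  for (a in names(aliases)) {
    if (a %in% names(x) && !aliases[[a]] %in% names(x)) {
      names(x)[names(x) == a] <- aliases[[a]]
    }
  }
  require_cols(x, c("sample_id", "analyte", "channel", "area"), "peak table")
  dup <- duplicated(x[, c("sample_id", "analyte", "channel")])
  if (any(dup)) {
    schema_abort(
      "duplicate (sample, analyte, channel) rows, first at row ",
      which(dup)[1]
    )
  }
  if (any(!is.finite(x$area)) || any(x$area < 0)) {
    schema_abort("peak areas must be finite and non-negative")
  }
  tibble::as_tibble(x[, c("sample_id", "analyte", "channel", "area")])
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `patient`, `sex`, `morphology`
#' (TAV/BAV), `stage`, `tissue_mass_mg`. Stage labels are normalized
#' case-insensitively (e.g. "Calcific" -> "calcific").
#'
#' @param path TSV file path.
#' @return Metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_cols(
    x, c("sample_id", "patient", "sex", "morphology", "stage", "tissue_mass_mg"),
    "sample metadata"
  )
  if (anyDuplicated(x$sample_id)) {
    schema_abort("duplicate sample_id in metadata")
  }
  stage <- gsub("[ -]", "_", tolower(trimws(x$stage)))
  bad <- !stage %in% .STAGE_LEVELS
  if (any(bad)) {
    schema_abort(
      "unknown stage labels: ", paste(unique(x$stage[bad]), collapse = ", ")
    )
  }
  x$stage <- stage
  x$morphology <- toupper(x$morphology)
  if (!all(x$morphology %in% c("TAV", "BAV"))) {
    schema_abort("morphology must be TAV or BAV")
  }
  x$sex <- tolower(x$sex)
  if (any(!is.finite(x$tissue_mass_mg)) || any(x$tissue_mass_mg <= 0)) {
    schema_abort("tissue_mass_mg must be positive")
  }
  tibble::as_tibble(x)
}

#' Read an internal-standard specification table
#'
#' TSV with columns `standard_name`, `serves_subclass`, `species`,
#' `deuterium_count`, `purity`, `spiked_pmol`.
#'
#' @param path TSV file path.
#' @return ISTD tibble with a parsed `formula` list-column.
#' @export
read_istd_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_cols(
    x,
    c(
      "standard_name", "serves_subclass", "species", "deuterium_count",
      "purity", "spiked_pmol"
    ),
    "internal-standard table"
  )
  if (anyDuplicated(x$serves_subclass)) {
    schema_abort("exactly one standard per served subclass is required")
  }
  if (any(x$spiked_pmol <= 0) || any(x$purity <= 0 | x$purity > 1)) {
    schema_abort("spiked_pmol must be > 0 and purity in (0, 1]")
  }
  f <- lipid_formulas(x$species)$formula
  x$formula <- mapply(label_formula, f, x$deuterium_count, SIMPLIFY = FALSE)
  tibble::as_tibble(x)
}

#' Write / read a concentration matrix
#'
#' The wide interchange form: lipids as rows, samples as columns,
#' pmol/mg values, NA for missing. Metadata travels in a companion TSV.
#'
#' @param concentrations long concentration tibble.
#' @param path output TSV path for the matrix.
#' @param metadata_path optional output TSV for the sample metadata.
#' @return `path`, invisibly.
#' @export
write_concentration_matrix <- function(concentrations, path,
                                       metadata_path = NULL) {
  wide <- tidyr::pivot_wider(
    concentrations[, c("lipid", "sample_id", "conc_pmol_mg")],
    names_from = "sample_id", values_from = "conc_pmol_mg"
  )
  readr::write_tsv(wide, path)
  if (!is.null(metadata_path)) {
    meta <- dplyr::distinct(
      concentrations[, conc_meta_cols(concentrations)]
    )
    readr::write_tsv(meta, metadata_path)
  }
  invisible(path)
}

#' @rdname write_concentration_matrix
#' @param metadata metadata tibble (or path) to re-attach when reading.
#' @export
read_concentration_matrix <- function(path, metadata = NULL) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_cols(wide, "lipid", "concentration matrix")
  if (anyDuplicated(wide$lipid)) {
    schema_abort("duplicate lipid rows in concentration matrix")
  }
  long <- tidyr::pivot_longer(
    wide, -"lipid",
    names_to = "sample_id", values_to = "conc_pmol_mg"
  )
  parsed <- parse_lipid_names(unique(long$lipid))
  long$subclass <- parsed$subclass[match(long$lipid, parsed$raw_name)]
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  if (!is.null(metadata)) {
    long <- dplyr::left_join(long, metadata, by = "sample_id")
  }
  dplyr::relocate(
    tibble::as_tibble(long), "lipid", "subclass",
    .before = 1
  )
}

#' Run the full analysis pipeline
#'
#' Quantification, stage/sex statistics, ratio metrics, trend clustering,
#' topology embedding and sphingolipid flows, with every table written as
#' TSV plus a JSON run manifest (inputs, seeds, file hashes). Configure
#' with a YAML file or an equivalent named list; unset keys fall back to
#' defaults. Keys: `peak_table`, `metadata`, `istd` (paths; all three
#' required unless `concentrations` is given), `concentrations` (matrix
#' TSV, alternative entry point), `out_dir`, `p_threshold`, `fc_threshold`,
#' `k`, `seed`, `umap_neighbors`, `umap_min_dist`.
#'
#' @param config YAML path or named list.
#' @return Invisibly, a list with the main result objects and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(
      out_dir = "av_pipeline_out", p_threshold = 0.05, fc_threshold = 1.5,
      k = 5, seed = 42, umap_neighbors = 15, umap_min_dist = 0.1
    ),
    config
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(
        paste0("[", name, "] ", conditionMessage(e)),
        class = "avl_pipeline_error"
      )
    })
  }

  inputs <- character(0)
  if (!is.null(cfg$concentrations)) {
    inputs <- c(inputs, cfg$concentrations, cfg$metadata)
    conc <- stage("read", read_concentration_matrix(
      cfg$concentrations,
      metadata = cfg$metadata
    ))
  } else {
    for (key in c("peak_table", "metadata", "istd")) {
      if (is.null(cfg[[key]])) {
        schema_abort("config key '", key, "' is required")
      }
      if (!file.exists(cfg[[key]])) {
        schema_abort("input file missing: ", cfg[[key]])
      }
    }
    inputs <- c(cfg$peak_table, cfg$metadata, cfg$istd)
    peaks <- stage("read", read_peak_table(cfg$peak_table))
    metadata <- stage("read", read_sample_metadata(cfg$metadata))
    istd <- stage("read", read_istd_table(cfg$istd))
    conc <- stage("quantify", quantify_areas(peaks, metadata, istd = istd))
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(cfg$out_dir, name)

  write_concentration_matrix(
    conc, outfile("concentrations.tsv"), outfile("sample_metadata.tsv")
  )

  totals <- stage("stats", class_totals(conc, summarise_by = c("stage")))
  readr::write_tsv(totals, outfile("class_totals.tsv"))

  ratios <- stage("stats", dplyr::bind_rows(lapply(
    c("LPC_PC", "LPE_PE", "Cer_SM", "SM_PC", "CE_TG"),
    function(nm) glance(ratio_metric(conc, nm))
  )))
  readr::write_tsv(ratios, outfile("ratio_metrics.tsv"))

  anova <- stage("stats", anova_by_lipid(conc))
  readr::write_tsv(anova, outfile("anova_by_lipid.tsv"))

  volcano <- stage("stats", volcano_prep(
    conc, "stage", c("calcific", "mildly_diseased"),
    fc_threshold = cfg$fc_threshold, p_threshold = cfg$p_threshold
  ))
  readr::write_tsv(volcano, outfile("volcano_calcific_vs_mild.tsv"))

  imputed <- stage("trends", impute_min_fifth(conc))
  sig <- anova$lipid[!is.na(anova$p_value) & anova$p_value < cfg$p_threshold]
  trends <- NULL
  if (length(sig) >= cfg$k) {
    trends <- stage("trends", gmm_trend_cluster(
      stage_average(imputed[imputed$lipid %in% sig, ]),
      k = cfg$k, seed = cfg$seed
    ))
    readr::write_tsv(tidy(trends), outfile("trend_membership.tsv"))
    readr::write_tsv(trend_summary(trends), outfile("trend_trajectories.tsv"))
  }

  features <- stage("topology", topology_features(imputed))
  embedding <- stage("topology", embed_lipidome(
    features,
    seed = cfg$seed, n_neighbors = cfg$umap_neighbors,
    min_dist = cfg$umap_min_dist
  ))
  readr::write_tsv(embedding, outfile("umap_embedding.tsv"))

  flow <- stage("sphingo", sphingo_flow(conc))
  readr::write_tsv(tibble::as_tibble(flow), outfile("sphingo_flow.tsv"))

  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  manifest <- list(
    package = "avlipidomics",
    version = as.character(utils::packageVersion("avlipidomics")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    output_md5 = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(
    manifest, outfile("run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    concentrations = conc, class_totals = totals, ratios = ratios,
    anova = anova, volcano = volcano, trends = trends,
    embedding = embedding, flow = flow, manifest = manifest
  ))
}
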