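# Stage/sex differential statistics on quantified lipidomes: class totals,
# lipoprotein-proxy ratios, fold changes, Welch t / one-way ANOVA, volcano
# and heatmap preparation, and class-distribution plot data.
#
# All functions take the long concentration tibble produced by
# quantify_areas() or simulate_av_study(): one row per lipid x sample with
# metadata columns (sample_id, patient, sex, morphology, stage,
# tissue_mass_mg) and conc_pmol_mg (NA = not detected).

.RATIO_SETS <- list(
  LPC_PC = list(num = "LPC", den = "PC"),
  LPE_PE = list(num = "LPE", den = "PE"),
  Cer_SM = list(num = c("Cer", "dhCer", "deoxyCer", "phytoCer", "sphdCer"), den = "SM"),
  SM_PC = list(num = "SM", den = "PC"),
  CE_TG = list(num = "CE", den = "TG")
)

conc_meta_cols <- function(concentrations) {
  intersect(
    c("sample_id", "patient", "sex", "morphology", "stage", "tissue_mass_mg"),
    names(concentrations)
  )
}

#' Per-sample class totals
#'
#' Sums member species per sample at subclass or category level; missing
#' values are treated as absent (zero contribution).
#'
#' @param concentrations long concentration tibble.
#' @param level `"subclass"` or `"category"`.
#' @param summarise_by optional metadata columns (e.g. `c("stage")` or
#'   `c("stage", "sex")`); when given, group means of the per-sample
#'   totals are returned instead.
#' @return Tibble of per-sample totals (`total_pmol_mg`), or group means
#'   (`mean_total_pmol_mg`, `sd_total_pmol_mg`, `n`).
#' @export
class_totals <- function(concentrations, level = c("subclass", "category"),
                         summarise_by = NULL) {
  level <- match.arg(level)
  stopifnot(nrow(concentrations) > 0)
  x <- concentrations
  if (level == "category") {
    x$group_class <- lipid_category(x$subclass)
  } else {
    x$group_class <- x$subclass
  }
  meta <- setdiff(conc_meta_cols(x), "tissue_mass_mg")
  totals <- dplyr::summarise(
    dplyr::group_by(
      x, dplyr::across(dplyr::all_of(c("group_class", meta)))
    ),
    total_pmol_mg = sum(.data$conc_pmol_mg, na.rm = TRUE),
    .groups = "drop"
  )
  names(totals)[names(totals) == "group_class"] <- level
  if (is.null(summarise_by)) {
    return(totals)
  }
  stopifnot(all(summarise_by %in% names(totals)))
  dplyr::summarise(
    dplyr::group_by(
      totals, dplyr::across(dplyr::all_of(c(level, summarise_by)))
    ),
    mean_total_pmol_mg = mean(.data$total_pmol_mg),
    sd_total_pmol_mg = stats::sd(.data$total_pmol_mg),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Lipoprotein-proxy class ratio
#'
#' Per-sample ratio of two class totals. `LPC_PC` and `Cer_SM` proxy
#' lipoprotein-associated phospholipase A2 and sphingomyelinase activity;
#' `SM_PC`, `LPE_PE` and `CE_TG` are the other reported composition
#' ratios. Ceramide variants (dhCer, deoxyCer, phytoCer, sphdCer) count
#' towards the Cer pool.
#'
#' @param concentrations long concentration tibble.
#' @param name one of `"LPC_PC"`, `"LPE_PE"`, `"Cer_SM"`, `"SM_PC"`,
#'   `"CE_TG"`.
#' @return An `av_ratio_metric` object: list with `name`, `samples`
#'   (per-sample ratios with metadata) and, when stages are present,
#'   `stage_summary` (per-stage mean, sd, n and fold change versus the
#'   mildly diseased stage).
#' @export
#' @examples
#' sim <- simulate_av_study(av_study_design(2, 2), seed = 1)
#' ratio_metric(sim$concentrations, "LPC_PC")
ratio_metric <- function(concentrations, name = names(.RATIO_SETS)) {
  name <- match.arg(name)
  set <- .RATIO_SETS[[name]]
  totals <- class_totals(concentrations, "subclass")
  meta <- setdiff(names(totals), c("subclass", "total_pmol_mg"))
  per_sample <- dplyr::summarise(
    dplyr::group_by(totals, dplyr::across(dplyr::all_of(meta))),
    num = sum(.data$total_pmol_mg[.data$subclass %in% set$num]),
    den = sum(.data$total_pmol_mg[.data$subclass %in% set$den]),
    .groups = "drop"
  )
  bad <- per_sample$den <= 0
  if (any(bad)) {
    rlang::warn(paste0(
      sum(bad), " samples with zero ", paste(set$den, collapse = "+"),
      " total excluded from ratio ", name
    ))
    per_sample <- per_sample[!bad, ]
  }
  if (nrow(per_sample) == 0) {
    rlang::abort(paste0("ratio ", name, " undefined in every sample"),
      class = "avl_undefined_ratio"
    )
  }
  per_sample$ratio <- per_sample$num / per_sample$den
  out <- list(name = name, samples = tibble::as_tibble(per_sample))
  if ("stage" %in% names(per_sample)) {
    s <- dplyr::summarise(
      dplyr::group_by(per_sample, .data$stage),
      mean = mean(.data$ratio), sd = stats::sd(.data$ratio),
      n = dplyr::n(), .groups = "drop"
    )
    ref <- s$mean[s$stage == "mildly_diseased"]
    s$fold_change <- if (length(ref) == 1) s$mean / ref else NA_real_
    out$stage_summary <- s
  }
  structure(out, class = "av_ratio_metric")
}

#' @export
print.av_ratio_metric <- function(x, ...) {
  cat("Class ratio ", x$name, " over ", nrow(x$samples), " samples\n", sep = "")
  if (!is.null(x$stage_summary)) print(x$stage_summary)
  invisible(x)
}

#' @export
tidy.av_ratio_metric <- function(x, ...) x$samples

#' @export
glance.av_ratio_metric <- function(x, ...) {
  if (is.null(x$stage_summary)) {
    return(tibble::tibble(name = x$name, n = nrow(x$samples)))
  }
  s <- x$stage_summary
  pick <- function(st) {
    v <- s$fold_change[s$stage == st]
    if (length(v) == 1) v else NA_real_
  }
  tibble::tibble(
    name = x$name,
    fold_fibrotic = pick("fibrotic"),
    fold_calcific = pick("calcific"),
    n = nrow(x$samples)
  )
}

#' Fold changes of group means versus the mildly diseased stage
#'
#' Ratios of arithmetic group means of concentrations, per lipid, per
#' class, or for the grand total, optionally stratified (e.g. by sex).
#'
#' @param concentrations long concentration tibble.
#' @param by `"lipid"`, `"subclass"`, `"category"` or `"total"`.
#' @param stratify_by optional metadata columns defining strata within
#'   which fold changes are computed.
#' @return Tibble with the unit column, strata, `stage`, `mean_pmol_mg`
#'   and `fold_change` (reference stage = 1).
#' @export
stage_fold_changes <- function(concentrations,
                               by = c("subclass", "lipid", "category", "total"),
                               stratify_by = NULL) {
  by <- match.arg(by)
  x <- concentrations
  unit <- switch(by,
    lipid = "lipid",
    subclass = "subclass",
    category = {
      x$category <- lipid_category(x$subclass)
      "category"
    },
    total = {
      x$total <- "total"
      "total"
    }
  )
  if (!"stage" %in% names(x)) {
    rlang::abort("concentrations carry no stage labels",
      class = "avl_schema_error"
    )
  }
  if (by %in% c("subclass", "category", "total")) {
    # total class load per sample, then group means across samples
    keep <- c(unit, setdiff(conc_meta_cols(x), "tissue_mass_mg"))
    per_sample <- dplyr::summarise(
      dplyr::group_by(x, dplyr::across(dplyr::all_of(keep))),
      value = sum(.data$conc_pmol_mg, na.rm = TRUE), .groups = "drop"
    )
  } else {
    per_sample <- dplyr::rename(x, value = "conc_pmol_mg")
  }
  means <- dplyr::summarise(
    dplyr::group_by(
      per_sample,
      dplyr::across(dplyr::all_of(c(unit, stratify_by, "stage")))
    ),
    mean_pmol_mg = mean(.data$value, na.rm = TRUE), .groups = "drop"
  )
  means <- dplyr::group_by(
    means, dplyr::across(dplyr::all_of(c(unit, stratify_by)))
  )
  means <- dplyr::mutate(
    means,
    fold_change = .data$mean_pmol_mg /
      .data$mean_pmol_mg[.data$stage == "mildly_diseased"][1]
  )
  dplyr::ungroup(means)
}

#' Welch's unequal-variance t test
#'
#' @param x,y numeric vectors (at least two values each).
#' @return Tibble with `statistic`, `df`, `p_value` (two-sided).
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
welch_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("need >= 2 observations per group",
      class = "avl_insufficient_data"
    )
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble::tibble(
      statistic = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
      df = NA_real_,
      p_value = if (same) 1 else 0
    ))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Classical one-way ANOVA
#'
#' Unpaired equal-variance F test across groups (disease stages).
#'
#' @param values numeric vector.
#' @param groups group labels, same length as `values`.
#' @return Tibble with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
one_way_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  counts <- table(groups)
  if (length(counts) < 2 || any(counts < 2)) {
    rlang::abort("need >= 2 groups with >= 2 observations each",
      class = "avl_insufficient_data"
    )
  }
  if (stats::sd(values) == 0) {
    return(tibble::tibble(
      statistic = 0, df1 = length(counts) - 1,
      df2 = length(values) - length(counts), p_value = 1
    ))
  }
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df1 = unname(ht$parameter[1]),
    df2 = unname(ht$parameter[2]),
    p_value = ht$p.value
  )
}

#' Per-lipid one-way ANOVA across stages
#'
#' @param concentrations long concentration tibble.
#' @param group metadata column defining groups (default `"stage"`).
#' @return Tibble `lipid`, `subclass`, `statistic`, `p_value`; lipids
#'   with insufficient data carry NA.
#' @export
anova_by_lipid <- function(concentrations, group = "stage") {
  stopifnot(group %in% names(concentrations))
  dplyr::summarise(
    dplyr::group_by(concentrations, .data$lipid, .data$subclass),
    res = list(tryCatch(
      one_way_anova(.data$conc_pmol_mg, .data[[group]]),
      avl_insufficient_data = function(e) {
        tibble::tibble(
          statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
          p_value = NA_real_
        )
      }
    )),
    .groups = "drop"
  ) |>
    tidyr::unnest("res") |>
    dplyr::select("lipid", "subclass", "statistic", "p_value")
}

#' Volcano-plot table for a two-group comparison
#'
#' Per lipid: fold change of group means, Welch t p-value and the
#' significance call requiring both fold change beyond the threshold (in
#' either direction) and p below the cutoff. Lipids missing in more than
#' half of either group's samples are excluded.
#'
#' @param concentrations long concentration tibble.
#' @param compare metadata column to compare (`"stage"`, `"sex"`,
#'   `"morphology"`).
#' @param groups length-2 character vector: numerator and denominator
#'   group labels.
#' @param within optional named list filtering samples first, e.g.
#'   `list(stage = "calcific")` for a sex comparison within a stage.
#' @param fc_threshold fold-change gate (default 1.5).
#' @param p_threshold p-value gate (default 0.05).
#' @param p_adjust multiple-testing adjustment passed to
#'   [stats::p.adjust()] (`"none"` by default, matching raw-p reporting;
#'   `"BH"` for Benjamini-Hochberg).
#' @return Tibble: `lipid`, `subclass`, group means, `fold_change`,
#'   `log2_fc`, `p_value`, `neg_log10_p`, `significant`, `direction`.
#' @export
volcano_prep <- function(concentrations, compare, groups, within = NULL,
                         fc_threshold = 1.5, p_threshold = 0.05,
                         p_adjust = "none") {
  stopifnot(compare %in% names(concentrations), length(groups) == 2)
  x <- concentrations
  for (nm in names(within)) {
    x <- x[x[[nm]] %in% within[[nm]], ]
  }
  x <- x[x[[compare]] %in% groups, ]
  if (nrow(x) == 0) {
    rlang::abort("no samples left after filtering", class = "avl_schema_error")
  }
  n_group <- vapply(
    groups,
    function(g) length(unique(x$sample_id[x[[compare]] == g])),
    integer(1)
  )
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$lipid, .data$subclass),
    n_a = sum(!is.na(.data$conc_pmol_mg[.data[[compare]] == groups[1]])),
    n_b = sum(!is.na(.data$conc_pmol_mg[.data[[compare]] == groups[2]])),
    mean_a = mean(.data$conc_pmol_mg[.data[[compare]] == groups[1]], na.rm = TRUE),
    mean_b = mean(.data$conc_pmol_mg[.data[[compare]] == groups[2]], na.rm = TRUE),
    p_value = tryCatch(
      welch_t(
        .data$conc_pmol_mg[.data[[compare]] == groups[1]],
        .data$conc_pmol_mg[.data[[compare]] == groups[2]]
      )$p_value,
      avl_insufficient_data = function(e) NA_real_
    ),
    .groups = "drop"
  )
  out <- out[out$n_a >= n_group[1] / 2 & out$n_b >= n_group[2] / 2, ]
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$fold_change <- out$mean_a / out$mean_b
  out$log2_fc <- log2(out$fold_change)
  out$neg_log10_p <- -log10(out$p_value)
  out$significant <- !is.na(out$p_value) & out$p_value < p_threshold &
    (out$fold_change > fc_threshold | out$fold_change < 1 / fc_threshold)
  out$direction <- dplyr::case_when(
    out$significant & out$fold_change > 1 ~ paste0("up_in_", groups[1]),
    out$significant ~ paste0("up_in_", groups[2]),
    TRUE ~ "ns"
  )
  dplyr::select(out, -"n_a", -"n_b")
}

#' Row-scaled matrix for heatmap display
#'
#' Missing cells are imputed by the one-fifth-minimum rule, values are
#' log-transformed with a small additive guard (the smallest positive
#' value times 1e-3) so zeros stay finite, then each lipid row is
#' mean-centered and divided by its standard deviation. Zero-variance
#' rows are dropped with a warning.
#'
#' @param concentrations long concentration tibble.
#' @param lipids optional subset of lipids (e.g. the ANOVA-significant
#'   set); defaults to all.
#' @return Numeric matrix, lipids x samples, each row mean 0 / sd 1.
#' @export
heatmap_prep <- function(concentrations, lipids = NULL) {
  x <- concentrations
  if (!is.null(lipids)) x <- x[x$lipid %in% lipids, ]
  if (nrow(x) == 0) {
    rlang::abort("empty lipid subset", class = "avl_schema_error")
  }
  x <- impute_min_fifth(x)
  wide <- tidyr::pivot_wider(
    x[, c("lipid", "sample_id", "conc_pmol_mg")],
    names_from = "sample_id", values_from = "conc_pmol_mg"
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$lipid
  guard <- min(m[m > 0], na.rm = TRUE) * 1e-3
  m <- log(m + guard)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    rlang::warn(paste0(
      sum(sds == 0), " constant lipid rows dropped from heatmap matrix"
    ))
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (m - rowMeans(m)) / sds
}

#' Class-distribution plot data
#'
#' Species means over a sample group, sorted within each subclass, plus
#' the subclass sum -- the data behind a banded log-scale distribution
#' plot of the lipidome.
#'
#' @param concentrations long concentration tibble.
#' @param within optional named list of metadata filters, e.g.
#'   `list(stage = "mildly_diseased")`.
#' @return Tibble: `subclass`, `lipid`, `mean_pmol_mg`, `rank` (1 = most
#'   abundant within its subclass), `class_total_pmol_mg`,
#'   `log10_mean`, `log10_class_total`.
#' @export
distribution_plot_data <- function(concentrations, within = NULL) {
  x <- concentrations
  for (nm in names(within)) {
    x <- x[x[[nm]] %in% within[[nm]], ]
  }
  means <- dplyr::summarise(
    dplyr::group_by(x, .data$subclass, .data$lipid),
    mean_pmol_mg = mean(.data$conc_pmol_mg, na.rm = TRUE),
    .groups = "drop_last"
  )
  means <- dplyr::arrange(
    means, .data$subclass, dplyr::desc(.data$mean_pmol_mg)
  )
  means <- dplyr::mutate(
    means,
    rank = dplyr::row_number(),
    class_total_pmol_mg = sum(.data$mean_pmol_mg, na.rm = TRUE)
  )
  means <- dplyr::ungroup(means)
  means$log10_mean <- log10(means$mean_pmol_mg)
  means$log10_class_total <- log10(means$class_total_pmol_mg)
  means
}
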