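# From internal-standard-spiked peak areas to pmol per mg wet tissue:
# channel summation -> type II isotopic correction -> class-matched
# single-point calibration with type I correction and deuterium-purity
# handling -> tissue-weight normalization, plus the calibration-linearity,
# per-lipid regression screening and recovery diagnostics.

#' Sum adduct and in-source-fragment channels per analyte
#'
#' Collapses a long peak table to one summed area per (sample, analyte).
#' Channels not listed for the analyte's subclass are ignored with a
#' warning; analytes whose subclass has an empty channel list are flagged.
#'
#' @param peaks tibble with columns `sample_id`, `analyte`, `channel`,
#'   `area` (and optionally `subclass`; parsed from `analyte` otherwise,
#'   with internal standards resolved through `istd`).
#' @param channel_map tibble `subclass`, `channel` (see [av_channel_map()];
#'   a `fraction` column, if present, is ignored here).
#' @param istd optional internal-standard panel used to resolve the
#'   subclass of standard analytes.
#' @return Tibble `sample_id`, `analyte`, `subclass`, `area` with one row
#'   per (sample, analyte).
#' @export
sum_channels <- function(peaks, channel_map = av_channel_map(), istd = NULL) {
  stopifnot(all(c("sample_id", "analyte", "channel", "area") %in% names(peaks)))
  if (any(peaks$area < 0, na.rm = TRUE)) {
    rlang::abort("peak areas must be non-negative", class = "avl_schema_error")
  }
  if (!"subclass" %in% names(peaks)) {
    peaks$subclass <- resolve_analyte_subclass(peaks$analyte, istd)
  }
  known <- unique(channel_map$subclass)
  no_map <- setdiff(unique(peaks$subclass), known)
  if (length(no_map) > 0) {
    rlang::abort(
      paste0("empty channel list for subclass: ", paste(no_map, collapse = ", ")),
      class = "avl_channel_error"
    )
  }
  keep <- paste(peaks$subclass, peaks$channel) %in%
    paste(channel_map$subclass, channel_map$channel)
  if (any(!keep)) {
    rlang::warn(paste0(
      sum(!keep), " peak rows on unmapped channels ignored (",
      paste(utils::head(unique(peaks$channel[!keep]), 3), collapse = ", "), ")"
    ))
  }
  out <- dplyr::summarise(
    dplyr::group_by(
      peaks[keep, ], .data$sample_id, .data$analyte, .data$subclass
    ),
    area = sum(.data$area), .groups = "drop"
  )
  out
}

resolve_analyte_subclass <- function(analyte, istd = NULL) {
  out <- rep(NA_character_, length(analyte))
  if (!is.null(istd)) {
    hit <- match(analyte, istd$standard_name)
    out[!is.na(hit)] <- istd$serves_subclass[hit[!is.na(hit)]]
  }
  todo <- is.na(out)
  if (any(todo)) {
    out[todo] <- parse_lipid_names(unique(analyte[todo]))$subclass[
      match(analyte[todo], unique(analyte[todo]))
    ]
  }
  out
}

#' Type II isotopic correction of summed peak areas
#'
#' Within each subclass and sample, subtracts from each species' area the
#' M+2 isotopologue contribution of the species with the same carbon
#' number and one more double bond, cascading from the most unsaturated
#' species downwards and clipping at zero. Species without a (C, d+1)
#' partner are untouched, so the correction is idempotent there.
#'
#' @param summed output of [sum_channels()] for endogenous analytes
#'   (standards are matched by name and passed through).
#' @param istd internal-standard panel whose names are passed through.
#' @return `summed` with corrected `area`.
#' @export
type2_correct <- function(summed, istd = NULL) {
  is_std <- if (is.null(istd)) {
    rep(FALSE, nrow(summed))
  } else {
    summed$analyte %in% istd$standard_name
  }
  endo <- summed[!is_std, ]
  if (nrow(endo) == 0) {
    return(summed)
  }
  parsed <- lipid_formulas(unique(endo$analyte))
  info <- tibble::tibble(
    analyte = unique(endo$analyte),
    series = homologous_series_key(parsed),
    double_bonds = parsed$total_double_bonds,
    m2 = vapply(parsed$formula, m2_m0_ratio, numeric(1))
  )
  endo <- dplyr::left_join(endo, info, by = "analyte")
  endo <- dplyr::arrange(
    endo, .data$sample_id, .data$series, dplyr::desc(.data$double_bonds)
  )
  groups <- paste(endo$sample_id, endo$series)
  area <- endo$area
  for (idx in split(seq_len(nrow(endo)), groups)) {
    if (length(idx) < 2) next
    for (k in seq_along(idx)[-1]) {
      i <- idx[k]
      j <- idx[k - 1]
      if (endo$double_bonds[j] == endo$double_bonds[i] + 1L) {
        area[i] <- max(0, area[i] - area[j] * endo$m2[j])
      }
    }
  }
  endo$area <- area
  dplyr::bind_rows(
    endo[, c("sample_id", "analyte", "subclass", "area")],
    summed[is_std, ]
  )
}

#' Quantify peak areas by class-matched single-point calibration
#'
#' The full inversion of the measurement model: channels are summed,
#' optionally type-II-corrected, the analyte/standard area ratio is
#' type-I-corrected by the ratio of monoisotopic fractions (deuterium
#' purity included on the standard side), scaled by the spiked amount and
#' normalized to wet tissue mass:
#' `conc = area_ratio * M0(istd)/M0(analyte) * spiked_pmol / mass_mg`.
#'
#' @param peaks long peak table (`sample_id`, `analyte`, `channel`, `area`).
#' @param metadata sample metadata tibble with `sample_id`,
#'   `tissue_mass_mg` and any design columns (patient, sex, morphology,
#'   stage) to carry through.
#' @param istd internal-standard panel, see [av_istd_panel()].
#' @param channel_map channel map, see [av_channel_map()].
#' @param type2 apply type II correction (default TRUE).
#' @return Long concentration tibble: metadata columns, `lipid`,
#'   `subclass`, `conc_pmol_mg` (NA where the analyte had zero signal).
#' @export
quantify_areas <- function(peaks, metadata, istd = av_istd_panel(),
                           channel_map = av_channel_map(), type2 = TRUE) {
  stopifnot(all(c("sample_id", "tissue_mass_mg") %in% names(metadata)))
  if (any(metadata$tissue_mass_mg <= 0)) {
    rlang::abort("tissue masses must be positive", class = "avl_schema_error")
  }
  summed <- sum_channels(peaks, channel_map, istd = istd)
  if (type2) summed <- type2_correct(summed, istd = istd)

  is_std <- summed$analyte %in% istd$standard_name
  std <- summed[is_std, ]
  endo <- summed[!is_std, ]

  uncovered <- setdiff(unique(endo$subclass), istd$serves_subclass)
  if (length(uncovered) > 0) {
    rlang::abort(
      paste0(
        "no internal standard for subclass: ",
        paste(uncovered, collapse = ", ")
      ),
      class = "avl_missing_istd"
    )
  }
  if (any(std$area <= 0)) {
    bad <- std[std$area <= 0, ]
    rlang::abort(
      paste0(
        "zero internal-standard area for ",
        paste(utils::head(paste(bad$analyte, bad$sample_id), 3), collapse = "; ")
      ),
      class = "avl_zero_istd_area"
    )
  }

  parsed <- lipid_formulas(unique(endo$analyte))
  analyte_m0 <- stats::setNames(
    monoisotopic_fraction(parsed$formula), unique(endo$analyte)
  )
  istd_m0 <- stats::setNames(
    vapply(seq_len(nrow(istd)), function(i) {
      monoisotopic_fraction(istd$formula[[i]], purity = istd$purity[i])
    }, numeric(1)),
    istd$serves_subclass
  )

  std$istd_area <- std$area
  endo <- dplyr::left_join(
    endo,
    dplyr::left_join(
      istd[, c("standard_name", "serves_subclass", "spiked_pmol")],
      std[, c("sample_id", "analyte", "istd_area")],
      by = c("standard_name" = "analyte")
    ),
    by = c("subclass" = "serves_subclass", "sample_id" = "sample_id")
  )
  if (anyNA(endo$istd_area)) {
    rlang::abort("internal-standard signal missing for some samples",
      class = "avl_missing_istd"
    )
  }
  endo$conc_pmol_mg <- endo$area / endo$istd_area *
    unname(istd_m0[endo$subclass]) / unname(analyte_m0[endo$analyte]) *
    endo$spiked_pmol
  endo <- dplyr::left_join(endo, metadata, by = "sample_id")
  endo$conc_pmol_mg <- endo$conc_pmol_mg / endo$tissue_mass_mg
  endo$conc_pmol_mg[endo$area == 0] <- NA_real_

  out <- dplyr::rename(endo, lipid = "analyte")
  keep <- c(
    "lipid", "subclass",
    intersect(
      c(
        "sample_id", "patient", "sex", "morphology", "stage",
        "tissue_mass_mg"
      ),
      names(out)
    ),
    "conc_pmol_mg"
  )
  dplyr::arrange(
    tibble::as_tibble(out[, keep]), .data$lipid, .data$sample_id
  )
}

#' Fit a calibration curve and assess its linear range
#'
#' Ordinary least squares of corrected area on spiked amount. The linear
#' range is the widest contiguous window of calibration levels for which
#' a line refitted within the window leaves every level's mean area
#' within `rel_tol` relative deviation of its prediction; ties prefer the
#' window starting at the lower amount.
#'
#' @param points tibble with columns `amount` and `area` (replicates as
#'   repeated amounts).
#' @param rel_tol maximal tolerated relative deviation of a calibration
#'   level from the fitted line (default 0.2).
#' @return An object of class `av_calibration`: list with `slope`,
#'   `intercept`, `r_squared` (full-data fit), `linear_range`,
#'   `n_points`, `points`.
#' @export
fit_calibration <- function(points, rel_tol = 0.2) {
  stopifnot(all(c("amount", "area") %in% names(points)))
  pts <- points[stats::complete.cases(points[, c("amount", "area")]), ]
  if (length(unique(pts$amount)) < 3) {
    rlang::abort("need >= 3 distinct calibration amounts",
      class = "avl_insufficient_data"
    )
  }
  if (stats::sd(pts$amount) == 0 || stats::sd(pts$area) == 0) {
    rlang::abort("degenerate calibration design",
      class = "avl_degenerate_design"
    )
  }
  coefs <- stats::coef(stats::lm(area ~ amount, data = pts))
  resid <- pts$area - (coefs[1] + coefs[2] * pts$amount)
  r2 <- 1 - sum(resid^2) / sum((pts$area - mean(pts$area))^2)

  levels_all <- sort(unique(pts$amount))
  k <- length(levels_all)
  best <- c(1L, 3L)
  best_width <- 0L
  for (i in seq_len(k - 2)) {
    for (j in seq(i + 2, k)) {
      lv <- levels_all[i:j]
      cur <- pts[pts$amount %in% lv, ]
      cf <- stats::coef(stats::lm(area ~ amount, data = cur))
      obs <- vapply(lv, function(a) mean(cur$area[cur$amount == a]), numeric(1))
      pred <- cf[1] + cf[2] * lv
      rel <- abs(obs - pred) / pmax(abs(pred), .Machine$double.eps)
      if (all(rel <= rel_tol) && (j - i) > best_width) {
        best <- c(i, j)
        best_width <- j - i
      }
    }
  }
  structure(
    list(
      slope = unname(coefs[2]),
      intercept = unname(coefs[1]),
      r_squared = r2,
      linear_range = c(levels_all[best[1]], levels_all[best[2]]),
      n_points = nrow(pts),
      points = tibble::as_tibble(pts)
    ),
    class = "av_calibration"
  )
}

#' @export
print.av_calibration <- function(x, ...) {
  cat(
    "Calibration: area = ", signif(x$slope, 4), " * amount + ",
    signif(x$intercept, 4), "  (R² = ", signif(x$r_squared, 4), ")\n",
    "Linear range: ", x$linear_range[1], " to ", x$linear_range[2],
    " over ", x$n_points, " points\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.av_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.av_calibration <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    linear_min = x$linear_range[1],
    linear_max = x$linear_range[2],
    n_points = x$n_points
  )
}

#' Screen quantified lipids for non-linear response and outlier samples
#'
#' Regresses each lipid's calculated concentration on its summed area
#' across samples. Lipids with R-squared below `r2_min` are flagged as
#' non-linear; samples with externally studentized residuals beyond
#' `resid_max` in absolute value are flagged as outliers. Flags only;
#' removal is the caller's decision.
#'
#' @param concentrations long concentration tibble.
#' @param summed summed peak areas (see [sum_channels()]).
#' @param r2_min minimum per-lipid R-squared (default 0.8).
#' @param resid_max studentized-residual cutoff (default 3).
#' @param min_samples lipids observed in fewer samples are skipped with a
#'   warning (default 5).
#' @return Tibble `lipid`, `sample_id` (NA for lipid-level flags),
#'   `flag` (`nonlinear` or `outlier_sample`), `r_squared`, `residual`.
#' @export
linearity_screen <- function(concentrations, summed, r2_min = 0.8,
                             resid_max = 3, min_samples = 5) {
  joined <- dplyr::inner_join(
    concentrations[
      !is.na(concentrations$conc_pmol_mg),
      c("lipid", "sample_id", "conc_pmol_mg")
    ],
    dplyr::rename(summed, lipid = "analyte")[, c("lipid", "sample_id", "area")],
    by = c("lipid", "sample_id")
  )
  # externally studentized residuals, zeroed when the fit is numerically
  # exact (no meaningful residual scale) or at leverage-one points (those
  # surface as y-outliers in the reverse regression instead)
  stud <- function(y, x) {
    fit <- stats::lm(y ~ x)
    if (sum(stats::residuals(fit)^2) <=
      (1e-10 * max(stats::sd(y), .Machine$double.eps))^2 * length(y)) {
      return(numeric(length(y)))
    }
    rs <- stats::rstudent(fit)
    # rstudent is NaN when deleting the point leaves an (almost) exact
    # fit; studentize against the deleted fit directly in that case
    for (i in which(!is.finite(rs))) {
      cf <- stats::coef(stats::lm(y[-i] ~ x[-i]))
      dev <- y[i] - (cf[1] + cf[2] * x[i])
      s <- stats::sd(y[-i] - (cf[1] + cf[2] * x[-i]))
      rs[i] <- if (abs(dev) <= 1e-8 * max(abs(y))) {
        0
      } else if (s <= 1e-10 * max(abs(y))) {
        sign(dev) * Inf
      } else {
        dev / s
      }
    }
    rs
  }
  out <- list()
  skipped <- 0
  for (lp in unique(joined$lipid)) {
    d <- joined[joined$lipid == lp, ]
    if (nrow(d) < min_samples) {
      skipped <- skipped + 1
      next
    }
    sst <- sum((d$conc_pmol_mg - mean(d$conc_pmol_mg))^2)
    r2 <- if (sst == 0) {
      1
    } else {
      fit <- stats::lm(conc_pmol_mg ~ area, data = d)
      1 - sum(stats::residuals(fit)^2) / sst
    }
    if (r2 < r2_min) {
      out[[length(out) + 1]] <- tibble::tibble(
        lipid = lp, sample_id = NA_character_, flag = "nonlinear",
        r_squared = r2, residual = NA_real_
      )
    }
    rs_fwd <- stud(d$conc_pmol_mg, d$area)
    rs_rev <- stud(d$area, d$conc_pmol_mg)
    rs <- ifelse(abs(rs_fwd) >= abs(rs_rev), rs_fwd, rs_rev)
    hit <- which(abs(rs) > resid_max)
    if (length(hit) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        lipid = lp, sample_id = d$sample_id[hit], flag = "outlier_sample",
        r_squared = r2, residual = rs[hit]
      )
    }
  }
  if (skipped > 0) {
    rlang::warn(paste0(
      skipped, " lipids skipped in linearity screen (fewer than ",
      min_samples, " samples)"
    ))
  }
  if (length(out) == 0) {
    tibble::tibble(
      lipid = character(), sample_id = character(), flag = character(),
      r_squared = numeric(), residual = numeric()
    )
  } else {
    dplyr::bind_rows(out)
  }
}

#' Extraction recovery rate
#'
#' Ratio of mean signals of samples spiked before versus after extraction,
#' as a percentage.
#'
#' @param before,after numeric vectors of areas for pre- and
#'   post-extraction spiking.
#' @return Percentage (100 = full recovery).
#' @export
#' @examples
#' recovery_rate(c(50, 60, 70), c(100, 120, 140))
recovery_rate <- function(before, after) {
  if (length(before) == 0 || length(after) == 0) {
    rlang::abort("both spike groups must be non-empty",
      class = "avl_insufficient_data"
    )
  }
  m <- mean(after)
  if (m == 0) {
    rlang::abort("post-extraction mean area is zero",
      class = "avl_zero_denominator"
    )
  }
  100 * mean(before) / m
}
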