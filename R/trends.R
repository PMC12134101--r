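# Lipid Trend Analysis: impute missing cells, average each lipid to the
# three disease stages, z-score the stage triplet, and cluster the
# trajectories with a Gaussian mixture model (k = 5 by default). Cluster
# ids are re-labelled in descending size so results are stable to
# component permutation.

#' Impute missing cells with one fifth of the per-lipid minimum
#'
#' Fills every missing (lipid, sample) cell with min(observed)/5 for that
#' lipid; observed values are never changed. Cells can be missing either
#' as NA rows or as absent rows (the grid is completed first). Lipids
#' observed in no sample are dropped with a warning.
#'
#' @param concentrations long concentration tibble.
#' @return The completed tibble with no missing concentrations.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   lipid = "CE 18:2", subclass = "CE",
#'   sample_id = c("a", "b", "c"), conc_pmol_mg = c(10, NA, 20)
#' )
#' impute_min_fifth(x)$conc_pmol_mg
impute_min_fifth <- function(concentrations) {
  x <- concentrations
  meta_cols <- setdiff(names(x), c("lipid", "subclass", "conc_pmol_mg"))
  samples <- dplyr::distinct(x[, c("sample_id", setdiff(meta_cols, "sample_id"))])
  lipids <- dplyr::distinct(x[, c("lipid", "subclass")])
  grid <- tidyr::crossing(lipids, samples["sample_id"])
  full <- dplyr::left_join(
    grid, x[, c("lipid", "sample_id", "conc_pmol_mg")],
    by = c("lipid", "sample_id")
  )
  full <- dplyr::left_join(full, samples, by = "sample_id")

  mins <- dplyr::summarise(
    dplyr::group_by(full, .data$lipid),
    lipid_min = suppressWarnings(min(.data$conc_pmol_mg, na.rm = TRUE)),
    .groups = "drop"
  )
  dead <- mins$lipid[!is.finite(mins$lipid_min)]
  if (length(dead) > 0) {
    rlang::warn(paste0(
      length(dead), " lipids observed in no sample dropped before imputation"
    ))
    full <- full[!full$lipid %in% dead, ]
    mins <- mins[!mins$lipid %in% dead, ]
  }
  full <- dplyr::left_join(full, mins, by = "lipid")
  full$conc_pmol_mg <- ifelse(
    is.na(full$conc_pmol_mg), full$lipid_min / 5, full$conc_pmol_mg
  )
  full$lipid_min <- NULL
  tibble::as_tibble(full[, names(x)[names(x) %in% names(full)]])
}

#' Average each lipid to the three disease stages
#'
#' @param concentrations long concentration tibble covering all three
#'   stages (impute first; remaining NAs are ignored in the means).
#' @return Tibble `lipid`, `subclass`, `stage`, `mean_pmol_mg`.
#' @export
stage_average <- function(concentrations) {
  stages <- unique(concentrations$stage)
  missing_stage <- setdiff(
    c("mildly_diseased", "fibrotic", "calcific"), stages
  )
  if (length(missing_stage) > 0) {
    rlang::abort(
      paste0("stage(s) absent: ", paste(missing_stage, collapse = ", ")),
      class = "avl_missing_stage"
    )
  }
  dplyr::summarise(
    dplyr::group_by(concentrations, .data$lipid, .data$subclass, .data$stage),
    mean_pmol_mg = mean(.data$conc_pmol_mg, na.rm = TRUE),
    .groups = "drop"
  )
}

zscore_rows <- function(m) {
  sds <- apply(m, 1, stats::sd)
  keep <- sds > 0
  m <- m[keep, , drop = FALSE]
  (m - rowMeans(m)) / sds[keep]
}

#' Gaussian-mixture clustering of stage trajectories
#'
#' Z-scores each lipid's three stage means and fits a k-component
#' Gaussian mixture with unconstrained (full) covariance; lipids are
#' hard-assigned by maximum posterior and clusters re-labelled in
#' descending size. A near-singular fit is retried with the default
#' conjugate prior as covariance regularization (reported in the result).
#'
#' @param stage_means output of [stage_average()] (or a numeric matrix of
#'   lipids x stages).
#' @importFrom mclust Mclust mclustBIC priorControl
#' @param k number of mixture components (default 5).
#' @param seed integer seed (the EM initialization is deterministic, but
#'   the seed is fixed for any stochastic fallback path).
#' @return An `av_trend_clusters` object: `membership` (tibble lipid,
#'   subclass, cluster), `trajectories` (cluster x stage mean, sd, n of
#'   member z-scores), `z` (z-score matrix), `k`, `seed`, `regularized`.
#' @export
gmm_trend_cluster <- function(stage_means, k = 5, seed = 42) {
  if (is.data.frame(stage_means)) {
    wide <- tidyr::pivot_wider(
      stage_means[, c("lipid", "stage", "mean_pmol_mg")],
      names_from = "stage", values_from = "mean_pmol_mg"
    )
    m <- as.matrix(wide[, c("mildly_diseased", "fibrotic", "calcific")])
    rownames(m) <- wide$lipid
    subclass_of <- stats::setNames(
      stage_means$subclass[!duplicated(stage_means$lipid)],
      stage_means$lipid[!duplicated(stage_means$lipid)]
    )
  } else {
    m <- as.matrix(stage_means)
    subclass_of <- NULL
  }
  if (anyNA(m)) {
    rlang::abort("stage means contain missing values; impute first",
      class = "avl_schema_error"
    )
  }
  if (nrow(m) < k) {
    rlang::abort(paste0("need at least k = ", k, " lipids"),
      class = "avl_insufficient_data"
    )
  }
  dropped <- nrow(m)
  z <- zscore_rows(m)
  dropped <- dropped - nrow(z)
  if (dropped > 0) {
    rlang::warn(paste0(dropped, " flat (zero-variance) trajectories dropped"))
  }

  # z-scored triplets have mean 0 and sd 1, i.e. two degrees of freedom;
  # fit in an orthonormal basis of the zero-sum plane where the full
  # covariance model is non-degenerate (hard assignments are invariant
  # under this orthogonal change of coordinates)
  basis <- cbind(c(1, -1, 0) / sqrt(2), c(1, 1, -2) / sqrt(6))
  zf <- z %*% basis

  fit <- NULL
  regularized <- FALSE
  withr::with_seed(seed, {
    fit <- suppressWarnings(
      Mclust(zf, G = k, modelNames = "VVV", verbose = FALSE)
    )
    if (is.null(fit)) {
      regularized <- TRUE
      fit <- suppressWarnings(Mclust(
        zf,
        G = k, modelNames = "VVV", verbose = FALSE,
        prior = priorControl()
      ))
    }
  })
  if (is.null(fit)) {
    rlang::abort("Gaussian mixture fit failed even with regularization",
      class = "avl_singular_fit"
    )
  }
  raw <- fit$classification
  sizes <- table(raw)
  relabel <- stats::setNames(
    seq_along(sizes),
    names(sort(sizes, decreasing = TRUE))
  )
  cluster <- unname(relabel[as.character(raw)])

  membership <- tibble::tibble(
    lipid = rownames(z),
    subclass = if (is.null(subclass_of)) {
      NA_character_
    } else {
      unname(subclass_of[rownames(z)])
    },
    cluster = cluster
  )
  traj <- trend_trajectories(z, cluster)
  structure(
    list(
      membership = membership, trajectories = traj, z = z,
      k = k, seed = seed, regularized = regularized,
      loglik = fit$loglik, bic = fit$bic
    ),
    class = "av_trend_clusters"
  )
}

trend_trajectories <- function(z, cluster) {
  stages <- colnames(z)
  dplyr::bind_rows(lapply(sort(unique(cluster)), function(cl) {
    zc <- z[cluster == cl, , drop = FALSE]
    tibble::tibble(
      cluster = cl,
      stage = stages,
      mean = colMeans(zc),
      sd = apply(zc, 2, function(v) if (length(v) > 1) stats::sd(v) else 0),
      n = nrow(zc)
    )
  }))
}

#' Plot-ready per-cluster trajectory summary
#'
#' @param tc an `av_trend_clusters` object.
#' @return Tibble `cluster`, `stage`, `mean`, `sd`, `n` of member
#'   z-scores, with stage an ordered factor.
#' @export
trend_summary <- function(tc) {
  stopifnot(inherits(tc, "av_trend_clusters"))
  out <- tc$trajectories
  out$stage <- factor(
    out$stage,
    levels = c("mildly_diseased", "fibrotic", "calcific"), ordered = TRUE
  )
  out
}

#' @export
print.av_trend_clusters <- function(x, ...) {
  sizes <- table(x$membership$cluster)
  cat(
    "Gaussian-mixture trend clustering: k = ", x$k, ", ",
    nrow(x$membership), " lipids\n",
    "Cluster sizes: ", paste(sizes, collapse = " / "),
    if (x$regularized) "\n(covariance prior regularization applied)" else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.av_trend_clusters <- function(x, ...) x$membership

#' @export
glance.av_trend_clusters <- function(x, ...) {
  sizes <- table(x$membership$cluster)
  tibble::tibble(
    k = x$k, n_lipids = nrow(x$membership),
    largest = max(sizes), smallest = min(sizes),
    loglik = x$loglik, bic = x$bic, regularized = x$regularized
  )
}

#' @export
autoplot.av_trend_clusters <- function(object, ...) {
  traj <- trend_summary(object)
  sizes <- table(object$membership$cluster)
  traj$panel <- factor(
    paste0("cluster ", traj$cluster, " (n = ", sizes[as.character(traj$cluster)], ")")
  )
  ggplot2::ggplot(traj, ggplot2::aes(
    x = .data$stage, y = .data$mean, group = 1
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      fill = "grey80"
    ) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = NULL, y = "z-scored concentration") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
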