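# Structure-aware lipidome topology. Each lipid subclass is represented by
# a class backbone (acyl chains stripped to acetyl stubs, sphingoid base
# truncated, sugar units schematic) given as SMILES. Pairwise backbone
# distances are maximum-common-edge-subgraph (MCES) distances:
#   d(G1, G2) = |E1| + |E2| - 2 * mces(G1, G2),
# computed by an exact branch-and-bound over label-compatible vertex
# mappings. The 24 x 24 matrix is reduced by PCA; its top components join
# z-scored abundances and chain features (min-max scaled, per-block
# weights) in the feature matrix embedded by UMAP.

#' Convert a SMILES string into a labelled molecular graph
#'
#' Heavy-atom graph with element labels and integer bond orders, parsed
#' through ChemmineR/OpenBabel.
#'
#' @param smiles a single SMILES string.
#' @return A list with `elements` (character), `edges` (matrix with
#'   columns i, j, order) and `adj` (bond-order adjacency matrix).
#' @export
smiles_to_graph <- function(smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) {
      rlang::abort(
        paste0("cannot parse structure '", smiles, "': ", conditionMessage(e)),
        class = "avl_unparsable_structure"
      )
    }
  )
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- gsub("_\\d+$", "", rownames(ab))
  n <- length(elements)
  if (n == 0) {
    rlang::abort(paste0("empty structure: '", smiles, "'"),
      class = "avl_unparsable_structure"
    )
  }
  if (is.null(dim(bb)) || ncol(bb) < 3) {
    if (n > 1) {
      rlang::abort(
        paste0("no bond block for multi-atom structure '", smiles, "'"),
        class = "avl_unparsable_structure"
      )
    }
    bb <- matrix(0L, 0, 3)
  }
  edges <- cbind(
    i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
    order = as.integer(bb[, 3])
  )
  if (any(is.na(edges)) || any(edges[, 1:2] < 1) || any(edges[, 1:2] > n)) {
    rlang::abort(paste0("malformed bond block for '", smiles, "'"),
      class = "avl_unparsable_structure"
    )
  }
  adj <- matrix(0L, n, n)
  for (r in seq_len(nrow(edges))) {
    adj[edges[r, 1], edges[r, 2]] <- edges[r, 3]
    adj[edges[r, 2], edges[r, 1]] <- edges[r, 3]
  }
  list(elements = elements, edges = edges, adj = adj)
}

# Exact maximum common edge subgraph size: branch and bound over
# label-compatible injective vertex mappings (compiled search, see
# src/mces.cpp). min_size primes the incumbent for thresholded search.
mces_size <- function(g1, g2, min_size = 0L) {
  if (length(g1$elements) > length(g2$elements)) {
    tmp <- g1
    g1 <- g2
    g2 <- tmp
  }
  codes <- unique(c(g1$elements, g2$elements))
  e1 <- match(g1$elements, codes)
  e2 <- match(g2$elements, codes)
  fix_edges <- function(e) {
    if (nrow(e) == 0) {
      matrix(0L, 0, 3)
    } else {
      matrix(as.integer(e), ncol = 3)
    }
  }
  mces_size_cpp(
    e1, fix_edges(g1$edges), e2, fix_edges(g2$edges),
    as.integer(max(0L, min_size))
  )
}

#' Myopic MCES distance between two structures
#'
#' Edge-count distance `|E1| + |E2| - 2 * |MCES|` where MCES is the
#' maximum common edge subgraph (element- and bond-order-labelled, not
#' necessarily connected), found by exact branch and bound. With a finite
#' `threshold` the distance is "myopic": computed exactly below the
#' threshold and reported as the threshold beyond it, which keeps
#' dissimilar-pair searches tractable while preserving the informative
#' near-field structure.
#'
#' @param a,b SMILES strings or graphs from [smiles_to_graph()].
#' @param threshold distance cap; `Inf` (default) for a fully exact
#'   distance.
#' @return Non-negative integer distance (0 for identical graphs),
#'   capped at `threshold`.
#' @export
#' @examples
#' mces_distance("CCCO", "CCC")
mces_distance <- function(a, b, threshold = Inf) {
  g1 <- if (is.character(a)) smiles_to_graph(a) else a
  g2 <- if (is.character(b)) smiles_to_graph(b) else b
  e_sum <- nrow(g1$edges) + nrow(g2$edges)
  min_size <- if (is.finite(threshold)) {
    floor((e_sum - threshold) / 2) + 1
  } else {
    0L
  }
  m <- mces_size(g1, g2, min_size = min_size)
  if (is.finite(threshold) && m < min_size) {
    as.numeric(threshold)
  } else {
    e_sum - 2 * m
  }
}

#' Backbone structure table
#'
#' The bundled table of class-backbone SMILES (one per structural
#' backbone; ceramide variants share the Cer backbone). Acyl chains are
#' truncated to acetyl stubs so that chain identity never contributes,
#' while slot counts and head groups do.
#'
#' @param path optional TSV with columns `backbone`, `smiles`.
#' @return Tibble `backbone`, `smiles`.
#' @export
av_backbones <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "backbone_smiles.tsv", package = "avlipidomics")
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Pairwise backbone MCES distance matrix
#'
#' Either computes the matrix exactly from backbone structures (minutes
#' of CPU for the full 24-backbone panel) or loads a precomputed square
#' TSV. The bundled matrix was computed with [mces_distance()] on the
#' bundled backbone table.
#'
#' @param backbones backbone table, see [av_backbones()]; ignored when
#'   `precomputed` is given.
#' @param precomputed path to a square TSV with header ids, or `NULL`
#'   (default: the bundled matrix). Use `compute = TRUE` to force
#'   computation.
#' @param compute recompute from structures instead of loading.
#' @param threshold myopic distance cap used when computing (the bundled
#'   matrix was computed with the default cap of 15).
#' @return Symmetric numeric matrix with zero diagonal and a
#'   `provenance` attribute (`"computed"` or `"loaded"`).
#' @export
backbone_distances <- function(backbones = av_backbones(),
                               precomputed = NULL, compute = FALSE,
                               threshold = 15) {
  if (!compute) {
    path <- precomputed %||% system.file(
      "extdata", "backbone_mces_distances.tsv",
      package = "avlipidomics"
    )
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab[[1]]
    provenance <- "loaded"
  } else {
    graphs <- lapply(backbones$smiles, smiles_to_graph)
    n <- length(graphs)
    m <- matrix(0, n, n, dimnames = list(backbones$backbone, backbones$backbone))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- mces_distance(
          graphs[[i]], graphs[[j]],
          threshold = threshold
        )
      }
    }
    provenance <- "computed"
  }
  validate_distance_matrix(m)
  attr(m, "provenance") <- provenance
  m
}

validate_distance_matrix <- function(m) {
  stopifnot(nrow(m) == ncol(m))
  if (!isTRUE(all.equal(unname(m), unname(t(m))))) {
    rlang::abort("distance matrix must be symmetric", class = "avl_schema_error")
  }
  if (any(diag(m) != 0) || any(m < 0)) {
    rlang::abort("distance matrix needs zero diagonal and no negatives",
      class = "avl_schema_error"
    )
  }
  invisible(m)
}

#' PCA reduction of the backbone distance matrix
#'
#' Column-centered principal components of the distance matrix rows (each
#' backbone's distance profile is its feature vector); the top `keep`
#' component scores feed the topology feature matrix.
#'
#' @param d square distance matrix from [backbone_distances()].
#' @param n_components components computed (capped by the matrix rank).
#' @param keep components returned.
#' @return Matrix of backbone x `keep` component scores.
#' @export
pca_top <- function(d, n_components = 10, keep = 5) {
  validate_distance_matrix(d)
  n_components <- min(n_components, nrow(d) - 1, ncol(d))
  keep <- min(keep, n_components)
  p <- stats::prcomp(d, center = TRUE, scale. = FALSE, rank. = n_components)
  scores <- p$x[, seq_len(keep), drop = FALSE]
  rownames(scores) <- rownames(d)
  scores
}

minmax_cols <- function(m) {
  apply(m, 2, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) {
      return(rep(0, length(v)))
    }
    (v - rng[1]) / diff(rng)
  })
}

#' Topology feature matrix for lipidome embedding
#'
#' One row per lipid species: a z-scored abundance block (log10 group
#' means by default), a min-max-scaled chain-feature block (total chain
#' carbons and double bonds) and the min-max-scaled top backbone PCA
#' components mapped through each species' subclass, with per-block
#' weight factors.
#'
#' @param concentrations long concentration tibble (possibly pooling
#'   several tissues as distinct groups).
#' @param group metadata column whose levels become abundance columns
#'   (default `"stage"`).
#' @param backbone_pca backbone PCA scores from [pca_top()]; rownames are
#'   backbone ids matched through the registry.
#' @param weights named per-block weights (`abundance`, `chains`,
#'   `backbone`).
#' @param log10_abundance log10-transform mean concentrations before
#'   z-scoring (recommended for a lipidome spanning 6 orders).
#' @param registry subclass registry.
#' @return Numeric matrix (lipids x features) with attribute `blocks`.
#' @export
topology_features <- function(concentrations, group = "stage",
                              backbone_pca = pca_top(backbone_distances()),
                              weights = c(abundance = 1, chains = 1, backbone = 1),
                              log10_abundance = TRUE,
                              registry = av_class_registry()) {
  stopifnot(group %in% names(concentrations))
  stopifnot(all(weights > 0))
  means <- dplyr::summarise(
    dplyr::group_by(
      concentrations, .data$lipid, .data$subclass, .data[[group]]
    ),
    mean_conc = mean(.data$conc_pmol_mg, na.rm = TRUE), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    means,
    names_from = dplyr::all_of(group), values_from = "mean_conc"
  )
  ab <- as.matrix(wide[, -(1:2)])
  rownames(ab) <- wide$lipid
  if (anyNA(ab) || any(ab <= 0)) {
    keep <- apply(ab, 1, function(v) all(is.finite(v) & v > 0))
    if (!all(keep)) {
      rlang::warn(paste0(
        sum(!keep), " lipids without complete positive abundances dropped"
      ))
    }
    ab <- ab[keep, , drop = FALSE]
    wide <- wide[keep, ]
  }
  if (log10_abundance) ab <- log10(ab)
  ab_z <- apply(ab, 2, function(v) (v - mean(v)) / stats::sd(v))

  parsed <- parse_lipid_names(wide$lipid, registry)
  chains <- cbind(
    carbons = parsed$total_carbons,
    double_bonds = parsed$total_double_bonds
  )
  chains_mm <- minmax_cols(chains)

  bb_id <- registry$backbone[match(wide$subclass, registry$subclass)]
  missing_bb <- setdiff(unique(bb_id), rownames(backbone_pca))
  if (length(missing_bb) > 0) {
    rlang::abort(
      paste0(
        "no backbone PCA scores for: ", paste(missing_bb, collapse = ", ")
      ),
      class = "avl_missing_feature"
    )
  }
  bb <- backbone_pca[bb_id, , drop = FALSE]
  bb_mm <- minmax_cols(bb)

  out <- cbind(
    weights[["abundance"]] * ab_z,
    weights[["chains"]] * chains_mm,
    weights[["backbone"]] * bb_mm
  )
  rownames(out) <- wide$lipid
  colnames(out) <- c(
    paste0("abund_", colnames(ab)),
    c("chain_carbons", "chain_double_bonds"),
    paste0("backbone_pc", seq_len(ncol(bb)))
  )
  attr(out, "blocks") <- rep(
    c("abundance", "chains", "backbone"),
    c(ncol(ab), ncol(chains_mm), ncol(bb_mm))
  )
  attr(out, "subclass") <- stats::setNames(wide$subclass, wide$lipid)
  out
}

#' UMAP embedding of the lipidome feature matrix
#'
#' Deterministic per seed (single-threaded SGD). Coordinates carry no
#' contract beyond determinism and neighbourhood preservation; co-cluster
#' structure is what downstream interpretation uses.
#'
#' @param features feature matrix from [topology_features()].
#' @param seed integer seed.
#' @param n_neighbors,min_dist UMAP parameters (library defaults of the
#'   field: 15 and 0.1).
#' @return Tibble `lipid`, `umap_1`, `umap_2` (plus `subclass` when the
#'   feature matrix carries it).
#' @export
embed_lipidome <- function(features, seed = 42, n_neighbors = 15,
                           min_dist = 0.1) {
  stopifnot(nrow(features) >= 10)
  n_neighbors <- min(n_neighbors, nrow(features) - 1)
  set.seed(seed)
  coords <- uwot::umap(
    unclass(features[, , drop = FALSE]),
    n_neighbors = n_neighbors, min_dist = min_dist, metric = "euclidean",
    n_threads = 1, n_sgd_threads = 0, verbose = FALSE
  )
  out <- tibble::tibble(
    lipid = rownames(features),
    umap_1 = coords[, 1],
    umap_2 = coords[, 2]
  )
  sc <- attr(features, "subclass")
  if (!is.null(sc)) out$subclass <- unname(sc[out$lipid])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
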