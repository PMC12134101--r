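# Sphingolipid decomposition: each chain-resolved sphingolipid splits
# into its sphingoid base (first chain), subclass, and N-acyl (second
# chain). Aggregated over a sample group this yields the two-sided flow
# table (base -> subclass -> acyl) behind a Sankey diagram.

#' Decompose sphingolipids into base, subclass and N-acyl
#'
#' Applies to chain-resolved (molecular-level) sphingolipid species; the
#' first chain is the sphingoid base, the second the amide-linked fatty
#' acyl. Species-level sphingolipids cannot be decomposed and are
#' excluded with a warning (their count is reported, never silently
#' dropped).
#'
#' @param x character vector of lipid names or a parsed tibble from
#'   [parse_lipid_names()].
#' @return Tibble: `lipid` (the input name), `lipid_normalized`,
#'   `subclass`, `base` (e.g. `"18:1;O2"`),
#'   `acyl` (e.g. `"FA 24:0"`), `acyl_carbons`, `acyl_double_bonds`,
#'   `vlcfa` (very-long-chain acyl, C22-C26). Attribute `n_unresolved`
#'   counts the excluded species-level sphingolipids.
#' @export
#' @examples
#' decompose_sphingolipids("Cer 18:1;O2/24:0")
decompose_sphingolipids <- function(x) {
  parsed <- if (is.data.frame(x)) x else parse_lipid_names(x)
  sp <- parsed[parsed$category == "SP", ]
  unresolved <- sum(sp$level != "molecular")
  if (unresolved > 0) {
    rlang::warn(paste0(
      unresolved, " species-level sphingolipids cannot be decomposed ",
      "into base and acyl and were excluded"
    ))
  }
  sp <- sp[sp$level == "molecular", ]
  out <- dplyr::bind_rows(lapply(seq_len(nrow(sp)), function(i) {
    ch <- sp$chains[[i]]
    tibble::tibble(
      lipid = sp$raw_name[i], # caller's key; canonical form alongside
      lipid_normalized = sp$lipid[i],
      subclass = sp$subclass[i],
      base = format_chain(ch$carbons[1], ch$double_bonds[1], ch$oxygens[1]),
      acyl = paste0(
        "FA ", format_chain(ch$carbons[2], ch$double_bonds[2], ch$oxygens[2])
      ),
      acyl_carbons = ch$carbons[2],
      acyl_double_bonds = ch$double_bonds[2]
    )
  }))
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      lipid = character(), lipid_normalized = character(),
      subclass = character(), base = character(),
      acyl = character(), acyl_carbons = integer(),
      acyl_double_bonds = integer()
    )
  }
  out$vlcfa <- vlcfa_flag(out$acyl_carbons)
  attr(out, "n_unresolved") <- unresolved
  out
}

#' Very-long-chain fatty acyl flag
#'
#' TRUE for N-acyl chains of 22 to 26 carbons (inclusive).
#'
#' @param acyl_carbons integer vector of acyl carbon counts.
#' @return Logical vector.
#' @export
#' @examples
#' vlcfa_flag(c(16, 22, 24, 26, 28))
vlcfa_flag <- function(acyl_carbons) {
  acyl_carbons >= 22L & acyl_carbons <= 26L
}

#' Sphingolipid flow table for Sankey display
#'
#' Mean concentrations over a sample group are decomposed and summed per
#' (base, subclass) and (subclass, acyl) link. Left-side and right-side
#' link sums both equal the pool total (flow conservation); percentages
#' are relative to the pool.
#'
#' @param concentrations long concentration tibble.
#' @param pool_subclasses sphingolipid subclasses forming the pool
#'   (default: the five ceramide subclasses).
#' @param within named list of metadata filters selecting the sample
#'   group (default: mildly diseased sections).
#' @return An `av_sphingo_flow` object: tibble of links (`side`,
#'   `source`, `target`, `value_pmol_mg`, `percent`) with the pool total
#'   and species table as attributes.
#' @export
sphingo_flow <- function(concentrations,
                         pool_subclasses = c(
                           "Cer", "dhCer", "deoxyCer", "phytoCer", "sphdCer"
                         ),
                         within = list(stage = "mildly_diseased")) {
  x <- concentrations[concentrations$subclass %in% pool_subclasses, ]
  for (nm in names(within)) {
    x <- x[x[[nm]] %in% within[[nm]], ]
  }
  if (nrow(x) == 0) {
    rlang::abort("empty sphingolipid pool after filtering",
      class = "avl_empty_pool"
    )
  }
  means <- dplyr::summarise(
    dplyr::group_by(x, .data$lipid, .data$subclass),
    mean_pmol_mg = mean(.data$conc_pmol_mg, na.rm = TRUE),
    .groups = "drop"
  )
  means <- means[is.finite(means$mean_pmol_mg), ]
  parts <- decompose_sphingolipids(means$lipid)
  species <- dplyr::inner_join(
    means, parts[, c("lipid", "base", "acyl", "vlcfa")],
    by = "lipid"
  )
  if (nrow(species) == 0) {
    rlang::abort("no decomposable species in the pool",
      class = "avl_empty_pool"
    )
  }
  total <- sum(species$mean_pmol_mg)
  left <- dplyr::summarise(
    dplyr::group_by(species, source = .data$base, target = .data$subclass),
    value_pmol_mg = sum(.data$mean_pmol_mg), .groups = "drop"
  )
  right <- dplyr::summarise(
    dplyr::group_by(species, source = .data$subclass, target = .data$acyl),
    value_pmol_mg = sum(.data$mean_pmol_mg), .groups = "drop"
  )
  links <- dplyr::bind_rows(
    dplyr::mutate(left, side = "base_to_subclass", .before = 1),
    dplyr::mutate(right, side = "subclass_to_acyl", .before = 1)
  )
  links$percent <- 100 * links$value_pmol_mg / total
  links <- dplyr::arrange(
    links, .data$side, dplyr::desc(.data$value_pmol_mg)
  )
  structure(links,
    class = c("av_sphingo_flow", class(links)),
    pool_total_pmol_mg = total,
    species = species
  )
}

#' Per-node shares of a sphingolipid flow
#'
#' @param flow an `av_sphingo_flow` object.
#' @param side `"base"` or `"acyl"`: which side of the flow to summarise.
#' @return Tibble `node`, `value_pmol_mg`, `percent`, sorted descending.
#' @export
flow_shares <- function(flow, side = c("base", "acyl")) {
  side <- match.arg(side)
  links <- flow[flow$side == if (side == "base") {
    "base_to_subclass"
  } else {
    "subclass_to_acyl"
  }, ]
  key <- if (side == "base") links$source else links$target
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(
      node = key, value_pmol_mg = links$value_pmol_mg,
      percent = links$percent
    ), .data$node),
    value_pmol_mg = sum(.data$value_pmol_mg),
    percent = sum(.data$percent), .groups = "drop"
  )
  dplyr::arrange(out, dplyr::desc(.data$percent))
}
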