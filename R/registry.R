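# The 28-subclass registry of the aortic-valve lipid panel. The panel is
# study-specific, so the registry ships as an editable TSV rather than code;
# users profiling other tissues can extend or replace it.

.registry_cache <- new.env(parent = emptyenv())

#' Load the lipid subclass registry
#'
#' Reads the subclass registry table: one row per subclass with its category
#' (NL, GPL, lysoGPL, SP or ST), the elemental formula of the head
#' group/scaffold, the number of chain slots and the linkage rule used when
#' composing elemental formulas (`ester`, `ether`, `sphingo`, `free`,
#' `none`), plus the structural backbone id used by the topology module.
#'
#' @param path optional path to a registry TSV with columns `subclass`,
#'   `category`, `scaffold_formula`, `n_chain_slots`, `linkage`, `backbone`.
#'   Defaults to the registry bundled with the package (28 subclasses).
#' @return A tibble with one row per subclass and a `scaffold` list-column
#'   of parsed elemental formulas.
#' @export
#' @examples
#' av_class_registry()
av_class_registry <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.registry_cache$default)) {
    return(.registry_cache$default)
  }
  if (default) {
    path <- system.file("extdata", "class_registry.tsv", package = "avlipidomics")
  }
  reg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subclass", "category", "scaffold_formula", "n_chain_slots", "linkage", "backbone")
  if (!all(required %in% names(reg))) {
    stop("registry file must have columns: ", paste(required, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reg$subclass)) {
    stop("registry subclasses must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(reg$category), c("NL", "GPL", "lysoGPL", "SP", "ST"))
  if (length(bad) > 0) {
    stop("unknown registry categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  reg$scaffold <- parse_formula(reg$scaffold_formula)
  reg <- tibble::as_tibble(reg)
  if (default) .registry_cache$default <- reg
  reg
}

registry_lookup <- function(subclass, registry = av_class_registry()) {
  idx <- match(subclass, registry$subclass)
  if (anyNA(idx)) {
    stop(
      "unknown lipid subclass: ",
      paste(unique(subclass[is.na(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  registry[idx, ]
}

#' Map lipid subclasses to lipid categories
#'
#' Subclasses partition into five categories: neutral lipids (NL),
#' glycerophospholipids (GPL), their lyso forms (lysoGPL), sphingolipids
#' (SP) and free sterol (ST).
#'
#' @param subclass character vector of registry subclass keys.
#' @param registry registry tibble, see [av_class_registry()].
#' @return Character vector of categories.
#' @export
#' @examples
#' lipid_category(c("SM", "LPC", "CE"))
lipid_category <- function(subclass, registry = av_class_registry()) {
  registry_lookup(subclass, registry)$category
}
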