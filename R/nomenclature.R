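# Lipid shorthand nomenclature: "CLASS C:D;On" at species level and
# "CLASS c1:d1;Oa/c2:d2;Ob" at molecular (chain-resolved) level, with
# O-/P- ether prefixes on the first chain. The subclass of ceramides is
# resolved from the sphingoid base composition (oxygenation/unsaturation),
# not from the class token, mirroring how the family is usually annotated:
#   18:1;O2 sphingosine -> Cer,  18:0;O2 sphinganine -> dhCer,
#   18:1;O  deoxysphingosine -> deoxyCer, 18:2;O2 sphingadienine -> sphdCer,
#   ;O3 phytosphingosine -> phytoCer   (any base carbon count).

.CER_FAMILY <- c("Cer", "dhCer", "deoxyCer", "phytoCer", "sphdCer")

.chain_regex <- "^(\\d+):(\\d+)(;O(\\d*))?$"

parse_chain_token <- function(tok) {
  m <- regmatches(tok, regexec(.chain_regex, tok))[[1]]
  if (length(m) == 0) {
    return(NULL)
  }
  o <- if (m[4] == "") 0L else if (m[5] == "") 1L else as.integer(m[5])
  list(carbons = as.integer(m[2]), double_bonds = as.integer(m[3]), oxygens = o)
}

sphingoid_subclass <- function(double_bonds, oxygens) {
  if (oxygens >= 3L) {
    "phytoCer"
  } else if (oxygens == 1L) {
    "deoxyCer"
  } else if (double_bonds == 0L) {
    "dhCer"
  } else if (double_bonds == 1L) {
    "Cer"
  } else {
    "sphdCer"
  }
}

parse_one_name <- function(name, registry) {
  raw <- trimws(name)
  if (is.na(raw) || raw == "") {
    rlang::abort("empty lipid name", class = "avl_malformed_composition")
  }
  token <- sub("^(\\S+).*$", "\\1", raw)
  comp <- trimws(sub("^\\S+", "", raw))
  if (!token %in% registry$subclass) {
    rlang::abort(
      paste0("unknown lipid class token '", token, "' in '", raw, "'"),
      class = "avl_unknown_class"
    )
  }
  reg <- registry[match(token, registry$subclass), ]
  subclass <- token
  ether_type <- if (token == "etherPE") "O" else "none"

  # ST (free sterol) carries a fixed composition.
  if (reg$linkage == "none") {
    if (!comp %in% c("", "27:1;O")) {
      rlang::abort(
        paste0("unexpected composition for ", token, ": '", raw, "'"),
        class = "avl_malformed_composition"
      )
    }
    return(tibble::tibble(
      raw_name = name, subclass = token, category = reg$category,
      level = "species", ether_type = "none",
      total_carbons = 27L, total_double_bonds = 1L, total_oxygens = 1L,
      chains = list(tibble::tibble(
        carbons = integer(), double_bonds = integer(), oxygens = integer()
      ))
    ))
  }

  if (comp == "") {
    rlang::abort(
      paste0("missing composition in '", raw, "'"),
      class = "avl_malformed_composition"
    )
  }
  if (grepl("^[OP]-", comp)) {
    ether_type <- substr(comp, 1, 1)
    comp <- sub("^[OP]-", "", comp)
    if (token == "PE") subclass <- "etherPE"
    if (!subclass %in% c("etherPE")) {
      rlang::abort(
        paste0("ether prefix not supported for class ", token, " in '", raw, "'"),
        class = "avl_malformed_composition"
      )
    }
    reg <- registry[match(subclass, registry$subclass), ]
  }

  level <- if (grepl("/", comp, fixed = TRUE)) "molecular" else "species"
  toks <- strsplit(comp, "/", fixed = TRUE)[[1]]
  parsed <- lapply(toks, parse_chain_token)
  if (any(vapply(parsed, is.null, logical(1)))) {
    rlang::abort(
      paste0("malformed chain composition in '", raw, "'"),
      class = "avl_malformed_composition"
    )
  }
  chains <- dplyr::bind_rows(lapply(parsed, tibble::as_tibble))

  # "0:0" placeholders name empty slots (e.g. "PC 18:1/0:0" for the lyso
  # species); they stay in the chain table for faithful printing but do
  # not count as occupied slots when composing formulas.
  if (level == "molecular" && nrow(chains) != reg$n_chain_slots) {
    rlang::abort(
      paste0(
        "'", raw, "' resolves ", nrow(chains), " chains but ", subclass,
        " has ", reg$n_chain_slots, " chain slots"
      ),
      class = "avl_malformed_composition"
    )
  }

  # Ceramide-family subclass is keyed on the sphingoid base when resolved.
  if (level == "molecular" && subclass %in% .CER_FAMILY) {
    subclass <- sphingoid_subclass(chains$double_bonds[1], chains$oxygens[1])
    reg <- registry[match(subclass, registry$subclass), ]
  }

  tibble::tibble(
    raw_name = name, subclass = subclass, category = reg$category,
    level = level, ether_type = ether_type,
    total_carbons = sum(chains$carbons),
    total_double_bonds = sum(chains$double_bonds),
    total_oxygens = sum(chains$oxygens),
    chains = list(if (level == "molecular") {
      chains
    } else {
      tibble::tibble(
        carbons = integer(), double_bonds = integer(), oxygens = integer()
      )
    })
  )
}

#' Parse lipid shorthand names
#'
#' Parses species-level (`"CE 18:2"`, `"SM 32:0;O3"`) and molecular-level
#' (`"Cer 18:1;O2/24:0"`, `"PE P-16:0/18:1"`) shorthand against the
#' subclass registry. `";O"` without a digit counts one oxygen. Ceramide
#' subclasses (Cer, dhCer, deoxyCer, phytoCer, sphdCer) are resolved from
#' the sphingoid base whenever chains are resolved.
#'
#' @param names character vector of shorthand names.
#' @param registry subclass registry, see [av_class_registry()].
#' @return A tibble with one row per name: `raw_name`, normalized `lipid`,
#'   `subclass`, `category`, `level` (species/molecular), `ether_type`
#'   (none/O/P), totals (`total_carbons`, `total_double_bonds`,
#'   `total_oxygens`) and a `chains` list-column of per-chain compositions.
#' @export
#' @examples
#' parse_lipid_names(c("CE 18:2", "Cer 18:1;O2/17:0;O", "PC 16:0/18:1"))
parse_lipid_names <- function(names, registry = av_class_registry()) {
  out <- dplyr::bind_rows(lapply(names, parse_one_name, registry = registry))
  out$lipid <- format_lipid_rows(out)
  dplyr::relocate(out, "lipid", .after = "raw_name")
}

format_chain <- function(c, d, o) {
  paste0(c, ":", d, if (o == 1) ";O" else if (o > 1) paste0(";O", o) else "")
}

format_lipid_rows <- function(parsed, level = c("as_is", "species")) {
  level <- match.arg(level)
  vapply(seq_len(nrow(parsed)), function(i) {
    row <- parsed[i, ]
    token <- row$subclass
    prefix <- if (row$ether_type == "none") "" else paste0(row$ether_type, "-")
    if (token == "etherPE") token <- "PE"
    if (row$subclass == "ST") {
      return("ST 27:1;O")
    }
    chains <- row$chains[[1]]
    if (row$level == "molecular" && level == "as_is") {
      body <- paste(
        mapply(format_chain, chains$carbons, chains$double_bonds, chains$oxygens),
        collapse = "/"
      )
    } else {
      body <- format_chain(
        row$total_carbons, row$total_double_bonds, row$total_oxygens
      )
    }
    paste0(token, " ", prefix, body)
  }, character(1))
}

#' Normalize lipid shorthand names
#'
#' Re-emits parsed names in canonical form; parsing a normalized name
#' reproduces an identical record. With `level = "species"` molecular
#' names are collapsed to their sum composition
#' (e.g. `"Cer 18:1;O2/24:0"` to `"Cer 42:1;O2"`).
#'
#' @param x character vector of names, or a parsed tibble from
#'   [parse_lipid_names()].
#' @param level `"as_is"` keeps the resolved level, `"species"` collapses
#'   chains to the sum composition.
#' @param registry subclass registry.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_lipid_names("Cer 18:1;O2/24:0", level = "species")
normalize_lipid_names <- function(x, level = c("as_is", "species"),
                                  registry = av_class_registry()) {
  level <- match.arg(level)
  parsed <- if (is.data.frame(x)) x else parse_lipid_names(x, registry)
  format_lipid_rows(parsed, level = level)
}

# Key of the homologous series within which M+2 interference cascades:
# members differ only in double-bond count, so the d+1 member is isobaric
# with the M+2 of d. Species-level members share subclass, ether linkage,
# carbon and oxygen counts; chain-resolved members additionally share the
# chain skeleton (per-chain carbons and oxygens), since chromatography
# separates isobars with different chain makeup.
homologous_series_key <- function(parsed) {
  vapply(seq_len(nrow(parsed)), function(i) {
    row <- parsed[i, ]
    if (row$level == "molecular") {
      ch <- row$chains[[1]]
      paste(
        row$subclass, row$ether_type,
        paste(ch$carbons, collapse = ","),
        paste(ch$oxygens, collapse = ",")
      )
    } else {
      paste(
        row$subclass, row$ether_type,
        row$total_carbons, row$total_oxygens
      )
    }
  }, character(1))
}

#' Compose elemental formulas for parsed lipids
#'
#' Builds each species' elemental formula as scaffold plus chain
#' contributions minus one water per ester/amide linkage. Species-level
#' names are supported for all classes because the linkage count is fixed
#' by the registry slot number; glycan head groups (HexCer, Hex2Cer, GM3)
#' come from the registry scaffold table.
#'
#' @param parsed tibble from [parse_lipid_names()] (or character names).
#' @param registry subclass registry.
#' @return `parsed` with added list-column `formula` (named integer
#'   vectors) and character column `formula_string`.
#' @export
#' @examples
#' lipid_formulas("PC 34:1")$formula_string
lipid_formulas <- function(parsed, registry = av_class_registry()) {
  if (is.character(parsed)) parsed <- parse_lipid_names(parsed, registry)
  formulas <- lapply(seq_len(nrow(parsed)), function(i) {
    row <- parsed[i, ]
    reg <- registry[match(row$subclass, registry$subclass), ]
    slots <- if (row$level == "molecular") {
      sum(row$chains[[1]]$carbons > 0L)
    } else {
      reg$n_chain_slots
    }
    scaffold <- reg$scaffold[[1]]
    ct <- row$total_carbons
    dt <- row$total_double_bonds
    ot <- row$total_oxygens
    f <- empty_formula()
    if (reg$linkage == "none") {
      f <- scaffold
    } else if (reg$linkage == "free") {
      f <- chain_fa_formula(ct, dt, ot)
    } else if (reg$linkage == "ester") {
      f["C"] <- ct
      f["H"] <- 2L * ct - 2L * dt
      f["O"] <- 2L * slots + ot
      f <- f + scaffold - slots * .WATER
    } else if (reg$linkage == "ether") {
      f["C"] <- ct
      f["H"] <- 2L * ct - 2L * dt + 2L - if (row$ether_type == "P") 2L else 0L
      f["O"] <- 2L * slots - 1L + ot
      f <- f + scaffold - slots * .WATER
    } else if (reg$linkage == "sphingo") {
      f["C"] <- ct
      f["H"] <- 2L * ct + 1L - 2L * dt
      f["N"] <- 1L
      f["O"] <- ot + 1L
      f <- f + scaffold
    } else {
      rlang::abort(
        paste0("no formula rule for subclass ", row$subclass),
        class = "avl_unsupported_formula"
      )
    }
    if (any(f < 0)) {
      rlang::abort(
        paste0("negative element count composing formula for '", row$raw_name, "'"),
        class = "avl_unsupported_formula"
      )
    }
    f
  })
  parsed$formula <- formulas
  parsed$formula_string <- vapply(formulas, format_formula, character(1))
  parsed
}
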