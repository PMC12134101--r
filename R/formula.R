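# Elemental formulas are named integer vectors over C, H, N, O, P, S and D
# (deuterium, tracked separately from H for labelled internal standards).

.FORMULA_ELEMENTS <- c("C", "H", "N", "O", "P", "S", "D")

# Monoisotopic masses of the lightest isotope of each element (Da).
.MONO_MASS <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052,
  O = 15.9949146221, P = 30.97376151, S = 31.97207069,
  D = 2.0141017779
)

#' Parse a Hill-style elemental formula string
#'
#' Accepts strings such as `"C42H82NO8P"`; an element without a trailing
#' number counts once. `"-"` and `""` denote the empty formula.
#'
#' @param x character vector of formula strings.
#' @return A list of named integer vectors over C, H, N, O, P, S, D.
#' @export
#' @examples
#' parse_formula("C42H82NO8P")[[1]]
parse_formula <- function(x) {
  lapply(x, function(s) {
    out <- stats::setNames(integer(length(.FORMULA_ELEMENTS)), .FORMULA_ELEMENTS)
    if (is.na(s) || s == "" || s == "-") {
      return(out)
    }
    m <- gregexpr("([A-Z][a-z]?)(\\d*)", s, perl = TRUE)[[1]]
    toks <- regmatches(s, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(s)) {
      stop("malformed formula string: '", s, "'", call. = FALSE)
    }
    for (tok in toks) {
      el <- gsub("\\d", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (n == "") 1L else as.integer(n)
      if (!el %in% .FORMULA_ELEMENTS) {
        stop("unsupported element '", el, "' in formula '", s, "'", call. = FALSE)
      }
      out[el] <- out[el] + n
    }
    out
  })
}

empty_formula <- function() {
  stats::setNames(integer(length(.FORMULA_ELEMENTS)), .FORMULA_ELEMENTS)
}

formula_add <- function(a, b, scale = 1L) {
  a + scale * b
}

# Chain building blocks. An acyl chain (c carbons, d double bonds, o extra
# hydroxyl oxygens) contributes as the free fatty acid CcH(2c-2d)O(2+o);
# linkage water is subtracted by the caller per slot.
chain_fa_formula <- function(c, d, o = 0L) {
  f <- empty_formula()
  f["C"] <- c
  f["H"] <- 2L * c - 2L * d
  f["O"] <- 2L + o
  f
}

# Fatty alcohol for ether-linked (O-/P-) chains: CcH(2c+2-2d)O(1+o).
chain_alcohol_formula <- function(c, d, o = 0L) {
  f <- empty_formula()
  f["C"] <- c
  f["H"] <- 2L * c + 2L - 2L * d
  f["O"] <- 1L + o
  f
}

# Free sphingoid base CcH(2c+3-2d)N Oo (e.g. sphingosine 18:1;O2 = C18H37NO2).
chain_sphingoid_formula <- function(c, d, o = 2L) {
  f <- empty_formula()
  f["C"] <- c
  f["H"] <- 2L * c + 3L - 2L * d
  f["N"] <- 1L
  f["O"] <- o
  f
}

.WATER <- local({
  f <- stats::setNames(integer(7), c("C", "H", "N", "O", "P", "S", "D"))
  f["H"] <- 2L
  f["O"] <- 1L
  f
})

#' Replace hydrogens by deuterium in a formula
#'
#' Used for deuterated internal standards: `d_count` hydrogens are moved to
#' the D slot so that isotopic purity can attenuate the monoisotopic peak.
#'
#' @param formula named integer vector as returned by [parse_formula()].
#' @param d_count number of deuterium positions.
#' @return The labelled formula.
#' @export
label_formula <- function(formula, d_count) {
  stopifnot(d_count >= 0, formula["H"] >= d_count)
  formula["H"] <- formula["H"] - as.integer(d_count)
  formula["D"] <- formula["D"] + as.integer(d_count)
  formula
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula named integer vector or list of them.
#' @return Numeric mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  if (is.list(formula)) {
    return(vapply(formula, monoisotopic_mass, numeric(1)))
  }
  sum(formula * .MONO_MASS[names(formula)])
}

format_formula <- function(formula) {
  parts <- character(0)
  for (el in c("C", "H", "D", "N", "O", "P", "S")) {
    n <- formula[[el]]
    if (n > 0) {
      parts <- c(parts, paste0(el, if (n > 1) n else ""))
    }
  }
  if (length(parts) == 0) "-" else paste(parts, collapse = "")
}
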