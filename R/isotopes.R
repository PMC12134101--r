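# Isotopic correction machinery for single-point lipid quantification.
#
# Type I correction rescales an analyte/standard area ratio by the share of
# each species' signal residing in its monoisotopic (M0) peak. Type II
# correction removes the M+2 isotopologue of the species with one more
# double bond (same subclass, same carbon number), which co-elutes on the
# monoisotopic peak of the less unsaturated species in MS1/SRM assays.
#
# Natural abundances of the lightest isotopes are a fixed, configurable
# table. Deuterium labels contribute purity^n to the monoisotopic share;
# the impurity (D -> H) shifts mass down, so it never leaks into the
# M+1/M+2 region handled here.

.DEFAULT_ABUNDANCES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  P = 1.0,
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

#' Isotope abundance table
#'
#' Per-element vectors of isotope abundances ordered by mass shift
#' (+0, +1, +2, ...) relative to the lightest isotope.
#'
#' @return Named list of numeric vectors for C, H, N, O, P, S.
#' @export
isotope_abundances <- function() .DEFAULT_ABUNDANCES

#' Monoisotopic fraction of an elemental formula
#'
#' The share of the full isotopologue distribution residing in the
#' monoisotopic peak: the product over elements of the lightest-isotope
#' abundance raised to the atom count, with deuterium positions
#' contributing `purity^count`.
#'
#' @param formula named integer vector (see [parse_formula()]) or a list
#'   of them.
#' @param purity isotopic purity per deuterium position, in (0, 1].
#' @param abundances isotope abundance table, see [isotope_abundances()].
#' @return Numeric fraction in (0, 1].
#' @export
#' @examples
#' monoisotopic_fraction(parse_formula("C42H82NO8P")[[1]])
monoisotopic_fraction <- function(formula, purity = 0.98,
                                  abundances = isotope_abundances()) {
  if (is.list(formula) && !is.numeric(formula)) {
    return(vapply(formula, monoisotopic_fraction, numeric(1),
      purity = purity, abundances = abundances
    ))
  }
  stopifnot(purity > 0, purity <= 1)
  f <- 1
  for (el in names(abundances)) {
    n <- formula[[el]]
    if (!is.na(n) && n > 0) f <- f * abundances[[el]][1]^n
  }
  nd <- formula[["D"]]
  if (!is.na(nd) && nd > 0) f <- f * purity^nd
  f
}

#' Isotopologue distribution of an elemental formula
#'
#' Convolves the per-element isotope vectors to the full distribution of
#' mass shifts M+0 ... M+`max_shift`. Deuterium positions attenuate the
#' whole distribution by `purity^count` (shifts are taken relative to the
#' fully labelled monoisotopic species; the impurity sits at negative
#' shifts and is not reported).
#'
#' @inheritParams monoisotopic_fraction
#' @param max_shift largest mass shift retained.
#' @return Numeric vector of length `max_shift + 1`; element k+1 is the
#'   absolute abundance share of the M+k isotopologue.
#' @export
#' @examples
#' isotopologue_distribution(parse_formula("C45H76O2")[[1]])
isotopologue_distribution <- function(formula, purity = 0.98, max_shift = 6,
                                      abundances = isotope_abundances()) {
  width <- max_shift + 1L
  dist <- c(1, numeric(max_shift))
  conv <- function(a, b) {
    out <- numeric(width)
    for (i in seq_len(width)) {
      if (a[i] == 0) next
      jmax <- width - i + 1L
      out[i:width] <- out[i:width] + a[i] * b[seq_len(jmax)]
    }
    out
  }
  for (el in names(abundances)) {
    n <- formula[[el]]
    if (is.na(n) || n == 0) next
    base <- c(abundances[[el]], numeric(width))[seq_len(width)]
    # binary exponentiation of the per-element polynomial
    pow <- c(1, numeric(max_shift))
    sq <- base
    k <- n
    while (k > 0) {
      if (k %% 2 == 1) pow <- conv(pow, sq)
      sq <- conv(sq, sq)
      k <- k %/% 2
    }
    dist <- conv(dist, pow)
  }
  nd <- formula[["D"]]
  if (!is.na(nd) && nd > 0) dist <- dist * purity^nd
  dist
}

#' Type I isotopic correction factor
#'
#' Factor by which an analyte/standard area ratio is multiplied so that
#' both signals are expressed on the scale of their full isotopologue
#' envelopes: the ratio of the standard's monoisotopic fraction to the
#' analyte's. Reduces to the familiar carbon-only correction when the two
#' formulas differ only in carbon count.
#'
#' @param analyte_formula,istd_formula named integer vectors.
#' @inheritParams monoisotopic_fraction
#' @return Positive numeric scalar.
#' @export
#' @examples
#' fs <- parse_formula(c("C42H82NO8P", "C40H80NO8P"))
#' type1_factor(fs[[1]], fs[[2]])
type1_factor <- function(analyte_formula, istd_formula, purity = 0.98,
                         abundances = isotope_abundances()) {
  monoisotopic_fraction(istd_formula, purity = purity, abundances = abundances) /
    monoisotopic_fraction(analyte_formula, purity = purity, abundances = abundances)
}

#' M+2 to M0 isotopologue ratio
#'
#' The ratio used by type II correction: how much signal the M+2 peak of a
#' species carries relative to its own monoisotopic peak.
#'
#' @inheritParams monoisotopic_fraction
#' @return Non-negative numeric scalar.
#' @export
m2_m0_ratio <- function(formula, purity = 0.98,
                        abundances = isotope_abundances()) {
  d <- isotopologue_distribution(formula,
    purity = purity, max_shift = 2,
    abundances = abundances
  )
  d[3] / d[1]
}
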