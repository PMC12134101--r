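# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

# Combinatorial closed form for the M0/M1/M2 shares of an isotopologue
# distribution: P0 = prod a0^n; P1/P0 = sum_e n_e r1_e;
# P2/P0 = sum_e n_e r2_e + sum_e C(n_e,2) r1_e^2 + sum_{e<f} n_e n_f r1_e r1_f
# with r_k = a_k / a0. Independent of the package's polynomial convolution.
oracle_m012 <- function(formula, abundances = isotope_abundances()) {
  els <- names(abundances)
  n <- vapply(els, function(e) {
    v <- formula[[e]]
    if (is.na(v)) 0 else as.numeric(v)
  }, numeric(1))
  a0 <- vapply(abundances, function(a) a[1], numeric(1))
  r1 <- vapply(abundances, function(a) if (length(a) >= 2) a[2] / a[1] else 0, numeric(1))
  r2 <- vapply(abundances, function(a) if (length(a) >= 3) a[3] / a[1] else 0, numeric(1))
  p0 <- prod(a0^n)
  pairs_same <- sum(choose(n, 2) * r1^2) # two +1 atoms of one element
  nm <- n * r1
  cross <- (sum(nm)^2 - sum(nm^2)) / 2 # +1 atoms of two different elements
  p1 <- p0 * sum(nm)
  p2 <- p0 * (sum(n * r2) + pairs_same + cross)
  c(M0 = p0, M1 = p1, M2 = p2)
}

# Building-block monoisotopic mass oracle: sums monoisotopic masses of
# whole residues (computed from AME2020 isotope masses) rather than
# composing per-element counts the way the package does.
oracle_block_mass <- function(blocks) {
  masses <- c(
    water = 18.0105646837,
    cholesterol = 386.354866095, # C27H46O
    glycerol = 92.0473441154, # C3H8O3
    gpc = 257.1028239938, # C8H20NO6P glycerophosphocholine
    gpe = 215.0558738014, # C5H14NO6P glycerophosphoethanolamine
    phosphocholine_linked = 165.0554798784, # C5H12NO3P (phosphocholine - H2O)
    sphingosine = 299.282429431, # C18H37NO2
    fa160 = 256.240230265, # C16H32O2
    fa170 = 270.255880329, # C17H34O2
    fa180 = 284.271530393, # C18H36O2
    fa181 = 282.255880329, # C18H34O2
    fa182 = 280.240230265, # C18H32O2
    fa240 = 368.3654307786, # C24H48O2
    hexose_linked = 162.0528234187 # C6H10O5 (hexose - H2O)
  )
  sum(masses[blocks])
}

# Exhaustive maximum-common-edge-subgraph size for tiny graphs: every
# vertex of g1 maps to an unused element-compatible vertex of g2 or stays
# unmapped; preserved edges (same bond order) are counted. Pure
# enumeration, no pruning. Graphs are lists with $elements (chr),
# $edges (matrix i, j, order) and $adj.
oracle_mces_size <- function(g1, g2) {
  n1 <- length(g1$elements)
  n2 <- length(g2$elements)
  stopifnot(n1 <= 8)
  adj2 <- matrix(0L, n2, n2)
  for (r in seq_len(nrow(g2$edges))) {
    e <- g2$edges[r, ]
    adj2[e[1], e[2]] <- e[3]
    adj2[e[2], e[1]] <- e[3]
  }
  adj1 <- matrix(0L, n1, n1)
  for (r in seq_len(nrow(g1$edges))) {
    e <- g1$edges[r, ]
    adj1[e[1], e[2]] <- e[3]
    adj1[e[2], e[1]] <- e[3]
  }
  best <- 0
  assign_next <- function(v, map) {
    if (v > n1) {
      common <- 0
      for (r in seq_len(nrow(g1$edges))) {
        e <- g1$edges[r, ]
        m1 <- map[e[1]]
        m2 <- map[e[2]]
        if (!is.na(m1) && !is.na(m2) && adj2[m1, m2] == e[3]) {
          common <- common + 1
        }
      }
      best <<- max(best, common)
      return()
    }
    for (u in seq_len(n2)) {
      if (!u %in% map && g2$elements[u] == g1$elements[v]) {
        map[v] <- u
        assign_next(v + 1, map)
        map[v] <- NA_integer_
      }
    }
    assign_next(v + 1, map) # leave v unmapped
  }
  assign_next(1, rep(NA_integer_, n1))
  best
}

# Monte-Carlo permutation two-sided p-value for a difference in means.
oracle_permutation_p <- function(x, y, n_perm = 20000, seed = 421) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  nx <- length(x)
  withr::with_seed(seed, {
    hits <- sum(replicate(n_perm, {
      idx <- sample.int(length(pool), nx)
      abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
    }))
  })
  (hits + 1) / (n_perm + 1)
}
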