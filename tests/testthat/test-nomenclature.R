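test_that("shorthand parsing resolves class, level, chains and totals", {
  p <- parse_lipid_names(c(
    "CE 18:2", "Cer 18:1;O2/17:0;O", "PC 16:0/18:1", "SM 32:0;O3",
    "PE P-38:4", "PE O-16:0/18:1", "LPC 18:1", "ST 27:1;O"
  ))

  expect_equal(p$subclass[1], "CE")
  expect_equal(p$level[1], "species")
  expect_equal(p$total_carbons[1], 18L)
  expect_equal(p$total_double_bonds[1], 2L)
  expect_equal(p$total_oxygens[1], 0L)

  expect_equal(p$subclass[2], "Cer")
  expect_equal(p$level[2], "molecular")
  expect_equal(p$chains[[2]]$carbons, c(18L, 17L))
  expect_equal(p$chains[[2]]$double_bonds, c(1L, 0L))
  expect_equal(p$chains[[2]]$oxygens, c(2L, 1L))
  expect_equal(p$total_carbons[2], 35L)
  expect_equal(p$total_double_bonds[2], 1L)
  expect_equal(p$total_oxygens[2], 3L)

  expect_equal(p$level[3], "molecular")
  expect_equal(p$total_carbons[3], 34L)
  expect_equal(p$total_double_bonds[3], 1L)
  expect_equal(p$ether_type[3], "none")

  expect_equal(p$total_oxygens[4], 3L) # ";O3" = three oxygens
  expect_equal(p$subclass[5], "etherPE")
  expect_equal(p$ether_type[5], "P")
  expect_equal(p$subclass[6], "etherPE")
  expect_equal(p$ether_type[6], "O")
  expect_equal(p$subclass[8], "ST")

  expect_error(parse_lipid_names("XYZ 18:1"), class = "avl_unknown_class")
  expect_error(parse_lipid_names("PC 16:0/banana"), class = "avl_malformed_composition")
  expect_error(parse_lipid_names("PC 16:0/18:1/18:0"), class = "avl_malformed_composition")
})

test_that("ceramide subclasses are resolved from the sphingoid base", {
  p <- parse_lipid_names(c(
    "Cer 18:1;O2/24:0", "Cer 18:0;O2/16:0", "Cer 18:1;O/16:0",
    "Cer 18:0;O3/24:0", "Cer 18:2;O2/24:1", "Cer 16:1;O2/22:0"
  ))
  expect_equal(
    p$subclass,
    c("Cer", "dhCer", "deoxyCer", "phytoCer", "sphdCer", "Cer")
  )
  expect_true(all(p$category == "SP"))
})

test_that("normalization round-trips and species collapse sums chains", {
  names <- c(
    "SM 32:0;O3", "PE P-38:4", "Cer 18:1;O2/24:0", "PC 16:0/18:1",
    "Cer 18:1;O/16:0", "CE 18:2", "CL 72:8", "TG 52:3"
  )
  norm <- normalize_lipid_names(names)
  expect_equal(norm[1:2], c("SM 32:0;O3", "PE P-38:4"))
  # base-resolved token is canonical for the ceramide family
  expect_equal(norm[5], "deoxyCer 18:1;O/16:0")
  # idempotence: parse -> normalize -> parse reproduces identical records
  p1 <- parse_lipid_names(norm)
  p2 <- parse_lipid_names(normalize_lipid_names(p1))
  expect_equal(
    p1[setdiff(names(p1), "raw_name")],
    p2[setdiff(names(p2), "raw_name")]
  )
  expect_equal(
    normalize_lipid_names("Cer 18:1;O2/24:0", level = "species"),
    "Cer 42:1;O2"
  )
})

test_that("round-trip and composition additivity hold on the packaged panel", {
  panel <- readr::read_tsv(
    system.file("extdata", "av_lipid_panel.tsv", package = "avlipidomics"),
    show_col_types = FALSE
  )
  expect_equal(nrow(panel), 480L)
  expect_equal(length(unique(panel$subclass)), 28L)

  p1 <- parse_lipid_names(panel$lipid)
  expect_equal(p1$lipid, panel$lipid) # fixture names are already canonical
  p2 <- parse_lipid_names(normalize_lipid_names(p1))
  expect_equal(
    p1[setdiff(names(p1), "raw_name")],
    p2[setdiff(names(p2), "raw_name")]
  )

  mol <- dplyr::filter(p1, level == "molecular")
  expect_gt(nrow(mol), 90) # the chain-resolved sphingolipid block
  for (i in seq_len(nrow(mol))) {
    expect_equal(mol$total_carbons[i], sum(mol$chains[[i]]$carbons))
    expect_equal(mol$total_double_bonds[i], sum(mol$chains[[i]]$double_bonds))
    expect_equal(mol$total_oxygens[i], sum(mol$chains[[i]]$oxygens))
  }
})

test_that("category assignment is a total partition", {
  expect_equal(lipid_category(c("SM", "LPC", "CE")), c("SP", "lysoGPL", "NL"))
  expect_error(lipid_category("NOPE"))
  panel <- readr::read_tsv(
    system.file("extdata", "av_lipid_panel.tsv", package = "avlipidomics"),
    show_col_types = FALSE
  )
  p <- parse_lipid_names(panel$lipid)
  expect_true(all(p$category %in% c("NL", "GPL", "lysoGPL", "SP", "ST")))
  expect_false(anyNA(p$category))
})

test_that("composed elemental formulas match reference structures", {
  f <- lipid_formulas(c("PC 34:1", "CE 18:2", "LPC 18:1", "PC 18:1/0:0"))
  expect_equal(f$formula_string[1], "C42H82NO8P") # POPC
  expect_equal(f$formula_string[2], "C45H76O2") # cholesteryl linoleate
  expect_equal(f$formula_string[3], "C26H52NO7P")
  # a lyso species named two ways composes to the same formula
  expect_equal(f$formula[[4]], f$formula[[3]])
})

test_that("composed monoisotopic masses match a building-block oracle", {
  cases <- list(
    list("PC 34:1", c("gpc", "fa160", "fa181"), 2), # POPC
    list("PC 32:0", c("gpc", "fa160", "fa160"), 2), # DPPC
    list("PC 36:2", c("gpc", "fa181", "fa181"), 2), # DOPC
    list("PE 34:1", c("gpe", "fa160", "fa181"), 2), # POPE
    list("CE 18:2", c("cholesterol", "fa182"), 1),
    list("CE 16:0", c("cholesterol", "fa160"), 1),
    list("CE 18:1", c("cholesterol", "fa181"), 1),
    list("ST 27:1;O", "cholesterol", 0),
    list("TG 48:0", c("glycerol", "fa160", "fa160", "fa160"), 3), # tripalmitin
    list("TG 54:3", c("glycerol", "fa181", "fa181", "fa181"), 3), # triolein
    list("DG 32:0", c("glycerol", "fa160", "fa160"), 2),
    list("MG 18:1", c("glycerol", "fa181"), 1),
    list("LPC 16:0", c("gpc", "fa160"), 1),
    list("LPC 18:1", c("gpc", "fa181"), 1),
    list("LPE 18:1", c("gpe", "fa181"), 1),
    list("FA 16:0", "fa160", 0),
    list("FA 18:2", "fa182", 0),
    list("Cer 18:1;O2/24:0", c("sphingosine", "fa240"), 1),
    list("Cer 18:1;O2/16:0", c("sphingosine", "fa160"), 1),
    list("SM 18:1;O2/16:0", c("sphingosine", "phosphocholine_linked", "fa160"), 1),
    list("HexCer 18:1;O2/24:0", c("sphingosine", "hexose_linked", "fa240"), 1),
    list("Hex2Cer 18:1;O2/16:0", c("sphingosine", "hexose_linked", "hexose_linked", "fa160"), 1)
  )
  f <- lipid_formulas(vapply(cases, `[[`, character(1), 1))
  for (i in seq_along(cases)) {
    expected <- oracle_block_mass(cases[[i]][[2]]) -
      cases[[i]][[3]] * oracle_block_mass("water")
    expect_equal(monoisotopic_mass(f$formula[[i]]), expected,
      tolerance = 1e-6 / expected,
      info = cases[[i]][[1]]
    )
  }
})

test_that("every panel species composes to a valid formula", {
  panel <- readr::read_tsv(
    system.file("extdata", "av_lipid_panel.tsv", package = "avlipidomics"),
    show_col_types = FALSE
  )
  f <- lipid_formulas(panel$lipid)
  masses <- monoisotopic_mass(f$formula)
  expect_true(all(masses > 200 & masses < 2500))
  counts <- do.call(rbind, f$formula)
  expect_true(all(counts >= 0))
})
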