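path_graph <- function(n, elem = "C") {
  edges <- if (n > 1) {
    cbind(i = seq_len(n - 1), j = seq(2, n), order = 1L)
  } else {
    matrix(0L, 0, 3)
  }
  adj <- matrix(0L, n, n)
  for (r in seq_len(nrow(edges))) {
    adj[edges[r, 1], edges[r, 2]] <- 1L
    adj[edges[r, 2], edges[r, 1]] <- 1L
  }
  list(elements = rep(elem, n), edges = edges, adj = adj)
}

test_that("MCES distance matches exhaustive enumeration on toy graphs", {
  # path with 4 edges vs the same path plus one pendant edge -> distance 1
  p5 <- path_graph(5)
  p5_pendant <- local({
    g <- path_graph(6)
    g$edges[5, ] <- c(3L, 6L, 1L)
    g$adj <- matrix(0L, 6, 6)
    for (r in seq_len(5)) {
      g$adj[g$edges[r, 1], g$edges[r, 2]] <- 1L
      g$adj[g$edges[r, 2], g$edges[r, 1]] <- 1L
    }
    g
  })
  expect_equal(mces_distance(p5, p5_pendant), 1)
  expect_equal(
    4 + 5 - 2 * oracle_mces_size(p5, p5_pendant),
    1
  )

  # identical graphs -> distance 0
  expect_equal(mces_distance(p5, p5), 0)
  expect_equal(mces_distance("CCO", "CCO"), 0)

  # randomized cross-check against the exhaustive oracle
  withr::with_seed(11, {
    for (rep in 1:15) {
      mk <- function(n, p) {
        el <- sample(c("C", "O", "N"), n, replace = TRUE)
        ed <- NULL
        for (i in 1:(n - 1)) {
          for (j in (i + 1):n) {
            if (stats::runif(1) < p) ed <- rbind(ed, c(i, j, sample(1:2, 1)))
          }
        }
        if (is.null(ed)) ed <- matrix(c(1L, 2L, 1L), 1)
        adj <- matrix(0L, n, n)
        for (r in seq_len(nrow(ed))) {
          adj[ed[r, 1], ed[r, 2]] <- ed[r, 3]
          adj[ed[r, 2], ed[r, 1]] <- ed[r, 3]
        }
        list(elements = el, edges = ed, adj = adj)
      }
      g1 <- mk(sample(3:6, 1), 0.45)
      g2 <- mk(sample(4:7, 1), 0.45)
      if (length(g1$elements) > length(g2$elements)) {
        tmp <- g1
        g1 <- g2
        g2 <- tmp
      }
      want <- nrow(g1$edges) + nrow(g2$edges) - 2 * oracle_mces_size(g1, g2)
      expect_equal(mces_distance(g1, g2), want)
    }
  })
})

test_that("myopic thresholding caps far pairs and keeps near pairs exact", {
  a <- path_graph(8) # 7 edges
  b <- path_graph(8, elem = "N") # no common labels at all
  expect_equal(mces_distance(a, b), 14)
  expect_equal(mces_distance(a, b, threshold = 5), 5)
  # a near pair stays exact under the cap
  expect_equal(mces_distance(a, path_graph(7), threshold = 5), 1)
})

test_that("SMILES parsing yields the expected heavy-atom graphs", {
  g <- smiles_to_graph("CC(=O)O") # acetic acid
  expect_equal(sort(g$elements), c("C", "C", "O", "O"))
  expect_equal(nrow(g$edges), 3)
  expect_equal(sum(g$edges[, "order"] == 2), 1)
  expect_error(smiles_to_graph("[["), class = "avl_unparsable_structure")
})

test_that("the bundled backbone distance matrix is valid and reproducible", {
  m <- backbone_distances()
  expect_equal(attr(m, "provenance"), "loaded")
  expect_equal(nrow(m), 24)
  expect_true(all(m == t(m)))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0))

  # registry backbones are exactly the matrix ids
  reg <- av_class_registry()
  expect_setequal(unique(reg$backbone), rownames(m))

  # spot-recompute cheap entries from the bundled structures
  bb <- av_backbones()
  g <- lapply(bb$smiles, smiles_to_graph)
  names(g) <- bb$backbone
  for (pair in list(c("FA", "MG"), c("CE", "ST"), c("PC", "LPC"))) {
    expect_equal(
      mces_distance(g[[pair[1]]], g[[pair[2]]], threshold = 15),
      unname(m[pair[1], pair[2]]),
      info = paste(pair, collapse = "-")
    )
  }
})

test_that("PCA of the distance matrix has the stated structure", {
  m <- backbone_distances()
  scores <- pca_top(m, n_components = 10, keep = 5)
  expect_equal(dim(scores), c(24, 5))
  # component scores are orthogonal
  gram <- crossprod(scores)
  off <- gram - diag(diag(gram))
  expect_lt(max(abs(off)), 1e-8)

  # two-block binary distance matrix: rows take two patterns, so after
  # centering all variance sits on the first component
  g2 <- rep(1:2, each = 3)
  r1 <- (outer(g2, g2, "!=")) * 1
  s <- pca_top(r1, keep = 3)
  v <- apply(s, 2, stats::var)
  expect_gt(v[1] / sum(v), 1 - 1e-10)

  # 10-component reconstruction reproduces a small matrix exactly
  toy <- as.matrix(stats::dist(matrix(stats::rnorm(18, sd = 3), 6)))
  p <- stats::prcomp(toy, center = TRUE, rank. = 10)
  rec <- p$x %*% t(p$rotation) + matrix(p$center, 6, 6, byrow = TRUE)
  expect_lt(max(abs(rec - toy)), 1e-9)
})

test_that("feature matrix blocks are scaled and weighted as documented", {
  sim <- simulate_av_study(av_study_design(3, 3), seed = 41)
  conc <- impute_min_fifth(sim$concentrations)
  f <- topology_features(conc)
  blocks <- attr(f, "blocks")
  expect_setequal(unique(blocks), c("abundance", "chains", "backbone"))

  ab <- f[, blocks == "abundance", drop = FALSE]
  expect_lt(max(abs(colMeans(ab))), 1e-10)
  expect_lt(max(abs(apply(ab, 2, stats::sd) - 1)), 1e-10)

  mm <- f[, blocks != "abundance", drop = FALSE]
  expect_gte(min(mm), 0)
  expect_lte(max(mm), 1)
  expect_true(any(apply(mm, 2, max) == 1))

  # doubling a block weight doubles its contribution to pairwise
  # squared distances restricted to that block
  f2 <- topology_features(conc, weights = c(abundance = 1, chains = 2, backbone = 1))
  ch1 <- f[, blocks == "chains"]
  ch2 <- f2[, attr(f2, "blocks") == "chains"]
  expect_equal(ch2, 2 * ch1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("embedding is deterministic per seed and separates planted groups", {
  sim <- simulate_av_study(av_study_design(3, 3), seed = 42)
  conc <- impute_min_fifth(sim$concentrations)
  f <- topology_features(conc)
  e1 <- embed_lipidome(f, seed = 7)
  e2 <- embed_lipidome(f, seed = 7)
  expect_identical(e1, e2)

  # two well-separated synthetic blocks: silhouette > 0.5
  n <- 60
  block <- rbind(
    matrix(stats::rnorm(n * 4, mean = 0, sd = 0.3), n),
    matrix(stats::rnorm(n * 4, mean = 8, sd = 0.3), n)
  )
  rownames(block) <- paste0("L", seq_len(2 * n))
  emb <- embed_lipidome(block, seed = 3)
  labels <- rep(1:2, each = n)
  sil <- cluster::silhouette(
    labels, stats::dist(as.matrix(emb[, c("umap_1", "umap_2")]))
  )
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  # row order must not change the recovered neighbourhood structure
  # (coordinates themselves are order-dependent through the SGD schedule)
  perm <- withr::with_seed(5, sample(nrow(block)))
  emb_perm <- embed_lipidome(block[perm, ], seed = 3)
  labels_perm <- labels[perm]
  sil_perm <- cluster::silhouette(
    labels_perm, stats::dist(as.matrix(emb_perm[, c("umap_1", "umap_2")]))
  )
  expect_gt(mean(sil_perm[, "sil_width"]), 0.5)
})

test_that("shared class profiles co-localize across synthetic tissues", {
  # two tissues with shared plasma-dominant classes: species of the same
  # subclass should sit closer together than species of different
  # subclasses, on average
  sim <- simulate_av_study(av_study_design(4, 3), seed = 47)
  conc <- impute_min_fifth(sim$concentrations)
  keep <- conc$subclass %in% c("CE", "TG", "PC", "SM")
  f <- topology_features(conc[keep, ])
  emb <- embed_lipidome(f, seed = 11)
  xy <- as.matrix(emb[, c("umap_1", "umap_2")])
  d <- as.matrix(stats::dist(xy))
  same <- outer(emb$subclass, emb$subclass, "==")
  diag(same) <- NA
  expect_lt(
    mean(d[same & upper.tri(d)], na.rm = TRUE),
    mean(d[!same & upper.tri(d)], na.rm = TRUE)
  )
})
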