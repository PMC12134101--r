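# Planted stage-trajectory archetypes for clustering tests. Z-scored
# 3-stage trajectories live on a circle (mean 0, sd 1 leaves one free
# angle); five archetypes are placed at even 72-degree spacing so that
# each is identifiable under angular noise. The shapes read as: monotone
# down, calcific loss, fibrotic peak, monotone up, fibrotic dip.
trajectory_archetypes <- function() {
  angles <- (18 + 72 * (0:4)) * pi / 180
  basis <- cbind(c(1, -1, 0) / sqrt(2), c(1, 1, -2) / sqrt(6))
  shapes <- lapply(angles, function(a) {
    as.numeric(basis %*% (sqrt(2) * c(cos(a), sin(a))))
  })
  names(shapes) <- c("down", "calcific_loss", "fibrotic_peak", "up", "fibrotic_dip")
  shapes
}

archetype_matrix <- function(n_per = 40, noise = 0.25, seed = 99) {
  arch <- trajectory_archetypes()
  withr::with_seed(seed, {
    m <- do.call(rbind, lapply(arch, function(a) {
      matrix(rep(a, each = n_per), nrow = n_per) +
        matrix(stats::rnorm(3 * n_per, 0, noise), n_per)
    }))
  })
  rownames(m) <- paste0("L", seq_len(nrow(m)))
  colnames(m) <- c("mildly_diseased", "fibrotic", "calcific")
  list(m = m, truth = rep(names(arch), each = n_per))
}
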