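# Small, fast simulation settings shared across tests. Cells are 160 px /
# 6 um radius rather than full size so Monte-Carlo loops stay quick; the
# acceptance tests use the full-size defaults.

small_config <- function(...) {
  args <- list(image_shape = c(160L, 160L), cell_radius = 6,
               n_filaments = 20)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

small_roi <- c(32L, 32L)

measure_small <- function(cell, ...) {
  measure_cells(list(cell), roi_shape = small_roi, ...)
}

# Independent naive Spearman oracle: average ranks by explicit counting,
# then the textbook Pearson formula written out by hand.
naive_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Sinusoidal test image: horizontal wavelength in um on a given grid.
sinusoid_image <- function(n, pixel_size, wavelength) {
  outer(rep(1, n), sin(2 * pi * (seq_len(n) - 1) * pixel_size / wavelength))
}
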