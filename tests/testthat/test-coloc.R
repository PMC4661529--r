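test_that("spearman coefficient matches the no-ties closed form", {
  expect_equal(spearman_coef(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_coef(1:3, c(3, 2, 1)), -1)
  # d^2 = (1,1,1,1,0): 1 - 6*4/120
  expect_equal(spearman_coef(1:5, c(2, 1, 4, 3, 5)), 0.8)
  # symmetry and monotone-transform invariance
  x <- c(3, 9, 1, 4, 4, 7); y <- c(2, 8, 8, 1, 5, 6)
  expect_equal(spearman_coef(x, y), spearman_coef(y, x))
  expect_equal(spearman_coef(x^3, y), spearman_coef(x, y))
  expect_equal(spearman_coef(x, log1p(y)), spearman_coef(x, y))
})

test_that("spearman coefficient agrees with a naive rank-Pearson oracle under ties", {
  set.seed(20)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    x <- sample(0:5, n, replace = TRUE)
    y <- sample(0:5, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_coef(x, y), naive_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("degenerate spearman inputs raise typed errors", {
  expect_error(spearman_coef(1:3, 1:4), "equal length")
  expect_error(spearman_coef(c(1, 2), c(2, 1)), "at least 3")
  expect_error(spearman_coef(rep(1, 5), 1:5),
               class = "mtbench_constant_error")
  expect_error(spearman_coef(1:5, rep(2, 5)),
               class = "mtbench_constant_error")
})

test_that("ROI selection finds the filament and respects the constraints", {
  # one bright horizontal stripe in the upper half of a disk-masked image
  n <- 128
  mask <- matrix(TRUE, n, n)
  img <- matrix(0, n, n)
  img[40:43, ] <- 100
  img <- img + matrix(rnorm(n * n, 0, 0.01), n)
  rois <- select_rois(img, mask, n_rois = 3, roi_shape = c(32, 32))
  expect_equal(nrow(rois), 3)
  expect_true(all(rois$height == 32 & rois$width == 32))
  # best window covers the stripe (exhaustive-score equivalent: any window
  # containing rows 40:43 dominates every window that misses it)
  expect_true(rois$top[1] <= 40 && rois$top[1] + 31 >= 43)
  # pairwise non-overlap
  for (i in 1:2) for (j in (i + 1):3) {
    sep <- abs(rois$top[i] - rois$top[j]) >= 32 ||
      abs(rois$left[i] - rois$left[j]) >= 32
    expect_true(sep)
  }
  # fully inside the mask: shrink the mask and ask for too much
  small_mask <- matrix(FALSE, n, n)
  small_mask[1:40, 1:40] <- TRUE
  expect_error(select_rois(img, small_mask, n_rois = 4,
                           roi_shape = c(32, 32)), "insufficient|overlap")
})

test_that("constant or empty bait content cannot yield ROIs", {
  mask <- matrix(TRUE, 64, 64)
  expect_error(select_rois(matrix(0, 64, 64), mask, 3, c(16, 16)),
               "constant")
  expect_error(select_rois(matrix(rnorm(64^2), 64), matrix(FALSE, 64, 64),
                           3, c(16, 16)), "insufficient")
})

test_that("ROI selection is deterministic with lexicographic tie-breaks", {
  set.seed(30)
  img <- matrix(rnorm(96 * 96), 96)
  mask <- matrix(TRUE, 96, 96)
  a <- select_rois(img, mask, 3, c(24, 24))
  b <- select_rois(img, mask, 3, c(24, 24))
  expect_identical(a, b)
  # pure-tie field: every window scores equally except floating noise; use
  # an exactly tied checkerboard so order falls back to (top, left)
  tie <- matrix(rep(c(0, 1), length.out = 96 * 96), 96)
  r <- select_rois(tie, mask, 2, c(24, 24))
  expect_equal(r$top, c(1L, 1L))
  expect_equal(r$left, c(1L, 25L))
})

test_that("measuring a cell against its own bait gives rho 1", {
  cell <- simulate_cell(small_config(seed = 15, interaction_strength = 1))
  m <- measure_cell(cell$bait, cell$bait, cell$mask, cell$pixel_size,
                    roi_shape = small_roi)
  expect_equal(m$rho_mean, 1)
  expect_equal(c(m$rho_1, m$rho_2, m$rho_3), rep(1, 3))
  expect_true(m$qc_pass)
})

test_that("strong interactions yield high per-cell rho, null stays low", {
  strong <- vapply(1:20, function(seed) {
    cell <- simulate_cell(small_config(seed = seed,
                                       interaction_strength = 1e3,
                                       photon_gain = 50,
                                       read_noise_sigma = 1))
    measure_small(cell)$rho_mean
  }, numeric(1))
  expect_gt(mean(strong), 0.8)
})

test_that("cells without enough valid ROIs are flagged, not dropped silently", {
  cell <- simulate_cell(small_config(seed = 16))
  tiny_mask <- matrix(FALSE, 160, 160)
  tiny_mask[1:20, 1:20] <- TRUE
  m <- measure_cell(cell$bait, cell$prey, tiny_mask, cell$pixel_size,
                    roi_shape = small_roi)
  expect_false(m$qc_pass)
  expect_match(m$qc_reason, "insufficient")
  expect_equal(nrow(m), 1)
})

test_that("per-cell measurement table has the documented tidy shape", {
  cells <- simulate_condition(small_config(interaction_strength = 0.5),
                              c(30, 100), 1, condition = "demo", seed = 21)
  m <- measure_cells(cells, roi_shape = small_roi)
  expect_s3_class(m, "tbl_df")
  expect_equal(nrow(m), 2)
  expect_true(all(c("cell_id", "condition", "bait_expression",
                    "prey_expression", "rho_1", "rho_2", "rho_3",
                    "rho_mean", "qc_pass") %in% names(m)))
  expect_equal(m$rho_mean, rowMeans(cbind(m$rho_1, m$rho_2, m$rho_3)))
  expect_true(all(abs(c(m$rho_1, m$rho_2, m$rho_3)) <= 1))
  # expression estimates rank with the ground truth
  expect_gt(m$bait_expression[2], m$bait_expression[1])
})
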