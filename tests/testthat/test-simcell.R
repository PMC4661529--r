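test_that("network growth respects count, start point and boundary", {
  cfg <- small_config(seed = 3)
  net <- grow_network(cfg)
  expect_equal(dplyr::n_distinct(net$filament), cfg$n_filaments)
  starts <- dplyr::filter(net, vertex == 1)
  expect_true(all(starts$row_um == cfg$centrosome[1]))
  expect_true(all(starts$col_um == cfg$centrosome[2]))
  expect_true(all(net$row_um^2 + net$col_um^2 <= cfg$cell_radius^2 + 1e-9))
  # vacuous case
  empty <- grow_network(small_config(n_filaments = 0))
  expect_equal(nrow(empty), 0)
})

test_that("zero angular noise gives straight radial filaments of full length", {
  cfg <- small_config(angular_sigma = 0, n_filaments = 10, seed = 5)
  net <- grow_network(cfg)
  ends <- dplyr::filter(dplyr::group_by(net, filament),
                        vertex == max(vertex))
  len <- sqrt(ends$row_um^2 + ends$col_um^2)
  expect_true(all(abs(len - cfg$cell_radius) < 1e-9))
  # collinearity: every vertex lies on the ray to the endpoint
  per_fil <- split(net, net$filament)
  for (fp in per_fil) {
    e <- c(fp$row_um[nrow(fp)], fp$col_um[nrow(fp)])
    crossp <- fp$row_um * e[2] - fp$col_um * e[1]
    expect_lt(max(abs(crossp)), 1e-9)
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- small_config(seed = 42, interaction_strength = 0.5,
                      nonspecific_coefficient = 0.01, channel_shift = c(1, -2))
  a <- simulate_cell(cfg)
  b <- simulate_cell(cfg)
  expect_identical(a$bait, b$bait)
  expect_identical(a$prey, b$prey)
  expect_identical(a$filament_density, b$filament_density)
  c2 <- simulate_cell(small_config(seed = 43))
  expect_false(identical(a$bait, c2$bait))
})

test_that("rendered rasters are well-formed 16-bit count images", {
  cell <- simulate_cell(small_config(seed = 1))
  for (m in list(cell$bait, cell$prey)) {
    expect_true(all(m >= 0 & m <= 65535))
    expect_true(all(m == round(m)))
    expect_identical(dim(m), dim(cell$mask))
  }
  expect_gt(sum(cell$mask), 0)
  expect_equal(max(cell$filament_density), 1)
})

test_that("zero bait expression leaves only the camera background", {
  cfg <- small_config(seed = 2, bait_expression = 0)
  cell <- simulate_cell(cfg)
  expect_lt(abs(mean(cell$bait) - cfg$baseline), 1)
  expect_lt(sd(cell$bait), 2 * cfg$read_noise_sigma)
})

test_that("invalid configurations are rejected", {
  expect_error(small_config(centrosome = c(50, 0)), "centrosome")
  expect_error(small_config(cell_radius = 50), "too small")
  expect_error(small_config(filament_affinity = 1.2), "affinity")
  expect_error(small_config(interaction_strength = -1), ">= 0")
  expect_error(simulate_condition(small_config(), numeric(0)), "nonempty")
})

test_that("a saturating interaction makes the channels monotone copies", {
  cfg <- small_config(seed = 6, interaction_strength = 1e3,
                      filament_affinity = 1, camera = FALSE,
                      read_noise_sigma = 0)
  cell <- simulate_cell(cfg)
  rho <- spearman_coef(cell$bait[cell$mask], cell$prey[cell$mask])
  # near-boundary pixels mix in the blurred cytoplasmic pool, so the
  # finite-kappa limit is just below 1 over the full mask
  expect_gt(rho, 0.98)
  # exact limit: w = 1 makes the noiseless channels proportional
  cfg$interaction_strength <- Inf
  exact <- simulate_cell(cfg)
  expect_equal(spearman_coef(exact$bait[exact$mask],
                             exact$prey[exact$mask]), 1)
})

test_that("no interaction means no filament structure in the prey", {
  # Monte-Carlo null: mean |rho| over seeds stays near zero
  rhos <- vapply(1:50, function(seed) {
    cell <- simulate_cell(small_config(seed = seed))
    measure_small(cell)$rho_mean
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 0.05)
  expect_gt(mean(abs(rhos) < 0.15), 0.9)
})

test_that("nonspecific recruitment grows with bait expression", {
  mean_rho <- function(eb) {
    mean(vapply(1:20, function(seed) {
      cell <- simulate_cell(small_config(
        seed = seed, bait_expression = eb,
        nonspecific_coefficient = 0.02))
      measure_small(cell)$rho_mean
    }, numeric(1)))
  }
  lo <- mean_rho(10); hi <- mean_rho(100)
  expect_gt(hi, lo)
})

test_that("condition simulation enumerates the grid deterministically", {
  cfg <- small_config()
  cells <- simulate_condition(cfg, c(10, 50, 100), 2, condition = "x",
                              seed = 9)
  expect_length(cells, 6)
  truth <- dataset_truth(cells)
  expect_equal(sort(unique(truth$E_b)), c(10, 50, 100))
  expect_equal(length(unique(truth$seed)), 6)
  again <- simulate_condition(cfg, c(10, 50, 100), 2, condition = "x",
                              seed = 9)
  expect_identical(dataset_truth(again), truth)
  expect_identical(cells[[4]]$bait, again[[4]]$bait)
})

test_that("expression grid spans its bounds with lognormal spacing", {
  g <- expression_grid(20)
  expect_length(g, 20)
  expect_true(all(g >= 10 & g <= 300))
  expect_true(all(diff(g) > 0))
  # denser at low expression than at high
  expect_gt(sum(g < 100), sum(g > 100))
})
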