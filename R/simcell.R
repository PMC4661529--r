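# Ground-truthed synthetic two-channel cells: a persistent-random-walk
# microtubule network radiating from a centrosome, a bait channel whose
# filament signal scales with expression, and a prey channel whose filament
# recruitment mixes a specific interaction term with a nonspecific term
# that grows with bait expression (the expression-driven false-positive
# mechanism the zero-expression extrapolation is designed to cancel).

#' Simulation configuration
#'
#' All generative parameters for one synthetic cell. Defaults describe a
#' HeLa-scale cell: 512x512 px at 0.1 um/px, a 15 um radius disk mask,
#' 40 microtubules, a 0.15 um Gaussian PSF, and a mildly nonspecific
#' detector (Poisson shot noise, Gaussian read noise, fixed baseline).
#'
#' @param image_shape Integer `(rows, cols)` in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param cell_radius Cell mask radius in micrometres; the disk must fit in
#'   the image.
#' @param centrosome Nucleation point `(row, col)` in cell-centred
#'   micrometres; must lie inside the cell.
#' @param n_filaments Number of microtubules to grow.
#' @param step_length Random-walk step in micrometres.
#' @param angular_sigma SD of the per-step heading perturbation in radians;
#'   0 gives straight radial filaments.
#' @param bait_expression,prey_expression Per-cell expression levels in
#'   arbitrary units (`E_b`, `E_p`).
#' @param filament_affinity Fraction `alpha` of bait signal on filaments
#'   (the rest is a diffuse cytoplasmic pool).
#' @param interaction_strength Specific bait:prey interaction `kappa >= 0`.
#' @param nonspecific_coefficient Nonspecific recruitment `eta >= 0` per
#'   unit of bait expression. The prey's on-filament weight is
#'   `w = (kappa + eta * E_b) / (1 + kappa + eta * E_b)`.
#' @param psf_sigma Isotropic Gaussian PSF SD in micrometres.
#' @param photon_gain Electrons per arbitrary intensity unit (Poisson rate
#'   scale).
#' @param read_noise_sigma Gaussian read noise SD in counts.
#' @param baseline Detector offset in counts added to both channels.
#' @param channel_shift `(drow, dcol)` px translation applied to the prey
#'   channel, emulating chromatic misalignment.
#' @param camera If `FALSE`, skip shot/read noise and quantization and
#'   return continuous noiseless rasters (useful for ground-truth checks).
#' @param seed Integer RNG seed; identical configs give bit-identical cells.
#' @param cell_id,condition Identity metadata propagated into results.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(image_shape = c(512L, 512L),
                       pixel_size = 0.1,
                       cell_radius = 15,
                       centrosome = c(0, 0),
                       n_filaments = 40,
                       step_length = 0.3,
                       angular_sigma = 0.15,
                       bait_expression = 100,
                       prey_expression = 100,
                       filament_affinity = 0.9,
                       interaction_strength = 0,
                       nonspecific_coefficient = 0,
                       psf_sigma = 0.15,
                       photon_gain = 15,
                       read_noise_sigma = 3,
                       baseline = 100,
                       channel_shift = c(0, 0),
                       camera = TRUE,
                       seed = 1L,
                       cell_id = "cell_1",
                       condition = "condition_1") {
  cfg <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
              cell_radius = cell_radius, centrosome = centrosome,
              n_filaments = n_filaments, step_length = step_length,
              angular_sigma = angular_sigma,
              bait_expression = bait_expression,
              prey_expression = prey_expression,
              filament_affinity = filament_affinity,
              interaction_strength = interaction_strength,
              nonspecific_coefficient = nonspecific_coefficient,
              psf_sigma = psf_sigma, photon_gain = photon_gain,
              read_noise_sigma = read_noise_sigma, baseline = baseline,
              channel_shift = channel_shift, camera = isTRUE(camera),
              seed = as.integer(seed), cell_id = cell_id,
              condition = condition)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(image_shape) != 2L || any(image_shape < 8L))
      stop("image_shape must be two dimensions of at least 8 px", call. = FALSE)
    if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
    if (cell_radius <= 0) stop("cell_radius must be positive", call. = FALSE)
    if (2 * cell_radius > min(image_shape) * pixel_size)
      stop("image too small to contain the cell: need at least ",
           ceiling(2 * cell_radius / pixel_size), " px per side", call. = FALSE)
    if (sqrt(sum(centrosome^2)) >= cell_radius)
      stop("centrosome lies outside the cell boundary", call. = FALSE)
    if (n_filaments < 0) stop("n_filaments must be >= 0", call. = FALSE)
    if (step_length <= 0) stop("step_length must be positive", call. = FALSE)
    if (angular_sigma < 0) stop("angular_sigma must be >= 0", call. = FALSE)
    if (filament_affinity < 0 || filament_affinity > 1)
      stop("filament_affinity must lie in [0, 1]", call. = FALSE)
    if (interaction_strength < 0 || nonspecific_coefficient < 0)
      stop("interaction_strength and nonspecific_coefficient must be >= 0",
           call. = FALSE)
    if (bait_expression < 0 || prey_expression < 0)
      stop("expression levels must be >= 0", call. = FALSE)
    if (psf_sigma < 0 || photon_gain <= 0 || read_noise_sigma < 0 ||
        baseline < 0)
      stop("optics/noise parameters out of range", call. = FALSE)
  })
  invisible(cfg)
}

# Run code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Grow a microtubule network
#'
#' Each filament is a persistent random walk that starts at the centrosome
#' with a uniformly random initial direction; at every step of
#' `step_length` the heading is perturbed by a Gaussian of SD
#' `angular_sigma`. A filament ends when it meets the cell boundary (the
#' final segment is clipped onto the boundary circle) or reaches a total
#' length of twice the cell radius.
#'
#' @param config A [sim_config()].
#' @param reseed Seed the RNG from `config$seed` (set `FALSE` to consume an
#'   already-seeded stream, as [simulate_cell()] does).
#' @return Tibble of class `filament_network` with columns `filament`,
#'   `vertex`, `row_um`, `col_um` (cell-centred micrometres) and attributes
#'   `cell_radius` and `centrosome`.
#' @export
grow_network <- function(config, reseed = TRUE) {
  validate_sim_config(config)
  grow <- function() {
    polys <- vector("list", config$n_filaments)
    max_steps <- ceiling(2 * config$cell_radius / config$step_length)
    R <- config$cell_radius
    for (i in seq_len(config$n_filaments)) {
      theta <- stats::runif(1, 0, 2 * pi)
      turns <- stats::rnorm(max_steps, 0, config$angular_sigma)
      pos <- matrix(NA_real_, max_steps + 1L, 2L)
      pos[1, ] <- config$centrosome
      heading <- theta
      k <- 1L
      for (s in seq_len(max_steps)) {
        if (s > 1L) heading <- heading + turns[s]
        nxt <- pos[k, ] + config$step_length * c(cos(heading), sin(heading))
        if (sum(nxt^2) >= R^2) {
          # clip the last segment onto the boundary circle
          p <- pos[k, ]; d <- nxt - p
          a <- sum(d^2); b <- 2 * sum(p * d); cc <- sum(p^2) - R^2
          t_hit <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
          pos[k + 1L, ] <- p + t_hit * d
          k <- k + 1L
          break
        }
        pos[k + 1L, ] <- nxt
        k <- k + 1L
      }
      polys[[i]] <- pos[seq_len(k), , drop = FALSE]
    }
    polys
  }
  polys <- if (reseed) with_seed(config$seed, grow()) else grow()
  net <- purrr::map2_dfr(polys, seq_along(polys), function(p, i) {
    tibble::tibble(filament = i, vertex = seq_len(nrow(p)),
                   row_um = p[, 1], col_um = p[, 2])
  })
  if (nrow(net) == 0L) {
    net <- tibble::tibble(filament = integer(), vertex = integer(),
                          row_um = numeric(), col_um = numeric())
  }
  structure(net, cell_radius = config$cell_radius,
            centrosome = config$centrosome,
            class = c("filament_network", class(tibble::tibble())))
}

# Anti-aliased rasterization of the network: sample each segment at a
# sub-pixel pitch and splat each sample bilinearly onto its 4 neighbours.
rasterize_network <- function(network, config) {
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  dens <- matrix(0, nr, nc)
  if (nrow(network) == 0L) return(dens)
  px <- config$pixel_size
  pitch <- px / 3
  pts_r <- c(); pts_c <- c()
  segs <- dplyr::group_split(dplyr::group_by(network, .data$filament))
  sample_list <- purrr::map(segs, function(fp) {
    p <- cbind(fp$row_um, fp$col_um)
    if (nrow(p) < 2L) return(NULL)
    out <- purrr::map(seq_len(nrow(p) - 1L), function(j) {
      a <- p[j, ]; b <- p[j + 1L, ]
      len <- sqrt(sum((b - a)^2))
      nsmp <- max(1L, ceiling(len / pitch))
      t <- (seq_len(nsmp) - 0.5) / nsmp
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])) # um
    })
    do.call(rbind, out)
  })
  pts <- do.call(rbind, sample_list)
  if (is.null(pts) || nrow(pts) == 0L) return(dens)
  # cell-centred um -> fractional 1-based pixel coordinates (pixel centres)
  pr <- pts[, 1] / px + nr / 2 + 0.5
  pc <- pts[, 2] / px + nc / 2 + 0.5
  r0 <- floor(pr); c0 <- floor(pc)
  fr <- pr - r0; fc <- pc - c0
  splat_r <- c(r0, r0, r0 + 1, r0 + 1)
  splat_c <- c(c0, c0 + 1, c0, c0 + 1)
  splat_w <- c((1 - fr) * (1 - fc), (1 - fr) * fc, fr * (1 - fc), fr * fc)
  ok <- splat_r >= 1 & splat_r <= nr & splat_c >= 1 & splat_c <= nc
  idx <- (splat_c[ok] - 1) * nr + splat_r[ok]
  acc <- rowsum(splat_w[ok], idx)
  dens[as.integer(rownames(acc))] <- acc[, 1]
  dens
}

disk_mask <- function(config) {
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  px <- config$pixel_size
  ru <- (seq_len(nr) - 0.5 - nr / 2) * px
  cu <- (seq_len(nc) - 0.5 - nc / 2) * px
  outer(ru^2, cu^2, "+") <= config$cell_radius^2
}

#' Render a synthetic two-channel cell
#'
#' Builds the noiseless channels from the rasterized filament density
#' `F` (peak-normalized) and the uniform cytoplasmic pool `U` (the cell
#' mask indicator):
#' bait `= E_b * (alpha * F + (1 - alpha) * U)` and prey
#' `= E_p * (w * F + (1 - w) * U)` with on-filament weight
#' `w = (kappa + eta * E_b) / (1 + kappa + eta * E_b)`. Both channels are
#' blurred by the Gaussian PSF, then (when `camera = TRUE`) pass through
#' Poisson shot noise at `photon_gain`, a constant baseline, additive
#' Gaussian read noise, rounding, and clipping to the 16-bit range.
#' Finally the prey channel is translated by `channel_shift` with subpixel
#' interpolation.
#'
#' @param network A [grow_network()] result.
#' @inheritParams grow_network
#' @return A list of class `synthetic_cell`: matrices `bait`, `prey`,
#'   logical `mask`, ground-truth `filament_density`, `pixel_size`,
#'   `cell_id`, `condition`, and a one-row `truth` tibble.
#' @export
render_cell <- function(network, config, reseed = TRUE) {
  validate_sim_config(config)
  render <- function() {
    Fd <- rasterize_network(network, config)
    if (max(Fd) > 0) Fd <- Fd / max(Fd)
    mask <- disk_mask(config)
    U <- mask * 1
    sig_px <- config$psf_sigma / config$pixel_size
    Fb <- fft_gaussian_blur(Fd, sig_px)
    Ub <- fft_gaussian_blur(U, sig_px)
    Fb[Fb < 0] <- 0; Ub[Ub < 0] <- 0
    kappa <- config$interaction_strength
    drive <- kappa + config$nonspecific_coefficient * config$bait_expression
    w <- if (is.infinite(drive)) 1 else drive / (1 + drive)
    alpha <- config$filament_affinity
    bait0 <- config$bait_expression * (alpha * Fb + (1 - alpha) * Ub)
    prey0 <- config$prey_expression * (w * Fb + (1 - w) * Ub)
    shoot <- function(signal) {
      el <- signal * config$photon_gain
      if (config$camera) {
        n <- length(el)
        counts <- stats::rpois(n, el) + config$baseline +
          stats::rnorm(n, 0, config$read_noise_sigma)
        counts <- round(counts)
        counts[counts < 0] <- 0
        counts[counts > 65535] <- 65535
        matrix(counts, nrow(signal), ncol(signal))
      } else {
        el + config$baseline
      }
    }
    bait <- shoot(bait0)
    prey <- shoot(prey0)
    if (any(config$channel_shift != 0)) {
      prey <- apply_shift(prey, config$channel_shift)
      if (config$camera) prey <- round(pmax(pmin(prey, 65535), 0))
    }
    structure(list(
      bait = bait, prey = prey, mask = mask, filament_density = Fd,
      pixel_size = config$pixel_size, cell_id = config$cell_id,
      condition = config$condition,
      truth = tibble::tibble(
        cell_id = config$cell_id, condition = config$condition,
        E_b = config$bait_expression, E_p = config$prey_expression,
        kappa = kappa, eta = config$nonspecific_coefficient,
        shift_row = config$channel_shift[1],
        shift_col = config$channel_shift[2], seed = config$seed)
    ), class = "synthetic_cell")
  }
  if (reseed) with_seed(config$seed + 1L, render()) else render()
}

#' Simulate one cell (network growth plus rendering)
#'
#' @inheritParams grow_network
#' @return A `synthetic_cell`.
#' @export
simulate_cell <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    net <- grow_network(config, reseed = FALSE)
    render_cell(net, config, reseed = FALSE)
  })
}

#' Lognormal expression design
#'
#' Quantile grid of a truncated lognormal distribution, emulating how bait
#' expression spreads over cells in a transient transfection: many cells
#' at low-to-moderate expression, a long tail of bright cells. This is the
#' default bait expression design of the simulated conditions.
#'
#' @param n Number of levels (one cell per level by default downstream).
#' @param median Median of the underlying lognormal, in a.u.
#' @param sdlog SD of log expression.
#' @param min,max Truncation bounds in a.u.
#' @return Sorted numeric vector of `n` expression levels.
#' @export
expression_grid <- function(n = 20, median = 30, sdlog = 0.9,
                            min = 10, max = 300) {
  stopifnot(n >= 1, min > 0, max > min)
  mu <- log(median)
  plo <- stats::plnorm(min, mu, sdlog)
  phi <- stats::plnorm(max, mu, sdlog)
  stats::qlnorm(plo + (phi - plo) * (seq_len(n) - 0.5) / n, mu, sdlog)
}

#' Simulate a condition: cells across a bait expression grid
#'
#' One cell per (expression level, replicate), each with an independent
#' sub-seed derived deterministically from `seed`. This is the generative
#' analogue of imaging a transfected coverslip at varying bait expression.
#'
#' @param config A [sim_config()] template; its `bait_expression`, `seed`,
#'   `cell_id` and `condition` are overridden per cell.
#' @param expression_levels Numeric vector of bait expression levels (a.u.).
#' @param n_cells_per_level Replicate cells per level.
#' @param condition Condition label for all cells.
#' @param seed Master seed.
#' @return List of `synthetic_cell` objects (class `synthetic_dataset`).
#' @export
simulate_condition <- function(config, expression_levels,
                               n_cells_per_level = 1L,
                               condition = config$condition,
                               seed = config$seed) {
  if (length(expression_levels) == 0L)
    stop("expression_levels must be nonempty", call. = FALSE)
  if (n_cells_per_level < 1L)
    stop("n_cells_per_level must be >= 1", call. = FALSE)
  grid <- tidyr::expand_grid(level = expression_levels,
                             replicate = seq_len(n_cells_per_level))
  sub_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max - 1L, nrow(grid)))
  cells <- purrr::pmap(list(grid$level, grid$replicate, sub_seeds,
                            seq_len(nrow(grid))),
                       function(level, rep, sseed, i) {
    cfg <- config
    cfg$bait_expression <- level
    cfg$seed <- sseed
    cfg$condition <- condition
    cfg$cell_id <- sprintf("%s_%03d", condition, i)
    simulate_cell(cfg)
  })
  structure(cells, class = "synthetic_dataset")
}

#' Ground-truth table of a simulated dataset
#'
#' @param cells A list of `synthetic_cell` objects.
#' @return Tibble with one row per cell (id, condition, expressions,
#'   interaction parameters, channel shift, seed).
#' @export
dataset_truth <- function(cells) {
  purrr::map_dfr(cells, "truth")
}
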