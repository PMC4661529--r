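# Disk-backed pipeline: simulate a dataset to TIFF + CSV, analyze a cell
# table (register, filter, measure), and fit/report per condition. These
# are the functions the command-line script at `inst/cli/mtbench.R` wraps.

#' Pipeline configuration
#'
#' Analysis-stage settings shared by [bench_analyze()] and [bench_fit()].
#'
#' @param pixel_size Micrometres per pixel of the input images.
#' @param cutoff_wavelength High-pass cutoff in micrometres.
#' @param n_rois,roi_shape ROI count and fixed `(height, width)` in px.
#' @param manual_roi_path Optional CSV of manual ROIs (columns `cell_id`,
#'   `top`, `left`, `height`, `width`; 0-based, top-left origin, half-open)
#'   overriding automatic selection for listed cells.
#' @param registration `"per-cell"` (estimate and correct each pair),
#'   `"per-session"` (correct every pair by the session-mean shift), or
#'   `"off"`.
#' @param statistics_mode `"intercepts"` (t-test on extrapolated
#'   intercepts) or `"cells"` (t-test on per-cell coefficients).
#' @param control Control condition label for comparisons, or `NULL`.
#' @param exclude Character vector of cell ids to exclude (the explicit
#'   curation list: unhealthy cells, stress-granule cells, ...), logged in
#'   the rejects table rather than silently dropped.
#' @param seed Integer seed recorded in output metadata.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = 0.1,
                            cutoff_wavelength = 2,
                            n_rois = 3L,
                            roi_shape = c(64L, 64L),
                            manual_roi_path = NULL,
                            registration = c("per-cell", "per-session", "off"),
                            statistics_mode = c("intercepts", "cells"),
                            control = NULL,
                            exclude = character(),
                            seed = 1L) {
  registration <- match.arg(registration)
  statistics_mode <- match.arg(statistics_mode)
  structure(list(pixel_size = pixel_size,
                 cutoff_wavelength = cutoff_wavelength,
                 n_rois = as.integer(n_rois),
                 roi_shape = as.integer(roi_shape),
                 manual_roi_path = manual_roi_path,
                 registration = registration,
                 statistics_mode = statistics_mode,
                 control = control, exclude = exclude,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pkg_version <- function() {
  as.character(utils::packageVersion("mtbench"))
}

#' Write a CSV with a metadata header
#'
#' Output tables carry `#`-prefixed header lines (tool version, config
#' hash, seed) so every file records how it was produced. Numeric columns
#' are written with 6 significant digits for reproducible diffs.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param config Optional configuration list hashed into the header.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_bench_csv <- function(df, path, config = NULL, seed = NULL) {
  meta <- c(paste0("# mtbench version: ", pkg_version()),
            if (!is.null(config)) paste0("# config hash: ",
                                         rlang::hash(unclass(config))),
            if (!is.null(seed)) paste0("# seed: ", seed))
  out <- dplyr::mutate(as.data.frame(df),
                       dplyr::across(dplyr::where(is.numeric),
                                     ~ signif(.x, 6)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_bench_csv()]
#'
#' @param path CSV path; `#` header lines are skipped.
#' @return A tibble.
#' @export
read_bench_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

write_tiff16 <- function(m, path) {
  m <- pmax(pmin(m, 65535), 0)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a single-plane 16-bit grayscale TIFF as a count matrix
#'
#' @param path TIFF path.
#' @return Numeric matrix of counts in `[0, 65535]`.
#' @export
read_tiff16 <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  round(m * 65535)
}

#' Simulate a dataset to disk
#'
#' Generates one condition per row of `conditions`, each across the same
#' bait expression grid, and writes per-cell bait/prey/mask TIFF triplets,
#' a ground-truth sidecar CSV, the cell table CSV that [bench_analyze()]
#' consumes, and a YAML copy of the generative configuration. Deterministic
#' per seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param conditions Data frame with columns `name`, `kappa`, `eta` (one
#'   row per prey condition).
#' @param expression_levels Bait expression grid in arbitrary units.
#' @param n_cells_per_level Replicate cells per level and condition.
#' @param config A [sim_config()] template for everything else.
#' @param seed Master seed; condition `i` uses `seed + i - 1`.
#' @return The cell table tibble (invisibly), with file paths.
#' @export
bench_simulate <- function(out_dir, conditions,
                           expression_levels = expression_grid(20),
                           n_cells_per_level = 1L,
                           config = sim_config(), seed = 1L) {
  stopifnot(is.data.frame(conditions),
            all(c("name", "kappa", "eta") %in% names(conditions)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); truths <- list()
  for (i in seq_len(nrow(conditions))) {
    cfg <- config
    cfg$interaction_strength <- conditions$kappa[i]
    cfg$nonspecific_coefficient <- conditions$eta[i]
    cells <- simulate_condition(cfg, expression_levels, n_cells_per_level,
                                condition = conditions$name[i],
                                seed = seed + i - 1L)
    truths[[i]] <- dataset_truth(cells)
    rows[[i]] <- purrr::map_dfr(cells, function(cell) {
      stem <- file.path(out_dir, cell$cell_id)
      write_tiff16(cell$bait, paste0(stem, "_bait.tif"))
      write_tiff16(cell$prey, paste0(stem, "_prey.tif"))
      write_tiff16(cell$mask * 65535, paste0(stem, "_mask.tif"))
      tibble::tibble(cell_id = cell$cell_id, condition = cell$condition,
                     bait_path = paste0(stem, "_bait.tif"),
                     prey_path = paste0(stem, "_prey.tif"),
                     mask_path = paste0(stem, "_mask.tif"))
    })
  }
  cell_table <- dplyr::bind_rows(rows)
  write_bench_csv(dplyr::bind_rows(truths),
                  file.path(out_dir, "ground_truth.csv"),
                  config = config, seed = seed)
  write_bench_csv(cell_table, file.path(out_dir, "cell_table.csv"),
                  config = config, seed = seed)
  yaml::write_yaml(c(unclass(config),
                     list(conditions = as.list(conditions),
                          expression_levels = expression_levels,
                          n_cells_per_level = n_cells_per_level,
                          master_seed = seed)),
                   file.path(out_dir, "simulation_config.yaml"))
  invisible(cell_table)
}

#' Segment a cell mask from a raw channel
#'
#' Convenience segmentation for tables without a mask file: the channel is
#' blurred (1 um Gaussian) and thresholded halfway between its background
#' (lower quartile) and cell (95th percentile) levels. Synthetic masks
#' written by [bench_simulate()] make this unnecessary for simulated data.
#'
#' @param raw Raw channel matrix.
#' @param pixel_size Micrometres per pixel.
#' @return Logical matrix.
#' @export
estimate_cell_mask <- function(raw, pixel_size) {
  blurred <- fft_gaussian_blur(raw, 1 / pixel_size)
  lo <- stats::quantile(blurred, 0.25)
  hi <- stats::quantile(blurred, 0.95)
  blurred > (lo + hi) / 2
}

read_manual_rois <- function(path) {
  df <- read_bench_csv(path)
  stopifnot(all(c("cell_id", "top", "left", "height", "width") %in%
                  names(df)))
  # manual ROI files use 0-based half-open extents; internal is 1-based
  df$top <- df$top + 1L
  df$left <- df$left + 1L
  df
}

#' Analyze a cell table: register, filter, measure
#'
#' For every row of the cell table, reads the channel TIFFs and mask,
#' optionally estimates and corrects the inter-channel shift (per cell or
#' with one session-mean shift), then runs the per-cell measurement
#' ([measure_cell()]). Cells that fail (unreadable files, mismatched
#' shapes, too little mask area, constant ROIs, or an explicit exclude
#' list) are recorded in the rejects table with a reason and the run
#' continues.
#'
#' @param cell_table Tibble from [bench_simulate()] / a CSV path with
#'   columns `cell_id`, `condition`, `bait_path`, `prey_path`, optional
#'   `mask_path`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes
#'   `measurements.csv` and `rejects.csv`.
#' @return Measurement tibble (one row per analyzed cell, with the applied
#'   `shift_row`/`shift_col`); the rejects tibble is attached as attribute
#'   `"rejects"`.
#' @export
bench_analyze <- function(cell_table, config = pipeline_config(),
                          out_dir = NULL) {
  if (is.character(cell_table)) cell_table <- read_bench_csv(cell_table)
  stopifnot(all(c("cell_id", "condition", "bait_path", "prey_path") %in%
                  names(cell_table)))
  if (nrow(cell_table) == 0L) {
    warning("empty cell table: nothing to analyze", call. = FALSE)
  }
  manual <- if (!is.null(config$manual_roi_path))
    read_manual_rois(config$manual_roi_path) else NULL
  fs <- filter_settings(config$cutoff_wavelength)
  rejects <- list(); loaded <- list()
  for (i in seq_len(nrow(cell_table))) {
    row <- cell_table[i, ]
    if (row$cell_id %in% config$exclude) {
      rejects[[length(rejects) + 1L]] <-
        tibble::tibble(cell_id = row$cell_id,
                       reason = "listed in the exclude list")
      next
    }
    cell <- tryCatch({
      bait <- read_tiff16(row$bait_path)
      prey <- read_tiff16(row$prey_path)
      if (!all(dim(bait) == dim(prey)))
        stop("bait and prey images have different shapes")
      mask <- if ("mask_path" %in% names(row) && !is.na(row$mask_path) &&
                  nzchar(row$mask_path)) {
        read_tiff16(row$mask_path) > 0
      } else {
        estimate_cell_mask(bait, config$pixel_size)
      }
      list(row = row, bait = bait, prey = prey, mask = mask)
    }, error = function(e) e)
    if (inherits(cell, "error")) {
      rejects[[length(rejects) + 1L]] <-
        tibble::tibble(cell_id = row$cell_id, reason = conditionMessage(cell))
      next
    }
    loaded[[length(loaded) + 1L]] <- cell
  }
  # registration
  shifts <- purrr::map(loaded, function(cell) {
    if (config$registration == "off") return(c(0, 0))
    tryCatch(as_shift_vector(estimate_shift(cell$bait, cell$prey)),
             error = function(e) c(NA_real_, NA_real_))
  })
  if (config$registration == "per-session") {
    ok <- purrr::map_lgl(shifts, ~ all(is.finite(.x)))
    session <- if (any(ok))
      colMeans(do.call(rbind, shifts[ok])) else c(0, 0)
    shifts <- purrr::map(shifts, ~ session)
  }
  results <- list()
  for (j in seq_along(loaded)) {
    cell <- loaded[[j]]
    s <- shifts[[j]]
    prey <- cell$prey
    if (config$registration != "off" && all(is.finite(s)) && any(s != 0)) {
      prey <- apply_shift(prey, s)
    }
    cell_rois <- NULL
    if (!is.null(manual) && cell$row$cell_id %in% manual$cell_id) {
      cell_rois <- manual[manual$cell_id == cell$row$cell_id, ]
    }
    m <- tryCatch(
      measure_cell(cell$bait, prey, cell$mask, config$pixel_size,
                   cell_id = cell$row$cell_id,
                   condition = cell$row$condition,
                   settings = fs, n_rois = config$n_rois,
                   roi_shape = config$roi_shape, rois = cell_rois),
      error = function(e) e)
    if (inherits(m, "error")) {
      rejects[[length(rejects) + 1L]] <-
        tibble::tibble(cell_id = cell$row$cell_id,
                       reason = conditionMessage(m))
      next
    }
    m$shift_row <- if (all(is.finite(s))) s[1] else NA_real_
    m$shift_col <- if (all(is.finite(s))) s[2] else NA_real_
    results[[length(results) + 1L]] <- m
  }
  measurements <- dplyr::bind_rows(results)
  rejects <- if (length(rejects)) dplyr::bind_rows(rejects) else
    tibble::tibble(cell_id = character(), reason = character())
  if (nrow(rejects) > 0L) {
    warning(nrow(rejects), " cell(s) rejected; see the rejects table",
            call. = FALSE)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bench_csv(dplyr::select(measurements, -dplyr::any_of("rois")),
                    file.path(out_dir, "measurements.csv"),
                    config = config, seed = config$seed)
    write_bench_csv(rejects, file.path(out_dir, "rejects.csv"),
                    config = config, seed = config$seed)
  }
  attr(measurements, "rejects") <- rejects
  measurements
}

#' Fit and report per condition
#'
#' Runs the zero-expression extrapolation per condition and, when a
#' control is configured, the per-condition comparisons against it.
#'
#' @param measurements Measurement tibble or CSV path from
#'   [bench_analyze()].
#' @param config A [pipeline_config()] (supplies `control` and
#'   `statistics_mode`).
#' @param out_dir Optional directory; when given, writes `fits.csv`,
#'   `report.csv` and the plot-ready `points.csv` (expression, rho,
#'   condition).
#' @return The [condition_report()] tibble.
#' @export
bench_fit <- function(measurements, config = pipeline_config(),
                      out_dir = NULL) {
  if (is.character(measurements)) {
    measurements <- read_bench_csv(measurements)
    measurements$qc_pass <- as.logical(measurements$qc_pass)
  }
  report <- condition_report(measurements, control = config$control,
                             mode = config$statistics_mode)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fit <- attr(report, "fit")
    write_bench_csv(tibble::as_tibble(fit), file.path(out_dir, "fits.csv"),
                    config = config, seed = config$seed)
    write_bench_csv(report, file.path(out_dir, "report.csv"),
                    config = config, seed = config$seed)
    pts <- dplyr::select(attr(fit, "measurements"),
                         "cell_id", "condition", "bait_expression",
                         "prey_expression", "rho_mean")
    write_bench_csv(pts, file.path(out_dir, "points.csv"),
                    config = config, seed = config$seed)
  }
  report
}
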