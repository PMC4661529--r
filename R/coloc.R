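# Per-cell colocalization: fixed-area ROIs placed where microtubules are
# clearly visible in the bait channel, Spearman rank correlation of the
# high-passed pixel intensities per ROI, and the three-ROI mean per cell.

constant_vector_error <- function(which) {
  structure(class = c("mtbench_constant_error", "error", "condition"),
            list(message = paste0("Spearman coefficient undefined: the ",
                                  which, " vector is constant"),
                 call = NULL))
}

#' Spearman rank colocalization coefficient
#'
#' Pearson correlation of the two vectors' fractional (average) ranks;
#' equals `1 - 6 * sum(d^2) / (n (n^2 - 1))` when there are no ties. The
#' rank transform makes the coefficient invariant under any strictly
#' increasing transform of either channel, which is why it is preferred
#' over Pearson for fluorophores with nonlinear responses.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` (paired pixel
#'   intensities of the two channels within one ROI).
#' @return A value in `[-1, 1]`.
#' @export
spearman_coef <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired pixels", call. = FALSE)
  if (length(unique(x)) < 2L) stop(constant_vector_error("x"))
  if (length(unique(y)) < 2L) stop(constant_vector_error("y"))
  stats::cor(x, y, method = "spearman")
}

#' Select fixed-area ROIs on the filtered bait channel
#'
#' Candidate windows of shape `roi_shape` are placed on a half-window
#' stride, kept only if they lie fully inside the cell mask, and scored by
#' the standard deviation of the high-passed bait signal inside them (a
#' filament-contrast score: windows crossed by microtubules score high).
#' The `n_rois` top-scoring pairwise non-overlapping windows are returned;
#' ties break by `(top, left)` lexicographic order, so the selection is
#' deterministic. All ROIs share one fixed area to avoid any bias from the
#' surface over which the correlation is computed.
#'
#' @param bait_filtered High-passed bait channel matrix.
#' @param cell_mask Logical matrix, `TRUE` inside the cell.
#' @param n_rois Number of ROIs (3 by default, averaged downstream).
#' @param roi_shape Integer `(height, width)` in pixels.
#' @param cell_id Optional label used in error messages.
#' @return Tibble with columns `roi`, `top`, `left`, `height`, `width`,
#'   `score` (`top`/`left` are 1-based).
#' @export
select_rois <- function(bait_filtered, cell_mask, n_rois = 3L,
                        roi_shape = c(64L, 64L), cell_id = NULL) {
  stopifnot(is.matrix(bait_filtered), is.matrix(cell_mask),
            all(dim(bait_filtered) == dim(cell_mask)))
  h <- as.integer(roi_shape[1]); w <- as.integer(roi_shape[2])
  nr <- nrow(bait_filtered); nc <- ncol(bait_filtered)
  who <- if (is.null(cell_id)) "" else paste0(" for cell '", cell_id, "'")
  if (sum(cell_mask) < n_rois * h * w) {
    stop("insufficient in-mask area", who, ": need ", n_rois * h * w,
         " px, mask has ", sum(cell_mask), call. = FALSE)
  }
  tops <- seq(1L, nr - h + 1L, by = max(1L, h %/% 2L))
  lefts <- seq(1L, nc - w + 1L, by = max(1L, w %/% 2L))
  # integral images make the per-window mask coverage, mean and sd O(1)
  ii <- function(m) {
    p <- matrix(0, nr + 1L, nc + 1L)
    p[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
    p
  }
  Sm <- ii(cell_mask * 1); Sx <- ii(bait_filtered); Sx2 <- ii(bait_filtered^2)
  win_sum <- function(S, t, l) {
    S[cbind(t + h, l + w)] - S[cbind(t, l + w)] -
      S[cbind(t + h, l)] + S[cbind(t, l)]
  }
  cand <- tidyr::expand_grid(top = tops, left = lefts)
  npx <- h * w
  inside <- win_sum(Sm, cand$top, cand$left) == npx
  cand <- cand[inside, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("no candidate window lies fully inside the cell mask", who,
         call. = FALSE)
  }
  sx <- win_sum(Sx, cand$top, cand$left)
  sx2 <- win_sum(Sx2, cand$top, cand$left)
  var_hat <- pmax(0, (sx2 - sx^2 / npx) / (npx - 1))
  cand$score <- sqrt(var_hat)
  if (max(cand$score) <= 0) {
    stop("bait channel is constant inside the mask", who,
         ": no filament contrast to select ROIs on", call. = FALSE)
  }
  cand <- cand[order(-cand$score, cand$top, cand$left), , drop = FALSE]
  chosen <- list()
  for (i in seq_len(nrow(cand))) {
    ti <- cand$top[i]; li <- cand$left[i]
    overlaps <- any(purrr::map_lgl(chosen, function(ch) {
      ti < ch$top + h && ch$top < ti + h && li < ch$left + w && ch$left < li + w
    }))
    if (!overlaps) {
      chosen[[length(chosen) + 1L]] <- list(top = ti, left = li,
                                            score = cand$score[i])
      if (length(chosen) == n_rois) break
    }
  }
  if (length(chosen) < n_rois) {
    stop("could not place ", n_rois, " non-overlapping ROIs", who,
         " (only ", length(chosen), " fit)", call. = FALSE)
  }
  tibble::tibble(roi = seq_len(n_rois),
                 top = purrr::map_int(chosen, ~ as.integer(.x$top)),
                 left = purrr::map_int(chosen, ~ as.integer(.x$left)),
                 height = h, width = w,
                 score = purrr::map_dbl(chosen, "score"))
}

roi_pixels <- function(image, roi) {
  image[roi$top:(roi$top + roi$height - 1L),
        roi$left:(roi$left + roi$width - 1L)]
}

#' Measure one cell's colocalization
#'
#' The per-cell recipe: high-pass filter both (already registered)
#' channels, select `n_rois` fixed-area ROIs on the filtered bait channel,
#' compute the Spearman coefficient of the paired filtered pixels in each
#' ROI, and average. Expression levels are estimated on the raw
#' (unfiltered) channels, since filtering removes the mean intensity.
#'
#' @param bait,prey Raw registered channel matrices.
#' @param mask Logical cell mask.
#' @param pixel_size Micrometres per pixel.
#' @param cell_id,condition Metadata carried into the result row.
#' @param settings A [filter_settings()].
#' @param n_rois,roi_shape ROI count and fixed shape in pixels.
#' @param rois Optional pre-specified ROI tibble (columns `top`, `left`,
#'   `height`, `width`, 1-based) overriding automatic selection.
#' @return One-row tibble: ids, `bait_expression`, `prey_expression`,
#'   `rho_1..rho_n`, `rho_mean`, `n_valid_rois`, `qc_pass`, and a `rois`
#'   list-column with the windows used. `qc_pass` is `FALSE` when fewer
#'   than `n_rois` ROIs yielded a defined coefficient; such cells are
#'   excluded from downstream fits.
#' @export
measure_cell <- function(bait, prey, mask, pixel_size,
                         cell_id = "cell", condition = "condition",
                         settings = filter_settings(),
                         n_rois = 3L, roi_shape = c(64L, 64L), rois = NULL) {
  stopifnot(all(dim(bait) == dim(prey)), all(dim(bait) == dim(mask)))
  bait_f <- highpass(bait, pixel_size, settings)
  prey_f <- highpass(prey, pixel_size, settings)
  fail <- function(reason) {
    res <- tibble::tibble(cell_id = cell_id, condition = condition,
                          bait_expression = NA_real_,
                          prey_expression = NA_real_,
                          rho_mean = NA_real_, n_valid_rois = 0L,
                          qc_pass = FALSE, qc_reason = reason,
                          rois = list(NULL))
    for (i in seq_len(n_rois)) res[[paste0("rho_", i)]] <- NA_real_
    order_measurement_cols(res, n_rois)
  }
  if (is.null(rois)) {
    rois <- tryCatch(
      select_rois(bait_f, mask, n_rois = n_rois, roi_shape = roi_shape,
                  cell_id = cell_id),
      error = function(e) e)
    if (inherits(rois, "error")) return(fail(conditionMessage(rois)))
  }
  rho <- purrr::map_dbl(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    tryCatch(spearman_coef(as.vector(roi_pixels(bait_f, r)),
                           as.vector(roi_pixels(prey_f, r))),
             mtbench_constant_error = function(e) {
               warning("cell '", cell_id, "', ROI ", i, ": ",
                       conditionMessage(e), " (skipped)", call. = FALSE)
               NA_real_
             })
  })
  expr_b <- estimate_expression(bait, mask)$expression
  expr_p <- estimate_expression(prey, mask)$expression
  n_valid <- sum(!is.na(rho))
  res <- tibble::tibble(cell_id = cell_id, condition = condition,
                        bait_expression = expr_b, prey_expression = expr_p,
                        rho_mean = if (n_valid > 0) mean(rho, na.rm = TRUE)
                                   else NA_real_,
                        n_valid_rois = n_valid,
                        qc_pass = n_valid >= n_rois,
                        qc_reason = if (n_valid >= n_rois) NA_character_
                                    else "fewer than n_rois valid ROIs",
                        rois = list(rois))
  for (i in seq_len(n_rois)) res[[paste0("rho_", i)]] <- rho[i]
  order_measurement_cols(res, n_rois)
}

order_measurement_cols <- function(res, n_rois) {
  front <- c("cell_id", "condition", "bait_expression", "prey_expression",
             paste0("rho_", seq_len(n_rois)), "rho_mean", "n_valid_rois",
             "qc_pass", "qc_reason")
  res[, c(front, setdiff(names(res), front))]
}

#' Measure every cell of a simulated dataset
#'
#' Convenience wrapper mapping [measure_cell()] over `synthetic_cell`
#' objects (registration is assumed done or unnecessary; use the pipeline
#' functions for shift correction on disk-backed data).
#'
#' @param cells List of `synthetic_cell` objects.
#' @inheritParams measure_cell
#' @return Tibble with one row per cell.
#' @export
measure_cells <- function(cells, settings = filter_settings(),
                          n_rois = 3L, roi_shape = c(64L, 64L)) {
  purrr::map_dfr(cells, function(cell) {
    measure_cell(cell$bait, cell$prey, cell$mask, cell$pixel_size,
                 cell_id = cell$cell_id, condition = cell$condition,
                 settings = settings, n_rois = n_rois, roi_shape = roi_shape)
  })
}
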