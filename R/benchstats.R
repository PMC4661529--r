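# Expression estimation, Spearman-vs-expression extrapolation to zero bait
# expression, and condition comparisons with significance stars.

#' Estimate a per-cell expression level
#'
#' Expression proxy: mean raw intensity over the cell mask minus the median
#' of the out-of-mask pixels (camera background), floored at zero. Computed
#' on unfiltered channels.
#'
#' @param raw_channel Raw intensity matrix.
#' @param cell_mask Logical matrix, `TRUE` inside the cell.
#' @return One-row tibble: `mean_cell_intensity`, `background`,
#'   `expression`.
#' @export
estimate_expression <- function(raw_channel, cell_mask) {
  stopifnot(is.matrix(raw_channel), all(dim(raw_channel) == dim(cell_mask)))
  if (!any(cell_mask)) stop("cell mask is empty", call. = FALSE)
  if (all(cell_mask)) {
    stop("mask covers the entire image: background is undefined",
         call. = FALSE)
  }
  m <- mean(raw_channel[cell_mask])
  bg <- stats::median(raw_channel[!cell_mask])
  tibble::tibble(mean_cell_intensity = m, background = bg,
                 expression = max(0, m - bg))
}

#' Extrapolate the Spearman coefficient to zero bait expression
#'
#' Fits an ordinary (unweighted) least-squares line
#' `rho = rho0 + s * E` to the per-cell (expression, mean Spearman) points,
#' separately per condition. The intercept `rho0` estimates colocalization
#' in the virtual absence of overexpressed bait — the quantity that cancels
#' expression-driven false positives — and `intercept_sd` is its standard
#' error from the fit covariance.
#'
#' @param measurements Per-cell tibble from [measure_cells()] (needs
#'   `rho_mean`, the expression column, and optionally `condition` and
#'   `qc_pass`; QC failures are dropped).
#' @param axis Which expression axis to extrapolate along: `"bait"`
#'   (default, the false-positive driver) or `"prey"`.
#' @param strict If `TRUE`, a condition violating the preconditions (fewer
#'   than 2 cells, or all expressions identical) is an error; if `FALSE` it
#'   is skipped with a warning. Fits with fewer than 3 cells are always
#'   flagged with a warning, as below the reporting minimum.
#' @return Tibble of class `bench_extrapolation`, one row per condition:
#'   `condition`, `intercept`, `slope`, `intercept_sd`, `residual_sd`,
#'   `n_cells`. The fitted `lm` objects are kept in the `"models"`
#'   attribute and the input points in `"measurements"` (used by
#'   [autoplot.bench_extrapolation()] and [tidy.bench_extrapolation()]).
#' @export
fit_zero_expression <- function(measurements, axis = c("bait", "prey"),
                                strict = TRUE) {
  axis <- match.arg(axis)
  xcol <- paste0(axis, "_expression")
  stopifnot(is.data.frame(measurements),
            all(c(xcol, "rho_mean") %in% names(measurements)))
  df <- tibble::as_tibble(measurements)
  if (!"condition" %in% names(df)) df$condition <- "all"
  if ("qc_pass" %in% names(df)) df <- dplyr::filter(df, .data$qc_pass)
  df <- dplyr::filter(df, is.finite(.data[[xcol]]), is.finite(.data$rho_mean))
  groups <- split(df, df$condition)
  models <- list()
  rows <- purrr::imap(groups, function(g, cond) {
    problem <- NULL
    if (nrow(g) < 2L) {
      problem <- paste0("condition '", cond, "': need at least 2 usable ",
                        "cells, got ", nrow(g))
    } else if (length(unique(g[[xcol]])) < 2L) {
      problem <- paste0("condition '", cond, "': all expression values ",
                        "identical, fit is rank-deficient")
    }
    if (!is.null(problem)) {
      if (strict) stop(problem, call. = FALSE)
      warning(problem, " (condition skipped)", call. = FALSE)
      return(NULL)
    }
    if (nrow(g) < 3L) {
      warning("condition '", cond, "': only ", nrow(g), " cells, below the ",
              "n >= 3 reporting minimum; fit is exact interpolation",
              call. = FALSE)
    }
    fit <- stats::lm(rho_mean ~ E, data = data.frame(rho_mean = g$rho_mean,
                                                     E = g[[xcol]]))
    models[[cond]] <<- fit
    sm <- summary(fit)
    co <- sm$coefficients
    tibble::tibble(condition = cond,
                   intercept = unname(co["(Intercept)", "Estimate"]),
                   slope = unname(co["E", "Estimate"]),
                   intercept_sd = if (fit$df.residual > 0)
                     unname(co["(Intercept)", "Std. Error"]) else NA_real_,
                   residual_sd = if (fit$df.residual > 0) sm$sigma else 0,
                   n_cells = nrow(g))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stop("no condition could be fitted", call. = FALSE)
  tibble::new_tibble(out, models = models, measurements = df, axis = axis,
                     class = "bench_extrapolation")
}

#' Significance stars for a p-value
#'
#' `"**"` for `p < 0.01`, `"*"` for `0.01 <= p < 0.05`, `""` otherwise
#' (two-tailed t-test convention used throughout).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars.
#' @export
stars_for_p <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Compare two conditions
#'
#' Two modes. `"cells"`: a two-tailed t-test (Welch by default) on the
#' per-cell mean Spearman values of the two conditions. `"intercepts"`: a
#' two-tailed t-test on the two fitted zero-expression intercepts, using
#' each intercept's standard error with Welch-Satterthwaite degrees of
#' freedom on the fits' residual degrees of freedom (`n - 2` each).
#'
#' @param x For mode `"cells"`, a per-cell measurement tibble containing
#'   both conditions; for mode `"intercepts"`, a
#'   [fit_zero_expression()] result.
#' @param condition_a,condition_b Condition labels to compare.
#' @param mode `"cells"` or `"intercepts"`.
#' @param pooled Use the pooled-variance t-test instead of Welch
#'   (mode `"cells"` only).
#' @return One-row tibble: `condition_a`, `condition_b`, `mode`,
#'   `t_statistic`, `df`, `p_value`, `stars`.
#' @export
compare_conditions <- function(x, condition_a, condition_b,
                               mode = c("cells", "intercepts"),
                               pooled = FALSE) {
  mode <- match.arg(mode)
  if (mode == "cells") {
    stopifnot(is.data.frame(x), all(c("condition", "rho_mean") %in% names(x)))
    df <- x
    if ("qc_pass" %in% names(df)) df <- dplyr::filter(df, .data$qc_pass)
    a <- df$rho_mean[df$condition == condition_a]
    b <- df$rho_mean[df$condition == condition_b]
    for (lab in list(c(condition_a, length(a)), c(condition_b, length(b)))) {
      if (as.integer(lab[2]) < 3L) {
        stop("condition '", lab[1], "' has fewer than 3 usable cells",
             call. = FALSE)
      }
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: no variance anywhere; p by convention
      p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      tt <- list(statistic = c(t = if (p == 1) 0 else Inf),
                 parameter = c(df = length(a) + length(b) - 2), p.value = p)
    } else {
      tt <- stats::t.test(a, b, var.equal = pooled)
    }
    t_stat <- unname(tt$statistic); dfree <- unname(tt$parameter)
    p <- tt$p.value
  } else {
    stopifnot(inherits(x, "bench_extrapolation"))
    pick <- function(cond) {
      row <- x[x$condition == cond, ]
      if (nrow(row) != 1L) {
        stop("condition '", cond, "' not found in the fit; available: ",
             paste(x$condition, collapse = ", "), call. = FALSE)
      }
      row
    }
    ra <- pick(condition_a); rb <- pick(condition_b)
    va <- ra$intercept_sd^2; vb <- rb$intercept_sd^2
    dfa <- ra$n_cells - 2L; dfb <- rb$n_cells - 2L
    if (!is.finite(va) || !is.finite(vb) || dfa < 1L || dfb < 1L) {
      stop("intercept mode needs both fits to have residual degrees of ",
           "freedom (n_cells >= 3)", call. = FALSE)
    }
    if (va + vb == 0) {
      p <- if (isTRUE(all.equal(ra$intercept, rb$intercept))) 1 else 0
      t_stat <- if (p == 1) 0 else Inf
      dfree <- dfa + dfb
    } else {
      t_stat <- (ra$intercept - rb$intercept) / sqrt(va + vb)
      dfree <- (va + vb)^2 / (va^2 / dfa + vb^2 / dfb)
      p <- 2 * stats::pt(-abs(t_stat), dfree)
    }
  }
  tibble::tibble(condition_a = condition_a, condition_b = condition_b,
                 mode = mode, t_statistic = t_stat, df = dfree,
                 p_value = p, stars = stars_for_p(p))
}

#' Per-condition summary report
#'
#' One row per condition with the zero-expression intercept, its standard
#' error, the number of cells, and (when a control condition is named) the
#' two-tailed t-test of that condition against the control with stars.
#'
#' @param measurements Per-cell measurement tibble.
#' @param control Optional control condition label; `NULL` gives fits only.
#' @param mode Comparison mode passed to [compare_conditions()].
#' @param axis Expression axis for the extrapolation.
#' @return Tibble, one row per condition; also carries the
#'   `bench_extrapolation` fit in attribute `"fit"`.
#' @export
condition_report <- function(measurements, control = NULL,
                             mode = c("intercepts", "cells"),
                             axis = "bait") {
  mode <- match.arg(mode)
  fit <- fit_zero_expression(measurements, axis = axis, strict = FALSE)
  out <- tibble::as_tibble(fit)
  if (!is.null(control)) {
    if (!control %in% out$condition) {
      stop("unknown control condition '", control, "'; available: ",
           paste(out$condition, collapse = ", "), call. = FALSE)
    }
    cmp <- purrr::map_dfr(setdiff(out$condition, control), function(cond) {
      if (mode == "intercepts") {
        compare_conditions(fit, cond, control, mode = "intercepts")
      } else {
        compare_conditions(measurements, cond, control, mode = "cells")
      }
    })
    out <- dplyr::left_join(
      out,
      dplyr::select(cmp, condition = "condition_a", "t_statistic",
                    "p_value", "stars"),
      by = "condition")
    out$control <- control
    out$comparison_mode <- mode
  }
  attr(out, "fit") <- fit
  out
}
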