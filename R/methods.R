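# broom-style accessors and print methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a zero-expression extrapolation
#'
#' One row per condition and model term (intercept and expression slope),
#' with estimates, standard errors, t statistics and p-values from the
#' underlying least-squares fits.
#'
#' @param x A [fit_zero_expression()] result.
#' @param ... Unused.
#' @return A tibble with columns `condition`, `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.bench_extrapolation <- function(x, ...) {
  models <- attr(x, "models")
  purrr::imap_dfr(models, function(fit, cond) {
    co <- summary(fit)$coefficients
    tibble::tibble(condition = cond,
                   term = ifelse(rownames(co) == "E", "expression",
                                 "intercept"),
                   estimate = co[, "Estimate"],
                   std.error = co[, "Std. Error"],
                   statistic = co[, "t value"],
                   p.value = co[, "Pr(>|t|)"])
  })
}

#' Glance at a zero-expression extrapolation
#'
#' @param x A [fit_zero_expression()] result.
#' @param ... Unused.
#' @return One row per condition: intercept, slope, `intercept_sd`,
#'   `residual_sd`, `n_cells`, and the fit's `r.squared`.
#' @export
glance.bench_extrapolation <- function(x, ...) {
  models <- attr(x, "models")
  r2 <- purrr::map_dbl(models, ~ summary(.x)$r.squared)
  out <- tibble::as_tibble(x)
  out$r.squared <- unname(r2[out$condition])
  out
}

#' Confidence interval for the zero-expression intercepts
#'
#' @param object A [fit_zero_expression()] result.
#' @param parm Unused (only the intercept is reported).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Tibble: `condition`, `intercept`, `conf.low`, `conf.high`.
#' @export
confint.bench_extrapolation <- function(object, parm = "intercept",
                                        level = 0.95, ...) {
  models <- attr(object, "models")
  purrr::imap_dfr(models, function(fit, cond) {
    ci <- stats::confint(fit, "(Intercept)", level = level)
    tibble::tibble(condition = cond,
                   intercept = unname(stats::coef(fit)["(Intercept)"]),
                   conf.low = ci[1, 1], conf.high = ci[1, 2])
  })
}

#' @export
print.synthetic_cell <- function(x, ...) {
  cat("<synthetic_cell> ", x$cell_id, " (", x$condition, "): ",
      nrow(x$bait), "x", ncol(x$bait), " px at ", x$pixel_size,
      " um/px; E_b = ", x$truth$E_b, ", E_p = ", x$truth$E_p,
      ", kappa = ", x$truth$kappa, ", eta = ", x$truth$eta, "\n", sep = "")
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat("  ", format(nm, width = 24), paste(format(x[[nm]]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
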