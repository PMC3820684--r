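#' @export
print.selectivity_fit <- function(x, ...) {
  cat("Joint selectivity fit (gamma mesh nets + lognormal predator)\n")
  g <- gear_info(x$table)
  cat(sprintf("  data: %d length classes x %d gears%s\n",
              nrow(x$mu), nrow(g),
              if (x$normalized) " (per-gear normalised frequencies)" else
                " (raw counts)"))
  cat(sprintf("  log-likelihood kernel: %.4f  (converged: %s, %d evaluations)\n",
              x$loglik, x$converged, x$n_evals))
  print(tidy(x), n = 4)
  invisible(x)
}

#' Tidy a selectivity fit
#'
#' @param x A [selectivity_fit][fit_selectivity].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy selectivity_fit
#' @export
tidy.selectivity_fit <- function(x, ...) {
  tibble::tibble(term = names(params_vector(x$params)),
                 estimate = unname(params_vector(x$params)),
                 std.error = unname(x$std_errors))
}

#' One-row summary of a selectivity fit
#'
#' @param x A [selectivity_fit][fit_selectivity].
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `converged`, `n_evals`, `n_gears`,
#'   `n_classes`, `normalized`.
#' @method glance selectivity_fit
#' @export
glance.selectivity_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik,
                 converged = x$converged,
                 n_evals = x$n_evals,
                 n_gears = nrow(gear_info(x$table)),
                 n_classes = nrow(x$mu),
                 normalized = x$normalized)
}

#' Plot fitted selectivity curves
#'
#' Draws the mode-rescaled selectivity curve of every gear over a length
#' grid: mesh nets dashed, predators solid, in the style of a standard
#' multi-gear selectivity figure.
#'
#' @param object A [selectivity_fit][fit_selectivity].
#' @param lower,upper,step Length grid (cm).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selectivity_fit
#' @export
autoplot.selectivity_fit <- function(object, lower = 0.5, upper = 45,
                                     step = 0.05, ...) {
  plot_selectivity(gear_info(object$table), object$params,
                   lower = lower, upper = upper, step = step)
}

#' @rdname autoplot.selectivity_fit
#' @param gears,params As in [curve_table()].
#' @export
plot_selectivity <- function(gears, params = NULL, lower = 0.5, upper = 45,
                             step = 0.05) {
  res <- resolve_gears_params(gears, params)
  ct <- curve_table(res$gears, res$params, lower = lower, upper = upper,
                    step = step)
  fam <- setNames(res$gears$family, res$gears$gear)
  ct$family <- fam[ct$gear]
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$length, y = .data$selectivity,
                                   colour = .data$gear,
                                   linetype = .data$family)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_linetype_manual(values = c(mesh = "dashed",
                                              predator = "solid"),
                                   guide = "none") +
    ggplot2::labs(x = "Length (cm)", y = "Relative selectivity",
                  colour = "Gear") +
    ggplot2::theme_minimal()
}
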