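# Fit reports: JSON round-trip and a parameter table in the layout of a
# published estimates table (term, estimate, standard error).

#' Export a fit report as JSON
#'
#' Serialises everything needed to reproduce downstream summaries without
#' the data: parameter estimates, standard errors, log-likelihood,
#' convergence diagnostics, starting values, settings and gear metadata.
#'
#' @param fit A [selectivity_fit][fit_selectivity].
#' @param path Destination `.json` file.
#' @return `path`, invisibly.
#' @export
export_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "selectivity_fit"))
  g <- gear_info(fit$table)
  report <- list(
    params = as.list(params_vector(fit$params)),
    std_errors = as.list(setNames(unname(fit$std_errors),
                                  names(fit$std_errors))),
    loglik = fit$loglik,
    converged = fit$converged,
    n_evals = fit$n_evals,
    init = as.list(params_vector(fit$init)),
    normalized = fit$normalized,
    control = fit$control,
    gears = purrr::pmap(g, function(gear, family, mesh_size) {
      list(gear = gear, family = family,
           mesh_size = if (is.na(mesh_size)) NULL else mesh_size)
    }),
    mu = list(length_class = fit$mu$length_class, mu = fit$mu$mu),
    package_version = as.character(utils::packageVersion("gearselect")))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a fit report written by [export_fit_json()]
#'
#' @param path A fit-report `.json` file.
#' @return A list with `params` ([selectivity_params]), `std_errors`,
#'   `gears` (a [gear_spec()] tibble), `loglik`, `converged` and the other
#'   stored fields.
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  gl <- rep$gears
  gears <- if (is.data.frame(gl)) {
    gear_spec(gl$gear, gl$family,
              if ("mesh_size" %in% names(gl)) gl$mesh_size else NA_real_)
  } else {
    dplyr::bind_rows(purrr::map(gl, function(x) {
      gear_spec(x$gear, x$family, x$mesh_size %||% NA_real_)
    }))
  }
  rep$params <- as_selectivity_params(unlist(rep$params))
  rep$init <- as_selectivity_params(unlist(rep$init))
  rep$std_errors <- unlist(rep$std_errors)
  rep$gears <- gears
  rep
}

#' Write the parameter table as delimited text
#'
#' One row per parameter with its estimate and standard error, the layout of
#' a published parameter table.
#'
#' @param fit A [selectivity_fit][fit_selectivity].
#' @param path Destination (`.csv` comma-separated, else tab).
#' @return `path`, invisibly.
#' @export
export_fit_table <- function(fit, path) {
  stopifnot(inherits(fit, "selectivity_fit"))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(tidy(fit), path, delim = delim)
  invisible(path)
}
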