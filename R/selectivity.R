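# Selectivity families.
#
# Mesh nets: gamma density rescaled to a modal value of one, with the mode
# proportional to mesh size and one curve variance shared by all nets
# (geometric similarity). Predators: lognormal density rescaled to a modal
# value of one. All evaluations run in log space so extreme lengths underflow
# gracefully instead of overflowing.

#' Selectivity-curve parameters
#'
#' The four estimands of the joint selectivity model:
#'
#' * `theta1` — length at maximum net selectivity per mm of mesh (cm/mm); a
#'   net of mesh size `m` peaks at `theta1 * m` cm.
#' * `theta2` — variance of every net's gamma curve (cm^2), shared across
#'   mesh sizes under geometric similarity.
#' * `theta3` — location of the predator's lognormal curve on the log-length
#'   scale (log cm).
#' * `theta4` — spread of the predator's curve on the log-length scale
#'   (dimensionless standard deviation); the predator curve peaks at
#'   `exp(theta3 - theta4^2)` cm.
#'
#' @param theta1,theta2,theta4 Positive numbers.
#' @param theta3 Real number (log cm).
#' @return An object of class `selectivity_params`.
#' @examples
#' selectivity_params(0.71, 12.94, 2.13, 0.41)
#' @export
selectivity_params <- function(theta1, theta2, theta3, theta4) {
  th <- c(theta1 = as.numeric(theta1), theta2 = as.numeric(theta2),
          theta3 = as.numeric(theta3), theta4 = as.numeric(theta4))
  if (length(th) != 4 || any(!is.finite(th))) {
    abort("All four parameters must be finite scalars.")
  }
  if (th[["theta1"]] <= 0 || th[["theta2"]] <= 0 || th[["theta4"]] <= 0) {
    abort("theta1, theta2 and theta4 must be positive.")
  }
  structure(as.list(th), class = "selectivity_params")
}

#' @export
print.selectivity_params <- function(x, ...) {
  cat("<selectivity_params>\n")
  print(unlist(x))
  invisible(x)
}

as_selectivity_params <- function(x) {
  if (inherits(x, "selectivity_params")) return(x)
  x <- unlist(x, use.names = FALSE)
  if (length(x) != 4) abort("Expected four parameters.")
  selectivity_params(x[1], x[2], x[3], x[4])
}

params_vector <- function(params) {
  unlist(params)[c("theta1", "theta2", "theta3", "theta4")]
}

#' Gamma-curve constants implied by a mesh size
#'
#' Under geometric similarity a net of mesh size `m` has modal length
#' `theta1 * m` and curve variance `theta2`. With a gamma curve (shape
#' `alpha`, scale `beta`) the mode is `(alpha - 1) * beta` and the variance
#' `alpha * beta^2`, so `beta` is the positive root of
#' `beta^2 + theta1 * m * beta - theta2 = 0` and
#' `alpha = theta1 * m / beta + 1`. The implied shape always exceeds one, so
#' every net curve has an interior mode.
#'
#' @param mesh Mesh size(s) in mm, positive.
#' @param params A [selectivity_params] object.
#' @return A tibble with columns `mesh`, `alpha`, `beta`, `mode`, `variance`.
#' @examples
#' solve_gamma_shape(14, selectivity_params(0.71, 12.94, 2.13, 0.41))
#' @export
solve_gamma_shape <- function(mesh, params) {
  params <- as_selectivity_params(params)
  mesh <- as.numeric(mesh)
  if (any(!is.finite(mesh) | mesh <= 0)) {
    abort("Mesh sizes must be finite and positive.")
  }
  mode <- params$theta1 * mesh
  beta <- (-mode + sqrt(mode^2 + 4 * params$theta2)) / 2
  alpha <- mode / beta + 1
  tibble::tibble(mesh = mesh, alpha = alpha, beta = beta,
                 mode = mode, variance = alpha * beta^2)
}

#' Mesh-net selectivity curve
#'
#' Relative selectivity of a gillnet at length `l`: the gamma density with
#' the constants from [solve_gamma_shape()], divided by its value at the
#' mode, so the curve equals one exactly at `theta1 * mesh` and lies in
#' (0, 1] elsewhere.
#'
#' @param length Length(s) in cm, positive.
#' @param mesh Mesh size in mm (scalar).
#' @param params A [selectivity_params] object.
#' @return Numeric vector of relative selectivities in (0, 1].
#' @export
gamma_selectivity <- function(length, mesh, params) {
  params <- as_selectivity_params(params)
  if (any(!is.finite(length) | length <= 0)) {
    abort("Lengths must be finite and positive (cm).")
  }
  gs <- solve_gamma_shape(mesh, params)
  # log of pdf(l)/pdf(mode) for a gamma with mode (alpha-1)*beta
  exp((gs$alpha - 1) * (log(length) - log(gs$mode)) + (gs$mode - length) / gs$beta)
}

#' Predator selectivity curve
#'
#' Relative selectivity of the predator at length `l`: a lognormal density
#' with log-scale location `theta3` and spread `theta4`, divided by its value
#' at the mode `exp(theta3 - theta4^2)`, so the curve peaks at exactly one.
#'
#' @inheritParams gamma_selectivity
#' @return Numeric vector of relative selectivities in (0, 1].
#' @export
lognormal_selectivity <- function(length, params) {
  params <- as_selectivity_params(params)
  if (any(!is.finite(length) | length <= 0)) {
    abort("Lengths must be finite and positive (cm).")
  }
  mode <- exp(params$theta3 - params$theta4^2)
  exp(dlnorm(length, params$theta3, params$theta4, log = TRUE) -
        dlnorm(mode, params$theta3, params$theta4, log = TRUE))
}

gear_selectivity <- function(length, family, mesh_size, params) {
  if (family == "mesh") {
    gamma_selectivity(length, mesh_size, params)
  } else {
    lognormal_selectivity(length, params)
  }
}

#' Mode and variance of each gear's selectivity curve
#'
#' For a mesh net the mode is `theta1 * mesh` and the variance the shared
#' `theta2`; for the predator the mode is `exp(theta3 - theta4^2)` and the
#' variance the lognormal-distribution variance
#' `(exp(theta4^2) - 1) * exp(2 * theta3 + theta4^2)`.
#'
#' @param gears A gear-metadata tibble ([gear_spec()]), a `catch_table`, or a
#'   [selectivity_fit][fit_selectivity].
#' @param params A [selectivity_params] object; taken from the fit when
#'   `gears` is one.
#' @return A tibble with columns `gear`, `family`, `mesh_size`, `mode`,
#'   `variance`.
#' @examples
#' th <- selectivity_params(0.71, 12.94, 2.13, 0.41)
#' curve_summary(gear_spec(c("G14", "GC"), c("mesh", "predator"),
#'                         c(14, NA)), th)
#' @export
curve_summary <- function(gears, params = NULL) {
  res <- resolve_gears_params(gears, params)
  g <- res$gears
  params <- res$params
  mode <- ifelse(g$family == "mesh",
                 params$theta1 * g$mesh_size,
                 exp(params$theta3 - params$theta4^2))
  variance <- ifelse(g$family == "mesh",
                     params$theta2,
                     (exp(params$theta4^2) - 1) *
                       exp(2 * params$theta3 + params$theta4^2))
  dplyr::mutate(g, mode = mode, variance = variance)
}

# Resolve a (gears, params) pair from a fit, catch_table or gear tibble.
resolve_gears_params <- function(gears, params) {
  if (inherits(gears, "selectivity_fit")) {
    params <- params %||% gears$params
    gears <- gear_info(gears$table)
  } else if (inherits(gears, "catch_table")) {
    gears <- gear_info(gears)
  }
  if (!is.data.frame(gears) || !all(c("gear", "family") %in% names(gears))) {
    abort("`gears` must be a gear_spec tibble, catch_table or selectivity_fit.")
  }
  if (is.null(params)) abort("`params` is required.")
  list(gears = gears, params = as_selectivity_params(params))
}

#' Selectivity of every gear at every length class
#'
#' @param tab A `catch_table` (only its length classes and gear metadata are
#'   used).
#' @param params A [selectivity_params] object.
#' @return A length-class x gear matrix with entries in (0, 1].
#' @export
selectivity_matrix <- function(tab, params) {
  stopifnot(inherits(tab, "catch_table"))
  params <- as_selectivity_params(params)
  lc <- length_classes(tab)
  g <- gear_info(tab)
  S <- matrix(vapply(seq_len(nrow(g)), function(i) {
    gear_selectivity(lc, g$family[i], g$mesh_size[i], params)
  }, numeric(length(lc))), nrow = length(lc))
  dimnames(S) <- list(lc, g$gear)
  S
}
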