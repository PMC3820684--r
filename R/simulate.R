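# Poisson catch simulator.
#
# Generates multi-gear catch-at-length tables from the same model the
# estimator assumes: cell counts Poisson with mean f_i * mu_j * S_ij(theta).
# Used for parameter-recovery studies and estimator calibration.

#' Configure a catch simulation
#'
#' @param params True [selectivity_params].
#' @param gears A [gear_spec()] tibble (or `catch_table` to copy gears from).
#' @param population Relative abundance per length class: a tibble with
#'   columns `length_class` and `mu`, or a numeric vector paired with
#'   `length_classes`. Non-negative with at least one positive entry.
#' @param length_classes Numeric vector of class labels (cm) when
#'   `population` is a bare vector.
#' @param fishing_powers Positive multiplier per gear (recycled); scales a
#'   gear's expected sample size without changing its length distribution.
#' @param target_per_gear If given, overrides `fishing_powers` so that every
#'   gear's expected total catch equals this number.
#' @param seed Integer RNG seed. Each replicate draws from its own
#'   deterministic substream, so replicate r is reproducible regardless of
#'   how many replicates are requested.
#' @param replicates Number of tables to generate (positive integer).
#' @return A `sim_config` object.
#' @examples
#' g <- gear_spec(c("G14", "G25", "GC"), c("mesh", "mesh", "predator"),
#'                c(14, 25, NA))
#' cfg <- sim_config(selectivity_params(0.7, 12, 2.1, 0.4), g,
#'                   population = rep(1, 30), length_classes = 2:31,
#'                   target_per_gear = 500, seed = 42)
#' @export
sim_config <- function(params, gears, population, length_classes = NULL,
                       fishing_powers = 1, target_per_gear = NULL,
                       seed = 1, replicates = 1) {
  params <- as_selectivity_params(params)
  if (inherits(gears, "catch_table")) gears <- gear_info(gears)
  gears <- gear_spec(gears$gear, gears$family, gears$mesh_size)
  if (is.data.frame(population)) {
    stopifnot(all(c("length_class", "mu") %in% names(population)))
    length_classes <- population$length_class
    mu <- population$mu
  } else {
    mu <- as.numeric(population)
    if (is.null(length_classes) || length(length_classes) != length(mu)) {
      abort("`length_classes` must accompany a bare `population` vector.")
    }
  }
  ord <- order(length_classes)
  length_classes <- as.numeric(length_classes[ord])
  mu <- mu[ord]
  if (any(mu < 0) || !any(mu > 0)) {
    abort("`population` must be non-negative with at least one positive entry.")
  }
  if (is.unsorted(length_classes, strictly = TRUE)) {
    abort("Length classes must be distinct.")
  }
  fishing_powers <- rep_len(as.numeric(fishing_powers), nrow(gears))
  if (any(fishing_powers <= 0)) abort("Fishing powers must be positive.")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1) {
    abort("`replicates` must be a positive integer.")
  }
  cfg <- structure(list(params = params, gears = gears, mu = mu,
                        length_classes = length_classes,
                        fishing_powers = fishing_powers,
                        seed = as.integer(seed),
                        replicates = replicates),
                   class = "sim_config")
  if (!is.null(target_per_gear)) {
    m <- expected_catch(cfg)
    cfg$fishing_powers <- cfg$fishing_powers * target_per_gear / colSums(m)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d classes x %d gears, %d replicate(s), seed %d\n",
              length(x$length_classes), nrow(x$gears), x$replicates, x$seed))
  cat("  expected totals per gear:",
      paste(signif(colSums(expected_catch(x)), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Expected catch matrix of a simulation
#'
#' Cell (j, i) holds `f_i * mu_j * S_ij` under the configured truth.
#'
#' @param config A [sim_config()].
#' @return A length-class x gear matrix of Poisson means.
#' @export
expected_catch <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$gears
  S <- vapply(seq_len(nrow(g)), function(i) {
    gear_selectivity(config$length_classes, g$family[i], g$mesh_size[i],
                     config$params)
  }, numeric(length(config$length_classes)))
  m <- sweep(S * config$mu, 2, config$fishing_powers, "*")
  dimnames(m) <- list(config$length_classes, g$gear)
  m
}

replicate_seed <- function(seed, r) {
  as.integer((abs(as.numeric(seed)) + 1000003 * r) %% 2147483647)
}

#' Draw Poisson catch tables
#'
#' Each replicate is an independent Poisson draw around
#' [expected_catch()], generated from a substream seeded by
#' `(seed, replicate index)`: requesting more replicates never reshuffles
#' earlier ones.
#'
#' @param config A [sim_config()].
#' @param replicates Overrides `config$replicates` if given.
#' @return A list of `catch_table`s of raw counts.
#' @export
sample_catch <- function(config, replicates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  replicates <- replicates %||% config$replicates
  m <- expected_catch(config)
  g <- config$gears
  lapply(seq_len(replicates), function(r) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(replicate_seed(config$seed, r))
    counts <- matrix(rpois(length(m), as.vector(m)), nrow(m), ncol(m))
    dat <- tibble::tibble(
      length_class = rep(config$length_classes, times = nrow(g)),
      gear = rep(g$gear, each = length(config$length_classes)),
      catch = as.vector(counts))
    as_catch_table(dat, gears = g)
  })
}

#' Parameter-recovery experiment
#'
#' Simulates `config$replicates` catch tables, fits each one, and reports
#' the estimates alongside the truth. Fit failures are returned as flagged
#' rows (`converged = NA`, estimates `NA`); the batch never aborts.
#'
#' @param config A [sim_config()].
#' @param ... Passed on to [fit_selectivity()] (e.g. `normalize = FALSE` to
#'   fit the raw counts, `se = FALSE` to skip Hessians for speed).
#' @return A tibble with one row per replicate: `replicate`, `converged`,
#'   `theta1` ... `theta4` (and `se_theta1` ... when SEs are computed), with
#'   the truth stored in `attr(, "truth")`. Summarise with
#'   [summarize_recovery()].
#' @export
recovery_experiment <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  tabs <- sample_catch(config)
  rows <- purrr::imap_dfr(tabs, function(tab, r) {
    fit <- tryCatch(fit_selectivity(tab, ...), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(replicate = r, converged = NA,
                            theta1 = NA_real_, theta2 = NA_real_,
                            theta3 = NA_real_, theta4 = NA_real_))
    }
    th <- params_vector(fit$params)
    out <- tibble::tibble(replicate = r, converged = fit$converged,
                          theta1 = th[1], theta2 = th[2],
                          theta3 = th[3], theta4 = th[4])
    if (!all(is.na(fit$std_errors))) {
      se <- setNames(as.list(unname(fit$std_errors)),
                     paste0("se_", names(th)))
      out <- dplyr::bind_cols(out, tibble::as_tibble(se))
    }
    out
  })
  structure(rows, truth = params_vector(config$params))
}

#' Summarise a recovery experiment
#'
#' @param results Output of [recovery_experiment()].
#' @return A tibble with one row per parameter: `term`, `truth`, `bias`
#'   (mean estimate minus truth), `median_bias`, `sd`, `rmse` and
#'   `convergence_rate`.
#' @export
summarize_recovery <- function(results) {
  truth <- attr(results, "truth")
  if (is.null(truth)) abort("`results` must come from recovery_experiment().")
  ok <- !is.na(results$converged)
  purrr::map_dfr(names(truth), function(term) {
    est <- results[[term]][ok]
    tr <- truth[[term]]
    tibble::tibble(term = term, truth = tr,
                   bias = mean(est) - tr,
                   median_bias = stats::median(est) - tr,
                   sd = stats::sd(est),
                   rmse = sqrt(mean((est - tr)^2)),
                   convergence_rate = mean(results$converged[ok]))
  })
}

#' Population abundances implied by a catch table
#'
#' A data-grounded default population for simulations: the profiled
#' abundances of `tab` at the supplied parameters (row totals divided by
#' summed selectivities), i.e. the population under which the observed table
#' is typical.
#'
#' @param tab A `catch_table` of raw counts.
#' @param params A [selectivity_params] object.
#' @return A tibble with columns `length_class` and `mu`, usable as the
#'   `population` argument of [sim_config()].
#' @export
population_from_table <- function(tab, params) {
  mu <- profile_mu(tab, selectivity_matrix(tab, params))
  mu[c("length_class", "mu")]
}

#' Read a simulation configuration from YAML or JSON
#'
#' Expected top-level fields: `params` (list or vector of theta1..theta4),
#' `gears` (named list as in [infer_gears()] or a vector of G-style ids),
#' `population` (named map length_class -> mu, or a list with
#' `length_class` and `mu` vectors), and optional `fishing_powers`,
#' `target_per_gear`, `seed`, `replicates`.
#'
#' @param path A `.yml`/`.yaml` or `.json` file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (f in c("params", "gears", "population")) {
    if (is.null(cfg[[f]])) abort(paste0("Config field missing: ", f))
  }
  params <- as_selectivity_params(unlist(cfg$params))
  gears <- if (is.character(cfg$gears)) {
    infer_gears(cfg$gears)
  } else {
    as_gear_decl(cfg$gears)
  }
  pop <- cfg$population
  if (!is.null(names(pop)) && is.null(pop$length_class)) {
    population <- tibble::tibble(length_class = as.numeric(names(pop)),
                                 mu = as.numeric(unlist(pop)))
  } else {
    population <- tibble::tibble(length_class = as.numeric(pop$length_class),
                                 mu = as.numeric(pop$mu))
  }
  sim_config(params, gears, population,
             fishing_powers = cfg$fishing_powers %||% 1,
             target_per_gear = cfg$target_per_gear,
             seed = cfg$seed %||% 1,
             replicates = cfg$replicates %||% 1)
}
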