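# Conditional Poisson likelihood with profiled abundances.
#
# Catches n_ij are modelled as independent Poisson draws with mean
# f_i * mu_j * S_ij(theta). With fishing powers absorbed by per-gear
# normalization, the per-class abundances mu_j maximise the likelihood in
# closed form, mu_j = sum_i n_ij / sum_i S_ij, leaving a four-parameter
# profile likelihood that Nelder-Mead handles comfortably.

PENALTY <- 1e10  # finite stand-in for -Inf so the simplex stays informative

#' Profiled relative abundance per length class
#'
#' For fixed selectivity curves the per-class relative abundances that
#' maximise the Poisson likelihood have the closed form
#' `mu_j = sum_i n_ij / sum_i S_ij`. Classes with no catch in any gear get
#' `mu_j = 0` and drop out of the likelihood.
#'
#' @param tab A `catch_table`.
#' @param S A length-class x gear selectivity matrix matching `tab`, e.g.
#'   from [selectivity_matrix()].
#' @return A tibble with columns `length_class`, `total` (summed catch) and
#'   `mu`.
#' @export
profile_mu <- function(tab, S) {
  stopifnot(inherits(tab, "catch_table"))
  n <- catch_matrix(tab)
  if (!all(dim(S) == dim(n))) {
    abort(sprintf("Selectivity matrix is %d x %d but the table is %d x %d.",
                  nrow(S), ncol(S), nrow(n), ncol(n)))
  }
  tot <- unname(rowSums(n))
  denom <- unname(rowSums(S))
  mu <- ifelse(tot > 0, tot / denom, 0)
  tibble::tibble(length_class = length_classes(tab), total = tot, mu = mu)
}

# Fast likelihood kernel on precomputed pieces; theta is the natural-scale
# parameter vector. Returns the negative log-likelihood without the
# parameter-free ln(n!) term.
nll_kernel <- function(theta, n, lc, family, mesh_size) {
  logS <- matrix(0, length(lc), length(family))
  lt <- log(lc)
  for (i in seq_along(family)) {
    if (family[i] == "mesh") {
      mode <- theta[1] * mesh_size[i]
      beta <- (-mode + sqrt(mode^2 + 4 * theta[2])) / 2
      alpha <- mode / beta + 1
      logS[, i] <- (alpha - 1) * (lt - log(mode)) + (mode - lc) / beta
    } else {
      mode <- exp(theta[3] - theta[4]^2)
      logS[, i] <- dlnorm(lc, theta[3], theta[4], log = TRUE) -
        dlnorm(mode, theta[3], theta[4], log = TRUE)
    }
  }
  tot <- rowSums(n)
  keep <- tot > 0
  denom <- rowSums(exp(logS))
  if (any(keep & (!is.finite(denom) | denom <= 0))) return(PENALTY)
  logmu <- log(tot[keep]) - log(denom[keep])
  pos <- n[keep, , drop = FALSE] > 0
  ll_obs <- sum((n[keep, , drop = FALSE] *
                   (logmu + logS[keep, , drop = FALSE]))[pos])
  if (!is.finite(ll_obs)) return(PENALTY)
  # sum_ij mu_j S_ij = sum_j tot_j once mu is profiled
  -(ll_obs - sum(tot[keep]))
}

#' Negative profile log-likelihood
#'
#' The Poisson log-likelihood kernel
#' `sum_ij [n_ij * ln(mu_j * S_ij) - mu_j * S_ij]` with the abundances
#' `mu_j` replaced by their closed-form maximisers ([profile_mu()]), negated.
#' The parameter-free `ln(n_ij!)` term is omitted; it shifts the value by a
#' constant (and is undefined for non-integer frequencies) but leaves the
#' maximiser unchanged. Length classes with zero total catch contribute
#' nothing. Invalid parameters return `+Inf` with a warning rather than
#' erroring, so an optimizer can step back into the admissible region.
#'
#' @param params A [selectivity_params] object (or a length-4 numeric).
#' @param tab A `catch_table`; typically per-gear normalised frequencies
#'   ([normalize_catch()]), though raw counts are accepted.
#' @return A scalar.
#' @export
negative_loglik <- function(params, tab) {
  stopifnot(inherits(tab, "catch_table"))
  params <- tryCatch(as_selectivity_params(params), error = function(e) {
    warn(paste0("Invalid parameters, returning +Inf: ", conditionMessage(e)))
    NULL
  })
  if (is.null(params)) return(Inf)
  g <- gear_info(tab)
  nll_kernel(params_vector(params), catch_matrix(tab), length_classes(tab),
             g$family, g$mesh_size)
}

#' Heuristic starting values
#'
#' Starting points for the optimizer, built from the shape of the observed
#' length-frequency distributions: the mode of a gear's catch curve sits near
#' the mode of its selectivity curve, and two-thirds of the occupied length
#' range of that gear gives a workable scale for the curve's spread.
#' Concretely, with `m*` the modal class of the first mesh gear and `w` its
#' occupied range, `theta1_0 = m*/mesh` and `theta2_0 = (2/3) w`; for the
#' predator, two-thirds of the occupied range on the log scale (divided by 4,
#' reading the range as roughly +/- 2 standard deviations) gives `theta4_0`,
#' and `theta3_0 = ln(modal class) + theta4_0^2` puts the initial lognormal
#' mode on the predator's modal class. Gears occupying a single class fall
#' back to `theta2_0 = 10` and `theta4_0 = 0.5`; tables without a predator
#' gear use the defaults `theta3_0 = ln(10) + theta4_0^2`, `theta4_0 = 0.5`.
#'
#' @param tab A `catch_table`.
#' @return A [selectivity_params] object with all components positive.
#' @export
init_params <- function(tab) {
  stopifnot(inherits(tab, "catch_table"))
  n <- catch_matrix(tab)
  lc <- length_classes(tab)
  g <- gear_info(tab)
  occupied <- function(i) lc[n[, i] > 0]
  modal <- function(i) lc[which.max(n[, i])]

  mesh_idx <- which(g$family == "mesh")
  if (length(mesh_idx)) {
    i <- mesh_idx[1]
    theta1 <- modal(i) / g$mesh_size[i]
    w <- diff(range(occupied(i)))
    theta2 <- if (w > 0) (2 / 3) * w else 10
  } else {
    theta1 <- 0.7
    theta2 <- 10
  }
  pred_idx <- which(g$family == "predator")
  if (length(pred_idx)) {
    i <- pred_idx[1]
    occ <- occupied(i)
    wlog <- diff(range(log(occ)))
    theta4 <- if (wlog > 0) (2 / 3) * wlog / 4 else 0.5
    theta3 <- log(modal(i)) + theta4^2
  } else {
    theta4 <- 0.5
    theta3 <- log(10) + theta4^2
  }
  selectivity_params(theta1, theta2, theta3, theta4)
}

#' Fit the joint selectivity model
#'
#' Maximises the profile likelihood ([negative_loglik()]) over the four
#' curve parameters with the Nelder-Mead simplex. The search runs on the log
#' of each parameter, which enforces positivity without constraints; after
#' the first run the simplex is restarted once from the incumbent to guard
#' against premature collapse. By default the table is first converted to
#' per-gear normalised frequencies, the preprocessing under which data from
#' gears with unknown, unequal fishing powers are comparable; set
#' `normalize = FALSE` to fit raw counts (all fishing powers assumed equal).
#'
#' @param tab A `catch_table`.
#' @param init Optional [selectivity_params] starting point; default
#'   [init_params()].
#' @param normalize Normalise per gear before fitting (default `TRUE`).
#' @param control Passed to [stats::optim()]'s control list; defaults
#'   `reltol = 1e-10`, `maxit = 5000`.
#' @param se Compute standard errors from the observed information
#'   (default `TRUE`).
#' @return An object of class `selectivity_fit` with elements `params`
#'   (the MLE), `std_errors`, `loglik` (maximised kernel value), `mu`
#'   (profiled abundances, a tibble), `converged`, `n_evals`, `init`,
#'   `normalized` and `table` (the data as fitted). Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`.
#' @examples
#' \donttest{
#' fit <- fit_selectivity(curonian_perch())
#' tidy(fit)
#' }
#' @export
fit_selectivity <- function(tab, init = NULL, normalize = TRUE,
                            control = list(), se = TRUE) {
  validate_catch_table(tab)
  g <- gear_info(tab)
  n_occ <- sum(rowSums(catch_matrix(tab)) > 0)
  if (nrow(g) < 2 && n_occ < 2) {
    abort("Degenerate table: a single gear with a single occupied class.")
  }
  did_normalize <- FALSE
  if (normalize && !is_normalized(tab)) {
    tab <- normalize_catch(tab)
    did_normalize <- TRUE
  }
  init <- if (is.null(init)) init_params(tab) else as_selectivity_params(init)
  ctrl <- modifyList(list(reltol = 1e-10, maxit = 5000), control)

  n <- catch_matrix(tab)
  lc <- length_classes(tab)
  fn <- function(lth) nll_kernel(exp(lth), n, lc, g$family, g$mesh_size)

  o1 <- optim(log(params_vector(init)), fn, method = "Nelder-Mead",
              control = ctrl)
  o2 <- optim(o1$par, fn, method = "Nelder-Mead", control = ctrl)
  converged <- o2$convergence == 0
  if (!converged) {
    warn("Nelder-Mead did not converge; returning the best point found.")
  }
  params <- as_selectivity_params(exp(o2$par))
  S <- selectivity_matrix(tab, params)
  mu <- profile_mu(tab, S)

  std_errors <- rep(NA_real_, 4)
  names(std_errors) <- names(params_vector(params))
  if (se) std_errors <- standard_errors(params, tab)

  structure(list(params = params,
                 std_errors = std_errors,
                 loglik = -o2$value,
                 mu = mu,
                 converged = converged,
                 n_evals = unname(o1$counts[1] + o2$counts[1]),
                 init = init,
                 normalized = is_normalized(tab),
                 did_normalize = did_normalize,
                 control = ctrl,
                 table = tab),
            class = "selectivity_fit")
}

#' Observed-information standard errors
#'
#' Standard errors as the square roots of the diagonal of the inverse
#' numerical Hessian of [negative_loglik()] at the estimate (central
#' differences with Richardson extrapolation, via \pkg{numDeriv}). If the
#' Hessian is not positive definite the SEs are reported as `NA` with a
#' warning and the attribute `positive_definite = FALSE` — never fabricated.
#' Note that SEs computed on per-gear normalised frequencies inherit that
#' scale: frequencies carry less Poisson information than the raw counts
#' they came from.
#'
#' @param params The fitted [selectivity_params] (a local minimum of the
#'   negative log-likelihood).
#' @param tab The `catch_table` the fit used (same normalization state).
#' @return Named numeric vector of four SEs, with attribute
#'   `positive_definite`.
#' @export
standard_errors <- function(params, tab) {
  params <- as_selectivity_params(params)
  g <- gear_info(tab)
  n <- catch_matrix(tab)
  lc <- length_classes(tab)
  fn <- function(th) nll_kernel(th, n, lc, g$family, g$mesh_size)
  H <- numDeriv::hessian(fn, params_vector(params))
  nm <- names(params_vector(params))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)) || min(ev) <= 0) {
    warn("Hessian not positive definite; standard errors undefined.")
    out <- setNames(rep(NA_real_, 4), nm)
    attr(out, "positive_definite") <- FALSE
    return(out)
  }
  out <- setNames(sqrt(diag(solve(H))), nm)
  attr(out, "positive_definite") <- TRUE
  out
}
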