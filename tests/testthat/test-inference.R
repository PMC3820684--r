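test_that("profiled abundances follow the closed form", {
  tab <- as_catch_table(data.frame(length_class = c(10, 12),
                                   A = c(3, 0), B = c(5, 0)),
                        predators = c("A", "B"))
  S <- matrix(1, 2, 2, dimnames = list(c(10, 12), c("A", "B")))
  mu <- profile_mu(tab, S)
  expect_equal(mu$mu, c(4, 0))  # (3 + 5) / (1 + 1); all-zero class -> 0
  expect_error(profile_mu(tab, matrix(1, 3, 2)), "matrix is")
})

test_that("closed-form mu matches per-class numerical maximization to 1e-6", {
  tab <- normalize_catch(curonian_perch())
  th <- ref_params()
  S <- selectivity_matrix(tab, th)
  mu <- profile_mu(tab, S)
  n <- catch_matrix(tab)
  for (j in seq_len(nrow(n))) {
    if (sum(n[j, ]) == 0) next
    # per-class Poisson log-likelihood in mu_j alone
    f <- function(m) sum(n[j, ] * log(m * S[j, ]) - m * S[j, ])
    opt <- optimize(f, c(1e-8, 10 * mu$mu[j] + 1), maximum = TRUE,
                    tol = 1e-10)
    expect_equal(mu$mu[j], opt$maximum, tolerance = 1e-6)
    # profile consistency: perturbing mu_j never increases the likelihood
    expect_lte(f(mu$mu[j] * 1.05), f(mu$mu[j]))
    expect_lte(f(mu$mu[j] * 0.95), f(mu$mu[j]))
  }
})

test_that("the likelihood kernel collapses to 1 for a single normalized cell", {
  tab <- as_catch_table(data.frame(length_class = 10, G14 = 1),
                        normalized = TRUE)
  # mu profiles to 1/S so mu * S = 1: kernel = -(1 * ln 1 - 1) = 1
  expect_equal(negative_loglik(ref_params(), tab), 1)
  expect_equal(negative_loglik(selectivity_params(2, 30, 1, 1), tab), 1)
})

test_that("invalid parameters give +Inf with a warning, not an error", {
  tab <- small_table()
  expect_warning(v <- negative_loglik(c(-1, 12, 2, 0.4), tab), "Invalid")
  expect_identical(v, Inf)
})

test_that("the fitted point is a local minimum of the kernel", {
  tab <- normalize_catch(curonian_perch())
  fit <- fit_selectivity(tab, se = FALSE)
  v0 <- negative_loglik(fit$params, tab)
  th <- unlist(fit$params)
  for (k in 1:4) {
    for (d in c(-0.1, 0.1)) {
      pert <- th
      pert[k] <- pert[k] + d
      expect_gt(negative_loglik(pert, tab), v0)
    }
  }
})

test_that("the MLE is invariant to a common rescaling of all gears", {
  tab <- small_table()
  fit1 <- fit_selectivity(tab, normalize = FALSE, se = FALSE)
  scaled <- as_catch_table(
    dplyr::mutate(tibble::as_tibble(tab), catch = catch * 2.5),
    gears = gear_info(tab))
  fit2 <- fit_selectivity(scaled, normalize = FALSE, se = FALSE,
                          init = fit1$init)
  expect_equal(unlist(fit1$params), unlist(fit2$params), tolerance = 1e-4)
})

test_that("starting values follow the frequency-shape heuristics", {
  tab <- curonian_perch()
  init <- init_params(tab)
  # modal class of the first mesh gear (11 cm in G14) over its mesh size
  expect_equal(init$theta1, 11 / 14)
  # two-thirds of G14's occupied range (10-20 cm)
  expect_equal(init$theta2, (2 / 3) * 10)
  # predator: initial lognormal mode sits on the predator's modal class (8 cm)
  expect_equal(exp(init$theta3 - init$theta4^2), 8)
  expect_true(all(unlist(init) > 0))

  # single-occupied-class gears fall back to documented defaults
  tiny <- as_catch_table(data.frame(length_class = c(10, 11),
                                    G14 = c(7, 0), GC = c(3, 0)),
                         predators = "GC")
  i2 <- init_params(tiny)
  expect_equal(i2$theta2, 10)
  expect_equal(i2$theta4, 0.5)

  # predator-free tables still initialize all four components positive
  mesh_only <- as_catch_table(data.frame(length_class = 9:12,
                                         G14 = c(1, 5, 3, 1)))
  expect_true(all(unlist(init_params(mesh_only)) > 0))
})

test_that("fit recovers the truth exactly from noise-free expected counts", {
  truth <- selectivity_params(0.7, 12, 2.1, 0.4)
  tab <- exact_mean_table(truth)
  fit <- fit_selectivity(tab, normalize = FALSE, se = FALSE)
  expect_true(fit$converged)
  expect_equal(unlist(fit$params), unlist(truth), tolerance = 1e-3)

  # oracle: a dense 4-D grid around the truth confirms it is the optimum
  nll_hat <- negative_loglik(fit$params, tab)
  grid <- expand.grid(theta1 = 0.7 * c(0.9, 1, 1.1),
                      theta2 = 12 * c(0.9, 1, 1.1),
                      theta3 = 2.1 * c(0.95, 1, 1.05),
                      theta4 = 0.4 * c(0.9, 1, 1.1))
  vals <- apply(grid, 1, function(r) negative_loglik(r, tab))
  # the grid contains the exact truth; allow for the optimizer's own
  # terminal tolerance in this very flat bowl
  expect_true(all(vals >= nll_hat - 1e-6))
})

test_that("different admissible starts reach the same optimum", {
  tab <- curonian_perch()
  fit1 <- fit_selectivity(tab, se = FALSE)
  fit2 <- fit_selectivity(tab, init = selectivity_params(0.5, 20, 2.5, 0.6),
                          se = FALSE)
  expect_equal(unlist(fit1$params), unlist(fit2$params), tolerance = 1e-4)
})

test_that("fit results carry diagnostics and positive parameters", {
  fit <- fit_selectivity(curonian_perch())
  expect_s3_class(fit, "selectivity_fit")
  expect_true(fit$converged)
  expect_true(all(unlist(fit$params) > 0))
  expect_true(is.finite(fit$loglik))
  expect_gt(fit$n_evals, 0)
  expect_true(all(fit$mu$mu >= 0))
  expect_true(all(fit$mu$mu[fit$mu$total == 0] == 0))
  td <- tidy(fit)
  expect_equal(td$term, paste0("theta", 1:4))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$n_gears, 9)
  expect_true(gl$normalized)
})

test_that("degenerate one-gear one-class tables are refused", {
  tab <- as_catch_table(data.frame(length_class = 10, G14 = 5))
  expect_error(fit_selectivity(tab), "Degenerate")
})

test_that("standard errors come from a positive-definite observed information", {
  tab <- normalize_catch(curonian_perch())
  fit <- fit_selectivity(tab, se = FALSE)
  se <- standard_errors(fit$params, tab)
  expect_true(attr(se, "positive_definite"))
  expect_true(all(se > 0))
  expect_named(se, paste0("theta", 1:4))
})
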