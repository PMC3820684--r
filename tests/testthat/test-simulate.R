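test_that("expected catch is f * mu * S, linear in fishing power", {
  th <- ref_params()
  cfg <- sim_config(th, small_gears(), population = c(10, 20, 5),
                    length_classes = c(8, 12, 20))
  m <- expected_catch(cfg)
  S <- cbind(gamma_selectivity(c(8, 12, 20), 14, th),
             gamma_selectivity(c(8, 12, 20), 25, th),
             lognormal_selectivity(c(8, 12, 20), th))
  expect_equal(unname(m), S * c(10, 20, 5), tolerance = 1e-12)

  cfg2 <- sim_config(th, small_gears(), population = c(10, 20, 5),
                     length_classes = c(8, 12, 20),
                     fishing_powers = c(2, 1, 1))
  m2 <- expected_catch(cfg2)
  expect_equal(m2[, 1], 2 * m[, 1])
  expect_equal(m2[, 2:3], m[, 2:3])

  # target_per_gear calibrates every gear's expected total
  cfg3 <- sim_config(th, small_gears(), population = c(10, 20, 5),
                     length_classes = c(8, 12, 20), target_per_gear = 300)
  expect_equal(unname(colSums(expected_catch(cfg3))), rep(300, 3))
})

test_that("invalid configurations are rejected by field", {
  th <- ref_params()
  g <- small_gears()
  expect_error(sim_config(th, g, population = c(0, 0), length_classes = 1:2),
               "positive entry")
  expect_error(sim_config(th, g, population = c(1, -2), length_classes = 1:2),
               "non-negative")
  expect_error(sim_config(th, g, population = c(1, 2), length_classes = 1:2,
                          fishing_powers = c(1, -1, 1)),
               "Fishing powers")
  expect_error(sim_config(th, g, population = c(1, 2), length_classes = 1:2,
                          replicates = 0),
               "replicates")
  expect_error(sim_config(th, g, population = c(1, 2)),
               "length_classes")
})

test_that("sampling is reproducible and extensible by replicate", {
  cfg <- sim_config(ref_params(), small_gears(),
                    population = c(50, 80, 30, 10),
                    length_classes = c(8, 12, 16, 22),
                    seed = 99, replicates = 3)
  a <- sample_catch(cfg)
  b <- sample_catch(cfg)
  expect_identical(lapply(a, catch_matrix), lapply(b, catch_matrix))
  # replicate r does not depend on how many replicates were requested
  five <- sample_catch(cfg, replicates = 5)
  expect_identical(lapply(five[1:3], catch_matrix), lapply(a, catch_matrix))
  # and the global RNG stream is left untouched
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(sample_catch(cfg, replicates = 1)); y <- runif(1)
  expect_identical(x, y)
})

test_that("cell means agree with the Poisson expectation over replicates", {
  cfg <- sim_config(ref_params(), small_gears(),
                    population = c(60, 90, 40),
                    length_classes = c(8, 12, 18),
                    seed = 5, replicates = 400)
  m <- expected_catch(cfg)
  sims <- sample_catch(cfg)
  avg <- Reduce(`+`, lapply(sims, catch_matrix)) / length(sims)
  se <- sqrt(m / length(sims))
  expect_true(all(abs(avg - m) <= 4 * pmax(se, 1e-12) + 1e-9))
})

test_that("a Table-1-scale configuration reproduces the observed gear totals", {
  tab <- curonian_perch()
  th <- ref_params()
  pop <- population_from_table(tab, th)
  obs <- colSums(catch_matrix(tab))
  cfg <- sim_config(th, tab, pop,
                    fishing_powers = obs / colSums(expected_catch(
                      sim_config(th, tab, pop))),
                    seed = 12, replicates = 50)
  expected_totals <- colSums(expected_catch(cfg))
  expect_equal(unname(expected_totals), unname(obs), tolerance = 1e-9)
  sims <- sample_catch(cfg)
  totals <- t(vapply(sims, function(s) colSums(catch_matrix(s)), obs))
  z <- abs(colMeans(totals) - obs) / sqrt(obs / nrow(totals))
  expect_true(all(z < 4))
})

test_that("recovery_experiment fits every replicate and summarises bias", {
  truth <- selectivity_params(0.7, 12, 2.1, 0.4)
  cfg <- sim_config(truth, small_gears(),
                    population = 150 * exp(-((seq(4, 30, 2) - 11)^2) / 60),
                    length_classes = seq(4, 30, 2),
                    seed = 31, replicates = 5)
  res <- recovery_experiment(cfg, se = FALSE, normalize = FALSE)
  expect_equal(nrow(res), 5)
  expect_true(all(res$converged))
  s <- summarize_recovery(res)
  expect_equal(s$term, paste0("theta", 1:4))
  expect_equal(s$convergence_rate, rep(1, 4))
  expect_true(all(is.finite(s$rmse)))
  expect_error(summarize_recovery(tibble::tibble(a = 1)),
               "recovery_experiment")
})

test_that("starting at the truth converges immediately", {
  truth <- selectivity_params(0.7, 12, 2.1, 0.4)
  tab <- exact_mean_table(truth)
  fit <- fit_selectivity(tab, init = truth, normalize = FALSE, se = FALSE)
  expect_true(fit$converged)
  expect_equal(unlist(fit$params), unlist(truth), tolerance = 1e-4)
})

test_that("simulation configs round-trip through YAML and JSON", {
  path <- system.file("extdata", "sim_config.yml", package = "gearselect")
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$replicates, 3)
  expect_equal(unname(colSums(expected_catch(cfg))), rep(500, 3),
               tolerance = 1e-9)

  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    params = list(theta1 = 0.7, theta2 = 12, theta3 = 2.1, theta4 = 0.4),
    gears = c("G14", "G25"),
    population = list(length_class = c(8, 12, 16), mu = c(5, 9, 4)),
    seed = 3, replicates = 2), js, auto_unbox = TRUE)
  cfg2 <- read_sim_config(js)
  expect_equal(nrow(cfg2$gears), 2)
  expect_equal(cfg2$seed, 3L)

  broken <- tempfile(fileext = ".yml")
  writeLines(c("params:", "  theta1: 0.7"), broken)
  expect_error(read_sim_config(broken), "field missing")
})
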