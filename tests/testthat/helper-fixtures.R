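# Shared fixtures, built in code.

# Point estimates from the published analysis of the bundled data; used as a
# convenient, well-behaved parameter set throughout the suite.
ref_params <- function() selectivity_params(0.71, 12.94, 2.13, 0.41)

# Two mesh nets and a predator over a coarse grid.
small_gears <- function() {
  gear_spec(c("G14", "G25", "GC"), c("mesh", "mesh", "predator"),
            c(14, 25, NA))
}

# A small raw-count table with both families occupied.
small_table <- function() {
  as_catch_table(data.frame(
    length_class = c(6, 8, 10, 12, 14, 16, 18, 20),
    G14 = c(0, 1, 12, 30, 18, 5, 1, 0),
    G25 = c(0, 0, 0, 2, 9, 25, 22, 8),
    GC = c(14, 40, 35, 18, 9, 4, 1, 0)), predators = "GC")
}

# Table whose cells are the exact Poisson means at `params`: the likelihood
# is maximised exactly at the generating parameters.
exact_mean_table <- function(params, gears = small_gears(),
                             length_classes = seq(4, 30, by = 2),
                             mu = NULL) {
  if (is.null(mu)) mu <- 100 * exp(-0.1 * (length_classes - 10)^2 / 40)
  cfg <- sim_config(params, gears, population = mu,
                    length_classes = length_classes)
  m <- expected_catch(cfg)
  dat <- data.frame(length_class = as.numeric(rownames(m)), m,
                    check.names = FALSE)
  as_catch_table(dat, gears = gears)
}
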