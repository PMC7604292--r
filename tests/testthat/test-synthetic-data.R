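test_that("simulated dosages stay in the 0/1/2 domain and respect the seed", {
  cfg <- sim_config(n_lines = 2, n_markers = 1, maf_range = c(0.5, 0.5),
                    n_founders = NULL, true_components = feature_panel(2),
                    seed = 3)
  mk <- simulate_genotypes(cfg)
  expect_true(all(mk %in% c(0, 1, 2)))
  expect_identical(unclass(simulate_genotypes(cfg)), unclass(mk))
  # related simulation stays in domain too
  cfg2 <- sim_config(n_lines = 30, n_markers = 100, n_founders = 8,
                     geno_missing_rate = 0.05,
                     true_components = feature_panel(2), seed = 3)
  mk2 <- simulate_genotypes(cfg2)
  expect_true(all(is.na(mk2) | mk2 %in% c(0, 1, 2)))
  expect_gt(sum(is.na(mk2)), 0)
})

test_that("founder crossing induces relatedness visible in G", {
  base <- list(n_lines = 150, n_markers = 1500,
               true_components = feature_panel(2), seed = 21)
  g_rel <- build_grm(simulate_genotypes(do.call(sim_config, c(base, n_founders = 10, n_self = 0))))
  g_unrel <- build_grm(simulate_genotypes(do.call(sim_config, c(base, list(n_founders = NULL)))))
  mo <- function(g) mean(abs(g$G[upper.tri(g$G)]))
  expect_gt(mo(g_rel), mo(g_unrel))
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(maf_range = c(0, 0)), "degenerate")
  expect_error(sim_config(maf_range = c(0.2, 0.1)), "0.5")
  expect_error(sim_config(true_components = matrix(-1, 1, 6)), "nonnegative")
})

test_that("the design has location x year environments and target replication", {
  cfg <- sim_config(n_lines = 565, n_locations = 2, n_years = 3,
                    reps_per_line = 4.65, true_components = feature_panel(2),
                    seed = 4)
  d <- simulate_design(cfg)
  expect_equal(length(unique(d$env)), 6L)
  expect_equal(nrow(d) / 565, 4.65, tolerance = 0.001)
  expect_true(all(table(d$line) >= 1))
  # trials are nested in environments
  expect_true(all(startsWith(d$trial, d$env)))
  # single line, single plot
  cfg1 <- sim_config(n_lines = 1, n_locations = 1, n_years = 1,
                     trials_per_env = 1, reps_per_line = 1,
                     true_components = feature_panel(2), seed = 4)
  d1 <- simulate_design(cfg1)
  expect_equal(nrow(d1), 1L)
  expect_error(simulate_design(sim_config(n_lines = 2, n_years = 1,
                                          trials_per_env = 5,
                                          true_components = feature_panel(2))),
               "more trials")
})

test_that("phenotype simulation is deterministic and honours the model", {
  fx <- small_sim(n_lines = 20, n_features = 2, seed = 77)
  fx2 <- small_sim(n_lines = 20, n_features = 2, seed = 77)
  expect_identical(fx$sim$features, fx2$sim$features)
  expect_identical(fx$sim$traits, fx2$sim$traits)

  # pure noise: all components zero except residual
  tc <- matrix(c(0, 0, 0, 0, 0, 1), 1)
  cfg <- sim_config(n_lines = 30, n_markers = 300, n_founders = 8,
                    reps_per_line = 3, true_components = tc, fixed_sd = 0,
                    seed = 5)
  mk <- simulate_genotypes(cfg); d <- simulate_design(cfg)
  sim <- simulate_phenotypes(mk, d, cfg)
  expect_equal(sim$truth$h2[[1]], 0)
  expect_true(all(sim$truth$g[, 1] == 0))
  expect_equal(var(sim$features[, 1]), 1, tolerance = 0.35)

  # only genomic variance: plots of the same line in one environment agree
  tc2 <- matrix(c(1, 0, 0, 0, 0, 0), 1)
  cfg2 <- sim_config(n_lines = 5, n_markers = 200, n_founders = 6,
                     n_locations = 1, n_years = 1, trials_per_env = 1,
                     reps_per_line = 3, true_components = tc2, fixed_sd = 0,
                     dilution_sd = 0, seed = 6)
  mk2 <- simulate_genotypes(cfg2); d2 <- simulate_design(cfg2)
  sim2 <- simulate_phenotypes(mk2, d2, cfg2)
  same <- d2$line == d2$line[1]
  expect_lt(diff(range(sim2$features[same, 1])), 1e-10)
})

test_that("realised genomic effects match the requested covariance scale", {
  fx <- small_sim(n_lines = 100, n_features = 1, seed = 31, h2 = 0.3)
  grm <- fx$sim$grm
  # across fresh effect realisations, mean square of g approaches Gbar*sigma_g
  msq <- vapply(1:25, function(r) {
    cfg_r <- fx$cfg; cfg_r$seed <- 1000L + r
    s <- simulate_phenotypes(fx$markers, fx$design, cfg_r)
    mean(s$truth$g[, 1]^2)
  }, numeric(1))
  expect_equal(mean(msq), grm$g_bar * 0.3, tolerance = 0.15)
})

test_that("a unit genetic covariance yields correlation near one", {
  n_f <- 1
  ts <- list(TT = list(variances = c(g = 0.3, l = 0.05, ig = 0.05, il = 0.1, t = 0.05, e = 0.45),
                       cov_g = sqrt(0.3 * 0.3), cov_e = 0, missing_rate = 0))
  fx <- small_sim(n_lines = 200, n_features = n_f, seed = 41, trait_specs = ts)
  g <- fx$sim$truth$g
  expect_equal(fx$sim$truth$r_g[1, 1], 1)
  expect_gt(cor(g[, 1], g[, 2]), 0.99)
  expect_true(all(fx$sim$truth$h2 >= 0 & fx$sim$truth$h2 <= 1))
  expect_true(all(abs(fx$sim$truth$r_p) <= 1, na.rm = TRUE))
})

test_that("inconsistent covariance requests fail with the offending block", {
  ts <- list(BG = list(variances = c(g = 0.1, l = 0, ig = 0, il = 0, t = 0, e = 0.9),
                       cov_g = 0.5, cov_e = 0, missing_rate = 0))
  expect_error(sim_config(true_components = matrix(c(0.3, 0, 0, 0, 0, 0.7), 1),
                          trait_specs = ts),
               "genetic covariance block.*not PSD")
})
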