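ctl_w <- function(...) reml_control(on_nonconvergence = "warning", ...)

test_that("identical responses give genetic correlation at the +1 boundary", {
  fx <- small_sim(n_lines = 40, n_features = 1, seed = 51)
  y <- fx$sim$features[, 1]
  # exact duplicate: V is singular at the optimum, but the genetic block must
  # still be driven to the correlation-1 boundary
  mod <- build_design(fx$design, fx$sim$grm, cbind(y, y))
  fit <- suppressWarnings(reml_fit_bivariate(mod, control = ctl_w(max_iter = 60L)))
  expect_gt(genetic_correlation(fit)$estimate, 0.95)
  # near-duplicate (1% independent noise): all shared blocks approach
  # correlation 1 and the phenotypic correlation follows
  set.seed(511)
  y2 <- y + rnorm(length(y), sd = 0.1 * sd(y))
  mod2 <- build_design(fx$design, fx$sim$grm, cbind(y, y2))
  fit2 <- suppressWarnings(reml_fit_bivariate(mod2, control = ctl_w(max_iter = 60L)))
  expect_gt(phenotypic_correlation(fit2)$estimate, 0.9)
  # every shared term with positive variance sits at its correlation boundary
  for (b in fit2$blocks) {
    if (b[1, 1] > 1e-6 && b[2, 2] > 1e-6)
      expect_gt(b[1, 2] / sqrt(b[1, 1] * b[2, 2]), 0.9)
  }
})

test_that("independently simulated responses show no systematic covariance", {
  np <- 6
  tc <- matrix(rep(c(0.3, 0.1, 0.1, 0.1, 0.1, 0.3), np), nrow = np, byrow = TRUE)
  ts <- lapply(seq_len(np), function(j)
    list(variances = c(g = 0.3, l = 0.05, ig = 0.05, il = 0.1, t = 0.05, e = 0.45),
         cov_g = rep(0, np), cov_e = rep(0, np), missing_rate = 0))
  names(ts) <- sprintf("T%02d", seq_len(np))
  cfg <- sim_config(n_lines = 80, n_markers = 800, n_founders = 15, n_self = 0,
                    reps_per_line = 3, true_components = tc, trait_specs = ts,
                    seed = 52)
  mk <- simulate_genotypes(cfg); d <- simulate_design(cfg)
  sim <- simulate_phenotypes(mk, d, cfg)
  zs <- vapply(seq_len(np), function(j) {
    mod <- build_design(d, sim$grm, cbind(sim$features[, j], sim$traits[[j + 1L]]))
    fit <- suppressWarnings(reml_fit_bivariate(mod, control = ctl_w()))
    rg <- genetic_correlation(fit)
    if (is.finite(rg$z)) rg$z else 0
  }, numeric(1))
  # under the null of no genetic covariance, z scores are not systematically
  # large; the mean of 6 independent pairs stays well inside +-2/sqrt(6)
  expect_lt(abs(mean(zs)), 2.5 / sqrt(np) * 2)
})

test_that("the bivariate fitter matches a grid search over the genetic block", {
  fx <- small_sim(n_lines = 25, n_features = 1, seed = 53,
                  trait_specs = list(TT = list(
                    variances = c(g = 0.3, l = 0.05, ig = 0.05, il = 0.1, t = 0.05, e = 0.45),
                    cov_g = -0.12, cov_e = 0, missing_rate = 0)))
  mod <- build_design(fx$design, fx$sim$grm,
                      cbind(fx$sim$features[, 1], fx$sim$traits$TT),
                      terms = c("g", "l"))
  fit <- suppressWarnings(reml_fit_bivariate(mod, control = ctl_w()))
  expect_equal(restricted_loglik(mod, fit$components), fit$loglik, tolerance = 1e-8)
  # grid over the genetic block with the other parameters held at the fit
  th <- fit$components
  gv <- seq(0.02, 1.22, by = 0.08)
  cv <- seq(-0.6, 0.6, by = 0.08)
  best <- -Inf; arg <- NULL
  for (a in gv) for (b in gv) for (cc in cv) {
    if (cc^2 > a * b) next
    th2 <- th; th2[c("g_v1", "g_v2", "g_cov")] <- c(a, b, cc)
    ll <- restricted_loglik(mod, th2)
    if (ll > best) { best <- ll; arg <- c(a, b, cc) }
  }
  expect_gte(fit$loglik, best - 1e-6)
  # along a flat likelihood ridge the coarse-grid argmax can sit a cell or
  # two away; require agreement within two grid steps and require the grid
  # cell containing the fit to be as good as the grid optimum
  expect_lt(max(abs(th[c("g_v1", "g_v2", "g_cov")] - arg)), 2 * 0.08 + 1e-9)
  near <- function(x, grid) grid[which.min(abs(grid - x))]
  th_near <- th
  th_near[c("g_v1", "g_v2", "g_cov")] <- c(near(th[["g_v1"]], gv), near(th[["g_v2"]], gv),
                                           near(th[["g_cov"]], cv))
  expect_gte(restricted_loglik(mod, th_near), best - 0.5)
})

test_that("missing trait records are handled with unequal row sets", {
  fx <- small_sim(n_lines = 30, n_features = 1, seed = 54)
  y1 <- fx$sim$features[, 1]
  y2 <- fx$sim$traits[[2]]
  y2[1:10] <- NA
  mod <- build_design(fx$design, fx$sim$grm, cbind(y1, y2))
  expect_equal(mod$meta$n_obs, c(sum(!is.na(y1)), sum(!is.na(y2))))
  fit <- suppressWarnings(reml_fit_bivariate(mod, control = ctl_w()))
  expect_true(all(is.finite(fit$components)))
  # every 2x2 block is PSD at the solution
  for (b in fit$blocks) expect_gte(min(eigen(b, symmetric = TRUE)$values), -1e-10)
})

test_that("constant responses are rejected", {
  fx <- small_sim(n_lines = 10, n_features = 1, seed = 55)
  y <- fx$sim$features[, 1]
  expect_error(build_design(fx$design, fx$sim$grm, cbind(y, rep(1, length(y)))),
               "constant")
})

test_that("shared residual covariance reproduces the closed-form r_p", {
  # two traits share only residual covariance: r_p = cov_e / sqrt(sP1 sP2)
  np <- 1
  ts <- list(TT = list(variances = c(g = 0.3, l = 0.05, ig = 0.05, il = 0.1, t = 0.05, e = 0.45),
                       cov_g = 0, cov_e = 0.5 * sqrt(0.3 * 0.45), missing_rate = 0))
  fx <- small_sim(n_lines = 150, n_features = np, seed = 56, trait_specs = ts)
  truth <- fx$sim$truth$r_p[1, 1]
  mod <- build_design(fx$design, fx$sim$grm,
                      cbind(fx$sim$features[, 1], fx$sim$traits$TT))
  fit <- suppressWarnings(reml_fit_bivariate(mod, control = ctl_w()))
  rp <- phenotypic_correlation(fit)
  expect_lt(abs(rp$estimate - truth), 0.12)
  expect_true(abs(rp$estimate) <= 1)
})
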