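# balanced one-way fixture: REML equals the closed-form ANOVA estimators
oneway_model <- function(y = c(1, 2, 3, 7, 8, 9), k = 2, r = 3) {
  grp <- rep(seq_len(k), each = r)
  model_spec(y, matrix(1, k * r, 1), list(group = outer(grp, grp, "==") + 0), q = k)
}

test_that("REML reproduces balanced one-way ANOVA estimators", {
  f <- reml_fit(oneway_model())
  expect_equal(unname(f$components[["e"]]), 1, tolerance = 1e-6)
  expect_equal(unname(f$components[["group"]]), 53 / 3, tolerance = 1e-5)
  expect_true(f$converged)
})

test_that("restricted_loglik matches lme4 on a random-intercept model", {
  set.seed(11)
  k <- 8; r <- 4
  grp <- factor(rep(seq_len(k), each = r))
  y <- rnorm(k)[grp] * 1.5 + rnorm(k * r)
  mod <- oneway_model(y, k, r)
  lf <- lme4::lmer(y ~ 1 + (1 | grp), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  ours <- reml_fit(mod)
  expect_equal(unname(ours$components[["group"]]), vc$vcov[1], tolerance = 1e-4)
  expect_equal(unname(ours$components[["e"]]), vc$vcov[2], tolerance = 1e-4)
  # the restricted likelihood itself agrees at the lme4 solution
  ll_lme4 <- as.numeric(stats::logLik(lf))
  expect_equal(restricted_loglik(mod, c(group = vc$vcov[1], e = vc$vcov[2])),
               ll_lme4, tolerance = 1e-6)
})

grid_instance <- function() {
  # 12 plots, 4 lines, 2 environments, hand-built G; terms g + ig + residual
  G <- tiny_G(4)
  d <- tiny_design(n_lines = 4, n_years = 2, reps = 2, batch_size = 16)
  d <- d[-seq(1, 16, by = 4), ]   # 12 plots, every line still present
  set.seed(23)
  L <- chol(G)
  g <- drop(crossprod(L, rnorm(4))) * sqrt(0.5)
  ig <- sapply(1:2, function(e) drop(crossprod(L, rnorm(4))) * sqrt(0.3))
  ei <- match(d$env, unique(d$env))
  y <- g[match(d$line, rownames(G))] +
    ig[cbind(match(d$line, rownames(G)), ei)] + rnorm(nrow(d), sd = sqrt(0.4))
  build_design(d, as_grm(G), y, terms = c("g", "ig"))
}

test_that("the fitter matches a grid search of the restricted likelihood", {
  mod <- grid_instance()
  f <- reml_fit(mod, control = reml_control(on_nonconvergence = "warning"))
  # the reported maximum is the likelihood at the reported estimates
  expect_equal(restricted_loglik(mod, f$components), f$loglik, tolerance = 1e-8)
  # coarse grid over the three components
  gr <- seq(0.01, 2.01, by = 0.125)
  best <- -Inf; arg <- NULL
  for (a in gr) for (b in gr) for (e in gr) {
    ll <- restricted_loglik(mod, c(g = a, ig = b, e = e))
    if (ll > best) { best <- ll; arg <- c(a, b, e) }
  }
  expect_gte(f$loglik, best - 1e-6)
  expect_lt(max(abs(f$components - arg)), 0.125 + 1e-9)
})

test_that("the fitted solution beats random perturbations", {
  mod <- grid_instance()
  f <- reml_fit(mod, control = reml_control(on_nonconvergence = "warning"))
  set.seed(99)
  for (i in 1:100) {
    pert <- pmax(f$components + rnorm(3, sd = 0.05), 1e-6)
    expect_lte(restricted_loglik(mod, pert), f$loglik + 1e-8)
  }
})

test_that("accepted iterations never decrease the restricted likelihood", {
  fx <- small_sim(n_lines = 40, n_features = 1, seed = 15)
  mod <- build_design(fx$design, fx$sim$grm, fx$sim$features[, 1])
  f <- reml_fit(mod, control = reml_control(on_nonconvergence = "warning"))
  expect_true(all(diff(f$ll_path) >= -1e-8))
})

test_that("estimates are equivariant under response scaling", {
  fx <- small_sim(n_lines = 40, n_features = 1, seed = 16)
  mod1 <- build_design(fx$design, fx$sim$grm, fx$sim$features[, 1])
  mod2 <- build_design(fx$design, fx$sim$grm, 3 * fx$sim$features[, 1])
  ctl <- reml_control(on_nonconvergence = "warning")
  f1 <- reml_fit(mod1, control = ctl)
  f2 <- reml_fit(mod2, control = ctl)
  expect_equal(f2$components, 9 * f1$components, tolerance = 1e-3)
})

test_that("likelihood is invariant to shifting y when X absorbs the mean", {
  mod <- grid_instance()
  comp <- c(g = 0.4, ig = 0.2, e = 0.5)
  ll1 <- restricted_loglik(mod, comp)
  mod$y <- mod$y + 5
  expect_equal(restricted_loglik(mod, comp), ll1, tolerance = 1e-8)
})

test_that("design construction exposes the model structure", {
  fx <- small_sim(n_lines = 10, n_features = 1, seed = 18)
  mod <- build_design(fx$design, fx$sim$grm, fx$sim$features[, 1])
  # ig covariance is G within an environment, zero across environments
  same_env <- outer(fx$design$env, fx$design$env, "==") + 0
  expect_equal(mod$K$ig, mod$K$g * same_env, ignore_attr = TRUE)
  expect_equal(mod$K$il, mod$K$l * same_env, ignore_attr = TRUE)
  # missing responses are dropped row-wise
  y <- fx$sim$features[, 1]; y[c(2, 5)] <- NA
  mod2 <- build_design(fx$design, fx$sim$grm, y)
  expect_equal(mod2$n, nrow(fx$design) - 2L)
  # unknown lines are named in the error
  d_bad <- fx$design; d_bad$line[1] <- "L9999"
  expect_error(build_design(d_bad, fx$sim$grm, y), "L9999")
})

test_that("single-level terms are dropped and flagged", {
  d <- tiny_design(n_lines = 4, n_years = 2, reps = 2, batch_size = 100)
  set.seed(2)
  mod <- build_design(d, as_grm(tiny_G(4)), rnorm(nrow(d)))
  expect_false("t" %in% names(mod$K))
  expect_true("t" %in% mod$meta$dropped_terms)
})

test_that("degenerate responses are rejected", {
  d <- tiny_design(n_lines = 4, n_years = 2, reps = 2)
  expect_error(reml_fit(build_design(d, as_grm(tiny_G(4)), rep(0, nrow(d)))),
               "constant|degenerate")
})
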