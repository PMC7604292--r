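# Validation experiments: simulation studies with known ground truth used to
# check calibration and parameter recovery of the whole pipeline. Estimates
# from features that share one simulated data set are correlated (they see
# the same realised design and relationship matrix), so every experiment
# averages over independent data-set replicates and reports a Monte-Carlo
# standard error computed from the data-set means.

.recovery_components <- c(g = 0.3, l = 0.1, ig = 0.1, il = 0.1, t = 0.1, e = 0.3)

# Recovery experiments use a tight founder pool (6 founders, outbred
# crosses): strong realised relatedness is what separates the genomic term
# (covariance G) from the i.i.d. line term, and it matches the single-cluster
# population structure of elite breeding material. Outbred (unselfed) crosses
# keep the mean G diagonal near 1 so the component vector below implies a
# plot-level h2 of ~0.30.
.recovery_config <- function(n_lines, reps, n_features, trait_specs, seed) {
  sim_config(n_lines = n_lines, n_markers = 2000L, n_founders = 6L, n_self = 0L,
             n_locations = 2L, n_years = 3L, trials_per_env = 2L,
             reps_per_line = reps,
             true_components = matrix(rep(.recovery_components, each = n_features),
                                      nrow = n_features,
                                      dimnames = list(NULL, names(.recovery_components))),
             trait_specs = trait_specs, seed = seed)
}

#' Heritability parameter-recovery experiment
#'
#' Simulates independent data sets of related lines in 6 location x year
#' environments, with every feature generated at true variance components
#' (0.3, 0.1, 0.1, 0.1, 0.1, 0.3) — a plot-level heritability of 0.30 when
#' the mean G diagonal is 1, which the outbred founder-cross relatedness
#' model delivers — fits the univariate model to each feature, and reports
#' the mean estimated h2 together with its Monte-Carlo standard error over
#' data-set replicates.
#'
#' @param n_datasets independent simulated data sets.
#' @param n_features features per data set.
#' @param n_lines,reps lines and mean plots per line in each data set.
#' @param seed master seed.
#' @param control a [reml_control()] list.
#' @return a list: `h2` (all estimates), `mean`, `mc_se`, `true_mean` (mean
#'   realised true h2), `dataset_means`.
#' @export
h2_recovery_experiment <- function(n_datasets = 10L, n_features = 5L,
                                   n_lines = 200L, reps = 3, seed = 1L,
                                   control = reml_control()) {
  ts <- list(DUMMY = list(variances = .recovery_components,
                          cov_g = rep(0, n_features), cov_e = rep(0, n_features),
                          missing_rate = 0))
  h2s <- matrix(NA_real_, n_datasets, n_features)
  truth <- numeric(n_datasets)
  for (s in seq_len(n_datasets)) {
    cfg <- .recovery_config(n_lines, reps, n_features, ts, derive_seed(seed, s))
    mk <- simulate_genotypes(cfg)
    d <- simulate_design(cfg)
    sim <- simulate_phenotypes(mk, d, cfg)
    sc <- h2_scan(sim$features, d, sim$grm, control = control)
    h2s[s, ] <- sc$h2
    truth[s] <- mean(sim$truth$h2)
  }
  dm <- rowMeans(h2s)
  list(h2 = h2s, mean = mean(h2s), mc_se = stats::sd(dm) / sqrt(n_datasets),
       true_mean = mean(truth), dataset_means = dm)
}

#' Genetic-correlation parameter-recovery experiment
#'
#' Simulates independent data sets in which each feature shares additive
#' genomic effects with its own trait at a true genetic correlation `rho`,
#' fits the bivariate model per pair, and reports the mean estimated genetic
#' correlation with its Monte-Carlo standard error over data sets.
#'
#' @param n_datasets independent simulated data sets.
#' @param n_pairs feature-trait pairs per data set.
#' @param rho true genetic correlation (default -0.6).
#' @param n_lines,reps data-set dimensions.
#' @param seed master seed.
#' @param control a [reml_control()] list (non-convergence demoted to a
#'   warning; boundary pairs still contribute their estimates).
#' @return a list: `r_g` (all estimates), `mean`, `mc_se`, `dataset_means`.
#' @export
rg_recovery_experiment <- function(n_datasets = 10L, n_pairs = 3L, rho = -0.6,
                                   n_lines = 200L, reps = 3, seed = 1L,
                                   control = reml_control(max_iter = 150L,
                                                          stall_window = 15L,
                                                          stall_tol = 0.02)) {
  control$on_nonconvergence <- "warning"
  vg <- .recovery_components[["g"]]
  ts <- lapply(seq_len(n_pairs), function(j) {
    cg <- rep(0, n_pairs); cg[j] <- rho * vg
    list(variances = .recovery_components, cov_g = cg,
         cov_e = rep(0, n_pairs), missing_rate = 0.02)
  })
  names(ts) <- sprintf("T%02d", seq_len(n_pairs))
  rg <- matrix(NA_real_, n_datasets, n_pairs)
  for (s in seq_len(n_datasets)) {
    cfg <- .recovery_config(n_lines, reps, n_pairs, ts, derive_seed(seed, 100L + s))
    mk <- simulate_genotypes(cfg)
    d <- simulate_design(cfg)
    sim <- simulate_phenotypes(mk, d, cfg)
    for (j in seq_len(n_pairs)) {
      mod <- build_design(d, sim$grm,
                          cbind(sim$features[, j], sim$traits[[names(ts)[j]]]))
      fit <- suppressWarnings(reml_fit_bivariate(mod, control = control))
      rg[s, j] <- genetic_correlation(fit)$estimate
    }
  }
  # pairs whose genomic variance is pinned at zero have undefined r_g and
  # carry no information about the correlation; average over defined pairs
  dm <- rowMeans(rg, na.rm = TRUE)
  dm <- dm[is.finite(dm)]
  list(r_g = rg, mean = mean(rg, na.rm = TRUE),
       mc_se = stats::sd(dm) / sqrt(length(dm)),
       n_defined = sum(is.finite(rg)), true = rho, dataset_means = dm)
}

#' Type-I error calibration of the null-distribution cutoff
#'
#' Builds one experimental design, derives the heritability significance
#' cutoff from `n_replicates` null simulations, then generates `n_fresh`
#' further null features on the same design and measures the fraction
#' flagged. Under correct calibration that fraction is statistically
#' compatible with `alpha`.
#'
#' @param n_lines,reps design dimensions (2 locations x 3 years).
#' @param n_replicates null replicates behind the cutoff.
#' @param n_fresh fresh null features scored against the cutoff.
#' @param alpha upper-tail probability (default 0.01).
#' @param seed master seed.
#' @param control a [reml_control()] list.
#' @return a list: `cutoff`, `flagged_fraction`, `n_fresh`, `binomial_ci`
#'   (95\% interval around `alpha`), plus the two null distributions.
#' @export
null_calibration_experiment <- function(n_lines = 60L, reps = 2, n_replicates = 500L,
                                        n_fresh = 500L, alpha = 0.01, seed = 1L,
                                        control = reml_control()) {
  cfg <- sim_config(n_lines = n_lines, n_markers = 800L, n_founders = 15L,
                    n_self = 0L, n_locations = 2L, n_years = 3L,
                    trials_per_env = 1L, reps_per_line = reps,
                    true_components = feature_panel(2L),
                    seed = derive_seed(seed, 7L))
  mk <- simulate_genotypes(cfg)
  d <- simulate_design(cfg)
  grm <- build_grm(mk)
  nd <- null_cutoff(d, grm, n_replicates = n_replicates, alpha = alpha,
                    seed = derive_seed(seed, 8L), control = control)
  fresh <- null_cutoff(d, grm, n_replicates = n_fresh, alpha = alpha,
                       seed = derive_seed(seed, 9L), control = control)
  frac <- mean(fresh$h2 > nd$cutoff)
  ci <- alpha + c(-1, 1) * 1.96 * sqrt(alpha * (1 - alpha) / n_fresh)
  list(cutoff = nd$cutoff, flagged_fraction = frac, n_fresh = n_fresh,
       binomial_ci = pmax(ci, 0), null = nd, fresh = fresh)
}
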