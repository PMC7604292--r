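#' Default panel of true feature variance components
#'
#' Builds a feature panel whose target plot-level heritabilities are spread
#' evenly over \[0, h2_max\]. Non-genomic components are held at modest
#' levels typical of multi-environment field trials (line 0.05, genomic x
#' environment 0.05, line x environment 0.10, batch 0.05) and the residual
#' absorbs the remainder so the phenotypic variance is near 1.
#'
#' @param n_features number of features.
#' @param h2_max largest target heritability (default 0.4).
#' @return an `n_features` x 6 matrix with columns g, l, ig, il, t, e.
#' @export
feature_panel <- function(n_features, h2_max = 0.4) {
  h2 <- if (n_features == 1L) h2_max else seq(0, h2_max, length.out = n_features)
  cbind(g = h2, l = 0.05, ig = 0.05, il = 0.10, t = 0.05,
        e = pmax(1 - h2 - 0.25, 0.15))
}

#' Default malting-quality trait specifications
#'
#' Six traits (FS, WCL, EY, WCO, BG, WV) with plot-level heritability near
#' 0.3 and, by default, no genetic or residual covariance with any feature.
#'
#' @param n_features number of features the covariance vectors refer to.
#' @return a named list of per-trait specs (`variances`, `cov_g`, `cov_e`,
#'   `missing_rate`).
#' @export
trait_specs_default <- function(n_features) {
  one <- function() list(variances = c(g = 0.3, l = 0.05, ig = 0.05, il = 0.10, t = 0.05, e = 0.45),
                         cov_g = rep(0, n_features), cov_e = rep(0, n_features),
                         missing_rate = 0.02)
  stats::setNames(lapply(1:6, function(i) one()),
                  c("FS", "WCL", "EY", "WCO", "BG", "WV"))
}

#' Simulation configuration
#'
#' Holds the design constants and ground-truth dispersion parameters for the
#' synthetic-data generator. Defaults mirror the structure of a commercial
#' spring-barley malting programme: 565 related lines genotyped at 3,889
#' SNPs with MAF at least 5\%, grown in 2 locations x 3 years (6
#' environments) with trials nested in environments, about 4.65 plots per
#' line (2,628 plots in total), and wort NMR bucket tables on a 0.70-9.00
#' ppm grid.
#'
#' @param n_lines,n_markers numbers of lines and SNP markers.
#' @param maf_range allele-frequency range (both ends in (0, 0.5\]) founder
#'   frequencies are drawn from.
#' @param n_founders founder lines for the relatedness model; `NULL` for
#'   unrelated Hardy-Weinberg lines.
#' @param n_self selfing generations after the founder cross.
#' @param geno_missing_rate fraction of dosages set missing.
#' @param n_locations,n_years,trials_per_env design constants; environments
#'   are location x year cells with trials nested inside.
#' @param reps_per_line mean number of plots per line after thinning.
#' @param batch_size consecutive plots malted/mashed per batch.
#' @param ppm_range chemical-shift range (min, max) the simulated features
#'   are placed on; the grid has one bucket per feature.
#' @param true_components per-feature true variances, an n_features x 6
#'   matrix with columns g, l, ig, il, t, e (see [feature_panel()]).
#' @param trait_specs per-trait list of variances and per-feature genetic and
#'   residual covariances (see [trait_specs_default()]).
#' @param fixed_sd standard deviation of the fixed location x year x trial
#'   cell effects.
#' @param baseline,dilution_sd additive baseline and log-normal per-plot
#'   dilution applied when emitting spectra-like bucket tables (dilution is
#'   exactly removed by PQN).
#' @param seed master seed; generator stages draw from derived sub-streams.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 565L, n_markers = 3889L, maf_range = c(0.05, 0.5),
                       n_founders = 25L, n_self = 4L, geno_missing_rate = 0,
                       n_locations = 2L, n_years = 3L, trials_per_env = 2L,
                       reps_per_line = 4.65, batch_size = 48L,
                       ppm_range = c(0.70, 9.00),
                       true_components = feature_panel(96L),
                       trait_specs = NULL,
                       fixed_sd = 0.5, baseline = 10, dilution_sd = 0.05,
                       seed = 1L) {
  if (length(maf_range) != 2L || maf_range[2] <= 0)
    .stopf("degenerate maf_range: must have positive width inside (0, 0.5]")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    .stopf("maf_range must lie within (0, 0.5]")
  stopifnot(.is_count(n_lines), .is_count(n_markers), .is_count(n_locations),
            .is_count(n_years), .is_count(trials_per_env), reps_per_line > 0,
            .is_count(batch_size), fixed_sd >= 0, dilution_sd >= 0)
  true_components <- as.matrix(true_components)
  if (ncol(true_components) != 6L) .stopf("true_components must have 6 columns (g, l, ig, il, t, e)")
  colnames(true_components) <- c("g", "l", "ig", "il", "t", "e")
  if (any(true_components < 0)) .stopf("true variance components must be nonnegative")
  n_features <- nrow(true_components)
  rownames(true_components) <- rownames(true_components) %||% sprintf("F%04d", seq_len(n_features))
  trait_specs <- trait_specs %||% trait_specs_default(n_features)
  for (tn in names(trait_specs)) {
    sp <- trait_specs[[tn]]
    if (any(sp$variances < 0)) .stopf("trait %s has negative variances", tn)
    sp$cov_g <- sp$cov_g %||% rep(0, n_features)
    sp$cov_e <- sp$cov_e %||% rep(0, n_features)
    sp$missing_rate <- sp$missing_rate %||% 0
    bad_g <- which(sp$cov_g^2 > true_components[, "g"] * sp$variances[["g"]] + 1e-12)
    if (length(bad_g)) .stopf("genetic covariance block (feature %s, trait %s) is not PSD",
                              rownames(true_components)[bad_g[1]], tn)
    bad_e <- which(sp$cov_e^2 > true_components[, "e"] * sp$variances[["e"]] + 1e-12)
    if (length(bad_e)) .stopf("residual covariance block (feature %s, trait %s) is not PSD",
                              rownames(true_components)[bad_e[1]], tn)
    trait_specs[[tn]] <- sp
  }
  structure(list(n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
                 maf_range = maf_range, n_founders = if (is.null(n_founders)) NULL else as.integer(n_founders),
                 n_self = as.integer(n_self), geno_missing_rate = geno_missing_rate,
                 n_locations = as.integer(n_locations), n_years = as.integer(n_years),
                 trials_per_env = as.integer(trials_per_env), reps_per_line = reps_per_line,
                 batch_size = as.integer(batch_size), ppm_range = ppm_range,
                 true_components = true_components, trait_specs = trait_specs,
                 fixed_sd = fixed_sd, baseline = baseline, dilution_sd = dilution_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d lines x %d markers, %d locations x %d years, ",
                     "%d features, %d traits, seed %d\n"),
              x$n_lines, x$n_markers, x$n_locations, x$n_years,
              nrow(x$true_components), length(x$trait_specs), x$seed))
  invisible(x)
}
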