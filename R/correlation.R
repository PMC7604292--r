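.block_params <- function(tm) paste0(tm, c("_v1", "_cov", "_v2"))

#' Additive genetic correlation from a bivariate fit
#'
#' `r_g = cov_g / sqrt(vg1 * vg2)` with a delta-method standard error from
#' the parameter covariance. When either genomic variance is pinned at zero
#' the correlation is undefined and a reason code is returned instead of a
#' silent zero. Estimates beyond the \[-1, 1\] boundary (possible before the
#' final PSD projection bites) are clamped and flagged.
#'
#' @param fit a [reml_fit_bivariate()] result.
#' @return a list: `estimate`, `se`, `z`, `boundary`, `reason` (NA when
#'   defined).
#' @export
genetic_correlation <- function(fit) {
  stopifnot(inherits(fit, "bivariate_components"))
  .block_correlation(fit, "g")
}

.block_correlation <- function(fit, tm) {
  pars <- .block_params(tm)
  if (!all(pars %in% names(fit$components)))
    return(list(estimate = NA_real_, se = NA_real_, z = NA_real_,
                boundary = FALSE, reason = sprintf("term_%s_absent", tm)))
  v1 <- fit$components[[pars[1]]]; cv <- fit$components[[pars[2]]]; v2 <- fit$components[[pars[3]]]
  tol <- 1e-12 * max(1, abs(fit$components))
  if (v1 <= tol || v2 <= tol)
    return(list(estimate = NA_real_, se = NA_real_, z = NA_real_,
                boundary = FALSE, reason = sprintf("zero_%s_variance", tm)))
  r_raw <- cv / sqrt(v1 * v2)
  r <- min(1, max(-1, r_raw))
  boundary <- abs(r_raw) >= 1 - 1e-8
  grad <- c(-r / (2 * v1), 1 / sqrt(v1 * v2), -r / (2 * v2))
  Vsub <- fit$vcov[pars, pars]
  se <- if (all(is.finite(Vsub))) sqrt(max(0, drop(t(grad) %*% Vsub %*% grad))) else NA_real_
  z <- if (is.finite(se) && se > 0) r / se else NA_real_
  list(estimate = r, se = se, z = z, boundary = boundary, reason = NA_character_)
}

#' Phenotypic correlation from a bivariate fit
#'
#' The phenotypic covariance mirrors the univariate phenotypic-variance
#' identity, with the average G diagonal weighting the genomic blocks:
#' `cov_P = Gbar cov_g + cov_l + Gbar cov_ig + cov_il + cov_t + cov_e`, and
#' `r_p = cov_P / sqrt(sigma_P1^2 * sigma_P2^2)`. Standard error by the
#' delta method over all dispersion parameters.
#'
#' @param fit a [reml_fit_bivariate()] result.
#' @param g_bar average diagonal of G; defaults to the value stored in the
#'   fit.
#' @return a list: `estimate`, `se`, `z`, `boundary`, `reason`.
#' @export
phenotypic_correlation <- function(fit, g_bar = NULL) {
  stopifnot(inherits(fit, "bivariate_components"))
  g_bar <- g_bar %||% fit$g_bar
  terms_all <- names(fit$blocks)
  w <- .gbar_weights(terms_all, g_bar)
  p1 <- sum(w * vapply(fit$blocks, function(b) b[1, 1], numeric(1)))
  p2 <- sum(w * vapply(fit$blocks, function(b) b[2, 2], numeric(1)))
  if (p1 <= 0 || p2 <= 0)
    return(list(estimate = NA_real_, se = NA_real_, z = NA_real_,
                boundary = FALSE, reason = "zero_phenotypic_variance"))
  cp <- sum(w * vapply(fit$blocks, function(b) b[1, 2], numeric(1)))
  r_raw <- cp / sqrt(p1 * p2)
  r <- min(1, max(-1, r_raw))
  boundary <- abs(r_raw) >= 1 - 1e-8
  pars <- names(fit$components)
  grad <- stats::setNames(numeric(length(pars)), pars)
  for (tm in terms_all) {
    grad[paste0(tm, "_cov")] <- w[[tm]] / sqrt(p1 * p2)
    grad[paste0(tm, "_v1")] <- -r * w[[tm]] / (2 * p1)
    grad[paste0(tm, "_v2")] <- -r * w[[tm]] / (2 * p2)
  }
  se <- if (all(is.finite(fit$vcov))) sqrt(max(0, drop(t(grad) %*% fit$vcov %*% grad))) else NA_real_
  z <- if (is.finite(se) && se > 0) r / se else NA_real_
  list(estimate = r, se = se, z = z, boundary = boundary, reason = NA_character_)
}

#' Two-sided z test for a correlation estimate
#'
#' Significant when `|estimate / se|` strictly exceeds `threshold`; the
#' default 2.326 corresponds to 1\% on each side of the normal distribution.
#'
#' @param estimate correlation estimate.
#' @param se positive standard error.
#' @param threshold critical value (default 2.326).
#' @return logical flag.
#' @export
z_test <- function(estimate, se, threshold = 2.326) {
  if (!is.finite(se) || se <= 0) .stopf("z_test(): se must be positive")
  abs(estimate / se) > threshold
}

#' Bivariate correlation scan of features against traits
#'
#' For each (feature, trait) pair fits the bivariate model and extracts the
#' genetic and phenotypic correlations with their z tests. Typically run on
#' the features flagged significantly heritable.
#'
#' @param features matrix (plots x features) or [standardize()] result.
#' @param traits data frame with a `plot` column and one column per trait.
#' @param design a `plot_design` data frame.
#' @param grm a [build_grm()] result.
#' @param feature_ids,trait_ids subsets to analyse (defaults: all columns).
#' @param threshold z critical value (default 2.326).
#' @param control a [reml_control()] list (non-convergence demoted to a
#'   warning so one pair cannot abort a scan).
#' @param verbose print progress.
#' @return a `correlation_result` data frame, one row per pair: `r_g`,
#'   `r_g_se`, `r_g_z`, `r_g_sig`, `r_g_boundary`, the `r_p` equivalents,
#'   and `reason` for undefined estimates.
#' @export
estimate_correlations <- function(features, traits, design, grm,
                                  feature_ids = NULL, trait_ids = NULL,
                                  threshold = 2.326, control = reml_control(),
                                  verbose = FALSE) {
  M <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  feature_ids <- feature_ids %||% colnames(M) %||% sprintf("F%04d", seq_len(ncol(M)))
  trait_ids <- trait_ids %||% setdiff(names(traits), "plot")
  stopifnot(all(feature_ids %in% colnames(M)), all(trait_ids %in% names(traits)))
  tr <- traits[match(design$plot, traits$plot), , drop = FALSE]
  control$on_nonconvergence <- "warning"
  rows <- list()
  for (f in feature_ids) for (tn in trait_ids) {
    pair <- cbind(M[, f], tr[[tn]])
    fit <- tryCatch(suppressWarnings(
      reml_fit_bivariate(build_design(design, grm, pair), control = control)),
      error = function(e) NULL)
    if (is.null(fit)) {
      rg <- rp <- list(estimate = NA_real_, se = NA_real_, z = NA_real_,
                       boundary = FALSE, reason = "fit_failed")
    } else {
      rg <- genetic_correlation(fit)
      rp <- phenotypic_correlation(fit)
    }
    sig <- function(x) if (is.finite(x$se) && x$se > 0 && is.finite(x$estimate))
      z_test(x$estimate, x$se, threshold) else NA
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, trait = tn,
      r_g = rg$estimate, r_g_se = rg$se, r_g_z = rg$z,
      r_g_sig = sig(rg), r_g_boundary = rg$boundary,
      r_p = rp$estimate, r_p_se = rp$se, r_p_z = rp$z,
      r_p_sig = sig(rp), r_p_boundary = rp$boundary,
      reason = if (!is.na(rg$reason)) rg$reason else if (!is.na(rp$reason)) rp$reason else NA_character_,
      stringsAsFactors = FALSE)
    if (verbose) message(sprintf("  pair %s x %s done (%d/%d)", f, tn,
                                 length(rows), length(feature_ids) * length(trait_ids)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Per-trait summary of correlation results
#'
#' Range of the genetic and phenotypic correlations with each trait and the
#' percentage significantly different from zero. Percentages are computed
#' over defined estimates only (pairs with a reason code are excluded and
#' the denominator reported).
#'
#' @param results an [estimate_correlations()] data frame.
#' @param trait optional single trait id; default summarises every trait.
#' @return a data frame, one row per trait.
#' @export
summarize_trait <- function(results, trait = NULL) {
  traits <- trait %||% unique(results$trait)
  rows <- lapply(traits, function(tn) {
    d <- results[results$trait == tn, , drop = FALSE]
    dg <- d[is.finite(d$r_g), , drop = FALSE]
    dp <- d[is.finite(d$r_p), , drop = FALSE]
    pct <- function(x) if (length(x)) 100 * sum(x, na.rm = TRUE) / length(x) else NA_real_
    data.frame(trait = tn, n_pairs = nrow(d),
               n_defined_g = nrow(dg),
               min_r_g = if (nrow(dg)) min(dg$r_g) else NA_real_,
               max_r_g = if (nrow(dg)) max(dg$r_g) else NA_real_,
               pct_sig_g = pct(dg$r_g_sig),
               n_defined_p = nrow(dp),
               min_r_p = if (nrow(dp)) min(dp$r_p) else NA_real_,
               max_r_p = if (nrow(dp)) max(dp$r_p) else NA_real_,
               pct_sig_p = pct(dp$r_p_sig),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Descriptive statistics for trait records
#'
#' Record count, mean, standard deviation (n-1 divisor), range and the
#' coefficient of variation `CV = 100 * SD / mean` for each trait column.
#'
#' @param traits data frame with a `plot` column and one column per trait.
#' @return a data frame, one row per trait.
#' @export
compute_descriptives <- function(traits) {
  ids <- setdiff(names(traits), "plot")
  rows <- lapply(ids, function(tn) {
    x <- traits[[tn]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) .stopf("trait %s has no records", tn)
    if (length(x) < 2L) .stopf("trait %s has fewer than 2 records", tn)
    m <- mean(x); s <- stats::sd(x)
    data.frame(trait = tn, n = length(x), mean = m, sd = s,
               min = min(x), max = max(x), cv = 100 * s / m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
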