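.gbar_weights <- function(terms, g_bar) {
  w <- stats::setNames(rep(1, length(terms)), terms)
  w[terms %in% c("g", "ig")] <- g_bar
  w
}

#' Relative variance components
#'
#' Each component's share of the plot-level phenotypic variance, with the
#' average G diagonal weighting the genomic terms:
#' `sigma_P^2 = Gbar sigma_g^2 + sigma_l^2 + Gbar sigma_ig^2 + sigma_il^2 +
#' sigma_t^2 + sigma_e^2`. The shares sum to 1.
#'
#' @param components a [reml_fit()] result or a named numeric vector.
#' @param g_bar average diagonal of G; taken from the fit when available.
#' @return named numeric vector of shares.
#' @export
compute_rvc <- function(components, g_bar = NULL) {
  if (inherits(components, "variance_components")) {
    g_bar <- g_bar %||% components$g_bar
    components <- components$components
  }
  if (is.null(g_bar) || is.na(g_bar)) .stopf("g_bar is required")
  w <- .gbar_weights(names(components), g_bar)
  wtd <- w * components
  sp2 <- sum(wtd)
  if (sp2 <= 0) .stopf("phenotypic variance is zero")
  wtd / sp2
}

#' Plot-level genomic heritability
#'
#' `h2 = Gbar * sigma_g^2 / sigma_P^2` where `sigma_P^2` is the Gbar-weighted
#' sum of all components: the heritability of a single plot measurement, not
#' of a line mean. The standard error is a delta-method extension computed
#' from the asymptotic covariance of the component estimates.
#'
#' @param components a [reml_fit()] result (a `variance_components` object).
#' @param g_bar average diagonal of G; defaults to the value stored in the
#'   fit.
#' @param feature_id optional id carried into the result.
#' @return an object of class `heritability_result`: `h2`, `sigma_p2`, `se`,
#'   `rvc`, `components`, `significant` (NA until [flag_significant()]).
#' @export
compute_h2 <- function(components, g_bar = NULL, feature_id = NA_character_) {
  stopifnot(inherits(components, "variance_components"))
  g_bar <- g_bar %||% components$g_bar
  if (is.null(g_bar) || is.na(g_bar)) .stopf("g_bar is required")
  est <- components$components
  if (any(!is.finite(est))) .stopf("non-finite component estimates")
  w <- .gbar_weights(names(est), g_bar)
  sp2 <- sum(w * est)
  if (sp2 <= 0) .stopf("phenotypic variance is zero")
  vg <- if ("g" %in% names(est)) est[["g"]] else 0
  h2 <- g_bar * vg / sp2
  grad <- -h2 * w / sp2
  if ("g" %in% names(est)) grad[["g"]] <- grad[["g"]] + g_bar / sp2
  se <- if (all(is.finite(components$vcov))) {
    sqrt(max(0, drop(t(grad) %*% components$vcov %*% grad)))
  } else NA_real_
  structure(list(feature_id = feature_id, h2 = h2, sigma_p2 = sp2, se = se,
                 rvc = w * est / sp2, g_bar = g_bar, components = est,
                 converged = components$converged, significant = NA),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("h2 = %.4f (se %.4f), sigma_P2 = %.4f%s\n", x$h2, x$se, x$sigma_p2,
              if (is.na(x$significant)) "" else if (x$significant) ", significant" else ", not significant"))
  invisible(x)
}

#' Simulation-based null distribution of the heritability estimator
#'
#' Determines the significance cutoff for plot-level genomic heritability on
#' the exact experimental design: under the null hypothesis every component
#' except the residual is zero, so each replicate draws i.i.d. standard
#' normal responses for all plots, fits the full model by REML and records
#' the estimated h2. The cutoff is the empirical upper `alpha` quantile
#' (linear interpolation) of the replicate estimates. Replicates whose fit
#' fails are retried with a fresh derived seed; more than 5\% failures abort.
#'
#' @param design a `plot_design` data frame.
#' @param grm a [build_grm()] result.
#' @param n_replicates number of null replicates (at least 100).
#' @param alpha upper-tail probability of the cutoff (default 0.01).
#' @param seed master seed for the replicate streams.
#' @param control a [reml_control()] list for the per-replicate fits.
#' @return an object of class `null_distribution`: `h2` (replicate values),
#'   `cutoff`, `alpha`, `n_replicates`, `seed`, `n_retried`.
#' @export
null_cutoff <- function(design, grm, n_replicates = 1000L, alpha = 0.01,
                        seed = 1L, control = reml_control()) {
  stopifnot(n_replicates >= 100L, alpha > 0, alpha < 1)
  template <- build_design(design, grm, rep(0, nrow(design)) + seq_len(nrow(design)))
  n <- template$n
  h2s <- numeric(n_replicates)
  n_retried <- 0L
  max_fail <- ceiling(0.05 * n_replicates)
  for (r in seq_len(n_replicates)) {
    done <- FALSE
    attempt <- 0L
    while (!done) {
      set.seed(derive_seed(seed, r + n_replicates * attempt))
      template$y <- stats::rnorm(n)
      fit <- tryCatch(reml_fit(template, control = control), error = function(e) NULL)
      if (!is.null(fit)) {
        h2s[r] <- compute_h2(fit, g_bar = grm$g_bar)$h2
        done <- TRUE
      } else {
        attempt <- attempt + 1L
        n_retried <- n_retried + 1L
        if (n_retried > max_fail)
          .stopf("more than 5%% of null replicates failed to fit (%d of %d)", n_retried, n_replicates)
      }
    }
  }
  cutoff <- unname(stats::quantile(h2s, 1 - alpha, type = 7))
  structure(list(h2 = h2s, cutoff = cutoff, alpha = alpha,
                 n_replicates = n_replicates, seed = seed, n_retried = n_retried),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %d replicates, alpha = %g, cutoff = %.4f (%d retried)\n",
              x$n_replicates, x$alpha, x$cutoff, x$n_retried))
  invisible(x)
}

#' Flag features with significant heritability
#'
#' A feature is significant when its estimated h2 is strictly larger than
#' the null-distribution cutoff.
#'
#' @param results a list of [compute_h2()] results or a data frame with an
#'   `h2` column (e.g. from [h2_scan()]).
#' @param null a [null_cutoff()] result (or a single numeric cutoff).
#' @return the input with `significant` filled in; attribute `summary` gives
#'   the count and percentage flagged.
#' @export
flag_significant <- function(results, null) {
  cutoff <- if (inherits(null, "null_distribution")) null$cutoff else as.numeric(null)
  if (is.data.frame(results)) {
    results$significant <- results$h2 > cutoff
    n_sig <- sum(results$significant, na.rm = TRUE)
    n_tot <- nrow(results)
  } else {
    results <- lapply(results, function(r) { r$significant <- r$h2 > cutoff; r })
    n_sig <- sum(vapply(results, function(r) isTRUE(r$significant), logical(1)))
    n_tot <- length(results)
  }
  pct <- if (n_tot > 0) 100 * n_sig / n_tot else 0
  attr(results, "summary") <- list(n_significant = n_sig, n_total = n_tot,
                                   percent = pct, cutoff = cutoff)
  message(sprintf("%d of %d features significant (%.2f%%) at cutoff %.4g",
                  n_sig, n_tot, pct, cutoff))
  results
}

#' Univariate heritability scan over a feature matrix
#'
#' Fits the univariate model to every feature column and collects the
#' variance components, phenotypic variance and plot-level heritability.
#'
#' @param features a [standardize()] result or a plots x features matrix
#'   (rows aligned with `design$plot`).
#' @param design a `plot_design` data frame.
#' @param grm a [build_grm()] result.
#' @param control a [reml_control()] list; non-convergence is reported as a
#'   warning so a single feature cannot abort a scan.
#' @param verbose print progress every 25 features.
#' @return a data frame, one row per feature: components, `sigma_p2`, `h2`,
#'   `h2_se`, `converged`.
#' @export
h2_scan <- function(features, design, grm, control = reml_control(), verbose = FALSE) {
  M <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  if (nrow(M) != nrow(design)) .stopf("feature rows (%d) != plots (%d)", nrow(M), nrow(design))
  control$on_nonconvergence <- "warning"
  ids <- colnames(M) %||% sprintf("F%04d", seq_len(ncol(M)))
  template <- build_design(design, grm, seq_len(nrow(design)) + 0)
  rows <- vector("list", ncol(M))
  for (j in seq_len(ncol(M))) {
    y <- M[, j]
    obs <- !is.na(y)
    mod <- if (all(obs)) { template$y <- y; template } else build_design(design, grm, y)
    fit <- suppressWarnings(reml_fit(mod, control = control))
    h <- compute_h2(fit, g_bar = grm$g_bar, feature_id = ids[j])
    rows[[j]] <- data.frame(feature = ids[j], t(fit$components),
                            sigma_p2 = h$sigma_p2, h2 = h$h2, h2_se = h$se,
                            converged = fit$converged, stringsAsFactors = FALSE)
    if (verbose && j %% 25L == 0L) message(sprintf("  fitted %d/%d features", j, ncol(M)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
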