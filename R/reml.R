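.full_K <- function(model) {
  c(model$K, list(e = diag(model$n)))
}

# per-parameter factors mapping internally scaled bivariate parameters back
# to the original response scale
.biv_fscale <- function(model) {
  scl <- model$meta$scales
  fs <- stats::setNames(rep(1, length(model$par_names)), model$par_names)
  for (tm in c(model$meta$terms, "e")) {
    fs[paste0(tm, "_v1")] <- scl[1]^2
    fs[paste0(tm, "_cov")] <- scl[1] * scl[2]
    fs[paste0(tm, "_v2")] <- scl[2]^2
  }
  fs
}

# REML log-likelihood offset from internal unit-variance scaling
.biv_ll_offset <- function(model) {
  scl <- model$meta$scales
  df <- model$meta$n_obs - model$meta$rank_X
  -sum(df * log(scl))
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML log-likelihood of the model's response under
#' `V = sum_k K_k sigma_k^2 + I sigma_e^2`, with fixed effects profiled out.
#' Used for convergence checks and brute-force validation of the fitter.
#'
#' @param model a [model_spec()] / [build_design()] result.
#' @param components named numeric vector of components, one per random term
#'   plus `e` (univariate), or one per dispersion parameter (bivariate).
#' @return the restricted log-likelihood (a scalar).
#' @export
restricted_loglik <- function(model, components) {
  stopifnot(inherits(model, "model_spec"))
  par_names <- if (model$bivariate) model$par_names else names(.full_K(model))
  if (length(components) != length(par_names))
    .stopf("expected %d components (%s), got %d", length(par_names),
           paste(par_names, collapse = ", "), length(components))
  if (!is.null(names(components))) components <- components[par_names]
  components <- as.numeric(components)
  if (model$bivariate) {
    components <- components / .biv_fscale(model)
    pc <- .reml_pieces_biv(components, model$y, model$X, model$B,
                           model$n1, model$n2, derivs = FALSE)
    if (is.null(pc)) .stopf("V is singular at the supplied components")
    return(pc$ll + .biv_ll_offset(model))
  }
  if (any(components < 0)) .stopf("variance components must be nonnegative")
  if (all(components == 0)) .stopf("components must not all be zero")
  pc <- .reml_pieces(components, model$y, model$X, .full_K(model), derivs = FALSE)
  if (is.null(pc)) .stopf("V is singular at the supplied components")
  pc$ll
}

#' Fit the univariate mixed model by AI-REML
#'
#' Maximises the restricted likelihood over the nonnegative variance
#' components with EM warm-start iterations followed by average-information
#' updates with step halving. Components whose update would go negative are
#' pinned at zero and freed again when their gradient turns positive, so
#' exact zero estimates (common for weakly heritable features) are
#' representable. Standard errors come from the inverse average-information
#' matrix at convergence.
#'
#' @param model a univariate [build_design()] / [model_spec()] result.
#' @param start optional named starting values (one per term plus `e`).
#' @param control a [reml_control()] list.
#' @return an object of class `variance_components`: fields `components`
#'   (named estimates, residual last), `se`, `vcov`, `loglik`, `converged`,
#'   `iterations`, `pinned`, `g_bar` (when built from a genomic design).
#' @export
reml_fit <- function(model, start = NULL, control = reml_control()) {
  stopifnot(inherits(model, "model_spec"), !model$bivariate)
  K <- .full_K(model)
  m <- length(K)
  vy <- stats::var(model$y)
  if (!is.finite(vy) || vy <= 0) .stopf("response is constant or degenerate")
  lower <- c(rep(0, m - 1L), 1e-8 * vy)
  q <- c(model$q, model$n)
  if (!is.null(start)) {
    start <- if (!is.null(names(start))) as.numeric(start[names(K)]) else as.numeric(start)
  } else {
    start <- vapply(K, function(Kj) {
      trn <- sum(diag(Kj))
      if (trn > 0) 0.5 * vy * model$n / (m * trn) else 0
    }, numeric(1))
  }
  pieces <- function(theta, derivs = TRUE) .reml_pieces(theta, model$y, model$X, K, derivs)
  fit <- .aireml(pieces, start = start, q = q, lower = lower,
                 control = control, vy = vy)
  fit$n <- model$n
  fit$rank_X <- ncol(model$X)
  est <- stats::setNames(fit$theta, names(K))
  dimnames(fit$vcov) <- list(names(K), names(K))
  structure(list(components = est, se = stats::setNames(fit$se, names(K)),
                 vcov = fit$vcov, loglik = fit$loglik, converged = fit$converged,
                 iterations = fit$iterations, pinned = stats::setNames(fit$pinned, names(K)),
                 score = stats::setNames(fit$score, names(K)), ll_path = fit$ll_path,
                 n = fit$n, rank_X = fit$rank_X,
                 g_bar = model$meta$g_bar %||% NA_real_,
                 dropped_terms = model$meta$dropped_terms %||% character(0)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components (REML, %s in %d iterations), logL = %.4f\n",
              if (x$converged) "converged" else "NOT converged", x$iterations, x$loglik))
  print(round(rbind(estimate = x$components, se = x$se), 6))
  invisible(x)
}

#' Fit the bivariate mixed model by AI-REML
#'
#' Expands every dispersion parameter of the univariate model to a 2 x 2
#' covariance block and maximises the joint restricted likelihood. Responses
#' are scaled to unit variance internally (estimates are reported on the
#' original scale) and the fit is warm-started from the two univariate fits
#' with zero covariances. Any indefinite block update is projected back onto
#' the PSD cone by 2 x 2 eigenvalue clipping, which keeps every implied
#' correlation inside \[-1, 1\] and lets boundary solutions (correlation of
#' exactly +/-1) be represented.
#'
#' @param model a bivariate [build_design()] result.
#' @param start optional starting values on the original scale (named
#'   `<term>_v1`, `<term>_cov`, `<term>_v2`).
#' @param control a [reml_control()] list.
#' @return an object of class `bivariate_components` with fields `components`
#'   (named vector), `blocks` (per-term 2 x 2 matrices), `se`, `vcov`,
#'   `loglik`, `converged`, `g_bar`, `n_obs`.
#' @export
reml_fit_bivariate <- function(model, start = NULL, control = reml_control()) {
  stopifnot(inherits(model, "model_spec"), model$bivariate)
  terms_all <- c(model$meta$terms, "e")
  fscale <- .biv_fscale(model)
  if (is.null(start)) {
    ctl_uni <- control
    ctl_uni$on_nonconvergence <- "warning"
    f1 <- reml_fit(model$meta$uni1, control = ctl_uni)
    f2 <- reml_fit(model$meta$uni2, control = ctl_uni)
    start <- numeric(length(model$par_names))
    names(start) <- model$par_names
    for (tm in terms_all) {
      start[paste0(tm, "_v1")] <- if (tm %in% names(f1$components)) f1$components[[tm]] else 0
      start[paste0(tm, "_v2")] <- if (tm %in% names(f2$components)) f2$components[[tm]] else 0
      start[paste0(tm, "_cov")] <- 0
    }
  } else {
    start <- as.numeric(start[model$par_names]) / fscale
  }
  pieces <- function(theta, derivs = TRUE)
    .reml_pieces_biv(theta, model$y, model$X, model$B, model$n1, model$n2, derivs)
  fit <- .aireml(pieces, start = start, q = model$q,
                 lower = model$meta$lower, blocks = model$meta$blocks,
                 control = control, vy = 1)
  est <- stats::setNames(fit$theta * fscale, model$par_names)
  vcov <- fit$vcov * outer(fscale, fscale)
  dimnames(vcov) <- list(model$par_names, model$par_names)
  blocks <- lapply(stats::setNames(terms_all, terms_all), function(tm) {
    matrix(c(est[[paste0(tm, "_v1")]], est[[paste0(tm, "_cov")]],
             est[[paste0(tm, "_cov")]], est[[paste0(tm, "_v2")]]), 2L,
           dimnames = list(c("y1", "y2"), c("y1", "y2")))
  })
  n_obs <- model$meta$n_obs
  ll <- fit$loglik + .biv_ll_offset(model)
  structure(list(components = est, blocks = blocks,
                 se = stats::setNames(fit$se * fscale, model$par_names),
                 vcov = vcov, loglik = ll, converged = fit$converged,
                 iterations = fit$iterations,
                 pinned = stats::setNames(fit$pinned, model$par_names),
                 g_bar = model$meta$g_bar %||% NA_real_,
                 terms = model$meta$terms, n_obs = n_obs),
            class = "bivariate_components")
}

#' @export
print.bivariate_components <- function(x, ...) {
  cat(sprintf("bivariate_components (REML, %s in %d iterations), logL = %.4f\n",
              if (x$converged) "converged" else "NOT converged", x$iterations, x$loglik))
  for (tm in names(x$blocks)) {
    b <- x$blocks[[tm]]
    cat(sprintf("  %-3s v1 = %.5f  cov = %.5f  v2 = %.5f\n", tm, b[1, 1], b[1, 2], b[2, 2]))
  }
  invisible(x)
}
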