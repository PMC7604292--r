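#' Construct a mixed-model specification directly
#'
#' Low-level constructor used by [build_design()] and by tests that need
#' full control over the covariance structure. The model is
#' `y = X b + sum_k u_k + e` with `u_k ~ N(0, K_k * sigma_k^2)` expressed
#' through plot-level covariance matrices `K_k = Z_k A_k Z_k'`.
#'
#' @param y numeric response vector (no missing values).
#' @param X fixed-effect design matrix; reduced to full column rank with
#'   trailing aliased columns dropped.
#' @param K named list of n x n symmetric covariance matrices, one per random
#'   term, excluding the residual (handled internally as identity).
#' @param q integer vector of level counts per term (EM denominators);
#'   defaults to `n` for each term.
#' @param meta optional list of metadata carried through to the fit.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(y, X, K, q = NULL, meta = list()) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) .stopf("model_spec(): response must not contain NA (drop rows first)")
  X <- as.matrix(X)
  if (nrow(X) != n) .stopf("X has %d rows; response has %d", nrow(X), n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    meta$aliased <- colnames(X)[drop_cols] %||% drop_cols
    X <- X[, -drop_cols, drop = FALSE]
  }
  if (n <= ncol(X)) .stopf("need more observations (%d) than fixed-effect rank (%d)", n, ncol(X))
  stopifnot(is.list(K), length(K) >= 1L)
  for (nm in names(K)) {
    if (!all(dim(K[[nm]]) == c(n, n))) .stopf("K[[%s]] is not %d x %d", nm, n, n)
  }
  structure(list(y = y, X = X, K = K, q = q %||% rep(n, length(K)),
                 n = n, bivariate = FALSE, meta = meta),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  tms <- if (isTRUE(x$bivariate)) x$meta$terms else names(x$K)
  cat(sprintf("model_spec: n = %d, fixed rank = %d, random terms: %s + residual%s\n",
              x$n, ncol(x$X), paste(tms, collapse = ", "),
              if (isTRUE(x$bivariate)) " (bivariate, 2x2 blocks)" else ""))
  invisible(x)
}

# plot-level covariance block between two row subsets for one model term
.term_block <- function(term, G, line_a, line_b, env_a, env_b, batch_a, batch_b,
                        plot_a, plot_b) {
  switch(term,
    g  = G[line_a, line_b, drop = FALSE],
    l  = outer(line_a, line_b, "==") + 0,
    ig = G[line_a, line_b, drop = FALSE] * (outer(env_a, env_b, "==") + 0),
    il = (outer(line_a, line_b, "==") & outer(env_a, env_b, "==")) + 0,
    t  = outer(batch_a, batch_b, "==") + 0,
    e  = outer(plot_a, plot_b, "==") + 0,
    .stopf("unknown term %s", term))
}

.design_indices <- function(design, grm) {
  miss <- setdiff(unique(design$line), grm$line_ids)
  if (length(miss)) .stopf("line(s) in the design absent from G: %s",
                           paste(utils::head(miss, 5), collapse = ", "))
  list(line = match(design$line, grm$line_ids),
       env = match(design$env, sort(unique(design$env))),
       batch = match(design$batch, sort(unique(design$batch))),
       plot = design$plot)
}

.term_levels <- function(term, idx) {
  switch(term,
    g = , l = length(unique(idx$line)),
    ig = , il = length(unique(paste(idx$line, idx$env))),
    t = length(unique(idx$batch)),
    length(idx$plot))
}

#' Build the mixed-model specification for one response (or a pair)
#'
#' Translates a plot design and a genomic relationship matrix into the
#' model specification: fixed location x year x trial cell effects, additive
#' genomic line effects `g` (covariance `G`), i.i.d. line effects `l`,
#' genomic x environment effects `ig` (covariance `G` within each
#' location x year environment, zero across environments, i.e. a
#' block-diagonal `diag(G, ..., G)` structure), line x environment effects
#' `il`, malting-batch effects `t`, and residual. Rows with missing response
#' are dropped. Terms with fewer than two levels (e.g. the batch term when
#' all plots share one batch) are inestimable; they are dropped and flagged
#' in `meta$dropped_terms`.
#'
#' When `response` has two columns a stacked bivariate specification is
#' returned in which every dispersion parameter is expanded to a 2 x 2
#' block (parameters `<term>_v1`, `<term>_cov`, `<term>_v2`); each response
#' keeps its own rows, so traits recorded on fewer plots than the feature
#' lose nothing.
#'
#' @param design a `plot_design` data frame (columns plot, line, location,
#'   year, env, trial, batch).
#' @param grm a [build_grm()] result covering every line in the design.
#' @param response numeric vector (one response) or two-column matrix /
#'   data frame (bivariate); `NA` entries are dropped row-wise per response.
#' @param terms random terms to include, a subset of
#'   `c("g", "l", "ig", "il", "t")`.
#' @return a `model_spec` (bivariate when `response` has two columns).
#' @export
build_design <- function(design, grm, response,
                         terms = c("g", "l", "ig", "il", "t")) {
  stopifnot(inherits(grm, "genomic_relationship"))
  terms <- match.arg(terms, several.ok = TRUE)
  if (is.matrix(response) || is.data.frame(response)) {
    response <- as.matrix(response)
    if (ncol(response) == 2L)
      return(.build_design_bivariate(design, grm, response, terms))
    if (ncol(response) != 1L) .stopf("response must have 1 or 2 columns")
    response <- response[, 1L]
  }
  if (length(response) != nrow(design))
    .stopf("response length (%d) != plot count (%d)", length(response), nrow(design))
  obs <- which(!is.na(response))
  d <- design[obs, , drop = FALSE]
  idx <- .design_indices(d, grm)
  X <- stats::model.matrix(~ 0 + cell, data.frame(cell = factor(d$trial)))
  K <- list(); q <- integer(0); dropped <- character(0)
  for (tm in terms) {
    lev <- .term_levels(tm, idx)
    if (lev < 2L) { dropped <- c(dropped, tm); next }
    K[[tm]] <- .term_block(tm, grm$G, idx$line, idx$line, idx$env, idx$env,
                           idx$batch, idx$batch, idx$plot, idx$plot)
    q[tm] <- lev
  }
  if (!length(K)) .stopf("no estimable random terms besides the residual")
  model_spec(response[obs], X, K, q = q,
             meta = list(g_bar = grm$g_bar, plots = d$plot,
                         dropped_terms = dropped, terms = names(K)))
}

.build_design_bivariate <- function(design, grm, response, terms) {
  y1 <- response[, 1L]; y2 <- response[, 2L]
  obs1 <- which(!is.na(y1)); obs2 <- which(!is.na(y2))
  if (!length(intersect(obs1, obs2)))
    .stopf("the two responses share no observed plots")
  s1 <- stats::sd(y1[obs1]); s2 <- stats::sd(y2[obs2])
  if (!is.finite(s1) || s1 == 0) .stopf("first response is constant")
  if (!is.finite(s2) || s2 == 0) .stopf("second response is constant")
  d1 <- design[obs1, , drop = FALSE]; d2 <- design[obs2, , drop = FALSE]
  i1 <- .design_indices(d1, grm); i2 <- .design_indices(d2, grm)
  n1 <- length(obs1); n2 <- length(obs2); n <- n1 + n2
  X1 <- stats::model.matrix(~ 0 + cell, data.frame(cell = factor(d1$trial)))
  X2 <- stats::model.matrix(~ 0 + cell, data.frame(cell = factor(d2$trial)))
  X <- matrix(0, n, ncol(X1) + ncol(X2))
  X[seq_len(n1), seq_len(ncol(X1))] <- X1
  X[n1 + seq_len(n2), ncol(X1) + seq_len(ncol(X2))] <- X2
  B <- list(); blocks <- list(); lower <- numeric(0); par_names <- character(0)
  use <- c(terms[vapply(terms, function(tm) {
    .term_levels(tm, i1) >= 2L || .term_levels(tm, i2) >= 2L
  }, logical(1))], "e")
  dropped <- setdiff(terms, use)
  for (tm in use) {
    B[[tm]] <- list(
      B11 = .term_block(tm, grm$G, i1$line, i1$line, i1$env, i1$env, i1$batch, i1$batch, i1$plot, i1$plot),
      B12 = .term_block(tm, grm$G, i1$line, i2$line, i1$env, i2$env, i1$batch, i2$batch, i1$plot, i2$plot),
      B22 = .term_block(tm, grm$G, i2$line, i2$line, i2$env, i2$env, i2$batch, i2$batch, i2$plot, i2$plot))
    blocks[[tm]] <- 3L * (length(B) - 1L) + 1:3
    lo <- if (tm == "e") 1e-8 else 0
    lower <- c(lower, lo, -Inf, lo)
    par_names <- c(par_names, paste0(tm, c("_v1", "_cov", "_v2")))
  }
  spec <- structure(list(y = c(y1[obs1] / s1, y2[obs2] / s2), X = X, B = B,
                         par_names = par_names, n1 = n1, n2 = n2,
                         q = rep(NA_integer_, 3L * length(B)), n = n, bivariate = TRUE,
                         meta = list(g_bar = grm$g_bar, scales = c(s1, s2),
                                     terms = setdiff(use, "e"), dropped_terms = dropped,
                                     blocks = blocks, lower = lower,
                                     n_obs = c(n1, n2),
                                     rank_X = c(ncol(X1), ncol(X2)))),
                    class = "model_spec")
  # univariate sub-models used for warm starts
  spec$meta$uni1 <- build_design(design, grm, y1 / s1, terms = terms)
  spec$meta$uni2 <- build_design(design, grm, y2 / s2, terms = terms)
  spec
}
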