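# Dense-V average-information REML engine.
#
# The variance model is V(theta) = sum_j theta_j K_j with K_j symmetric and
# residual variances kept strictly positive so V stays invertible. Fixed
# effects are profiled out through P = Vi - Vi X (X'Vi X)^-1 X'Vi. The
# restricted log-likelihood is
#   ll = -1/2 [ (n-p) log 2pi + log|V| + log|X'ViX| + y'Py ],
# the score for theta_j is -1/2 [tr(P K_j) - y'P K_j P y] and the
# average-information matrix is AI_jk = 1/2 y'P K_j P K_k P y. Bivariate
# models use the same engine through a block-structured evaluator in which
# each dispersion parameter touches one quadrant of V.

#' REML iteration control
#'
#' @param n_em expectation-maximisation warm-start iterations before
#'   switching to average-information updates (EM is robust far from the
#'   optimum; AI converges quadratically near it).
#' @param max_iter iteration cap.
#' @param tol_ll relative log-likelihood change declaring convergence.
#' @param tol_par relative parameter change declaring convergence.
#' @param max_halvings step-halvings tried before an AI step is abandoned.
#' @param stall_window,stall_tol ridge-stall rule: stop when `stall_window`
#'   successive iterations gain less than `stall_tol` log-likelihood units
#'   (well below the ~0.5 units corresponding to one standard error).
#' @param on_nonconvergence `"error"` (default) or `"warning"`.
#' @param verbose print per-iteration progress.
#' @return a list of control settings.
#' @export
reml_control <- function(n_em = 5L, max_iter = 200L, tol_ll = 1e-8,
                         tol_par = 1e-6, max_halvings = 15L,
                         stall_window = 25L, stall_tol = 0.01,
                         on_nonconvergence = c("error", "warning"),
                         verbose = FALSE) {
  list(n_em = n_em, max_iter = max_iter, tol_ll = tol_ll, tol_par = tol_par,
       max_halvings = max_halvings, stall_window = stall_window,
       stall_tol = stall_tol,
       on_nonconvergence = match.arg(on_nonconvergence), verbose = verbose)
}

.build_V <- function(theta, K, n) {
  V <- matrix(0, n, n)
  for (j in seq_along(K)) if (theta[j] != 0) V <- V + theta[j] * K[[j]]
  V
}

# shared likelihood core for a fully built V
.reml_core <- function(V, y, X, derivs) {
  n <- length(y); p <- ncol(X)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  XtViXi <- chol2inv(chx)
  Viy <- Vi %*% y
  beta <- XtViXi %*% crossprod(X, Viy)
  Py <- drop(Viy - ViX %*% beta)
  ll <- -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                  2 * sum(log(diag(chx))) + sum(y * Py))
  out <- list(ll = ll, Py = Py, beta = drop(beta))
  if (derivs) out$P <- Vi - ViX %*% tcrossprod(XtViXi, ViX)
  out
}

# univariate evaluator: V = sum theta_j K_j
.reml_pieces <- function(theta, y, X, K, derivs = TRUE) {
  n <- length(y)
  core <- .reml_core(.build_V(theta, K, n), y, X, derivs)
  if (is.null(core) || !derivs) return(core)
  P <- core$P; Py <- core$Py
  m <- length(K)
  W <- matrix(0, n, m)
  trPK <- numeric(m)
  for (j in seq_len(m)) {
    W[, j] <- K[[j]] %*% Py
    trPK[j] <- sum(P * K[[j]])
  }
  yPKPy <- drop(crossprod(Py, W))
  AI <- 0.5 * crossprod(W, P %*% W)
  core$score <- -0.5 * (trPK - yPKPy)
  core$trPK <- trPK; core$yPKPy <- yPKPy; core$AI <- AI
  core$P <- NULL
  core
}

# bivariate evaluator: parameters ordered (v1, cov, v2) per term; B[[k]]
# holds the three covariance blocks of term k on the two responses' rows
.reml_pieces_biv <- function(theta, y, X, B, n1, n2, derivs = TRUE) {
  n <- n1 + n2
  r1 <- seq_len(n1); r2 <- n1 + seq_len(n2)
  V11 <- matrix(0, n1, n1); V12 <- matrix(0, n1, n2); V22 <- matrix(0, n2, n2)
  for (k in seq_along(B)) {
    i <- 3L * (k - 1L)
    if (theta[i + 1L] != 0) V11 <- V11 + theta[i + 1L] * B[[k]]$B11
    if (theta[i + 2L] != 0) V12 <- V12 + theta[i + 2L] * B[[k]]$B12
    if (theta[i + 3L] != 0) V22 <- V22 + theta[i + 3L] * B[[k]]$B22
  }
  V <- matrix(0, n, n)
  V[r1, r1] <- V11; V[r1, r2] <- V12; V[r2, r1] <- t(V12); V[r2, r2] <- V22
  core <- .reml_core(V, y, X, derivs)
  if (is.null(core) || !derivs) return(core)
  P <- core$P; Py <- core$Py
  Py1 <- Py[r1]; Py2 <- Py[r2]
  P11 <- P[r1, r1]; P12 <- P[r1, r2]; P22 <- P[r2, r2]
  m <- 3L * length(B)
  W <- matrix(0, n, m)
  trPK <- numeric(m)
  for (k in seq_along(B)) {
    i <- 3L * (k - 1L); bb <- B[[k]]
    W[r1, i + 1L] <- bb$B11 %*% Py1
    trPK[i + 1L] <- sum(P11 * bb$B11)
    W[r1, i + 2L] <- bb$B12 %*% Py2
    W[r2, i + 2L] <- crossprod(bb$B12, Py1)
    trPK[i + 2L] <- 2 * sum(P12 * bb$B12)
    W[r2, i + 3L] <- bb$B22 %*% Py2
    trPK[i + 3L] <- sum(P22 * bb$B22)
  }
  yPKPy <- drop(crossprod(Py, W))
  AI <- 0.5 * crossprod(W, P %*% W)
  core$score <- -0.5 * (trPK - yPKPy)
  core$trPK <- trPK; core$yPKPy <- yPKPy; core$AI <- AI
  core$P <- NULL
  core
}

# project each (v1, cov, v2) triple onto the PSD cone (2x2 eigenvalue clip)
.project_blocks <- function(theta, blocks) {
  for (b in blocks) {
    M <- matrix(theta[b][c(1L, 2L, 2L, 3L)], 2L)
    if (M[1, 2]^2 > M[1, 1] * M[2, 2] || M[1, 1] < 0 || M[2, 2] < 0) {
      ev <- eigen(M, symmetric = TRUE)
      Mp <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
      theta[b] <- c(Mp[1, 1], Mp[1, 2], Mp[2, 2])
    }
  }
  theta
}

.clamp <- function(theta, lower, blocks = NULL) {
  if (!is.null(blocks)) theta <- .project_blocks(theta, blocks)
  pmax(theta, lower)
}

# core fitter shared by reml_fit() and reml_fit_bivariate(); `pieces` is an
# evaluator closure theta -> likelihood pieces
.aireml <- function(pieces, start, q, lower, blocks = NULL,
                    control = reml_control(), vy = 1) {
  m <- length(start)
  theta <- .clamp(start, lower, blocks)
  pc <- pieces(theta, derivs = TRUE)
  if (is.null(pc)) {
    theta[lower > 0] <- pmax(theta[lower > 0], 0.1 * vy)
    pc <- pieces(theta, derivs = TRUE)
    if (is.null(pc)) .stopf("restricted likelihood undefined at starting values (singular V)")
  }
  em_ok <- all(is.finite(q))
  converged <- FALSE
  it <- 0L
  sa_used <- 0L
  sa_cap <- 20L
  ll_path <- numeric(0)
  try_step <- function(prop, strict = FALSE) {
    prop <- .clamp(prop, lower, blocks)
    pc2 <- pieces(prop, derivs = FALSE)
    if (is.null(pc2) || !is.finite(pc2$ll)) return(NULL)
    ok <- if (strict) pc2$ll > pc$ll + control$tol_ll * (1 + abs(pc$ll))
          else pc2$ll >= pc$ll - 1e-10
    if (ok) list(theta = prop, ll = pc2$ll) else NULL
  }
  while (it < control$max_iter) {
    it <- it + 1L
    ll_path[it] <- pc$ll
    accepted <- NULL
    use_em <- em_ok && it <= control$n_em
    if (!use_em) {
      at0 <- is.finite(lower) & (theta <= lower + 1e-14)
      pinned_now <- at0 & pc$score <= 0
      # a covariance cannot leave zero while its block variance is pinned
      # (KKT on the PSD cone: the variance's own gradient governs release;
      # the covariance follows once the variance is interior)
      if (!is.null(blocks)) for (b in blocks) {
        if ((pinned_now[b[1L]] || pinned_now[b[3L]]) &&
            abs(theta[b[2L]]) <= 1e-12) {
          pinned_now[b[2L]] <- TRUE
        }
      }
      free <- which(!pinned_now)
      if (length(free)) {
        AIf <- pc$AI[free, free, drop = FALSE]
        dbar <- mean(diag(AIf))
        for (lam in c(0, 1e-2, 1, 100) * max(dbar, 1e-12)) {
          delta <- tryCatch(solve(AIf + diag(lam, length(free)), pc$score[free]),
                            error = function(e) NULL)
          if (is.null(delta)) next
          alpha <- 1
          for (h in seq_len(4L)) {
            prop <- theta
            prop[free] <- prop[free] + alpha * delta
            accepted <- try_step(prop)
            if (!is.null(accepted)) break
            alpha <- alpha / 2
          }
          if (!is.null(accepted)) break
        }
      }
    }
    if (is.null(accepted) && em_ok) {
      accepted <- try_step(theta + theta^2 * (pc$yPKPy - pc$trPK) / q)
    }
    if (is.null(accepted) && !use_em) {
      # projected steepest ascent can slide along the PSD/positivity
      # boundary when the Newton-type directions all point outside it;
      # bounded by sa_cap rescues so a boundary solution cannot crawl
      if (sa_used < sa_cap) {
        stepsize <- 0.1 * max(mean(abs(theta)), 1e-3) / max(abs(pc$score))
        for (h in seq_len(control$max_halvings)) {
          accepted <- try_step(theta + stepsize * pc$score, strict = TRUE)
          if (!is.null(accepted)) break
          stepsize <- stepsize / 2
        }
        if (!is.null(accepted)) sa_used <- sa_used + 1L
      }
      if (is.null(accepted)) {
        # no feasible direction improves the restricted likelihood beyond
        # tolerance (or the rescue budget is spent): treat as a
        # (possibly boundary-constrained) maximum
        converged <- TRUE
        break
      }
    }
    if (is.null(accepted)) next  # EM warm-start produced no step; try AI
    dll <- accepted$ll - pc$ll
    dpar <- max(abs(accepted$theta - theta))
    theta <- accepted$theta
    pc <- pieces(theta, derivs = TRUE)
    .msg(control$verbose, sprintf("iter %3d  logL %.6f  max|score| %.3g",
                                  it, pc$ll, max(abs(pc$score))))
    if (it > control$n_em &&
        abs(dll) < control$tol_ll * (1 + abs(pc$ll)) &&
        dpar < control$tol_par * (1 + max(abs(theta)))) {
      converged <- TRUE
      break
    }
    # ridge stall: when many successive iterations barely move the
    # likelihood the surface is flat far below one standard error
    # (Delta logL ~ 0.5); typical of sliding along a PSD boundary
    if (it > control$n_em + control$stall_window &&
        ll_path[it] - ll_path[it - control$stall_window] < control$stall_tol) {
      converged <- TRUE
      break
    }
  }
  at0 <- is.finite(lower) & (theta <= lower + 1e-14)
  if (!converged) {
    msg <- sprintf("REML did not converge in %d iterations (logL %.4f, max|score| %.3g)",
                   it, pc$ll, max(abs(pc$score)))
    if (control$on_nonconvergence == "error") {
      cond <- structure(class = c("maltmet_reml_error", "error", "condition"),
                        list(message = msg, call = sys.call(-1),
                             theta = theta, score = pc$score, loglik = pc$ll))
      stop(cond)
    }
    .warnf("%s", msg)
  }
  free <- which(!at0)
  vcov <- matrix(0, m, m)
  if (length(free)) {
    AIf <- pc$AI[free, free, drop = FALSE]
    Vf <- tryCatch(solve(AIf), error = function(e)
      tryCatch(solve(AIf + diag(1e-8 * mean(diag(AIf)) + 1e-14, length(free))),
               error = function(e2) matrix(NA_real_, length(free), length(free))))
    vcov[free, free] <- Vf
  }
  theta[at0 & lower == 0] <- 0
  list(theta = theta, vcov = vcov, se = sqrt(pmax(diag(vcov), 0)),
       loglik = pc$ll, converged = converged, iterations = it,
       pinned = at0 & lower == 0, score = pc$score, ll_path = ll_path,
       AI = pc$AI)
}
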