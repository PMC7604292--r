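#' Simulate line genotypes
#'
#' Draws biallelic SNP dosages for a set of related breeding lines. Founder
#' lines are sampled in Hardy-Weinberg proportions at allele frequencies
#' drawn from `maf_range`; each line is produced by crossing two founders
#' (recombination-free gamete sampling, loci independent) followed by
#' `n_self` generations of selfing, which reproduces the relatedness of
#' elite material without modelling a genetic map. With `n_founders = NULL`
#' lines are drawn independently under Hardy-Weinberg equilibrium.
#'
#' @param config a [sim_config()].
#' @return a [marker_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_lines < 2L) .stopf("need at least 2 lines")
  set.seed(derive_seed(config$seed, 1L))
  m <- config$n_markers
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  line_ids <- sprintf("L%04d", seq_len(config$n_lines))
  if (is.null(config$n_founders)) {
    W <- matrix(stats::rbinom(config$n_lines * m, 2L, rep(p, each = config$n_lines)),
                nrow = config$n_lines)
  } else {
    nf <- max(2L, config$n_founders)
    founders <- matrix(stats::rbinom(nf * m, 2L, rep(p, each = nf)), nrow = nf)
    W <- matrix(0, config$n_lines, m)
    for (i in seq_len(config$n_lines)) {
      par <- sample.int(nf, 2L, replace = FALSE)
      g1 <- stats::rbinom(m, 1L, founders[par[1L], ] / 2)
      g2 <- stats::rbinom(m, 1L, founders[par[2L], ] / 2)
      W[i, ] <- g1 + g2
    }
    for (s in seq_len(config$n_self)) {
      het <- which(W == 1)
      if (!length(het)) break
      W[het] <- stats::rbinom(length(het), 2L, 0.5)
    }
  }
  if (config$geno_missing_rate > 0) {
    nmiss <- round(config$geno_missing_rate * length(W))
    W[sample.int(length(W), nmiss)] <- NA_real_
  }
  marker_matrix(W, line_ids = line_ids, marker_ids = sprintf("M%05d", seq_len(m)))
}

#' Simulate the field and malting design
#'
#' Each line enters the programme in one year and is grown at every location
#' that year; within each location x year environment the lines present are
#' split into `trials_per_env` trials, each a randomised block with three
#' replicate plots per line. Plots are then thinned at random (keeping at
#' least one plot per line) until the mean number of replicates per line
#' equals `reps_per_line`. Consecutive plots are grouped into malting
#' batches of `batch_size`.
#'
#' @param config a [sim_config()].
#' @return a `plot_design` data frame with columns plot, line, location,
#'   year, env, trial, batch.
#' @export
simulate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  lines <- sprintf("L%04d", seq_len(config$n_lines))
  years <- sprintf("Y%d", seq_len(config$n_years))
  locs <- sprintf("S%d", seq_len(config$n_locations))
  line_year <- sample(rep_len(years, config$n_lines))
  rows <- list()
  for (yr in years) {
    ly <- lines[line_year == yr]
    if (!length(ly)) next
    if (length(ly) < config$trials_per_env)
      .stopf("more trials (%d) than lines (%d) in year %s", config$trials_per_env, length(ly), yr)
    trial_of <- sample(rep_len(seq_len(config$trials_per_env), length(ly)))
    for (loc in locs) {
      env <- paste(loc, yr, sep = "_")
      rows[[length(rows) + 1L]] <- data.frame(
        line = rep(ly, each = 3L), location = loc, year = yr, env = env,
        trial = paste(env, sprintf("T%d", rep(trial_of, each = 3L)), sep = "_"),
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  n_target <- max(config$n_lines, round(config$n_lines * config$reps_per_line))
  if (n_target < nrow(d)) {
    ord <- sample.int(nrow(d))
    first <- ord[!duplicated(d$line[ord])]
    rest <- setdiff(ord, first)
    keep <- sort(c(first, rest[seq_len(n_target - length(first))]))
    d <- d[keep, , drop = FALSE]
  }
  d <- d[order(d$env, d$trial, d$line), , drop = FALSE]
  d$plot <- sprintf("P%05d", seq_len(nrow(d)))
  d$batch <- sprintf("B%03d", ceiling(seq_len(nrow(d)) / config$batch_size))
  rownames(d) <- NULL
  d <- d[, c("plot", "line", "location", "year", "env", "trial", "batch")]
  class(d) <- c("plot_design", "data.frame")
  d
}

# factor of a PSD matrix via symmetric eigendecomposition, negatives clipped to 0
.psd_factor <- function(M, label = "covariance matrix") {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values), 1)))
    .stopf("%s is not positive semi-definite", label)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Simulate feature and trait phenotypes with known ground truth
#'
#' Realises the plot-level mixed model for every feature and trait: additive
#' genomic line effects with covariance `G * sigma_g^2` (drawn through a
#' symmetric PSD factorisation of G), i.i.d. line, line x environment and
#' batch effects, genomic x environment effects drawn independently per
#' environment with covariance `G * sigma_ig^2`, fixed trial-cell effects,
#' and residuals. Features and traits share genomic and residual effects
#' according to the covariances in `trait_specs`. A spectra-like bucket
#' table is emitted alongside the raw responses: intensities are
#' `dilution * (baseline + response)` so that probabilistic quotient
#' normalisation removes the per-plot dilution exactly.
#'
#' @param markers a [marker_matrix()] for the lines in `design`.
#' @param design a `plot_design` from [simulate_design()].
#' @param config the [sim_config()] used to generate both.
#' @return a list of class `sim_phenotypes` with elements `features` (plots x
#'   features response matrix), `spectra` ([spectrum_set()]), `traits`
#'   (data frame of plot + trait values, missing allowed), `grm` (the
#'   [build_grm()] of `markers`) and `truth` (realised effects, true
#'   plot-level h2 per feature, true genetic/phenotypic correlations).
#' @export
simulate_phenotypes <- function(markers, design, config) {
  stopifnot(inherits(config, "sim_config"))
  miss_lines <- setdiff(unique(design$line), rownames(markers))
  if (length(miss_lines)) .stopf("design lines absent from marker matrix: %s",
                                 paste(utils::head(miss_lines, 3), collapse = ", "))
  set.seed(derive_seed(config$seed, 3L))
  grm <- suppressWarnings(build_grm(markers))
  lines <- grm$line_ids
  n_l <- length(lines)
  tc <- config$true_components
  n_f <- nrow(tc)
  specs <- config$trait_specs
  n_t <- length(specs)
  resp <- c(rownames(tc), names(specs))
  n_r <- n_f + n_t
  vmat <- rbind(tc, t(vapply(specs, function(s) s$variances, numeric(6L))))
  rownames(vmat) <- resp

  # genetic and residual cross-response covariance matrices
  Sg <- diag(vmat[, "g"], n_r)
  Se <- diag(vmat[, "e"], n_r)
  for (j in seq_len(n_t)) {
    Sg[seq_len(n_f), n_f + j] <- Sg[n_f + j, seq_len(n_f)] <- specs[[j]]$cov_g
    Se[seq_len(n_f), n_f + j] <- Se[n_f + j, seq_len(n_f)] <- specs[[j]]$cov_e
  }
  Lg_resp <- .psd_factor(Sg, "genetic covariance matrix across responses")
  Le_resp <- .psd_factor(Se, "residual covariance matrix across responses")
  L_G <- .psd_factor(grm$G, "genomic relationship matrix")

  n_p <- nrow(design)
  line_idx <- match(design$line, lines)
  envs <- sort(unique(design$env))
  env_idx <- match(design$env, envs)
  batches <- sort(unique(design$batch))
  cells <- sort(unique(design$trial))

  g_mat <- L_G %*% matrix(stats::rnorm(n_l * n_r), n_l) %*% t(Lg_resp)
  l_mat <- matrix(stats::rnorm(n_l * n_r), n_l) %*% diag(sqrt(vmat[, "l"]), n_r)
  t_mat <- matrix(stats::rnorm(length(batches) * n_r), length(batches)) %*% diag(sqrt(vmat[, "t"]), n_r)
  b_mat <- matrix(stats::rnorm(length(cells) * n_r, sd = config$fixed_sd), length(cells))
  e_mat <- matrix(stats::rnorm(n_p * n_r), n_p) %*% t(Le_resp)

  y <- b_mat[match(design$trial, cells), , drop = FALSE] +
    g_mat[line_idx, , drop = FALSE] + l_mat[line_idx, , drop = FALSE] +
    t_mat[match(design$batch, batches), , drop = FALSE] + e_mat
  for (ei in seq_along(envs)) {
    rowsel <- which(env_idx == ei)
    if (!length(rowsel)) next
    ig_e <- L_G %*% matrix(stats::rnorm(n_l * n_r), n_l) %*% diag(sqrt(vmat[, "ig"]), n_r)
    il_e <- matrix(stats::rnorm(n_l * n_r), n_l) %*% diag(sqrt(vmat[, "il"]), n_r)
    y[rowsel, ] <- y[rowsel, ] + ig_e[line_idx[rowsel], , drop = FALSE] +
      il_e[line_idx[rowsel], , drop = FALSE]
  }
  dimnames(y) <- list(design$plot, resp)

  features <- y[, seq_len(n_f), drop = FALSE]
  traits <- as.data.frame(y[, n_f + seq_len(n_t), drop = FALSE])
  for (j in seq_len(n_t)) {
    mr <- specs[[j]]$missing_rate
    if (mr > 0) traits[[j]][stats::runif(n_p) < mr] <- NA_real_
  }
  traits <- cbind(data.frame(plot = design$plot, stringsAsFactors = FALSE), traits)
  rownames(traits) <- NULL

  ppm <- seq(config$ppm_range[1], config$ppm_range[2], length.out = n_f)
  dil <- exp(stats::rnorm(n_p, 0, config$dilution_sd))
  spectra <- spectrum_set(dil * (config$baseline + features), ppm, design$plot)

  gbar <- grm$g_bar
  w <- c(g = gbar, l = 1, ig = gbar, il = 1, t = 1, e = 1)
  sp2 <- as.numeric(vmat %*% w)
  names(sp2) <- resp
  h2_true <- gbar * vmat[seq_len(n_f), "g"] / sp2[seq_len(n_f)]
  r_g <- r_p <- matrix(NA_real_, n_f, n_t, dimnames = list(rownames(tc), names(specs)))
  for (j in seq_len(n_t)) {
    vg_t <- specs[[j]]$variances[["g"]]
    r_g[, j] <- ifelse(tc[, "g"] > 0 & vg_t > 0,
                       specs[[j]]$cov_g / sqrt(tc[, "g"] * vg_t), NA_real_)
    r_p[, j] <- (gbar * specs[[j]]$cov_g + specs[[j]]$cov_e) /
      sqrt(sp2[seq_len(n_f)] * sp2[n_f + j])
  }
  truth <- list(components = vmat, sigma_p2 = sp2, g_bar = gbar,
                g = g_mat, h2 = h2_true, r_g = r_g, r_p = r_p)
  structure(list(features = features, spectra = spectra, traits = traits,
                 grm = grm, truth = truth),
            class = "sim_phenotypes")
}
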