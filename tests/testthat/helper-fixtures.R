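# shared in-code fixtures; everything deterministic under the seeds set here

# small hand-built positive-definite relationship matrix for n lines
tiny_G <- function(n = 4) {
  A <- 0.3^abs(outer(seq_len(n), seq_len(n), "-"))
  diag(A) <- 1.1
  dimnames(A) <- list(sprintf("L%04d", 1:n), sprintf("L%04d", 1:n))
  A
}

as_grm <- function(G) {
  structure(list(G = G, g_bar = mean(diag(G)), p = NULL,
                 line_ids = rownames(G), n_clipped = 0L),
            class = "genomic_relationship")
}

# fully crossed plot design: every line in every environment, `reps` plots
tiny_design <- function(n_lines = 4, n_loc = 1, n_years = 2, reps = 2,
                        batch_size = 6) {
  lines <- sprintf("L%04d", seq_len(n_lines))
  d <- expand.grid(line = lines, location = sprintf("S%d", seq_len(n_loc)),
                   year = sprintf("Y%d", seq_len(n_years)), rep = seq_len(reps),
                   stringsAsFactors = FALSE)
  d$env <- paste(d$location, d$year, sep = "_")
  d$trial <- paste0(d$env, "_T1")
  d <- d[order(d$env, d$line), ]
  d$plot <- sprintf("P%05d", seq_len(nrow(d)))
  d$batch <- sprintf("B%03d", ceiling(seq_len(nrow(d)) / batch_size))
  rownames(d) <- NULL
  d <- d[, c("plot", "line", "location", "year", "env", "trial", "batch")]
  class(d) <- c("plot_design", "data.frame")
  d
}

# small related-lines simulation shared across tests
small_sim <- function(n_lines = 60, n_features = 4, seed = 301, reps = 3,
                      h2 = 0.3, trait_specs = NULL, ...) {
  tc <- matrix(rep(c(h2, 0.1, 0.1, 0.1, 0.1, 1 - h2 - 0.4), n_features),
               nrow = n_features, byrow = TRUE)
  cfg <- sim_config(n_lines = n_lines, n_markers = 800, n_founders = 15,
                    n_self = 0, reps_per_line = reps, true_components = tc,
                    trait_specs = trait_specs, seed = seed, ...)
  mk <- simulate_genotypes(cfg)
  d <- simulate_design(cfg)
  sim <- simulate_phenotypes(mk, d, cfg)
  list(cfg = cfg, markers = mk, design = d, sim = sim)
}

# spectra fixture with known structure
tiny_spectra <- function(n_plots = 6, ppm = seq(1, 5, by = 0.5), seed = 42) {
  set.seed(seed)
  Y <- matrix(stats::runif(n_plots * length(ppm), 1, 3), n_plots)
  spectrum_set(Y, ppm, sprintf("P%05d", seq_len(n_plots)))
}

fake_vc <- function(components, g_bar = 1, vcov = NULL) {
  nm <- names(components)
  vcov <- vcov %||% diag(1e-4, length(components))
  dimnames(vcov) <- list(nm, nm)
  structure(list(components = components, se = sqrt(diag(vcov)), vcov = vcov,
                 loglik = NA_real_, converged = TRUE, iterations = 0L,
                 pinned = components == 0, g_bar = g_bar,
                 dropped_terms = character(0)),
            class = "variance_components")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bivariate_components stand-in built from per-term 2x2 blocks
fake_biv <- function(blocks, g_bar = 1, vcov_diag = 1e-4) {
  est <- numeric(0)
  for (tm in names(blocks)) {
    b <- blocks[[tm]]
    est[paste0(tm, "_v1")] <- b[1, 1]
    est[paste0(tm, "_cov")] <- b[1, 2]
    est[paste0(tm, "_v2")] <- b[2, 2]
  }
  vc <- diag(vcov_diag, length(est))
  dimnames(vc) <- list(names(est), names(est))
  structure(list(components = est, blocks = blocks, se = sqrt(diag(vc)),
                 vcov = vc, loglik = NA_real_, converged = TRUE,
                 iterations = 0L, pinned = est == 0, g_bar = g_bar,
                 terms = setdiff(names(blocks), "e"), n_obs = c(NA, NA)),
            class = "bivariate_components")
}
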