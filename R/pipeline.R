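#' Validate a pipeline configuration
#'
#' A configuration (a named list, or a path to a YAML key-value file) must
#' contain exactly one data source: `inputs` (paths `genotypes`, `design`,
#' `spectra`) or `simulation` (arguments for [sim_config()]). Optional
#' blocks: `qc` (`maf_min`, `missing_max`), `exclude_regions`, `align`
#' (`n_segments`, `max_shift`), `null` (`n_replicates`, `alpha`), `reml`
#' (tolerances/caps for [reml_control()]), `z_threshold`, `seed`.
#'
#' @param config named list or YAML path.
#' @return the validated configuration list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_in <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulation)
  if (has_in == has_sim)
    .stopf("config must contain exactly one of 'inputs' and 'simulation'")
  if (has_in) {
    miss <- setdiff(c("genotypes", "design", "spectra"), names(config$inputs))
    if (length(miss)) .stopf("inputs block missing: %s", paste(miss, collapse = ", "))
  }
  config$seed <- config$seed %||% 1L
  config$qc <- utils::modifyList(list(maf_min = 0.05, missing_max = 0.20), config$qc %||% list())
  config$exclude_regions <- config$exclude_regions %||% list(c(4.7, 4.9), c(-0.2, 0.2))
  config$align <- utils::modifyList(list(enabled = TRUE, n_segments = 4L, max_shift = 3L),
                                    config$align %||% list())
  config$null <- utils::modifyList(list(n_replicates = 1000L, alpha = 0.01), config$null %||% list())
  config$reml <- do.call(reml_control, config$reml %||% list())
  config$z_threshold <- config$z_threshold %||% 2.326
  config
}

.hist_table <- function(x, breaks = 30L) {
  h <- graphics::hist(x[is.finite(x)], breaks = breaks, plot = FALSE)
  data.frame(lower = utils::head(h$breaks, -1), upper = h$breaks[-1], count = h$counts)
}

#' Run the full analysis pipeline
#'
#' Executes the two-step analysis end to end: preprocess the bucket table
#' (region exclusion, PQN, optional segment alignment, autoscaling), build
#' the genomic relationship matrix from QC-passed markers, fit the
#' univariate model to every feature, calibrate the heritability
#' significance cutoff by null simulation on the exact design, and run the
#' bivariate model for every significantly heritable feature against every
#' trait. All artifacts are written as TSV under `out_dir` together with a
#' JSON manifest recording seeds, versions and row counts.
#'
#' @param config a [pipeline_config()] list or YAML path.
#' @param out_dir output directory (created if needed).
#' @param verbose log stage progress.
#' @return a `pipeline_report` list (counts, cutoff, summaries, file paths).
#' @export
run_pipeline <- function(config, out_dir = "maltmet-run", verbose = TRUE) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "maltmet",
                   version = as.character(utils::packageVersion("maltmet")),
                   seed = config$seed, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  paths <- list()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    .write_tsv(df, p)
    paths[[name]] <<- p
    p
  }

  # --- stage: data -----------------------------------------------------
  .msg(verbose, "[data] loading inputs")
  truth <- NULL
  if (!is.null(config$simulation)) {
    simargs <- config$simulation
    simargs$seed <- simargs$seed %||% config$seed
    if (!is.null(simargs$true_components)) simargs$true_components <- as.matrix(simargs$true_components)
    cfg <- do.call(sim_config, simargs)
    markers <- simulate_genotypes(cfg)
    design <- simulate_design(cfg)
    sim <- simulate_phenotypes(markers, design, cfg)
    spectra <- sim$spectra
    traits <- sim$traits
    truth <- sim$truth
    write_genotypes(markers, file.path(out_dir, "genotypes.tsv"))
    write_design(design, file.path(out_dir, "design_traits.tsv"), traits)
    write_spectra(spectra, file.path(out_dir, "spectra.tsv"))
    emit(data.frame(feature = names(truth$h2), true_h2 = truth$h2), "ground_truth.tsv")
  } else {
    markers <- read_genotypes(config$inputs$genotypes)
    dt <- read_design(config$inputs$design)
    design <- dt$design
    traits <- dt$traits
    spectra <- read_spectra(config$inputs$spectra)
  }
  if (!identical(spectra$plot_ids, design$plot))
    spectra <- spectrum_set(spectra$intensity[match(design$plot, spectra$plot_ids), , drop = FALSE],
                            spectra$ppm, design$plot)
  manifest$n_plots <- nrow(design)
  manifest$n_lines <- length(unique(design$line))

  # --- stage: preprocess ------------------------------------------------
  .msg(verbose, "[preprocess] exclusion, PQN, alignment, autoscaling")
  sidecar <- list()
  spectra <- exclude_regions(spectra, config$exclude_regions)
  sidecar$excluded <- attr(spectra, "excluded")
  spectra <- pqn_normalize(spectra)
  if (isTRUE(config$align$enabled)) {
    ns <- config$align$n_segments
    br <- seq(min(spectra$ppm), max(spectra$ppm), length.out = ns + 1L)
    segs <- lapply(seq_len(ns), function(i) c(br[i], br[i + 1L] - if (i < ns) 1e-9 else 0))
    seg_len <- vapply(segs, function(b) sum(spectra$ppm >= b[1] & spectra$ppm <= b[2]), numeric(1))
    if (all(seg_len >= 2 * config$align$max_shift + 1)) {
      spectra <- align_segments(spectra, segment_bounds = segs, max_shift = config$align$max_shift)
      sidecar$shifts_range <- range(attr(spectra, "shifts"))
    } else {
      .msg(verbose, "[preprocess] segments too short for requested max_shift; alignment skipped")
    }
  }
  features <- standardize(spectra)
  sidecar$dropped_features <- features$dropped
  jsonlite::write_json(sidecar, file.path(out_dir, "preprocess.json"), auto_unbox = TRUE)
  manifest$n_features <- ncol(features$values)

  # --- stage: grm -------------------------------------------------------
  .msg(verbose, "[grm] marker QC and VanRaden G")
  markers_qc <- filter_markers(markers, config$qc$maf_min, config$qc$missing_max)
  manifest$marker_qc <- attr(markers_qc, "filter_report")
  grm <- build_grm(markers_qc)
  manifest$g_bar <- grm$g_bar
  gdf <- data.frame(line = grm$line_ids, grm$G, check.names = FALSE)
  emit(gdf, "grm.tsv")

  # --- stage: univariate scan ------------------------------------------
  .msg(verbose, sprintf("[h2scan] univariate REML over %d features", ncol(features$values)))
  scan <- h2_scan(features, design, grm, control = config$reml, verbose = verbose)

  # --- stage: null cutoff ----------------------------------------------
  .msg(verbose, sprintf("[nullcut] %d null replicates", config$null$n_replicates))
  null <- null_cutoff(design, grm, n_replicates = config$null$n_replicates,
                      alpha = config$null$alpha, seed = derive_seed(config$seed, 17L),
                      control = config$reml)
  emit(data.frame(h2 = null$h2), "null_h2.tsv")
  jsonlite::write_json(list(seed = null$seed, n_replicates = null$n_replicates,
                            alpha = null$alpha, cutoff = null$cutoff,
                            n_retried = null$n_retried),
                       file.path(out_dir, "null_meta.json"), auto_unbox = TRUE, digits = NA)
  scan <- suppressMessages(flag_significant(scan, null))
  sig_summary <- attr(scan, "summary")
  emit(scan, "heritability.tsv")
  emit(.hist_table(scan$h2), "h2_hist.tsv")
  manifest$cutoff <- null$cutoff
  manifest$n_significant <- sig_summary$n_significant
  manifest$pct_significant <- sig_summary$percent
  .msg(verbose, sprintf("[nullcut] cutoff %.4f; %d of %d features significant (%.2f%%)",
                        null$cutoff, sig_summary$n_significant, sig_summary$n_total,
                        sig_summary$percent))

  # --- stage: bivariate correlations -----------------------------------
  corr <- summaries <- NULL
  if (!is.null(traits)) {
    desc <- compute_descriptives(traits)
    emit(desc, "trait_descriptives.tsv")
    sig_feats <- scan$feature[scan$significant]
    .msg(verbose, sprintf("[corr] %d significant features x %d traits",
                          length(sig_feats), length(setdiff(names(traits), "plot"))))
    if (length(sig_feats)) {
      corr <- estimate_correlations(features, traits, design, grm,
                                    feature_ids = sig_feats,
                                    threshold = config$z_threshold,
                                    control = config$reml, verbose = FALSE)
      emit(corr, "correlations.tsv")
      emit(.hist_table(corr$r_g), "r_g_hist.tsv")
      emit(.hist_table(corr$r_p), "r_p_hist.tsv")
      summaries <- summarize_trait(corr)
      emit(summaries, "trait_summaries.tsv")
      manifest$n_pairs <- nrow(corr)
    } else manifest$n_pairs <- 0L
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest$outputs <- names(paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(manifest = manifest, scan = scan, null = null, corr = corr,
                 summaries = summaries, truth = truth, out_dir = out_dir,
                 paths = paths),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("pipeline_report: %d plots, %d lines, %d features\n",
                     "  cutoff %.4f; %d significant (%.2f%%); %s pair fits\n  outputs in %s\n"),
              m$n_plots, m$n_lines, m$n_features, m$cutoff, m$n_significant,
              m$pct_significant, m$n_pairs %||% 0L, x$out_dir))
  invisible(x)
}
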