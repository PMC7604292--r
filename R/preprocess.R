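#' Spectrum set constructor
#'
#' A `spectrum_set` holds a plot x chemical-shift bucket table: one row per
#' plot, one column per ppm bucket. The ppm grid is stored in ascending order
#' regardless of input order (NMR convention displays descending; one
#' canonical orientation avoids sign errors downstream).
#'
#' @param intensity numeric matrix, plots in rows, buckets in columns.
#' @param ppm numeric vector of bucket centres, strictly monotone, one per
#'   column.
#' @param plot_ids character vector of plot ids, one per row, no duplicates.
#' @return an object of class `spectrum_set`.
#' @export
spectrum_set <- function(intensity, ppm, plot_ids = NULL) {
  intensity <- as.matrix(intensity)
  plot_ids <- plot_ids %||% rownames(intensity) %||% sprintf("P%05d", seq_len(nrow(intensity)))
  if (length(ppm) != ncol(intensity)) .stopf("ppm grid length (%d) != bucket count (%d)", length(ppm), ncol(intensity))
  if (anyDuplicated(plot_ids)) .stopf("duplicate plot ids in spectrum set")
  d <- diff(ppm)
  if (length(d) && !(all(d > 0) || all(d < 0))) .stopf("ppm grid must be strictly monotone")
  if (length(d) && all(d < 0)) {  # canonicalise to ascending
    ppm <- rev(ppm)
    intensity <- intensity[, rev(seq_along(ppm)), drop = FALSE]
  }
  rownames(intensity) <- plot_ids
  colnames(intensity) <- formatC(ppm, format = "fg", width = 1)
  structure(list(plot_ids = plot_ids, ppm = as.numeric(ppm), intensity = intensity),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d plots x %d buckets, %.4f-%.4f ppm\n",
              nrow(x$intensity), length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Remove spectral regions
#'
#' Drops every bucket whose ppm centre lies inside any of the given closed
#' intervals. Defaults remove the residual water peak (4.7-4.9 ppm) and the
#' region of the DSS concentration standard (-0.2 to 0.2 ppm).
#'
#' @param spectra a [spectrum_set()].
#' @param regions list of length-2 numeric vectors `(lo, hi)` in ppm.
#' @return the reduced `spectrum_set`; attribute `excluded` records the
#'   regions and the number of buckets removed.
#' @export
exclude_regions <- function(spectra, regions = list(c(4.7, 4.9), c(-0.2, 0.2))) {
  stopifnot(inherits(spectra, "spectrum_set"))
  drop <- rep(FALSE, length(spectra$ppm))
  for (r in regions) {
    if (length(r) != 2L || r[1] > r[2]) .stopf("regions must be ordered (lo, hi) pairs")
    drop <- drop | (spectra$ppm >= r[1] & spectra$ppm <= r[2])
  }
  if (all(drop)) .stopf("exclusion regions remove all %d buckets", length(drop))
  out <- spectrum_set(spectra$intensity[, !drop, drop = FALSE],
                      spectra$ppm[!drop], spectra$plot_ids)
  attr(out, "excluded") <- list(regions = regions, n_removed = sum(drop))
  out
}

#' Probabilistic quotient normalisation
#'
#' Each spectrum is divided by the median of its bucket-wise quotients to a
#' reference spectrum, correcting sample-to-sample dilution. Buckets where the
#' reference is not strictly positive are skipped when forming quotients.
#'
#' @param spectra a [spectrum_set()].
#' @param reference optional reference spectrum (one value per bucket);
#'   defaults to the bucket-wise median across plots, the standard choice.
#' @return the normalised `spectrum_set`; attribute `pqn_factors` holds the
#'   per-plot dilution factors divided out.
#' @export
pqn_normalize <- function(spectra, reference = NULL) {
  stopifnot(inherits(spectra, "spectrum_set"))
  Y <- spectra$intensity
  if (any(!is.finite(Y))) .stopf("intensities must be finite for PQN")
  ref <- reference %||% apply(Y, 2L, stats::median)
  if (length(ref) != ncol(Y)) .stopf("reference length != bucket count")
  ok <- ref > 0
  if (!any(ok)) .stopf("reference spectrum has no positive buckets")
  Q <- sweep(Y[, ok, drop = FALSE], 2L, ref[ok], "/")
  fac <- apply(Q, 1L, stats::median)
  bad <- !is.finite(fac) | fac <= 0
  if (any(bad)) .stopf("no valid positive quotient for plot(s): %s",
                       paste(spectra$plot_ids[bad], collapse = ", "))
  out <- spectrum_set(Y / fac, spectra$ppm, spectra$plot_ids)
  attr(out, "pqn_factors") <- stats::setNames(fac, spectra$plot_ids)
  out
}

# integer shift with edge-value padding; d > 0 moves the profile rightwards
.shift_pad <- function(x, d) {
  n <- length(x)
  if (d == 0L) return(x)
  if (d > 0L) c(rep(x[1L], d), x[seq_len(n - d)])
  else c(x[(1L - d):n], rep(x[n], -d))
}

#' Segment-wise spectral alignment by cross-correlation
#'
#' A simplified interval alignment in the spirit of icoshift: within each
#' segment, every spectrum is shifted by the integer bucket offset in
#' `[-max_shift, max_shift]` that maximises its cross-correlation with the
#' reference segment; vacated positions are filled with the segment's edge
#' value. Ties prefer the smaller absolute shift.
#'
#' @param spectra a [spectrum_set()].
#' @param reference reference spectrum (one value per bucket); defaults to
#'   the bucket-wise median spectrum.
#' @param segment_bounds list of ppm intervals `(lo, hi)` defining
#'   non-overlapping segments; defaults to one segment spanning the grid.
#' @param max_shift maximum shift in buckets (non-negative integer).
#' @return the aligned `spectrum_set`; attribute `shifts` is a plots x
#'   segments matrix of applied offsets.
#' @export
align_segments <- function(spectra, reference = NULL, segment_bounds = NULL,
                           max_shift = 5L) {
  stopifnot(inherits(spectra, "spectrum_set"), max_shift >= 0)
  max_shift <- as.integer(max_shift)
  ref <- reference %||% apply(spectra$intensity, 2L, stats::median)
  ppm <- spectra$ppm
  segment_bounds <- segment_bounds %||% list(range(ppm))
  seg_idx <- lapply(segment_bounds, function(b) which(ppm >= b[1] & ppm <= b[2]))
  used <- unlist(seg_idx)
  if (anyDuplicated(used)) .stopf("segments overlap")
  short <- lengths(seg_idx) < 2L * max_shift + 1L
  if (any(short)) .stopf("segment %d has %d buckets; need at least 2*max_shift+1 = %d",
                         which(short)[1], lengths(seg_idx)[which(short)[1]], 2L * max_shift + 1L)
  lags <- order(abs(seq(-max_shift, max_shift)), seq(-max_shift, max_shift))
  lags <- seq(-max_shift, max_shift)[lags]      # 0, -1, 1, -2, 2, ...
  Y <- spectra$intensity
  shifts <- matrix(0L, nrow(Y), length(seg_idx),
                   dimnames = list(spectra$plot_ids, NULL))
  for (s in seq_along(seg_idx)) {
    idx <- seg_idx[[s]]
    rs <- ref[idx]
    for (i in seq_len(nrow(Y))) {
      xs <- Y[i, idx]
      best <- -Inf; best_d <- 0L
      for (d in lags) {
        cc <- sum(.shift_pad(xs, d) * rs)
        if (cc > best) { best <- cc; best_d <- d }  # lag order breaks ties
      }
      if (best_d != 0L) Y[i, idx] <- .shift_pad(xs, best_d)
      shifts[i, s] <- best_d
    }
  }
  out <- spectrum_set(Y, ppm, spectra$plot_ids)
  attr(out, "shifts") <- shifts
  out
}

#' Centre and autoscale buckets into a feature matrix
#'
#' Column-wise standardisation `(x - mean) / sd` with the n-1 divisor, the
#' final preprocessing step before variance-component analysis. Columns with
#' zero standard deviation carry no information and are dropped with a
#' warning.
#'
#' @param spectra a [spectrum_set()].
#' @return an object of class `feature_matrix` with fields `values`
#'   (standardised plots x features matrix), `plot_ids`, `feature_ids` (ppm
#'   centres), `center`, `scale` (pre-standardisation mean and sd of retained
#'   features, for back-transformation) and `dropped`.
#' @export
standardize <- function(spectra) {
  stopifnot(inherits(spectra, "spectrum_set"))
  Y <- spectra$intensity
  if (nrow(Y) < 2L) .stopf("standardisation needs at least 2 plots")
  mu <- colMeans(Y)
  sd_ <- apply(Y, 2L, stats::sd)
  keep <- sd_ > 0
  if (!all(keep)) .warnf("dropping %d constant bucket(s)", sum(!keep))
  if (!any(keep)) .stopf("all buckets constant; nothing to standardise")
  V <- sweep(sweep(Y[, keep, drop = FALSE], 2L, mu[keep]), 2L, sd_[keep], "/")
  structure(list(values = V, plot_ids = spectra$plot_ids,
                 feature_ids = colnames(Y)[keep], ppm = spectra$ppm[keep],
                 center = mu[keep], scale = sd_[keep],
                 dropped = colnames(Y)[!keep]),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d plots x %d standardised features (%d dropped)\n",
              nrow(x$values), ncol(x$values), length(x$dropped)))
  invisible(x)
}
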