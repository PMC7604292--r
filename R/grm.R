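#' Marker matrix constructor
#'
#' A marker matrix holds allele dosages (0, 1, 2, or `NA` for missing) for a
#' set of lines at a set of biallelic SNP markers, lines in rows.
#'
#' @param dosage numeric matrix of dosages in \{0, 1, 2, NA\}.
#' @param line_ids,marker_ids optional row/column ids; taken from `dimnames`
#'   when absent and generated when those are missing too.
#' @return an object of class `marker_matrix` (a numeric matrix with dimnames).
#' @export
marker_matrix <- function(dosage, line_ids = NULL, marker_ids = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) .stopf("dosages must be 0, 1, 2 or NA; found %s", dosage[bad][1])
  rownames(dosage) <- line_ids %||% rownames(dosage) %||% sprintf("L%04d", seq_len(nrow(dosage)))
  colnames(dosage) <- marker_ids %||% colnames(dosage) %||% sprintf("M%05d", seq_len(ncol(dosage)))
  if (anyDuplicated(rownames(dosage))) .stopf("duplicate line ids in marker matrix")
  class(dosage) <- c("marker_matrix", class(dosage))
  dosage
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d lines x %d markers, %.2f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

.allele_freq <- function(markers) colMeans(markers, na.rm = TRUE) / 2

#' Marker quality control
#'
#' Keeps markers whose minor allele frequency is strictly greater than
#' `maf_min` and whose missing fraction is strictly less than `missing_max`
#' (a marker with exactly 20\% missing is removed at `missing_max = 0.20`).
#'
#' @param markers a [marker_matrix()].
#' @param maf_min minimum minor allele frequency in \[0, 0.5\].
#' @param missing_max maximum missing proportion in \[0, 1\].
#' @return the filtered `marker_matrix`, with a `filter_report` attribute
#'   giving the number of markers removed by each rule.
#' @export
filter_markers <- function(markers, maf_min = 0.05, missing_max = 0.20) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  p <- .allele_freq(markers)
  maf <- pmin(p, 1 - p)
  missfrac <- colMeans(is.na(markers))
  keep_maf <- !is.na(maf) & maf > maf_min
  keep_mis <- missfrac < missing_max
  keep <- keep_maf & keep_mis
  if (!any(keep)) .stopf("no markers survive QC (maf_min = %g, missing_max = %g)", maf_min, missing_max)
  out <- markers[, keep, drop = FALSE]
  attr(out, "filter_report") <- list(
    n_in = ncol(markers), n_kept = sum(keep),
    n_removed_maf = sum(!keep_maf), n_removed_missing = sum(!keep_mis))
  class(out) <- class(markers)
  out
}

#' Mean-impute missing dosages
#'
#' Missing dosages are replaced by the marker mean (`2 * p_j`), consistent
#' with the centering used for the genomic relationship matrix.
#'
#' @param markers a [marker_matrix()].
#' @return the imputed matrix; attribute `n_imputed` records replacements.
#' @export
impute_missing <- function(markers) {
  miss <- is.na(markers)
  n_imp <- sum(miss)
  if (n_imp == 0L) {
    attr(markers, "n_imputed") <- 0L
    return(markers)
  }
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing)) {
    .stopf("marker(s) entirely missing (e.g. %s); filter before imputing",
           colnames(markers)[all_missing][1])
  }
  mu <- 2 * .allele_freq(markers)
  idx <- which(miss, arr.ind = TRUE)
  markers[idx] <- mu[idx[, 2L]]
  attr(markers, "n_imputed") <- n_imp
  markers
}

#' VanRaden method-1 genomic relationship matrix
#'
#' Computes `G = Z Z' / (2 * sum(p_j (1 - p_j)))` where column j of Z is the
#' (imputed) dosage centred by `2 p_j` and `p_j` is the in-sample allele
#' frequency. Eigenvalues below `clip` are raised to `clip` so that G is
#' positive definite and can be factorised; a warning is issued when genuinely
#' negative eigenvalues are encountered.
#'
#' @param markers a [marker_matrix()]; missing dosages are mean-imputed first.
#' @param clip eigenvalue floor (default `1e-8`).
#' @return an object of class `genomic_relationship` with fields `G`
#'   (symmetric matrix), `g_bar` (mean of `diag(G)`), `p` (allele frequencies
#'   used), `line_ids` and `n_clipped`.
#' @export
build_grm <- function(markers, clip = 1e-8) {
  markers <- impute_missing(markers)
  p <- .allele_freq(markers)
  poly <- p > 0 & p < 1
  if (!any(poly)) .stopf("all markers are monomorphic: VanRaden denominator is zero")
  W <- unclass(markers)[, , drop = FALSE]
  Z <- sweep(W, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  ev <- eigen(G, symmetric = TRUE)
  n_clip <- sum(ev$values < clip)
  if (any(ev$values < -clip)) {
    .warnf("G has %d negative eigenvalue(s); clipped to %g", sum(ev$values < -clip), clip)
  }
  if (n_clip > 0L) {
    lam <- pmax(ev$values, clip)
    G <- ev$vectors %*% (lam * t(ev$vectors))
    G <- (G + t(G)) / 2
    dimnames(G) <- list(rownames(markers), rownames(markers))
  }
  structure(list(G = G, g_bar = mean(diag(G)), p = p,
                 line_ids = rownames(markers), n_clipped = n_clip),
            class = "genomic_relationship")
}

#' @export
print.genomic_relationship <- function(x, ...) {
  cat(sprintf("genomic_relationship: %d lines, g_bar = %.4f (%d eigenvalue(s) clipped)\n",
              length(x$line_ids), x$g_bar, x$n_clipped))
  invisible(x)
}
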