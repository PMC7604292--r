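.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read a genotype matrix from TSV or VCF
#'
#' TSV input has one row per line, a `line` id column and one column per
#' marker with dosages 0/1/2 (missing empty or NA). VCF input (requires the
#' vcfR package) converts the GT field to ALT-allele dosage; any call with a
#' missing allele becomes NA.
#'
#' @param path file path; `.vcf` (or `.vcf.gz`) triggers VCF parsing.
#' @return a [marker_matrix()].
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      .stopf("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(s) {
      if (is.na(s)) return(NA_real_)
      al <- strsplit(s, "[/|]")[[1]]
      if (any(al == ".")) return(NA_real_)
      sum(al != "0")
    })
    return(marker_matrix(t(dos), line_ids = colnames(gt), marker_ids = rownames(gt)))
  }
  df <- .read_tsv(path)
  if (!"line" %in% names(df)) .stopf("genotype TSV needs a 'line' column")
  m <- as.matrix(df[setdiff(names(df), "line")])
  marker_matrix(m, line_ids = df$line)
}

#' Write a genotype matrix as TSV
#' @param markers a [marker_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(markers, path) {
  df <- data.frame(line = rownames(markers), unclass(markers),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read a plot design (+ optional trait columns) from TSV
#'
#' Expects columns plot, line, location, year, trial, batch; `env` is
#' derived as location x year when absent. Any further numeric columns are
#' treated as trait records.
#'
#' @param path file path.
#' @return a list with `design` (a `plot_design`) and `traits` (data frame
#'   of plot + trait columns, or NULL when none present).
#' @export
read_design <- function(path) {
  df <- .read_tsv(path, colClasses = c(year = "character"))
  need <- c("plot", "line", "location", "year", "trial", "batch")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("design TSV missing column(s): %s", paste(miss, collapse = ", "))
  if (!"env" %in% names(df)) df$env <- paste(df$location, df$year, sep = "_")
  dcols <- c("plot", "line", "location", "year", "env", "trial", "batch")
  design <- df[dcols]
  class(design) <- c("plot_design", "data.frame")
  tcols <- setdiff(names(df), dcols)
  traits <- if (length(tcols)) cbind(df["plot"], df[tcols]) else NULL
  list(design = design, traits = traits)
}

#' Write a plot design with trait columns as TSV
#' @param design a `plot_design` data frame.
#' @param traits optional data frame of plot + trait columns.
#' @param path output path.
#' @export
write_design <- function(design, path, traits = NULL) {
  df <- as.data.frame(design)
  if (!is.null(traits)) df <- merge(df, traits, by = "plot", sort = FALSE, all.x = TRUE)
  .write_tsv(df[order(df$plot), , drop = FALSE], path)
}

#' Read a bucket table as a spectrum set
#'
#' One row per plot (first column `plot`), one column per bucket with the
#' ppm centre as the column name. Either grid orientation is accepted; the
#' stored grid is ascending.
#'
#' @param path file path.
#' @return a [spectrum_set()].
#' @export
read_spectra <- function(path) {
  df <- .read_tsv(path)
  if (!"plot" %in% names(df)) .stopf("spectra TSV needs a 'plot' column")
  ppm <- suppressWarnings(as.numeric(setdiff(names(df), "plot")))
  if (anyNA(ppm)) .stopf("spectra TSV column names must be numeric ppm values")
  spectrum_set(as.matrix(df[setdiff(names(df), "plot")]), ppm, df$plot)
}

#' Write a spectrum set as TSV
#' @param spectra a [spectrum_set()].
#' @param path output path.
#' @param descending emit buckets in descending ppm order for display
#'   (default FALSE: ascending, matching internal storage).
#' @export
write_spectra <- function(spectra, path, descending = FALSE) {
  ord <- if (descending) rev(seq_along(spectra$ppm)) else seq_along(spectra$ppm)
  df <- data.frame(plot = spectra$plot_ids,
                   spectra$intensity[, ord, drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- format(spectra$ppm[ord], trim = TRUE)
  .write_tsv(df, path)
}
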