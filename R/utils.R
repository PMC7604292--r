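`%||%` <- function(a, b) if (is.null(a)) b else a

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed; each stage draws
#' from its own derived stream so that, e.g., adding null replicates does not
#' perturb the simulated data.
#'
#' @param seed master seed (integer).
#' @param offset non-negative integer identifying the stream.
#' @return an integer seed strictly below `.Machine$integer.max`.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) + 100003 * as.numeric(offset)) %% (.Machine$integer.max - 1)) + 1L
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
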