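#' @keywords internal
"_PACKAGE"

# HAM-D assessment schedule (weeks from baseline) used throughout.
HAMD_WEEKS <- c(0L, 1L, 2L, 3L, 6L, 9L, 12L)

#' Column names for HAM-D scores at the standard assessment weeks
#'
#' @param weeks integer vector of weeks; defaults to the full visit schedule
#'   (0, 1, 2, 3, 6, 9, 12).
#' @return character vector like `"hamd_w0"`, `"hamd_w2"`, ...
#' @export
hamd_cols <- function(weeks = HAMD_WEEKS) paste0("hamd_w", weeks)

#' Canonical variant key
#'
#' Builds the `chrom:pos:ref:alt` identifier used to align annotation tables
#' with genotype matrix columns.
#'
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Geometric mean with optional positive integer weights.
geometric_mean <- function(x, w = NULL) {
  if (length(x) == 0L) return(NA_real_)
  if (is.null(w)) return(exp(mean(log(x))))
  exp(sum(w * log(x)) / sum(w))
}

is_binary01 <- function(x) all(x %in% c(0, 1))

#' @useDynLib gvburden, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
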