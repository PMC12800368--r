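#' @importFrom methods new validObject is as setClass setGeneric setMethod
#'   setValidity slot
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
NULL

# package-level message helper: all diagnostics go through message() so
# callers can silence them with suppressMessages()
pm_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}

pm_warn <- function(...) warning(paste0(...), call. = FALSE)

#' Median of a numeric vector (mean-of-central-pair for even lengths)
#'
#' Plain sample median as used for the automatic coverage threshold: the
#' arithmetic mean of the two central order statistics when the length is
#' even. Identical to [stats::median()] for numeric input; kept as a named
#' wrapper so the threshold definition is explicit.
#'
#' @param x numeric vector, NAs removed.
#' @return a single numeric value (possibly fractional).
#' @keywords internal
pm_median <- function(x) {
  stats::median(as.numeric(x), na.rm = TRUE)
}

# stopifnot-with-message
pm_assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# collapse an integer vector to the semicolon-joined string used in CSV
# position-list columns; empty vector -> ""
pm_join_positions <- function(x) {
  if (length(x) == 0L) "" else paste(x, collapse = ";")
}

pm_split_positions <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";", fixed = TRUE)[[1L]])
}
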