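#' @noRd
pmMsg <- function(fmt, ...) message(sprintf(fmt, ...))

# Every filter stage reports input count, output count and threshold, so an
# analysis funnel can be reconstructed from the log.
#' @noRd
pmFunnel <- function(stage, n_in, n_out, threshold) {
  pmMsg("%s: %d -> %d records (%s)", stage, n_in, n_out, threshold)
}

#' @noRd
stopData <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("poreMethyl_data_error", "error")))
}

#' @noRd
stopUsage <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("poreMethyl_usage_error", "error")))
}

# count occurrences of a fixed pattern in each element of a character vector
#' @noRd
countFixed <- function(x, pattern) {
  m <- gregexpr(pattern, x, fixed = TRUE)
  vapply(m, function(v) if (v[1L] == -1L) 0L else length(v), integer(1))
}
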