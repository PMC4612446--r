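#' Skin conductance recording
#'
#' Container for a uniformly sampled skin conductance trace. Values are in
#' microsiemens (or normalised units after preprocessing); the time of sample
#' `k` (1-based) is `t0 + (k - 1) / rate`.
#'
#' @param values Numeric vector of conductance samples. Must be finite and of
#'   length at least 2.
#' @param rate Sampling frequency in Hz (> 0).
#' @param t0 Time of the first sample in seconds. Defaults to 0.
#' @param source_id Free-text provenance label.
#' @param provenance Character vector describing processing steps already
#'   applied (filled in by the preprocessing functions).
#'
#' @return An object of class `scr_recording`: a list with elements
#'   `values`, `rate`, `t0`, `source_id` and `provenance`.
#' @examples
#' rec <- scr_recording(sin(seq(0, 2 * pi, length.out = 100)), rate = 10)
#' rec
#' @export
scr_recording <- function(values, rate, t0 = 0, source_id = "",
                          provenance = character()) {
  values <- as.numeric(values)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (length(values) < 2L)
    stop("a recording needs at least 2 samples")
  bad <- which(!is.finite(values))
  if (length(bad))
    stop("non-finite samples at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L))
  structure(
    list(values = values, rate = as.numeric(rate), t0 = as.numeric(t0),
         source_id = as.character(source_id), provenance = provenance),
    class = "scr_recording"
  )
}

#' @export
print.scr_recording <- function(x, ...) {
  cat(sprintf("<scr_recording> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$values), x$rate, length(x$values) / x$rate,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Sample times of a recording
#'
#' @param rec An [scr_recording()].
#' @return Numeric vector of times (s), one per sample.
#' @export
rec_times <- function(rec) {
  stopifnot(inherits(rec, "scr_recording"))
  rec$t0 + (seq_along(rec$values) - 1) / rec$rate
}

#' Duration of a recording in seconds
#' @param rec An [scr_recording()].
#' @return Length of the recording in seconds.
#' @export
rec_duration <- function(rec) length(rec$values) / rec$rate

# internal: replace values, appending a provenance entry
rec_update <- function(rec, values, step) {
  rec$values <- values
  rec$provenance <- c(rec$provenance, step)
  rec
}
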