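#' Peak scoring of one trial
#'
#' Conventional anticipatory SCR scoring. The response onset is searched in
#' a window 1 to 4.5 s after CS onset: the first sample at which the first
#' derivative turns positive and stays positive for at least `sustain`
#' seconds, taking the preceding trough as baseline. The peak is the
#' maximum in a window 0.5 to 5 s after the detected onset, and the
#' amplitude is the baseline-corrected peak height. With no qualifying
#' onset the amplitude is 0 and onset/peak are `NA`.
#'
#' @param rec An [scr_recording()] (10 Hz recommended).
#' @param cs_onset CS onset time (s); the recording must cover
#'   `cs_onset + 9.5` s.
#' @param sustain Minimum duration (s) the derivative must stay positive
#'   for a rise to count (default 0.3).
#' @return A list with `onset` (s or `NA`), `peak_latency` (s or `NA`) and
#'   `amplitude` (>= 0).
#' @export
peak_score_trial <- function(rec, cs_onset, sustain = 0.3) {
  stopifnot(inherits(rec, "scr_recording"))
  rate <- rec$rate
  end_needed <- cs_onset + 9.5
  if (rec$t0 + (length(rec$values) - 1) / rate < end_needed - 1e-9)
    stop("recording does not cover cs_onset + 9.5 s")
  x <- rec$values
  at <- function(t) round((t - rec$t0) * rate) + 1L
  i_lo <- at(cs_onset + 1); i_hi <- at(cs_onset + 4.5)
  d <- diff(x)
  ns <- max(1L, round(sustain * rate))
  onset_i <- NA_integer_
  for (i in i_lo:i_hi) {
    if (i + ns - 1L > length(d)) break
    if (all(d[i:(i + ns - 1L)] > 0)) { onset_i <- i; break }
  }
  if (is.na(onset_i))
    return(list(onset = NA_real_, peak_latency = NA_real_, amplitude = 0))
  onset_t <- rec$t0 + (onset_i - 1L) / rate
  p_lo <- at(onset_t + 0.5); p_hi <- min(length(x), at(onset_t + 5))
  pk_rel <- which.max(x[p_lo:p_hi])
  peak_i <- p_lo + pk_rel - 1L
  amp <- x[peak_i] - x[onset_i]
  if (amp < 0) amp <- 0
  list(onset = onset_t,
       peak_latency = rec$t0 + (peak_i - 1L) / rate,
       amplitude = amp)
}

#' Peak scoring of a session
#'
#' Applies [peak_score_trial()] to every trial and computes participant
#' mean amplitudes per CS type, excluding reinforced CS+ trials (whose
#' unconditioned response would confound the anticipatory score).
#'
#' @param rec An [scr_recording()].
#' @param design The [session_design()].
#' @return A list with `scores` (data.frame: `trial`, `cs_type`,
#'   `reinforced`, `onset`, `peak_latency`, `amplitude`) and `means`
#'   (named numeric: mean amplitude for `CS+` and `CS-`; `NA` with a
#'   warning when a cell is empty).
#' @export
peak_score_session <- function(rec, design) {
  stopifnot(inherits(design, "session_design"))
  tr <- design$trials
  sc <- lapply(tr$cs_onset, function(o) peak_score_trial(rec, o))
  scores <- data.frame(
    trial = seq_len(nrow(tr)), cs_type = tr$cs_type,
    reinforced = tr$reinforced,
    onset = vapply(sc, `[[`, numeric(1L), "onset"),
    peak_latency = vapply(sc, `[[`, numeric(1L), "peak_latency"),
    amplitude = vapply(sc, `[[`, numeric(1L), "amplitude"))
  keep <- !(scores$cs_type == "CS+" & scores$reinforced)
  means <- c(
    "CS+" = mean(scores$amplitude[keep & scores$cs_type == "CS+"]),
    "CS-" = mean(scores$amplitude[keep & scores$cs_type == "CS-"]))
  if (anyNA(means) || any(is.nan(means))) {
    means[is.nan(means)] <- NA_real_
    warning("a CS-type cell is empty after excluding reinforced trials",
            call. = FALSE)
  }
  list(scores = scores, means = means)
}
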