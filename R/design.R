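#' Experimental session design
#'
#' The timeline of a fear-conditioning session: conditioned-stimulus (CS)
#' onsets, CS types, reinforcement flags, and the fixed design constants.
#' The conditioned stimulus lasts `cs_duration` seconds and the (potential)
#' unconditioned stimulus (US) occurs `soa` seconds after CS onset, so
#' anticipatory arousal is confined to `[cs_onset, cs_onset + soa]`.
#'
#' @param cs_onset Numeric vector of CS onset times (s), strictly increasing.
#' @param cs_type Character or factor, one of `"CS+"` / `"CS-"` per trial
#'   (the Unicode minus is accepted and normalised).
#' @param reinforced Logical per trial: was the US delivered? Only CS+ trials
#'   may be reinforced.
#' @param participant_id Participant label.
#' @param soa CS-onset-to-US latency in seconds (default 3.5).
#' @param cs_duration CS duration in seconds (default 4).
#' @param evoked_dispersion Fixed Gaussian width (SD, s) of the evoked
#'   sudomotor burst at US time (default 0.3, a sub-second burst for a
#'   punctate stimulus).
#'
#' @return An object of class `session_design`: a list with a `trials`
#'   data.frame (`cs_onset`, `cs_type`, `reinforced`) plus the constants.
#' @examples
#' session_design(c(10, 22, 35), c("CS+", "CS-", "CS+"),
#'                reinforced = c(TRUE, FALSE, FALSE))
#' @export
session_design <- function(cs_onset, cs_type, reinforced,
                           participant_id = "p01",
                           soa = 3.5, cs_duration = 4,
                           evoked_dispersion = 0.3) {
  cs_onset <- as.numeric(cs_onset)
  cs_type <- normalise_cs_type(cs_type)
  reinforced <- as.logical(reinforced)
  n <- length(cs_onset)
  if (n == 0L) stop("no trials")
  if (length(cs_type) != n || length(reinforced) != n)
    stop("cs_onset, cs_type and reinforced must have equal length")
  if (n > 1L && any(diff(cs_onset) <= 0))
    stop("cs_onset must be strictly increasing")
  if (any(reinforced & cs_type == "CS-"))
    stop("a CS- trial cannot be reinforced")
  if (soa > cs_duration)
    stop("soa must not exceed cs_duration")
  if (n > 1L && any(diff(cs_onset) < cs_duration))
    stop("inter-onset gaps must be at least cs_duration")
  structure(
    list(trials = data.frame(cs_onset = cs_onset, cs_type = cs_type,
                             reinforced = reinforced,
                             stringsAsFactors = FALSE),
         participant_id = as.character(participant_id),
         soa = soa, cs_duration = cs_duration,
         evoked_dispersion = evoked_dispersion),
    class = "session_design"
  )
}

normalise_cs_type <- function(x) {
  x <- as.character(x)
  x <- gsub("−", "-", x)  # Unicode minus
  if (!all(x %in% c("CS+", "CS-")))
    stop("cs_type must be 'CS+' or 'CS-'")
  x
}

#' @export
print.session_design <- function(x, ...) {
  tr <- x$trials
  cat(sprintf(
    "<session_design> %s: %d trials (%d CS+, %d reinforced), soa %g s, CS %g s\n",
    x$participant_id, nrow(tr), sum(tr$cs_type == "CS+"), sum(tr$reinforced),
    x$soa, x$cs_duration))
  invisible(x)
}

#' Number of trials in a design
#' @param design A [session_design()].
#' @return Integer number of trials.
#' @export
n_trials <- function(design) nrow(design$trials)

#' End of the anticipation window for each trial
#' @param design A [session_design()].
#' @return Numeric vector of US (or omission) times, `cs_onset + soa`.
#' @export
us_times <- function(design) design$trials$cs_onset + design$soa
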