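#' Synthetic cohort specification
#'
#' Describes a simulated discriminant delay fear-conditioning study. The
#' defaults emulate a typical session of the designs the package targets:
#' 4 s conditioned stimuli, the unconditioned stimulus (or its omission)
#' 3.5 s after CS onset, inter-trial intervals drawn from 7-11 s, half of
#' the trials CS+ with 50 percent reinforcement, and 90 trials per CS type.
#'
#' @param n_participants Number of participants (default 20).
#' @param trials_per_type Trials per CS type per participant (default 90).
#' @param cs_duration CS duration in seconds (default 4).
#' @param soa CS-onset-to-US latency in seconds (default 3.5).
#' @param iti_choices Possible inter-trial intervals in seconds, drawn
#'   uniformly per trial (default `c(7, 8, 9, 10, 11)`).
#' @param reinforcement_rate Fraction of CS+ trials that are reinforced
#'   (default 0.5; applied as an exact count).
#' @param effect Named mean anticipatory burst amplitude per CS type
#'   (default `c("CS+" = 1, "CS-" = 0.3)`).
#' @param amp_sd Trial-to-trial SD of anticipatory amplitudes (truncated at
#'   0; default 0.3).
#' @param onset_jitter_sd SD (s) of the anticipatory onset jitter within the
#'   CS-US window (default 0.8; the unknown, variable anticipation latency
#'   is precisely what defeats fixed-latency scorers).
#' @param onset_mean Mean anticipatory onset latency after CS onset
#'   (default 1.5 s; jitter is truncated to `[0, soa]`).
#' @param evoked_amp Mean evoked burst amplitude on reinforced trials
#'   (default 2).
#' @param sf_rate Spontaneous fluctuations per minute during inter-trial
#'   intervals (default 3).
#' @param sf_amp Mean spontaneous-fluctuation burst amplitude (default 0.4;
#'   spontaneous responses are commonly of the same order as event-related
#'   ones).
#' @param scl_drift_sd SD of per-trial tonic level increments (default
#'   0.02 microsiemens-equivalent).
#' @param noise_sd Measurement noise SD. The default `NA` sets it at run
#'   time to 10 percent of the mean anticipatory response peak.
#' @param gain_sd SD of the per-participant log-normal gain applied to the
#'   CS-locked (anticipatory and evoked) burst amplitudes (default 0.5),
#'   modelling peripheral differences in phasic response amplitude.
#' @param lability_sd SD of the per-participant log-normal electrodermal
#'   lability factor (default 0.5) that scales spontaneous-fluctuation
#'   amplitudes and measurement noise. Lability is an individual trait
#'   independent of stimulus-locked response gain; because whole-trace
#'   normalisation divides by a background-driven SD, independent lability
#'   is what lets response-scale differences survive preprocessing.
#' @param rate Recording sampling rate in Hz (default 10).
#' @param mri_spikes Inject 2 ms gradient-artefact spikes (only meaningful
#'   at high sampling rates)? Default `FALSE`.
#' @param seed Integer seed for the cohort's random generator.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 20L, trials_per_type = 90L,
                        cs_duration = 4, soa = 3.5,
                        iti_choices = c(7, 8, 9, 10, 11),
                        reinforcement_rate = 0.5,
                        effect = c("CS+" = 1, "CS-" = 0.3),
                        amp_sd = 0.3, onset_jitter_sd = 0.8,
                        onset_mean = 1.5, evoked_amp = 2,
                        sf_rate = 3, sf_amp = 0.4, scl_drift_sd = 0.02,
                        noise_sd = NA_real_, gain_sd = 0.5,
                        lability_sd = 0.5,
                        rate = 10, mri_spikes = FALSE, seed = 1L) {
  if (effect[["CS+"]] < effect[["CS-"]] || effect[["CS-"]] < 0)
    stop("effects must satisfy CS+ >= CS- >= 0")
  if (any(c(amp_sd, onset_jitter_sd, sf_rate, sf_amp, scl_drift_sd,
            gain_sd, lability_sd) < 0))
    stop("rates and SDs must be non-negative")
  if (min(iti_choices) <= 0) stop("inter-trial intervals must be positive")
  structure(as.list(environment()), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d participants x %d trials (%d per CS type), seed %d\n",
    x$n_participants, 2L * x$trials_per_type, x$trials_per_type, x$seed))
  invisible(x)
}

# documented sub-stream derivation: one sub-seed per participant, kept
# inside the 32-bit integer range
participant_seed <- function(seed, participant) {
  (as.integer(seed) * 131L + as.integer(participant) * 7919L) %% 2147483647L
}

#' Generate one synthetic session
#'
#' Draws a pseudo-randomised trial order, inter-trial intervals, ground
#' truth burst parameters (anticipatory amplitudes per CS type, jittered
#' onsets, evoked bursts on reinforced trials, Poisson spontaneous
#' fluctuations, tonic drift), applies the per-participant gain to all
#' burst amplitudes, renders the noise-free trace through the forward model
#' and adds white measurement noise. All draws come from a generator seeded
#' by a documented participant sub-seed.
#'
#' @param spec A [cohort_spec()].
#' @param participant Participant index (1-based).
#' @param rf Response function used for generation (default
#'   [canonical_rf()]).
#' @param render Render the conductance trace? Set `FALSE` for design-only
#'   simulations (ground truth and timeline without the forward model),
#'   which is much faster; `recording` is then `NULL`.
#' @return A list with elements `recording` ([scr_recording()]), `design`
#'   ([session_design()]), `truth` ([trial_params()]), `gain` and
#'   `lability`.
#' @export
generate_session <- function(spec, participant = 1L, rf = canonical_rf(),
                             render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (min(spec$iti_choices) < 1)
    stop("impossible design: inter-trial interval too short")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(participant_seed(spec$seed, participant))
  nt <- 2L * spec$trials_per_type
  cs_type <- sample(rep(c("CS+", "CS-"), spec$trials_per_type))
  plus_idx <- which(cs_type == "CS+")
  n_reinf <- round(spec$reinforcement_rate * length(plus_idx))
  reinforced <- logical(nt)
  reinforced[sample(plus_idx, n_reinf)] <- TRUE
  itis <- sample(spec$iti_choices, nt, replace = TRUE)
  cs_onset <- 10 + cumsum(c(0, (spec$cs_duration + itis)[-nt]))
  design <- session_design(cs_onset, cs_type, reinforced,
                           participant_id = sprintf("p%02d", participant),
                           soa = spec$soa, cs_duration = spec$cs_duration)
  gain <- exp(stats::rnorm(1L, 0, spec$gain_sd))
  lability <- exp(stats::rnorm(1L, 0, spec$lability_sd))
  amp <- truncnorm_pos(nt, unname(spec$effect[cs_type]), spec$amp_sd)
  lat <- pmin(pmax(stats::rnorm(nt, spec$onset_mean, spec$onset_jitter_sd),
                   0), spec$soa)
  onset <- cs_onset + lat
  disp <- rep(0.3, nt)
  amp_evk <- ifelse(reinforced, truncnorm_pos(nt, spec$evoked_amp, 0.3), 0)
  scl <- stats::rnorm(nt, 0, spec$scl_drift_sd)
  # spontaneous fluctuations: Poisson count per ITI at sf_rate per minute
  sf <- NULL
  offs <- cs_onset + spec$cs_duration
  nxt <- c(cs_onset[-1L], cs_onset[nt] + spec$cs_duration + max(itis))
  for (j in seq_len(nt)) {
    len <- nxt[j] - offs[j]
    k <- stats::rpois(1L, spec$sf_rate * len / 60)
    if (k > 0L)
      sf <- rbind(sf, data.frame(
        onset = sort(stats::runif(k, offs[j], nxt[j] - 1e-6)),
        amplitude = truncnorm_pos(k, spec$sf_amp, spec$sf_amp / 2),
        dispersion = 0.3))
  }
  truth <- trial_params(design,
                        amp_ant = gain * amp, onset_ant = onset,
                        disp_ant = disp, amp_evoked = gain * amp_evk,
                        scl_change = scl,
                        sf = if (is.null(sf)) NULL else
                          transform(sf, amplitude = lability * amplitude))
  if (!render)
    return(list(recording = NULL, design = design, truth = truth,
                gain = gain, lability = lability, noise_sd = NA_real_))
  duration <- cs_onset[nt] + spec$cs_duration + max(itis) + 20
  clean <- predict_scr(truth, design, rf, rate = spec$rate,
                       include_scl = TRUE, duration = duration)
  noise_sd <- spec$noise_sd
  if (is.na(noise_sd)) {
    # 10% of the mean anticipatory response peak: unit-peak kernel times
    # the (gained) mean amplitude, scaled by the burst's effective area
    kpk <- max(conv_causal(
      gauss_input(seq(0, 20, by = 1 / spec$rate), 5, 1, 0.3),
      rf_kernel(rf, spec$rate), 1 / spec$rate))
    noise_sd <- 0.1 * mean(gain * amp) * kpk
  }
  noise_sd <- lability * noise_sd
  vals <- clean$values + stats::rnorm(length(clean$values), 0, noise_sd)
  if (spec$mri_spikes && spec$rate >= 500) {
    n_spk <- max(1L, round(duration / 10))
    at <- sample(seq_along(vals), n_spk)
    wid <- max(1L, round(0.002 * spec$rate))
    for (a in at) vals[a:min(length(vals), a + wid - 1L)] <-
      vals[a] + 5 * stats::sd(vals)
  }
  rec <- scr_recording(vals, rate = spec$rate,
                       source_id = design$participant_id)
  list(recording = rec, design = design, truth = truth, gain = gain,
       lability = lability, noise_sd = noise_sd)
}

truncnorm_pos <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)

#' Generate a cohort of synthetic sessions
#'
#' One session per participant, each from a documented participant
#' sub-seed, plus a manifest describing the cohort.
#'
#' @param spec A [cohort_spec()].
#' @param rf Response function used for generation.
#' @return A list with `sessions` (list of [generate_session()] results)
#'   and `manifest` (data.frame of participant ids, sub-seeds and design
#'   digests).
#' @export
generate_cohort <- function(spec, rf = canonical_rf()) {
  stopifnot(inherits(spec, "cohort_spec"))
  sessions <- lapply(seq_len(spec$n_participants), function(p)
    generate_session(spec, p, rf))
  manifest <- data.frame(
    participant = seq_len(spec$n_participants),
    participant_id = vapply(sessions, function(s)
      s$design$participant_id, character(1L)),
    sub_seed = vapply(seq_len(spec$n_participants), function(p)
      participant_seed(spec$seed, p), integer(1L)),
    n_trials = vapply(sessions, function(s)
      n_trials(s$design), integer(1L)),
    checksum = vapply(sessions, function(s)
      sum(s$recording$values^2), numeric(1L)))
  list(sessions = sessions, manifest = manifest)
}
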