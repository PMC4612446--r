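#' Trial-structured sudomotor burst parameters
#'
#' Per-trial parameters of the generative model. Each trial has one
#' anticipatory Gaussian burst (free amplitude, onset and dispersion, with
#' the onset confined to the CS-US window), one evoked burst at the fixed
#' US latency (free amplitude, fixed dispersion), optional spontaneous
#' fluctuation (SF) bursts confined to the inter-trial interval, and a
#' signed tonic level change.
#'
#' @param design A [session_design()].
#' @param amp_ant,onset_ant,disp_ant Numeric vectors (one per trial):
#'   anticipatory burst peak amplitude (>= 0), onset (s, absolute time
#'   within `[cs_onset, cs_onset + soa]`) and Gaussian SD (s, > 0).
#' @param amp_evoked Evoked burst amplitudes (>= 0), one per trial; the
#'   evoked onset is `cs_onset + soa` and its dispersion is
#'   `design$evoked_dispersion`.
#' @param scl_change Signed tonic (skin conductance level) change per trial;
#'   defaults to zeros.
#' @param sf Optional data.frame of spontaneous fluctuations with columns
#'   `onset` (s), `amplitude` (>= 0) and `dispersion` (s); onsets must lie
#'   in an inter-trial interval (between a CS offset and the next CS onset).
#' @return An object of class `trial_params`.
#' @export
trial_params <- function(design, amp_ant, onset_ant, disp_ant,
                         amp_evoked = NULL, scl_change = NULL, sf = NULL) {
  stopifnot(inherits(design, "session_design"))
  nt <- n_trials(design)
  amp_ant <- rep_len(as.numeric(amp_ant), nt)
  onset_ant <- rep_len(as.numeric(onset_ant), nt)
  disp_ant <- rep_len(as.numeric(disp_ant), nt)
  amp_evoked <- if (is.null(amp_evoked)) numeric(nt)
                else rep_len(as.numeric(amp_evoked), nt)
  scl_change <- if (is.null(scl_change)) numeric(nt)
                else rep_len(as.numeric(scl_change), nt)
  if (any(amp_ant < 0) || any(amp_evoked < 0))
    stop("burst amplitudes must be non-negative")
  if (any(disp_ant <= 0)) stop("dispersions must be positive")
  on <- design$trials$cs_onset
  lo <- on; hi <- on + design$soa
  if (any(onset_ant < lo - 1e-9 | onset_ant > hi + 1e-9))
    stop("anticipatory onsets must lie within [cs_onset, cs_onset + soa]")
  if (!is.null(sf) && nrow(sf)) {
    stopifnot(all(c("onset", "amplitude", "dispersion") %in% names(sf)))
    if (any(sf$amplitude < 0) || any(sf$dispersion <= 0))
      stop("invalid spontaneous fluctuation parameters")
    offs <- on + design$cs_duration
    nexts <- c(on[-1L], Inf)
    ok <- vapply(sf$onset, function(o)
      any(o >= offs - 1e-9 & o < nexts + 1e-9), logical(1L))
    if (!all(ok))
      stop("spontaneous fluctuations must lie within an inter-trial interval")
  } else sf <- data.frame(onset = numeric(0), amplitude = numeric(0),
                          dispersion = numeric(0))
  structure(list(trials = data.frame(amp_ant = amp_ant, onset_ant = onset_ant,
                                     disp_ant = disp_ant,
                                     amp_evoked = amp_evoked,
                                     scl_change = scl_change),
                 sf = sf),
            class = "trial_params")
}

#' @export
print.trial_params <- function(x, ...) {
  cat(sprintf("<trial_params> %d trials, %d spontaneous fluctuations\n",
              nrow(x$trials), nrow(x$sf)))
  invisible(x)
}

# all bursts as one data.frame (onset, amplitude, dispersion)
all_bursts <- function(params, design) {
  tr <- params$trials
  on <- design$trials$cs_onset
  rbind(
    data.frame(onset = tr$onset_ant, amplitude = tr$amp_ant,
               dispersion = tr$disp_ant),
    data.frame(onset = on + design$soa, amplitude = tr$amp_evoked,
               dispersion = design$evoked_dispersion),
    params$sf[, c("onset", "amplitude", "dispersion")]
  )
}

# sum of Gaussian bursts evaluated at times tt
gauss_input <- function(tt, onset, amplitude, dispersion) {
  amplitude <- rep_len(amplitude, length(onset))
  dispersion <- rep_len(dispersion, length(onset))
  u <- numeric(length(tt))
  for (i in seq_along(onset)) {
    if (amplitude[i] == 0) next
    u <- u + amplitude[i] *
      exp(-(tt - onset[i])^2 / (2 * dispersion[i]^2))
  }
  u
}

#' Sudomotor nerve input time series
#'
#' The summed Gaussian burst train
#' \eqn{u(t) = \sum_i a_i \exp(-(t - o_i)^2 / (2 d_i^2))}
#' over all anticipatory, evoked and spontaneous bursts.
#'
#' @param params A [trial_params()].
#' @param design The matching [session_design()].
#' @param rate Sampling rate in Hz.
#' @param duration Length of the series in seconds; defaults to the last
#'   trial onset plus 60 s.
#' @return An [scr_recording()] holding the input series.
#' @export
sudomotor_input <- function(params, design, rate = 10, duration = NULL) {
  stopifnot(inherits(params, "trial_params"))
  if (is.null(duration))
    duration <- max(design$trials$cs_onset) + 60
  tt <- seq(0, duration, by = 1 / rate)
  b <- all_bursts(params, design)
  scr_recording(gauss_input(tt, b$onset, b$amplitude, b$dispersion),
                rate = rate, t0 = 0, source_id = "sudomotor_input")
}

#' Predicted skin conductance trace
#'
#' Integrates the response-function ODE driven by the sudomotor burst input
#' with a fixed-step classical Runge-Kutta scheme at 10 times the output
#' rate, then decimates. When `include_scl` is `TRUE`, a tonic drift
#' component is added: a per-trial step of height `scl_change` at each CS
#' onset, smoothed by a first-order lag with a 30 s time constant (slow
#' enough to stay disjoint from phasic responses). When `FALSE`, a single
#' constant baseline is used.
#'
#' @inheritParams sudomotor_input
#' @param rf An [ode_rf()].
#' @param include_scl Model per-trial tonic changes? Default `TRUE`.
#' @param baseline Constant baseline added to the output.
#' @return An [scr_recording()] holding the predicted trace.
#' @export
predict_scr <- function(params, design, rf, rate = 10, include_scl = TRUE,
                        baseline = 0, duration = NULL) {
  stopifnot(inherits(params, "trial_params"), inherits(rf, "ode_rf"))
  if (!rf_is_stable(rf)) stop("unstable response function")
  if (is.null(duration))
    duration <- max(design$trials$cs_onset) + 60
  b <- all_bursts(params, design)
  n_out <- floor(duration * rate) + 1L
  h <- 1 / (10 * rate)
  nsub <- (n_out - 1L) * 10L
  A <- rf_state_matrix(rf)
  ufun <- function(t) gauss_input(t, b$onset, b$amplitude, b$dispersion)
  # precompute input on the half-step grid used by RK4
  tsub <- seq(0, by = h, length.out = nsub + 1L)
  u_full <- ufun(tsub)
  u_half <- ufun(tsub[-length(tsub)] + h / 2)
  out <- rk4_lti(A, c(0, 0, rf$b), h, u_full, u_half)
  y <- out[seq(1L, nsub + 1L, by = 10L)]
  tt <- seq(0, by = 1 / rate, length.out = n_out)
  y <- y + baseline
  if (include_scl)
    y <- y + scl_drift(tt, design$trials$cs_onset, params$trials$scl_change)
  scr_recording(y, rate = rate, t0 = 0, source_id = "predicted_scr")
}

# Classical fixed-step RK4 for the LTI system x' = A x + B u(t) from rest.
# The RK4 step is the linear recursion x[k+1] = M x[k] + P1 u[k] +
# P2 u[k+1/2] + P4 u[k+1]; when M has real distinct eigenvalues the
# recursion is diagonalised and evaluated with stats::filter (identical
# arithmetic to the explicit loop up to machine precision), otherwise the
# loop is used.
rk4_lti <- function(A, Bv, h, u_full, u_half) {
  nsub <- length(u_half)
  Ah <- A * h
  M <- diag(nrow(A)) + Ah + Ah %*% Ah / 2 + Ah %*% Ah %*% Ah / 6 +
    Ah %*% Ah %*% Ah %*% Ah / 24
  step_input <- function(u1, u2, u4) {
    k1 <- Bv * u1
    k2 <- (Ah / 2) %*% k1 + Bv * u2
    k3 <- (Ah / 2) %*% k2 + Bv * u2
    k4 <- Ah %*% k3 + Bv * u4
    h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  P1 <- step_input(1, 0, 0); P2 <- step_input(0, 1, 0)
  P4 <- step_input(0, 0, 1)
  u1 <- u_full[seq_len(nsub)]
  u4 <- u_full[-1L]
  ev <- eigen(M)
  if (all(abs(Im(ev$values)) < 1e-12) &&
      min(dist(Re(ev$values))) > 1e-9) {
    V <- Re(ev$vectors)
    D <- cbind(P1, P2, P4)
    E <- solve(V, D)  # forcing in eigen coordinates
    out <- numeric(nsub + 1L)
    for (j in seq_len(nrow(V))) {
      ej <- E[j, 1L] * u1 + E[j, 2L] * u_half + E[j, 3L] * u4
      zj <- stats::filter(ej, Re(ev$values[j]), method = "recursive")
      out[-1L] <- out[-1L] + V[1L, j] * as.numeric(zj)
    }
    return(out)
  }
  x <- numeric(nrow(A))
  out <- numeric(nsub + 1L)
  for (k in seq_len(nsub)) {
    x <- M %*% x + P1 * u1[k] + P2 * u_half[k] + P4 * u4[k]
    out[k + 1L] <- x[1L]
  }
  out
}

# smoothed tonic drift: per-trial steps through a first-order lag (tau s)
scl_drift <- function(tt, onsets, changes, tau = 30) {
  d <- numeric(length(tt))
  for (j in seq_along(onsets)) {
    if (changes[j] == 0) next
    a <- tt >= onsets[j]
    d[a] <- d[a] + changes[j] * (1 - exp(-(tt[a] - onsets[j]) / tau))
  }
  d
}
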