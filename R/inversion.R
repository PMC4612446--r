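#' Inversion options
#'
#' Settings for the chunk-wise MAP inversion. Priors are Gaussian in
#' transformed parameter space: log for amplitudes and dispersions
#' (non-negativity), a scaled logit for the anticipatory onset (confining it
#' to the CS-US window), identity for tonic changes and baseline.
#'
#' @param trial_depth Number of successive trials estimated simultaneously
#'   (default 2; 3 supported).
#' @param include_scl Model per-trial tonic (skin conductance level)
#'   changes? Default `TRUE`. When `FALSE` the baseline is estimated for the
#'   first chunk and held constant.
#' @param priors Named list of prior hyper-parameters; see Details.
#' @param max_iterations Optimiser iteration cap per restart (default 500).
#' @param max_passes Cap on noise-variance/restart passes per chunk
#'   (default 12).
#' @param tol Relative convergence tolerance on the objective (default 1e-8).
#' @param sf_spacing Spacing (s) of the spontaneous-fluctuation amplitude
#'   grid within each inter-trial interval (default 2).
#' @param sf_dispersion Fixed Gaussian SD (s) of spontaneous-fluctuation
#'   bursts (default 0.3, the anticipatory dispersion prior median).
#' @param kernel_duration Length (s) of the response kernel used for
#'   prediction (default 60, beyond which the canonical response has decayed
#'   to ~1e-6 of its peak).
#' @param lead_in Seconds of signal included before the first chunk onset
#'   (default 2), so burst inputs that leak slightly before the window are
#'   represented.
#' @param noise_floor Floor on the per-chunk noise variance (default 1e-8, a numerical guard).
#' @param seed Unused by the deterministic optimiser; kept so a fixed
#'   configuration file fully describes a run.
#'
#' @details Default priors: anticipatory and evoked amplitudes are
#' log-normal with median 0.1 normalised units and log-SD 1; the onset prior
#' is centred mid-window (logit scale, SD 1); the dispersion is log-normal
#' with median 0.3 s and log-SD 0.5; tonic changes are `N(0, 0.5)`; the
#' baseline prior is centred on the window median with SD 10 (effectively
#' flat, so constant shifts of the recording are absorbed).
#'
#' @return An object of class `inversion_options`.
#' @export
inversion_options <- function(trial_depth = 2L, include_scl = TRUE,
                              priors = list(), max_iterations = 500L,
                              max_passes = 12L,
                              tol = 1e-8, sf_spacing = 2,
                              sf_dispersion = 0.3, kernel_duration = 60,
                              lead_in = 2, noise_floor = 1e-8, seed = NULL) {
  if (trial_depth < 1L) stop("trial_depth must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  pr <- list(amp_meanlog = log(0.1), amp_sdlog = 1,
             onset_mean = 0, onset_sd = 1,
             disp_meanlog = log(0.3), disp_sdlog = 0.5,
             sf_meanlog = log(0.1), sf_sdlog = 1,
             scl_sd = 0.5, b0_sd = 10)
  pr[names(priors)] <- priors
  structure(list(trial_depth = as.integer(trial_depth),
                 include_scl = include_scl, priors = pr,
                 max_iterations = as.integer(max_iterations),
                 max_passes = as.integer(max_passes), tol = tol,
                 sf_spacing = sf_spacing, sf_dispersion = sf_dispersion,
                 kernel_duration = kernel_duration, lead_in = lead_in,
                 noise_floor = noise_floor, seed = seed),
            class = "inversion_options")
}

# lower-triangular Toeplitz convolution matrix for a kernel, cached by size
conv_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(kern, n, dt) {
    key <- sprintf("%d|%.17g|%.17g", n, dt, kern[2L])
    if (is.null(cache[[key]])) {
      kk <- c(kern, numeric(max(0L, n - length(kern))))[seq_len(n)]
      idx <- outer(seq_len(n), seq_len(n), "-") + 1L
      K <- matrix(0, n, n)
      pos <- idx >= 1L
      K[pos] <- kk[idx[pos]] * dt
      cache[[key]] <- K
    }
    cache[[key]]
  }
})

# describe the parameter vector and burst layout of one chunk
chunk_layout <- function(design, chunk_trials, win_end_t, opts) {
  tr <- design$trials[chunk_trials, , drop = FALSE]
  pr <- opts$priors
  idx <- 0L
  nm <- character(0); mu <- numeric(0); sd <- numeric(0)
  add <- function(name, m, s) {
    idx <<- idx + 1L
    nm[idx] <<- name; mu[idx] <<- m; sd[idx] <<- s
    idx
  }
  bursts <- list()
  for (j in seq_len(nrow(tr))) {
    aj <- add(paste0("amp_ant", j), pr$amp_meanlog, pr$amp_sdlog)
    oj <- add(paste0("onset", j), pr$onset_mean, pr$onset_sd)
    dj <- add(paste0("disp", j), pr$disp_meanlog, pr$disp_sdlog)
    bursts[[length(bursts) + 1L]] <-
      list(kind = "ant", trial = j, a = aj, o = oj, d = dj,
           o_lo = tr$cs_onset[j], o_hi = tr$cs_onset[j] + design$soa,
           onset = NA, disp = NA)
    ej <- add(paste0("amp_evk", j), pr$amp_meanlog, pr$amp_sdlog)
    bursts[[length(bursts) + 1L]] <-
      list(kind = "evk", trial = j, a = ej, o = NA, d = NA,
           onset = tr$cs_onset[j] + design$soa,
           disp = design$evoked_dispersion)
  }
  # spontaneous-fluctuation grid within each ITI covered by the window
  nexts <- c(tr$cs_onset[-1L], win_end_t)
  for (j in seq_len(nrow(tr))) {
    iti0 <- tr$cs_onset[j] + design$cs_duration
    iti1 <- min(nexts[j], win_end_t)
    if (iti1 - iti0 < opts$sf_spacing / 2) next
    grid <- seq(iti0 + opts$sf_spacing / 2, iti1, by = opts$sf_spacing)
    for (g in grid) {
      fj <- add(sprintf("sf_%d_%.1f", j, g), pr$sf_meanlog, pr$sf_sdlog)
      bursts[[length(bursts) + 1L]] <-
        list(kind = "sf", trial = j, a = fj, o = NA, d = NA,
             onset = g, disp = opts$sf_dispersion)
    }
  }
  scl_idx <- integer(0)
  if (opts$include_scl)
    scl_idx <- vapply(seq_len(nrow(tr)), function(j)
      add(paste0("scl", j), 0, pr$scl_sd), integer(1L))
  b0_idx <- add("b0", 0, pr$b0_sd)  # prior mean set per chunk
  list(n_par = idx, names = nm, mu = mu, sd = sd, bursts = bursts,
       scl_idx = scl_idx, b0_idx = b0_idx, trials = tr)
}

# penalised objective for one chunk, as a stacked nonlinear least-squares
# problem: residuals = [ (y - pred)/sigma ; (theta - mu)/prior_sd ] so that
# 2 * f = sum(residuals^2). Returns the residual vector and, on request,
# the analytic Jacobian (rows follow the residuals, columns the
# parameters).
chunk_objective <- function(layout, tv, y, K, S, sigma2, b0_fixed = NULL) {
  bursts <- layout$bursts
  nb <- length(bursts)
  n <- length(y)
  mu <- layout$mu; psd <- layout$sd
  npar <- layout$n_par
  sig <- sqrt(sigma2)
  function(theta, want_jac = FALSE) {
    amp <- numeric(nb); ons <- numeric(nb); dsp <- numeric(nb)
    pvec <- numeric(nb)
    for (i in seq_len(nb)) {
      bi <- bursts[[i]]
      amp[i] <- exp(theta[bi$a])
      if (is.na(bi$o)) { ons[i] <- bi$onset } else {
        p <- stats::plogis(theta[bi$o])
        pvec[i] <- p
        ons[i] <- bi$o_lo + (bi$o_hi - bi$o_lo) * p
      }
      dsp[i] <- if (is.na(bi$d)) bi$disp else exp(theta[bi$d])
    }
    Tm <- outer(tv, ons, "-")
    G <- exp(-Tm^2 / (2 * rep(dsp^2, each = n)))
    u <- as.vector(G %*% amp)
    b0 <- if (is.null(b0_fixed)) theta[layout$b0_idx] else b0_fixed
    pred <- as.vector(K %*% u) + b0
    if (length(layout$scl_idx))
      pred <- pred + as.vector(S %*% theta[layout$scl_idx])
    r <- c((pred - y) / sig, (theta - mu) / psd)
    f <- 0.5 * sum(r^2)
    if (!want_jac) return(list(f = f, resid = r))
    # d u / d theta, column per parameter touching the burst input
    dU <- matrix(0, n, npar)
    for (i in seq_len(nb)) {
      bi <- bursts[[i]]
      aG <- amp[i] * G[, i]
      dU[, bi$a] <- dU[, bi$a] + aG
      if (!is.na(bi$o))
        dU[, bi$o] <- dU[, bi$o] + aG * Tm[, i] / dsp[i]^2 *
          (bi$o_hi - bi$o_lo) * pvec[i] * (1 - pvec[i])
      if (!is.na(bi$d))
        dU[, bi$d] <- dU[, bi$d] + aG * Tm[, i]^2 / dsp[i]^2
    }
    Jtop <- K %*% dU
    if (is.null(b0_fixed)) Jtop[, layout$b0_idx] <- 1
    if (length(layout$scl_idx)) Jtop[, layout$scl_idx] <- S
    J <- rbind(Jtop / sig, diag(1 / psd, npar))
    list(f = f, resid = r, jac = J)
  }
}

#' Invert a single chunk of trials
#'
#' Maximum-a-posteriori estimation of the burst parameters of
#' `trial_depth` successive trials. The penalised Gaussian log-likelihood
#' (residual sum of squares over the chunk window divided by the chunk noise
#' variance, plus Gaussian prior penalties in transformed space) is
#' minimised by a deterministic damped Gauss-Newton scheme
#' (Levenberg-Marquardt on the stacked data/prior residuals with an
#' analytic Jacobian) started from the prior means. Response tails and tonic steps
#' of earlier, already-estimated trials enter through `carry_in`.
#'
#' @param rec The preprocessed [scr_recording()] (10 Hz).
#' @param design The [session_design()].
#' @param first_trial Index of the chunk's first trial.
#' @param rf An [ode_rf()].
#' @param opts An [inversion_options()].
#' @param carry_in Either `NULL` or a list with elements `pred` (the
#'   predicted contribution of earlier trials over the whole recording) and
#'   `b0` (fixed baseline, used when `include_scl` is off after the first
#'   chunk).
#' @return A list with `params` (data.frame of per-trial estimates for the
#'   chunk's trials), `sf` (spontaneous-fluctuation estimates), `objective`
#'   (the attained value of the negative penalised misfit), `converged`,
#'   `b0` and `sigma2`.
#' @export
invert_chunk <- function(rec, design, first_trial, rf, opts = inversion_options(),
                         carry_in = NULL) {
  stopifnot(inherits(rec, "scr_recording"), inherits(design, "session_design"))
  nt <- n_trials(design)
  depth <- min(opts$trial_depth, nt - first_trial + 1L)
  chunk_trials <- first_trial:(first_trial + depth - 1L)
  on <- design$trials$cs_onset
  rate <- rec$rate
  n_all <- length(rec$values)
  win_start_t <- max(rec$t0, on[first_trial] - opts$lead_in)
  win_end_t <- if (first_trial + depth <= nt) on[first_trial + depth]
               else rec$t0 + (n_all - 1L) / rate
  i0 <- round((win_start_t - rec$t0) * rate) + 1L
  i1 <- min(n_all, round((win_end_t - rec$t0) * rate) + 1L)
  if (i1 <= i0) stop("chunk window lies outside the recording")
  tv <- rec$t0 + (seq(i0, i1) - 1L) / rate
  y <- rec$values[i0:i1]
  if (!is.null(carry_in) && !is.null(carry_in$pred))
    y <- y - carry_in$pred[i0:i1]
  layout <- chunk_layout(design, chunk_trials, win_end_t, opts)
  layout$mu[layout$b0_idx] <- stats::median(y)
  kern <- rf_kernel(rf, rate, opts$kernel_duration)
  K <- conv_matrix(kern, length(y), 1 / rate)
  S <- NULL
  if (length(layout$scl_idx)) {
    S <- vapply(seq_len(depth), function(j) {
      o <- layout$trials$cs_onset[j]
      ifelse(tv >= o, 1 - exp(-(tv - o) / 30), 0)
    }, numeric(length(tv)))
  }
  sigma2 <- max((stats::mad(diff(y)) / sqrt(2))^2, opts$noise_floor)
  b0_fixed <- if (!opts$include_scl && !is.null(carry_in$b0)) carry_in$b0
              else NULL
  # Deterministic damped Gauss-Newton (Levenberg-Marquardt) on the stacked
  # residuals with the analytic Jacobian, started from the prior means.
  # The noise variance is then iterated to its fixed point (residual
  # variance with a floor), refitting from the warm start after each
  # update.
  run_lm <- function(objfun, th0) {
    minpack.lm::nls.lm(
      par = th0,
      fn = function(th) objfun(th)$resid,
      jac = function(th) objfun(th, want_jac = TRUE)$jac,
      control = minpack.lm::nls.lm.control(
        maxiter = opts$max_iterations, ftol = opts$tol, ptol = opts$tol,
        gtol = 0))
  }
  objfun <- chunk_objective(layout, tv, y, K, S, sigma2, b0_fixed)
  res <- run_lm(objfun, layout$mu)
  for (pass in seq_len(max(2L, opts$max_passes))) {
    r_fit <- objfun(res$par)
    rss <- 2 * sigma2 *
      (r_fit$f - 0.5 * sum(((res$par - layout$mu) / layout$sd)^2))
    s2_new <- max(rss / length(y), opts$noise_floor)
    if (s2_new > 0.8 * sigma2 && s2_new < 1.25 * sigma2) break
    sigma2 <- s2_new
    objfun <- chunk_objective(layout, tv, y, K, S, sigma2, b0_fixed)
    res <- run_lm(objfun, res$par)
  }
  converged <- res$info %in% 1:4
  res$value <- objfun(res$par)$f
  if (!converged)
    warning(sprintf("chunk at trial %d: optimiser stopped early (%s)",
                    first_trial, res$message), call. = FALSE)
  th <- res$par
  tr <- layout$trials
  pars <- data.frame(
    trial = chunk_trials,
    amp_ant = numeric(depth), onset_ant = numeric(depth),
    disp_ant = numeric(depth), amp_evoked = numeric(depth),
    scl_change = numeric(depth))
  sf <- data.frame(trial = integer(0), onset = numeric(0),
                   amplitude = numeric(0), dispersion = numeric(0))
  for (b in layout$bursts) {
    if (b$kind == "ant") {
      pars$amp_ant[b$trial] <- exp(th[b$a])
      p <- stats::plogis(th[b$o])
      pars$onset_ant[b$trial] <- b$o_lo + (b$o_hi - b$o_lo) * p
      pars$disp_ant[b$trial] <- exp(th[b$d])
    } else if (b$kind == "evk") {
      pars$amp_evoked[b$trial] <- exp(th[b$a])
    } else {
      sf <- rbind(sf, data.frame(trial = chunk_trials[b$trial],
                                 onset = b$onset,
                                 amplitude = exp(th[b$a]),
                                 dispersion = b$disp))
    }
  }
  if (length(layout$scl_idx)) pars$scl_change <- th[layout$scl_idx]
  b0 <- if (is.null(b0_fixed)) th[layout$b0_idx] else b0_fixed
  list(params = pars, sf = sf, objective = -res$value,
       objective_start = -objfun(layout$mu)$f,
       converged = converged, b0 = b0, sigma2 = sigma2,
       window = c(i0, i1))
}

#' Invert a whole session
#'
#' Slides a window of `trial_depth` trials across the session in steps of
#' one trial. Each chunk is inverted by [invert_chunk()]; the estimates for
#' the window's first trial are retained (the final window retains all its
#' trials), and the retained trials' predicted contribution — response
#' tails and tonic steps — is carried forward so later chunks see a
#' residualised signal.
#'
#' @inheritParams invert_chunk
#' @return An object of class `sa_estimates`: a data.frame with one row per
#'   trial (`trial`, `cs_type`, `reinforced`, `amp_ant`, `onset_ant`,
#'   `disp_ant`, `amp_evoked`, `scl_change`, `objective`, `converged`),
#'   with the participant id, spontaneous-fluctuation table, baseline and
#'   options stored as attributes.
#' @export
invert_session <- function(rec, design, rf = canonical_rf(),
                           opts = inversion_options()) {
  stopifnot(inherits(rec, "scr_recording"), inherits(design, "session_design"))
  nt <- n_trials(design)
  span_end <- max(us_times(design)) + 1
  if (rec_duration(rec) + rec$t0 < span_end)
    stop("recording shorter than the design span")
  depth <- opts$trial_depth
  if (depth > nt) {
    warning(sprintf("trial_depth %d clamped to the %d available trial(s)",
                    depth, nt), call. = FALSE)
    depth <- nt
    opts$trial_depth <- nt
  }
  rate <- rec$rate
  n_all <- length(rec$values)
  carry <- list(pred = numeric(n_all), b0 = NULL)
  kern <- rf_kernel(rf, rate, opts$kernel_duration)
  est <- data.frame(trial = seq_len(nt),
                    cs_type = design$trials$cs_type,
                    reinforced = design$trials$reinforced,
                    amp_ant = NA_real_, onset_ant = NA_real_,
                    disp_ant = NA_real_, amp_evoked = NA_real_,
                    scl_change = NA_real_, objective = NA_real_,
                    converged = NA)
  sf_all <- NULL
  starts <- seq_len(max(1L, nt - depth + 1L))
  for (s in starts) {
    ch <- invert_chunk(rec, design, s, rf, opts, carry)
    if (!opts$include_scl && is.null(carry$b0)) carry$b0 <- ch$b0
    retain <- if (s == max(starts)) seq_len(nrow(ch$params)) else 1L
    for (rj in retain) {
      tr_idx <- ch$params$trial[rj]
      est[tr_idx, c("amp_ant", "onset_ant", "disp_ant", "amp_evoked",
                    "scl_change")] <-
        ch$params[rj, c("amp_ant", "onset_ant", "disp_ant", "amp_evoked",
                        "scl_change")]
      est$objective[tr_idx] <- ch$objective
      est$converged[tr_idx] <- ch$converged
      sf_keep <- ch$sf[ch$sf$trial == tr_idx, , drop = FALSE]
      sf_all <- rbind(sf_all, sf_keep)
      carry$pred <- carry$pred +
        trial_contribution(ch$params[rj, ], sf_keep, design, kern,
                           rate, n_all, rec$t0,
                           include_scl = opts$include_scl)
    }
  }
  structure(est,
            class = c("sa_estimates", "data.frame"),
            participant_id = design$participant_id,
            sf = sf_all, b0 = carry$b0, opts = opts, rf_label = rf$label)
}

# predicted contribution of one finalised trial over the whole recording
trial_contribution <- function(par, sf, design, kern, rate, n_all, t0,
                               include_scl = TRUE) {
  tr_idx <- par$trial
  cs_on <- design$trials$cs_onset[tr_idx]
  span0_t <- max(t0, cs_on - 2)
  a0 <- round((span0_t - t0) * rate) + 1L
  span_len <- min(n_all - a0 + 1L,
                  ceiling((design$soa + 90) * rate))
  tt <- t0 + (seq(a0, a0 + span_len - 1L) - 1L) / rate
  onsets <- c(par$onset_ant, cs_on + design$soa, sf$onset)
  amps <- c(par$amp_ant, par$amp_evoked, sf$amplitude)
  disps <- c(par$disp_ant, design$evoked_dispersion, sf$dispersion)
  u <- gauss_input(tt, onsets, amps, disps)
  cv <- conv_causal(u, kern, 1 / rate)
  out <- numeric(n_all)
  out[a0:(a0 + span_len - 1L)] <- cv
  # response tail beyond the computed span is negligible (kernel ~1e-6 of
  # peak at 60 s) but the tonic step persists to the end of the recording
  if (include_scl && par$scl_change != 0) {
    tfull <- t0 + (seq_len(n_all) - 1L) / rate
    a <- tfull >= cs_on
    out[a] <- out[a] + par$scl_change * (1 - exp(-(tfull[a] - cs_on) / 30))
  }
  out
}

# causal discrete convolution, output length = length(u)
conv_causal <- function(u, kern, dt) {
  n <- length(u)
  kk <- c(kern, numeric(max(0L, n - length(kern))))
  v <- stats::convolve(u, rev(kk), type = "open")[seq_len(n)] * dt
  v
}

#' @export
print.sa_estimates <- function(x, ...) {
  cat(sprintf("<sa_estimates> %s: %d trials (%d CS+)\n",
              attr(x, "participant_id"), nrow(x), sum(x$cs_type == "CS+")))
  print.data.frame(utils::head(as.data.frame(x), 6L), digits = 3)
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}
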