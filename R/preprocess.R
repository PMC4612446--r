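#' High-pass cutoff presets (Hz)
#'
#' The candidate high-pass cutoff frequencies evaluated for electrodermal
#' preprocessing; 0.0159 Hz (a 10 s time constant) is the default.
#' @export
hp_cutoff_presets <- c(0.005, 0.01, 0.0159, 0.035, 0.05, 0.06)

#' Filter specification
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff Cutoff frequency in Hz; must lie in (0, rate/2) for the
#'   recording it is applied to.
#' @param order Filter order (default 1, the standard choice for skin
#'   conductance).
#' @param direction For high-pass filters only: `"bi"` applies the filter
#'   forward then backward (zero net phase); `"uni"` applies it twice in the
#'   forward direction. Both apply the filter twice, so their magnitude
#'   responses are identical and only the phase differs.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("highpass", "lowpass"), cutoff,
                        order = 1L, direction = c("bi", "uni")) {
  kind <- match.arg(kind)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("`cutoff` must be a single positive frequency (Hz)")
  if (order < 1L) stop("`order` must be >= 1")
  direction <- if (kind == "highpass") match.arg(direction) else NA_character_
  structure(list(kind = kind, cutoff = cutoff, order = as.integer(order),
                 direction = direction),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s %g Hz, order %d%s\n", x$kind, x$cutoff,
              x$order,
              if (!is.na(x$direction)) paste0(", ", x$direction) else ""))
  invisible(x)
}

#' Median despiking
#'
#' Replaces each sample by the median of a centred window containing the
#' sample plus `n_neighbours` neighbours (window length `n_neighbours + 1`);
#' windows are truncated at the edges. Used to remove short (~2 ms)
#' MRI-gradient spikes from recordings acquired at high sampling rates.
#'
#' @param rec An [scr_recording()].
#' @param n_neighbours Even integer >= 2; number of neighbouring samples in
#'   the window (default 10, i.e. an 11-point median).
#' @return The despiked recording.
#' @export
median_despike <- function(rec, n_neighbours = 10L) {
  stopifnot(inherits(rec, "scr_recording"))
  if (n_neighbours < 2L || n_neighbours %% 2L != 0L)
    stop("`n_neighbours` must be an even integer >= 2")
  x <- rec$values
  n <- length(x)
  if (n <= n_neighbours)
    stop("recording shorter than the despiking window")
  half <- n_neighbours %/% 2L
  # stats::runmed is an efficient running median with the same centred
  # window; its "keep" endrule leaves edges untouched, so handle the edges
  # with explicit truncated windows.
  y <- stats::runmed(x, k = n_neighbours + 1L, endrule = "keep")
  for (i in seq_len(half)) {
    y[i] <- stats::median(x[1:(i + half)])
    y[n - i + 1L] <- stats::median(x[(n - i + 1L - half):n])
  }
  rec_update(rec, as.numeric(y),
             sprintf("median_despike(%d)", n_neighbours))
}

#' Butterworth filtering
#'
#' Low-pass filters are applied in a single forward pass of the stated
#' order. High-pass filters are always applied twice: forward then backward
#' when `direction = "bi"` (zero net phase shift), forward twice when
#' `direction = "uni"` (peaks shift later in time). Startup transients are
#' reduced by odd-reflection padding of three filter time constants at both
#' ends.
#'
#' @param rec An [scr_recording()].
#' @param spec A [filter_spec()].
#' @return The filtered recording (same length as the input).
#' @export
butter_filter <- function(rec, spec) {
  stopifnot(inherits(rec, "scr_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$rate / 2
  if (spec$cutoff >= nyq)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 spec$cutoff, nyq))
  bf <- signal::butter(spec$order, spec$cutoff / nyq,
                       type = if (spec$kind == "lowpass") "low" else "high")
  x <- rec$values
  n <- length(x)
  # pad with odd reflection over ~3 time constants to tame edge transients
  np <- min(n - 1L, max(1L, round(3 * rec$rate / (2 * pi * spec$cutoff))))
  xp <- c(2 * x[1L] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
  # start each pass from the steady state for the first sample, so a
  # constant trace maps to an exactly constant (zero, for high-pass) output
  dc_gain <- if (spec$kind == "lowpass") 1 else 0
  ord <- spec$order
  run <- function(v) as.numeric(signal::filter(
    bf$b, bf$a, v, init.x = rep(v[1L], ord),
    init.y = rep(dc_gain * v[1L], ord)))
  if (spec$kind == "lowpass") {
    yp <- run(xp)
  } else if (spec$direction == "bi") {
    yp <- rev(run(rev(run(xp))))
  } else {
    yp <- run(run(xp))
  }
  y <- yp[(np + 1L):(np + n)]
  rec_update(rec, y,
             sprintf("butter_%s(%g Hz, order %d%s)", spec$kind, spec$cutoff,
                     spec$order,
                     if (!is.na(spec$direction)) paste0(", ", spec$direction)
                     else ""))
}

#' Resample a recording to a lower rate
#'
#' Decimates by an integer factor when the source rate is an integer
#' multiple of the target rate (keeping the first sample), otherwise
#' linearly interpolates onto the target grid. Upsampling is refused. A 5 Hz
#' low-pass is expected upstream for anti-aliasing (not enforced).
#'
#' @param rec An [scr_recording()].
#' @param target_rate Target sampling rate in Hz (default 10).
#' @return The resampled recording.
#' @export
resample_to <- function(rec, target_rate = 10) {
  stopifnot(inherits(rec, "scr_recording"))
  if (target_rate > rec$rate)
    stop("no upsampling: target_rate exceeds the recording rate")
  if (target_rate == rec$rate) return(rec)
  ratio <- rec$rate / target_rate
  x <- rec$values
  if (abs(ratio - round(ratio)) < 1e-9) {
    y <- x[seq(1L, length(x), by = round(ratio))]
  } else {
    told <- rec_times(rec)
    tnew <- seq(told[1L], told[length(told)], by = 1 / target_rate)
    y <- stats::approx(told, x, xout = tnew)$y
  }
  out <- scr_recording(y, rate = target_rate, t0 = rec$t0,
                       source_id = rec$source_id,
                       provenance = rec$provenance)
  out$provenance <- c(out$provenance, sprintf("resample(%g Hz)", target_rate))
  out
}

#' Normalise a recording
#'
#' Subtracts the minimum and divides by the sample standard deviation
#' (n - 1 denominator), removing inter-individual differences in overall
#' signal level and scale. The output has minimum 0 and SD 1.
#'
#' @param rec An [scr_recording()].
#' @return The normalised recording.
#' @export
normalise <- function(rec) {
  stopifnot(inherits(rec, "scr_recording"))
  s <- stats::sd(rec$values)
  if (!is.finite(s) || s == 0)
    stop("degenerate recording: constant signal cannot be normalised")
  rec_update(rec, (rec$values - min(rec$values)) / s, "normalise")
}

#' Full preprocessing pipeline
#'
#' Applies, in order: optional median despiking (intended for
#' MRI-contaminated recordings), a first-order 5 Hz low-pass, downsampling
#' to 10 Hz, the configurable high-pass, and normalisation. Each step is
#' recorded in the output's provenance.
#'
#' @param rec An [scr_recording()].
#' @param hp A high-pass [filter_spec()]; default bi-directional 0.0159 Hz.
#' @param despike Apply [median_despike()] first? Default `FALSE`.
#' @param lowpass_cutoff Anti-aliasing low-pass cutoff in Hz (default 5).
#' @param target_rate Analysis sampling rate in Hz (default 10).
#' @return The preprocessed recording (10 Hz, minimum 0, SD 1).
#' @export
preprocess_pipeline <- function(rec,
                                hp = filter_spec("highpass", 0.0159,
                                                 direction = "bi"),
                                despike = FALSE,
                                lowpass_cutoff = 5,
                                target_rate = 10) {
  stopifnot(inherits(rec, "scr_recording"))
  if (!inherits(hp, "filter_spec") || hp$kind != "highpass")
    stop("`hp` must be a highpass filter_spec")
  if (despike) rec <- median_despike(rec)
  if (lowpass_cutoff < rec$rate / 2)
    rec <- butter_filter(rec, filter_spec("lowpass", lowpass_cutoff))
  rec <- resample_to(rec, target_rate)
  rec <- butter_filter(rec, hp)
  normalise(rec)
}
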