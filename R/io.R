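#' Read a skin conductance recording
#'
#' Two plain-text layouts are supported: a delimited two-column file
#' (`time`, `conductance`; the sampling rate is inferred from the time
#' column) and the BIDS physiological-recording convention
#' (`*_physio.tsv.gz` with a JSON sidecar carrying `SamplingFrequency`,
#' `StartTime` and `Columns`).
#'
#' @param path Path to the recording file.
#' @param format `"tsv"` or `"bids_physio"`. Guessed from the filename when
#'   missing (`*_physio.tsv(.gz)` selects BIDS).
#' @param source_id Provenance label; defaults to the file name.
#' @return An [scr_recording()] with values in microsiemens.
#' @export
read_recording <- function(path, format = c("auto", "tsv", "bids_physio"),
                           source_id = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("_physio\\.tsv(\\.gz)?$", path)) "bids_physio" else "tsv"
  if (format == "tsv") read_recording_tsv(path, source_id)
  else read_recording_bids(path, source_id)
}

read_recording_tsv <- function(path, source_id) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("recording TSV needs two columns (time, conductance)")
  tt <- as.numeric(tab[[1L]]); vv <- as.numeric(tab[[2L]])
  dts <- diff(tt)
  if (length(dts) < 1L || any(dts <= 0))
    stop("time column must be strictly increasing")
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-6 * max(dt, 1))
    stop("time column is not uniformly sampled; cannot infer a rate")
  rate <- 1 / dt
  if (abs(rate - round(rate)) < 1e-6 * rate) rate <- round(rate)
  scr_recording(vv, rate = rate, t0 = tt[1L], source_id = source_id)
}

read_recording_bids <- function(path, source_id) {
  sidecar <- sub("\\.tsv(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar))
    stop("BIDS sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$SamplingFrequency))
    stop("sidecar lacks SamplingFrequency: ", sidecar)
  rate <- as.numeric(meta$SamplingFrequency)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  tab <- utils::read.table(con, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  cols <- meta$Columns
  idx <- 1L
  if (!is.null(cols)) {
    hit <- grep("skin|conduct|eda|gsr|scr", cols, ignore.case = TRUE)
    if (length(hit)) idx <- hit[1L]
    if (ncol(tab) != length(cols))
      stop("column count mismatch between sidecar Columns and data")
  }
  vv <- as.numeric(tab[[idx]])
  vv <- vv * bids_unit_factor(meta$Units)
  t0 <- if (!is.null(meta$StartTime)) as.numeric(meta$StartTime) else 0
  scr_recording(vv, rate = rate, t0 = t0, source_id = source_id)
}

# conversion factor to microsiemens
bids_unit_factor <- function(units) {
  if (is.null(units)) return(1)
  u <- tolower(as.character(units)[1L])
  switch(u,
         "us" = , "microsiemens" = , "usiemens" = , "µs" = 1,
         "ms" = , "millisiemens" = 1e3,
         "s" = , "siemens" = 1e6,
         "ns" = , "nanosiemens" = 1e-3,
         stop("unrecognised conductance unit: ", units))
}

#' Read an event table into a session design
#'
#' Expects a delimited table (TSV/CSV, header required) with columns
#' `cs_onset` (s), `cs_type` (`CS+`/`CS-`) and `reinforced` (logical or 0/1).
#' An optional `participant_id` column labels the session.
#'
#' @param path Path to the event table.
#' @param ... Design constants passed to [session_design()]
#'   (`soa`, `cs_duration`, `evoked_dispersion`).
#' @return A [session_design()].
#' @export
read_events <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("no trials in ", path)
  need <- c("cs_onset", "cs_type", "reinforced")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  pid <- if ("participant_id" %in% names(tab)) tab$participant_id[1L] else "p01"
  session_design(tab$cs_onset, tab$cs_type,
                 as.logical(tab$reinforced),
                 participant_id = pid, ...)
}

#' Write an event table
#'
#' @param design A [session_design()].
#' @param path Output path (TSV).
#' @return Invisibly, `path`.
#' @export
write_events <- function(design, path) {
  tr <- design$trials
  tr$participant_id <- design$participant_id
  utils::write.table(format_num_df(tr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-trial arousal estimates
#'
#' One row per trial: trial index, CS type, reinforcement, anticipatory
#' amplitude/onset/duration, evoked amplitude, the chunk objective value and
#' a convergence flag. Excluded trials keep their row with amplitudes set to
#' `NA`. Values are written with enough digits to round-trip to 1e-9.
#'
#' @param estimates An `sa_estimates` data.frame as returned by
#'   [invert_session()] (or the `estimates` element of an [scr_dcm()] fit).
#' @param path Output path (TSV).
#' @return Invisibly, `path`.
#' @export
write_estimates <- function(estimates, path) {
  est <- as.data.frame(estimates)
  utils::write.table(format_num_df(est), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-trial arousal estimates written by [write_estimates()]
#' @param path Path to the estimates TSV.
#' @return An `sa_estimates` data.frame.
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  est <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(est) <- c("sa_estimates", "data.frame")
  est
}

#' Write a recording as a two-column TSV
#' @param rec An [scr_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  tab <- data.frame(time = rec_times(rec), conductance = rec$values)
  utils::write.table(format_num_df(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# format numeric columns with full precision so round-trips are lossless
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- trimws(formatC(df[[j]], format = "g", digits = 17))
  }
  df
}
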