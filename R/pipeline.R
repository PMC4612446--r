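#' Trial-level arousal table from model estimates
#'
#' @param estimates An `sa_estimates` data.frame from [invert_session()].
#' @param participant Participant label; defaults to the attribute stored
#'   on the estimates.
#' @return A data.frame with columns `participant`, `trial`, `cs_type`,
#'   `reinforced`, `sa` (the anticipatory amplitude).
#' @export
sa_table <- function(estimates, participant = NULL) {
  if (is.null(participant)) participant <- attr(estimates, "participant_id")
  data.frame(participant = participant, trial = estimates$trial,
             cs_type = estimates$cs_type, reinforced = estimates$reinforced,
             sa = estimates$amp_ant)
}

#' Trial-level arousal table from peak scores
#'
#' @param peaks Result of [peak_score_session()].
#' @param participant Participant label.
#' @return A data.frame in the same layout as [sa_table()].
#' @export
peak_table <- function(peaks, participant) {
  s <- peaks$scores
  data.frame(participant = participant, trial = s$trial,
             cs_type = s$cs_type, reinforced = s$reinforced,
             sa = s$amplitude)
}

#' Analyse a synthetic cohort with the model and the peak-scoring benchmark
#'
#' For every session: preprocess the recording (standard chain), fit the
#' chunk-wise MAP inversion, and run conventional peak scoring on the same
#' preprocessed trace. Returns trial-level arousal tables for both methods.
#'
#' @param cohort Result of [generate_cohort()].
#' @param opts An [inversion_options()].
#' @param hp High-pass [filter_spec()] for preprocessing.
#' @param rf `"canonical"`, `"individual"` or an [ode_rf()].
#' @param preprocess Apply the preprocessing chain? Default `TRUE`.
#' @param verbose Print one line per session?
#' @return A list with `dcm` and `peak` trial-level tables (see
#'   [sa_table()]).
#' @export
analyse_cohort <- function(cohort, opts = inversion_options(),
                           hp = filter_spec("highpass", 0.0159,
                                            direction = "bi"),
                           rf = "canonical", preprocess = TRUE,
                           verbose = FALSE) {
  dcm_rows <- list(); peak_rows <- list()
  for (i in seq_along(cohort$sessions)) {
    s <- cohort$sessions[[i]]
    rec <- if (preprocess) preprocess_pipeline(s$recording, hp = hp)
           else s$recording
    rf_i <- if (is.character(rf) && rf == "individual")
      individual_rf_or_canonical(rec, s$design, quiet = TRUE)
    else if (is.character(rf)) canonical_rf() else rf
    est <- invert_session(rec, s$design, rf_i, opts)
    pk <- peak_score_session(rec, s$design)
    pid <- s$design$participant_id
    dcm_rows[[i]] <- sa_table(est, pid)
    peak_rows[[i]] <- peak_table(pk, pid)
    if (verbose)
      message(sprintf("session %d/%d done", i, length(cohort$sessions)))
  }
  list(dcm = do.call(rbind, dcm_rows), peak = do.call(rbind, peak_rows))
}

#' Predictive validity of a trial-level arousal table
#'
#' Convenience wrapper: optional within-participant z-standardisation,
#' reinforced-trial exclusion and collapsing to cell means, then the
#' CS-type regression of [predictive_validity()].
#'
#' @param tbl A trial-level table (see [sa_table()]).
#' @param z Apply [z_standardise()] first? Default `FALSE`.
#' @return An `scr_comparison` object.
#' @export
table_validity <- function(tbl, z = FALSE) {
  if (z) tbl <- z_standardise(tbl)
  predictive_validity(sa_cell_means(tbl))
}
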