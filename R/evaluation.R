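#' Exclude reinforced CS+ trials
#'
#' Removes trials on which the US was delivered, so the unconditioned
#' response cannot confound the anticipatory arousal comparison. All CS-
#' and non-reinforced CS+ trials are retained.
#'
#' @param estimates An `sa_estimates` data.frame (or any data.frame with a
#'   `reinforced` column).
#' @param design Optional [session_design()]; when supplied, its
#'   reinforcement flags are used instead of the estimates' column.
#' @return The filtered estimates.
#' @export
exclude_reinforced <- function(estimates, design = NULL) {
  reinf <- if (!is.null(design)) design$trials$reinforced
           else estimates$reinforced
  out <- estimates[!reinf, , drop = FALSE]
  if (!any(!reinf & estimates$cs_type == "CS+"))
    warning("no CS+ trials remain after excluding reinforced trials",
            call. = FALSE)
  out
}

#' Within-participant z-standardisation of arousal estimates
#'
#' For each participant, subtracts the mean arousal estimate across all of
#' that participant's trials and divides by their standard deviation
#' (n - 1 denominator), removing between-subject scale differences.
#'
#' @param tbl A data.frame with columns `participant` and `sa` (one row per
#'   trial).
#' @return The same data.frame with `sa` standardised within participant.
#' @export
z_standardise <- function(tbl) {
  stopifnot(all(c("participant", "sa") %in% names(tbl)))
  for (p in unique(tbl$participant)) {
    i <- tbl$participant == p
    if (sum(i) < 2L)
      stop("participant ", p, " has fewer than 2 trials")
    s <- stats::sd(tbl$sa[i])
    if (!is.finite(s) || s == 0)
      stop("participant ", p, " has zero variance in arousal estimates")
    tbl$sa[i] <- (tbl$sa[i] - mean(tbl$sa[i])) / s
  }
  tbl
}

#' Per-participant cell means by CS type
#'
#' Collapses a trial-level arousal table to one mean per participant per CS
#' type, excluding reinforced trials first.
#'
#' @param tbl A data.frame with columns `participant`, `cs_type`,
#'   `reinforced` and `sa`.
#' @return A data.frame with columns `participant`, `cs_type`, `sa` (two
#'   rows per participant).
#' @export
sa_cell_means <- function(tbl) {
  stopifnot(all(c("participant", "cs_type", "reinforced", "sa") %in%
                  names(tbl)))
  tbl <- tbl[!tbl$reinforced, , drop = FALSE]
  agg <- stats::aggregate(sa ~ participant + cs_type, data = tbl, FUN = mean)
  agg[order(agg$participant, agg$cs_type), c("participant", "cs_type", "sa")]
}

#' Predictive validity of arousal estimates
#'
#' Fits, by least squares, the regression of numeric CS type (CS+ coded 1,
#' CS- coded 0) on the per-participant cell-mean arousal estimates plus one
#' constant per participant. Returns the residual sum of squares `rss`, the
#' row count `n`, the negative log likelihood `nll = n * log(rss / n)` (the
#' negative model evidence), the t statistic of the arousal coefficient
#' (algebraically the paired t test for this design) and its degrees of
#' freedom `n - (participants + 1)`.
#'
#' Because the dependent variable is the same for every candidate set of
#' estimates, `nll` values are comparable across estimate sets, and
#' rescaling or shifting the estimates leaves `nll` and `t` unchanged (the
#' shift is absorbed by the participant constants, the scale by the
#' coefficient).
#'
#' @param cell_means A data.frame as returned by [sa_cell_means()]: columns
#'   `participant`, `cs_type`, `sa`, two rows (one per CS type) per
#'   participant. Participants with a missing cell are dropped with a
#'   warning.
#' @return An object of class `scr_comparison`: a list with `nll`, `rss`,
#'   `n`, `t`, `df`, `coef` and `participants`.
#' @export
predictive_validity <- function(cell_means) {
  cm <- cell_means
  stopifnot(all(c("participant", "cs_type", "sa") %in% names(cm)))
  cm$cs_type <- normalise_cs_type(cm$cs_type)
  cnt <- table(cm$participant)
  complete <- names(cnt)[cnt == 2L]
  if (length(complete) < length(cnt))
    warning("dropping participant(s) with a missing CS-type cell: ",
            paste(setdiff(names(cnt), complete), collapse = ", "),
            call. = FALSE)
  cm <- cm[cm$participant %in% complete, , drop = FALSE]
  P <- length(complete)
  if (P < 3L) stop("need at least 3 participants with both cell means")
  y <- as.numeric(cm$cs_type == "CS+")
  fit <- stats::lm(y ~ 0 + factor(participant) + sa, data = cm)
  rss <- sum(stats::residuals(fit)^2)
  n <- length(y)
  if (is.na(stats::coef(fit)["sa"])) {
    # arousal column collinear with the participant constants: no signal
    tval <- 0; beta <- 0
  } else {
    co <- summary(fit)$coefficients["sa", , drop = FALSE]
    tval <- unname(co[1L, "t value"])
    beta <- unname(co[1L, "Estimate"])
  }
  structure(list(nll = n * log(rss / n), rss = rss, n = n,
                 t = tval, df = n - (P + 1L), coef = beta,
                 participants = P),
            class = "scr_comparison")
}

#' @export
print.scr_comparison <- function(x, ...) {
  cat(sprintf(
    "<scr_comparison> n = %d (%d participants)\n  NLL %.3f  RSS %.4f  t(%d) = %.3f\n",
    x$n, x$participants, x$nll, x$rss, x$df, x$t))
  invisible(x)
}

#' Log Bayes factor between two estimate sets
#'
#' `lbf = nll(result) - nll(reference)`. Negative values mean the evaluated
#' estimates have higher model evidence (better predictive validity) than
#' the reference. An absolute value above 3 is conventionally decisive:
#' the posterior probability of the null is about `1/exp(3)`, just below
#' 0.05.
#'
#' @param result,reference `scr_comparison` objects computed on the same
#'   participants and labels.
#' @return The log Bayes factor (numeric scalar) with attribute
#'   `decisive` (`abs(lbf) > 3`).
#' @export
log_bayes_factor <- function(result, reference) {
  stopifnot(inherits(result, "scr_comparison"),
            inherits(reference, "scr_comparison"))
  if (result$n != reference$n)
    stop("result and reference were computed on different row counts")
  lbf <- result$nll - reference$nll
  attr(lbf, "decisive") <- abs(lbf) > 3
  lbf
}

#' Comparison report across estimate sets
#'
#' Builds the standard comparison table: one row per evaluated set of
#' arousal estimates with its NLL, t statistic, degrees of freedom, LBF
#' against the reference (the first entry by default) and a decisiveness
#' flag.
#'
#' @param results Named list of `scr_comparison` objects.
#' @param reference Name or index of the reference entry (default 1).
#' @return A data.frame with columns `model`, `nll`, `t`, `df`, `lbf`,
#'   `decisive`.
#' @export
comparison_report <- function(results, reference = 1L) {
  ref <- results[[reference]]
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    lbf <- log_bayes_factor(r, ref)
    data.frame(model = nm, nll = r$nll, t = r$t, df = r$df,
               lbf = as.numeric(lbf), decisive = attr(lbf, "decisive"))
  })
  do.call(rbind, rows)
}
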