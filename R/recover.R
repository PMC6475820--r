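#' Compare pipeline estimates with the simulator's planted truth
#'
#' Validation harness for end-to-end runs on synthetic data: checks the
#' estimated sustained-interest share against the configured fraction, and
#' each concept's estimated query ratio against its planted pre-window
#' multiplier (concepts without a planted multiplier are expected at 1).
#' Estimates are flagged when they fall outside three standard errors —
#' binomial for the share, delta-method
#' `qr * sqrt(1/n_before + 1/n_after)` for a ratio of counts.
#'
#' @param truth `ground_truth` from [generate_logs()].
#' @param cohort A `cohort` (or members table) built from the generated
#'   log.
#' @param qr_table Optional [query_ratio_table()] output.
#' @param auc Optional `auc_result` to echo alongside the planted signal.
#' @return List of class `recovery_report`: `sustained` (estimate,
#'   expected, se, flag), `qr` (per-concept table with `expected`, `se`,
#'   `flagged`; defined ratios only), `auc`, and `n_flagged`.
#' @export
recover_parameters <- function(truth, cohort, qr_table = NULL,
                               auc = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  members <- if (inherits(cohort, "cohort")) cohort$members else cohort

  sustained <- NULL
  if (nrow(members)) {
    p_hat <- mean(members$interest == "sustained")
    se <- sqrt(max(p_hat * (1 - p_hat), 1e-12) / nrow(members))
    sustained <- list(estimate = p_hat,
                      expected = truth$sustained_fraction,
                      se = se,
                      n = nrow(members),
                      flagged = abs(p_hat - truth$sustained_fraction) >
                        3 * se)
  }

  qr <- NULL
  if (!is.null(qr_table)) {
    qr <- as.data.table(qr_table)[defined == TRUE & n_before > 0]
    mult <- truth$concept_multipliers
    qr[, expected := fifelse(concept_id %in% names(mult),
                             mult[concept_id], 1)]
    qr[, se := qr * sqrt(1 / n_before + 1 / n_after)]
    qr[, flagged := abs(qr - expected) > 3 * se]
  }

  n_flagged <- sum(c(isTRUE(sustained$flagged), qr$flagged))
  structure(list(sustained = sustained, qr = qr, auc = auc,
                 n_flagged = n_flagged),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  if (!is.null(x$sustained)) {
    s <- x$sustained
    cat(sprintf("  sustained share: %.4f (expected %.4f, se %.4f)%s\n",
                s$estimate, s$expected, s$se,
                if (s$flagged) "  ** FLAGGED" else ""))
  }
  if (!is.null(x$qr) && nrow(x$qr)) {
    cat(sprintf("  query ratios: %d concepts, %d flagged beyond 3 se\n",
                nrow(x$qr), sum(x$qr$flagged)))
  }
  if (!is.null(x$auc)) {
    cat(sprintf("  classifier mean AUC: %.3f (%s)\n", x$auc$mean_auc,
                x$auc$model))
  }
  cat(sprintf("  total flags: %d\n", x$n_flagged))
  invisible(x)
}

utils::globalVariables(c("expected", "se", "flagged"))
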