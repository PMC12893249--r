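## ---- detection and effect statistics ---------------------------------------

#' Window- and event-level detection metrics
#'
#' Confusion counts from equal-length binary label vectors plus derived
#' scores: sensitivity tp/(tp+fn), specificity tn/(tn+fp), F1, Matthews
#' correlation, negative predictive value, and (when probabilities are
#' supplied) AUROC and area under the precision--recall curve. When burst
#' intervals and trigger times are supplied, event-level sensitivity is the
#' fraction of true bursts receiving at least one trigger.
#'
#' @param pred_labels Predicted binary window labels.
#' @param true_labels True binary window labels.
#' @param probabilities Optional predicted probabilities for AUROC/AUPRC.
#' @param burst_intervals Optional two-column matrix/data.frame of burst
#'   `[start_s, end_s)` intervals for event-level scoring.
#' @param trigger_times_s Optional trigger times for event-level scoring;
#'   a burst counts as detected if a trigger's causing window overlaps it,
#'   assessed with `event_slack_s` tolerance after burst end.
#' @param event_slack_s Slack after burst end within which a trigger still
#'   counts (processing delay); default 1.
#' @return An object of class `detection_outcome`: counts, derived scores
#'   (undefined scores are `NA`, never 0), and event-level counts when
#'   available.
#' @export
detection_metrics <- function(pred_labels, true_labels, probabilities = NULL,
                              burst_intervals = NULL, trigger_times_s = NULL,
                              event_slack_s = 1) {
  stopifnot(length(pred_labels) == length(true_labels))
  tp <- sum(pred_labels == 1 & true_labels == 1)
  fp <- sum(pred_labels == 1 & true_labels == 0)
  tn <- sum(pred_labels == 0 & true_labels == 0)
  fn <- sum(pred_labels == 0 & true_labels == 1)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  npv <- div(tn, tn + fn)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  auroc <- auprc <- NA_real_
  if (!is.null(probabilities) && tp + fn > 0 && tn + fp > 0) {
    roc <- pROC::roc(true_labels, probabilities, quiet = TRUE,
                     direction = "<", levels = c(0, 1))
    auroc <- as.numeric(pROC::auc(roc))
    auprc <- pr_auc(probabilities, true_labels)
  }
  ev_tp <- ev_fn <- NA_integer_
  ev_sens <- NA_real_
  if (!is.null(burst_intervals)) {
    bi <- as.matrix(burst_intervals)
    if (nrow(bi) > 0) {
      detected <- vapply(seq_len(nrow(bi)), function(b) {
        any(trigger_times_s >= bi[b, 1] &
              trigger_times_s <= bi[b, 2] + event_slack_s)
      }, TRUE)
      ev_tp <- sum(detected)
      ev_fn <- sum(!detected)
      ev_sens <- ev_tp / nrow(bi)
    }
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, f1 = f1, mcc = mcc,
                 npv = npv, auroc = auroc, auprc = auprc,
                 event_tp = ev_tp, event_fn = ev_fn,
                 event_sensitivity = ev_sens),
            class = "detection_outcome")
}

## step-wise area under the precision-recall curve (average precision)
pr_auc <- function(probabilities, truth) {
  ord <- order(probabilities, decreasing = TRUE)
  y <- truth[ord]
  tp <- cumsum(y == 1)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / sum(y == 1)
}

#' False-positive trigger rate per minute
#'
#' @param fp_triggers Number of triggers during normal EEG.
#' @param session_minutes Session duration in minutes (> 0).
#' @return `fp_triggers / session_minutes`.
#' @export
fp_rate_per_min <- function(fp_triggers, session_minutes) {
  if (session_minutes <= 0) {
    sl_stop("session duration must be > 0", "spikeloop_invalid_configuration")
  }
  fp_triggers / session_minutes
}

#' Session reaction-time prolongation
#'
#' Mean RT during IED-bursts minus mean RT during normal EEG (the responses
#' to false-positive triggers serve as the within-session baseline); missed
#' trials are excluded from both means.
#'
#' @param rts_ied RTs (ms) for IED-state stimuli.
#' @param rts_normal RTs (ms) for normal-state stimuli.
#' @return Difference of means in ms, or `NA` if either side is empty.
#' @export
delta_rt <- function(rts_ied, rts_normal) {
  rts_ied <- rts_ied[!is.na(rts_ied)]
  rts_normal <- rts_normal[!is.na(rts_normal)]
  if (length(rts_ied) == 0 || length(rts_normal) == 0) return(NA_real_)
  mean(rts_ied) - mean(rts_normal)
}

#' Crash probabilities
#'
#' IED-associated crash probability (crashes during bursts per burst, in %),
#' normal-EEG crash probability (crashes during normal EEG per false-positive
#' trigger, in %), and their difference, the crash probability due to
#' IED-bursts (negative values preserved).
#'
#' @param n_crash_ied Crashes during IED-bursts.
#' @param n_ied Number of IED-bursts in the session.
#' @param n_crash_normal Crashes during normal EEG.
#' @param n_fp_triggers Triggers during normal EEG.
#' @return Named list `p_ied_pct`, `p_normal_pct`, `p_due_ied_pct`; a
#'   component with a zero denominator is `NA`.
#' @export
crash_probabilities <- function(n_crash_ied, n_ied, n_crash_normal,
                                n_fp_triggers) {
  p_ied <- if (is.na(n_ied) || n_ied == 0) NA_real_ else
    100 * n_crash_ied / n_ied
  p_normal <- if (is.na(n_fp_triggers) || n_fp_triggers == 0) NA_real_ else
    100 * n_crash_normal / n_fp_triggers
  list(p_ied_pct = p_ied, p_normal_pct = p_normal,
       p_due_ied_pct = p_ied - p_normal)
}

#' Cumulative crash-risk curve
#'
#' A logistic curve in the session RT prolongation, calibrated in closed form
#' to two published anchor points: 20% risk at 100 ms and 50% at 150 ms of
#' mean RT prolongation. The curve is strictly increasing and stands in for
#' the deployed nonlinear risk equation, whose exact form is not public; the
#' anchors (and thus the curve) are replaceable.
#'
#' @param anchors Two-row matrix/data.frame of `(delta_rt_ms, risk_fraction)`
#'   anchor points.
#' @return An object of class `risk_curve` with the fitted logistic
#'   parameters.
#' @export
risk_curve <- function(anchors = cbind(delta_rt_ms = c(100, 150),
                                       risk_fraction = c(0.2, 0.5))) {
  a <- as.matrix(anchors)
  if (nrow(a) != 2 || any(a[, 2] <= 0) || any(a[, 2] >= 1) ||
      a[1, 1] == a[2, 1]) {
    sl_stop("need two distinct anchors with risk in (0,1)",
            "spikeloop_invalid_configuration")
  }
  logit <- function(p) log(p / (1 - p))
  slope <- (logit(a[2, 2]) - logit(a[1, 2])) / (a[2, 1] - a[1, 1])
  intercept <- logit(a[1, 2]) - slope * a[1, 1]
  if (slope <= 0) {
    sl_stop("risk must increase with RT prolongation",
            "spikeloop_invalid_configuration")
  }
  structure(list(intercept = unname(intercept), slope = unname(slope),
                 anchors = a,
                 family = "logistic"), class = "risk_curve")
}

#' Cumulative crash risk for a session RT prolongation
#'
#' @param delta_rt_ms Session RT prolongation in ms.
#' @param params A fitted [risk_curve()].
#' @return Risk in percent, strictly increasing in `delta_rt_ms`.
#' @export
cumulative_crash_risk <- function(delta_rt_ms, params = risk_curve()) {
  if (!inherits(params, "risk_curve")) {
    sl_stop("params must be a fitted risk_curve", "spikeloop_invalid_configuration")
  }
  100 / (1 + exp(-(params$intercept + params$slope * delta_rt_ms)))
}

#' Cognitive-probe response probabilities
#'
#' Raw per-state percentages (incorrect/missed during IED-bursts relative to
#' all bursts; incorrect/missed during normal EEG relative to all
#' false-positive triggers) and the adjusted percentages (IED-state minus
#' normal-state, negative values preserved).
#'
#' @param n_incorrect_ied,n_missed_ied,n_ied IED-state counts and denominator.
#' @param n_incorrect_normal,n_missed_normal,n_fp_triggers Normal-state
#'   counts and denominator.
#' @return Named list of raw and adjusted percentages; components with a
#'   zero denominator are `NA`.
#' @export
iart_probabilities <- function(n_incorrect_ied, n_missed_ied, n_ied,
                               n_incorrect_normal, n_missed_normal,
                               n_fp_triggers) {
  pct <- function(num, den) if (is.na(den) || den == 0) NA_real_ else
    100 * num / den
  p_inc_ied <- pct(n_incorrect_ied, n_ied)
  p_miss_ied <- pct(n_missed_ied, n_ied)
  p_inc_norm <- pct(n_incorrect_normal, n_fp_triggers)
  p_miss_norm <- pct(n_missed_normal, n_fp_triggers)
  list(p_incorrect_normal_pct = p_inc_norm, p_missed_normal_pct = p_miss_norm,
       p_incorrect_ied_pct = p_inc_ied, p_missed_ied_pct = p_miss_ied,
       p_incorrect_due_ied_pct = p_inc_ied - p_inc_norm,
       p_missed_due_ied_pct = p_miss_ied - p_miss_norm)
}

#' Squared Pearson correlation of pairwise-complete pairs
#'
#' @param x,y Equal-length numeric vectors (>= 3 complete pairs).
#' @return R-squared, or `NA` when variance vanishes.
#' @export
correlate_r2 <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  if (sum(keep) < 3) sl_stop("need >= 3 complete pairs", "spikeloop_input")
  if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) return(NA_real_)
  stats::cor(x[keep], y[keep])^2
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (the signed-rank convention); the exact
#' distribution is used for n <= 25 untied nonzero differences and the
#' normal approximation above (or in the presence of ties).
#'
#' @param a,b Paired numeric vectors.
#' @return List with `statistic` (V), `p_value` (two-sided), `n_nonzero`;
#'   both are `NA` when all differences are zero.
#' @export
paired_wilcoxon <- function(a, b) {
  keep <- stats::complete.cases(a, b)
  d <- a[keep] - b[keep]
  d <- d[d != 0]
  if (length(d) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, n_nonzero = 0L))
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = length(d))
}

#' Distribution-free 95% confidence interval for the median
#'
#' Conservative order-statistic (binomial) interval: the largest `l` with
#' `pbinom(l - 1, n, 1/2) <= alpha/2` gives `(x_(l), x_(n-l+1))`.
#'
#' @param x Numeric vector (NAs dropped).
#' @param conf_level Confidence level (default 0.95).
#' @return Named vector `median`, `ci_low`, `ci_high` (CI is `NA` for n < 6,
#'   where no such interval exists at the 95% level).
#' @export
median_ci <- function(x, conf_level = 0.95) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  med <- stats::median(x)
  if (n == 0) return(c(median = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  alpha <- 1 - conf_level
  l <- 0L
  while (stats::pbinom(l, n, 0.5) <= alpha / 2) l <- l + 1L
  if (l < 1) return(c(median = med, ci_low = NA_real_, ci_high = NA_real_))
  c(median = med, ci_low = x[l], ci_high = x[n - l + 1])
}
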