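# Censoring-aware evaluation suite. All binary-status metrics at a horizon
# share one evaluable-set rule: positives are events by tau, negatives are
# patients followed at least to tau without a prior event, and patients
# censored before tau are excluded.

metric_result <- function(name, estimate, ci_low = NA_real_, ci_high = NA_real_,
                          n = NA_integer_) {
  structure(list(name = name, estimate = estimate, ci_low = ci_low,
                 ci_high = ci_high, n = n),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%s: %.4f", x$name, x$estimate))
  if (!is.na(x$ci_low)) cat(sprintf(" [%.4f, %.4f]", x$ci_low, x$ci_high))
  cat(sprintf(" (n = %d)\n", x$n))
  invisible(x)
}

#' Evaluable set and horizon status
#'
#' Shared rule for all binary-status metrics at horizon `tau`: status 1 if the
#' event occurred by `tau`; status 0 if followed to at least `tau` without a
#' prior event; patients censored before `tau` are excluded.
#'
#' @param times,events Follow-up times (months) and event indicators.
#' @param tau Horizon (months).
#' @return List with `keep` (logical) and `status` (0/1, length
#'   `sum(keep)`).
#' @export
evaluable_set <- function(times, events, tau) {
  pos <- events == 1 & times <= tau
  neg <- times >= tau & !pos
  keep <- pos | neg
  list(keep = keep, status = as.integer(pos[keep]))
}

#' Harrell's concordance index
#'
#' Probability that, of a randomly selected comparable pair, the patient with
#' the higher predicted risk experiences the event sooner. Pairs `(i, j)` are
#' comparable iff `t_i < t_j` and patient `i` had the event; ties in predicted
#' risk receive credit 0.5.
#'
#' @param times,events Follow-up times and event indicators.
#' @param risks Predicted risks (higher = worse prognosis).
#' @return A `metric_result`.
#' @export
c_index <- function(times, events, risks) {
  n <- length(times)
  stopifnot(length(events) == n, length(risks) == n)
  conc <- 0; comp <- 0
  ord <- order(times)
  tt <- times[ord]; ee <- events[ord]; rr <- risks[ord]
  for (i in seq_len(n)) {
    if (ee[i] != 1) next
    later <- which(tt > tt[i])
    if (length(later) == 0) next
    comp <- comp + length(later)
    conc <- conc + sum(rr[i] > rr[later]) + 0.5 * sum(rr[i] == rr[later])
  }
  if (comp == 0) stop_config("no comparable pairs")
  metric_result("c_index", conc / comp, n = n)
}

#' Area under the precision-recall curve at a horizon
#'
#' Average-precision summation over the evaluable set (ties in risk handled
#' as blocks).
#'
#' @inheritParams c_index
#' @param tau Horizon in months.
#' @return A `metric_result`.
#' @export
auprc_at_horizon <- function(risks, times, events, tau) {
  if (tau <= 0) stop_config("tau must be > 0")
  es <- evaluable_set(times, events, tau)
  r <- risks[es$keep]; y <- es$status
  n_pos <- sum(y)
  if (n_pos == 0) stop_config("no positives by the horizon")
  ord <- order(r, decreasing = TRUE)
  r <- r[ord]; y <- y[ord]
  grp <- cumsum(!duplicated(r))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  tp <- cumsum(tp_g); nn <- cumsum(n_g)
  prec <- tp / nn
  recall <- tp / n_pos
  d_recall <- diff(c(0, recall))
  metric_result("auprc", sum(d_recall * prec), n = length(y))
}

# Restricted cubic spline basis with three knots: natural cubic spline with
# an interior knot at the risk median and boundary knots at the 10th/90th
# percentiles.
rcs3_basis <- function(x, knots) {
  splines::ns(x, knots = knots[2], Boundary.knots = knots[c(1, 3)])
}

#' Smoothed calibration curve and integrated calibration index
#'
#' Fits a logistic restricted-cubic-spline smoother (three knots at the
#' 10th/50th/90th percentiles of predicted risk) of the horizon status on the
#' predicted risk over the evaluable set, and reports the ICI: the mean
#' absolute difference between smoothed observed risk and predicted risk
#' (0 is ideal).
#'
#' @inheritParams auprc_at_horizon
#' @return List of class `calibration_curve`: data frame `curve`
#'   (`predicted`, `observed`), `ici`, and the evaluable-set size `n`.
#' @export
calibration_curve_ici <- function(risks, times, events, tau) {
  es <- evaluable_set(times, events, tau)
  r <- risks[es$keep]; y <- es$status
  knots <- unname(stats::quantile(r, c(0.1, 0.5, 0.9)))
  if (length(unique(knots)) < 3 || length(unique(r)) < 4) {
    stop_config("degenerate risk distribution: calibration spline needs spread")
  }
  basis <- rcs3_basis(r, knots)
  fit <- stats::glm(y ~ basis, family = stats::binomial())
  obs <- stats::fitted(fit)
  ord <- order(r)
  structure(list(curve = data.frame(predicted = r[ord], observed = obs[ord]),
                 ici = mean(abs(obs - r)), n = length(y)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration curve: ICI = %.4f (n = %d)\n", x$ici, x$n))
  invisible(x)
}

#' Decision curve analysis with Kaplan-Meier censoring correction
#'
#' Net benefit at each threshold `p_t`:
#' `NB = TP/n - FP/n * p_t / (1 - p_t)`, where among patients predicted
#' positive (risk >= p_t) the event probability by `tau` is estimated by
#' Kaplan-Meier within that group, so `TP = n_pos * (1 - S_KM(tau))` and
#' `FP = n_pos * S_KM(tau)`. Includes treat-all and treat-none strategies.
#'
#' @inheritParams auprc_at_horizon
#' @param thresholds Decision thresholds in (0, 1).
#' @return A `decision_curve` data frame with columns `threshold`,
#'   `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(risks, times, events, tau, thresholds) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop_config("thresholds must lie strictly in (0, 1)")
  }
  n <- length(risks)
  km_event_prob <- function(sel) {
    if (sum(sel) == 0) return(0)
    fit <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1)
    s <- summary(fit, times = tau, extend = TRUE)$surv
    1 - s
  }
  p_all <- km_event_prob(rep(TRUE, n))
  nb <- vapply(thresholds, function(pt) {
    sel <- risks >= pt
    npos <- sum(sel)
    if (npos == 0) return(0)
    pe <- km_event_prob(sel)
    (npos * pe) / n - (npos * (1 - pe)) / n * pt / (1 - pt)
  }, 0)
  ta <- vapply(thresholds, function(pt) p_all - (1 - p_all) * pt / (1 - pt), 0)
  structure(data.frame(threshold = thresholds, net_benefit = nb,
                       treat_all = ta, treat_none = 0),
            class = c("decision_curve", "data.frame"))
}

#' Impact analysis at decision thresholds
#'
#' Confusion counts, positive predictive value and sensitivity per threshold
#' on the evaluable set.
#'
#' @inheritParams auprc_at_horizon
#' @param thresholds Decision thresholds (default 0.25, 0.50, 0.75).
#' @return An `impact_table` data frame with one row per threshold.
#' @export
impact_analysis <- function(risks, times, events, tau,
                            thresholds = c(0.25, 0.5, 0.75)) {
  es <- evaluable_set(times, events, tau)
  r <- risks[es$keep]; y <- es$status
  if (length(y) == 0) stop_config("empty evaluable set")
  rows <- lapply(thresholds, function(pt) {
    pred <- r >= pt
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
    data.frame(threshold = pt, TP = tp, FP = fp, FN = fn, TN = tn,
               PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  })
  structure(do.call(rbind, rows), class = c("impact_table", "data.frame"))
}

#' Compare two models' impact tables
#'
#' False-positive/false-negative differences and percentage changes of
#' `model` relative to `reference` at matched thresholds.
#'
#' @param model,reference `impact_table` objects with identical thresholds.
#' @return Data frame of per-threshold differences.
#' @export
impact_comparison <- function(model, reference) {
  stopifnot(all(model$threshold == reference$threshold))
  data.frame(threshold = model$threshold,
             FP_diff = model$FP - reference$FP,
             FN_diff = model$FN - reference$FN,
             FP_pct_change = ifelse(reference$FP > 0,
                                    100 * (model$FP - reference$FP) / reference$FP,
                                    NA_real_),
             FN_pct_change = ifelse(reference$FN > 0,
                                    100 * (model$FN - reference$FN) / reference$FN,
                                    NA_real_),
             PPV_diff = model$PPV - reference$PPV,
             sensitivity_diff = model$sensitivity - reference$sensitivity)
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples patients with replacement and reports the 2.5/97.5 percentile
#' interval of the metric across resamples; seeded and deterministic.
#'
#' @param metric_fn Function of a data frame of patient-level data returning
#'   a scalar (or a `metric_result`, whose estimate is used).
#' @param data Data frame, one row per patient.
#' @param B_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param name Metric name for the result.
#' @return A `metric_result` with the point estimate on the full data and the
#'   bootstrap CI.
#' @export
bootstrap_ci <- function(metric_fn, data, B_boot = 200L, seed = 1L,
                         name = "metric") {
  est <- metric_fn(data)
  if (inherits(est, "metric_result")) est <- est$estimate
  vals <- with_local_seed(seed, {
    vapply(seq_len(B_boot), function(b) {
      d <- data[sample(nrow(data), replace = TRUE), , drop = FALSE]
      v <- tryCatch(metric_fn(d), error = function(e) NA_real_)
      if (inherits(v, "metric_result")) v <- v$estimate
      as.numeric(v)
    }, 0)
  })
  ok <- is.finite(vals)
  if (mean(ok) < 0.5) stop_config("metric undefined on more than half the resamples")
  qs <- stats::quantile(vals[ok], c(0.025, 0.975), names = FALSE)
  metric_result(name, est, qs[1], qs[2], nrow(data))
}

#' Subgroup evaluation with deviation from the overall estimate
#'
#' Computes a metric per subgroup and its signed deviation from the
#' all-patients estimate. Groups below `min_size` evaluable patients are
#' skipped with a warning.
#'
#' @param metric_fn As in [bootstrap_ci()].
#' @param data Patient-level data frame.
#' @param grouping Name of the grouping column in `data`, or a factor.
#' @param min_size Minimum group size (default 50).
#' @return Data frame with one row per group: estimate, n, and deviation from
#'   the overall estimate.
#' @export
subgroup_eval <- function(metric_fn, data, grouping, min_size = 50L) {
  g <- if (is.character(grouping) && length(grouping) == 1) {
    factor(data[[grouping]])
  } else {
    factor(grouping)
  }
  overall <- metric_fn(data)
  if (inherits(overall, "metric_result")) overall <- overall$estimate
  rows <- lapply(levels(g), function(lv) {
    d <- data[which(g == lv), , drop = FALSE]
    if (nrow(d) < min_size) {
      warning(sprintf("subgroup '%s' below minimum size (%d < %d); skipped",
                      lv, nrow(d), min_size), call. = FALSE)
      return(NULL)
    }
    v <- metric_fn(d)
    if (inherits(v, "metric_result")) v <- v$estimate
    data.frame(group = lv, estimate = v, n = nrow(d),
               deviation = v - overall, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "overall") <- overall
  out
}

#' Nelson-Aalen cumulative hazard estimator
#'
#' `H(t) = sum over event times t_i <= t of d_i / n_i`, with `d_i` events and
#' `n_i` at risk. Returned as a right-continuous step function; used as the
#' auxiliary outcome variable in chained-equation imputation.
#'
#' @param times,events Follow-up times and event indicators.
#' @return A function `H(t)`; the step coordinates are in attributes `time`
#'   and `hazard`.
#' @export
nelson_aalen <- function(times, events) {
  if (length(times) == 0) stop_config("empty input")
  ord <- order(times)
  tt <- times[ord]; ee <- events[ord]
  ut <- unique(tt[ee == 1])
  if (length(ut) == 0) {
    f <- function(t) rep(0, length(t))
    attr(f, "time") <- numeric(0); attr(f, "hazard") <- numeric(0)
    return(f)
  }
  d <- vapply(ut, function(u) sum(tt == u & ee == 1), 0)
  n_at_risk <- vapply(ut, function(u) sum(tt >= u), 0)
  H <- cumsum(d / n_at_risk)
  f <- stats::stepfun(ut, c(0, H), right = FALSE)
  attr(f, "time") <- ut; attr(f, "hazard") <- H
  f
}
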