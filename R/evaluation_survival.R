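#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator computed from its definition: at each distinct
#' event time `t`, the survival curve is multiplied by `1 - d/n` with `d`
#' events and `n` at risk. The median is the first time at which survival
#' drops to 0.5 or below; `NA` means the median was not reached.
#'
#' @param times Nonnegative follow-up times.
#' @param events Logical event indicators (`FALSE` = censored).
#' @return List of class `"km_fit"`: `steps` (data.frame `time`, `n_risk`,
#'   `n_event`, `survival`) and `median`.
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0)) stop("negative follow-up time")
  events <- as.logical(events)
  ut <- sort(unique(times[events]))
  surv <- 1
  steps <- lapply(ut, function(t) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events)
    surv <<- surv * (1 - d / n_risk)
    data.frame(time = t, n_risk = n_risk, n_event = d, survival = surv)
  })
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(time = numeric(0), n_risk = integer(0),
               n_event = integer(0), survival = numeric(0))
  med <- if (any(steps$survival <= 0.5)) {
    steps$time[which(steps$survival <= 0.5)[1]]
  } else NA_real_
  structure(list(steps = steps, median = med), class = "km_fit")
}

#' Mantel-Haenszel (log-rank) test and O/E hazard ratio
#'
#' Standard log-rank statistic summed over distinct event times: observed
#' minus expected events in group A under the hypergeometric null, squared
#' and divided by the summed variance, referred to chi-square with 1 df.
#' The hazard ratio is the ratio of observed-to-expected ratios,
#' `(O_A/E_A) / (O_B/E_B)` (group A in the numerator), with a log-scale
#' confidence interval using `se(log HR) = sqrt(1/E_A + 1/E_B)`.
#'
#' @param times_a,events_a Follow-up and event flags of group A.
#' @param times_b,events_b Follow-up and event flags of group B.
#' @param conf Confidence level (default 0.95).
#' @return List: `chi2`, `p_value`, `observed`, `expected`, `hazard_ratio`,
#'   `hr_lower`, `hr_upper` (HR components `NA` when a group has no
#'   expected events; with zero events overall, `p_value = 1`).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b, conf = 0.95) {
  times <- c(times_a, times_b)
  events <- as.logical(c(events_a, events_b))
  grp_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  ut <- sort(unique(times[events]))

  o_a <- e_a <- v <- 0
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp_a)
    d <- sum(times == t & events)
    d_a <- sum(times == t & events & grp_a)
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) {
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
  }
  o <- sum(events)
  if (o == 0) {
    return(list(chi2 = 0, p_value = 1, observed = c(a = 0, b = 0),
                expected = c(a = 0, b = 0), hazard_ratio = NA_real_,
                hr_lower = NA_real_, hr_upper = NA_real_))
  }
  o_b <- o - o_a
  e_b <- o - e_a
  chi2 <- if (v > 0) (o_a - e_a)^2 / v else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)

  if (e_a > 0 && e_b > 0 && o_a > 0 && o_b > 0) {
    hr <- (o_a / e_a) / (o_b / e_b)
    se <- sqrt(1 / e_a + 1 / e_b)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    hr_l <- exp(log(hr) - z * se)
    hr_u <- exp(log(hr) + z * se)
  } else {
    hr <- hr_l <- hr_u <- NA_real_
  }
  list(chi2 = chi2, p_value = p,
       observed = c(a = o_a, b = o_b), expected = c(a = e_a, b = e_b),
       hazard_ratio = hr, hr_lower = hr_l, hr_upper = hr_u)
}

#' ROC curve and AUC
#'
#' AUC as the Mann-Whitney concordance probability (ties credited 1/2),
#' computed from ranks; the curve is a threshold sweep over the observed
#' scores.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param truth Class labels.
#' @param positive The positive class (default `"N-CB"`, the convention
#'   for sensitivity in this analysis).
#' @return List: `auc` and `curve` (data.frame `threshold`, `tpr`, `fpr`).
#' @export
roc_auc <- function(scores, truth, positive = "N-CB") {
  pos <- truth == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)          # average ranks give the 1/2 tie credit
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)))
  list(auc = auc, curve = curve)
}

#' Confusion-matrix metrics with N-CB as the positive class
#'
#' Sensitivity is computed with respect to N-CB (true positives) and
#' specificity with respect to CB (true negatives).
#'
#' @param predicted,truth Character vectors of `"CB"` / `"N-CB"` labels.
#' @param positive Positive class (default `"N-CB"`).
#' @return List of class `"performance_summary"`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(predicted, truth, positive = "N-CB") {
  stopifnot(length(predicted) == length(truth))
  pos <- truth == positive
  pred_pos <- predicted == positive
  tp <- sum(pred_pos & pos)
  fp <- sum(pred_pos & !pos)
  tn <- sum(!pred_pos & !pos)
  fn <- sum(!pred_pos & pos)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "performance_summary")
}

#' Wilcoxon test (signed-rank or rank-sum)
#'
#' Thin wrapper over [stats::wilcox.test()] matching the analysis
#' conventions: exact p for 25 or fewer observations without ties, normal
#' approximation with continuity and tie correction otherwise. A paired
#' test whose differences are all zero returns p = 1.
#'
#' @param x,y Numeric samples (equal length when `paired`).
#' @param paired Signed-rank on differences when `TRUE`, rank-sum otherwise.
#' @return List: `statistic`, `p_value`, `method`.
#' @export
wilcoxon_test <- function(x, y, paired = FALSE) {
  if (paired) {
    stopifnot(length(x) == length(y))
    d <- x - y
    if (all(d == 0)) {
      return(list(statistic = 0, p_value = 1,
                  method = "Wilcoxon signed rank (degenerate)"))
    }
    nz <- d[d != 0]
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    wt <- stats::wilcox.test(x, y, paired = TRUE, exact = exact,
                             correct = TRUE)
  } else {
    exact <- length(x) + length(y) <= 25 && !any(duplicated(c(x, y)))
    wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  }
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}

#' Survival stratification by predicted label
#'
#' Kaplan-Meier fits per predicted group plus the log-rank comparison with
#' the predicted-CB group as the hazard-ratio reference (group A = N-CB, so
#' HR > 1 means faster progression in the predicted N-CB group).
#'
#' @param labels Predicted `"CB"` / `"N-CB"` labels.
#' @param pfs,event PFS (months) and event flags.
#' @return List: `km` (per-group [km_estimate()] fits), `logrank`, and
#'   `medians`.
#' @export
stratify_survival <- function(labels, pfs, event) {
  km <- lapply(split(seq_along(labels), labels), function(i) {
    km_estimate(pfs[i], event[i])
  })
  lr <- if (all(c("CB", "N-CB") %in% labels)) {
    logrank_test(pfs[labels == "N-CB"], event[labels == "N-CB"],
                 pfs[labels == "CB"], event[labels == "CB"])
  } else NULL
  list(km = km, logrank = lr,
       medians = vapply(km, function(f) f$median, numeric(1)))
}
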