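# Kaplan-Meier estimation, two-group log-rank testing, and best-cutoff
# stratification of a continuous score (the cutoff minimizing the log-rank
# p-value). KM and log-rank wrap the survival package; the cutoff scan and
# signature reporting are this package's logic.
#
# Caveat baked into the design: minimal-p cutoff selection inflates type-I
# error; best_cutoff() can attach a permutation-adjusted p for the selected
# cutoff (off by default to mirror common practice).

#' Survival records
#'
#' @param time Positive follow-up times.
#' @param event Event indicator, 1 = death/recurrence, 0 = censored.
#' @return data.frame with validated \code{time} and \code{event}.
#' @export
survival_records <- function(time, event) {
  if (any(time <= 0)) stop_("times must be > 0")
  if (!all(event %in% c(0, 1))) stop_("event flags must be 0 or 1")
  data.frame(time = time, event = as.integer(event))
}

#' Kaplan-Meier curve
#'
#' Product-limit estimate; individuals censored at an event time remain at
#' risk for that time (standard convention).
#'
#' @param time,event As in [survival_records()].
#' @return data.frame: time (ordered unique event/censoring times), n_risk,
#'   n_event, n_censor, surv (non-increasing, S(0) = 1).
#' @export
km_curve <- function(time, event) {
  rec <- survival_records(time, event)
  fit <- survival::survfit(survival::Surv(rec$time, rec$event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank with hypergeometric variance; p from chi-squared with
#' 1 df.
#'
#' @param time,event Survival data for all subjects.
#' @param group Two-level factor (or coercible) of group labels.
#' @return List: \code{statistic}, \code{p}, \code{observed} and
#'   \code{expected} event counts per group, \code{n} per group.
#' @export
logrank <- function(time, event, group) {
  rec <- survival_records(time, event)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop_("`group` must have exactly two levels")
  if (any(table(group) == 0L)) stop_("both groups must be non-empty")
  if (sum(rec$event) == 0L) stop_("no events; log-rank undefined")
  sd <- survival::survdiff(survival::Surv(rec$time, rec$event) ~ group)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp,
       n = as.vector(table(group)))
}

#' Best-cutoff stratification of a continuous score
#'
#' Scans candidate thresholds (the unique score values within the quantile
#' bounds), performs a log-rank test of \{score > c\} vs \{score <= c\} at
#' each, and returns the cutoff with the lowest p-value (ties -> smallest
#' cutoff). Optionally attaches a permutation-adjusted p that accounts for
#' the selection (fraction of score permutations whose minimal p is <= the
#' observed minimal p).
#'
#' @param scores Numeric score per subject.
#' @param time,event Survival data.
#' @param quantile_bounds Candidate cutoffs restricted to this score
#'   quantile range (default 10-90%), preventing degenerate splits.
#' @param n_perm Number of permutations for the adjusted p (0 = off).
#' @param seed Seed for the permutation draw.
#' @return List of class \code{cutoff_scan}: \code{candidates}, \code{p}
#'   (per candidate, NA where no valid split), \code{cutoff}, \code{p_value}
#'   (minimal p), \code{p_adjusted} (NULL unless \code{n_perm > 0}),
#'   \code{groups} (high/low subject indices at the chosen cutoff).
#' @export
best_cutoff <- function(scores, time, event, quantile_bounds = c(0.10, 0.90),
                        n_perm = 0L, seed = 1L) {
  rec <- survival_records(time, event)
  if (length(scores) != nrow(rec)) stop_("scores and records differ in length")
  if (length(unique(scores)) < 2L) stop_("all scores equal; no cutoff possible")
  qb <- stats::quantile(scores, quantile_bounds)
  cand <- sort(unique(scores[scores >= qb[1] & scores <= qb[2]]))
  cand <- cand[cand < max(scores)]  # a cutoff at the max leaves an empty high group
  if (length(cand) == 0L) stop_("no candidate cutoff yields two groups")
  scan_p <- function(sc) {
    vapply(cand, function(cc) {
      hi <- sc > cc
      if (!any(hi) || all(hi)) return(NA_real_)
      if (sum(rec$event) == 0L) return(NA_real_)
      sd <- survival::survdiff(survival::Surv(rec$time, rec$event) ~ hi)
      stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    }, numeric(1))
  }
  p <- scan_p(scores)
  if (all(is.na(p))) stop_("no candidate cutoff yields a valid test")
  best <- which(p == min(p, na.rm = TRUE))[1L]  # ties -> smallest cutoff
  p_adj <- NULL
  if (n_perm > 0L) {
    obs <- p[best]
    p_adj <- with_seed_(seed, {
      hits <- vapply(seq_len(n_perm), function(i) {
        pm <- scan_p(sample(scores))
        min(pm, na.rm = TRUE) <= obs
      }, logical(1))
      (sum(hits) + 1) / (n_perm + 1)
    })
  }
  structure(list(candidates = cand, p = p, cutoff = cand[best],
                 p_value = p[best], p_adjusted = p_adj,
                 groups = list(high = which(scores > cand[best]),
                               low = which(scores <= cand[best]))),
            class = "cutoff_scan")
}

#' Signature survival report
#'
#' Splits a cohort on a signature score (median or best cutoff), runs the
#' log-rank test, and labels the signature's direction: "unfavorable" when
#' the high-score group's KM curve is lower at the last common follow-up
#' time, "favorable" when higher.
#'
#' @param scores Numeric score per subject.
#' @param time,event Survival data.
#' @param split "median" or "best-cutoff".
#' @param ... Passed to [best_cutoff()] when used.
#' @return List: \code{split}, \code{cutoff}, \code{logrank},
#'   \code{direction}, \code{km} (list of high/low KM curves),
#'   \code{group} (high/low label per subject).
#' @export
signature_survival_report <- function(scores, time, event,
                                      split = c("median", "best-cutoff"), ...) {
  split <- match.arg(split)
  rec <- survival_records(time, event)
  if (split == "median") {
    med <- stats::median(scores)
    hi <- scores > med
    cutoff <- med
  } else {
    cs <- best_cutoff(scores, time, event, ...)
    hi <- scores > cs$cutoff
    cutoff <- cs$cutoff
  }
  if (sum(hi) < 2L || sum(!hi) < 2L)
    stop_("a group has fewer than 2 subjects after the split")
  lr <- logrank(rec$time, rec$event, factor(ifelse(hi, "high", "low"),
                                            levels = c("low", "high")))
  km_hi <- km_curve(rec$time[hi], rec$event[hi])
  km_lo <- km_curve(rec$time[!hi], rec$event[!hi])
  t_common <- min(max(rec$time[hi]), max(rec$time[!hi]))
  s_at <- function(km, t) {
    idx <- km$time <= t
    if (!any(idx)) 1 else km$surv[max(which(idx))]
  }
  s_hi <- s_at(km_hi, t_common); s_lo <- s_at(km_lo, t_common)
  direction <- if (s_hi < s_lo) "unfavorable" else if (s_hi > s_lo) "favorable" else "indeterminate"
  list(split = split, cutoff = cutoff, logrank = lr, direction = direction,
       km = list(high = km_hi, low = km_lo),
       group = ifelse(hi, "high", "low"))
}
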