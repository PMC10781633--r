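#' @importFrom stats qnorm
NULL

# Fast product-limit core. Returns distinct observation times with at-risk
# and event counts and the survival estimate; used directly by the bootstrap
# engine where the construction cost of a full survfit object would dominate.
# Ties between events and censorings at equal times are resolved
# events-first (both reduce the risk set after the time point, so a single
# pass over the sorted distinct times suffices).
km_core <- function(times, events) {
  o <- order(times)
  t_s <- times[o]
  e_s <- events[o]
  r <- rle(t_s)
  ut <- r$values
  grp <- rep.int(seq_along(ut), r$lengths)
  d <- as.numeric(rowsum(as.numeric(e_s), grp, reorder = FALSE))
  n_at <- length(t_s) - c(0, cumsum(r$lengths)[-length(ut)])
  surv <- cumprod(1 - d / n_at)
  list(times = ut, surv = surv, n_risk = n_at, n_event = d)
}

#' Kaplan-Meier product-limit fit
#'
#' Product-limit estimate of the survival function with Greenwood variance.
#' Ties between an event and a censoring at the same time are resolved
#' events-first (the standard convention). At times where the estimate has
#' reached zero the Greenwood sum is undefined and the variance is reported
#' as zero.
#'
#' @param times nonnegative event/censoring times (days).
#' @param events logical (or 0/1) event indicators, same length as
#'   \code{times}; \code{TRUE} = event observed, \code{FALSE} = censored.
#' @return a \code{\link{step_curve}} of type \code{"survival"} over the
#'   distinct observation times.
#' @examples
#' km_fit(c(1, 2, 3), c(TRUE, TRUE, TRUE))$estimate  # 2/3, 1/3, 0
#' @export
km_fit <- function(times, events) {
  times <- as.numeric(times)
  events <- as.logical(events)
  if (length(times) == 0L) stop("empty input")
  if (length(events) != length(times)) {
    stop("'times' and 'events' must have equal length")
  }
  if (any(is.na(times)) || any(is.na(events))) stop("missing values in input")
  if (any(times < 0)) stop("negative times")
  core <- km_core(times, events)
  # Greenwood: var S(t) = S(t)^2 * sum_{t_i <= t} d_i / (n_i (n_i - d_i))
  term <- ifelse(core$n_risk > core$n_event,
                 core$n_event / (core$n_risk * (core$n_risk - core$n_event)),
                 Inf)
  v <- core$surv^2 * cumsum(term)
  v[core$surv == 0] <- 0
  v[is.nan(v)] <- 0
  step_curve(core$times, core$surv, variance = v,
             n_risk = core$n_risk, n_event = core$n_event,
             initial = 1, type = "survival")
}

# complementary log-log pointwise CI for a survival probability
cloglog_ci <- function(s, var_s, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  lower <- upper <- s
  ok <- !is.na(s) & s > 0 & s < 1 & !is.na(var_s) & var_s > 0
  se_loglog <- sqrt(var_s[ok]) / (s[ok] * abs(log(s[ok])))
  lower[ok] <- s[ok]^exp(z * se_loglog)
  upper[ok] <- s[ok]^exp(-z * se_loglog)
  list(lower = pmin(pmax(lower, 0), 1), upper = pmin(pmax(upper, 1e-300), 1))
}

#' Survival probability at a fixed time with confidence interval
#'
#' Right-continuous lookup of the product-limit estimate with a two-sided
#' pointwise confidence interval on the complementary log-log scale
#' (Greenwood variance), truncated to [0, 1]. Degenerate at S = 0 or 1,
#' where the interval collapses to the estimate.
#'
#' @param curve a survival \code{\link{step_curve}} from \code{\link{km_fit}}.
#' @param t evaluation time(s), days, \code{>= 0}.
#' @param alpha two-sided level (default 0.05 for 95\% CI).
#' @return data frame with columns \code{time, estimate, lower, upper}.
#' @export
km_prob_at <- function(curve, t, alpha = 0.05) {
  stopifnot(inherits(curve, "step_curve"), curve$type == "survival")
  s <- step_eval(curve, t)
  v <- step_eval(curve, t, what = "variance")
  ci <- cloglog_ci(s, v, alpha)
  data.frame(time = t, estimate = s, lower = ci$lower, upper = ci$upper)
}

#' Median survival time with confidence interval
#'
#' Median = smallest time at which the survival estimate drops to 0.5 or
#' below; \code{NA} when the curve never reaches 0.5. The confidence
#' interval inverts the pointwise complementary log-log band
#' (Brookmeyer-Crowley construction): the limits are the first times at
#' which the respective confidence limit of S(t) drops to 0.5 or below.
#'
#' @param curve a survival \code{\link{step_curve}}.
#' @param alpha two-sided level (default 0.05).
#' @return list with elements \code{median}, \code{lower}, \code{upper}
#'   (days; \code{NA} where undefined).
#' @export
km_median <- function(curve, alpha = 0.05) {
  stopifnot(inherits(curve, "step_curve"), curve$type == "survival")
  ci <- cloglog_ci(curve$estimate, curve$variance, alpha)
  first_at_or_below <- function(vals) {
    i <- which(vals <= 0.5 + 1e-12)
    if (length(i)) curve$times[i[1]] else NA_real_
  }
  list(median = first_at_or_below(curve$estimate),
       lower = first_at_or_below(ci$lower),
       upper = first_at_or_below(ci$upper))
}

#' Failure-free survival times from raw records
#'
#' Failure-free survival (FFS) is the time from randomization to relapse of
#' the underlying disease, start of new systemic therapy, or death,
#' whichever comes first; subjects with none of these are censored at last
#' follow-up. Progression of the disease under study is deliberately not an
#' FFS event.
#'
#' @param raw data frame of raw subjects
#'   (see \code{\link{validate_raw_subjects}}).
#' @return data frame with columns \code{subject_id, arm, time, event},
#'   ready for \code{\link{km_fit}}.
#' @export
ffs_times <- function(raw) {
  raw <- validate_raw_subjects(raw)
  is_ffs <- !is.na(raw$event_reason) & raw$event_reason %in% FFS_REASONS
  data.frame(subject_id = raw$subject_id, arm = raw$arm,
             time = ifelse(is_ffs, raw$t_event, raw$t_last_followup),
             event = is_ffs)
}
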