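#' Probability of being in response (PBR) estimate
#'
#' Nonparametric estimator of the probability that a randomized subject
#' occupies the "in response" state at each time t since randomization,
#' under the progressive three-state model (0 = not in response, 1 = in
#' response, 2 = absorbing). The estimator aggregates two right-censored
#' time-to-event variables: the time of leaving the initial state
#' (\code{u_time, u_event}) and the time of entering the absorbing state
#' (\code{v_time, v_event}). With \code{h(t)} the product-limit survival
#' curve of the former ("still not in response and not absorbed") and
#' \code{g(t)} that of the latter ("not yet absorbed"),
#' \deqn{PBR(t) = g(t) - h(t),}
#' evaluated right-continuously on the union of the two jump grids. With no
#' censoring this reduces exactly to the empirical fraction of subjects in
#' response at t.
#'
#' Because g and h are estimated separately, sampling noise can make the
#' difference slightly negative; negative values are clipped to zero with a
#' warning and the raw difference is retained in the result.
#'
#' @param subjects multistate data frame
#'   (see \code{\link{derive_multistate}}).
#' @return an object of class \code{pbr_result}: list with elements
#'   \code{pbr} (a \code{\link{step_curve}} of type \code{"occupation"},
#'   starting at 0), \code{h_curve}, \code{g_curve} (the two product-limit
#'   curves), \code{raw_difference} (g - h before clipping) and
#'   \code{n_subjects}.
#' @export
pbr_estimate <- function(subjects) {
  subjects <- validate_multistate(subjects)
  if (nrow(subjects) == 0L) stop("empty input")
  h <- km_fit(subjects$u_time, subjects$u_event)
  g <- km_fit(subjects$v_time, subjects$v_event)
  grid <- sort(unique(c(h$times, g$times)))
  raw <- step_eval(g, grid) - step_eval(h, grid)
  est <- raw
  if (any(est < 0)) {
    warning(sprintf(
      "PBR difference g - h negative at %d grid point(s) (min %.3g); clipped to 0",
      sum(est < 0), min(est)))
    est[est < 0] <- 0
  }
  structure(
    list(pbr = step_curve(grid, pmin(est, 1), initial = 0,
                          type = "occupation"),
         h_curve = h, g_curve = g, raw_difference = raw,
         n_subjects = nrow(subjects)),
    class = "pbr_result")
}

#' @export
print.pbr_result <- function(x, ...) {
  cat(sprintf("PBR estimate from %d subjects, %d grid points\n",
              x$n_subjects, length(x$pbr$times)))
  pk <- which.max(x$pbr$estimate)
  cat(sprintf("  peak PBR %.3f at day %g; PBR at last grid point (day %g): %.3f\n",
              x$pbr$estimate[pk], x$pbr$times[pk],
              max(x$pbr$times), x$pbr$estimate[length(x$pbr$estimate)]))
  invisible(x)
}

# construct a curve_band object
curve_band <- function(curve, lower, upper, alpha, method, n_boot, seed) {
  stopifnot(length(lower) == length(curve$times),
            length(upper) == length(curve$times))
  structure(list(curve = curve, lower = lower, upper = upper,
                 alpha = alpha, method = method, n_boot = n_boot,
                 seed = seed),
            class = "curve_band")
}

#' @export
print.curve_band <- function(x, ...) {
  cat(sprintf("<curve_band: %s, %d grid points, alpha=%g, %s, n_boot=%d>\n",
              x$curve$type, length(x$curve$times), x$alpha, x$method,
              x$n_boot))
  invisible(x)
}

#' @export
as.data.frame.curve_band <- function(x, ...) {
  data.frame(time = x$curve$times, estimate = x$curve$estimate,
             lower = x$lower, upper = x$upper)
}

# evaluate one bootstrap replicate's PBR on a fixed grid
pbr_on_grid <- function(u_time, u_event, v_time, v_event, grid) {
  h <- km_core(u_time, u_event)
  g <- km_core(v_time, v_event)
  gh <- c(1, g$surv)[findInterval(grid, g$times) + 1L]
  hh <- c(1, h$surv)[findInterval(grid, h$times) + 1L]
  pmin(pmax(gh - hh, 0), 1)
}

#' Pointwise bootstrap confidence band for a PBR curve
#'
#' Nonparametric bootstrap: subjects are resampled with replacement, each
#' replicate's PBR is evaluated on the original jump grid, and pointwise
#' percentile limits at level \code{alpha} are taken. Fully deterministic
#' given \code{seed}.
#'
#' @param subjects multistate data frame.
#' @param alpha two-sided level (default 0.05).
#' @param n_boot number of bootstrap replicates, at least 100 (percentile
#'   limits are unstable below that); default 2000.
#' @param seed integer seed, required for reproducibility.
#' @return a \code{curve_band} whose \code{curve} is the point estimate on
#'   its jump grid, with aligned \code{lower}/\code{upper} limits in [0, 1].
#' @export
pbr_band <- function(subjects, alpha = 0.05, n_boot = 2000, seed) {
  if (missing(seed)) stop("'seed' is required for a reproducible band")
  if (n_boot < 100) stop("'n_boot' must be at least 100")
  fit <- pbr_estimate(subjects)
  grid <- fit$pbr$times
  n <- nrow(subjects)
  reps <- matrix(NA_real_, n_boot, length(grid))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[b, ] <- pbr_on_grid(subjects$u_time[idx], subjects$u_event[idx],
                             subjects$v_time[idx], subjects$v_event[idx],
                             grid)
  }
  q <- apply(reps, 2, stats::quantile,
             probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  curve_band(fit$pbr, lower = pmax(q[1, ], 0), upper = pmin(q[2, ], 1),
             alpha = alpha, method = "bootstrap_percentile",
             n_boot = n_boot, seed = seed)
}

#' Between-arm PBR difference curve with pointwise confidence band
#'
#' Difference of the two arms' PBR curves (first argument minus second) on
#' the union of their jump grids, with a pointwise percentile bootstrap
#' band; the arms are resampled independently within each replicate.
#'
#' @param arm_a_subjects,arm_b_subjects multistate data frames for the two
#'   arms; the difference is arm A minus arm B (e.g. treatment minus
#'   comparator).
#' @param alpha two-sided level (default 0.05).
#' @param n_boot number of bootstrap replicates (>= 100; default 2000).
#' @param seed integer seed, required.
#' @return a \code{curve_band} whose \code{curve} has type
#'   \code{"difference"} (values in [-1, 1]).
#' @export
pbr_difference <- function(arm_a_subjects, arm_b_subjects, alpha = 0.05,
                           n_boot = 2000, seed) {
  if (missing(seed)) stop("'seed' is required for a reproducible band")
  if (n_boot < 100) stop("'n_boot' must be at least 100")
  if (nrow(arm_a_subjects) == 0L || nrow(arm_b_subjects) == 0L) {
    stop("both arms must be nonempty")
  }
  fa <- pbr_estimate(arm_a_subjects)
  fb <- pbr_estimate(arm_b_subjects)
  grid <- sort(unique(c(fa$pbr$times, fb$pbr$times)))
  est <- step_eval(fa$pbr, grid) - step_eval(fb$pbr, grid)
  na <- nrow(arm_a_subjects)
  nb <- nrow(arm_b_subjects)
  reps <- matrix(NA_real_, n_boot, length(grid))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    ia <- sample.int(na, na, replace = TRUE)
    ib <- sample.int(nb, nb, replace = TRUE)
    pa <- pbr_on_grid(arm_a_subjects$u_time[ia], arm_a_subjects$u_event[ia],
                      arm_a_subjects$v_time[ia], arm_a_subjects$v_event[ia],
                      grid)
    pb <- pbr_on_grid(arm_b_subjects$u_time[ib], arm_b_subjects$u_event[ib],
                      arm_b_subjects$v_time[ib], arm_b_subjects$v_event[ib],
                      grid)
    reps[b, ] <- pa - pb
  }
  q <- apply(reps, 2, stats::quantile,
             probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  dcurve <- step_curve(grid, est, initial = 0, type = "difference")
  curve_band(dcurve, lower = pmax(q[1, ], -1), upper = pmin(q[2, ], 1),
             alpha = alpha, method = "bootstrap_percentile",
             n_boot = n_boot, seed = seed)
}

#' Expected duration of response (area under the PBR curve)
#'
#' The restricted area under the PBR curve on [0, tau]: the expected number
#' of days a randomized subject spends in response up to the horizon tau.
#' Computed as the exact rectangle sum of the step function.
#'
#' @param pbr a PBR \code{\link{step_curve}} (e.g. \code{pbr_estimate(x)$pbr})
#'   or a \code{pbr_result}.
#' @param tau restriction horizon in days, \code{> 0}.
#' @return expected duration of response in days.
#' @export
edor <- function(pbr, tau) {
  if (inherits(pbr, "pbr_result")) pbr <- pbr$pbr
  step_area(pbr, tau)
}

#' Cumulative responder curve
#'
#' The naive cumulative proportion of subjects whose first response occurred
#' at or before t (out of all subjects). Non-decreasing; its terminal value
#' is exactly the best-overall-response proportion. Unlike the PBR it
#' ignores that responders may later lose their response; it is intended as
#' a comparison overlay, not as an efficacy estimate.
#'
#' @param subjects multistate data frame.
#' @return a \code{\link{step_curve}} of type \code{"cumulative"} starting
#'   at 0, jumping at the distinct response times.
#' @export
cumulative_response <- function(subjects) {
  subjects <- validate_multistate(subjects)
  if (nrow(subjects) == 0L) stop("empty input")
  n <- nrow(subjects)
  rt <- sort(subjects$u_time[subjects$responded])
  if (length(rt) == 0L) {
    return(step_curve(numeric(0), numeric(0), initial = 0,
                      type = "cumulative"))
  }
  ut <- unique(rt)
  cum <- cumsum(tabulate(match(rt, ut))) / n
  step_curve(ut, cum,
             n_event = as.integer(tabulate(match(rt, ut))),
             initial = 0, type = "cumulative")
}

#' Trial endpoint summary
#'
#' Summary record of the standard response endpoints computed from the
#' multistate records: best overall response (BOR) proportion, overall
#' response at a fixed timepoint (in state 1 at that time), median time to
#' first response over all subjects with never-responders censored (TTFR),
#' and the duration-of-response (DOR) survival curve on responders only
#' (time from first response to loss of response).
#'
#' @param subjects multistate data frame (one arm, or pooled).
#' @param orr_timepoint day at which the in-response proportion is reported
#'   (default 168).
#' @param alpha two-sided level for the TTFR median CI.
#' @return list with elements \code{n}, \code{n_responders}, \code{bor},
#'   \code{orr_at} (with the timepoint), \code{ttfr} (median + CI, days),
#'   and \code{dor_curve} (a survival \code{step_curve}, or \code{NULL}
#'   when there are no responders).
#' @export
trial_summary <- function(subjects, orr_timepoint = 168, alpha = 0.05) {
  subjects <- validate_multistate(subjects)
  if (!is.numeric(orr_timepoint) || orr_timepoint < 0) {
    stop("'orr_timepoint' must be a nonnegative time")
  }
  n <- nrow(subjects)
  resp <- subjects$responded
  in_state1 <- resp & subjects$u_time <= orr_timepoint &
    !(subjects$v_event & subjects$v_time <= orr_timepoint)
  ttfr_fit <- km_fit(subjects$u_time, resp)
  dor_curve <- if (any(resp)) {
    km_fit(subjects$v_time[resp] - subjects$u_time[resp],
           subjects$v_event[resp])
  } else {
    NULL
  }
  list(n = n, n_responders = sum(resp), bor = mean(resp),
       orr_at = list(timepoint = orr_timepoint, estimate = mean(in_state1)),
       ttfr = km_median(ttfr_fit, alpha = alpha),
       ttfr_curve = ttfr_fit, dor_curve = dor_curve)
}
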