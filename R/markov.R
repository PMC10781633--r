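#' Transition rates of the exponential three-state response model
#'
#' Intensities of the progressive Markov model used as the simulation and
#' verification oracle: state 0 (not in response) can move to state 1 (in
#' response) at rate \code{lambda01} or directly to the absorbing state 2 at
#' rate \code{lambda02}; state 1 moves to state 2 (loss of response) at rate
#' \code{lambda12}. The response-window rule absorbs all remaining state-0
#' mass at \code{cutoff_days}: no new responses can occur after the window.
#'
#' @param lambda01 per-day hazard of first response, \code{>= 0}.
#' @param lambda02 per-day hazard of direct absorption without response.
#' @param lambda12 per-day hazard of losing an achieved response.
#' @param cutoff_days response window in days (\code{> 0}); \code{Inf}
#'   disables the window rule.
#' @return an object of class \code{markov_rates}.
#' @export
markov_rates <- function(lambda01, lambda02, lambda12, cutoff_days = 168) {
  for (v in c(lambda01, lambda02, lambda12)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("hazards must be single nonnegative numbers")
    }
  }
  if (!is.numeric(cutoff_days) || cutoff_days <= 0) {
    stop("'cutoff_days' must be positive (use Inf for no window)")
  }
  structure(list(lambda01 = lambda01, lambda02 = lambda02,
                 lambda12 = lambda12, cutoff_days = cutoff_days),
            class = "markov_rates")
}

# state-1 occupation before the cutoff, numerically stable in the
# near-degenerate case lambda01 + lambda02 ~ lambda12 via expm1
p1_free <- function(l01, l02, l12, t) {
  a <- l01 + l02
  gap <- a - l12
  if (gap == 0) {
    l01 * t * exp(-l12 * t)
  } else {
    l01 * exp(-l12 * t) * (-expm1(-gap * t)) / gap
  }
}

#' State occupation probabilities of the three-state model
#'
#' Closed-form occupation probabilities (p0, p1, p2) at time t. Before the
#' response window closes, the model is the standard progressive exponential
#' three-state model:
#' \deqn{p_0(t) = e^{-(\lambda_{01}+\lambda_{02}) t}, \quad
#'       p_1(t) = \lambda_{01}
#'         \frac{e^{-\lambda_{12} t} - e^{-(\lambda_{01}+\lambda_{02}) t}}
#'              {(\lambda_{01}+\lambda_{02}) - \lambda_{12}},}
#' with the limit \eqn{p_1(t) = \lambda_{01} t e^{-\lambda_{12} t}} when
#' \eqn{\lambda_{01}+\lambda_{02} = \lambda_{12}}. After the window closes
#' at c, remaining state-0 mass is absorbed (no new responses):
#' \eqn{p_0(t) = 0} and \eqn{p_1(t) = p_1(c) e^{-\lambda_{12}(t-c)}} for
#' \eqn{t > c}. Always \eqn{p_0 + p_1 + p_2 = 1}.
#'
#' @param rates a \code{\link{markov_rates}} object.
#' @param t nonnegative time(s) in days.
#' @return data frame with columns \code{t, p0, p1, p2}.
#' @export
markov_occupation <- function(rates, t) {
  stopifnot(inherits(rates, "markov_rates"))
  t <- as.numeric(t)
  if (any(is.na(t)) || any(t < 0)) stop("'t' must be nonnegative")
  l01 <- rates$lambda01; l02 <- rates$lambda02; l12 <- rates$lambda12
  cc <- rates$cutoff_days
  a <- l01 + l02
  pre <- t <= cc
  p0 <- ifelse(pre, exp(-a * t), 0)
  p1 <- numeric(length(t))
  p1[pre] <- p1_free(l01, l02, l12, t[pre])
  if (any(!pre)) {
    p1c <- p1_free(l01, l02, l12, cc)
    p1[!pre] <- p1c * exp(-l12 * (t[!pre] - cc))
  }
  data.frame(t = t, p0 = p0, p1 = p1, p2 = 1 - p0 - p1)
}

#' Closed-form expected duration of response
#'
#' Expected total time spent in the "in response" state, the area under the
#' model's state-1 occupation probability. Without a response window this is
#' \eqn{(\lambda_{01} / (\lambda_{01}+\lambda_{02})) / \lambda_{12}}
#' (probability of ever responding times mean response duration). With a
#' window at c it is \eqn{\int_0^c p_1(s) ds + p_1(c)/\lambda_{12}}.
#'
#' @param rates a \code{\link{markov_rates}} object; \code{lambda12} must be
#'   positive whenever \code{lambda01 > 0} (otherwise the expectation is
#'   infinite).
#' @return expected duration of response in days.
#' @export
edor_closed_form <- function(rates) {
  stopifnot(inherits(rates, "markov_rates"))
  l01 <- rates$lambda01; l02 <- rates$lambda02; l12 <- rates$lambda12
  cc <- rates$cutoff_days
  if (l01 == 0) return(0)
  if (l12 == 0) stop("lambda12 = 0 with lambda01 > 0: infinite expectation")
  a <- l01 + l02
  if (!is.finite(cc)) return((l01 / a) / l12)
  gap <- a - l12
  # integral of p1 over [0, c]
  int_p1 <- if (gap == 0) {
    l01 * (1 - exp(-l12 * cc) * (1 + l12 * cc)) / l12^2
  } else {
    (l01 / gap) * ((-expm1(-l12 * cc)) / l12 - (-expm1(-a * cc)) / a)
  }
  int_p1 + p1_free(l01, l02, l12, cc) / l12
}

#' Synthetic trial configuration
#'
#' Settings for \code{\link{simulate_trial}}: per-arm transition rates,
#' per-arm sample size, the censoring mechanism and the root seed.
#'
#' @param rates a named list of \code{\link{markov_rates}}, one per arm; the
#'   names are the arm labels.
#' @param n_per_arm subjects per arm (recycled across arms), \code{>= 1}.
#' @param censoring \code{"none"}, \code{"administrative"} (all subjects
#'   censored at \code{censor_time}) or \code{"exponential"} (independent
#'   censoring at rate \code{censor_rate}).
#' @param censor_time administrative censoring day.
#' @param censor_rate per-day exponential censoring hazard.
#' @param seed integer root seed; per-subject substreams are derived from it
#'   deterministically, so enlarging \code{n_per_arm} does not reshuffle
#'   earlier subjects.
#' @return an object of class \code{trial_config}.
#' @export
trial_config <- function(rates, n_per_arm,
                         censoring = c("none", "administrative",
                                       "exponential"),
                         censor_time = NULL, censor_rate = NULL,
                         seed) {
  censoring <- match.arg(censoring)
  if (!is.list(rates) || is.null(names(rates)) || any(names(rates) == "") ||
      !all(vapply(rates, inherits, TRUE, "markov_rates"))) {
    stop("'rates' must be a named list of markov_rates, one per arm")
  }
  n_per_arm <- as.integer(rep(n_per_arm, length.out = length(rates)))
  if (any(n_per_arm < 1L)) stop("'n_per_arm' must be >= 1")
  if (censoring == "administrative" &&
      (is.null(censor_time) || censor_time <= 0)) {
    stop("administrative censoring requires a positive 'censor_time'")
  }
  if (censoring == "exponential" &&
      (is.null(censor_rate) || censor_rate <= 0)) {
    stop("exponential censoring requires a positive 'censor_rate'")
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("'seed' (a single integer) is required")
  }
  structure(list(rates = rates, n_per_arm = n_per_arm,
                 censoring = censoring, censor_time = censor_time,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "trial_config")
}

# deterministic per-arm substream: subject i of arm j consumes the i-th
# block of 5 uniforms of a stream seeded by a multiplicative mix of the
# root seed and the arm index, so (a) different root seeds give genuinely
# different streams and (b) enlarging n_per_arm appends subjects without
# reshuffling earlier ones
arm_draws <- function(seed, arm_idx, n) {
  mixed <- (abs(as.numeric(seed)) * 48271 + arm_idx * 30269) %% 2147483647
  set.seed(as.integer(mixed))
  matrix(stats::runif(5L * n), nrow = n, ncol = 5L, byrow = TRUE)
}

rexp_inv <- function(u, rate) {
  if (rate > 0) -log(u) / rate else rep(Inf, length(u))
}

#' Simulate a synthetic two-arm response trial
#'
#' Draws subject trajectories from the exponential three-state model: a
#' competing pair of exponential times out of state 0 (first response vs
#' direct absorption), an exponential loss-of-response time for responders,
#' the response-window rule (subjects still in state 0 at the window's close
#' absorb there; responses are only possible within the window) and
#' independent censoring. Emits both the raw subject timelines (the CSV
#' schema of \code{\link{read_raw_subjects}}) and the derived multistate
#' records, which by construction satisfy all model invariants. Terminal
#' event reasons are sampled uniformly among the categories applicable to
#' the subject's path (responders may progress; never-responders may not).
#'
#' @param config a \code{\link{trial_config}}.
#' @return list with elements \code{raw} (raw subject data frame),
#'   \code{multistate} (derived records) and \code{config}.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  arms <- names(config$rates)
  per_arm <- vector("list", length(arms))
  for (j in seq_along(arms)) {
    r <- config$rates[[j]]
    n <- config$n_per_arm[j]
    cc <- r$cutoff_days
    # fallback follow-up horizon when neither an event nor censoring ends
    # observation (e.g. censoring "none" with a zero loss-of-response rate)
    horizon <- if (is.finite(cc)) 10 * cc else 3650
    u <- arm_draws(config$seed, j, n)
    t01 <- rexp_inv(u[, 1], r$lambda01)
    t02 <- rexp_inv(u[, 2], r$lambda02)
    t_cens <- switch(config$censoring,
                     none = rep(Inf, n),
                     administrative = rep(config$censor_time, n),
                     exponential = rexp_inv(u[, 4], config$censor_rate))

    t_resp <- t_ev <- lfu <- rep(NA_real_, n)
    reason <- rep(NA_character_, n)

    # responder path: first response observed at t01, exponential loss time
    rp <- t01 <= t02 & t01 <= cc & t01 <= t_cens
    t_fail <- t01 + rexp_inv(u[, 3], r$lambda12)
    lost_resp <- rp & is.finite(t_fail) & t_fail <= t_cens
    t_resp[rp] <- t01[rp]
    t_ev[lost_resp] <- t_fail[lost_resp]
    reason[lost_resp] <- EVENT_REASONS[1L + floor(u[lost_resp, 5] * 4)]
    lfu[lost_resp] <- t_fail[lost_resp]
    still <- rp & !lost_resp  # still in response at end of observation
    lfu[still] <- ifelse(is.finite(t_cens[still]), t_cens[still],
                         pmax(horizon, t01[still]))

    # direct absorption (death / new therapy / relapse) without response
    dr <- !rp & t02 < t01 & t02 <= cc & t02 <= t_cens
    t_ev[dr] <- t02[dr]
    reason[dr] <- FFS_REASONS[1L + floor(u[dr, 5] * 3)]
    lfu[dr] <- t02[dr]

    # lost while still in state 0, before the window closed
    ls <- !rp & !dr & t_cens < pmin(t01, t02, cc)
    lfu[ls] <- t_cens[ls]

    # never-responder, event-free through the window: absorbed at its close
    # by the no-response rule (post-window latent events are irrelevant
    # under the model and are not recorded)
    wd <- !rp & !dr & !ls
    lfu[wd] <- ifelse(is.finite(t_cens[wd]), t_cens[wd],
                      max(horizon, if (is.finite(cc)) cc else 0))

    per_arm[[j]] <- data.frame(
      subject_id = sprintf("%s-%04d", arms[j], seq_len(n)), arm = arms[j],
      t_first_response = t_resp, t_event = t_ev, event_reason = reason,
      t_last_followup = lfu)
  }
  raw <- do.call(rbind, per_arm)
  rules <- pbr_rules(cutoff_days = config$rates[[1]]$cutoff_days)
  ms <- derive_multistate(raw, rules)
  list(raw = raw, multistate = ms, config = config)
}
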