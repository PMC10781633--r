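#' Right-continuous step curve
#'
#' Container for a piecewise-constant, right-continuous estimate over time,
#' the common currency of all estimators in the package. The curve takes the
#' value \code{initial} on \code{[0, times[1])} and \code{estimate[i]} on
#' \code{[times[i], times[i+1])}.
#'
#' @param times strictly increasing vector of jump times (days).
#' @param estimate estimate at (and right of) each jump time; values in [0,1].
#' @param variance pointwise variance aligned to \code{times}, or \code{NA}.
#' @param n_risk,n_event integer counts aligned to \code{times}, or \code{NA}.
#' @param initial value of the curve before the first jump time
#'   (1 for survival curves, 0 for occupation / cumulative curves).
#' @param type one of \code{"survival"}, \code{"occupation"},
#'   \code{"cumulative"}, \code{"difference"}; controls validation and
#'   plotting defaults.
#' @return An object of class \code{step_curve}.
#' @export
step_curve <- function(times, estimate,
                       variance = rep(NA_real_, length(times)),
                       n_risk = rep(NA_integer_, length(times)),
                       n_event = rep(NA_integer_, length(times)),
                       initial = 1,
                       type = c("survival", "occupation", "cumulative",
                                "difference")) {
  type <- match.arg(type)
  times <- as.numeric(times)
  estimate <- as.numeric(estimate)
  k <- length(times)
  if (length(estimate) != k) {
    stop("'times' and 'estimate' must have equal length")
  }
  if (k > 0) {
    if (any(is.na(times)) || any(times < 0)) {
      stop("jump times must be nonnegative and non-missing")
    }
    if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
    lo <- if (type == "difference") -1 else 0
    if (any(estimate < lo - 1e-12 | estimate > 1 + 1e-12)) {
      stop("estimates outside [", lo, ", 1]")
    }
    if (type == "survival" && any(diff(c(initial, estimate)) > 1e-12)) {
      stop("survival estimates must be non-increasing")
    }
    if (type == "cumulative" && any(diff(c(initial, estimate)) < -1e-12)) {
      stop("cumulative estimates must be non-decreasing")
    }
    if (!all(is.na(n_risk)) && any(diff(n_risk) > 0)) {
      stop("'n_risk' must be non-increasing")
    }
  }
  structure(
    list(times = times, estimate = estimate, variance = as.numeric(variance),
         n_risk = as.integer(n_risk), n_event = as.integer(n_event),
         initial = initial, type = type),
    class = "step_curve"
  )
}

#' Evaluate a step curve at arbitrary times
#'
#' Right-continuous lookup: the value at \code{t} is the estimate at the
#' largest jump time not exceeding \code{t}, the initial value before the
#' first jump, and the last value carried forward beyond the grid.
#'
#' @param curve a \code{step_curve}.
#' @param t numeric vector of evaluation times (days), each \code{>= 0}.
#' @param what which aligned field to look up (default the estimate).
#' @return numeric vector of the same length as \code{t}.
#' @export
step_eval <- function(curve, t, what = c("estimate", "variance")) {
  what <- match.arg(what)
  stopifnot(inherits(curve, "step_curve"))
  if (any(is.na(t)) || any(t < 0)) stop("evaluation times must be >= 0")
  init <- if (what == "estimate") curve$initial else 0
  vals <- c(init, curve[[what]])
  vals[findInterval(t, curve$times) + 1L]
}

#' @export
print.step_curve <- function(x, ...) {
  cat(sprintf("<step_curve: %s, %d jump times, initial %g>\n",
              x$type, length(x$times), x$initial))
  print(utils::head(as.data.frame(x), 10))
  if (length(x$times) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.step_curve <- function(x, ...) {
  data.frame(time = x$times, estimate = x$estimate,
             std_err = sqrt(x$variance),
             n_risk = x$n_risk, n_event = x$n_event)
}

#' Area under a step curve on [0, tau]
#'
#' Exact rectangle sum of the right-continuous step function; no quadrature
#' error. Used for the expected duration of response (area under PBR).
#'
#' @param curve a \code{step_curve}.
#' @param tau upper integration limit (days), \code{> 0}.
#' @return the exact integral, a single number (days when the curve is a
#'   probability over days).
#' @export
step_area <- function(curve, tau) {
  stopifnot(inherits(curve, "step_curve"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("'tau' must be a single positive number")
  }
  knots <- c(0, curve$times[curve$times < tau], tau)
  heights <- step_eval(curve, knots[-length(knots)])
  sum(heights * diff(knots))
}

#' Export a step curve (optionally with a band) to CSV
#'
#' Writes the schema \code{time, estimate, std_err, lower, upper, n_risk,
#' n_event}; band columns are \code{NA} unless a \code{curve_band} is given.
#'
#' @param x a \code{step_curve} or \code{curve_band}.
#' @param path output file path.
#' @return the written data frame, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  if (inherits(x, "curve_band")) {
    df <- as.data.frame(x$curve)
    df$lower <- x$lower
    df$upper <- x$upper
  } else {
    df <- as.data.frame(x)
    df$lower <- NA_real_
    df$upper <- NA_real_
  }
  df <- df[, c("time", "estimate", "std_err", "lower", "upper",
               "n_risk", "n_event")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
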