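#' Analysis run configuration
#'
#' Bundles the settings shared by the pipeline runners
#' (\code{\link{run_pbr}}, \code{\link{run_difference}},
#' \code{\link{run_simulation}}): input path, arm handling, the response
#' window, bootstrap settings and output location. Used directly by the
#' \code{pbrkit} command-line script shipped in \code{inst/cli/}.
#'
#' @param input path to a raw-subject CSV
#'   (see \code{\link{read_raw_subjects}}).
#' @param output_dir directory for artifacts; created if absent.
#' @param treatment_arm,reference_arm arm labels; the difference curve is
#'   treatment minus reference. \code{NULL} = infer (input must then contain
#'   exactly two arms for difference runs; the first label in sorted order
#'   is the treatment).
#' @param cutoff_days response window (days), default 168.
#' @param alpha two-sided confidence level complement, in (0, 1).
#' @param n_boot bootstrap replicates for bands (>= 100); 0 disables bands.
#' @param seed integer seed; required whenever \code{n_boot > 0}.
#' @param timepoints days at which endpoint probabilities are tabulated
#'   (default months 3/6/12 as days 91/182/365).
#' @param plot write base-graphics PNG figures alongside the CSVs.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(input = NULL, output_dir = ".",
                       treatment_arm = NULL, reference_arm = NULL,
                       cutoff_days = 168, alpha = 0.05, n_boot = 2000,
                       seed = NULL, timepoints = c(91, 182, 365),
                       plot = FALSE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)")
  }
  if (n_boot > 0 && is.null(seed)) {
    stop("'seed' is required whenever n_boot > 0")
  }
  structure(list(input = input, output_dir = output_dir,
                 treatment_arm = treatment_arm,
                 reference_arm = reference_arm,
                 cutoff_days = cutoff_days, alpha = alpha,
                 n_boot = n_boot, seed = seed, timepoints = timepoints,
                 plot = plot),
            class = "run_config")
}

split_arms <- function(ms, config) {
  arms <- sort(unique(ms$arm))
  trt <- config$treatment_arm
  ref <- config$reference_arm
  if (is.null(trt) && is.null(ref)) {
    if (length(arms) != 2L) {
      stop("input has ", length(arms),
           " arm(s); specify treatment_arm and reference_arm explicitly")
    }
    trt <- arms[1]
    ref <- arms[2]
  }
  for (lab in c(trt, ref)) {
    if (!is.null(lab) && !(lab %in% arms)) {
      stop("unknown arm label '", lab, "'; arms present: ",
           paste(arms, collapse = ", "))
    }
  }
  list(treatment = trt, reference = ref, arms = arms)
}

#' Run the per-arm PBR analysis and write artifacts
#'
#' For every arm in the input: the PBR curve (with a pointwise bootstrap
#' band when \code{n_boot > 0}), the cumulative-responder curve, and a
#' trial-summary table of ORR/BOR/TTFR plus duration-of-response and
#' failure-free-survival probabilities at the configured timepoints. Writes
#' tidy CSVs (schema \code{time, estimate, std_err, lower, upper, n_risk,
#' n_event}) and, optionally, a figure overlaying solid PBR and dashed
#' cumulative-responder curves.
#'
#' @param config a \code{\link{run_config}} with \code{input} set.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with per-arm results and the paths written.
#' @export
run_pbr <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  raw <- read_raw_subjects(config$input)
  rules <- pbr_rules(cutoff_days = config$cutoff_days)
  ms <- derive_multistate(raw, rules)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say("pbrkit: %d subjects, arms: %s; cutoff %g days; seed %s",
      nrow(ms), paste(sort(unique(ms$arm)), collapse = ", "),
      config$cutoff_days, ifelse(is.null(config$seed), "-", config$seed))

  arms <- sort(unique(ms$arm))
  out <- list()
  paths <- character(0)
  ffs <- ffs_times(raw)
  for (a in arms) {
    sub <- ms[ms$arm == a, ]
    fit <- pbr_estimate(sub)
    obj <- if (config$n_boot > 0) {
      pbr_band(sub, alpha = config$alpha, n_boot = config$n_boot,
               seed = config$seed)
    } else {
      fit$pbr
    }
    p <- file.path(config$output_dir, paste0("pbr_", a, ".csv"))
    write_curve_csv(obj, p)
    cum <- cumulative_response(sub)
    pc <- file.path(config$output_dir, paste0("cumulative_response_", a,
                                              ".csv"))
    write_curve_csv(cum, pc)
    summ <- trial_summary(sub, orr_timepoint = config$cutoff_days,
                          alpha = config$alpha)
    ffs_a <- ffs[ffs$arm == a, ]
    summ$ffs_curve <- km_fit(ffs_a$time, ffs_a$event)
    out[[a]] <- list(fit = fit, band = obj, summary = summ,
                     cumulative = cum)
    paths <- c(paths, p, pc)
    say("  arm %s: n=%d, BOR %.1f%%, peak PBR %.3f", a, summ$n,
        100 * summ$bor, max(fit$pbr$estimate))
  }

  st <- summary_table(out, config$timepoints, config$alpha)
  pt <- file.path(config$output_dir, "trial_summary.csv")
  utils::write.csv(st, pt, row.names = FALSE)
  paths <- c(paths, pt)

  if (config$plot) {
    pp <- file.path(config$output_dir, "pbr_curves.png")
    grDevices::png(pp, width = 900, height = 600)
    plot_pbr_arms(out)
    grDevices::dev.off()
    paths <- c(paths, pp)
  }
  say("  wrote %d file(s) to %s", length(paths), config$output_dir)
  invisible(list(arms = out, table = st, paths = paths))
}

# Table-1-style long summary: one row per arm x endpoint x timepoint
summary_table <- function(arm_results, timepoints, alpha) {
  rows <- list()
  for (a in names(arm_results)) {
    s <- arm_results[[a]]$summary
    fit <- arm_results[[a]]$fit
    add <- function(endpoint, timepoint, estimate, lower = NA, upper = NA) {
      rows[[length(rows) + 1L]] <<- data.frame(
        arm = a, endpoint = endpoint, timepoint_days = timepoint,
        estimate = estimate, lower = lower, upper = upper)
    }
    add("n", NA, s$n)
    add("n_responders", NA, s$n_responders)
    add("bor", NA, s$bor)
    add("orr_at_cutoff", s$orr_at$timepoint, s$orr_at$estimate)
    add("ttfr_median_days", NA, s$ttfr$median, s$ttfr$lower, s$ttfr$upper)
    for (tp in timepoints) {
      p <- step_eval(fit$pbr, tp)
      add("pbr", tp, p)
      if (!is.null(s$dor_curve)) {
        d <- km_prob_at(s$dor_curve, tp, alpha)
        add("dor_probability", tp, d$estimate, d$lower, d$upper)
      }
      f <- km_prob_at(s$ffs_curve, tp, alpha)
      add("ffs_probability", tp, f$estimate, f$lower, f$upper)
    }
  }
  do.call(rbind, rows)
}

#' Run the between-arm PBR difference analysis and write artifacts
#'
#' Computes the difference curve (treatment minus reference) with a
#' pointwise percentile bootstrap band and writes it as a tidy CSV
#' (\code{time, estimate, lower, upper}), plus an optional figure.
#'
#' @param config a \code{\link{run_config}}; the input must resolve to
#'   exactly two arms (or name them explicitly).
#' @param quiet suppress progress messages.
#' @return invisibly, the \code{curve_band} and the paths written.
#' @export
run_difference <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_boot < 100) stop("difference bands require n_boot >= 100")
  say <- function(...) if (!quiet) message(sprintf(...))
  raw <- read_raw_subjects(config$input)
  ms <- derive_multistate(raw, pbr_rules(cutoff_days = config$cutoff_days))
  lab <- split_arms(ms, config)
  say("pbrkit: difference %s - %s, n_boot=%d, seed=%d",
      lab$treatment, lab$reference, config$n_boot, config$seed)
  band <- pbr_difference(ms[ms$arm == lab$treatment, ],
                         ms[ms$arm == lab$reference, ],
                         alpha = config$alpha, n_boot = config$n_boot,
                         seed = config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(config$output_dir,
                 sprintf("pbr_difference_%s_minus_%s.csv",
                         lab$treatment, lab$reference))
  utils::write.csv(as.data.frame(band), p, row.names = FALSE)
  paths <- p
  if (config$plot) {
    pp <- file.path(config$output_dir, "pbr_difference.png")
    grDevices::png(pp, width = 900, height = 600)
    plot(band, main = sprintf("PBR difference (%s - %s)",
                              lab$treatment, lab$reference))
    grDevices::dev.off()
    paths <- c(paths, pp)
  }
  say("  wrote %s", p)
  invisible(list(band = band, treatment = lab$treatment,
                 reference = lab$reference, paths = paths))
}

#' Simulate a synthetic trial and write its raw-subject CSV
#'
#' Thin wrapper over \code{\link{simulate_trial}} that writes the raw
#' records in the input schema of \code{\link{run_pbr}}, making the
#' simulate-derive-estimate pipeline round-trippable, and reports the
#' closed-form in-response probability at the configured timepoints for
#' comparison.
#'
#' @param trial a \code{\link{trial_config}}.
#' @param output_dir output directory.
#' @param timepoints days at which the closed-form state-1 probability is
#'   printed.
#' @param quiet suppress messages.
#' @return invisibly, the simulation result plus the CSV path.
#' @export
run_simulation <- function(trial, output_dir = ".",
                           timepoints = c(91, 182, 365), quiet = FALSE) {
  stopifnot(inherits(trial, "trial_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  sim <- simulate_trial(trial)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(output_dir, "simulated_subjects.csv")
  write_raw_subjects(sim$raw, p)
  say("pbrkit: simulated %d subjects (seed %d) -> %s",
      nrow(sim$raw), trial$seed, p)
  for (a in names(trial$rates)) {
    p1 <- markov_occupation(trial$rates[[a]], timepoints)$p1
    say("  arm %s closed-form P(in response) at day %s: %s", a,
        paste(timepoints, collapse = "/"),
        paste(sprintf("%.3f", p1), collapse = "/"))
  }
  invisible(c(sim, list(path = p)))
}

plot_pbr_arms <- function(arm_results, xlab = "Days since randomization",
                          ylab = "Probability of being in response") {
  xmax <- max(vapply(arm_results,
                     function(r) max(r$fit$pbr$times), 0))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab)
  cols <- seq_along(arm_results) + 1
  for (i in seq_along(arm_results)) {
    fit <- arm_results[[i]]$fit
    graphics::lines(stats::stepfun(fit$pbr$times,
                                   c(0, fit$pbr$estimate)),
                    do.points = FALSE, col = cols[i], lwd = 2)
    cum <- arm_results[[i]]$cumulative
    if (!is.null(cum) && length(cum$times)) {
      graphics::lines(stats::stepfun(cum$times, c(0, cum$estimate)),
                      do.points = FALSE, col = cols[i], lty = 2)
    }
  }
  graphics::legend("topright", legend = names(arm_results), col = cols,
                   lwd = 2, bty = "n")
}

#' @export
plot.curve_band <- function(x, xlab = "Days since randomization",
                            ylab = NULL, main = NULL, ...) {
  if (is.null(ylab)) {
    ylab <- if (x$curve$type == "difference") {
      "PBR difference"
    } else {
      "Probability of being in response"
    }
  }
  init <- if (x$curve$type == "difference") 0 else x$curve$initial
  ylim <- if (x$curve$type == "difference") c(-1, 1) else c(0, 1)
  graphics::plot(NA, xlim = c(0, max(x$curve$times)), ylim = ylim,
                 xlab = xlab, ylab = ylab, main = main, ...)
  graphics::lines(stats::stepfun(x$curve$times, c(init, x$curve$estimate)),
                  do.points = FALSE, lwd = 2)
  graphics::lines(stats::stepfun(x$curve$times, c(init, x$lower)),
                  do.points = FALSE, col = "blue")
  graphics::lines(stats::stepfun(x$curve$times, c(init, x$upper)),
                  do.points = FALSE, col = "blue")
  if (x$curve$type == "difference") graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
plot.step_curve <- function(x, xlab = "Days", ylab = "Estimate", ...) {
  graphics::plot(stats::stepfun(x$times, c(x$initial, x$estimate)),
                 do.points = FALSE, xlab = xlab, ylab = ylab,
                 ylim = c(min(0, x$estimate), 1), ...)
  invisible(x)
}
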