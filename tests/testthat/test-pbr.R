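toy_two <- function() {
  # A responds day 10 and loses response day 30; B absorbs directly day 20
  data.frame(subject_id = c("a", "b"), arm = "A",
             u_time = c(10, 20), u_event = TRUE,
             responded = c(TRUE, FALSE),
             v_time = c(30, 20), v_event = TRUE)
}

test_that("PBR on uncensored data is the empirical in-response fraction", {
  fit <- pbr_estimate(toy_two())
  expect_equal(step_eval(fit$pbr, c(0, 9.99, 10, 20, 29.99, 30, 100)),
               c(0, 0, 0.5, 0.5, 0.5, 0, 0))
  expect_equal(step_eval(fit$pbr, 0), 0)
})

test_that("PBR is identically zero when nobody responds", {
  ms <- data.frame(subject_id = c("a", "b", "c"), arm = "A",
                   u_time = c(5, 10, 20), u_event = c(TRUE, TRUE, FALSE),
                   responded = FALSE,
                   v_time = c(5, 10, 20), v_event = c(TRUE, TRUE, FALSE))
  fit <- pbr_estimate(ms)
  expect_true(all(fit$pbr$estimate == 0))
  expect_error(pbr_estimate(ms[0, ]), "empty")
})

test_that("PBR equals the hand product-limit difference under censoring", {
  # four subjects, one censored in state 1:
  #   a: responds 10, loses 40;  b: responds 20, censored in state 1 at 50
  #   c: direct absorption 15;   d: responds 30, loses 60
  ms <- data.frame(subject_id = letters[1:4], arm = "A",
                   u_time = c(10, 20, 15, 30),
                   u_event = TRUE,
                   responded = c(TRUE, TRUE, FALSE, TRUE),
                   v_time = c(40, 50, 15, 60),
                   v_event = c(TRUE, FALSE, TRUE, TRUE))
  fit <- pbr_estimate(ms)
  # h: events at 10,15,20,30 -> 3/4, 2/4, 1/4, 0
  expect_equal(step_eval(fit$h_curve, c(10, 15, 20, 30)),
               c(3 / 4, 1 / 2, 1 / 4, 0))
  # g: event 15 (n=4), event 40 (n=3), censor 50, event 60 (n=1)
  expect_equal(step_eval(fit$g_curve, c(15, 40, 50, 60)),
               c(3 / 4, 1 / 2, 1 / 2, 0))
  expect_equal(step_eval(fit$pbr, c(5, 10, 15, 20, 30, 40, 55, 60)),
               c(0, 1 / 4, 1 / 4, 1 / 2, 3 / 4, 1 / 2, 1 / 2, 0))
})

test_that("PBR matches direct counting on random uncensored data (property)", {
  for (s in 1:20) {
    tc <- trial_config(default_two_arm_rates(), n_per_arm = 30,
                       censoring = "none", seed = 100 + s)
    ms <- simulate_trial(tc)$multistate
    fit <- pbr_estimate(ms)
    grid <- fit$pbr$times
    expect_equal(step_eval(fit$pbr, grid), state1_fraction(ms, grid),
                 tolerance = 1e-12)
    # bounded, starts at zero, ends at zero once every responder absorbs
    expect_true(all(fit$pbr$estimate >= 0 & fit$pbr$estimate <= 1))
    expect_equal(step_eval(fit$pbr, 0), 0)
    expect_equal(fit$pbr$estimate[length(grid)], 0)
    # being in response implies having responded
    cum <- cumulative_response(ms)
    expect_true(all(step_eval(fit$pbr, grid) <=
                      step_eval(cum, grid) + 1e-12))
  }
})

test_that("the area under the PBR curve behaves like a duration", {
  fit <- pbr_estimate(toy_two())
  expect_equal(edor(fit, 40), 10)  # 0.5 * (30 - 10)
  expect_equal(edor(fit, 15), 2.5)
  expect_error(edor(fit, 0), "positive")

  zero <- step_curve(c(5, 10), c(0, 0), initial = 0, type = "occupation")
  expect_equal(step_area(zero, 100), 0)

  # additivity over abutting horizons
  tc <- trial_config(default_two_arm_rates(), n_per_arm = 50,
                     censoring = "none", seed = 9)
  ms <- simulate_trial(tc)$multistate
  pb <- pbr_estimate(ms)$pbr
  expect_equal(edor(pb, 120) + (edor(pb, 365) - edor(pb, 120)), edor(pb, 365))

  # uncensored: area equals the mean per-subject time in response
  dur <- ifelse(ms$responded, pmin(ms$v_time, 365) - pmin(ms$u_time, 365), 0)
  expect_equal(edor(pb, 365), mean(dur), tolerance = 1e-12)
})

test_that("cumulative responder curve counts responses and ends at the BOR", {
  ms <- data.frame(subject_id = letters[1:4], arm = "A",
                   u_time = c(10, 20, 15, 30),
                   u_event = c(TRUE, TRUE, TRUE, FALSE),
                   responded = c(TRUE, TRUE, FALSE, FALSE),
                   v_time = c(40, 50, 15, 30),
                   v_event = c(TRUE, FALSE, TRUE, FALSE))
  cum <- cumulative_response(ms)
  expect_equal(step_eval(cum, c(5, 10, 19, 20, 100)),
               c(0, 0.25, 0.25, 0.5, 0.5))
  expect_equal(cum$estimate[length(cum$estimate)], mean(ms$responded))
  expect_true(all(diff(cum$estimate) >= 0))

  none <- ms
  none$responded <- FALSE
  none$v_time <- none$u_time
  none$v_event <- none$u_event
  expect_equal(length(cumulative_response(none)$times), 0)
})

test_that("bootstrap bands are deterministic, ordered and bounded", {
  tc <- trial_config(default_two_arm_rates(), n_per_arm = 60,
                     censoring = "administrative", censor_time = 400,
                     seed = 12)
  ms <- simulate_trial(tc)$multistate
  a <- ms[ms$arm == "A", ]
  b1 <- pbr_band(a, n_boot = 150, seed = 5)
  b2 <- pbr_band(a, n_boot = 150, seed = 5)
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)
  expect_true(all(b1$lower <= b1$curve$estimate + 1e-12))
  expect_true(all(b1$curve$estimate <= b1$upper + 1e-12))
  expect_true(all(b1$lower >= 0 & b1$upper <= 1))
  expect_error(pbr_band(a, n_boot = 50, seed = 1), "at least 100")
  expect_error(pbr_band(a, n_boot = 200), "seed")

  # single subject: band collapses onto the estimate
  one <- a[1, ]
  bo <- pbr_band(one, n_boot = 100, seed = 3)
  expect_equal(bo$lower, bo$curve$estimate)
  expect_equal(bo$upper, bo$curve$estimate)
})

test_that("difference curves have the stated sign convention", {
  tc <- trial_config(default_two_arm_rates(), n_per_arm = 60,
                     censoring = "none", seed = 21)
  ms <- simulate_trial(tc)$multistate
  a <- ms[ms$arm == "A", ]
  b <- ms[ms$arm == "B", ]

  # identical arms: difference exactly zero, every interval contains zero
  same <- pbr_difference(a, a, n_boot = 120, seed = 2)
  expect_true(all(same$curve$estimate == 0))
  expect_true(all(same$lower <= 0 & 0 <= same$upper))

  # arm B without responders: the difference is arm A's PBR
  b0 <- b
  b0$responded <- FALSE
  b0$v_time <- b0$u_time
  b0$v_event <- b0$u_event
  d <- pbr_difference(a, b0, n_boot = 120, seed = 2)
  fa <- pbr_estimate(a)
  expect_equal(step_eval(d$curve, d$curve$times),
               step_eval(fa$pbr, d$curve$times))

  # swapping the arms negates the curve exactly
  d_ab <- pbr_difference(a, b, n_boot = 120, seed = 2)
  d_ba <- pbr_difference(b, a, n_boot = 120, seed = 2)
  expect_equal(d_ab$curve$estimate, -d_ba$curve$estimate)
  expect_error(pbr_difference(a[0, ], b, n_boot = 120, seed = 1), "nonempty")
})

test_that("trial summary reports BOR, timepoint response and TTFR correctly", {
  fitdat <- toy_two()
  s <- trial_summary(fitdat, orr_timepoint = 20)
  expect_equal(s$bor, 0.5)
  expect_equal(s$orr_at$estimate, 0.5)  # a in response at 20, b absorbed
  expect_equal(s$n_responders, 1)

  # losing response before the timepoint counts for BOR but not ORR
  s2 <- trial_summary(fitdat, orr_timepoint = 35)
  expect_equal(s2$bor, 0.5)
  expect_equal(s2$orr_at$estimate, 0)

  # responders-only DOR curve: a's duration 20 days
  expect_equal(s$dor_curve$times, 20)
  expect_equal(s$dor_curve$estimate, 0)

  none <- fitdat
  none$responded <- FALSE
  none$v_time <- none$u_time
  s3 <- trial_summary(none, orr_timepoint = 20)
  expect_equal(s3$bor, 0)
  expect_null(s3$dor_curve)
  expect_error(trial_summary(fitdat, orr_timepoint = -1), "nonnegative")

  # TTFR median: half the subjects respond early, the rest never do
  ms <- data.frame(subject_id = as.character(1:6), arm = "A",
                   u_time = c(10, 20, 30, 168, 168, 168),
                   u_event = TRUE,
                   responded = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                   v_time = c(500, 500, 500, 168, 168, 168),
                   v_event = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  s4 <- trial_summary(ms, orr_timepoint = 100)
  expect_equal(s4$ttfr$median, 30)  # S_u(30) = 0.5
})
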