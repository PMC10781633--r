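# Fixtures built in code: a seven-patient toy trial covering every state
# path, generators of random valid inputs, and the direct-counting oracle.

# one subject per path: still in response / response lost (three reasons) /
# direct absorption / window absorption / lost in state 0
seven_patients <- function(arm = "A") {
  data.frame(
    subject_id = paste0(arm, 1:7),
    arm = arm,
    t_first_response = c(30, 25, 60, NA, NA, 20, NA),
    t_event = c(NA, 200, 90, NA, 40, 100, NA),
    event_reason = c(NA, "new_systemic_therapy", "death", NA, "death",
                     "relapse", NA),
    t_last_followup = c(400, 200, 90, 300, 40, 100, 100),
    stringsAsFactors = FALSE
  )
}

# random valid raw subjects exercising all derivation branches
random_raw <- function(n, cutoff = 168) {
  kind <- sample(5, n, replace = TRUE)
  t_resp <- ifelse(kind %in% c(1, 2), round(runif(n, 1, cutoff), 1), NA)
  t_ev <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  lfu <- numeric(n)
  for (i in seq_len(n)) {
    switch(kind[i],
      { # responder still in response
        lfu[i] <- t_resp[i] + round(runif(1, 0, 400), 1)
      },
      { # responder losing response
        t_ev[i] <- t_resp[i] + round(runif(1, 0, 300), 1)
        reason[i] <- sample(c("death", "new_systemic_therapy", "relapse",
                              "progression"), 1)
        lfu[i] <- t_ev[i]
      },
      { # direct absorption before the window closes
        t_ev[i] <- round(runif(1, 0, cutoff), 1)
        reason[i] <- sample(c("death", "new_systemic_therapy", "relapse"), 1)
        lfu[i] <- t_ev[i]
      },
      { # event-free past the window
        lfu[i] <- cutoff + round(runif(1, 0, 300), 1)
      },
      { # lost in state 0 before the window
        lfu[i] <- round(runif(1, 0, cutoff - 1e-3), 1)
      })
  }
  data.frame(subject_id = sprintf("S%03d", seq_len(n)), arm = "A",
             t_first_response = t_resp, t_event = t_ev,
             event_reason = reason, t_last_followup = lfu,
             stringsAsFactors = FALSE)
}

# direct-counting oracle: empirical fraction of subjects in state 1 at t
# (right-continuous; valid without censoring)
state1_fraction <- function(ms, t) {
  vapply(t, function(tt) {
    mean(ms$responded & ms$u_time <= tt & tt < ms$v_time)
  }, numeric(1))
}

default_two_arm_rates <- function(cutoff = 168) {
  list(A = markov_rates(0.022, 0.004, 0.0012, cutoff),
       B = markov_rates(0.010, 0.006, 0.0025, cutoff))
}
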