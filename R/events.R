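#' Response-window rules
#'
#' Configuration of the event-derivation rules: the response window cut-off
#' (responses are only counted if the first response occurs on or before
#' \code{cutoff_days}; never-responders followed past the cut-off enter the
#' absorbing state there) and an optional administrative analysis cut-off.
#'
#' The default cut-off is week 24 counted as 24 x 7 = 168 days. Trials that
#' anchor the window to a cycle day (e.g. day 169 under 28-day cycles) can
#' set \code{cutoff_days} accordingly.
#'
#' @param cutoff_days response window in days, \code{> 0}. Default 168.
#' @param analysis_cutoff_days optional administrative censoring time: any
#'   follow-up or event time beyond it is truncated to a censoring at this
#'   time before derivation.
#' @return An object of class \code{pbr_rules}.
#' @export
pbr_rules <- function(cutoff_days = 168, analysis_cutoff_days = NULL) {
  if (!is.numeric(cutoff_days) || length(cutoff_days) != 1L ||
      is.na(cutoff_days) || cutoff_days <= 0) {
    stop("'cutoff_days' must be a single positive number")
  }
  if (!is.null(analysis_cutoff_days) &&
      (!is.numeric(analysis_cutoff_days) || analysis_cutoff_days <= 0)) {
    stop("'analysis_cutoff_days' must be positive when given")
  }
  structure(list(cutoff_days = cutoff_days,
                 analysis_cutoff_days = analysis_cutoff_days),
            class = "pbr_rules")
}

EVENT_REASONS <- c("death", "new_systemic_therapy", "relapse", "progression")
FFS_REASONS <- c("death", "new_systemic_therapy", "relapse")

#' Validate raw subject records
#'
#' Checks one row per subject with columns \code{subject_id}, \code{arm},
#' \code{t_first_response} (NA if never responded), \code{t_event} (NA if no
#' terminal event observed), \code{event_reason} (one of \code{death},
#' \code{new_systemic_therapy}, \code{relapse}, \code{progression}; NA iff
#' \code{t_event} is NA) and \code{t_last_followup}. All times are days since
#' randomization (day 0).
#'
#' @param raw data frame of raw subject records.
#' @return the validated data frame (character ids/arms, numeric times),
#'   invisibly the same content.
#' @export
validate_raw_subjects <- function(raw) {
  need <- c("subject_id", "arm", "t_first_response", "t_event",
            "event_reason", "t_last_followup")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  raw <- as.data.frame(raw)
  raw$subject_id <- as.character(raw$subject_id)
  raw$arm <- as.character(raw$arm)
  raw$event_reason <- as.character(raw$event_reason)
  raw$event_reason[!is.na(raw$event_reason) & raw$event_reason == ""] <-
    NA_character_
  for (col in c("t_first_response", "t_event", "t_last_followup")) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  if (anyDuplicated(raw$subject_id)) {
    stop("duplicated subject_id: ",
         raw$subject_id[duplicated(raw$subject_id)][1])
  }

  fail <- function(cond, rule) {
    bad <- which(cond)
    if (length(bad)) {
      stop(sprintf("subject '%s': %s", raw$subject_id[bad[1]], rule),
           call. = FALSE)
    }
  }
  fail(is.na(raw$t_last_followup) | raw$t_last_followup < 0,
       "t_last_followup must be present and nonnegative")
  fail(!is.na(raw$t_first_response) & raw$t_first_response < 0,
       "t_first_response must be nonnegative")
  fail(!is.na(raw$t_event) & raw$t_event < 0,
       "t_event must be nonnegative")
  fail(!is.na(raw$t_event) & is.na(raw$event_reason),
       "event_reason required when t_event is present")
  fail(is.na(raw$t_event) & !is.na(raw$event_reason),
       "event_reason given without t_event")
  fail(!is.na(raw$event_reason) & !(raw$event_reason %in% EVENT_REASONS),
       paste("event_reason must be one of",
             paste(EVENT_REASONS, collapse = "|")))
  fail(!is.na(raw$t_first_response) & !is.na(raw$t_event) &
         raw$t_first_response > raw$t_event,
       "t_first_response must be <= t_event")
  fail(raw$t_last_followup < pmax(raw$t_first_response, raw$t_event,
                                  0, na.rm = TRUE),
       "t_last_followup must be >= all recorded times")
  fail(is.na(raw$t_first_response) & !is.na(raw$event_reason) &
         raw$event_reason == "progression",
       "progression is not an absorbing event for never-responders")
  raw
}

#' Derive multistate records from raw subject timelines
#'
#' Maps each subject's raw timeline onto the progressive three-state model
#' (state 0 = not in response, state 1 = in response, state 2 = absorbing)
#' and emits the two right-censored time-to-event variables the PBR
#' estimator consumes: \code{(u_time, u_event)}, time of leaving state 0,
#' and \code{(v_time, v_event)}, time of entering state 2.
#'
#' The rules, applied per subject:
#' \enumerate{
#'   \item a first response at \code{t <= cutoff_days} enters state 1 at
#'     \code{t}; a response recorded after the cut-off is a validation error
#'     (the caller must pre-truncate deliberately, responses are never
#'     silently dropped);
#'   \item a responder with a subsequent terminal event (death, new systemic
#'     therapy, relapse, progression) enters state 2 at that time, otherwise
#'     is censored in state 1 at last follow-up;
#'   \item a never-responder with a terminal event (death, new systemic
#'     therapy, relapse) at or before the cut-off goes directly 0 to 2 at
#'     that time;
#'   \item a never-responder followed to or past the cut-off with no earlier
#'     terminal event enters state 2 at the cut-off (no response by the end
#'     of the window);
#'   \item a never-responder lost before the cut-off with no terminal event
#'     is censored in state 0 at last follow-up.
#' }
#' A terminal event falling exactly on the cut-off for a never-responder is
#' treated as rule 3 (the recorded reason is more informative than the
#' window rule). A responder whose terminal event falls on the response day
#' passes through state 1 with zero duration (\code{u_time == v_time}, both
#' events observed).
#'
#' @param raw data frame of raw subject records
#'   (see \code{\link{validate_raw_subjects}}).
#' @param rules a \code{\link{pbr_rules}} object.
#' @return data frame with columns \code{subject_id}, \code{arm},
#'   \code{u_time}, \code{u_event}, \code{responded}, \code{v_time},
#'   \code{v_event}; one row per subject.
#' @export
derive_multistate <- function(raw, rules = pbr_rules()) {
  stopifnot(inherits(rules, "pbr_rules"))
  raw <- validate_raw_subjects(raw)
  if (!is.null(rules$analysis_cutoff_days)) {
    ac <- rules$analysis_cutoff_days
    drop_resp <- !is.na(raw$t_first_response) & raw$t_first_response > ac
    raw$t_first_response[drop_resp] <- NA_real_
    drop_ev <- !is.na(raw$t_event) & raw$t_event > ac
    raw$t_event[drop_ev] <- NA_real_
    raw$event_reason[drop_ev] <- NA_character_
    raw$t_last_followup <- pmin(raw$t_last_followup, ac)
  }
  cc <- rules$cutoff_days
  late <- !is.na(raw$t_first_response) & raw$t_first_response > cc
  if (any(late)) {
    stop(sprintf(
      "subject '%s': first response at day %g is after the %g-day response window; pre-truncate explicitly if intended",
      raw$subject_id[which(late)[1]],
      raw$t_first_response[which(late)[1]], cc), call. = FALSE)
  }

  n <- nrow(raw)
  responded <- !is.na(raw$t_first_response)
  has_event <- !is.na(raw$t_event)
  u_time <- u_event <- v_time <- v_event <- rep(NA_real_, n)

  # responders: rules 1-2
  r <- responded
  u_time[r] <- raw$t_first_response[r]
  u_event[r] <- TRUE
  v_time[r] <- ifelse(has_event[r], raw$t_event[r], raw$t_last_followup[r])
  v_event[r] <- has_event[r]

  # never-responders: rules 3-5
  nr <- !responded
  direct <- nr & has_event & raw$t_event <= cc        # rule 3
  window <- nr & !direct & raw$t_last_followup >= cc  # rule 4
  lost <- nr & !direct & !window                      # rule 5
  u_time[direct] <- v_time[direct] <- raw$t_event[direct]
  u_time[window] <- v_time[window] <- cc
  u_time[lost] <- v_time[lost] <- raw$t_last_followup[lost]
  u_event[direct | window] <- v_event[direct | window] <- TRUE
  u_event[lost] <- v_event[lost] <- FALSE

  out <- data.frame(subject_id = raw$subject_id, arm = raw$arm,
                    u_time = u_time, u_event = as.logical(u_event),
                    responded = responded,
                    v_time = v_time, v_event = as.logical(v_event))
  validate_multistate(out)
}

#' Validate multistate subject records
#'
#' Enforces the invariants of the progressive model: \code{u_time <=
#' v_time}; responders left state 0 (\code{responded} implies
#' \code{u_event}) within the response window; state 2 is unreachable
#' without leaving state 0; a never-responder who left state 0 went straight
#' to state 2 (\code{u_time == v_time}, \code{v_event}).
#'
#' @param ms data frame with columns \code{subject_id}, \code{arm},
#'   \code{u_time}, \code{u_event}, \code{responded}, \code{v_time},
#'   \code{v_event}.
#' @param cutoff_days optional response window to check responders against.
#' @return \code{ms}, invisibly unchanged, after validation.
#' @export
validate_multistate <- function(ms, cutoff_days = NULL) {
  need <- c("subject_id", "arm", "u_time", "u_event", "responded",
            "v_time", "v_event")
  miss <- setdiff(need, names(ms))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  fail <- function(cond, rule) {
    bad <- which(cond)
    if (length(bad)) {
      stop(sprintf("subject '%s': %s", ms$subject_id[bad[1]], rule),
           call. = FALSE)
    }
  }
  fail(is.na(ms$u_time) | is.na(ms$v_time) | ms$u_time < 0,
       "u_time and v_time must be present and nonnegative")
  fail(ms$u_time > ms$v_time, "u_time must be <= v_time")
  fail(ms$responded & !ms$u_event, "responded implies u_event")
  if (!is.null(cutoff_days)) {
    fail(ms$responded & ms$u_time > cutoff_days,
         "responders must respond within the response window")
  }
  fail(!ms$u_event & ms$v_event,
       "cannot enter state 2 without leaving state 0")
  fail(ms$u_event & !ms$responded & !(ms$u_time == ms$v_time & ms$v_event),
       "a never-responder leaving state 0 must absorb at the same time")
  fail(!ms$u_event & ms$u_time != ms$v_time,
       "a subject censored in state 0 must have u_time == v_time")
  ms
}

#' Read raw subject records from CSV
#'
#' Expects columns \code{subject_id, arm, t_first_response, t_event,
#' event_reason, t_last_followup}; blank fields are missing values.
#'
#' @param path CSV file path.
#' @return validated data frame of raw subjects.
#' @export
read_raw_subjects <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  validate_raw_subjects(raw)
}

#' Write raw subject records to CSV
#'
#' @param raw data frame of raw subjects.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_raw_subjects <- function(raw, path) {
  utils::write.csv(raw, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write derived multistate records to CSV
#'
#' Schema: \code{subject_id, arm, u_time, u_event, responded, v_time,
#' v_event}.
#'
#' @param ms multistate data frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_multistate <- function(ms, path) {
  utils::write.csv(ms, path, row.names = FALSE)
  invisible(path)
}
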