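EVENT_KINDS <- c("cc_time_transition", "treatment_complete",
                 "triage_complete", "vehicle_arrival", "vehicle_departure",
                 "loading_complete", "sar_extraction", "admission",
                 "dispatch_wave")

#' Create a discrete-event simulation kernel
#'
#' A minimal deterministic event queue: events execute in (time, sequence)
#' order, where the sequence number is assigned at scheduling time, so
#' simultaneous events fire in scheduling order. Executed events are
#' appended to an event log together with free-form notes emitted by
#' handlers.
#'
#' @return an environment of class `mci_sim`.
#' @export
new_simulation <- function() {
  sim <- new.env(parent = emptyenv())
  sim$clock <- 0
  sim$seq <- 0L
  sim$ev_time <- numeric(0)
  sim$ev_seq <- integer(0)
  sim$ev_kind <- character(0)
  sim$ev_alive <- logical(0)
  sim$ev_payload <- list()
  sim$log <- list()
  class(sim) <- c("mci_sim", "environment")
  sim
}

#' Schedule an event
#'
#' @param sim an `mci_sim`.
#' @param time absolute simulation time, minutes; must not lie in the past.
#' @param kind one of the recognised event kinds.
#' @param payload list of subject identifiers and details.
#' @return an opaque event handle usable with `cancel_event()`.
#' @export
schedule <- function(sim, time, kind, payload = list()) {
  if (time < sim$clock) {
    stop("cannot schedule an event in the past (clock ", sim$clock,
         ", requested ", time, ")", call. = FALSE)
  }
  kind <- match.arg(kind, EVENT_KINDS)
  sim$seq <- sim$seq + 1L
  i <- length(sim$ev_time) + 1L
  sim$ev_time[i] <- time
  sim$ev_seq[i] <- sim$seq
  sim$ev_kind[i] <- kind
  sim$ev_alive[i] <- TRUE
  sim$ev_payload[[i]] <- payload
  i
}

#' Cancel a pending event
#'
#' @param sim an `mci_sim`.
#' @param handle value returned by `schedule()`.
#' @export
cancel_event <- function(sim, handle) {
  if (handle < 1 || handle > length(sim$ev_alive) || !sim$ev_alive[handle]) {
    stop("event already executed or cancelled (double-cancel?)",
         call. = FALSE)
  }
  sim$ev_alive[handle] <- FALSE
  invisible(NULL)
}

#' Append a note row to the event log
#'
#' Handlers use this to record state deltas (deaths, admissions,
#' discharges, treatment starts) alongside the executed events.
#'
#' @param sim an `mci_sim`.
#' @param kind short record label.
#' @param subject subject identifier (victim, vehicle, unit).
#' @param detail free-form detail string.
#' @export
sim_note <- function(sim, kind, subject = "", detail = "") {
  sim$log[[length(sim$log) + 1L]] <-
    list(time = sim$clock, kind = kind, subject = subject, detail = detail)
  invisible(NULL)
}

#' Run the simulation until a time horizon
#'
#' Executes all pending events with time <= `t_end` in deterministic
#' (time, sequence) order. `handler(sim, event)` is called for each event;
#' the event is a list with `time`, `kind` and `payload`.
#'
#' @param sim an `mci_sim`.
#' @param t_end horizon, minutes.
#' @param handler function of (sim, event), or NULL to just drain and log.
#' @return the event log as a data.frame (`time`, `kind`, `subject`,
#'   `detail`), invisibly obtainable again via `event_log()`.
#' @export
run_until <- function(sim, t_end = Inf, handler = NULL) {
  repeat {
    live <- which(sim$ev_alive & sim$ev_time <= t_end)
    if (!length(live)) break
    i <- live[order(sim$ev_time[live], sim$ev_seq[live])[1]]
    sim$ev_alive[i] <- FALSE
    sim$clock <- sim$ev_time[i]
    ev <- list(time = sim$ev_time[i], kind = sim$ev_kind[i],
               payload = sim$ev_payload[[i]])
    sim_note(sim, ev$kind, ev$payload$subject %||% "",
             ev$payload$detail %||% "")
    if (!is.null(handler)) handler(sim, ev)
  }
  event_log(sim)
}

#' Extract the event log
#'
#' @param sim an `mci_sim`.
#' @return data.frame with columns `time`, `kind`, `subject`, `detail`,
#'   ordered as executed (times non-decreasing).
#' @export
event_log <- function(sim) {
  if (!length(sim$log)) {
    return(data.frame(time = numeric(0), kind = character(0),
                      subject = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(time = vapply(sim$log, `[[`, 0, "time"),
             kind = vapply(sim$log, `[[`, "", "kind"),
             subject = vapply(sim$log, `[[`, "", "subject"),
             detail = vapply(sim$log, `[[`, "", "detail"),
             stringsAsFactors = FALSE)
}

#' Write an event log as line-delimited text
#'
#' Tab-separated `time  kind  subject  detail` rows under a versioned
#' header, for audit and golden-trace comparison.
#'
#' @param log data.frame from `event_log()`.
#' @param path output file.
#' @export
write_event_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# mci-event-log/1", con)
  writeLines(sprintf("%.6g\t%s\t%s\t%s", log$time, log$kind, log$subject,
                     log$detail), con)
  invisible(path)
}

#' Read a line-delimited event log
#' @param path file written by `write_event_log()`.
#' @return data.frame with `time`, `kind`, `subject`, `detail`.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "# mci-event-log/1")) {
    stop("unrecognised event log version", call. = FALSE)
  }
  lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(time = as.numeric(vapply(parts, `[[`, "", 1)),
             kind = vapply(parts, `[[`, "", 2),
             subject = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
             detail = vapply(parts, function(p) if (length(p) >= 4) p[4] else "", ""),
             stringsAsFactors = FALSE)
}

# ---- clinical trigger handlers -------------------------------------------
#
# A victim's runtime state is an environment with (at least): id, profile,
# cond (current condition id), rpm, category, pending_cc (handle of the one
# pending time transition, or NA), disposition. The response layer
# registers hooks on the state container: on_death(vid), on_stabilize(vid),
# on_condition_change(vid).

# Schedule the current condition's time transition (one pending per victim).
schedule_time_transition <- function(sim, state, vid) {
  v <- state$victims[[vid]]
  tr <- time_transition_from(v$profile, v$cond)
  if (is.null(tr)) { v$pending_cc <- NA; return(invisible(NULL)) }
  v$pending_cc <- schedule(sim, sim$clock + tr$delay, "cc_time_transition",
                           list(subject = vid, target = tr$target))
  invisible(NULL)
}

enter_condition <- function(sim, state, vid, target) {
  v <- state$victims[[vid]]
  cc <- v$profile$conditions[[target]]
  v$cond <- target
  v$rpm <- cc$rpm
  v$category <- cc$triage_category
  v$pending_cc <- NA
  if (cc$end_kind == "dead") {
    v$disposition <- "dead"
    sim_note(sim, "death", vid, death_location_of(v$location %||% ""))
    if (!is.null(state$hooks$on_death)) state$hooks$on_death(vid)
  } else if (cc$end_kind == "stabilized") {
    v$stabilized <- TRUE
    sim_note(sim, "stabilized", vid, v$location)
    if (!is.null(state$hooks$on_stabilize)) state$hooks$on_stabilize(vid)
  } else {
    schedule_time_transition(sim, state, vid)
    if (!is.null(state$hooks$on_condition_change)) {
      state$hooks$on_condition_change(vid)
    }
  }
  invisible(NULL)
}

#' Fire a victim's pending time trigger
#'
#' Moves the victim along the untreated (or current treated) pathway. If
#' the target is a dead end state the victim is withdrawn from the response
#' flow via the registered hook; otherwise the next time transition is
#' scheduled after its dwell. Firing on an end state is an engine bug.
#'
#' @param sim an `mci_sim`.
#' @param state scenario state container with `victims` and `hooks`.
#' @param vid victim id.
#' @param target target condition id from the event payload.
#' @export
on_time_trigger <- function(sim, state, vid, target) {
  v <- state$victims[[vid]]
  cc <- v$profile$conditions[[v$cond]]
  stopifnot(!cc$is_end_state)  # engine bug if a trigger fires on an end state
  enter_condition(sim, state, vid, target)
}

#' Fire a treatment trigger on a victim
#'
#' Called when a provider of `skill` completes treatment delivery. The
#' pending time transition is cancelled and the state change onto the
#' treatment pathway is scheduled after the transition's treatment-effect
#' delay. Treating a dead victim is a logged no-op; a skill for which the
#' current state has no (direct or substitutable) treatment transition is
#' likewise a logged no-op.
#'
#' @param sim an `mci_sim`.
#' @param state scenario state container.
#' @param vid victim id.
#' @param skill provider skill (EMT, PIT, MMT, ED).
#' @export
on_treatment_trigger <- function(sim, state, vid, skill) {
  v <- state$victims[[vid]]
  if (identical(v$disposition, "dead")) {
    sim_note(sim, "warning", vid, "treatment on dead victim ignored")
    return(invisible(NULL))
  }
  cc <- v$profile$conditions[[v$cond]]
  if (cc$is_end_state) return(invisible(NULL))
  tr <- treatment_transition_from(v$profile, v$cond, skill)
  if (is.null(tr)) {
    sim_note(sim, "warning", vid,
             paste0("no ", skill, " treatment transition from ", v$cond))
    return(invisible(NULL))
  }
  if (!is.na(v$pending_cc)) cancel_event(sim, v$pending_cc)
  v$pending_cc <- schedule(sim, sim$clock + tr$delay, "cc_time_transition",
                           list(subject = vid, target = tr$target,
                                detail = paste0("effect:", skill)))
  invisible(NULL)
}

# Start the clinical clock of every victim: enter the initial condition and
# schedule its first time transition.
init_clinical <- function(sim, state) {
  for (vid in names(state$victims)) {
    v <- state$victims[[vid]]
    cc <- v$profile$conditions[[v$profile$initial_condition]]
    v$cond <- cc$condition_id
    v$rpm <- cc$rpm
    v$category <- cc$triage_category
    schedule_time_transition(sim, state, vid)
  }
  invisible(NULL)
}
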