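#' Construct a clinical condition (health state)
#'
#' One node of a victim's health-state graph. Non-end states carry vital
#' signs, an RPM score consistent with those vitals, and a triage category.
#' End states are absorbing: `dead` or `stabilized`.
#'
#' @param condition_id opaque identifier, unique within a profile.
#' @param vitals a `vital_signs` object (may be NULL for end states).
#' @param rpm RPM score 0--12; if vitals are given it must equal their score.
#' @param triage_category one of T1--T4.
#' @param end_kind "none", "dead" or "stabilized".
#' @return an object of class `clinical_condition`.
#' @export
clinical_condition <- function(condition_id, vitals = NULL, rpm = NULL,
                               triage_category = "T1",
                               end_kind = c("none", "dead", "stabilized")) {
  end_kind <- match.arg(end_kind)
  triage_category <- match.arg(triage_category, TRIAGE_CATEGORIES)
  if (!is.null(vitals)) {
    stopifnot(inherits(vitals, "vital_signs"))
    scored <- rpm_score(vitals)
    if (is.null(rpm)) rpm <- scored
    if (rpm != scored) {
      stop("rpm (", rpm, ") does not equal the coded score of the vitals (",
           scored, ")", call. = FALSE)
    }
  }
  if (is.null(rpm)) rpm <- 0L
  if (rpm < 0 || rpm > 12 || rpm != floor(rpm)) {
    stop("rpm must be an integer in [0, 12]", call. = FALSE)
  }
  structure(list(condition_id = as.character(condition_id), vitals = vitals,
                 rpm = as.integer(rpm), triage_category = triage_category,
                 is_end_state = end_kind != "none", end_kind = end_kind),
            class = "clinical_condition")
}

#' Construct a clinical-condition transition
#'
#' Time transitions fire after a dwell in the source state; treatment
#' transitions fire when a provider of (at least) the required skill
#' completes treatment, after the treatment-effect delay.
#'
#' @param source,target condition identifiers.
#' @param trigger_kind "time" or "treatment".
#' @param delay minutes > 0: dwell time (time trigger) or treatment-effect
#'   time after delivery completion (treatment trigger).
#' @param required_skill one of EMT, PIT, MMT, ED, or "none" (time triggers).
#' @param required_supplies character vector of supply identifiers.
#' @return an object of class `cc_transition`.
#' @export
cc_transition <- function(source, target, trigger_kind = c("time", "treatment"),
                          delay, required_skill = "none",
                          required_supplies = character()) {
  trigger_kind <- match.arg(trigger_kind)
  if (delay <= 0) stop("transition delay must be > 0 minutes", call. = FALSE)
  if (trigger_kind == "treatment") {
    required_skill <- match.arg(required_skill, SKILL_LEVELS)
  } else if (!identical(required_skill, "none")) {
    stop("time transitions carry no required skill", call. = FALSE)
  }
  structure(list(source = as.character(source), target = as.character(target),
                 trigger_kind = trigger_kind, delay = as.numeric(delay),
                 required_skill = required_skill,
                 required_supplies = as.character(required_supplies)),
            class = "cc_transition")
}

#' Construct a victim profile
#'
#' A victim profile is the static description of one casualty: category in
#' the triage mix, mobility, destination need, and a clinical-condition
#' graph with an initial state, an untreated (time-trigger) pathway that is
#' total up to an end state, and treatment pathways per provider skill.
#'
#' @param victim_id profile identifier.
#' @param triage_mix_category initial category T1--T4.
#' @param ambulatory logical; can the victim walk out.
#' @param destination_need "general", "trauma_centre" or "burn_centre".
#' @param initial_condition id of the initial clinical condition.
#' @param conditions list of `clinical_condition`s.
#' @param transitions list of `cc_transition`s.
#' @param validate run `validate_profile()` on the result.
#' @return an object of class `victim_profile`.
#' @export
victim_profile <- function(victim_id, triage_mix_category, ambulatory,
                           destination_need = "general",
                           initial_condition, conditions, transitions,
                           validate = TRUE) {
  triage_mix_category <- match.arg(triage_mix_category, TRIAGE_CATEGORIES)
  destination_need <- match.arg(destination_need,
                                c("general", "trauma_centre", "burn_centre"))
  names(conditions) <- vapply(conditions, `[[`, "", "condition_id")
  p <- structure(list(victim_id = as.character(victim_id),
                      triage_mix_category = triage_mix_category,
                      ambulatory = isTRUE(ambulatory),
                      destination_need = destination_need,
                      initial_condition = as.character(initial_condition),
                      conditions = conditions, transitions = transitions),
                 class = "victim_profile")
  if (validate) validate_profile(p)
  p
}

#' Validate a victim profile
#'
#' Checks the structural invariants of the clinical-condition graph: the
#' initial condition exists; every referenced condition exists; every
#' non-end condition has exactly one outgoing time transition (the untreated
#' pathway is total and deterministic up to an end state); dead states have
#' no outgoing transitions; treatment transitions carry a real skill;
#' (source, trigger, skill) is unique; and the time-transition graph is
#' acyclic.
#'
#' @param p a `victim_profile`.
#' @return the profile, invisibly; stops on the first violation.
#' @export
validate_profile <- function(p) {
  stopifnot(inherits(p, "victim_profile"))
  ids <- names(p$conditions)
  if (anyDuplicated(ids)) stop("duplicate condition ids", call. = FALSE)
  if (!p$initial_condition %in% ids) {
    stop("initial condition not found among conditions", call. = FALSE)
  }
  keys <- character(0)
  time_next <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (tr in p$transitions) {
    if (!tr$source %in% ids || !tr$target %in% ids) {
      stop("transition references unknown condition: ", tr$source, " -> ",
           tr$target, call. = FALSE)
    }
    src <- p$conditions[[tr$source]]
    if (src$end_kind == "dead") {
      stop("dead state ", tr$source, " must have no outgoing transitions",
           call. = FALSE)
    }
    if (tr$trigger_kind == "treatment" && tr$required_skill == "none") {
      stop("treatment transition without a required skill", call. = FALSE)
    }
    key <- paste(tr$source, tr$trigger_kind, tr$required_skill)
    if (key %in% keys) {
      stop("multiple transitions for (", key, ")", call. = FALSE)
    }
    keys <- c(keys, key)
    if (tr$trigger_kind == "time") time_next[tr$source] <- tr$target
  }
  # untreated pathway total: every non-end condition has a time transition
  for (id in ids) {
    cc <- p$conditions[[id]]
    if (!cc$is_end_state && is.na(time_next[id])) {
      stop("non-end condition ", id, " has no time transition ",
           "(untreated pathway must be total)", call. = FALSE)
    }
  }
  # acyclicity of the time-transition graph: walk from every node
  for (id in ids) {
    seen <- character(0)
    cur <- id
    while (!is.na(time_next[cur])) {
      if (cur %in% seen) stop("cycle among time transitions at ", cur,
                              call. = FALSE)
      seen <- c(seen, cur)
      cur <- time_next[cur]
    }
  }
  invisible(p)
}

# Skill substitution: a higher-skill provider may fire a lower-skill
# treatment transition when no dedicated transition exists for their skill
# (MMT covers PIT covers EMT; the ED covers all).
skill_fallbacks <- function(skill) {
  switch(skill,
         EMT = "EMT",
         PIT = c("PIT", "EMT"),
         MMT = c("MMT", "PIT", "EMT"),
         ED  = c("ED", "MMT", "PIT", "EMT"),
         stop("unknown skill: ", skill, call. = FALSE))
}

#' Next clinical condition for a trigger
#'
#' Resolves the unique transition out of `current` for the given trigger.
#' Treatment triggers match on the provider skill, falling back to the
#' nearest lower-skill transition when no dedicated one exists; `"none"` is
#' returned when nothing matches (end state, or skill below every available
#' treatment transition).
#'
#' @param current condition id.
#' @param trigger_kind "time" or "treatment".
#' @param skill provider skill for treatment triggers.
#' @param p a `victim_profile`.
#' @return target condition id, or `"none"`.
#' @export
next_condition <- function(current, trigger_kind = c("time", "treatment"),
                           skill = "none", p) {
  trigger_kind <- match.arg(trigger_kind)
  if (!current %in% names(p$conditions)) {
    stop("unknown condition: ", current, call. = FALSE)
  }
  out <- p$transitions[vapply(p$transitions, function(tr) {
    tr$source == current && tr$trigger_kind == trigger_kind
  }, logical(1))]
  if (trigger_kind == "time") {
    if (length(out) == 0) return("none")
    if (length(out) > 1) stop("multiple time transitions from ", current,
                              call. = FALSE)
    return(out[[1]]$target)
  }
  for (s in skill_fallbacks(skill)) {
    hit <- out[vapply(out, function(tr) tr$required_skill == s, logical(1))]
    if (length(hit) > 1) stop("multiple ", s, " transitions from ", current,
                              call. = FALSE)
    if (length(hit) == 1) return(hit[[1]]$target)
  }
  "none"
}

# The unique time transition out of a condition, or NULL.
time_transition_from <- function(p, current) {
  for (tr in p$transitions) {
    if (tr$trigger_kind == "time" && tr$source == current) return(tr)
  }
  NULL
}

# The treatment transition a provider of `skill` would fire, or NULL.
treatment_transition_from <- function(p, current, skill) {
  target <- next_condition(current, "treatment", skill, p)
  if (identical(target, "none")) return(NULL)
  for (tr in p$transitions) {
    if (tr$trigger_kind == "treatment" && tr$source == current &&
        tr$target == target) return(tr)
  }
  NULL
}

#' Untreated time of death for a profile
#'
#' Walks the time-trigger (untreated) pathway from the initial condition,
#' accumulating dwell times, and returns the simulated clock time at which a
#' dead end state is entered. Returns `Inf` ("never") when the pathway
#' terminates in a stabilized or other non-lethal state.
#'
#' @param p a validated `victim_profile`.
#' @return minutes since incident start, or `Inf`.
#' @export
untreated_death_time <- function(p) {
  validate_profile(p)
  cur <- p$initial_condition
  t <- 0
  repeat {
    cc <- p$conditions[[cur]]
    if (cc$end_kind == "dead") return(t)
    if (cc$is_end_state) return(Inf)
    tr <- time_transition_from(p, cur)
    t <- t + tr$delay
    cur <- tr$target
  }
}
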