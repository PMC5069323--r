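#' Default parameters for the synthetic profile library
#'
#' Three profiles per triage category, each defined by an initial RPM score
#' and a per-30-minute RPM decrement on the untreated pathway. T3 (walking
#' wounded) profiles do not deteriorate and stabilize untreated; T1 profiles
#' deteriorate fast (untreated death within 60--90 min), T2 slowly
#' (150--330 min), T4 (expectant) fastest (30--60 min). The original victim
#' data behind the case study are not published, so this library is a
#' synthetic, documented stand-in with the same categorical structure.
#'
#' @return a named list of per-category parameter blocks.
#' @export
default_profile_params <- function() {
  list(
    T1 = list(initial_rpm = c(6L, 5L, 7L), decrement = c(2L, 2L, 2L)),
    T2 = list(initial_rpm = c(9L, 10L, 11L), decrement = c(1L, 1L, 1L)),
    T3 = list(initial_rpm = c(12L, 11L, 12L), decrement = c(0L, 0L, 0L)),
    T4 = list(initial_rpm = c(2L, 1L, 3L), decrement = c(1L, 1L, 2L))
  )
}

# Untreated (time-trigger) RPM trajectory: values at nominal times
# 0, 30, 60, ... until (exclusive) the first bin where survival reaches 0.
cct_trajectory <- function(r0, d, tab) {
  rpms <- integer(0)
  k <- 0
  repeat {
    r <- max(0L, r0 - k * d)
    if (survival_probability(r, k * tab$bin_width, tab) == 0) break
    rpms <- c(rpms, r)
    k <- k + 1
    if (k > 200) stop("runaway trajectory", call. = FALSE)
  }
  rpms
}

#' Build one synthetic victim profile
#'
#' Constructs the clinical-condition graph for a victim with initial RPM
#' `r0` deteriorating by `d` points per 30-minute bin untreated. The dead
#' end state is entered at the first tabulated bin where the survival
#' probability of the current RPM reaches zero (a deterministic death rule;
#' no random draws). Every live untreated state carries treatment
#' transitions: an EMT treatment holds the current RPM on a slowed pathway
#' (60-minute dwells), a PIT treatment improves RPM by 1 on a slowed
#' pathway (stabilizing outright when the improved score reaches 11), and
#' an MMT treatment improves RPM by 2 and stabilizes after 30 minutes.
#' Slowed-pathway states keep an oblique MMT escalation transition.
#'
#' @param victim_id profile identifier.
#' @param category triage category T1--T4.
#' @param r0 initial RPM score.
#' @param d RPM decrement per 30-minute bin (0 = stable, stabilizes).
#' @param tab deterioration table.
#' @param effect_delay treatment-effect time, minutes.
#' @param stabilize_dwell dwell before a stable state becomes an absorbing
#'   stabilized end state, minutes.
#' @return a validated `victim_profile`.
#' @export
build_profile <- function(victim_id, category, r0, d,
                          tab = deterioration_table(),
                          effect_delay = 5, stabilize_dwell = 30) {
  stopifnot(r0 >= 0, r0 <= 12, d >= 0)
  ambulatory <- category == "T3"
  conds <- list()
  trans <- list()
  add_cond <- function(id, rpm, end_kind = "none") {
    if (!is.null(conds[[id]])) return(invisible(NULL))
    v <- if (end_kind == "none") vitals_for_rpm(rpm) else NULL
    conds[[id]] <<- clinical_condition(id, vitals = v, rpm = rpm,
                                       triage_category = category,
                                       end_kind = end_kind)
    invisible(NULL)
  }
  add_trans <- function(...) { trans[[length(trans) + 1L]] <<- cc_transition(...) }
  add_cond("dead", 0L, "dead")
  add_cond("stab", 12L, "stabilized")

  mmt_target <- function(rpm) {
    r2 <- min(12L, rpm + 2L)
    id <- paste0("mmt", r2)
    if (is.null(conds[[id]])) {
      add_cond(id, r2)
      add_trans(id, "stab", "time", stabilize_dwell)
    }
    id
  }

  # a slowed treated pathway: 60-min dwells, same decrement, death at the
  # first nominal time whose survival is zero; states get MMT escalation
  slowed_chain <- function(prefix, r_start, t_start) {
    first_id <- NULL
    j <- 0
    prev <- NULL
    repeat {
      r <- max(0L, r_start - j * d)
      t_nom <- t_start + j * 60
      if (survival_probability(r, t_nom, tab) == 0) {
        if (!is.null(prev)) add_trans(prev, "dead", "time", 60)
        break
      }
      id <- sprintf("%s-%d-%d", prefix, t_start, j)
      add_cond(id, r)
      if (!is.null(prev)) add_trans(prev, id, "time", 60)
      if (is.null(first_id)) first_id <- id
      add_trans(id, mmt_target(r), "treatment", effect_delay,
                required_skill = "MMT")
      prev <- id
      j <- j + 1
      if (d == 0) { add_trans(id, "stab", "time", stabilize_dwell); break }
      if (j > 200) stop("runaway slowed chain", call. = FALSE)
    }
    first_id
  }

  if (d == 0) {
    # stable profile: one live state, stabilizes untreated
    id <- "cct-0"
    add_cond(id, r0)
    add_trans(id, "stab", "time", stabilize_dwell)
  } else {
    traj <- cct_trajectory(r0, d, tab)
    n <- length(traj)
    for (k in seq_len(n)) {
      id <- sprintf("cct-%d", k - 1L)
      r <- traj[k]
      t_nom <- (k - 1L) * tab$bin_width
      add_cond(id, r)
      nxt <- if (k < n) sprintf("cct-%d", k) else "dead"
      add_trans(id, nxt, "time", tab$bin_width)
      add_trans(id, mmt_target(r), "treatment", effect_delay,
                required_skill = "MMT")
      pit_r <- min(12L, r + 1L)
      if (pit_r >= 11L) {
        pid <- paste0("pithold", pit_r)
        if (is.null(conds[[pid]])) {
          add_cond(pid, pit_r)
          add_trans(pid, "stab", "time", stabilize_dwell)
        }
        add_trans(id, pid, "treatment", effect_delay, required_skill = "PIT")
      } else {
        pid <- slowed_chain("pit", pit_r, t_nom)
        add_trans(id, pid, "treatment", effect_delay, required_skill = "PIT")
      }
      eid <- slowed_chain("emt", r, t_nom)
      if (!is.null(eid)) {
        add_trans(id, eid, "treatment", effect_delay, required_skill = "EMT")
      }
    }
  }
  victim_profile(victim_id, category, ambulatory,
                 destination_need = "general",
                 initial_condition = "cct-0",
                 conditions = conds, transitions = trans)
}

#' Build the default synthetic profile library
#'
#' Three profiles per triage category ("T1-A" .. "T4-C"), constructed by
#' `build_profile()` from `default_profile_params()`. The construction is
#' fully deterministic; the `seed` argument is accepted for interface
#' symmetry with the other generators but has no effect.
#'
#' @param params per-category parameters, see `default_profile_params()`.
#' @param tab deterioration table.
#' @param seed ignored (construction is deterministic).
#' @param effect_delay treatment-effect time in minutes.
#' @return named list of `victim_profile`s.
#' @export
build_default_profiles <- function(params = default_profile_params(),
                                   tab = deterioration_table(),
                                   seed = NULL, effect_delay = 5) {
  lib <- list()
  for (cat in names(params)) {
    blk <- params[[cat]]
    if (any(blk$initial_rpm < 0 | blk$initial_rpm > 12) ||
        any(blk$decrement < 0)) {
      stop("profile params for ", cat, " violate the monotone ",
           "deterioration constraints", call. = FALSE)
    }
    tags <- LETTERS[seq_along(blk$initial_rpm)]
    for (i in seq_along(blk$initial_rpm)) {
      id <- paste0(cat, "-", tags[i])
      lib[[id]] <- build_profile(id, cat, blk$initial_rpm[i],
                                 blk$decrement[i], tab,
                                 effect_delay = effect_delay)
    }
  }
  lib
}

#' Write a profile library to a YAML file
#'
#' @param lib named list of `victim_profile`s.
#' @param path output file.
#' @export
write_profile_library <- function(lib, path) {
  ser <- lapply(unname(lib), function(p) {
    list(victim_id = p$victim_id,
         triage_mix_category = p$triage_mix_category,
         ambulatory = p$ambulatory,
         destination_need = p$destination_need,
         initial_condition = p$initial_condition,
         conditions = lapply(unname(p$conditions), function(cc) {
           out <- list(condition_id = cc$condition_id, rpm = cc$rpm,
                       triage_category = cc$triage_category,
                       end_kind = cc$end_kind)
           if (!is.null(cc$vitals)) {
             out$vitals <- list(respiratory_rate = cc$vitals$respiratory_rate,
                                pulse_rate = cc$vitals$pulse_rate,
                                motor_response = cc$vitals$motor_response)
           }
           out
         }),
         transitions = lapply(unname(p$transitions), function(tr) {
           list(source = tr$source, target = tr$target,
                trigger_kind = tr$trigger_kind, delay = tr$delay,
                required_skill = tr$required_skill,
                required_supplies = as.list(tr$required_supplies))
         }))
  })
  yaml::write_yaml(list(schema = "profile-library/1", profiles = ser), path)
  invisible(path)
}

#' Read a profile library from a YAML file
#'
#' @param path file written by `write_profile_library()`.
#' @return named list of validated `victim_profile`s.
#' @export
read_profile_library <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "profile-library/1")) {
    stop("unrecognised profile library schema", call. = FALSE)
  }
  lib <- lapply(doc$profiles, function(p) {
    conds <- lapply(p$conditions, function(cc) {
      v <- if (!is.null(cc$vitals)) {
        vital_signs(cc$vitals$respiratory_rate, cc$vitals$pulse_rate,
                    cc$vitals$motor_response)
      }
      clinical_condition(cc$condition_id, vitals = v, rpm = cc$rpm,
                         triage_category = cc$triage_category,
                         end_kind = cc$end_kind)
    })
    trans <- lapply(p$transitions, function(tr) {
      cc_transition(tr$source, tr$target, tr$trigger_kind, tr$delay,
                    tr$required_skill,
                    unlist(tr$required_supplies) %||% character())
    })
    victim_profile(p$victim_id, p$triage_mix_category, p$ambulatory,
                   p$destination_need, p$initial_condition, conds, trans)
  })
  names(lib) <- vapply(lib, `[[`, "", "victim_id")
  lib
}

`%||%` <- function(a, b) if (is.null(a)) b else a
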