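#' Travel time between two points
#'
#' Minutes = distance (km) / average speed (km/h) * 60.
#'
#' @param distance_km distance, km (>= 0).
#' @param speed_kmh average vehicle speed, km/h (> 0).
#' @return minutes.
#' @examples
#' travel_time(30, 60)  # 30 min
#' @export
travel_time <- function(distance_km, speed_kmh) {
  if (any(speed_kmh <= 0)) stop("speed must be positive", call. = FALSE)
  if (any(distance_km < 0)) stop("distance must be non-negative", call. = FALSE)
  distance_km / speed_kmh * 60
}

#' Default search-and-rescue rate levels
#'
#' Non-ambulatory victims extracted per 10 minutes, before and after the
#' additional fuselage openings cut at minute 21 (which triple the
#' throughput). Stand-in values for the unpublished appendix table.
#' @return named list of levels.
#' @export
default_sar_levels <- function() {
  list(low    = list(rate_before = 3, rate_after = 9),
       medium = list(rate_before = 5, rate_after = 15),
       high   = list(rate_before = 8, rate_after = 24))
}

#' Closed-form SAR extraction schedule
#'
#' The k-th non-ambulatory victim reaches the CCP at
#' `start + k / r1` while that lies before the openings at `holes_at`,
#' and at `holes_at + j / r2` thereafter, where r1, r2 are the per-minute
#' extraction rates before and after the openings.
#'
#' @param n number of non-ambulatory victims.
#' @param rate_level "low", "medium" or "high".
#' @param levels rate-level table, see `default_sar_levels()`.
#' @param start SAR start, minutes after the crash.
#' @param holes_at time of the additional fuselage openings, minutes.
#' @return numeric vector of n non-decreasing CCP arrival times.
#' @export
sar_schedule <- function(n, rate_level, levels = default_sar_levels(),
                         start = 5, holes_at = 21) {
  if (!rate_level %in% names(levels)) {
    stop("unknown SAR rate level: ", rate_level, call. = FALSE)
  }
  if (n == 0) return(numeric(0))
  r1 <- levels[[rate_level]]$rate_before / 10
  r2 <- levels[[rate_level]]$rate_after / 10
  k <- seq_len(n)
  t1 <- start + k / r1
  n1 <- sum(t1 <= holes_at)
  out <- t1
  if (n1 < n) out[(n1 + 1):n] <- holes_at + ((n1 + 1):n - n1) / r2
  out
}

#' Default resource levels
#'
#' Total ambulances and MMTs committed to the incident (the rest cover
#' day-to-day calls; at the "normal" level half of the regional fleet of 38
#' ambulances responds), the number of MMTs in the first wave at t = 0
#' (the high level sends 8, i.e. 7 working teams plus the commander), and
#' the dispatch time of the reinforcement wave.
#' @return named list of levels.
#' @export
default_resource_levels <- function() {
  list(low    = list(ambulances = 10, mmts = 4, first_wave_mmts = 4, wave2_at = 30),
       medium = list(ambulances = 14, mmts = 5, first_wave_mmts = 4, wave2_at = 20),
       normal = list(ambulances = 19, mmts = 6, first_wave_mmts = 4, wave2_at = 10),
       high   = list(ambulances = 24, mmts = 8, first_wave_mmts = 8, wave2_at = 10))
}

#' Default HCF treatment-capacity levels
#'
#' Per-hospital initial surge (patients admitted immediately) and
#' subsequent admission rate (patients per hour).
#' @return named list of levels.
#' @export
default_hcf_capacity_levels <- function() {
  list(low    = list(surge = 3, rate_per_hour = 2),
       medium = list(surge = 5, rate_per_hour = 4),
       high   = list(surge = 8, rate_per_hour = 6))
}

#' Transport supervision requirement
#'
#' Which crew must accompany a T1/T2 victim in the ambulance, per
#' supervision level: `emt` never adds crew; `nurse` requires a nurse for
#' T1 (a PIT-type ambulance satisfies this, otherwise an idle
#' physician/nurse team is borrowed); `physician` requires a
#' physician-nurse team for T1; `physician_all` requires one for both T1
#' and T2.
#'
#' @param level supervision level.
#' @param category the victim's triage-mix category.
#' @return "none", "nurse" or "mmt".
#' @export
supervision_requirement <- function(level, category) {
  level <- match.arg(level, c("emt", "nurse", "physician", "physician_all"))
  switch(level,
         emt = "none",
         nurse = if (category == "T1") "nurse" else "none",
         physician = if (category == "T1") "mmt" else "none",
         physician_all = if (category %in% c("T1", "T2")) "mmt" else "none")
}

#' Choose a destination hospital
#'
#' `nearest_first`: the closest capable hospital whose initial surge is not
#' yet fully assigned, else the next closest; when every surge is
#' exhausted, the capable hospital with the smallest load relative to its
#' surge. `round_robin`: capacity-proportional rotation -- the capable
#' hospital with the smallest assigned/surge ratio, ties broken by
#' distance. The victim's destination need restricts the capable set.
#'
#' @param victim victim environment (uses `dest`).
#' @param policy "nearest_first" or "round_robin".
#' @param hcfs list of hospital state environments (fields `id`, `dist`,
#'   `caps`, `surge`, `assigned`).
#' @return the chosen hospital id.
#' @export
distribute_to_hcf <- function(victim, policy, hcfs) {
  need <- switch(victim$dest, general = "general",
                 trauma_centre = "trauma", burn_centre = "burn")
  cap <- Filter(function(h) need %in% h$caps, hcfs)
  if (!length(cap)) stop("no capable HCF for need ", need, call. = FALSE)
  dists <- vapply(cap, `[[`, 0, "dist")
  assigned <- vapply(cap, `[[`, 0, "assigned")
  surge <- vapply(cap, `[[`, 0, "surge")
  i <- if (policy == "nearest_first") {
    open <- assigned < surge
    if (any(open)) which(open)[which.min(dists[open])] else
      order(assigned / pmax(surge, 1), dists)[1]
  } else {
    order(assigned / pmax(surge, 1), dists)[1]
  }
  cap[[i]]$id
}

#' Build the timed dispatch plan
#'
#' The initial wave is fixed by the intervention plan: 5 BLS ambulances
#' from the nearest stations, 4 MMTs (the first is the incident medical
#' commander and never treats or transports; the second triages at the
#' CCP; the third and fourth set up the FMP) and 2 Red Cross teams. At the
#' high resource level 8 MMTs leave in the first wave. Reinforcements up
#' to the level's totals leave at the level's second-wave time.
#'
#' @param resource_level one of the names of `levels`.
#' @param geometry an `mci_geometry`.
#' @param roster an `mci_roster`.
#' @param levels resource-level table.
#' @param policy operational policy (decides where late units report).
#' @return data.frame of units with departure times, destinations and
#'   arrival times.
#' @export
dispatch_plan <- function(resource_level, geometry, roster,
                          levels = default_resource_levels(),
                          policy = "stay_and_play") {
  if (!resource_level %in% names(levels)) {
    stop("unknown resource level: ", resource_level, call. = FALSE)
  }
  lv <- levels[[resource_level]]
  if (lv$ambulances > nrow(roster$ambulances) || lv$mmts > nrow(roster$mmts)) {
    stop("resource level exceeds the roster", call. = FALSE)
  }
  sp <- geometry$speed_kmh$ambulance
  rows <- list()
  add <- function(unit, type, depart, from_km, dest) {
    rows[[length(rows) + 1L]] <<- data.frame(
      unit = unit, type = type, depart = depart,
      travel = travel_time(from_km, sp), dest = dest,
      arrive = depart + travel_time(from_km, sp), stringsAsFactors = FALSE)
  }
  amb <- roster$ambulances             # already sorted by station distance
  bls <- amb[amb$type == "BLS", ]
  init_amb <- utils::head(bls, 5)      # initial wave: 5 BLS, nearest first
  for (i in seq_len(nrow(init_amb))) {
    add(init_amb$id[i], "ambulance", 0, init_amb$km[i],
        if (policy == "stay_and_play") "ccp_shuttle" else "ccp_transport")
  }
  mmts <- roster$mmts
  n_first <- min(lv$first_wave_mmts, lv$mmts)
  for (i in seq_len(n_first)) {
    dest <- if (mmts$commander[i]) "command"
      else if (i == 2) "ccp_triage"
      else if (i %in% c(3, 4) && policy == "stay_and_play") "fmp_setup"
      else if (policy == "stay_and_play") "fmp_treat" else "ccp_crew"
    add(mmts$id[i], "mmt", 0, mmts$base_km[i], dest)
  }
  for (i in seq_len(roster$n_rit)) add(sprintf("RIT%d", i), "rit", 0, 5, "nuca")
  # reinforcement wave
  rest_amb <- amb[!amb$id %in% init_amb$id, ]
  n_more <- lv$ambulances - nrow(init_amb)
  if (n_more > 0) {
    w <- utils::head(rest_amb, n_more)
    for (i in seq_len(nrow(w))) {
      add(w$id[i], "ambulance", lv$wave2_at, w$km[i],
          if (policy == "stay_and_play") "fmp_transport" else "ccp_transport")
    }
  }
  if (lv$mmts > n_first) {
    for (i in (n_first + 1):lv$mmts) {
      add(mmts$id[i], "mmt", lv$wave2_at, mmts$base_km[i],
          if (policy == "stay_and_play") "fmp_treat" else "ccp_crew")
    }
  }
  do.call(rbind, rows)
}

#' Default simulation configuration
#'
#' All operational parameters of the response choreography with their
#' default values: service durations, the SAR/resource/supervision/HCF
#' level tables, initial-wave composition and the simulation horizon.
#' Values printed in the intervention plan are fixed (FMP treatment starts
#' 8 minutes after the FMP teams arrive; the CCP-to-FMP leg is 1 minute;
#' ambulatory victims clear the plane within 3 minutes; SAR starts at
#' minute 5; the extra fuselage openings are cut at minute 21); the
#' remaining durations are documented stand-ins.
#'
#' @return a nested list of configuration blocks.
#' @export
default_config <- function() {
  list(
    census = list(),
    horizon = 720,
    sar = list(start = 5, holes_at = 21, ambulatory_by = 3,
               levels = default_sar_levels()),
    resources = list(levels = default_resource_levels()),
    hcf_capacity = list(levels = default_hcf_capacity_levels()),
    durations = list(triage = 0.5, loading = 2, ccp_loading = 1,
                     fmp_setup = 8, bus_boarding = 2, nuca_care = 30,
                     delivery = c(T1 = 10, T2 = 5, T3 = 3, T4 = 10)),
    nuca = list(bus_capacity = 20, n_buses = 2),
    attributes = list(),
    response = list(enabled = TRUE)
  )
}

#' Default factor levels (one design point)
#' @return named list: one level per interventional factor.
#' @export
default_factors <- function() {
  list(policy = "stay_and_play", triage = TRUE, sar = "medium",
       resources = "normal", supervision = "physician",
       distribution = "nearest_first", hcf_capacity = "medium")
}

#' Assemble a simulation scenario
#'
#' Bundles census, profile library, geometry, roster and configuration.
#'
#' @param config configuration list, see `default_config()`.
#' @param profiles profile library (default: `build_default_profiles()`).
#' @param geometry,roster geometry and roster (defaults).
#' @return an object of class `mci_scenario`.
#' @export
make_scenario <- function(config = default_config(),
                          profiles = build_default_profiles(),
                          geometry = default_geometry(),
                          roster = default_roster(geometry)) {
  census <- do.call(generate_census, config$census %||% list())
  structure(list(census = census, profiles = profiles, geometry = geometry,
                 roster = roster, config = config),
            class = "mci_scenario")
}

# ---- internal response state ---------------------------------------------

death_location_of <- function(loc) {
  switch(loc, site = "scene", ccp = "scene", fmp = "fmp", nuca = "nuca",
         ambulance = "transport", hcf = "awaiting_admission",
         if (is.null(loc)) "" else loc)
}

q_add <- function(state, qname, vid, code) {
  v <- state$victims[[vid]]
  v$queue <- qname
  v$code <- code
  v$entry_seq <- state$qseq <- state$qseq + 1L
  state$q[[qname]] <- c(state$q[[qname]], vid)
  invisible(NULL)
}

q_remove <- function(state, vid) {
  v <- state$victims[[vid]]
  if (!is.na(v$queue)) {
    state$q[[v$queue]] <- setdiff(state$q[[v$queue]], vid)
    v$queue <- NA
  }
  invisible(NULL)
}

q_pop_best <- function(state, qname) {
  ids <- state$q[[qname]]
  if (!length(ids)) return(NULL)
  codes <- vapply(ids, function(i) state$victims[[i]]$code, 0)
  seqs <- vapply(ids, function(i) state$victims[[i]]$entry_seq, 0L)
  vid <- ids[order(codes, seqs, ids)[1]]
  q_remove(state, vid)
  vid
}

q_peek_best <- function(state, qname) {
  ids <- state$q[[qname]]
  if (!length(ids)) return(NULL)
  codes <- vapply(ids, function(i) state$victims[[i]]$code, 0)
  seqs <- vapply(ids, function(i) state$victims[[i]]$entry_seq, 0L)
  ids[order(codes, seqs, ids)[1]]
}

# priority code for a victim entering a queue now; FIFO (entry order) when
# triage is off
entry_code <- function(state, v) {
  if (isTRUE(state$fac$triage)) {
    priority_code(v$base_category, v$rpm, floor(state$sim$clock))
  } else {
    state$qseq + 1L   # FIFO: monotone entry counter
  }
}

idle_mmt_at <- function(state, where, role = NULL) {
  for (m in state$mmts) {
    if (m$status == "idle" && m$location == where &&
        (is.null(role) || m$role %in% role)) return(m)
  }
  NULL
}

# ---- the orchestrator ----------------------------------------------------

#' Run one MCI response simulation
#'
#' Executes the full victim flow for one combination of the seven
#' interventional factors: search and rescue to the casualty collection
#' point, primary triage, disposition per operational policy, field
#' stabilization at the forward medical post (stay-and-play), ambulance
#' evacuation with transport supervision, hospital distribution and
#' admission, and the non-urgent branch through the NUCA. All randomness
#' (profile mapping, attribute draws, extraction order) flows from `seed`.
#'
#' @param scenario an `mci_scenario`.
#' @param factors factor levels, see `default_factors()`.
#' @param seed integer seed.
#' @param horizon simulation horizon, minutes (default from config).
#' @param audit run internal invariant checks after every event (slower;
#'   used by the test suite).
#' @return an object of class `mci_run`: total deaths, deaths by location,
#'   admissions per hospital, per-victim dispositions, the event log and
#'   run metadata.
#' @export
simulate_mci <- function(scenario, factors = default_factors(), seed = 1,
                         horizon = NULL, audit = FALSE) {
  stopifnot(inherits(scenario, "mci_scenario"))
  fac <- utils::modifyList(default_factors(), factors)
  cfg <- scenario$config
  horizon <- horizon %||% cfg$horizon
  sim <- new_simulation()
  state <- new.env(parent = emptyenv())
  state$sim <- sim
  state$fac <- fac
  state$cfg <- cfg
  state$scn <- scenario
  state$qseq <- 0L
  state$q <- list(ccp_triage = character(0), ccp_evac = character(0),
                  fmp_treat = character(0), fmp_evac = character(0),
                  nuca_bus = character(0))
  state$fmp_ready <- Inf
  state$fmp_operational <- FALSE
  state$fmp_setup_arrived <- 0L
  state$fmp_team_arrival <- NA_real_
  state$sar_remaining <- 0L
  state$deaths <- character(0)

  # victims
  mapping <- map_profiles(scenario$census, scenario$profiles, seed)
  mapping <- assign_attributes(mapping, cfg$attributes, seed)
  state$victims <- list()
  for (i in seq_len(nrow(mapping))) {
    v <- new.env(parent = emptyenv())
    v$id <- mapping$victim_id[i]
    v$profile <- scenario$profiles[[mapping$profile_id[i]]]
    v$base_category <- mapping$category[i]
    v$ambulatory <- mapping$ambulatory[i]
    v$dest <- mapping$destination_need[i]
    v$lane <- if (v$ambulatory) "nonurgent" else "urgent"
    v$location <- "site"
    v$queue <- NA
    v$code <- NA_real_
    v$entry_seq <- NA_integer_
    v$pending_cc <- NA
    v$disposition <- NA_character_
    v$stabilized <- FALSE
    v$triaged <- FALSE
    v$amb <- NA_character_
    v$hcf <- NA_character_
    state$victims[[v$id]] <- v
  }

  # hooks wiring clinical events into the response flow
  state$hooks <- list(
    on_death = function(vid) {
      v <- state$victims[[vid]]
      q_remove(state, vid)
      v$death_location <- death_location_of(v$location)
      state$deaths <- c(state$deaths, vid)
      if (!is.na(v$amb)) release_ambulance_of(state, vid)
    },
    on_stabilize = function(vid) invisible(NULL),
    on_condition_change = function(vid) reroute_deteriorated(state, vid)
  )

  init_clinical(sim, state)

  # SAR arrival stream
  non_amb <- mapping$victim_id[!mapping$ambulatory]
  amb_walk <- mapping$victim_id[mapping$ambulatory]
  if (length(amb_walk)) {
    times <- 1 + (seq_along(amb_walk) / length(amb_walk)) *
      (cfg$sar$ambulatory_by - 1)
    for (i in seq_along(amb_walk)) {
      schedule(sim, times[i], "sar_extraction",
               list(subject = amb_walk[i], detail = "ambulatory"))
    }
  }
  if (length(non_amb)) {
    rng <- local_rng(seed + 2)
    ord <- non_amb[rng$perm(length(non_amb))]
    times <- sar_schedule(length(ord), fac$sar, cfg$sar$levels,
                          cfg$sar$start, cfg$sar$holes_at)
    for (i in seq_along(ord)) {
      schedule(sim, times[i], "sar_extraction",
               list(subject = ord[i], detail = "extricated"))
    }
  }
  state$sar_remaining <- length(non_amb) + length(amb_walk)

  # responders (disabled for no-response oracle scenarios)
  if (!isFALSE(cfg$response$enabled)) {
    init_responders(state)
  } else {
    state$mmts <- list(); state$ambulances <- list()
    state$buses <- list(); state$triage_units <- list()
    state$hcfs <- list()
  }

  handler <- function(sim, ev) {
    handle_event(state, ev)
    pump(state)
    if (audit) audit_state(state)
  }
  run_until(sim, horizon, handler)
  finalize_run(state, seed, horizon)
}

init_responders <- function(state) {
  sim <- state$sim
  cfg <- state$cfg
  fac <- state$fac
  geom <- state$scn$geometry
  plan <- dispatch_plan(fac$resources, geom, state$scn$roster,
                        cfg$resources$levels, fac$policy)
  state$plan <- plan
  state$mmts <- list()
  state$ambulances <- list()
  state$triage_units <- list()
  # airport medical service physician + nurse: triage at the CCP from t = 2
  state$triage_units$AIRPORT <- local({
    u <- new.env(parent = emptyenv())
    u$id <- "AIRPORT"; u$available_from <- 2; u$busy <- FALSE
    u
  })
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    schedule(sim, row$arrive, "vehicle_arrival",
             list(subject = row$unit, detail = row$dest, unit_type = row$type))
    if (row$type == "mmt") {
      m <- new.env(parent = emptyenv())
      m$id <- row$unit
      m$role <- row$dest
      m$status <- "enroute"
      m$location <- "enroute"
      state$mmts[[m$id]] <- m
    } else if (row$type == "ambulance") {
      a <- new.env(parent = emptyenv())
      a$id <- row$unit
      a$type <- state$scn$roster$ambulances$type[
        match(row$unit, state$scn$roster$ambulances$id)]
      a$role <- sub("^(ccp|fmp)_", "", row$dest)
      a$base <- sub("_.*$", "", row$dest)   # ccp or fmp
      a$status <- "enroute"
      a$location <- "enroute"
      a$victim <- NA_character_
      a$crew <- NA_character_
      a$pending_load <- NA
      a$enroute_skill <- NA_character_
      state$ambulances[[a$id]] <- a
    }
  }
  # airport buses for the non-urgent branch, on site from minute 4
  state$buses <- list()
  for (i in seq_len(cfg$nuca$n_buses)) {
    b <- new.env(parent = emptyenv())
    b$id <- sprintf("BUS%d", i)
    b$status <- "enroute"
    b$location <- "enroute"
    b$victims <- character(0)
    state$buses[[b$id]] <- b
    schedule(sim, 4, "vehicle_arrival", list(subject = b$id, detail = "bus_ccp"))
  }
  # hospitals
  lv <- cfg$hcf_capacity$levels[[fac$hcf_capacity]]
  state$hcfs <- list()
  for (i in seq_len(nrow(state$scn$roster$hcfs))) {
    h <- new.env(parent = emptyenv())
    h$id <- state$scn$roster$hcfs$id[i]
    h$dist <- state$scn$roster$hcfs$distance_km[i]
    h$caps <- state$scn$roster$hcfs$capabilities[[i]]
    h$surge <- lv$surge
    h$rate <- lv$rate_per_hour
    h$assigned <- 0L
    h$immediate_used <- 0L
    h$admitted <- 0L
    h$next_slot <- 0
    state$hcfs[[h$id]] <- h
  }
  invisible(NULL)
}

handle_event <- function(state, ev) {
  sim <- state$sim
  p <- ev$payload
  switch(ev$kind,
    cc_time_transition = {
      v <- state$victims[[p$subject]]
      # cancelled handles never fire; a fired handle is cleared here
      if (identical(v$disposition, "admitted")) return(invisible(NULL))
      on_time_trigger(sim, state, p$subject, p$target)
    },
    sar_extraction = victim_arrives_ccp(state, p$subject),
    vehicle_arrival = unit_arrival(state, p),
    triage_complete = triage_done(state, p),
    treatment_complete = treatment_done(state, p),
    loading_complete = loading_done(state, p),
    vehicle_departure = invisible(NULL),   # informational marker
    admission = admit_victim(state, p),
    dispatch_wave = {
      if (identical(p$detail, "fmp_ready")) state$fmp_operational <- TRUE
    }
  )
  invisible(NULL)
}

victim_arrives_ccp <- function(state, vid) {
  v <- state$victims[[vid]]
  state$sar_remaining <- state$sar_remaining - 1L
  if (identical(v$disposition, "dead")) return(invisible(NULL))
  v$location <- "ccp"
  if (v$lane == "nonurgent") {
    q_add(state, "nuca_bus", vid, entry_code(state, v))
  } else if (isTRUE(state$fac$triage)) {
    q_add(state, "ccp_triage", vid, state$qseq + 1L)  # triage itself is FIFO
  } else {
    route_from_ccp(state, vid)
  }
  invisible(NULL)
}

route_from_ccp <- function(state, vid) {
  v <- state$victims[[vid]]
  if (v$base_category == "T4" && state$fac$policy != "stay_and_play") {
    # expectant victims are not evacuated by ambulance; under
    # scoop-and-run they receive supportive care where they lie
    sim_note(state$sim, "warning", vid, "expectant; held at CCP")
    return(invisible(NULL))
  }
  # stay-and-play: shuttle leg to the FMP; scoop-and-run: direct evacuation
  q_add(state, "ccp_evac", vid, entry_code(state, v))
  invisible(NULL)
}

triage_done <- function(state, p) {
  v <- state$victims[[p$subject]]
  u <- state$triage_units[[p$server]]
  u$busy <- FALSE
  if (identical(v$disposition, "dead")) return(invisible(NULL))
  v$triaged <- TRUE
  route_from_ccp(state, p$subject)
  invisible(NULL)
}

treatment_done <- function(state, p) {
  sim <- state$sim
  v <- state$victims[[p$subject]]
  if (identical(p$provider, "NUCA")) {
    # completion of non-urgent care: discharge home / to an NUCF
    if (!identical(v$disposition, "dead") && v$lane == "nonurgent" &&
        v$location == "nuca") {
      v$disposition <- "discharged"
      v$location <- "out"
      if (!is.na(v$pending_cc)) { cancel_event(sim, v$pending_cc); v$pending_cc <- NA }
      sim_note(sim, "discharge", v$id, "nuca")
    }
    return(invisible(NULL))
  }
  # field / en-route treatment delivery completed
  on_treatment_trigger(sim, state, p$subject, p$skill)
  if (!is.null(p$provider) && !is.na(p$provider) &&
      p$provider %in% names(state$mmts)) {
    m <- state$mmts[[p$provider]]
    if (m$status == "busy") m$status <- "idle"
  }
  if (!identical(v$disposition, "dead") && identical(p$then, "fmp_evac")) {
    # loading may only start after the delivery time has expired
    if (v$base_category %in% c("T1", "T2")) {
      q_add(state, "fmp_evac", v$id, entry_code(state, v))
    }
  }
  invisible(NULL)
}

release_ambulance_of <- function(state, vid) {
  v <- state$victims[[vid]]
  if (is.na(v$amb)) return(invisible(NULL))
  a <- state$ambulances[[v$amb]]
  # only a not-yet-departed assignment is released; a death in transit
  # completes the trip
  if (a$status %in% c("assigned", "loading")) {
    if (!is.na(a$crew)) {
      m <- state$mmts[[a$crew]]
      m$status <- "idle"
      a$crew <- NA_character_
    }
    if (!is.na(a$pending_load) && a$status == "loading") {
      cancel_event(state$sim, a$pending_load)
    }
    a$pending_load <- NA
    a$victim <- NA_character_
    a$status <- "idle"
    v$amb <- NA_character_
    if (!is.na(v$hcf)) {
      state$hcfs[[v$hcf]]$assigned <- state$hcfs[[v$hcf]]$assigned - 1L
      v$hcf <- NA_character_
    }
  }
  invisible(NULL)
}

loading_done <- function(state, p) {
  sim <- state$sim
  a <- state$ambulances[[p$subject]]
  a$pending_load <- NA
  vid <- a$victim
  if (is.na(vid)) return(invisible(NULL))   # released meanwhile
  v <- state$victims[[vid]]
  geom <- state$scn$geometry
  sp <- geom$speed_kmh$ambulance
  if (identical(p$leg, "shuttle")) {
    tt <- travel_time(node_distance(geom, "CCP", "FMP"), sp)
    schedule(sim, sim$clock, "vehicle_departure",
             list(subject = a$id, detail = paste0("shuttle:", vid)))
    v$location <- "ambulance"
    a$status <- "to_fmp"
    schedule(sim, sim$clock + tt, "vehicle_arrival",
             list(subject = a$id, detail = "shuttle_fmp", vid = vid))
  } else {
    from <- if (a$base == "fmp") "FMP" else "CCP"
    tt <- travel_time(node_distance(geom, from, v$hcf), sp)
    schedule(sim, sim$clock, "vehicle_departure",
             list(subject = a$id, detail = paste0("to:", v$hcf, ":", vid)))
    v$location <- "ambulance"
    a$status <- "to_hcf"
    # care en route, per the supervising skill, if the clinical state
    # still has a matching treatment transition
    skill <- a$enroute_skill
    if (!is.null(skill) && !is.na(skill) && !v$stabilized &&
        !identical(v$disposition, "dead") &&
        !identical(next_condition(v$cond, "treatment", skill, v$profile),
                   "none")) {
      del <- state$cfg$durations$delivery[[v$base_category]]
      sim_note(sim, "treatment_start", vid,
               paste0("ambulance:", skill, ":", a$id))
      schedule(sim, sim$clock + del, "treatment_complete",
               list(subject = vid, provider = a$crew %||% NA, skill = skill,
                    then = "enroute"))
    }
    schedule(sim, sim$clock + tt, "vehicle_arrival",
             list(subject = a$id, detail = "at_hcf", vid = vid, hcf = v$hcf))
  }
  invisible(NULL)
}

unit_arrival <- function(state, p) {
  sim <- state$sim
  id <- p$subject
  dest <- p$detail
  if (grepl("^MMT", id)) {
    m <- state$mmts[[id]]
    switch(dest,
      command = { m$status <- "command"; m$location <- "site" },
      ccp_triage = {
        m$status <- "triage"; m$location <- "ccp"
        u <- new.env(parent = emptyenv())
        u$id <- id; u$available_from <- sim$clock; u$busy <- FALSE
        state$triage_units[[id]] <- u
      },
      fmp_setup = {
        m$status <- "idle"; m$location <- "fmp"; m$role <- "treat"
        state$fmp_setup_arrived <- state$fmp_setup_arrived + 1L
        state$fmp_team_arrival <- max(state$fmp_team_arrival, sim$clock,
                                      na.rm = TRUE)
        if (state$fmp_setup_arrived >= 2L && !is.finite(state$fmp_ready)) {
          state$fmp_ready <- state$fmp_team_arrival +
            state$cfg$durations$fmp_setup
          schedule(sim, state$fmp_ready, "dispatch_wave",
                   list(subject = "FMP", detail = "fmp_ready"))
        }
      },
      fmp_treat = { m$status <- "idle"; m$location <- "fmp"; m$role <- "treat" },
      ccp_crew = { m$status <- "idle"; m$location <- "ccp"; m$role <- "crew" },
      crew_return = { m$status <- "idle"; m$location <- p$where },
      { m$status <- "idle"; m$location <- dest }
    )
  } else if (grepl("^A[0-9]", id)) {
    a <- state$ambulances[[id]]
    if (dest %in% c("ccp_shuttle", "ccp_transport")) {
      a$status <- "idle"; a$location <- "ccp"
    } else if (dest == "fmp_transport") {
      a$status <- "idle"; a$location <- "fmp"
    } else if (dest == "shuttle_fmp") {
      vid <- p$vid
      v <- state$victims[[vid]]
      a$victim <- NA_character_
      v$amb <- NA_character_
      if (!identical(v$disposition, "dead")) {
        v$location <- "fmp"
        q_add(state, "fmp_treat", vid, entry_code(state, v))
      }
      # return to the CCP for the next shuttle run
      tt <- travel_time(node_distance(state$scn$geometry, "CCP", "FMP"),
                        state$scn$geometry$speed_kmh$ambulance)
      a$status <- "returning"
      schedule(sim, sim$clock + tt, "vehicle_arrival",
               list(subject = id, detail = "ccp_shuttle"))
    } else if (dest == "at_hcf") {
      arrive_hcf(state, a, p)
    } else if (dest == "back_at_base") {
      a$status <- "idle"; a$location <- a$base
    }
  } else if (grepl("^BUS", id)) {
    b <- state$buses[[id]]
    if (dest == "bus_ccp") {
      b$status <- "idle"; b$location <- "ccp"
    } else if (dest == "bus_nuca") {
      for (vid in b$victims) {
        v <- state$victims[[vid]]
        if (identical(v$disposition, "dead")) next
        v$location <- "nuca"
        sim_note(sim, "treatment_start", vid, "nuca_care")
        schedule(sim, sim$clock + state$cfg$durations$nuca_care,
                 "treatment_complete",
                 list(subject = vid, provider = "NUCA", skill = "EMT"))
      }
      b$victims <- character(0)
      tt <- travel_time(node_distance(state$scn$geometry, "CCP", "NUCA"),
                        state$scn$geometry$speed_kmh$bus)
      b$status <- "returning"
      schedule(sim, sim$clock + tt, "vehicle_arrival",
               list(subject = id, detail = "bus_ccp"))
    }
  } else if (grepl("^RIT", id)) {
    invisible(NULL)   # logistics support at the NUCA; no queue of its own
  } else if (id == "TRANSFER") {
    vid <- p$vid
    v <- state$victims[[vid]]
    if (!identical(v$disposition, "dead")) {
      v$location <- "fmp"
      q_add(state, "fmp_treat", vid, entry_code(state, v))
    }
  }
  invisible(NULL)
}

arrive_hcf <- function(state, a, p) {
  sim <- state$sim
  vid <- p$vid
  v <- state$victims[[vid]]
  h <- state$hcfs[[p$hcf]]
  # the ambulance is released on arrival; the victim waits at the hospital
  a$victim <- NA_character_
  v$amb <- NA_character_
  if (!is.na(a$crew)) {
    m <- state$mmts[[a$crew]]
    # the supervising team rides back with the ambulance
    crew_id <- a$crew
    a$crew <- NA_character_
    tt_back <- travel_time(node_distance(state$scn$geometry,
                                         if (a$base == "fmp") "FMP" else "CCP",
                                         h$id),
                           state$scn$geometry$speed_kmh$ambulance)
    schedule(sim, sim$clock + tt_back, "vehicle_arrival",
             list(subject = crew_id, detail = "crew_return",
                  where = a$base))
    m$status <- "transport"
  }
  tt_back <- travel_time(node_distance(state$scn$geometry,
                                       if (a$base == "fmp") "FMP" else "CCP",
                                       h$id),
                         state$scn$geometry$speed_kmh$ambulance)
  a$status <- "returning"
  schedule(sim, sim$clock + tt_back, "vehicle_arrival",
           list(subject = a$id, detail = "back_at_base"))
  if (identical(v$disposition, "dead")) {
    sim_note(sim, "warning", vid, "arrived deceased")
    h$assigned <- h$assigned - 1L
    return(invisible(NULL))
  }
  v$location <- "hcf"
  if (h$immediate_used < h$surge) {
    h$immediate_used <- h$immediate_used + 1L
    schedule(sim, sim$clock, "admission", list(subject = vid, hcf = h$id))
  } else {
    t_adm <- max(sim$clock, h$next_slot)
    h$next_slot <- t_adm + 60 / h$rate
    schedule(sim, t_adm, "admission", list(subject = vid, hcf = h$id))
  }
  invisible(NULL)
}

admit_victim <- function(state, p) {
  sim <- state$sim
  v <- state$victims[[p$subject]]
  if (identical(v$disposition, "dead")) {
    h <- state$hcfs[[p$hcf]]
    h$assigned <- h$assigned - 1L
    return(invisible(NULL))
  }
  v$disposition <- "admitted"
  v$location <- "out"
  h <- state$hcfs[[p$hcf]]
  h$admitted <- h$admitted + 1L
  if (!is.na(v$pending_cc)) { cancel_event(sim, v$pending_cc); v$pending_cc <- NA }
  invisible(NULL)
}

reroute_deteriorated <- function(state, vid) {
  v <- state$victims[[vid]]
  if (v$lane != "nonurgent") return(invisible(NULL))
  if (!v$category %in% c("T1", "T2")) return(invisible(NULL))
  # a walking-wounded victim whose state worsened to urgent is re-examined
  # and transferred to the urgent pathway
  v$lane <- "urgent"
  v$base_category <- v$category
  sim_note(state$sim, "warning", vid, "deteriorated to urgent; transferred")
  q_remove(state, vid)
  if (v$location == "nuca") {
    if (state$fac$policy == "stay_and_play") {
      tt <- travel_time(node_distance(state$scn$geometry, "NUCA", "FMP"),
                        state$scn$geometry$speed_kmh$ambulance)
      schedule(state$sim, state$sim$clock + tt, "vehicle_arrival",
               list(subject = "TRANSFER", detail = "transfer_fmp", vid = vid))
    } else {
      v$location <- "ccp"
      q_add(state, "ccp_evac", vid, entry_code(state, v))
    }
  } else if (v$location == "ccp") {
    route_from_ccp(state, vid)
  }
  invisible(NULL)
}

# ---- work-conserving matching --------------------------------------------

pump <- function(state) {
  repeat {
    did <- FALSE
    did <- pump_triage(state) || did
    did <- pump_fmp_treatment(state) || did
    did <- pump_shuttles(state) || did
    did <- pump_evacuation(state) || did
    did <- pump_buses(state) || did
    if (!did) break
  }
  invisible(NULL)
}

pump_triage <- function(state) {
  if (!isTRUE(state$fac$triage)) return(FALSE)
  sim <- state$sim
  did <- FALSE
  # once primary triage is finished, the CCP triage team (an MMT) moves on
  # to the FMP (stay-and-play) or the transport-crew pool (scoop-and-run)
  if (state$sar_remaining == 0 && !length(state$q$ccp_triage)) {
    for (uid in names(state$triage_units)) {
      u <- state$triage_units[[uid]]
      if (!u$busy && uid %in% names(state$mmts)) {
        state$triage_units[[uid]] <- NULL
        dest <- if (state$fac$policy == "stay_and_play") "fmp_treat"
                else "ccp_crew"
        schedule(sim, sim$clock + 1, "vehicle_arrival",
                 list(subject = uid, detail = dest))
        did <- TRUE
      }
    }
  }
  for (u in state$triage_units) {
    if (u$busy || sim$clock < u$available_from) next
    ids <- state$q$ccp_triage
    if (!length(ids)) break
    vid <- q_pop_best(state, "ccp_triage")
    u$busy <- TRUE
    schedule(sim, sim$clock + state$cfg$durations$triage, "triage_complete",
             list(subject = vid, server = u$id))
    did <- TRUE
  }
  did
}

pump_fmp_treatment <- function(state) {
  if (state$fac$policy != "stay_and_play") return(FALSE)
  sim <- state$sim
  if (!isTRUE(state$fmp_operational)) return(FALSE)
  did <- FALSE
  repeat {
    if (!length(state$q$fmp_treat)) break
    m <- idle_mmt_at(state, "fmp", role = "treat")
    if (is.null(m)) break
    vid <- q_pop_best(state, "fmp_treat")
    v <- state$victims[[vid]]
    m$status <- "busy"
    del <- state$cfg$durations$delivery[[v$base_category]]
    sim_note(sim, "treatment_start", vid, paste0("fmp:MMT:", m$id))
    schedule(sim, sim$clock + del, "treatment_complete",
             list(subject = vid, provider = m$id, skill = "MMT",
                  then = "fmp_evac"))
    did <- TRUE
  }
  did
}

pump_shuttles <- function(state) {
  if (state$fac$policy != "stay_and_play") return(FALSE)
  sim <- state$sim
  did <- FALSE
  shuttles <- Filter(function(a) a$role == "shuttle", state$ambulances)
  urgent_left <- any(vapply(state$victims, function(v) {
    v$lane == "urgent" && is.na(v$disposition) &&
      v$location %in% c("site", "ccp")
  }, logical(1)))
  for (a in shuttles) {
    if (a$status != "idle" || a$location != "ccp") next
    if (!length(state$q$ccp_evac)) {
      # no more urgent victims will reach the CCP: re-role to transport
      if (state$sar_remaining == 0 && !urgent_left) {
        a$role <- "transport"
        a$base <- "fmp"
        a$status <- "returning"
        tt <- travel_time(node_distance(state$scn$geometry, "CCP", "FMP"),
                          state$scn$geometry$speed_kmh$ambulance)
        schedule(sim, sim$clock + tt, "vehicle_arrival",
                 list(subject = a$id, detail = "fmp_transport"))
        did <- TRUE
      }
      next
    }
    vid <- q_pop_best(state, "ccp_evac")
    v <- state$victims[[vid]]
    a$victim <- vid
    v$amb <- a$id
    a$status <- "loading"
    a$pending_load <- schedule(sim, sim$clock + state$cfg$durations$ccp_loading,
                               "loading_complete",
                               list(subject = a$id, leg = "shuttle"))
    did <- TRUE
  }
  did
}

pump_evacuation <- function(state) {
  sim <- state$sim
  point <- if (state$fac$policy == "stay_and_play") "fmp" else "ccp"
  qname <- if (point == "fmp") "fmp_evac" else "ccp_evac"
  if (state$fac$policy != "stay_and_play") qname <- "ccp_evac"
  did <- FALSE
  repeat {
    vid <- q_peek_best(state, qname)
    if (is.null(vid)) break
    a <- NULL
    for (cand in state$ambulances) {
      if (cand$role == "transport" && cand$status == "idle" &&
          cand$location == point) { a <- cand; break }
    }
    if (is.null(a)) break
    v <- state$victims[[vid]]
    req <- supervision_requirement(state$fac$supervision, v$base_category)
    crew <- NA_character_
    skill <- "EMT"
    if (req == "nurse") {
      if (a$type == "PIT") {
        skill <- "PIT"
      } else {
        m <- idle_mmt_at(state, point)
        if (is.null(m)) break   # departure waits for a qualified crew
        crew <- m$id; skill <- "MMT"
      }
    } else if (req == "mmt") {
      m <- idle_mmt_at(state, point)
      if (is.null(m)) break     # departure waits for a qualified crew
      crew <- m$id; skill <- "MMT"
    } else {
      if (a$type == "PIT") skill <- "PIT"
    }
    q_remove(state, vid)
    hid <- distribute_to_hcf(v, state$fac$distribution, state$hcfs)
    state$hcfs[[hid]]$assigned <- state$hcfs[[hid]]$assigned + 1L
    v$hcf <- hid
    v$amb <- a$id
    a$victim <- vid
    a$enroute_skill <- skill
    if (!is.na(crew)) {
      a$crew <- crew
      state$mmts[[crew]]$status <- "transport"
    }
    sim_note(sim, "assign", a$id, paste0(vid, ">", hid))
    a$status <- "loading"
    a$pending_load <- schedule(sim, sim$clock + state$cfg$durations$loading,
                               "loading_complete",
                               list(subject = a$id, leg = "transport"))
    did <- TRUE
  }
  did
}

pump_buses <- function(state) {
  sim <- state$sim
  did <- FALSE
  for (b in state$buses) {
    if (b$status != "idle" || b$location != "ccp") next
    if (!length(state$q$nuca_bus)) next
    n <- min(state$cfg$nuca$bus_capacity, length(state$q$nuca_bus))
    take <- character(0)
    for (i in seq_len(n)) take <- c(take, q_pop_best(state, "nuca_bus"))
    b$victims <- take
    b$status <- "boarding"
    tt <- travel_time(node_distance(state$scn$geometry, "CCP", "NUCA"),
                      state$scn$geometry$speed_kmh$bus)
    schedule(sim, sim$clock + state$cfg$durations$bus_boarding + tt,
             "vehicle_arrival", list(subject = b$id, detail = "bus_nuca"))
    did <- TRUE
  }
  did
}

# ---- invariant audit (test instrumentation) ------------------------------

audit_state <- function(state) {
  # work conservation at the FMP
  if (state$fac$policy == "stay_and_play" && isTRUE(state$fmp_operational) &&
      length(state$q$fmp_treat) > 0 &&
      !is.null(idle_mmt_at(state, "fmp", role = "treat"))) {
    stop("work-conservation violation: idle MMT with waiting FMP queue",
         call. = FALSE)
  }
  # a victim sits in at most one queue
  all_q <- unlist(state$q)
  if (anyDuplicated(all_q)) {
    stop("victim present in more than one queue", call. = FALSE)
  }
  invisible(NULL)
}

# ---- results -------------------------------------------------------------

finalize_run <- function(state, seed, horizon) {
  victims <- state$victims
  disp <- vapply(victims, function(v)
    if (is.na(v$disposition)) "in_system" else v$disposition, "")
  deaths_by <- table(vapply(victims[state$deaths], `[[`, "", "death_location"))
  adm <- vapply(state$hcfs, `[[`, 0L, "admitted")
  vict_df <- data.frame(
    victim_id = names(victims),
    category = vapply(victims, `[[`, "", "base_category"),
    profile_id = vapply(victims, function(v) v$profile$victim_id, ""),
    disposition = disp,
    location = vapply(victims, `[[`, "", "location"),
    rpm = vapply(victims, `[[`, 0L, "rpm"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    total_deaths = length(state$deaths),
    deaths_by_location = deaths_by,
    admissions = data.frame(hcf = names(adm), admitted = as.integer(adm),
                            stringsAsFactors = FALSE, row.names = NULL),
    dispositions = vict_df,
    event_log = event_log(state$sim),
    fmp_ready = state$fmp_ready,
    fmp_team_arrival = state$fmp_team_arrival,
    factors = state$fac, seed = seed, horizon = horizon,
    injured = census_injured(state$scn$census)
  ), class = "mci_run")
}

#' @export
print.mci_run <- function(x, ...) {
  cat("MCI simulation run (seed ", x$seed, ")\n", sep = "")
  cat("  factors: ", paste(names(x$factors),
                           vapply(x$factors, as.character, ""),
                           sep = "=", collapse = ", "), "\n", sep = "")
  cat("  injured victims: ", x$injured, "\n", sep = "")
  cat("  total deaths: ", x$total_deaths, "\n", sep = "")
  if (length(x$deaths_by_location)) {
    cat("  deaths by location: ",
        paste(names(x$deaths_by_location), x$deaths_by_location,
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  tab <- table(x$dispositions$disposition)
  cat("  dispositions: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
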