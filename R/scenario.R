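#' Generate the victim census
#'
#' Counts of plane occupants by outcome category. The default is the
#' airport crash case study: 205 injured (26 T1, 62 T2, 113 T3, 4 T4),
#' 5 immediate fatalities and 40 uninjured, 250 occupants in total.
#' Immediate fatalities never enter the response flow.
#'
#' @param T1,T2,T3,T4 injured victims per triage category.
#' @param immediate_fatalities occupants dead at impact.
#' @param uninjured unhurt occupants (walk out, need no care).
#' @param occupants optional total for a consistency check.
#' @return an object of class `census`.
#' @export
generate_census <- function(T1 = 26, T2 = 62, T3 = 113, T4 = 4,
                            immediate_fatalities = 5, uninjured = 40,
                            occupants = NULL) {
  counts <- c(T1 = T1, T2 = T2, T3 = T3, T4 = T4,
              immediate_fatalities = immediate_fatalities,
              uninjured = uninjured)
  assert_count(counts, "census counts")
  if (!is.null(occupants) && sum(counts) != occupants) {
    stop("census totals inconsistent: counts sum to ", sum(counts),
         " but occupants = ", occupants, call. = FALSE)
  }
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "census")
}

#' Total injured victims in a census
#' @param census a `census`.
#' @return integer.
#' @export
census_injured <- function(census) {
  census$T1 + census$T2 + census$T3 + census$T4
}

#' Default incident geometry
#'
#' Nodes of the airport scenario with pairwise distances: the crash site,
#' the casualty collection point (CCP, 25 m from the plane), the forward
#' medical post (FMP, the airport fire department, 1 km from the CCP so the
#' shuttle leg is 1 minute at 60 km/h), the non-urgent care area (NUCA),
#' 32 EMS stations on a 2--33 km ring, six hospitals (8--40 km, the nearest
#' also a trauma centre, one with a burn unit) and a non-urgent care
#' facility. Distances between two off-site nodes are taken through the
#' site (sum of ring distances), which keeps the matrix symmetric and
#' non-negative. Ambulances average 60 km/h, buses 40 km/h.
#'
#' @param n_stations number of EMS stations.
#' @param hcf_km distances of the hospitals from the site, km.
#' @param speed_kmh named list of vehicle speeds.
#' @return an object of class `mci_geometry`.
#' @export
default_geometry <- function(n_stations = 32,
                             hcf_km = c(8, 12, 18, 25, 32, 40),
                             speed_kmh = list(ambulance = 60, bus = 40)) {
  nodes <- data.frame(
    name = c("site", "CCP", "FMP", "NUCA",
             paste0("S", seq_len(n_stations)),
             paste0("H", seq_along(hcf_km)), "NUCF"),
    kind = c("site", "CCP", "FMP", "NUCA",
             rep("station", n_stations),
             rep("HCF", length(hcf_km)), "NUCF"),
    ring_km = c(0, 0.025, 1.025, 0.525,
                seq(2, length.out = n_stations, by = 1),
                hcf_km, 5),
    stringsAsFactors = FALSE
  )
  n <- nrow(nodes)
  d <- outer(nodes$ring_km, nodes$ring_km, `+`)
  # the on-site cluster is tightly packed: use ring offsets directly
  onsite <- nodes$kind %in% c("site", "CCP", "FMP", "NUCA")
  d[onsite, onsite] <- abs(outer(nodes$ring_km[onsite],
                                 nodes$ring_km[onsite], `-`))
  diag(d) <- 0
  dimnames(d) <- list(nodes$name, nodes$name)
  structure(list(nodes = nodes, dist_km = d, speed_kmh = speed_kmh),
            class = "mci_geometry")
}

#' Distance between two geometry nodes, km
#' @param geometry an `mci_geometry`.
#' @param from,to node names.
#' @export
node_distance <- function(geometry, from, to) {
  geometry$dist_km[from, to]
}

#' Default resource roster
#'
#' 38 ambulances (30 BLS, 8 PIT) homed cyclically on the EMS stations, 10
#' mobile medical teams based 3--25 km out (the first is the incident
#' medical commander and never treats or transports), 2 Red Cross rapid
#' intervention teams, and the hospitals from the geometry with per-level
#' surge capacities filled in at simulation time.
#'
#' @param geometry an `mci_geometry`.
#' @param n_ambulances,n_pit total ambulances and how many are PIT-type.
#' @param mmt_base_km home-base distances of the MMTs, km.
#' @param n_rit Red Cross rapid intervention teams.
#' @return an object of class `mci_roster`.
#' @export
default_roster <- function(geometry = default_geometry(),
                           n_ambulances = 38, n_pit = 8,
                           mmt_base_km = c(3, 5, 7, 8, 10, 12, 14, 15, 20, 25),
                           n_rit = 2) {
  stations <- geometry$nodes$name[geometry$nodes$kind == "station"]
  amb <- data.frame(
    id = sprintf("A%02d", seq_len(n_ambulances)),
    type = rep(c(rep("BLS", ceiling((n_ambulances - n_pit) / n_pit)), "PIT"),
               length.out = n_ambulances),
    station = rep(stations, length.out = n_ambulances),
    stringsAsFactors = FALSE
  )
  amb$km <- geometry$nodes$ring_km[match(amb$station, geometry$nodes$name)]
  amb <- amb[order(amb$km, amb$id), ]
  rownames(amb) <- NULL
  mmt <- data.frame(id = sprintf("MMT%02d", seq_along(mmt_base_km)),
                    base_km = mmt_base_km,
                    commander = c(TRUE, rep(FALSE, length(mmt_base_km) - 1)),
                    stringsAsFactors = FALSE)
  hcf_idx <- geometry$nodes$kind == "HCF"
  hcf <- data.frame(id = geometry$nodes$name[hcf_idx],
                    distance_km = geometry$nodes$ring_km[hcf_idx],
                    stringsAsFactors = FALSE)
  hcf$capabilities <- lapply(seq_len(nrow(hcf)), function(i) {
    caps <- "general"
    if (i == 1) caps <- c(caps, "trauma")
    if (i == 4) caps <- c(caps, "burn")
    caps
  })
  structure(list(ambulances = amb, mmts = mmt, n_rit = as.integer(n_rit),
                 hcfs = hcf),
            class = "mci_roster")
}

#' Map victim profiles onto a census
#'
#' Draws, for each injured victim, a profile from the category's pool in
#' the library (seeded, with replacement), preserving the census counts
#' exactly. Victims are numbered V001.. in category order T1, T2, T3, T4.
#'
#' @param census a `census`.
#' @param library named list of `victim_profile`s (the pools are formed by
#'   each profile's `triage_mix_category`).
#' @param seed integer seed for the draw.
#' @return data.frame with victim id, category and assigned profile id.
#' @export
map_profiles <- function(census, library, seed = 1) {
  cats <- rep(TRIAGE_CATEGORIES,
              times = c(census$T1, census$T2, census$T3, census$T4))
  pool <- split(names(library),
                vapply(library, `[[`, "", "triage_mix_category"))
  missing <- setdiff(unique(cats), names(pool))
  if (length(missing)) {
    stop("profile library has no profiles for category: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(victim_id = sprintf("V%03d", seq_along(cats)),
                    category = cats,
                    profile_id = rep(NA_character_, length(cats)),
                    stringsAsFactors = FALSE)
  rng <- local_rng(seed)
  for (cat in unique(cats)) {
    idx <- which(cats == cat)
    p <- pool[[cat]]
    out$profile_id[idx] <- if (length(p) == 1) rep(p, length(idx)) else
      p[rng$int(length(p), length(idx))]
  }
  out
}

#' Assign per-victim attributes
#'
#' Walking ability follows the category rule (T3 are the walking wounded;
#' T1/T2/T4 are non-ambulatory), and the destination need is drawn from
#' configured per-category fractions (default: everyone needs a general
#' hospital).
#'
#' @param victims data.frame from `map_profiles()`.
#' @param config list with optional per-category `trauma_fraction` and
#'   `burn_fraction` (named numeric, e.g. `c(T1 = 0.5)`).
#' @param seed integer seed for the draws.
#' @return the data.frame with `ambulatory` and `destination_need` added.
#' @export
assign_attributes <- function(victims, config = list(), seed = 1) {
  tf <- config$trauma_fraction %||% c(T1 = 0, T2 = 0, T3 = 0, T4 = 0)
  bf <- config$burn_fraction %||% c(T1 = 0, T2 = 0, T3 = 0, T4 = 0)
  frac <- function(f, cat) if (cat %in% names(f)) unname(f[cat]) else 0
  if (any(c(tf, bf) < 0 | c(tf, bf) > 1)) {
    stop("destination fractions must lie in [0, 1]", call. = FALSE)
  }
  victims$ambulatory <- victims$category == "T3"
  victims$destination_need <- rep("general", nrow(victims))
  rng <- local_rng(seed + 1)
  for (cat in TRIAGE_CATEGORIES) {
    idx <- which(victims$category == cat)
    if (!length(idx)) next
    u <- rng$unif(length(idx))
    t_cut <- frac(tf, cat)
    b_cut <- t_cut + frac(bf, cat)
    if (b_cut > 1) stop("trauma + burn fractions exceed 1 for ", cat,
                        call. = FALSE)
    victims$destination_need[idx[u < t_cut]] <- "trauma_centre"
    victims$destination_need[idx[u >= t_cut & u < b_cut]] <- "burn_centre"
  }
  victims
}

#' Duplicate a victim entity into clinical and logistics facets
#'
#' The simulator runs the health-state monitoring and the medical response
#' over the same victim. Both facets are light handles over one shared
#' mutable state, so a trigger raised through either facet is visible to
#' the other exactly once; there is no copying and no reconciliation.
#'
#' @param victim an environment holding the victim's runtime state.
#' @return list with `clinical` and `logistics` facets (class
#'   `victim_facet`), both pointing at `victim`.
#' @export
duplicate_entity <- function(victim) {
  stopifnot(is.environment(victim))
  facet <- function(role) structure(list(shared = victim, facet = role),
                                    class = "victim_facet")
  list(clinical = facet("clinical"), logistics = facet("logistics"))
}

#' Hash of a victim's visible state
#'
#' Stable digest of the fields both facets share; used to assert that
#' operations on one facet leave the other's view unchanged unless a
#' trigger fired.
#'
#' @param facet a `victim_facet` or victim environment.
#' @return character scalar.
#' @export
facet_state_hash <- function(facet) {
  v <- if (inherits(facet, "victim_facet")) facet$shared else facet
  paste(v$id, v$cond, v$rpm, v$category, v$location, v$disposition,
        sep = "|")
}

# Small self-contained RNG wrapper: keeps all scenario randomness on an
# explicit seed without touching the global RNG stream.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
        rm(".Random.seed", envir = globalenv())
    })
    f()
  }
  list(
    int = function(n, size) with_state(function() sample.int(n, size, replace = TRUE)),
    perm = function(n) with_state(function() sample.int(n, n)),
    unif = function(n) with_state(function() stats::runif(n))
  )
}
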