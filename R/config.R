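#' Load a scenario configuration file
#'
#' Reads a YAML configuration, merges it over the package defaults and
#' validates it. Unknown top-level keys are rejected.
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path) %||% list()
  known <- names(default_config())
  extra <- setdiff(names(user), c(known, "factors", "seed"))
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(default_config(), user[intersect(names(user), known)])
  if (!is.null(user$factors)) cfg$factors <- user$factors
  if (!is.null(user$seed)) cfg$seed <- user$seed
  rep <- validate_config(cfg)
  if (length(rep$violations)) {
    stop("invalid configuration:\n  ",
         paste(rep$violations, collapse = "\n  "), call. = FALSE)
  }
  cfg
}

#' Validate a configuration
#'
#' Returns the complete list of violations (not just the first), so a
#' configuration can be repaired in one pass.
#'
#' @param cfg configuration list, shape of `default_config()`.
#' @return list with `ok` and a character vector `violations`.
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  cen <- tryCatch(do.call(generate_census, cfg$census %||% list()),
                  error = function(e) { add(conditionMessage(e)); NULL })
  if (!is.null(cfg$horizon)) {
    if (cfg$horizon <= 0) add("horizon must be positive")
    if (cfg$horizon >= 1000) {
      add(paste0("horizon ", cfg$horizon, " min overflows the 3-digit ",
                 "arrival field of the priority code (must be < 1000)"))
    }
  }
  dur <- cfg$durations
  for (f in c("triage", "loading", "ccp_loading", "fmp_setup",
              "bus_boarding", "nuca_care")) {
    if (is.null(dur[[f]]) || dur[[f]] < 0) {
      add(paste0("duration '", f, "' missing or negative"))
    }
  }
  if (any(dur$delivery <= 0)) add("treatment delivery times must be positive")
  for (lname in names(cfg$sar$levels)) {
    l <- cfg$sar$levels[[lname]]
    if (l$rate_before <= 0 || l$rate_after <= 0) {
      add(paste0("SAR level '", lname, "' has a non-positive rate"))
    }
  }
  for (lname in names(cfg$hcf_capacity$levels)) {
    l <- cfg$hcf_capacity$levels[[lname]]
    if (l$surge < 0 || l$rate_per_hour <= 0) {
      add(paste0("HCF capacity level '", lname, "' invalid"))
    }
  }
  if (!is.null(cfg$geometry_file)) {
    add("geometry must be supplied as a geometry table, not in the config")
  }
  list(ok = length(v) == 0, violations = v)
}

#' Write the default case-study fixture bundle
#'
#' One directory with the census, the synthetic profile library, the
#' geometry and roster tables and a configuration file -- everything
#' needed to re-run the default scenario.
#'
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scn <- make_scenario()
  yaml::write_yaml(unclass(scn$census), file.path(dir, "census.yaml"))
  write_profile_library(scn$profiles, file.path(dir, "profiles.yaml"))
  utils::write.table(scn$geometry$nodes, file.path(dir, "geometry.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  amb <- scn$roster$ambulances
  utils::write.table(amb, file.path(dir, "roster_ambulances.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(scn$roster$mmts, file.path(dir, "roster_mmts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(default_config(), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write a run-results table
#'
#' @param results data.frame (e.g. from `run_replications()`).
#' @param path output TSV.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a run-results table written by `write_results()`
#' @param path TSV file.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
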