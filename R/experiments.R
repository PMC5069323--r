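#' The seven-factor interventional space
#'
#' Operational policy (2), triage (2), SAR rate (3), pre-hospital resource
#' level (4), transport supervision level (4), hospital distribution rule
#' (2) and hospital treatment capacity (3): 1152 combinations in full.
#'
#' @return a named list of factor levels.
#' @export
factor_space <- function() {
  list(policy = c("stay_and_play", "scoop_and_run"),
       triage = c(TRUE, FALSE),
       sar = c("low", "medium", "high"),
       resources = c("low", "medium", "normal", "high"),
       supervision = c("emt", "nurse", "physician", "physician_all"),
       distribution = c("nearest_first", "round_robin"),
       hcf_capacity = c("low", "medium", "high"))
}

#' Build the full-factorial design
#'
#' Exhaustive Cartesian product of the factor levels, in a deterministic
#' order (first factor varying fastest), with a design id per row.
#'
#' @param space named list of factor levels, see `factor_space()`.
#' @return data.frame of design points with a `design_id` column.
#' @export
build_factorial <- function(space = factor_space()) {
  if (any(lengths(space) == 0)) stop("empty factor", call. = FALSE)
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$design_id <- seq_len(nrow(grid))
  grid[, c("design_id", names(space))]
}

#' Deterministic per-run seed
#'
#' Stable integer hash of (base seed, design id, replication index), kept
#' below 2^31 so it is a valid R seed; changing one run's inputs never
#' perturbs another run's seed.
#'
#' @param base_seed integer.
#' @param design_id,replication integers.
#' @return integer seed.
#' @export
per_run_seed <- function(base_seed, design_id, replication) {
  m <- 2147483647
  x <- (as.numeric(base_seed) %% m)
  x <- (x * 69621 + as.numeric(design_id) * 7919 +
          as.numeric(replication) * 104729 + 12345) %% m
  as.integer(x)
}

#' Run replications over a set of design points
#'
#' Executes `simulator(factors, seed)` for every (design, replication)
#' pair with deterministically derived seeds. A failing run is recorded
#' (NA deaths plus the error message) without aborting the sweep.
#'
#' @param designs data.frame from `build_factorial()` (or a subset).
#' @param n_reps replications per design (>= 1).
#' @param base_seed integer base seed.
#' @param simulator function of (factors, seed) returning either a number
#'   of deaths or an `mci_run`; defaults to running `simulate_mci()` on
#'   `scenario`.
#' @param scenario an `mci_scenario` for the default simulator.
#' @return data.frame with one row per run: design id, factor levels,
#'   replication, seed, total_deaths, error.
#' @export
run_replications <- function(designs, n_reps, base_seed = 1,
                             simulator = NULL, scenario = NULL) {
  stopifnot(n_reps >= 1)
  if (is.null(simulator)) {
    if (is.null(scenario)) scenario <- make_scenario()
    simulator <- function(factors, seed) {
      simulate_mci(scenario, factors, seed)$total_deaths
    }
  }
  fac_cols <- setdiff(names(designs), "design_id")
  rows <- vector("list", nrow(designs) * n_reps)
  k <- 0L
  for (i in seq_len(nrow(designs))) {
    factors <- as.list(designs[i, fac_cols, drop = FALSE])
    for (rep in seq_len(n_reps)) {
      seed <- per_run_seed(base_seed, designs$design_id[i], rep)
      res <- tryCatch(simulator(factors, seed), error = identity)
      err <- NA_character_
      deaths <- NA_integer_
      if (inherits(res, "error")) {
        err <- conditionMessage(res)
      } else {
        deaths <- if (inherits(res, "mci_run")) res$total_deaths else res
      }
      k <- k + 1L
      rows[[k]] <- data.frame(design_id = designs$design_id[i],
                              designs[i, fac_cols, drop = FALSE],
                              replication = rep, seed = seed,
                              total_deaths = deaths, error = err,
                              stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Descriptive statistics of deaths per factor level
#'
#' Mean, median, standard deviation, minimum, maximum and run count of the
#' outcome over all runs at each level of one factor -- the layout of a
#' per-variable descriptive table.
#'
#' @param results data.frame from `run_replications()`.
#' @param factor factor column name.
#' @return data.frame with one row per level.
#' @export
summarize_by_factor <- function(results, factor) {
  if (!factor %in% names(results)) {
    stop("unknown factor: ", factor, call. = FALSE)
  }
  if (!nrow(results)) stop("empty results", call. = FALSE)
  x <- results$total_deaths
  g <- as.character(results[[factor]])
  levels <- unique(g)
  out <- do.call(rbind, lapply(levels, function(l) {
    v <- x[g == l & !is.na(x)]
    data.frame(factor = factor, level = l, n = length(v),
               mean = mean(v), median = stats::median(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-way analysis of variance for a main effect
#'
#' Standard one-way ANOVA of total deaths on one factor, with the share of
#' variance explained (eta squared = SS_factor / SS_total). Degenerate
#' inputs (zero total variance) are flagged rather than producing NaN
#' surprises downstream.
#'
#' @param results data.frame from `run_replications()`.
#' @param factor factor column name.
#' @return list with `F`, `p`, `eta_squared`, `df`, `ss` and `degenerate`.
#' @export
anova_oneway <- function(results, factor) {
  if (!factor %in% names(results)) stop("unknown factor: ", factor,
                                        call. = FALSE)
  d <- results[!is.na(results$total_deaths), ]
  d$g <- base::factor(as.character(d[[factor]]))
  if (nlevels(d$g) < 2 || any(table(d$g) < 2)) {
    stop("need >= 2 levels with >= 2 observations", call. = FALSE)
  }
  ss_total <- sum((d$total_deaths - mean(d$total_deaths))^2)
  if (ss_total == 0) {
    return(list(F = NA_real_, p = NA_real_, eta_squared = 0,
                df = c(nlevels(d$g) - 1L, nrow(d) - nlevels(d$g)),
                ss = c(factor = 0, residual = 0), degenerate = TRUE))
  }
  fit <- stats::aov(total_deaths ~ g, data = d)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       eta_squared = tab[["Sum Sq"]][1] / sum(tab[["Sum Sq"]]),
       df = tab[["Df"]],
       ss = c(factor = tab[["Sum Sq"]][1], residual = tab[["Sum Sq"]][2]),
       degenerate = FALSE)
}

#' Post-hoc Scheffe tests for a one-way layout
#'
#' All pairwise level contrasts with the Scheffe statistic
#' S^2 = (difference of means)^2 / ((k - 1) * MSE * (1/n_i + 1/n_j)),
#' referred to the F(k - 1, N - k) distribution.
#'
#' @param results data.frame from `run_replications()`.
#' @param factor factor column name.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame of pairwise comparisons.
#' @export
scheffe <- function(results, factor, alpha = 0.05) {
  d <- results[!is.na(results$total_deaths), ]
  g <- as.character(d[[factor]])
  levels <- unique(g)
  k <- length(levels)
  if (k < 2) stop("need >= 2 levels", call. = FALSE)
  N <- nrow(d)
  means <- vapply(levels, function(l) mean(d$total_deaths[g == l]), 0)
  ns <- vapply(levels, function(l) sum(g == l), 0)
  mse <- sum(vapply(levels, function(l) {
    v <- d$total_deaths[g == l]
    sum((v - mean(v))^2)
  }, 0)) / (N - k)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    diff <- means[i] - means[j]
    s2 <- diff^2 / ((k - 1) * mse * (1 / ns[i] + 1 / ns[j]))
    p <- stats::pf(s2, k - 1, N - k, lower.tail = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      level_a = levels[i], level_b = levels[j], diff = diff,
      statistic = s2, p = p, significant = p < alpha,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-design mortality difference between the two policies
#'
#' For every combination of the six non-policy factors, the difference in
#' (replication-averaged) deaths between stay-and-play and scoop-and-run.
#' Negative values mark scenarios where stay-and-play is the better
#' option; the returned object carries that share as an attribute
#' `share_sp_better`.
#'
#' @param results data.frame from `run_replications()` over a design that
#'   includes both policy levels.
#' @return data.frame of matched designs with `delta` (S&P minus S&R).
#' @export
delta_deaths <- function(results) {
  others <- setdiff(names(results),
                    c("design_id", "policy", "replication", "seed",
                      "total_deaths", "error"))
  key <- do.call(paste, c(results[others], sep = "\r"))
  agg <- stats::aggregate(total_deaths ~ key + policy,
                          data = cbind(results, key = key), FUN = mean)
  sp <- agg[agg$policy == "stay_and_play", c("key", "total_deaths")]
  sr <- agg[agg$policy == "scoop_and_run", c("key", "total_deaths")]
  m <- merge(sp, sr, by = "key", suffixes = c("_sp", "_sr"))
  out <- data.frame(key = m$key,
                    deaths_sp = m$total_deaths_sp,
                    deaths_sr = m$total_deaths_sr,
                    delta = m$total_deaths_sp - m$total_deaths_sr,
                    stringsAsFactors = FALSE)
  attr(out, "share_sp_better") <- mean(out$delta < 0)
  out
}
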