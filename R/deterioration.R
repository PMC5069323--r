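the_table_cache <- new.env(parent = emptyenv())

#' Load the RPM deterioration table
#'
#' Survival probability in percent, tabulated on 30-minute elapsed-time bins
#' (rows) by RPM score 0--12 (columns). The shipped grid digitises the
#' published deterioration rates of the Sacco triage method; rows are a
#' left-continuous step function of elapsed time. An alternative grid can be
#' supplied as a CSV with the same layout (`time_min, rpm0..rpm12`).
#'
#' @param path optional path to a CSV grid; default uses the shipped table.
#' @param validate check the structural invariants (range and monotonicity).
#' @return an object of class `deterioration_table` with fields `grid`
#'   (matrix, rows = time bins), `times` (minutes) and `bin_width`.
#' @export
deterioration_table <- function(path = NULL, validate = TRUE) {
  if (is.null(path)) {
    if (!is.null(the_table_cache$default)) return(the_table_cache$default)
    path <- system.file("extdata", "deterioration_rpm.csv", package = "mcisim")
    caching <- TRUE
  } else {
    caching <- FALSE
  }
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(names(df)[1] == "time_min", ncol(df) == 14)
  grid <- as.matrix(df[, -1, drop = FALSE])
  rownames(grid) <- df$time_min
  colnames(grid) <- 0:12
  times <- as.numeric(df$time_min)
  widths <- unique(diff(times))
  tab <- structure(list(grid = grid, times = times,
                        bin_width = if (length(widths) == 1) widths else NA_real_),
                   class = "deterioration_table")
  if (validate) validate_deterioration_table(tab)
  if (caching) the_table_cache$default <- tab
  tab
}

#' Validate a deterioration table
#'
#' All entries must be percentages in \[0, 100\]; for a fixed RPM, survival
#' must be non-increasing in elapsed time; for a fixed time, non-decreasing
#' in RPM.
#'
#' @param tab a `deterioration_table`.
#' @return the table, invisibly; stops with a message on violation.
#' @export
validate_deterioration_table <- function(tab) {
  stopifnot(inherits(tab, "deterioration_table"))
  g <- tab$grid
  if (any(g < 0 | g > 100)) {
    stop("deterioration table entries must lie in [0, 100]", call. = FALSE)
  }
  if (is.unsorted(tab$times, strictly = TRUE)) {
    stop("time bins must be strictly increasing", call. = FALSE)
  }
  if (any(apply(g, 2, function(col) any(diff(col) > 0)))) {
    stop("survival must be non-increasing in time for each RPM", call. = FALSE)
  }
  if (any(apply(g, 1, function(row) any(diff(row) < 0)))) {
    stop("survival must be non-decreasing in RPM at each time", call. = FALSE)
  }
  invisible(tab)
}

#' Survival probability for an RPM score at an elapsed time
#'
#' Left-continuous step-function lookup on the deterioration grid: the row
#' for the largest tabulated time not exceeding `t` is used; past the last
#' row the last row applies. No interpolation is performed, matching the
#' discrete tabulation.
#'
#' @param rpm RPM score(s) in 0--12.
#' @param t elapsed time(s) in minutes, non-negative.
#' @param tab a `deterioration_table` (default: shipped grid).
#' @return survival probability in percent.
#' @examples
#' survival_probability(12, 0)  # 98
#' survival_probability(6, 0)   # 63
#' @export
survival_probability <- function(rpm, t, tab = deterioration_table()) {
  if (anyNA(rpm) || any(rpm < 0) || any(rpm > 12) || any(rpm != floor(rpm))) {
    stop("rpm must be an integer in [0, 12]", call. = FALSE)
  }
  if (anyNA(t) || any(t < 0)) stop("t must be non-negative", call. = FALSE)
  n <- max(length(rpm), length(t))
  rpm <- rep_len(as.integer(rpm), n)
  t <- rep_len(t, n)
  row <- findInterval(t, tab$times)     # >= 1 since times start at 0
  tab$grid[cbind(row, rpm + 1L)]
}
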