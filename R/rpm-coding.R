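#' Motor response levels recognised by the RPM score
#'
#' Ordered from worst (no response) to best (obeys commands).
#' @export
MOTOR_LEVELS <- c("none", "extends_flexes", "withdraws", "localizes", "obeys")

#' Triage categories (NATO T1--T4)
#'
#' T1 immediate, T2 delayed, T3 minimal (walking wounded), T4 expectant.
#' @export
TRIAGE_CATEGORIES <- c("T1", "T2", "T3", "T4")

#' Pre-hospital provider skill levels
#'
#' Escalating skill: basic emergency medical technicians (EMT), paramedic
#' intervention teams (PIT), mobile medical teams of an emergency physician
#' and nurse (MMT), and the emergency department (ED).
#' @export
SKILL_LEVELS <- c("EMT", "PIT", "MMT", "ED")

assert_count <- function(x, what) {
  if (length(x) == 0 || anyNA(x) || !is.numeric(x) || any(x < 0) ||
      any(x != floor(x))) {
    stop(sprintf("%s must be a non-negative integer, got %s",
                 what, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Code a respiratory rate for the RPM score
#'
#' Maps breaths per minute onto the 0--4 coded value used by the RPM injury
#' severity score: 0 -> 0; 1--9 -> 1; 36+ -> 2; 25--35 -> 3; 10--24 -> 4.
#' Rates are whole breaths per minute, so the coding bands are exhaustive.
#'
#' @param rr breaths per minute, non-negative integer (vectorised).
#' @return integer coded value(s) in 0--4.
#' @examples
#' code_respiratory_rate(c(0, 20, 30))
#' @export
code_respiratory_rate <- function(rr) {
  rr <- assert_count(rr, "respiratory rate")
  out <- integer(length(rr))
  out[rr == 0] <- 0L
  out[rr >= 1 & rr <= 9] <- 1L
  out[rr >= 36] <- 2L
  out[rr >= 25 & rr <= 35] <- 3L
  out[rr >= 10 & rr <= 24] <- 4L
  out
}

#' Code a pulse rate for the RPM score
#'
#' Beats per minute onto 0--4: 0 -> 0; 1--40 -> 1; 41--60 -> 2; 121+ -> 3;
#' 61--120 -> 4.
#'
#' @param pr beats per minute, non-negative integer (vectorised).
#' @return integer coded value(s) in 0--4.
#' @export
code_pulse_rate <- function(pr) {
  pr <- assert_count(pr, "pulse rate")
  out <- integer(length(pr))
  out[pr == 0] <- 0L
  out[pr >= 1 & pr <= 40] <- 1L
  out[pr >= 41 & pr <= 60] <- 2L
  out[pr >= 121] <- 3L
  out[pr >= 61 & pr <= 120] <- 4L
  out
}

#' Code the best motor response for the RPM score
#'
#' @param m one of `MOTOR_LEVELS` (vectorised):
#'   none, extends_flexes, withdraws, localizes, obeys.
#' @return integer coded value(s) in 0--4.
#' @export
code_motor_response <- function(m) {
  idx <- match(m, MOTOR_LEVELS)
  if (anyNA(idx)) {
    stop("unknown motor response level: ",
         paste(unique(m[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx - 1L
}

#' Construct a set of vital signs
#'
#' @param respiratory_rate breaths per minute (non-negative integer).
#' @param pulse_rate beats per minute (non-negative integer).
#' @param motor_response one of `MOTOR_LEVELS`.
#' @return an object of class `vital_signs`.
#' @export
vital_signs <- function(respiratory_rate, pulse_rate, motor_response) {
  assert_count(respiratory_rate, "respiratory rate")
  assert_count(pulse_rate, "pulse rate")
  motor_response <- match.arg(motor_response, MOTOR_LEVELS)
  structure(list(respiratory_rate = as.integer(respiratory_rate),
                 pulse_rate = as.integer(pulse_rate),
                 motor_response = motor_response),
            class = "vital_signs")
}

#' RPM injury severity score
#'
#' Sum of the coded respiratory rate, pulse rate and best motor response;
#' an integer from 0 (worst) to 12 (best).
#'
#' @param v a `vital_signs` object.
#' @return integer in 0--12.
#' @examples
#' rpm_score(vital_signs(20, 80, "obeys"))  # 12
#' @export
rpm_score <- function(v) {
  stopifnot(inherits(v, "vital_signs"))
  code_respiratory_rate(v$respiratory_rate) +
    code_pulse_rate(v$pulse_rate) +
    code_motor_response(v$motor_response)
}

#' Representative vital signs for a target RPM score
#'
#' Deterministically decomposes an RPM value into coded components (motor
#' first, then pulse, then respiration) and picks a representative raw value
#' inside each coding band. Used by the default profile builder.
#'
#' @param rpm integer in 0--12.
#' @return a `vital_signs` object whose `rpm_score()` equals `rpm`.
#' @export
vitals_for_rpm <- function(rpm) {
  stopifnot(length(rpm) == 1, rpm >= 0, rpm <= 12, rpm == floor(rpm))
  m <- min(4L, as.integer(rpm))
  rest <- as.integer(rpm) - m
  p <- min(4L, rest)
  r <- rest - p
  rr_rep <- c(0L, 5L, 40L, 30L, 15L)   # representative rate per coded value
  pr_rep <- c(0L, 30L, 50L, 130L, 80L)
  vital_signs(rr_rep[r + 1L], pr_rep[p + 1L], MOTOR_LEVELS[m + 1L])
}
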