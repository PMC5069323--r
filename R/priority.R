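#' Treatment/evacuation priority code
#'
#' Encodes (triage level, RPM score, arrival minute in queue) as one integer
#' whose numeric order equals the lexicographic order of the triple: the
#' victim with the lowest code has the highest priority. The arrival field
#' occupies three decimal digits, so queue-entry times at or beyond minute
#' 1000 cannot be encoded and are a hard error (the simulation horizon is
#' well below that).
#'
#' A T1 victim with RPM 6 arriving at minute 45 codes to 106045; a T2 victim
#' with RPM 11 arriving at minute 110 codes to 211110.
#'
#' @param category triage level 1--4 (integer, or "T1".."T4").
#' @param rpm RPM score 0--12.
#' @param arrival whole minutes since incident start, 0--999.
#' @return integer priority code (vectorised).
#' @export
priority_code <- function(category, rpm, arrival) {
  if (is.character(category)) {
    idx <- match(category, TRIAGE_CATEGORIES)
    if (anyNA(idx)) stop("unknown triage category", call. = FALSE)
    category <- idx
  }
  if (anyNA(category) || any(category < 1) || any(category > 4) ||
      any(category != floor(category))) {
    stop("category must be an integer in 1..4", call. = FALSE)
  }
  if (anyNA(rpm) || any(rpm < 0) || any(rpm > 12) || any(rpm != floor(rpm))) {
    stop("rpm must be an integer in [0, 12]", call. = FALSE)
  }
  if (anyNA(arrival) || any(arrival < 0) || any(arrival != floor(arrival))) {
    stop("arrival must be a whole non-negative minute", call. = FALSE)
  }
  if (any(arrival >= 1000)) {
    stop("priority-code overflow: arrival minute >= 1000 cannot be encoded",
         call. = FALSE)
  }
  as.integer(category) * 100000L + as.integer(rpm) * 1000L +
    as.integer(arrival)
}
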