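# Shared fixtures, all built in code.

# A small incident (same structure as the default, fewer victims) for
# invariant tests that need speed rather than the full case study.
small_scenario <- function(T1 = 6, T2 = 10, T3 = 20, T4 = 2) {
  cfg <- default_config()
  cfg$census <- list(T1 = T1, T2 = T2, T3 = T3, T4 = T4,
                     immediate_fatalities = 1, uninjured = 5)
  make_scenario(cfg)
}

# Three-victim micro scenario with single-profile pools and no responders:
# clinical dynamics and SAR arrivals only.
micro_scenario <- function() {
  cfg <- default_config()
  cfg$census <- list(T1 = 1, T2 = 1, T3 = 0, T4 = 1,
                     immediate_fatalities = 0, uninjured = 0)
  cfg$response <- list(enabled = FALSE)
  lib <- build_default_profiles()
  make_scenario(cfg, profiles = lib[c("T1-A", "T2-A", "T4-A")])
}

micro_factors <- function() {
  utils::modifyList(default_factors(), list(triage = FALSE))
}

# Hand-derived golden event log for the three-victim micro scenario at a
# given seed. Times come from dwell arithmetic on the printed transition
# lists (T1-A and T4-A: 30 + 30 -> dead at 60; T2-A: five 30-minute steps
# -> dead at 150) and from the closed-form medium-SAR schedule
# (5 + k / 0.5 = 7, 9, 11); only the extraction order is seeded.
golden_micro_expected <- function(seed) {
  rng <- mcisim:::local_rng(seed + 2)
  ord <- c("V001", "V002", "V003")[rng$perm(3)]
  rows <- function(time, kind, subject, detail = "") {
    data.frame(time = time, kind = kind, subject = subject, detail = detail,
               stringsAsFactors = FALSE)
  }
  rbind(
    rows(7, "sar_extraction", ord[1], "extricated"),
    rows(9, "sar_extraction", ord[2], "extricated"),
    rows(11, "sar_extraction", ord[3], "extricated"),
    rows(30, "cc_time_transition", "V001"),
    rows(30, "cc_time_transition", "V002"),
    rows(30, "cc_time_transition", "V003"),
    rows(60, "cc_time_transition", "V001"),
    rows(60, "death", "V001", "scene"),
    rows(60, "cc_time_transition", "V002"),
    rows(60, "cc_time_transition", "V003"),
    rows(60, "death", "V003", "scene"),
    rows(90, "cc_time_transition", "V002"),
    rows(120, "cc_time_transition", "V002"),
    rows(150, "cc_time_transition", "V002"),
    rows(150, "death", "V002", "scene"))
}

# A hand-built two-state profile: one live condition that deteriorates to
# death after `dwell` minutes unless an EMT stabilizes it.
toy_profile <- function(id = "toy", category = "T1", rpm = 6, dwell = 60) {
  victim_profile(
    id, category, ambulatory = FALSE,
    initial_condition = "c0",
    conditions = list(
      clinical_condition("c0", rpm = rpm, triage_category = category),
      clinical_condition("dead", rpm = 0, triage_category = category,
                         end_kind = "dead"),
      clinical_condition("ok", rpm = min(12, rpm + 2),
                         triage_category = category,
                         end_kind = "stabilized")),
    transitions = list(
      cc_transition("c0", "dead", "time", dwell),
      cc_transition("c0", "ok", "treatment", 5, required_skill = "EMT")))
}

# A "walking wounded" profile that quietly deteriorates to an urgent (T2)
# condition after 10 minutes, then to death; used to exercise the NUCA
# re-examination transfer.
deteriorating_t3_profile <- function() {
  victim_profile(
    "T3-worsens", "T3", ambulatory = TRUE,
    initial_condition = "c0",
    conditions = list(
      clinical_condition("c0", rpm = 11, triage_category = "T3"),
      clinical_condition("c1", rpm = 7, triage_category = "T2"),
      clinical_condition("dead", rpm = 0, triage_category = "T2",
                         end_kind = "dead"),
      clinical_condition("stab", rpm = 9, triage_category = "T2",
                         end_kind = "stabilized")),
    transitions = list(
      cc_transition("c0", "c1", "time", 10),
      cc_transition("c1", "dead", "time", 240),
      cc_transition("c1", "stab", "treatment", 5, required_skill = "MMT")))
}
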