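test_that("profile validation enforces the state-machine invariants", {
  p <- toy_profile()
  expect_silent(validate_profile(p))
  # non-end condition without a time transition
  expect_error(victim_profile(
    "bad", "T1", FALSE, initial_condition = "c0",
    conditions = list(clinical_condition("c0", rpm = 6),
                      clinical_condition("dead", rpm = 0, end_kind = "dead")),
    transitions = list()), "no time transition")
  # dead state with an outgoing transition
  expect_error(victim_profile(
    "bad", "T1", FALSE, initial_condition = "c0",
    conditions = list(clinical_condition("c0", rpm = 6),
                      clinical_condition("dead", rpm = 0, end_kind = "dead")),
    transitions = list(cc_transition("c0", "dead", "time", 30),
                       cc_transition("dead", "c0", "time", 30))),
    "no outgoing")
  # cycle among time transitions
  expect_error(victim_profile(
    "bad", "T1", FALSE, initial_condition = "a",
    conditions = list(clinical_condition("a", rpm = 6),
                      clinical_condition("b", rpm = 5)),
    transitions = list(cc_transition("a", "b", "time", 30),
                       cc_transition("b", "a", "time", 30))), "cycle")
  # duplicate (source, trigger, skill)
  expect_error(victim_profile(
    "bad", "T1", FALSE, initial_condition = "c0",
    conditions = list(clinical_condition("c0", rpm = 6),
                      clinical_condition("stab", end_kind = "stabilized",
                                         rpm = 8)),
    transitions = list(cc_transition("c0", "stab", "time", 30),
                       cc_transition("c0", "stab", "time", 40))),
    "multiple transitions")
  # treatment transitions need a skill (constructor-level guard)
  expect_error(cc_transition("a", "b", "treatment", 5,
                             required_skill = "none"))
  expect_error(cc_transition("a", "b", "time", 0))
})

test_that("rpm must agree with the vitals it is stated for", {
  expect_error(clinical_condition("x", vitals = vital_signs(20, 80, "obeys"),
                                  rpm = 10), "does not equal")
})

test_that("next_condition resolves time, treatment and end states", {
  p <- toy_profile()
  expect_identical(next_condition("c0", "time", p = p), "dead")
  expect_identical(next_condition("dead", "time", p = p), "none")
  expect_identical(next_condition("c0", "treatment", "EMT", p), "ok")
  expect_identical(next_condition("ok", "treatment", "MMT", p), "none")
})

test_that("higher skills substitute for missing dedicated transitions", {
  p <- toy_profile()   # only an EMT treatment transition exists
  # enumeration of the substitution rule: MMT and PIT cover EMT; the ED
  # covers everything; EMT covers only itself
  expect_identical(next_condition("c0", "treatment", "EMT", p), "ok")
  expect_identical(next_condition("c0", "treatment", "PIT", p), "ok")
  expect_identical(next_condition("c0", "treatment", "MMT", p), "ok")
  expect_identical(next_condition("c0", "treatment", "ED", p), "ok")
  # a dedicated transition beats substitution
  p2 <- build_default_profiles()[["T1-A"]]
  direct <- next_condition("cct-0", "treatment", "MMT", p2)
  expect_match(direct, "^mmt")
})

test_that("untreated death time is the dwell sum along the untreated chain", {
  # [RPM 11, dwell 60] -> [RPM 5, dwell 30] -> dead
  p <- victim_profile(
    "chain", "T1", FALSE, initial_condition = "a",
    conditions = list(clinical_condition("a", rpm = 11),
                      clinical_condition("b", rpm = 5),
                      clinical_condition("dead", rpm = 0, end_kind = "dead")),
    transitions = list(cc_transition("a", "b", "time", 60),
                       cc_transition("b", "dead", "time", 30)))
  expect_equal(untreated_death_time(p), 90)
  # a stabilized terminal chain never dies
  p3 <- build_default_profiles()[["T3-A"]]
  expect_identical(untreated_death_time(p3), Inf)
})

test_that("the T1-A fixture walks to death at minute 60 by hand", {
  # hand walk of its transition list: cct-0 (RPM 6, dwell 30)
  # -> cct-1 (RPM 4, dwell 30) -> dead, so death at 30 + 30 = 60
  p <- build_default_profiles()[["T1-A"]]
  expect_identical(p$initial_condition, "cct-0")
  expect_identical(p$conditions[["cct-0"]]$rpm, 6L)
  expect_identical(next_condition("cct-0", "time", p = p), "cct-1")
  expect_identical(p$conditions[["cct-1"]]$rpm, 4L)
  expect_identical(next_condition("cct-1", "time", p = p), "dead")
  expect_equal(untreated_death_time(p), 60)
})
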