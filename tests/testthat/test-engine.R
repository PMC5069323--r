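test_that("the event kernel executes in (time, sequence) order", {
  sim <- new_simulation()
  schedule(sim, 5, "dispatch_wave", list(subject = "b"))
  schedule(sim, 5, "dispatch_wave", list(subject = "c"))
  schedule(sim, 1, "dispatch_wave", list(subject = "a"))
  log <- run_until(sim, Inf)
  expect_identical(log$subject, c("a", "b", "c"))   # ties in schedule order
  expect_true(!is.unsorted(log$time))
})

test_that("cancelled events never fire and double-cancel is an error", {
  sim <- new_simulation()
  h <- schedule(sim, 3, "dispatch_wave", list(subject = "x"))
  schedule(sim, 4, "dispatch_wave", list(subject = "y"))
  cancel_event(sim, h)
  log <- run_until(sim, Inf)
  expect_identical(log$subject, "y")
  expect_error(cancel_event(sim, h), "double-cancel")
})

test_that("an empty queue returns immediately and the past is rejected", {
  sim <- new_simulation()
  expect_identical(nrow(run_until(sim, 100)), 0L)
  schedule(sim, 10, "dispatch_wave")
  run_until(sim, Inf)
  expect_error(schedule(sim, 5, "dispatch_wave"), "in the past")
  expect_error(schedule(sim, 11, "not_a_kind"))
})

test_that("event logs round-trip through the line format", {
  sim <- new_simulation()
  schedule(sim, 1.5, "dispatch_wave", list(subject = "u", detail = "d"))
  schedule(sim, 2, "sar_extraction", list(subject = "V001"))
  log <- run_until(sim, Inf)
  f <- tempfile()
  write_event_log(log, f)
  expect_identical(read_event_log(f), log)
})

test_that("an untreated victim dies at exactly the profile's death time", {
  cfg <- default_config()
  cfg$census <- list(T1 = 1, T2 = 0, T3 = 0, T4 = 0,
                     immediate_fatalities = 0, uninjured = 0)
  cfg$response <- list(enabled = FALSE)
  lib <- build_default_profiles()["T1-A"]
  scn <- make_scenario(cfg, profiles = lib)
  run <- simulate_mci(scn, micro_factors(), seed = 1)
  expect_identical(run$total_deaths, 1L)
  dth <- run$event_log[run$event_log$kind == "death", ]
  expect_equal(dth$time, untreated_death_time(lib[["T1-A"]]))
})

test_that("the three-victim micro trace equals the hand-derived golden log", {
  scn <- micro_scenario()
  run <- simulate_mci(scn, micro_factors(), seed = 11)
  expected <- golden_micro_expected(11)
  got <- run$event_log
  rownames(got) <- rownames(expected) <- NULL
  expect_identical(got, expected)
})

test_that("identical scenario and seed give byte-identical event logs", {
  scn <- small_scenario()
  r1 <- simulate_mci(scn, default_factors(), seed = 5)
  r2 <- simulate_mci(scn, default_factors(), seed = 5)
  expect_identical(r1$event_log, r2$event_log)
  expect_identical(r1$total_deaths, r2$total_deaths)
  f1 <- tempfile(); f2 <- tempfile()
  write_event_log(r1$event_log, f1)
  write_event_log(r2$event_log, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("dead and stabilized states are absorbing in the log", {
  scn <- micro_scenario()
  run <- simulate_mci(scn, micro_factors(), seed = 3, horizon = 600)
  log <- run$event_log
  for (vid in unique(log$subject[log$kind == "death"])) {
    t_death <- log$time[log$kind == "death" & log$subject == vid]
    after <- log[log$subject == vid & log$time > t_death &
                   log$kind == "cc_time_transition", ]
    expect_identical(nrow(after), 0L)
  }
})

test_that("treatment triggers move victims onto the treated pathways", {
  # drive the handlers directly on a one-victim state
  lib <- build_default_profiles()
  p <- lib[["T1-A"]]
  sim <- new_simulation()
  state <- new.env()
  v <- new.env()
  v$id <- "V1"; v$profile <- p; v$pending_cc <- NA
  v$disposition <- NA_character_; v$location <- "fmp"; v$stabilized <- FALSE
  state$victims <- list(V1 = v)
  state$hooks <- list()
  mcisim:::init_clinical(sim, state)
  expect_identical(v$cond, "cct-0")
  # EMT treatment: cancel the pending deterioration, effect after 5 min
  on_treatment_trigger(sim, state, "V1", "EMT")
  run_until(sim, 5, function(sim, ev) {
    if (ev$kind == "cc_time_transition") {
      on_time_trigger(sim, state, ev$payload$subject, ev$payload$target)
    }
  })
  expect_match(v$cond, "^emt")           # on the EMT pathway
  # an MMT arriving mid-pathway escalates obliquely to the MMT pathway
  on_treatment_trigger(sim, state, "V1", "MMT")
  run_until(sim, 10, function(sim, ev) {
    if (ev$kind == "cc_time_transition") {
      on_time_trigger(sim, state, ev$payload$subject, ev$payload$target)
    }
  })
  expect_match(v$cond, "^mmt")
  # the MMT pathway ends stabilized; the victim can no longer die
  run_until(sim, 1000, function(sim, ev) {
    if (ev$kind == "cc_time_transition") {
      on_time_trigger(sim, state, ev$payload$subject, ev$payload$target)
    }
  })
  expect_true(v$stabilized)
  expect_false(identical(v$disposition, "dead"))
  # treating a dead victim is a logged no-op
  v2 <- new.env()
  v2$id <- "V2"; v2$profile <- p; v2$pending_cc <- NA
  v2$disposition <- "dead"; v2$location <- "fmp"
  state$victims$V2 <- v2
  on_treatment_trigger(sim, state, "V2", "MMT")
  log <- event_log(sim)
  expect_true(any(log$kind == "warning" & log$subject == "V2"))
})
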