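test_that("travel time is distance over speed", {
  expect_equal(travel_time(30, 60), 30)
  expect_equal(travel_time(0, 80), 0)
  expect_equal(travel_time(17, 85), 12)
  expect_error(travel_time(10, 0), "speed")
  expect_error(travel_time(-1, 60), "distance")
})

test_that("the SAR schedule follows its closed form and rate ordering", {
  lv <- default_sar_levels()
  s <- sar_schedule(20, "medium")
  r1 <- lv$medium$rate_before / 10
  r2 <- lv$medium$rate_after / 10
  k <- 1:20
  t1 <- 5 + k / r1
  n1 <- sum(t1 <= 21)
  expected <- t1
  expected[(n1 + 1):20] <- 21 + ((n1 + 1):20 - n1) / r2
  expect_equal(s, expected)
  expect_true(!is.unsorted(s))
  # throughput rises after the additional openings at minute 21
  gaps <- diff(s)
  expect_true(all(gaps[s[-1] > 21] < gaps[1]))
  # higher rate level finishes strictly earlier
  expect_lt(max(sar_schedule(50, "high")), max(sar_schedule(50, "low")))
  expect_identical(sar_schedule(0, "low"), numeric(0))
  expect_error(sar_schedule(5, "extreme"), "unknown SAR rate")
})

test_that("supervision requirements follow the level table", {
  expect_identical(supervision_requirement("emt", "T1"), "none")
  expect_identical(supervision_requirement("nurse", "T1"), "nurse")
  expect_identical(supervision_requirement("nurse", "T2"), "none")
  expect_identical(supervision_requirement("physician", "T1"), "mmt")
  expect_identical(supervision_requirement("physician", "T2"), "none")
  expect_identical(supervision_requirement("physician_all", "T2"), "mmt")
  expect_error(supervision_requirement("chaplain", "T1"))
})

make_hcfs <- function(dists, surge = 2, caps = NULL) {
  lapply(seq_along(dists), function(i) {
    h <- new.env()
    h$id <- paste0("H", i); h$dist <- dists[i]
    h$caps <- if (is.null(caps)) "general" else caps[[i]]
    h$surge <- surge; h$assigned <- 0L
    h
  })
}

test_that("hospital distribution honours both policies and capabilities", {
  v <- new.env(); v$dest <- "general"
  hcfs <- make_hcfs(c(10, 20, 30, 40))
  # nearest-first with capacity open always picks the closest
  expect_identical(distribute_to_hcf(v, "nearest_first", hcfs), "H1")
  hcfs[[1]]$assigned <- 2L   # closest full: second-closest next
  expect_identical(distribute_to_hcf(v, "nearest_first", hcfs), "H2")
  # round-robin with equal capacities: 8 victims -> 2 each
  hcfs <- make_hcfs(c(10, 20, 30, 40))
  picks <- character(8)
  for (i in 1:8) {
    picks[i] <- distribute_to_hcf(v, "round_robin", hcfs)
    j <- match(picks[i], vapply(hcfs, `[[`, "", "id"))
    hcfs[[j]]$assigned <- hcfs[[j]]$assigned + 1L
  }
  expect_identical(as.vector(table(picks)), rep(2L, 4))
  # destination need restricts the capable set
  vt <- new.env(); vt$dest <- "trauma_centre"
  hcfs <- make_hcfs(c(10, 20), caps = list("general", c("general", "trauma")))
  expect_identical(distribute_to_hcf(vt, "nearest_first", hcfs), "H2")
})

test_that("the dispatch plan fixes the initial wave and sorts by distance", {
  g <- default_geometry()
  r <- default_roster(g)
  plan <- dispatch_plan("normal", g, r)
  first <- plan[plan$depart == 0, ]
  expect_identical(sum(first$type == "ambulance"), 5L)
  expect_identical(sum(first$type == "mmt"), 4L)
  expect_identical(sum(first$type == "rit"), 2L)
  expect_identical(sum(first$dest == "command"), 1L)
  # ambulances leave from the nearest stations first
  amb <- plan[plan$type == "ambulance", ]
  init_amb <- amb[amb$depart == 0, ]
  later <- amb[amb$depart > 0, ]
  expect_lte(max(init_amb$travel), min(later$travel))
  # the high resource level fields 7 working MMTs in the first wave
  plan_hi <- dispatch_plan("high", g, r)
  first_hi <- plan_hi[plan_hi$depart == 0 & plan_hi$type == "mmt", ]
  expect_identical(nrow(first_hi), 8L)
  expect_identical(sum(first_hi$dest != "command"), 7L)
  expect_true(all(first_hi$arrive >= 3 & first_hi$arrive <= 15))
  expect_error(dispatch_plan("massive", g, r), "unknown resource level")
})

test_that("hospital admissions respect surge then hourly-rate spacing", {
  scn <- small_scenario(T1 = 10, T2 = 12, T3 = 0, T4 = 0)
  fac <- utils::modifyList(default_factors(), list(hcf_capacity = "low"))
  run <- simulate_mci(scn, fac, seed = 2)
  lv <- default_hcf_capacity_levels()$low
  log <- run$event_log
  adm <- log[log$kind == "admission", ]
  arr <- log[log$kind == "vehicle_arrival" & log$detail == "at_hcf", ]
  expect_gt(nrow(adm), lv$surge)   # at least one hospital past its surge
  # recover each admission's hospital from the assignment notes
  asg <- log[log$kind == "assign", ]
  vict_hcf <- sub("^.*>", "", asg$detail)
  names(vict_hcf) <- sub(">.*$", "", asg$detail)
  adm$hcf <- vict_hcf[adm$subject]
  for (h in unique(adm$hcf)) {
    times <- sort(adm$time[adm$hcf == h])
    if (length(times) <= lv$surge) next
    post <- times[-seq_len(lv$surge)]
    expect_true(all(diff(post) >= 60 / lv$rate_per_hour - 1e-9))
  }
})

test_that("victims are conserved across every disposition", {
  scn <- small_scenario()
  n <- census_injured(scn$census)
  for (fac in list(default_factors(),
                   utils::modifyList(default_factors(),
                                     list(policy = "scoop_and_run",
                                          triage = FALSE, sar = "low")))) {
    run <- simulate_mci(scn, fac, seed = 4, audit = TRUE)
    tab <- table(run$dispositions$disposition)
    expect_identical(sum(tab), as.integer(n))
    expect_identical(sum(run$dispositions$disposition == "dead"),
                     run$total_deaths)
  }
})

test_that("an ambulance assignment never changes after pickup", {
  scn <- small_scenario()
  run <- simulate_mci(scn, default_factors(), seed = 9)
  log <- run$event_log
  asg <- log[log$kind == "assign", ]
  dep <- log[log$kind == "vehicle_departure" & grepl("^to:", log$detail), ]
  # every departure carries exactly the victim assigned to that ambulance
  dep$vid <- sub("^to:[^:]+:", "", dep$detail)
  for (i in seq_len(nrow(dep))) {
    amb <- dep$subject[i]
    prior <- asg[asg$subject == amb & asg$time <= dep$time[i], ]
    expect_identical(sub(">.*$", "", prior$detail[nrow(prior)]), dep$vid[i])
  }
  # and an assigned victim is never re-assigned to another vehicle
  pairs <- data.frame(vid = sub(">.*$", "", asg$detail), amb = asg$subject)
  dead <- run$dispositions$victim_id[run$dispositions$disposition == "dead"]
  alive_pairs <- pairs[!pairs$vid %in% dead, ]
  expect_identical(anyDuplicated(alive_pairs$vid), 0L)
})

test_that("a deteriorating walking-wounded victim is transferred to the FMP", {
  cfg <- default_config()
  cfg$census <- list(T1 = 0, T2 = 0, T3 = 1, T4 = 0,
                     immediate_fatalities = 0, uninjured = 0)
  lib <- list(`T3-worsens` = deteriorating_t3_profile())
  scn <- make_scenario(cfg, profiles = lib)
  run <- simulate_mci(scn, default_factors(), seed = 1)
  log <- run$event_log
  expect_true(any(grepl("deteriorated to urgent", log$detail)))
  # the victim ends up treated and admitted, not discharged from the NUCA
  expect_identical(run$dispositions$disposition, "admitted")
  expect_identical(run$total_deaths, 0L)
})

test_that("without triage the urgent queue is served first-in-first-out", {
  scn <- small_scenario(T1 = 4, T2 = 4, T3 = 0, T4 = 0)
  fac <- utils::modifyList(default_factors(), list(triage = FALSE))
  run <- simulate_mci(scn, fac, seed = 6)
  log <- run$event_log
  arr <- log[log$kind == "sar_extraction", ]
  ts <- log[log$kind == "treatment_start" & grepl("^fmp", log$detail), ]
  # first treatment order equals CCP arrival order among treated victims
  treated <- ts$subject[!duplicated(ts$subject)]
  arrived <- arr$subject[arr$subject %in% treated]
  expect_identical(treated, arrived)
})

test_that("with triage, severe victims pre-empt the queue order", {
  # under triage the first victims treated at the FMP should include T1s
  # even when T2s arrived earlier
  scn <- small_scenario(T1 = 5, T2 = 5, T3 = 0, T4 = 0)
  run_tri <- simulate_mci(scn, default_factors(), seed = 12)
  ts <- run_tri$event_log
  ts <- ts[ts$kind == "treatment_start" & grepl("^fmp", ts$detail), ]
  first_batch <- utils::head(ts$subject[!duplicated(ts$subject)], 3)
  cats <- run_tri$dispositions$category[
    match(first_batch, run_tri$dispositions$victim_id)]
  expect_true("T1" %in% cats)
})
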