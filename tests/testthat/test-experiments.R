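test_that("the full factorial enumerates every design point once", {
  d <- build_factorial()
  expect_identical(nrow(d), 1152L)
  expect_identical(anyDuplicated(d[, -1]), 0L)
  toy <- build_factorial(list(a = c("x", "y"), b = c(1, 2)))
  expect_identical(nrow(toy), 4L)
  expect_identical(build_factorial(), d)   # deterministic ordering
  expect_error(build_factorial(list(a = character(0), b = 1:2)), "empty")
})

test_that("replication bookkeeping produces |designs| x n_reps rows", {
  toy <- build_factorial(list(policy = c("stay_and_play", "scoop_and_run"),
                              sar = c("low", "high")))
  stub <- function(factors, seed) (seed %% 7) + nchar(factors$sar)
  r <- run_replications(toy, n_reps = 3, base_seed = 42, simulator = stub)
  expect_identical(nrow(r), 12L)
  expect_identical(sum(table(r$design_id)), 12L)
  expect_true(all(table(r$design_id) == 3))
  r2 <- run_replications(toy, n_reps = 3, base_seed = 42, simulator = stub)
  expect_identical(r, r2)
  one <- run_replications(toy[1, ], n_reps = 1, base_seed = 1,
                          simulator = stub)
  expect_identical(nrow(one), 1L)
})

test_that("per-run seeds are isolated between designs", {
  s1 <- vapply(1:50, function(d) per_run_seed(7, d, 3), 0L)
  expect_identical(anyDuplicated(s1), 0L)
  expect_true(all(s1 >= 0 & s1 < 2^31))
  # another design's presence cannot perturb a run's seed
  expect_identical(per_run_seed(7, 12, 3), s1[12])
  # a failing run is recorded without aborting the sweep
  toy <- build_factorial(list(a = c("x", "y")))
  flaky <- function(factors, seed) {
    if (factors$a == "y") stop("boom") else 1
  }
  r <- run_replications(toy, 2, 1, simulator = flaky)
  expect_identical(nrow(r), 4L)
  expect_true(all(is.na(r$total_deaths[r$a == "y"])))
  expect_true(all(r$error[r$a == "y"] == "boom"))
})

test_that("per-level descriptive statistics follow the table layout", {
  res <- data.frame(level = c("a", "a", "b"), replication = 1:3,
                    total_deaths = c(1, 3, 2))
  s <- summarize_by_factor(res, "level")
  expect_identical(s$mean, c(2, 2))
  expect_identical(s$median, c(2, 2))
  expect_identical(s$n, c(2L, 1L))
  const <- data.frame(g = c("a", "a", "b", "b"), total_deaths = rep(4, 4))
  sc <- summarize_by_factor(const, "g")
  expect_true(all(sc$mean == 4 & sc$median == 4 & sc$min == 4 &
                    sc$max == 4 & sc$sd == 0))
  expect_error(summarize_by_factor(res, "nope"), "unknown factor")
})

test_that("one-way ANOVA matches the two-sample t-test identity", {
  set.seed(1)
  res <- data.frame(g = rep(c("a", "b"), each = 10),
                    total_deaths = c(rnorm(10, 5), rnorm(10, 7)))
  a <- anova_oneway(res, "g")
  tt <- t.test(total_deaths ~ g, data = res, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA sums of squares match a hand computation", {
  # groups: {1, 2, 3}, {2, 4, 6}: means 2 and 4, grand mean 3
  # SS_between = 3*(2-3)^2 + 3*(4-3)^2 = 6
  # SS_within  = (1 + 0 + 1) + (4 + 0 + 4) = 10; F = 6 / (10/4) = 2.4
  res <- data.frame(g = rep(c("a", "b"), each = 3),
                    total_deaths = c(1, 2, 3, 2, 4, 6))
  a <- anova_oneway(res, "g")
  expect_equal(unname(a$ss["factor"]), 6)
  expect_equal(unname(a$ss["residual"]), 10)
  expect_equal(a$F, 2.4)
  expect_equal(a$eta_squared, 6 / 16)
  # identical groups: explained variance zero, flagged degenerate
  same <- data.frame(g = rep(c("a", "b"), each = 3), total_deaths = rep(5, 6))
  expect_true(anova_oneway(same, "g")$degenerate)
  expect_identical(anova_oneway(same, "g")$eta_squared, 0)
})

test_that("Scheffe pairwise statistics follow the standard formula", {
  set.seed(2)
  res <- data.frame(g = rep(c("a", "b", "c"), each = 8),
                    total_deaths = c(rnorm(8, 5), rnorm(8, 5), rnorm(8, 9)))
  sc <- scheffe(res, "g")
  expect_identical(nrow(sc), 3L)
  # recompute one contrast by hand
  k <- 3; N <- 24
  mse <- sum(unlist(tapply(res$total_deaths, res$g,
                           function(v) sum((v - mean(v))^2)))) / (N - k)
  m <- tapply(res$total_deaths, res$g, mean)
  s2 <- (m["a"] - m["c"])^2 / ((k - 1) * mse * (1 / 8 + 1 / 8))
  row <- sc[sc$level_a == "a" & sc$level_b == "c", ]
  expect_equal(row$statistic, unname(s2))
  expect_equal(row$p, unname(stats::pf(s2, k - 1, N - k, lower.tail = FALSE)))
  expect_true(row$significant)
  expect_false(sc$significant[sc$level_a == "a" & sc$level_b == "b"])
})

test_that("the policy mortality difference is computed per matched design", {
  toy <- build_factorial(list(policy = c("stay_and_play", "scoop_and_run"),
                              sar = c("low", "high")))
  # deterministic stub: S&P deaths = 10, S&R = 8 at low; reversed at high
  stub <- function(factors, seed) {
    if (factors$sar == "low") {
      if (factors$policy == "stay_and_play") 10 else 8
    } else {
      if (factors$policy == "stay_and_play") 5 else 6
    }
  }
  r <- run_replications(toy, 2, 1, simulator = stub)
  d <- delta_deaths(r)
  expect_identical(nrow(d), 2L)
  expect_setequal(d$delta, c(2, -1))
  expect_equal(attr(d, "share_sp_better"), 0.5)
})
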