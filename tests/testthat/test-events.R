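th <- event_thresholds()

test_that("exponential event probability matches the printed worked value", {
  expect_equal(event_probability(10, 0.1), 0.6321, tolerance = 1e-4)
  expect_equal(event_probability(10, 0.1), 1 - exp(-1))
  expect_equal(event_probability(10, 0), 0)
  expect_equal(event_probability(0, 123), 0)
  # first-order behaviour for small rate * dt
  expect_equal(event_probability(0.01, 0.1), 0.001, tolerance = 1e-3)
  expect_error(event_probability(-1, 0.1), "non-negative")
})

test_that("event draw compares the uniform variate against the cdf", {
  expect_true(draw_event(0, 10, 0.1))
  expect_false(draw_event(1, 10, 0.1))
  expect_true(draw_event(0.5, 10, 0.1))  # 0.5 < 0.6321
  expect_false(draw_event(0.7, 10, 0.1))
  expect_error(draw_event(1.5, 10, 0.1), "\\[0, 1\\]")
})

test_that("memorylessness: two half steps multiply to one full step", {
  for (rate in c(0.3, 10)) {
    surv_full <- 1 - event_probability(rate, 0.1)
    surv_half <- (1 - event_probability(rate, 0.05))^2
    expect_equal(surv_full, surv_half, tolerance = 1e-12)
  }
})

test_that("empirical event frequency matches the exponential model", {
  withr::with_seed(99, {
    n <- 1e5
    hits <- sum(draw_event(runif(n), 10, 0.1))
  })
  p0 <- 1 - exp(-1)
  expect_lt(abs(hits / n - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("strain-energy gates and clocks select the allowed events", {
  expect_equal(eligible_events("epithelial", 0.02, 6), "divide")
  expect_equal(eligible_events("epithelial", 0.07, 12), "mutate")
  expect_equal(eligible_events("epithelial", 0.12, 12), c("mutate", "die"))
  expect_equal(eligible_events("epithelial", 0.02, 3), character())
  expect_equal(eligible_events("epithelial", 0.02, 6, divisions = 50),
               character())
  expect_equal(eligible_events("cancer", 0.035, 6, divisions = 1e6),
               "divide")
  expect_equal(eligible_events("cancer", 0.045, 6), character())
  expect_equal(eligible_events("cancer", 0.2, 100), character())
  expect_equal(eligible_events("tcell", 0.001, 100), character())
})

test_that("division places the daughter one radius away and resets clocks", {
  p <- model_params()
  cells <- cell_population(0, 0, "epithelial", p, clock = 7, divisions = 3L)
  out <- apply_division(cells, 1L, angle = pi / 4)
  expect_equal(nrow(out), 2L)
  d <- sqrt(diff(out$x)^2 + diff(out$y)^2)
  expect_equal(d, p$R)
  expect_equal(out$clock, c(0, 0))
  expect_equal(out$divisions, c(4L, 4L))
  expect_equal(out$phenotype[2L], "epithelial")
  expect_gt(out$id[2L], out$id[1L])
})

test_that("engulfment clocks accrue within range and reset outside", {
  tc <- list(id = 1L, x = 0, y = 0)
  cc <- list(id = 2L, x = 3.0, y = 0)
  none <- data.frame(tid = integer(), cid = integer(), clock = numeric())
  # 3.0 um is inside the strong kill distance (3.5) ...
  r1 <- update_immune_interactions(tc, cc, none, "strong", 0.1, th)
  expect_equal(nrow(r1$pair_clocks), 1L)
  expect_equal(r1$pair_clocks$clock, 0.1)
  # ... accrues across steps ...
  r2 <- update_immune_interactions(tc, cc, r1$pair_clocks, "strong", 0.1, th)
  expect_equal(r2$pair_clocks$clock, 0.2)
  # ... but is outside the weak kill distance (2.5), so no clock exists
  r3 <- update_immune_interactions(tc, cc, none, "weak", 0.1, th)
  expect_equal(nrow(r3$pair_clocks), 0L)
  # separation resets: far pair drops any carried clock
  far <- list(id = 2L, x = 30, y = 0)
  r4 <- update_immune_interactions(tc, far, r2$pair_clocks, "strong", 0.1, th)
  expect_equal(nrow(r4$pair_clocks), 0L)
})

test_that("no kill fires before the dwell time is reached", {
  tc <- list(id = 1L, x = 0, y = 0)
  cc <- list(id = 2L, x = 3.0, y = 0)
  carried <- data.frame(tid = 1L, cid = 2L, clock = th$kill_time_strong - 0.2)
  withr::with_seed(1, {
    r <- update_immune_interactions(tc, cc, carried, "strong", 0.1, th)
  })
  expect_length(r$killed, 0L)
  # once ripe the kill fires with high probability per step
  carried$clock <- th$kill_time_strong
  hits <- 0L
  withr::with_seed(2, {
    for (i in 1:50) {
      r <- update_immune_interactions(tc, cc, carried, "strong", 0.1, th)
      hits <- hits + length(r$killed)
    }
  })
  expect_gt(hits / 50, 0.4)  # nominal rate 0.632
  expect_lt(hits / 50, 0.9)
})

test_that("immunity none disables all engulfment bookkeeping", {
  tc <- list(id = 1L, x = 0, y = 0)
  cc <- list(id = 2L, x = 0.5, y = 0)
  none <- data.frame(tid = integer(), cid = integer(), clock = numeric())
  r <- update_immune_interactions(tc, cc, none, "none", 0.1, th)
  expect_equal(nrow(r$pair_clocks), 0L)
  expect_length(r$killed, 0L)
})

test_that("threshold table validates the strictness ordering", {
  expect_error(event_thresholds(kill_distance_weak = 4), "stricter")
  expect_error(event_thresholds(tau_div = -1), "non-negative")
})
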