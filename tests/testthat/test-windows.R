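test_that("a constant series yields the earliest minimal window", {
  day <- seq(0, 20, by = 2)
  w <- detect_pre_response(day, rep(4.2, length(day)), bounds = c(0, 20))
  expect_equal(w$start_day, 0)
  expect_equal(w$end_day, 2)
  expect_equal(w$c0, 4.2)
  expect_equal(w$variance, 0)
})

test_that("an embedded flat plateau is selected over fluctuating values", {
  day <- seq(0, 18, by = 2)
  value <- c(9, 2, 7.0, 7.0, 7.0, 3, 11, 5, 8, 1)
  w <- detect_pre_response(day, value, bounds = c(0, 18))
  # both 2- and 3-sample windows on the plateau have zero variance;
  # ties break to the earliest start, then the shortest window
  expect_equal(w$start_day, 4)
  expect_equal(w$end_day, 6)
  expect_equal(w$c0, 7)
  o <- oracle_min_var_window(day, value, c(0, 18))
  expect_equal(w[c("start_day", "end_day", "c0", "variance")],
               o[c("start_day", "end_day", "c0", "variance")])
})

test_that("window search agrees with brute-force enumeration", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(5:25, 1)
    day <- sort(sample(0:60, n))
    value <- exp(rnorm(n, 2, 1))
    w <- detect_pre_response(day, value, bounds = range(day))
    o <- oracle_min_var_window(day, value, range(day))
    expect_equal(w$start_day, o$start_day)
    expect_equal(w$end_day, o$end_day)
    expect_equal(w$c0, o$c0, tolerance = 1e-12)
    expect_equal(w$variance, o$variance, tolerance = 1e-10)
  }
})

test_that("window constraints require enough samples and span", {
  expect_error(detect_pre_response(c(0, 2), c(1, 2), bounds = c(0, 1)),
               class = "presspulse_invalid")
  # two samples only one day apart cannot span 3 calendar days
  expect_error(detect_pre_response(c(0, 1), c(1, 2), bounds = c(0, 1),
                                   min_span_days = 3),
               class = "presspulse_invalid")
  # but two samples two days apart span 3 days inclusive
  w <- detect_pre_response(c(0, 2), c(1, 2), bounds = c(0, 2))
  expect_equal(w$n_points, 2)
})

test_that("segmentation extracts one chained window per cycle", {
  # synthetic replicate: flat baseline, clean peaks, settled tails
  day <- seq(0, 104, by = 2)
  base <- rep(10, length(day))
  bump <- function(t0, amp, day) {
    tau <- pmax(0, day - t0)
    amp * (tau / 6)^2 * exp(2 * (1 - tau / 6))
  }
  value <- base + bump(4, 80, day) + bump(40, 30, day) + bump(68, 45, day)
  w <- segment_cycles(day, value, c(4, 40, 68))
  expect_equal(nrow(w), 3)
  expect_equal(w$cycle, 1:3)
  # chaining identity: post-event of p equals pre-response of p+1 exactly
  expect_identical(w$dx_level[1], w$c0[2])
  expect_identical(w$dx_level[2], w$c0[3])
  expect_identical(w$dx_start_day[1], w$c0_start_day[2])
  expect_identical(w$dx_end_day[2], w$c0_end_day[3])
  # peaks in the right place and windows inside the span
  expect_equal(w$peak_day, c(10, 46, 74))
  expect_true(all(w$c0_start_day >= 0 & w$dx_end_day <= 104))
  expect_true(all(w$recovered))
})

test_that("a single pulse with monotone decay recovers to its baseline", {
  day <- seq(0, 50, by = 2)
  tau <- pmax(0, day - 6)
  value <- 8 + 60 * (tau / 5)^2 * exp(2 * (1 - tau / 5))
  w <- segment_cycles(day, value, pulse_days = 6)
  expect_equal(nrow(w), 1)
  expect_equal(w$dx_level, w$c0, tolerance = 0.05)
  expect_true(w$recovered)
})

test_that("a series still rising at the end is flagged unrecovered", {
  day <- seq(0, 50, by = 2)
  value <- 8 + ifelse(day > 6, (day - 6)^1.8, 0)
  w <- segment_cycles(day, value, pulse_days = 6)
  expect_false(w$recovered)
})

test_that("windows are scale-equivariant", {
  set.seed(9)
  day <- seq(0, 104, by = 2)
  value <- exp(rnorm(length(day), 2, 0.3)) +
    40 * exp(-((day - 12) / 6)^2) + 25 * exp(-((day - 50) / 6)^2) +
    30 * exp(-((day - 78) / 6)^2)
  w1 <- segment_cycles(day, value, c(4, 40, 68))
  k <- 7.3
  w2 <- segment_cycles(day, k * value, c(4, 40, 68))
  expect_equal(w2$c0_start_day, w1$c0_start_day)
  expect_equal(w2$c0_end_day, w1$c0_end_day)
  expect_equal(w2$peak_day, w1$peak_day)
  expect_equal(w2$c0, k * w1$c0)
  expect_equal(w2$peak_value, k * w1$peak_value)
  expect_equal(w2$dx_level, k * w1$dx_level)
})

test_that("segmentation validates pulses and sample coverage", {
  day <- seq(0, 20, by = 2)
  value <- rnorm(length(day), 10)
  expect_error(segment_cycles(day, value, c(30)),
               class = "presspulse_invalid")
  expect_error(segment_cycles(day, value, c(10, 4)),
               class = "presspulse_invalid")
  expect_error(segment_cycles(day, value, 20),
               class = "presspulse_invalid")
})

test_that("segment_experiment emits one row per replicate and cycle", {
  d <- tiny_design()
  ts <- simulate_experiment(d, quiet_params(seed = 5))
  w <- segment_experiment(ts, d)
  expect_equal(nrow(w), 4 * 2)  # 4 replicates x 2 cycles
  expect_setequal(unique(w$replicate), unique(ts$replicate))
  # pre-response of the simulated cycle sits before the response onset
  first <- subset(w, replicate == "control_1" & cycle == 1)
  expect_lt(first$c0_end_day, first$peak_day)
  # equilibrium start: pre-response level equals the carrying capacity
  expect_equal(first$c0, 12, tolerance = 0.02)
})
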