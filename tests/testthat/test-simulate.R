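test_that("apply_pulse moves exactly the killed fraction to the dead pool", {
  s <- list(p_biomass = 10, p_dissolved = 2, p_dead = 1)
  expect_identical(apply_pulse(s, 0), s)
  full <- apply_pulse(s, 1)
  expect_identical(full$p_biomass, 0)
  expect_identical(full$p_dead, 11)
  expect_identical(full$p_dissolved, 2)
  part <- apply_pulse(s, 0.3)
  expect_equal(part$p_biomass, 7)
  expect_equal(part$p_dead, 1 + 3)
  # nitrogen pools follow when present; vector states work elementwise
  sv <- list(p_biomass = c(10, 4), p_dissolved = c(0, 0), p_dead = c(0, 1),
             n_biomass = c(72, 28.8), n_dissolved = c(5, 5), n_dead = c(0, 0))
  pv <- apply_pulse(sv, 0.5)
  expect_equal(pv$p_biomass, c(5, 2))
  expect_equal(pv$n_dead, c(36, 14.4))
  expect_error(apply_pulse(s, 1.2), class = "presspulse_invalid")
  expect_error(apply_pulse(list(p_biomass = 1), 0.5),
               class = "presspulse_invalid")
})

test_that("identical seeds reproduce output; different seeds differ", {
  d <- tiny_design()
  a <- simulate_experiment(d, simulation_params(seed = 3))
  b <- simulate_experiment(d, simulation_params(seed = 3))
  c <- simulate_experiment(d, simulation_params(seed = 4))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$chl_total, c$chl_total)))
})

test_that("the pulse-free limit follows the logistic closed form", {
  d <- experiment_design(treatments = "control",
                         tp_targets = list(control = NULL),
                         n_replicates = 1, duration_days = 60,
                         pulse_days = c(4, 30),
                         pulse_fractions = c(0, 0))
  p <- quiet_params(seed = 1, initial_biomass_frac = 0.3)
  ts <- simulate_experiment(d, p, return_state = TRUE)
  b0 <- 0.3 * p$base_K
  expected <- logistic_closed_form(ts$day, b0, p$growth_rate, p$base_K)
  expect_equal(ts$chl_total, expected, tolerance = 0.02)
})

test_that("a pure mortality pulse halves chlorophyll with growth disabled", {
  d <- experiment_design(treatments = "control",
                         tp_targets = list(control = NULL),
                         n_replicates = 1, duration_days = 20,
                         pulse_days = 8, pulse_fractions = 0.5)
  p <- quiet_params(seed = 1, growth_rate = 0, remineralization_rate = 0,
                    resp_amplitude = 0)
  ts <- simulate_experiment(d, p)
  before <- ts$chl_total[ts$day == 8]   # sampled before the pulse
  after <- ts$chl_total[ts$day > 8]
  expect_equal(after, rep(0.5 * before, length(after)))
})

test_that("total phosphorus is conserved in a closed configuration", {
  d <- experiment_design(treatments = "control",
                         tp_targets = list(control = NULL),
                         n_replicates = 2, duration_days = 80,
                         pulse_days = c(6, 40),
                         pulse_fractions = c(0.5, 0.3))
  p <- quiet_params(seed = 2)
  ts <- simulate_experiment(d, p, return_state = TRUE)
  total_p <- ts$p_biomass + ts$p_dissolved + ts$p_dead
  expect_equal(total_p, rep(d$initial_tp * 1000, nrow(ts)),
               tolerance = 1e-10)
  # nitrogen mass balance holds too (biomass N is quota-bound)
  total_n <- ts$p_biomass * p$n_to_p_mass + ts$n_dissolved + ts$n_dead
  expect_equal(total_n,
               rep(p$initial_din + ts$p_biomass[1] * p$n_to_p_mass, nrow(ts)),
               tolerance = 1e-10)
})

test_that("all emitted concentrations are non-negative", {
  d <- tiny_design()
  for (s in 1:3) {
    ts <- simulate_experiment(d, simulation_params(seed = s, noise_cv = 0.4))
    num <- c("chl_total", "chl_cyano", "chl_green", "chl_diatom",
             "po4", "din", "biovolume")
    for (cl in num) expect_true(all(ts[[cl]] >= 0))
  }
})

test_that("raising the enrichment multiplier raises enriched peaks only", {
  d <- tiny_design()
  lo <- simulate_experiment(d, quiet_params(seed = 1,
                                            eutro_displacement_multiplier = 1.5))
  hi <- simulate_experiment(d, quiet_params(seed = 1,
                                            eutro_displacement_multiplier = 3))
  for (tr in c("control", "enriched")) {
    w_lo <- segment_experiment(lo[lo$treatment == tr, ], d)
    w_hi <- segment_experiment(hi[hi$treatment == tr, ], d)
    if (tr == "control") {
      expect_equal(w_hi$peak_value, w_lo$peak_value)
    } else {
      expect_true(all(w_hi$peak_value >= w_lo$peak_value - 1e-9))
      expect_gt(max(w_hi$peak_value - w_lo$peak_value), 0)
    }
  }
})

test_that("enrichment roughly doubles absolute displacement but not c0 share", {
  # structural sanity of the generator on the full design, noise off
  d <- experiment_design()
  ts <- simulate_experiment(d, quiet_params(seed = 1))
  m <- compute_metrics(segment_experiment(ts, d), d)
  by_cycle <- aggregate(d0 ~ cycle + (treatment == "control"), m, mean)
  names(by_cycle)[2] <- "is_control"
  for (cy in 2:3) {
    r <- by_cycle$d0[by_cycle$cycle == cy & !by_cycle$is_control] /
      by_cycle$d0[by_cycle$cycle == cy & by_cycle$is_control]
    expect_equal(r, 2, tolerance = 0.15)
  }
})

test_that("simulation parameters are validated", {
  expect_error(simulation_params(growth_rate = -0.1),
               class = "presspulse_invalid")
  expect_error(simulation_params(chl_yield = 0),
               class = "presspulse_invalid")
  expect_error(simulation_params(noise_cv = NA),
               class = "presspulse_invalid")
  expect_error(experiment_design(pulse_days = c(10, 5),
                                 pulse_fractions = c(0.1, 0.1)),
               class = "presspulse_invalid")
  expect_error(experiment_design(pulse_days = 4, pulse_fractions = 1.4),
               class = "presspulse_invalid")
})
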