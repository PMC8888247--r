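test_that("cycle averages match hand-computed period means", {
  ts <- data.frame(
    day = rep(c(0, 2, 4, 6, 8, 10), 2),
    treatment = "t1",
    replicate = rep(c("r1", "r2"), each = 6),
    chl_total = 1,
    biovolume = c(1, 2, 3, 4, 5, 6,  10, 20, 30, 40, 50, 60)
  )
  out <- cycle_average_biovolume(ts, pulse_days = c(4, 8))
  expect_equal(nrow(out), 2 * 3)  # 2 replicates x (Baseline, P1, P2)
  r1 <- out[out$replicate == "r1", ]
  # day 4 and day 8 samples precede their pulses, so they close the
  # previous period: Baseline = days 0-4, P1 = days 6-8, P2 = day 10
  expect_equal(r1$mean_biovolume[r1$period == "Baseline"], mean(c(1, 2, 3)))
  expect_equal(r1$mean_biovolume[r1$period == "P1"], mean(c(4, 5)))
  expect_equal(r1$mean_biovolume[r1$period == "P2"], 6)
  # constant series: every mean equals the constant
  ts$biovolume <- 7
  out2 <- cycle_average_biovolume(ts, c(4, 8))
  expect_true(all(out2$mean_biovolume == 7))
})

test_that("the full study layout yields 72 period averages", {
  d <- experiment_design()
  ts <- simulate_experiment(d, simulation_params(seed = 1))
  out <- cycle_average_biovolume(ts, d)
  expect_equal(nrow(out), 3 * 6 * 4)
  expect_equal(sum(out$n_samples), nrow(ts))
})

test_that("total biovolume averages counts then sums bins", {
  expect_equal(total_biovolume(rep(0, 300)), 0)
  one <- rep(0, 300); one[37] <- 5.5
  expect_equal(total_biovolume(one), 5.5)
  set.seed(8)
  counts <- matrix(rexp(3 * 300), nrow = 3)
  # brute-force oracle: mean of the three counts, then plain sum
  expect_equal(total_biovolume(counts), sum(apply(counts, 2, mean)))
  expect_equal(total_biovolume(counts),
               total_biovolume(colMeans(counts)))
  expect_error(total_biovolume(c(-1, 2)), class = "presspulse_invalid")
})

test_that("noiseless chl~biovolume regression recovers the generating law", {
  set.seed(21)
  bio <- runif(90, 1e5, 5e6)
  treatment <- rep(c("control", "mid", "strong"), each = 30)
  slope <- c(control = 4e-6, mid = 6e-6, strong = 6e-6)
  chl <- 2 + slope[treatment] * bio
  d <- data.frame(chl_total = chl, biovolume = bio, treatment = treatment)
  fit <- fit_chl_biovolume(d, log10_transform = "never")
  expect_equal(unname(fit$slopes), unname(slope[names(fit$slopes)]),
               tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("the treatment interaction recovers a known slope difference", {
  set.seed(22)
  n <- 120
  bio <- runif(2 * n, 1e5, 5e6)
  treatment <- rep(c("control", "enriched"), each = n)
  delta <- 2e-6
  chl <- 2 + 4e-6 * bio + delta * bio * (treatment == "enriched") +
    rnorm(2 * n, 0, 1.5)
  d <- data.frame(chl_total = chl, biovolume = bio, treatment = treatment)
  fit <- fit_chl_biovolume(d, log10_transform = "never")
  est <- fit$slopes[["enriched"]] - fit$slopes[["control"]]
  se_int <- summary(fit$model)$coefficients["biovolume:treatmentenriched",
                                            "Std. Error"]
  expect_lt(abs(est - delta), 3 * se_int)
  expect_lt(fit$interaction_p, 0.05)
})

test_that("the interaction p-value is null-calibrated under label permutation", {
  set.seed(23)
  pvals <- replicate(60, {
    bio <- runif(60, 1e5, 5e6)
    chl <- 2 + 4e-6 * bio + rnorm(60, 0, 2)
    treatment <- sample(rep(c("a", "b"), each = 30))
    fit <- fit_chl_biovolume(data.frame(chl_total = chl, biovolume = bio,
                                        treatment = treatment),
                             log10_transform = "never")
    fit$interaction_p
  })
  # roughly uniform: mean near 0.5, no pile-up below .05
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals < 0.05), 0.2)
})

test_that("metric trends need at least two cycles", {
  m <- data.frame(replicate = c("a", "b"), treatment = c("x", "y"),
                  cycle = c(1, 1), pulse_intensity = 0.5,
                  c0 = c(1, 2), d0 = c(1, 2),
                  rs_scaled = c(5, 6), rc_scaled = c(5, 6))
  expect_error(fit_metric_trends(m), class = "presspulse_invalid")
})

test_that("metric trends recover built-in generator effects", {
  d <- experiment_design()
  ts <- simulate_experiment(d, simulation_params(seed = 11))
  m <- compute_metrics(segment_experiment(ts, d), d)
  tr <- fit_metric_trends(m)
  eff <- tr$effects
  # rising baselines: strong perturbation-count effect on pre-response C0
  expect_lt(eff$p_value[eff$metric == "c0" & eff$term == "n_perturbations"],
            0.01)
  # enrichment raises absolute displacement
  expect_lt(eff$p_value[eff$metric == "d0" & eff$term == "eutrophication"],
            0.05)
  # but not relative resistance
  expect_gt(eff$p_value[eff$metric == "rs_scaled" &
                          eff$term == "eutrophication"], 0.05)
  # displacement fold-change near the built-in multiplier
  expect_gt(estimate_displacement_ratio(m), 1.4)
  expect_lt(estimate_displacement_ratio(m), 2.6)
  # variance decomposition is coherent on every fit
  expect_true(all(eff$marginal_r2 >= 0 & eff$marginal_r2 <= 1))
  expect_true(all(eff$marginal_r2 <= eff$conditional_r2 + 1e-12))
})

test_that("a declining recovery trend is detected with the correct sign", {
  # enrichment off isolates the sequential-perturbation effect
  d <- experiment_design()
  hits <- 0
  for (s in 1:10) {
    ts <- simulate_experiment(d, simulation_params(
      seed = s, eutro_displacement_multiplier = 1,
      recovery_loss_per_cycle = 0.2))
    m <- compute_metrics(segment_experiment(ts, d), d)
    eff <- fit_metric_trends(m, metric_cols = "rc_scaled")$effects
    est <- eff$estimate[eff$term == "n_perturbations"]
    p <- eff$p_value[eff$term == "n_perturbations"]
    if (est < 0 && p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("permutation p-values broadly agree with parametric ones", {
  d <- experiment_design()
  ts <- simulate_experiment(d, simulation_params(seed = 2))
  m <- compute_metrics(segment_experiment(ts, d), d)
  par_p <- fit_metric_trends(m, metric_cols = "c0")$effects
  perm_p <- fit_metric_trends(m, metric_cols = "c0",
                              pvalues = "permutation",
                              n_permutations = 99, seed = 1)$effects
  # the strong c0 trend must be extreme under both calibrations
  expect_lt(perm_p$p_value[perm_p$term == "n_perturbations"], 0.05)
  expect_lt(par_p$p_value[par_p$term == "n_perturbations"], 0.01)
})
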