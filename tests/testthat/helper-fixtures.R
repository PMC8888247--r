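# shared fixtures and independent oracles

# small design for fast end-to-end tests
tiny_design <- function(...) {
  experiment_design(
    treatments = c("control", "enriched"),
    tp_targets = list(control = NULL, enriched = c(0.2, 0.4)),
    n_replicates = 2,
    duration_days = 60,
    sampling_interval_days = 2,
    pulse_days = c(4, 30),
    pulse_fractions = c(0.5, 0.3),
    ...
  )
}

quiet_params <- function(...) {
  simulation_params(noise_cv = 0, replicate_cv = 0, ...)
}

# independent brute-force oracle for the least-variance window search:
# plain enumeration with stats::var, no incremental arithmetic
oracle_min_var_window <- function(day, value, bounds,
                                  min_points = 2, min_span_days = 3) {
  keep <- day >= bounds[1] & day <= bounds[2]
  d <- day[keep]; v <- value[keep]
  best <- NULL
  for (i in seq_along(d)) {
    for (j in seq_along(d)) {
      if (j <= i) next
      if (j - i + 1 < min_points) next
      if (d[j] - d[i] + 1 < min_span_days) next
      vr <- stats::var(v[i:j])
      if (is.null(best) || vr < best$variance - 1e-12 * (1 + best$variance))
        best <- list(start_day = d[i], end_day = d[j],
                     c0 = mean(v[i:j]), variance = vr, n_points = j - i + 1)
    }
  }
  best
}

# logistic closed form used as integrator oracle
logistic_closed_form <- function(t, b0, r, k) {
  k * b0 * exp(r * t) / (k + b0 * (exp(r * t) - 1))
}
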