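#' Parameters of the synthetic mesocosm generator
#'
#' Collects every rate, yield and effect-size parameter governing
#' [simulate_experiment()]. The generator couples a mechanistic phosphorus
#' -quota logistic core (biomass, dissolved and dead-organic P pools, plus
#' parallel nitrogen pools) with phenomenological response modifiers that
#' impose the community-level dynamics the analysis pipeline is built to
#' detect: transient post-pulse chlorophyll peaks, per-cycle resistance
#' hardening, retained displacement (incomplete recovery) and a press-driven
#' amplification of the absolute response in enriched treatments.
#'
#' @param growth_rate intrinsic per-day chlorophyll-a growth rate.
#' @param chl_yield micrograms of chlorophyll-a fixable per microgram of
#'   dissolved phosphorus (the P quota).
#' @param base_K light-limited chlorophyll-a carrying capacity (ug/L); the
#'   realised capacity is the minimum of this ceiling and the P-derived
#'   capacity `chl_yield * accessible P`.
#' @param remineralization_rate per-day fraction of dead-organic-pool
#'   phosphorus (and nitrogen) returned to the dissolved pool.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   observation noise (0 disables noise).
#' @param replicate_cv coefficient of variation of the fixed per-replicate
#'   lognormal scale factor applied to chlorophyll and biovolume.
#' @param hardening_per_cycle multiplicative damping of the relative pulse
#'   response per completed pulse (1 = no hardening; values < 1 make the
#'   community progressively less responsive, i.e. more resistant).
#' @param recovery_loss_per_cycle per-cycle increment of the fraction of the
#'   transient displacement retained at the post-event state (0 = full
#'   recovery after every pulse). The retained fraction for cycle p is
#'   `min(0.95, recovery_loss_per_cycle * p)`.
#' @param eutro_displacement_multiplier multiplier on the absolute pulse
#'   response amplitude reached by enriched treatments once the press
#'   perturbation has taken effect (1 = enrichment changes nothing).
#' @param resp_amplitude relative chlorophyll displacement of the first
#'   pulse response per unit kill fraction (peak ~ C0 * (1 +
#'   resp_amplitude * fraction) before hardening).
#' @param resp_rise_days timescale (days) of the transient response shape;
#'   the post-pulse peak occurs roughly this many days after the pulse.
#' @param retention_delay_days delay (days) before retained displacement
#'   starts to accrue, keeping the transient peak and the new baseline
#'   separated in time.
#' @param retention_rate_days e-folding time (days) of retained-displacement
#'   accrual after the delay.
#' @param press_delay_days delay (days) between the first dosing and the
#'   onset of the press-driven capacity gain in enriched treatments.
#' @param press_rate_days e-folding time (days) of the press gain ramp.
#' @param n_to_p_mass nitrogen:phosphorus mass ratio of biomass (7.2 is the
#'   Redfield mass ratio).
#' @param initial_din initial dissolved inorganic nitrogen (ug N/L).
#' @param biovolume_per_chl total microbial biovolume (um^3/ml) per ug/L of
#'   chlorophyll-a.
#' @param chl_fractions named numeric vector summing to 1 giving the split
#'   of total chlorophyll-a into the cyanobacteria/green/diatom channels;
#'   `NULL` uses a fixed default split.
#' @param initial_biomass_frac starting chlorophyll-a as a fraction of the
#'   initial carrying capacity; 1 (the default) starts the community at
#'   equilibrium, as after an acclimation period.
#' @param steps_per_day Euler integration sub-steps per day.
#' @param seed integer RNG seed; identical seeds give identical output.
#'
#' @return An object of class `pp_sim_params`.
#' @examples
#' p <- simulation_params(noise_cv = 0, seed = 42)
#' p$growth_rate
#' @export
simulation_params <- function(growth_rate = 0.5,
                              chl_yield = 1.0,
                              base_K = 12,
                              remineralization_rate = 0.5,
                              noise_cv = 0.12,
                              replicate_cv = 0.08,
                              hardening_per_cycle = 0.8,
                              recovery_loss_per_cycle = 0.15,
                              eutro_displacement_multiplier = 2,
                              resp_amplitude = 16,
                              resp_rise_days = 6,
                              retention_delay_days = 14,
                              retention_rate_days = 6,
                              press_delay_days = 14,
                              press_rate_days = 2,
                              n_to_p_mass = 7.2,
                              initial_din = 250,
                              biovolume_per_chl = 2.5e5,
                              chl_fractions = NULL,
                              initial_biomass_frac = 1,
                              steps_per_day = 20,
                              seed = 1L) {
  check_finite_scalar(growth_rate, "growth_rate", min = 0)
  check_finite_scalar(chl_yield, "chl_yield")
  if (chl_yield <= 0) pp_stop_invalid("`chl_yield` must be > 0")
  check_finite_scalar(base_K, "base_K", min = 0)
  check_finite_scalar(remineralization_rate, "remineralization_rate", min = 0)
  check_finite_scalar(noise_cv, "noise_cv", min = 0)
  check_finite_scalar(replicate_cv, "replicate_cv", min = 0)
  check_finite_scalar(hardening_per_cycle, "hardening_per_cycle", min = 0)
  check_finite_scalar(recovery_loss_per_cycle, "recovery_loss_per_cycle", min = 0)
  check_finite_scalar(eutro_displacement_multiplier,
                      "eutro_displacement_multiplier", min = 0)
  check_finite_scalar(resp_amplitude, "resp_amplitude", min = 0)
  check_finite_scalar(resp_rise_days, "resp_rise_days", min = 0)
  check_finite_scalar(retention_delay_days, "retention_delay_days", min = 0)
  check_finite_scalar(retention_rate_days, "retention_rate_days", min = 0)
  check_finite_scalar(press_delay_days, "press_delay_days", min = 0)
  check_finite_scalar(press_rate_days, "press_rate_days", min = 0)
  check_finite_scalar(n_to_p_mass, "n_to_p_mass", min = 0)
  check_finite_scalar(initial_din, "initial_din", min = 0)
  check_finite_scalar(biovolume_per_chl, "biovolume_per_chl", min = 0)
  check_finite_scalar(initial_biomass_frac, "initial_biomass_frac", min = 0)
  if (initial_biomass_frac > 1)
    pp_stop_invalid("`initial_biomass_frac` must be <= 1")
  check_finite_scalar(steps_per_day, "steps_per_day", min = 1)
  check_finite_scalar(seed, "seed")

  if (is.null(chl_fractions))
    chl_fractions <- c(cyano = 0.2, green = 0.5, diatom = 0.3)
  if (!is.numeric(chl_fractions) || length(chl_fractions) != 3L ||
      any(chl_fractions < 0) || abs(sum(chl_fractions) - 1) > 1e-8 ||
      !setequal(names(chl_fractions), c("cyano", "green", "diatom")))
    pp_stop_invalid(
      "`chl_fractions` must be named (cyano, green, diatom) and sum to 1")

  structure(list(
    growth_rate = growth_rate, chl_yield = chl_yield, base_K = base_K,
    remineralization_rate = remineralization_rate, noise_cv = noise_cv,
    replicate_cv = replicate_cv,
    hardening_per_cycle = hardening_per_cycle,
    recovery_loss_per_cycle = recovery_loss_per_cycle,
    eutro_displacement_multiplier = eutro_displacement_multiplier,
    resp_amplitude = resp_amplitude, resp_rise_days = resp_rise_days,
    retention_delay_days = retention_delay_days,
    retention_rate_days = retention_rate_days,
    press_delay_days = press_delay_days, press_rate_days = press_rate_days,
    n_to_p_mass = n_to_p_mass, initial_din = initial_din,
    biovolume_per_chl = biovolume_per_chl,
    chl_fractions = chl_fractions[c("cyano", "green", "diatom")],
    initial_biomass_frac = initial_biomass_frac,
    steps_per_day = as.integer(steps_per_day),
    seed = as.integer(seed)
  ), class = "pp_sim_params")
}

#' @export
print.pp_sim_params <- function(x, ...) {
  cat("Mesocosm simulation parameters\n")
  cat(sprintf("  growth %.3g/d, yield %.3g ug chl / ug P, base K %.3g ug/L\n",
              x$growth_rate, x$chl_yield, x$base_K))
  cat(sprintf("  remineralization %.3g/d, noise cv %.3g, replicate cv %.3g\n",
              x$remineralization_rate, x$noise_cv, x$replicate_cv))
  cat(sprintf("  response amplitude %.3g per kill fraction, hardening %.3g/cycle\n",
              x$resp_amplitude, x$hardening_per_cycle))
  cat(sprintf("  recovery loss %.3g/cycle, enrichment multiplier %.3g\n",
              x$recovery_loss_per_cycle, x$eutro_displacement_multiplier))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
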