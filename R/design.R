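#' Describe a press-pulse mesocosm experiment
#'
#' An experiment design holds the layout of a press-pulse mesocosm study:
#' which treatments exist and their phosphorus dosing targets, how many
#' replicate mesocosms each treatment has, the sampling cadence, and the
#' pulse (mortality) schedule with per-cycle intensities.
#'
#' The defaults reproduce the layout of the study the package models:
#' a control plus two enrichment treatments with six replicates each
#' (N = 18), 105 days sampled every other day (53 sampling days, day 0
#' being the first sample), three pulse perturbations at days 4, 40 and 68
#' with volume fractions 50%, 15% and 30%, and stepwise total-phosphorus
#' (TP) dosing toward 0.41 mg/L (mid-strong) and 0.82 mg/L (strong).
#'
#' @param treatments character vector of treatment labels. The first label
#'   is taken as the unenriched reference (control) when fitting effects.
#' @param tp_targets named list, one element per treatment: either `NULL`
#'   (no dosing) or a numeric vector of per-cycle TP targets (mg/L), one
#'   per pulse day. Dosing is applied immediately after each pulse.
#' @param n_replicates replicate mesocosms per treatment.
#' @param duration_days experiment length in days; observations span days
#'   `0 ... duration_days - 1`.
#' @param sampling_interval_days cadence of observations in days.
#' @param pulse_days strictly increasing vector of pulse-application days.
#' @param pulse_fractions volume fraction (0-1) of each mesocosm subjected
#'   to the mortality pulse, one per pulse day.
#' @param mesocosm_volume vessel volume in litres.
#' @param refill_tp TP of the refill water (mg/L).
#' @param stock_tp TP of the dosing stock solution (mg/L).
#' @param initial_tp TP at the start of the experiment (mg/L), common to all
#'   treatments.
#'
#' @return An object of class `pp_design`.
#' @examples
#' d <- experiment_design()
#' d$pulse_days
#' @export
experiment_design <- function(treatments = c("control", "mid", "strong"),
                              tp_targets = NULL,
                              n_replicates = 6,
                              duration_days = 105,
                              sampling_interval_days = 2,
                              pulse_days = c(4, 40, 68),
                              pulse_fractions = c(0.5, 0.15, 0.3),
                              mesocosm_volume = 10,
                              refill_tp = 0.012,
                              stock_tp = 40,
                              initial_tp = 0.012) {
  if (!is.character(treatments) || length(treatments) < 1L ||
      anyDuplicated(treatments))
    pp_stop_invalid("`treatments` must be unique treatment labels")
  check_finite_scalar(n_replicates, "n_replicates", min = 1)
  check_finite_scalar(duration_days, "duration_days", min = 1)
  check_finite_scalar(sampling_interval_days, "sampling_interval_days", min = 1)
  check_finite_scalar(mesocosm_volume, "mesocosm_volume", min = 0)
  check_finite_scalar(refill_tp, "refill_tp", min = 0)
  check_finite_scalar(stock_tp, "stock_tp", min = 0)
  check_finite_scalar(initial_tp, "initial_tp", min = 0)

  if (length(pulse_days) > 0L) {
    if (!is.numeric(pulse_days) || any(!is.finite(pulse_days)))
      pp_stop_invalid("`pulse_days` must be finite numbers")
    if (any(diff(pulse_days) <= 0))
      pp_stop_invalid("`pulse_days` must be strictly increasing")
    if (any(pulse_days < 0) || any(pulse_days >= duration_days))
      pp_stop_invalid("`pulse_days` must lie within the experiment duration")
  }
  if (length(pulse_fractions) != length(pulse_days))
    pp_stop_invalid("`pulse_fractions` must have one entry per pulse day")
  if (length(pulse_fractions) &&
      (any(!is.finite(pulse_fractions)) ||
       any(pulse_fractions < 0) || any(pulse_fractions > 1)))
    pp_stop_invalid("`pulse_fractions` must lie in [0, 1]")

  if (is.null(tp_targets)) {
    tp_targets <- default_tp_targets(treatments, length(pulse_days))
  }
  if (!is.list(tp_targets) || is.null(names(tp_targets)) ||
      !setequal(names(tp_targets), treatments))
    pp_stop_invalid("`tp_targets` must be a named list with one element per treatment")
  for (tr in treatments) {
    tg <- tp_targets[[tr]]
    if (is.null(tg)) next
    if (!is.numeric(tg) || length(tg) != length(pulse_days) ||
        any(!is.finite(tg)) || any(tg < 0))
      pp_stop_invalid(sprintf(
        "`tp_targets$%s` must be NULL or %d non-negative TP targets (mg/L)",
        tr, length(pulse_days)))
  }

  structure(list(
    treatments = treatments,
    tp_targets = tp_targets[treatments],
    n_replicates = as.integer(n_replicates),
    duration_days = as.integer(duration_days),
    sampling_interval_days = as.integer(sampling_interval_days),
    pulse_days = as.numeric(pulse_days),
    pulse_fractions = as.numeric(pulse_fractions),
    mesocosm_volume = mesocosm_volume,
    refill_tp = refill_tp,
    stock_tp = stock_tp,
    initial_tp = initial_tp
  ), class = "pp_design")
}

# Stepwise TP targets: control undosed; enriched treatments step linearly to
# their final TP across the pulse cycles (0.41 and 0.82 mg/L by default).
default_tp_targets <- function(treatments, n_pulses) {
  finals <- c(NA, 0.41, 0.82)
  out <- vector("list", length(treatments))
  names(out) <- treatments
  for (i in seq_along(treatments)) {
    fin <- if (i <= length(finals)) finals[i] else NA
    out[i] <- list(
      if (is.na(fin) || n_pulses == 0L) NULL
      else fin * seq_len(n_pulses) / n_pulses)
  }
  out
}

#' @export
print.pp_design <- function(x, ...) {
  cat("Press-pulse experiment design\n")
  cat(sprintf("  treatments:    %s (x %d replicates)\n",
              paste(x$treatments, collapse = ", "), x$n_replicates))
  cat(sprintf("  duration:      %d days, sampled every %d days\n",
              x$duration_days, x$sampling_interval_days))
  if (length(x$pulse_days))
    cat(sprintf("  pulses:        day %s (fractions %s)\n",
                paste(x$pulse_days, collapse = "/"),
                paste(x$pulse_fractions, collapse = "/")))
  dosed <- names(Filter(Negate(is.null), x$tp_targets))
  if (length(dosed))
    cat(sprintf("  dosed:         %s\n", paste(dosed, collapse = ", ")))
  invisible(x)
}

#' Sampling days of a design
#'
#' @param design a [experiment_design()] object.
#' @return Integer vector of observation days (day 0 = first sample).
#' @export
sampling_days <- function(design) {
  stopifnot(inherits(design, "pp_design"))
  seq(0L, design$duration_days - 1L, by = design$sampling_interval_days)
}

# treatments that receive phosphorus dosing
enriched_treatments <- function(design) {
  names(Filter(Negate(is.null), design$tp_targets))
}
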