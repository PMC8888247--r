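#' Predict mesocosm total phosphorus after a dilution/dosing step
#'
#' Mass-balance dilution of three solutions mixed in one vessel: the water
#' left after sampling (concentration `cc_prev`, volume `vc`), refill water
#' (`cr`, `vr`) and dosing stock (`cs`, `vs`). The resulting concentration
#' is the total P mass divided by the total volume:
#' `(cc_prev*vc + cr*vr + cs*vs) / (vc + vr + vs)`.
#'
#' @param cc_prev TP in the mesocosm before the step (mg/L).
#' @param vc volume left after sampling (L).
#' @param cr refill-water TP (mg/L).
#' @param vr refill volume (L).
#' @param cs stock-solution TP (mg/L).
#' @param vs stock volume added (L).
#' @return Predicted TP (mg/L). Vectorized over all arguments.
#' @examples
#' predict_tp(0.010, 9, 0.010, 0.9, 40, 0.1)  # ~0.41 mg/L
#' @export
predict_tp <- function(cc_prev, vc, cr, vr, cs, vs) {
  args <- list(cc_prev = cc_prev, vc = vc, cr = cr, vr = vr, cs = cs, vs = vs)
  n <- max(lengths(args))
  args <- lapply(args, rep_len, n)
  for (nm in names(args)) {
    if (!is.numeric(args[[nm]]) || any(!is.finite(args[[nm]])))
      pp_stop_invalid(sprintf("`%s` must be finite numeric", nm))
    if (any(args[[nm]] < 0))
      pp_stop_invalid(sprintf("`%s` must be non-negative", nm))
  }
  total <- args$vc + args$vr + args$vs
  if (any(total <= 0))
    pp_stop_invalid("total volume `vc + vr + vs` must be positive")
  (args$cc_prev * args$vc + args$cr * args$vr + args$cs * args$vs) / total
}

#' Solve for the stock volume needed to reach a TP target
#'
#' Inverts [predict_tp()] for the stock volume `vs`, holding the total
#' vessel volume fixed: the refill volume absorbs the slack
#' (`vr = total_volume - vc - vs`), mirroring the use of refill water to
#' top vessels up after sampling.
#'
#' @param target_tp desired TP after the step (mg/L).
#' @param cc_prev TP before the step (mg/L).
#' @param vc volume left after sampling (L).
#' @param cr refill-water TP (mg/L).
#' @param cs stock-solution TP (mg/L).
#' @param total_volume vessel volume (L).
#' @return Stock volume `vs` (L) such that the completed step reproduces
#'   `target_tp`; round-trips with [predict_tp()] to 1e-9 relative.
#'   Targets below the no-dose mixture or above what the stock can reach
#'   raise an infeasibility error (condition class
#'   `presspulse_infeasible`), distinct from invariant violations
#'   (`presspulse_invalid`).
#' @examples
#' solve_dose_volume(0.4099, cc_prev = 0.010, vc = 9, cr = 0.010, cs = 40)
#' @export
solve_dose_volume <- function(target_tp, cc_prev, vc, cr, cs,
                              total_volume = 10) {
  for (nm in c("target_tp", "cc_prev", "vc", "cr", "cs", "total_volume")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      pp_stop_invalid(sprintf("`%s` must be a single non-negative number", nm))
  }
  if (vc > total_volume)
    pp_stop_invalid("`vc` must not exceed `total_volume`")
  if (abs(cs - cr) < 1e-12)
    pp_stop_invalid("stock and refill concentrations must differ to solve")

  vr_max <- total_volume - vc
  # mass balance: cc*vc + cr*(total - vc - vs) + cs*vs = target * total
  vs <- (target_tp * total_volume - cc_prev * vc - cr * vr_max) / (cs - cr)

  lo <- predict_tp(cc_prev, vc, cr, vr_max, cs, 0)
  hi <- predict_tp(cc_prev, vc, cr, 0, cs, vr_max)
  tol <- 1e-12 * max(1, target_tp)
  if (target_tp < min(lo, hi) - tol || target_tp > max(lo, hi) + tol)
    pp_stop_infeasible(sprintf(
      "target %.6g mg/L is outside the achievable range [%.6g, %.6g]",
      target_tp, min(lo, hi), max(lo, hi)))
  min(max(vs, 0), vr_max)
}

#' Thresholds for stoichiometric N:P limitation classification
#'
#' Molar dissolved N:P bands: above `upper` the system is considered
#' P-limited, between `lower` and `upper` (inclusive) co-limited, below
#' `lower` N-limited. Defaults are the Redfield ratio (16:1) and the 25:1
#' boundary commonly used for the onset of P limitation.
#'
#' @param lower lower molar N:P boundary.
#' @param upper upper molar N:P boundary.
#' @return Object of class `pp_limitation_thresholds`.
#' @export
limitation_thresholds <- function(lower = 16, upper = 25) {
  check_finite_scalar(lower, "lower")
  check_finite_scalar(upper, "upper")
  if (!(0 < lower && lower < upper))
    pp_stop_invalid("need 0 < lower < upper")
  structure(list(lower = lower, upper = upper),
            class = "pp_limitation_thresholds")
}

#' Classify nutrient limitation from dissolved N and P
#'
#' Converts mass concentrations to molar (atomic masses N = 14.007,
#' P = 30.974) and classifies the dissolved N:P ratio against
#' [limitation_thresholds()]. Boundary ratios are assigned to the
#' co-limited band.
#'
#' @param din dissolved inorganic nitrogen (ug N/L); vectorized.
#' @param dip dissolved inorganic phosphorus (ug P/L); vectorized.
#' @param thresholds a [limitation_thresholds()] object.
#' @return Character vector with values `"P-limited"`, `"co-limited"` or
#'   `"N-limited"`.
#' @examples
#' classify_limitation(c(450, 280, 140), c(31, 31, 31))
#' @export
classify_limitation <- function(din, dip, thresholds = limitation_thresholds()) {
  stopifnot(inherits(thresholds, "pp_limitation_thresholds"))
  n <- max(length(din), length(dip))
  din <- rep_len(din, n); dip <- rep_len(dip, n)
  if (!is.numeric(din) || !is.numeric(dip) ||
      any(!is.finite(din)) || any(!is.finite(dip)) ||
      any(din <= 0) || any(dip <= 0))
    pp_stop_invalid("`din` and `dip` must be positive and finite")
  ratio <- (din / 14.007) / (dip / 30.974)
  out <- rep("co-limited", n)
  out[ratio > thresholds$upper] <- "P-limited"
  out[ratio < thresholds$lower] <- "N-limited"
  out
}
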