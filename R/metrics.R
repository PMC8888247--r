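#' Maximum displacement of a perturbation cycle
#'
#' Magnitude of the difference between the response peak and the
#' pre-response condition, in chlorophyll-a units. The displacement is a
#' magnitude, so upward (overshoot) and downward excursions are treated
#' alike.
#'
#' @param c0 pre-response condition (ug/L), non-negative.
#' @param peak response peak (ug/L), non-negative.
#' @return `|c0 - peak|` (ug/L). Vectorized.
#' @examples
#' max_displacement(10, 20)  # 10
#' @export
max_displacement <- function(c0, peak) {
  if (any(!is.finite(c0)) || any(!is.finite(peak)) ||
      any(c0 < 0) || any(peak < 0))
    pp_stop_invalid("`c0` and `peak` must be finite and non-negative")
  abs(c0 - peak)
}

#' Resistance index
#'
#' Proportional index of how little a pulse displaced the system relative
#' to its pre-response condition: `RS = 1 - 2*d0 / (c0 + d0)`. RS = 1 means
#' no displacement (maximal resistance); RS = 0 means a 100% change
#' relative to the pre-response condition; RS approaches -1 as the
#' displacement grows without bound. The index is scale-invariant:
#' multiplying `c0` and `d0` by a common factor leaves it unchanged.
#'
#' @param c0 pre-response condition (ug/L).
#' @param d0 maximum displacement (ug/L).
#' @return Resistance index in (-1, 1]. Vectorized.
#' @examples
#' resistance(20, 20)  # 0: a 100% change
#' @export
resistance <- function(c0, d0) {
  if (any(!is.finite(c0)) || any(!is.finite(d0)) ||
      any(c0 < 0) || any(d0 < 0))
    pp_stop_invalid("`c0` and `d0` must be finite and non-negative")
  if (any(c0 + d0 <= 0))
    pp_stop_invalid("`c0 + d0` must be positive")
  1 - 2 * d0 / (c0 + d0)
}

#' Recovery index
#'
#' Engineering-resilience index of how completely the system returned
#' toward its pre-response condition after the peak:
#' `RC = 2*d0 / (d0 + dx) - 1`, where `dx` is the residual displacement of
#' the post-event level from the pre-response condition. RC = 1 means full
#' recovery (`dx = 0`), RC = 0 means no recovery (`dx = d0`), and negative
#' values mean the system drifted beyond its maximum displacement. A cycle
#' with `d0 + dx = 0` was never displaced; it is defined as full recovery
#' (1) with a warning rather than an error so batch processing never
#' aborts.
#'
#' @param d0 maximum displacement (ug/L).
#' @param dx residual displacement at the post-event condition (ug/L).
#' @return Recovery index in (-1, 1]. Vectorized.
#' @examples
#' recovery(10, 10)  # 0: no recovery
#' @export
recovery <- function(d0, dx) {
  if (any(!is.finite(d0)) || any(!is.finite(dx)) ||
      any(d0 < 0) || any(dx < 0))
    pp_stop_invalid("`d0` and `dx` must be finite and non-negative")
  n <- max(length(d0), length(dx))
  d0 <- rep_len(d0, n); dx <- rep_len(dx, n)
  degenerate <- (d0 + dx) == 0
  if (any(degenerate))
    warning("undisplaced cycle(s) (d0 = dx = 0): recovery defined as 1",
            call. = FALSE)
  out <- rep(1, length(degenerate))
  out[!degenerate] <- 2 * d0[!degenerate] / (d0 + dx)[!degenerate] - 1
  out
}

#' Rescale the resistance index to the 0-10 scale
#'
#' Strictly increasing piecewise-linear map of the raw resistance index
#' from \[-1, 1\] onto \[0, 10\] with the anchors: 10 = no change (raw 1),
#' 9 = 100% change (raw 0), 0 = raw -1. The negative branch is expanded so
#' low-resistance values occupy most of the scale.
#'
#' @param rs_raw raw resistance index in \[-1, 1\].
#' @return Rescaled index in \[0, 10\]. Vectorized.
#' @examples
#' rescale_resistance(c(1, 0, -1))  # 10 9 0
#' @export
rescale_resistance <- function(rs_raw) {
  if (any(!is.finite(rs_raw)) || any(rs_raw < -1) || any(rs_raw > 1))
    pp_stop_invalid("`rs_raw` must lie in [-1, 1]")
  ifelse(rs_raw >= 0, 9 + rs_raw, 9 * (1 + rs_raw))
}

#' Rescale the recovery index to the 0-10 scale
#'
#' Strictly increasing piecewise-linear map of the raw recovery index from
#' \[-1, 1\] onto \[0, 10\] with the anchors: 10 = full recovery (raw 1),
#' 1 = no recovery (raw 0), 0 = raw -1. Values below 1 therefore indicate
#' that the system drifted away after the perturbation; the positive branch
#' is expanded so degrees of partial recovery occupy most of the scale.
#'
#' @param rc_raw raw recovery index in \[-1, 1\].
#' @return Rescaled index in \[0, 10\]. Vectorized.
#' @examples
#' rescale_recovery(c(1, 0, -1))  # 10 1 0
#' @export
rescale_recovery <- function(rc_raw) {
  if (any(!is.finite(rc_raw)) || any(rc_raw < -1) || any(rc_raw > 1))
    pp_stop_invalid("`rc_raw` must lie in [-1, 1]")
  ifelse(rc_raw >= 0, 1 + 9 * rc_raw, 1 + rc_raw)
}

#' Compute perturbation metrics from response windows
#'
#' Evaluates maximum displacement, resistance and recovery (raw and
#' rescaled) for every response window produced by
#' [segment_experiment()]/[segment_cycles()], attaching the pulse intensity
#' from the experiment design. The residual displacement is
#' `dx = |dx_level - c0|`. Degenerate cycles (`d0 = dx = 0`) receive
#' `rs_raw = rc_raw = 1` and are flagged in the `degenerate` column rather
#' than erroring.
#'
#' The rescaling maps are injectable so alternative anchored maps can be
#' swapped in without touching callers.
#'
#' @param windows data.frame of response windows (one row per replicate x
#'   cycle) with at least `cycle`, `c0`, `peak_value`, `dx_level`;
#'   `treatment`, `replicate` and `recovered` are carried through when
#'   present.
#' @param design an [experiment_design()] supplying per-cycle pulse
#'   intensities, or `NULL` to omit them.
#' @param rescale_rs,rescale_rc rescaling functions for the two indices.
#' @return data.frame with one row per window: identifiers, `c0`, `peak`,
#'   `d0`, `dx`, `rs_raw`, `rc_raw`, `rs_scaled`, `rc_scaled`,
#'   `pulse_intensity`, `degenerate`.
#' @export
compute_metrics <- function(windows, design = NULL,
                            rescale_rs = rescale_resistance,
                            rescale_rc = rescale_recovery) {
  req <- c("cycle", "c0", "peak_value", "dx_level")
  missing_cols <- setdiff(req, names(windows))
  if (length(missing_cols))
    pp_stop_schema(paste0("`windows` is missing column(s): ",
                          paste(missing_cols, collapse = ", ")))

  d0 <- max_displacement(windows$c0, windows$peak_value)
  dx <- abs(windows$dx_level - windows$c0)
  degenerate <- (windows$c0 + d0 <= 0) | (d0 + dx <= 0)

  rs_raw <- rep(1, nrow(windows))
  ok <- windows$c0 + d0 > 0
  rs_raw[ok] <- resistance(windows$c0[ok], d0[ok])
  rc_raw <- rep(1, nrow(windows))
  ok <- d0 + dx > 0
  rc_raw[ok] <- recovery(d0[ok], dx[ok])

  pulse_intensity <- NA_real_
  if (!is.null(design)) {
    stopifnot(inherits(design, "pp_design"))
    if (any(!(windows$cycle %in% seq_along(design$pulse_fractions))))
      pp_stop_invalid("window cycle missing from the design's pulse schedule")
    pulse_intensity <- design$pulse_fractions[windows$cycle]
  }

  out <- data.frame(
    cycle = windows$cycle,
    c0 = windows$c0,
    peak = windows$peak_value,
    d0 = d0,
    dx = dx,
    rs_raw = rs_raw,
    rc_raw = rc_raw,
    rs_scaled = rescale_rs(pmax(-1, pmin(1, rs_raw))),
    rc_scaled = rescale_rc(pmax(-1, pmin(1, rc_raw))),
    pulse_intensity = pulse_intensity,
    degenerate = degenerate
  )
  for (id in c("replicate", "treatment", "recovered"))
    if (!is.null(windows[[id]])) out[[id]] <- windows[[id]]
  nid <- intersect(c("treatment", "replicate"), names(out))
  out[, c(nid, setdiff(names(out), nid))]
}
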