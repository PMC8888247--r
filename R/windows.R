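# centered moving average over an inclusive calendar span (days); each
# sample is replaced by the mean of all samples within (span - 1)/2 days
moving_average <- function(day, value, span_days) {
  if (span_days <= 0) return(value)
  half <- (span_days - 1) / 2
  vapply(seq_along(day),
         function(i) mean(value[abs(day - day[i]) <= half]),
         numeric(1))
}

#' Find the least-variance (pre-response) window of a chlorophyll series
#'
#' Scans every contiguous window of samples inside a day interval that has
#' at least `min_points` samples and spans at least `min_span_days` calendar
#' days (inclusive of both end days), and returns the window with minimum
#' unbiased sample variance. With every-other-day sampling the minimal
#' window is two samples spanning three calendar days. Ties are broken by
#' earliest start day, then shortest window. The window mean is the
#' pre-response condition C0.
#'
#' @param day numeric vector of sample days (sorted, unique).
#' @param value chlorophyll-a at those days (ug/L).
#' @param bounds length-2 numeric: search interval (inclusive); samples with
#'   `bounds[1] <= day <= bounds[2]` are candidates.
#' @param min_points minimum samples per window.
#' @param min_span_days minimum inclusive calendar span of a window (days).
#' @return List with `start_day`, `end_day`, `c0` (window mean),
#'   `variance`, and `n_points`.
#' @examples
#' detect_pre_response(c(0, 2, 4, 6, 8), c(5, 5.1, 5, 9, 14), c(0, 8))
#' @export
detect_pre_response <- function(day, value, bounds = range(day),
                                min_points = 2, min_span_days = 3) {
  if (length(day) != length(value))
    pp_stop_invalid("`day` and `value` must have equal length")
  if (is.unsorted(day, strictly = TRUE))
    pp_stop_invalid("`day` must be strictly increasing")
  keep <- day >= bounds[1] & day <= bounds[2] & is.finite(value)
  d <- day[keep]; v <- value[keep]
  n <- length(d)
  if (n < min_points)
    pp_stop_invalid(sprintf(
      "need at least %d samples in [%g, %g]; found %d",
      min_points, bounds[1], bounds[2], n))

  best <- NULL
  best_var <- Inf
  for (i in seq_len(n - 1L)) {
    # incremental mean/SS over growing window
    m <- v[i]; ss <- 0
    for (j in (i + 1L):n) {
      k <- j - i + 1L
      delta <- v[j] - m
      m <- m + delta / k
      ss <- ss + delta * (v[j] - m)
      if (k < min_points) next
      if (d[j] - d[i] + 1 < min_span_days) next
      vr <- ss / (k - 1L)
      if (is.null(best) || vr < best_var - 1e-12 * (1 + abs(best_var))) {
        best_var <- vr
        best <- list(start_day = d[i], end_day = d[j], c0 = m,
                     variance = vr, n_points = k)
      }
    }
  }
  if (is.null(best))
    pp_stop_invalid("no candidate window satisfies the span constraints")
  best
}

#' Segment a replicate's series into perturbation cycles
#'
#' Divides a chlorophyll-a timeseries into cycles running from each pulse
#' day to the next (the last cycle runs to the series end) and extracts,
#' per cycle: the response peak (maximum after the pulse day), the
#' pre-response condition C0 (least-variance window searched from the
#' second half of the previous cycle's post-peak tail up to just before the
#' current peak, so that a late plateau cannot be selected), and the
#' post-event condition. For interior cycles the post-event condition is
#' the next cycle's pre-response window (cross-cycle chaining; `recovered`
#' is then always `TRUE`); for the final cycle it is the least-variance
#' window in the cycle's final quarter, flagged unrecovered when its
#' variance exceeds `unrecovered_mult` times the pre-response variance
#' (windows with spread below 1% of their level always count as stable).
#'
#' @param day,value the sampled series (as in [detect_pre_response()]).
#' @param pulse_days pulse-application days, within the series span.
#' Before the variance scan the series is smoothed with a centered moving
#' average spanning `smooth_span_days` calendar days (the response peak is
#' always taken from the raw samples). Smoothing implements the
#' moving-average part of the detection rule and guards the least-variance
#' scan against incidentally flat two-sample windows on the shoulder of a
#' response peak; set `smooth_span_days = 0` to scan raw samples.
#'
#' @param lookback_frac fraction of the gap between the previous cycle's
#'   peak and the current pulse at which the pre-response search starts.
#' @param final_frac fraction of the last cycle used for its post-event
#'   window search (from the end).
#' @param unrecovered_mult variance multiple above which a post-event
#'   window is flagged unrecovered.
#' @param min_points,min_span_days window constraints, see
#'   [detect_pre_response()].
#' @param smooth_span_days inclusive calendar span (days) of the centered
#'   moving average applied before the window scan; 0 disables smoothing.
#' @return data.frame with one row per cycle: `cycle`, `pulse_day`, `c0`,
#'   `c0_start_day`, `c0_end_day`, `c0_var`, `peak_value`, `peak_day`,
#'   `dx_level`, `dx_start_day`, `dx_end_day`, `dx_var`, `recovered`.
#' @export
segment_cycles <- function(day, value, pulse_days,
                           lookback_frac = 0.5, final_frac = 0.25,
                           unrecovered_mult = 5,
                           min_points = 2, min_span_days = 3,
                           smooth_span_days = 5) {
  if (length(day) != length(value))
    pp_stop_invalid("`day` and `value` must have equal length")
  smoothed <- moving_average(day, value, smooth_span_days)
  if (!length(pulse_days))
    pp_stop_invalid("need at least one pulse day")
  if (any(diff(pulse_days) <= 0))
    pp_stop_invalid("`pulse_days` must be strictly increasing")
  if (min(pulse_days) < min(day) || max(pulse_days) > max(day))
    pp_stop_invalid("`pulse_days` must lie within the series span")

  P <- length(pulse_days)
  ends <- c(pulse_days[-1], max(day))

  peaks <- vector("list", P)
  for (p in seq_len(P)) {
    sel <- day > pulse_days[p] & day <= ends[p]
    if (!any(sel))
      pp_stop_invalid(sprintf("no samples after pulse day %g", pulse_days[p]))
    i <- which(sel)[which.max(value[sel])]
    peaks[[p]] <- list(day = day[i], value = value[i])
  }

  pre <- vector("list", P)
  for (p in seq_len(P)) {
    # lookback cascade: start from the previous cycle's post-peak half and
    # widen (previous peak, previous pulse, series start) until the region
    # holds enough samples before the current peak
    lo_candidates <- if (p == 1L) min(day)
      else c(peaks[[p - 1L]]$day +
               lookback_frac * (pulse_days[p] - peaks[[p - 1L]]$day),
             peaks[[p - 1L]]$day, pulse_days[p - 1L], min(day))
    hi_candidates <- numeric(0)
    for (lo in lo_candidates) {
      hi_candidates <- day[day < peaks[[p]]$day & day >= lo]
      if (length(hi_candidates) >= min_points) break
    }
    if (length(hi_candidates) < min_points)
      pp_stop_invalid(sprintf(
        "cycle %d: fewer than %d samples before the response peak",
        p, min_points))
    pre[[p]] <- detect_pre_response(day, smoothed,
                                    bounds = c(lo, max(hi_candidates)),
                                    min_points = min_points,
                                    min_span_days = min_span_days)
  }

  rows <- vector("list", P)
  for (p in seq_len(P)) {
    if (p < P) {
      # interior cycles chain: their post-event state is the next cycle's
      # (already validated) pre-response window
      post <- pre[[p + 1L]]
      recovered <- TRUE
    } else {
      span <- ends[P] - pulse_days[P]
      post <- detect_pre_response(day, smoothed,
                                  bounds = c(ends[P] - final_frac * span,
                                             ends[P]),
                                  min_points = min_points,
                                  min_span_days = min_span_days)
      # stable when its variance is within the configured multiple of the
      # pre-response variance; windows with spread below 1% of their level
      # count as stable even against a (near-)zero pre-response variance
      recovered <- post$variance <=
        unrecovered_mult * pre[[p]]$variance + (0.01 * post$c0)^2
    }
    rows[[p]] <- data.frame(
      cycle = p,
      pulse_day = pulse_days[p],
      c0 = pre[[p]]$c0,
      c0_start_day = pre[[p]]$start_day,
      c0_end_day = pre[[p]]$end_day,
      c0_var = pre[[p]]$variance,
      peak_value = peaks[[p]]$value,
      peak_day = peaks[[p]]$day,
      dx_level = post$c0,
      dx_start_day = post$start_day,
      dx_end_day = post$end_day,
      dx_var = post$variance,
      recovered = recovered
    )
  }
  do.call(rbind, rows)
}

#' Segment every replicate of an experiment
#'
#' Applies [segment_cycles()] to each replicate's total chlorophyll-a
#' series in a long-format timeseries table.
#'
#' @param timeseries long-format data.frame with at least `day`,
#'   `treatment`, `replicate`, `chl_total`.
#' @param pulse_days pulse days, or an [experiment_design()] from which
#'   they are taken.
#' @param ... passed to [segment_cycles()].
#' @return data.frame of response windows, one row per replicate x cycle,
#'   with `treatment` and `replicate` columns prepended.
#' @export
segment_experiment <- function(timeseries, pulse_days, ...) {
  if (inherits(pulse_days, "pp_design")) pulse_days <- pulse_days$pulse_days
  validate_timeseries(timeseries)
  parts <- split(timeseries, timeseries$replicate)
  out <- lapply(parts, function(df) {
    df <- df[order(df$day), ]
    w <- segment_cycles(df$day, df$chl_total, pulse_days, ...)
    cbind(treatment = df$treatment[1], replicate = df$replicate[1], w,
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
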