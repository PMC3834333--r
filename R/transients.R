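#' Baseline RMS noise of a trace
#'
#' Root-mean-square deviation from the window mean, measured over the fixed
#' pre-stimulus window from -1000 to -104 ms relative to the first pulse.
#' Five times this value is the peak-detection threshold.
#'
#' @param trace a [dff_trace()].
#' @param protocol a [stimulus_protocol()].
#' @param window window relative to the first pulse, s (default
#'   `c(-1, -0.104)`).
#' @return RMS noise (dF/F0 units), with the window mean in attribute
#'   `"baseline_mean"`.
#' @export
compute_rms <- function(trace, protocol, window = c(-1, -0.104)) {
  stopifnot(inherits(trace, "dff_trace"))
  t1 <- protocol$pulse_times[1]
  lo <- t1 + window[1]; hi <- t1 + window[2]
  if (trace$time[1] > lo + 1e-9 || trace$time[length(trace$time)] < hi - 1e-9)
    stopf("input error: RMS window [%.3f, %.3f] s outside the trace", lo, hi)
  idx <- which(trace$time >= lo - 1e-9 & trace$time <= hi + 1e-9)
  v <- trace$values[idx]
  out <- sqrt(mean((v - mean(v))^2))
  attr(out, "baseline_mean") <- mean(v)
  out
}

## per-pulse search windows: (pulse_k, pulse_{k+1}], last pulse gets +tail s
pulse_windows <- function(protocol, tail = 1) {
  starts <- protocol$pulse_times
  ends <- c(starts[-1], starts[length(starts)] + tail)
  cbind(start = starts, end = ends)
}

#' Detect stimulus-locked peaks in a train
#'
#' For each pulse, takes the trace maximum inside that pulse's search
#' window (from the pulse to the next pulse; 1 s after the last). A peak is
#' detected when this maximum crosses the threshold of `rms_mult` times the
#' RMS noise above the pre-stimulus baseline mean. The amplitude of a
#' detected peak is then measured relative to the baseline level: by
#' default the local baseline, i.e. the trace value immediately before the
#' pulse (sampled `baseline_lead` seconds ahead of it, outside the support
#' of the smoothing kernel), so train amplitudes are per-pulse increments
#' (`baseline_mode = "global"` refers every amplitude to the pre-train
#' baseline instead). A trace with no detected peak across the train is a
#' non-responder.
#'
#' @param trace a [dff_trace()], 15 Hz-filtered on the detection path.
#' @param protocol a [stimulus_protocol()].
#' @param rms RMS noise from [compute_rms()] (its `"baseline_mean"`
#'   attribute, when present, is used as the pre-stimulus reference).
#' @param rms_mult detection threshold multiplier (default 5).
#' @param baseline_mode `"local"` or `"global"` amplitude reference.
#' @param baseline_lead lead time (s) before each pulse at which the local
#'   baseline is read; the default 0.104 matches the end of the RMS window
#'   and clears the tail of the 5 and 15 Hz Gaussian kernels.
#' @param tail search window after the last pulse, s.
#' @return A data frame with one row per pulse: `pulse`, `pulse_time`,
#'   `peak_time`, `peak_value`, `baseline`, `amplitude`, `detected`.
#'   Attribute `"responder"` is `TRUE` when any peak was detected.
#' @export
detect_peaks <- function(trace, protocol, rms, rms_mult = 5,
                         baseline_mode = c("local", "global"),
                         baseline_lead = 0.104, tail = 1) {
  stopifnot(inherits(trace, "dff_trace"))
  baseline_mode <- match.arg(baseline_mode)
  ref <- attr(rms, "baseline_mean") %||% 0
  thr <- ref + rms_mult * as.numeric(rms)
  win <- pulse_windows(protocol, tail)
  n <- nrow(win)
  out <- data.frame(pulse = seq_len(n), pulse_time = win[, "start"],
                    peak_time = NA_real_, peak_value = NA_real_,
                    baseline = NA_real_, amplitude = NA_real_,
                    detected = FALSE)
  for (k in seq_len(n)) {
    ## intermediate windows end strictly before the next pulse (whose own
    ## rise must not be scanned); the final +tail window is closed
    idx <- if (k < n) {
      which(trace$time > win[k, "start"] & trace$time < win[k, "end"] - 1e-9)
    } else {
      which(trace$time > win[k, "start"] & trace$time <= win[k, "end"] + 1e-9)
    }
    if (!length(idx)) next
    pk <- idx[which.max(trace$values[idx])]
    base <- if (baseline_mode == "local") {
      before <- which(trace$time <= win[k, "start"] - baseline_lead + 1e-9)
      if (length(before)) trace$values[max(before)] else ref
    } else ref
    out$peak_time[k] <- trace$time[pk]
    out$peak_value[k] <- trace$values[pk]
    out$baseline[k] <- base
    out$amplitude[k] <- trace$values[pk] - base
    out$detected[k] <- trace$values[pk] >= thr
  }
  attr(out, "responder") <- any(out$detected)
  attr(out, "threshold") <- thr
  out
}

#' Peak amplitude in a fixed post-stimulus window
#'
#' The simple amplitude measure used when transients may be absent
#' (pharmacological blockade, single-pixel analysis): the highest point
#' 10-70 ms after the stimulus, measured as the difference from the F0
#' baseline (0 on the dF/F0 scale).
#'
#' @param trace a [dff_trace()].
#' @param pulse_time stimulus time (s).
#' @param window window after the pulse, s (default `c(0.010, 0.070)`,
#'   half-open on the left).
#' @param baseline reference level (default 0).
#' @return A list with `amplitude` and `peak_time`.
#' @export
peak_amplitude_simple <- function(trace, pulse_time,
                                  window = c(0.010, 0.070), baseline = 0) {
  stopifnot(inherits(trace, "dff_trace"))
  idx <- which(trace$time > pulse_time + window[1] + 1e-9 &
                 trace$time <= pulse_time + window[2] + 1e-9)
  if (!length(idx))
    stopf("input error: window (%.3f, %.3f] s after the pulse contains no samples",
          window[1], window[2])
  pk <- idx[which.max(trace$values[idx])]
  list(amplitude = trace$values[pk] - baseline, peak_time = trace$time[pk])
}

## locate the (interpolated) time at which the trace last crosses `level`
## downward before `before_time`, scanning indices `idx`
last_down_crossing <- function(v, t, level) {
  hits <- which(v[-length(v)] >= level & v[-1] < level)
  if (!length(hits)) return(NULL)
  i <- hits[length(hits)]
  frac <- (v[i] - level) / (v[i] - v[i + 1])
  t[i] + frac * (t[i + 1] - t[i])
}

first_down_crossing <- function(v, t, level) {
  hits <- which(v[-length(v)] >= level & v[-1] < level)
  if (!length(hits)) return(NULL)
  i <- hits[1]
  frac <- (v[i] - level) / (v[i] - v[i + 1])
  t[i] + frac * (t[i + 1] - t[i])
}

#' Fit a single-exponential decay to a transient
#'
#' Unconstrained least-squares fit of `a * exp(-t / tau)` to the falling
#' phase of a detected peak, over the contiguous segment running from the
#' last crossing of 80% of the peak amplitude to the first crossing of 20%
#' (crossings located by linear interpolation; the last-80/first-20 rule
#' resolves multiple noise crossings). Time is referenced to the peak, so
#' `fit_a` estimates the amplitude at the peak. The fit is initialized from
#' a log-linear regression and refined by Levenberg-Marquardt. Fits with
#' `r^2 < r2_min` (default 0.990) are flagged invalid and excluded from
#' summaries; a segment that never reaches 20% before `limit` is fitted as
#' is and flagged `truncated`.
#'
#' @param trace a [dff_trace()]; re-filter at 5 Hz ([filter_trace()])
#'   before fitting to reduce noise.
#' @param peak a list or one-row data frame with `peak_time`, `peak_value`
#'   and `baseline` (as returned by [detect_peaks()]).
#' @param limit do not use samples beyond this time (s); pass the next
#'   pulse time within trains. Default: end of trace.
#' @param r2_min goodness-of-fit acceptance threshold.
#' @param min_points minimum number of samples in the fitted segment.
#' @return A list: `tau`, `fit_a`, `r_squared`, `tau_valid`, `truncated`,
#'   `n_points`, `t80`, `t20`, and `reason` when invalid.
#' @export
fit_decay <- function(trace, peak, limit = NULL, r2_min = 0.990,
                      min_points = 5) {
  stopifnot(inherits(trace, "dff_trace"))
  invalid <- function(reason, truncated = FALSE)
    list(tau = NA_real_, fit_a = NA_real_, r_squared = NA_real_,
         tau_valid = FALSE, truncated = truncated, n_points = 0L,
         t80 = NA_real_, t20 = NA_real_, reason = reason)

  limit <- limit %||% trace$time[length(trace$time)]
  amp <- peak$peak_value - peak$baseline
  if (!is.finite(amp) || amp <= 0) return(invalid("no_peak"))
  l80 <- peak$baseline + 0.8 * amp
  l20 <- peak$baseline + 0.2 * amp

  idx <- which(trace$time >= peak$peak_time & trace$time <= limit + 1e-9)
  if (length(idx) < 2) return(invalid("segment_empty"))
  v <- trace$values[idx]; t <- trace$time[idx]

  t20 <- first_down_crossing(v, t, l20)
  truncated <- is.null(t20)
  t_end <- t20 %||% t[length(t)]
  pre <- v[t <= t_end]; tp <- t[t <= t_end]
  t80 <- last_down_crossing(pre, tp, l80)
  if (is.null(t80)) return(invalid("no_80pc_crossing", truncated))

  seg <- which(t >= t80 & t <= t_end)
  if (length(seg) < min_points) return(invalid("too_few_points", truncated))
  y <- v[seg] - peak$baseline
  tt <- t[seg] - peak$peak_time

  ## log-linear initialization (positive samples only)
  pos <- y > 0
  if (sum(pos) < 2) return(invalid("nonpositive_segment", truncated))
  init <- lm(log(y[pos]) ~ tt[pos])
  slope <- unname(coef(init)[2])
  tau0 <- if (is.finite(slope) && slope < 0) -1 / slope else diff(range(tt)) + 1e-3
  a0 <- unname(exp(coef(init)[1]))

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-tt / tau),
                      start = list(a = a0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(invalid("no_convergence", truncated))
  est <- coef(fit)
  res <- y - est["a"] * exp(-tt / est["tau"])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else as.numeric(sum(res^2) < 1e-20)
  list(tau = unname(est["tau"]), fit_a = unname(est["a"]), r_squared = r2,
       tau_valid = is.finite(r2) && r2 >= r2_min && est["tau"] > 0,
       truncated = truncated, n_points = length(seg),
       t80 = t80, t20 = if (truncated) NA_real_ else t20,
       reason = if (is.finite(r2) && r2 >= r2_min) NA_character_ else "poor_fit")
}

#' Cumulative calcium load over a stimulus train
#'
#' For each pulse k, the integral of the absolute dF/F0 trace from the
#' first stimulus onset until `tail` (default 1) seconds after pulse k,
#' computed by the rectangle rule at the frame interval, without any
#' normalization. Units are dF/F0 x s (arbitrary units).
#'
#' @param trace a [dff_trace()] extending at least `tail` s past the last
#'   pulse.
#' @param protocol a [stimulus_protocol()].
#' @param tail seconds past each pulse included in its window.
#' @return Numeric vector of per-pulse cumulative loads (nondecreasing for
#'   nonnegative traces).
#' @export
cumulative_load <- function(trace, protocol, tail = 1) {
  stopifnot(inherits(trace, "dff_trace"))
  t1 <- protocol$pulse_times[1]
  t_last <- protocol$pulse_times[protocol$n_pulses] + tail
  if (trace$time[length(trace$time)] < t_last - 1e-9)
    stopf("input error: trace ends %.2f s before the last pulse window",
          t_last - trace$time[length(trace$time)])
  dt <- mean(diff(trace$time))
  av <- abs(trace$values)
  vapply(protocol$pulse_times, function(tk) {
    idx <- which(trace$time >= t1 - 1e-9 & trace$time <= tk + tail + 1e-9)
    sum(av[idx]) * dt
  }, numeric(1))
}

#' Closed-form impact of a decay time constant
#'
#' For a transient normalized to unit peak, `F(t) = exp(-t / tau)`: the
#' total area under the decay is `Area(Inf) = tau`, and the time spent
#' above a fractional threshold is `T = tau * ln(1 / threshold)`. Both
#' scale linearly in tau, so ratios of areas or of supra-threshold times
#' between conditions equal the ratio of the taus.
#'
#' @param tau decay time constant (s), > 0.
#' @param threshold fractional threshold in (0, 1).
#' @return A list of class `decay_impact`: `area_total` (= tau),
#'   `time_above` (= tau * ln(1/threshold)), `threshold`.
#' @examples
#' decay_impact(2, exp(-1))  # time_above = 2
#' @export
decay_impact <- function(tau, threshold = 0.5) {
  if (!is_scalar_num(tau) || tau <= 0) stopf("parameter error: tau must be > 0")
  if (!is_scalar_num(threshold) || threshold <= 0 || threshold >= 1)
    stopf("parameter error: threshold must lie in (0, 1)")
  structure(list(area_total = tau, time_above = tau * log(1 / threshold),
                 threshold = threshold),
            class = "decay_impact")
}

#' Full transient metrics of one trace
#'
#' Convenience wrapper chaining the group-1 analysis: 15 Hz filtering, RMS
#' noise, per-pulse peak detection, 5 Hz re-filtered decay fits, and
#' per-pulse cumulative load.
#'
#' @param trace a raw (unfiltered) [dff_trace()].
#' @param protocol a [stimulus_protocol()].
#' @param filter_detect,filter_fit Gaussian cutoffs (Hz) for the detection
#'   and fitting paths.
#' @param rms_mult,r2_min,baseline_mode thresholds passed through.
#' @return A data frame with one row per pulse: detection fields from
#'   [detect_peaks()] plus `tau`, `fit_a`, `r_squared`, `tau_valid`,
#'   `truncated`, `cumulative_load`, `rms_noise`, `f0`. Attribute
#'   `"responder"`.
#' @export
transient_metrics <- function(trace, protocol, filter_detect = 15,
                              filter_fit = 5, rms_mult = 5, r2_min = 0.990,
                              baseline_mode = "local") {
  tr15 <- filter_trace(trace, filter_detect)
  rms <- compute_rms(tr15, protocol)
  peaks <- detect_peaks(tr15, protocol, rms, rms_mult = rms_mult,
                        baseline_mode = baseline_mode)
  tr5 <- filter_trace(trace, filter_fit)
  win <- pulse_windows(protocol)
  fits <- lapply(seq_len(nrow(peaks)), function(k) {
    if (!peaks$detected[k])
      return(list(tau = NA_real_, fit_a = NA_real_, r_squared = NA_real_,
                  tau_valid = FALSE, truncated = NA))
    lim <- if (k < nrow(peaks)) win[k, "end"] - 1e-6 else win[k, "end"]
    fit_decay(tr5, peaks[k, ], limit = lim, r2_min = r2_min)
  })
  loads <- cumulative_load(trace, protocol)
  out <- cbind(peaks,
               tau = vapply(fits, `[[`, numeric(1), "tau"),
               fit_a = vapply(fits, `[[`, numeric(1), "fit_a"),
               r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
               tau_valid = vapply(fits, `[[`, logical(1), "tau_valid"),
               cumulative_load = loads,
               rms_noise = as.numeric(rms),
               f0 = trace$f0_value)
  attr(out, "responder") <- attr(peaks, "responder")
  out
}
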