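#' Field-stimulation protocol
#'
#' Describes a train of field-stimulation pulses: pulse onset times, the
#' recording window preceding the first pulse (used for the baseline and the
#' RMS-noise window) and the window retained after the last pulse.
#'
#' @param n_pulses number of pulses in the train.
#' @param frequency pulse frequency in Hz (ignored when `pulse_times` given).
#' @param pre_window seconds of recording before the first pulse.
#' @param post_window seconds of recording after the last pulse.
#' @param pulse_times optional explicit pulse onset times (s), strictly
#'   increasing; overrides `n_pulses`/`frequency` spacing but `n_pulses`
#'   must match its length.
#' @return An object of class `stimulus_protocol` with fields
#'   `pulse_times`, `n_pulses`, `frequency`, `pre_window`, `post_window`
#'   and the implied total `duration` (s).
#' @examples
#' stimulus_protocol(n_pulses = 10, frequency = 1, pre_window = 2)
#' @export
stimulus_protocol <- function(n_pulses = 10, frequency = 1,
                              pre_window = 10, post_window = 10,
                              pulse_times = NULL) {
  if (is.null(pulse_times)) {
    pulse_times <- pre_window + (seq_len(n_pulses) - 1) / frequency
  }
  if (length(pulse_times) != n_pulses)
    stopf("n_pulses (%d) does not match length(pulse_times) (%d)",
          n_pulses, length(pulse_times))
  if (n_pulses > 1 && any(diff(pulse_times) <= 0))
    stopf("pulse_times must be strictly increasing")
  if (pre_window < 0 || post_window < 0)
    stopf("pre_window and post_window must be non-negative")
  structure(
    list(pulse_times = as.numeric(pulse_times),
         n_pulses = as.integer(n_pulses),
         frequency = frequency,
         pre_window = pre_window,
         post_window = post_window,
         duration = pulse_times[length(pulse_times)] + post_window),
    class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %d pulse(s) at %g Hz, first at %.3f s, duration %.2f s\n",
              x$n_pulses, x$frequency, x$pulse_times[1], x$duration))
  invisible(x)
}

#' Construct a dF/F0 time series
#'
#' A uniformly sampled \eqn{\Delta F/F_0} trace with its time axis and the
#' baseline fluorescence of the pixels it came from.
#'
#' @param values numeric vector of dF/F0 samples.
#' @param time numeric vector of sample times (s), strictly increasing and
#'   the same length as `values`.
#' @param f0_value mean baseline fluorescence (a.u.) over the source pixels.
#' @param source short label for the origin of the trace (e.g. `"roi"`,
#'   `"pixel"`, `"synthetic"`).
#' @return An object of class `dff_trace`.
#' @export
dff_trace <- function(values, time, f0_value = NA_real_, source = "trace") {
  if (length(values) != length(time))
    stopf("values and time differ in length")
  if (length(time) > 1 && any(diff(time) <= 0))
    stopf("time must be strictly increasing")
  structure(list(values = as.numeric(values), time = as.numeric(time),
                 f0_value = f0_value, source = source),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d samples over %.2f s (source: %s, F0 = %s)\n",
              length(x$values), diff(range(x$time)), x$source,
              format(x$f0_value, digits = 4)))
  invisible(x)
}

## sampling rate of a trace (Hz), assuming uniform spacing
trace_rate <- function(trace) 1 / mean(diff(trace$time))
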