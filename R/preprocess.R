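#' Subtract averaged dark frames from an image stack
#'
#' The shutter-closed frames are averaged pixelwise and the mean dark image
#' is subtracted from every frame. Values are allowed to go negative:
#' clipping would bias the baseline estimate.
#'
#' @param stack an `image_stack` (see [simulate_stack()]) with at least one
#'   dark frame.
#' @return The stack with `data` decremented and attribute
#'   `dark_subtracted = TRUE`.
#' @export
subtract_dark <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(stack$dark_frames) || dim(stack$dark_frames)[1] < 1)
    stopf("input error: stack has no dark frames")
  dm <- dim(stack$data)
  if (!all(dim(stack$dark_frames)[2:3] == dm[2:3]))
    stopf("dark frames do not match the stack's spatial shape")
  dark_mean <- colMeans(stack$dark_frames, dims = 1)       # rows x cols
  stack$data <- stack$data - rep(as.vector(dark_mean), each = dm[1])
  attr(stack, "dark_subtracted") <- TRUE
  stack
}

#' Pre-stimulus baseline fluorescence (F0)
#'
#' Averages, pixel by pixel, the frames acquired during the `window`
#' seconds immediately preceding the first stimulus (default 1 s, i.e.
#' frames with time in `[t1 - 1, t1)`).
#'
#' @param stack a (dark-subtracted) `image_stack`.
#' @param protocol a [stimulus_protocol()].
#' @param window baseline window length in s before the first pulse.
#' @return A rows x cols matrix of baseline fluorescence.
#' @export
compute_f0 <- function(stack, protocol, window = 1) {
  stopifnot(inherits(stack, "image_stack"))
  t1 <- protocol$pulse_times[1]
  if (t1 - stack$time[1] < window - 1e-9)
    stopf("input error: only %.2f s of data before the first pulse (need %g s)",
          t1 - stack$time[1], window)
  idx <- which(stack$time >= t1 - window - 1e-9 & stack$time < t1 - 1e-9)
  colMeans(stack$data[idx, , , drop = FALSE], dims = 1)
}

#' Convert a stack to dF/F0
#'
#' Elementwise `(F - F0) / F0`. Pixels whose baseline is not positive carry
#' no usable signal (background, or dark-subtraction residue) and are
#' marked invalid (`NA` throughout, `valid` matrix `FALSE`).
#'
#' @param stack a dark-subtracted `image_stack`.
#' @param f0 baseline matrix from [compute_f0()].
#' @param min_f0 positivity floor for a usable baseline (default 0:
#'   any strictly positive F0 is kept).
#' @return An object of class `dff_stack`: `dff` (frames x rows x cols),
#'   `f0`, `valid` (rows x cols logical), `time`, `frame_interval`,
#'   `pixel_size`.
#' @export
compute_dff <- function(stack, f0, min_f0 = 0) {
  stopifnot(inherits(stack, "image_stack"))
  dm <- dim(stack$data)
  if (!all(dim(f0) == dm[2:3])) stopf("f0 does not match the stack shape")
  valid <- f0 > min_f0
  if (!any(valid)) stopf("processing error: no pixel has a positive baseline")
  f0v <- as.vector(f0)
  f0v[!valid] <- NA_real_
  dff <- (stack$data - rep(f0v, each = dm[1])) / rep(f0v, each = dm[1])
  structure(list(dff = dff, f0 = f0, valid = valid, time = stack$time,
                 frame_interval = stack$frame_interval,
                 pixel_size = stack$pixel_size),
            class = "dff_stack")
}

#' @export
print.dff_stack <- function(x, ...) {
  d <- dim(x$dff)
  cat(sprintf("<dff_stack> %d frames of %dx%d px, %d valid pixel(s)\n",
              d[1], d[2], d[3], sum(x$valid)))
  invisible(x)
}

## Gaussian kernel with -3 dB point at `cutoff` Hz for a given sampling
## rate: sigma_t = sqrt(ln 2) / (2 pi f_c). Normalized to DC gain 1.
gaussian_kernel <- function(cutoff, rate) {
  sigma_s <- sqrt(log(2)) / (2 * pi * cutoff) * rate
  half <- max(1L, ceiling(4 * sigma_s))
  k <- dnorm(seq(-half, half), sd = sigma_s)
  k / sum(k)
}

#' Gaussian low-pass filter of a sampled signal
#'
#' Linear, zero-phase Gaussian smoothing whose -3 dB cutoff equals the
#' stated frequency (sigma_t = sqrt(ln 2) / (2 pi f_c)). Edges are padded by
#' replication so the DC gain is exactly 1.
#'
#' @param x numeric vector of samples.
#' @param cutoff -3 dB cutoff frequency (Hz); must be below the Nyquist
#'   frequency.
#' @param rate sampling rate (Hz).
#' @return The filtered vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, cutoff, rate) {
  if (cutoff >= rate / 2)
    stopf("parameter error: cutoff %g Hz is not below Nyquist (%g Hz)",
          cutoff, rate / 2)
  k <- gaussian_kernel(cutoff, rate)
  half <- (length(k) - 1L) / 2L
  padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
  out <- stats::filter(padded, k, method = "convolution", sides = 2)
  as.numeric(out[(half + 1):(half + length(x))])
}

#' Gaussian filtering of a dF/F0 trace
#'
#' Applies [gaussian_smooth()] to a trace with respect to time. The
#' detection path uses a 15 Hz cutoff; the decay-fitting path re-filters at
#' 5 Hz to reduce noise.
#'
#' @param trace a [dff_trace()].
#' @param cutoff -3 dB cutoff in Hz.
#' @return The filtered trace (metadata preserved; the cutoff is recorded
#'   in attribute `"filter_hz"`).
#' @export
filter_trace <- function(trace, cutoff) {
  stopifnot(inherits(trace, "dff_trace"))
  out <- trace
  out$values <- gaussian_smooth(trace$values, cutoff, trace_rate(trace))
  attr(out, "filter_hz") <- cutoff
  out
}
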