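#' Transient kinetics parameters
#'
#' Parameters of the dF/F0 response model. A stimulus at time \eqn{t_k}
#' adds a transient with instantaneous rise and single-exponential decay,
#' \eqn{a(x)\,e^{-(t-t_k)/\tau}}. The peak amplitude and the baseline
#' fluorescence vary along the dendrite: amplitude grows and F0 falls with
#' distance from the soma-dendrite border, emulating the surface-to-volume
#' and dye-load gradients seen in these neurons.
#'
#' @param amplitude_a peak dF/F0 at the reference dendritic position
#'   (`reference_offset` pixels from the border).
#' @param tau decay time constant (s).
#' @param distal_amplitude_slope fractional amplitude increase per pixel of
#'   dendritic distance.
#' @param f0_soma baseline fluorescence in the soma (a.u. counts).
#' @param f0_distal_slope fractional F0 decrease per pixel along the dendrite.
#' @param responder logical; `FALSE` silences the response entirely.
#' @param soma_amplitude_frac fraction of `amplitude_a` expressed in the
#'   somatic cytoplasm (the nucleus never responds).
#' @param reference_offset dendritic pixel (from the border) at which
#'   `amplitude_a` applies; default 6, the proximal ROI position.
#' @param tau_schedule optional per-pulse multipliers of `tau` (length =
#'   number of pulses), e.g. to accelerate decays late in a train.
#' @param peak_mode `"superpose"`: train responses add linearly, so peaks
#'   ride on the preceding decay; `"absolute"`: each pulse tops the trace up
#'   to the configured amplitude. Recorded in stack metadata.
#' @return An object of class `kinetics_params`.
#' @export
kinetics_params <- function(amplitude_a = 0.5, tau = 2,
                            distal_amplitude_slope = 0.02,
                            f0_soma = 400, f0_distal_slope = 0.01,
                            responder = TRUE,
                            soma_amplitude_frac = 0.1,
                            reference_offset = 6,
                            tau_schedule = NULL,
                            peak_mode = c("superpose", "absolute")) {
  if (tau <= 0) stopf("tau must be > 0")
  if (amplitude_a < 0) stopf("amplitude_a must be >= 0")
  if (f0_soma <= 0) stopf("f0_soma must be > 0")
  structure(list(amplitude_a = amplitude_a, tau = tau,
                 distal_amplitude_slope = distal_amplitude_slope,
                 f0_soma = f0_soma, f0_distal_slope = f0_distal_slope,
                 responder = isTRUE(responder),
                 soma_amplitude_frac = soma_amplitude_frac,
                 reference_offset = reference_offset,
                 tau_schedule = tau_schedule,
                 peak_mode = match.arg(peak_mode)),
            class = "kinetics_params")
}

#' Camera noise parameters
#'
#' EMCCD abstraction: a constant dark offset, Gaussian read noise, and
#' Poisson shot noise on the scaled photon intensity. With
#' `shot_noise = FALSE` and `read_noise_sd = 0` the simulator emits the
#' exact analytic model, which downstream recovery tests rely on.
#'
#' @param dark_offset camera offset in counts.
#' @param read_noise_sd Gaussian read noise SD in counts (>= 0).
#' @param photon_scale counts per unit model intensity (> 0); the Poisson
#'   rate is `photon_scale * F0(x) * (1 + dFF(x, t))`.
#' @param shot_noise logical; draw Poisson shot noise (default `TRUE`).
#' @param seed integer seed for the stack's random draws.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(dark_offset = 100, read_noise_sd = 2,
                         photon_scale = 1, shot_noise = TRUE, seed = NULL) {
  if (read_noise_sd < 0) stopf("read_noise_sd must be >= 0")
  if (photon_scale <= 0) stopf("photon_scale must be > 0")
  structure(list(dark_offset = dark_offset, read_noise_sd = read_noise_sd,
                 photon_scale = photon_scale, shot_noise = isTRUE(shot_noise),
                 seed = seed),
            class = "noise_params")
}

## Unit-amplitude train response: sum_k c_k * exp(-(t - t_k)/tau_k) for
## t >= t_k. In "superpose" mode c_k = 1; in "absolute" mode c_k tops the
## trace up to 1 at each pulse time.
unit_train <- function(time, pulse_times, tau, tau_schedule = NULL,
                       peak_mode = "superpose") {
  k <- length(pulse_times)
  taus <- tau * (tau_schedule %||% rep(1, k))
  if (length(taus) != k) stopf("tau_schedule must have one entry per pulse")
  out <- numeric(length(time))
  coefs <- numeric(k)
  for (i in seq_len(k)) {
    if (peak_mode == "absolute") {
      before <- 0
      if (i > 1) {
        dt_prev <- pulse_times[i] - pulse_times[seq_len(i - 1)]
        before <- sum(coefs[seq_len(i - 1)] * exp(-dt_prev / taus[seq_len(i - 1)]))
      }
      coefs[i] <- max(1 - before, 0)
    } else coefs[i] <- 1
    dt <- time - pulse_times[i]
    on <- dt >= 0
    out[on] <- out[on] + coefs[i] * exp(-dt[on] / taus[i])
  }
  out
}

## Per-pixel F0 and amplitude maps for a geometry + kinetics pair.
## Returns matrices (rows x cols): f0 (counts), amp (dF/F0), plus a label
## matrix ("" outside the cell).
intensity_maps <- function(geom, kin) {
  nr <- geom$dims[1]; nc <- geom$dims[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d_center <- sqrt((rows - geom$soma_center[1])^2 + (cols - geom$soma_center[2])^2)

  label <- matrix("", nr, nc)
  label[d_center <= geom$soma_radius_px] <- "soma"
  label[d_center <= geom$nucleus_radius_px] <- "nucleus"

  ## dendritic distance from the border (of the nearest centerline point),
  ## NA off-dendrite
  dist_px <- matrix(NA_real_, nr, nc)
  near2 <- matrix(Inf, nr, nc)
  for (den in geom$dendrites) {
    out_idx <- den$border:nrow(den$path)
    for (i in seq_along(out_idx)) {
      p <- den$path[out_idx[i], ]
      half <- den$width_um[out_idx[i]] / 2 / geom$pixel_size
      rr <- max(1, floor(p[1] - half)):min(nr, ceiling(p[1] + half))
      cc <- max(1, floor(p[2] - half)):min(nc, ceiling(p[2] + half))
      for (r in rr) for (cl in cc) {
        dd <- (r - p[1])^2 + (cl - p[2])^2
        if (dd <= half^2 && label[r, cl] == "" && dd < near2[r, cl]) {
          near2[r, cl] <- dd
          dist_px[r, cl] <- i - 1
        }
      }
    }
  }
  dend <- !is.na(dist_px)
  label[dend] <- "dendrite"

  f0 <- matrix(0, nr, nc)
  f0[label %in% c("soma", "nucleus")] <- kin$f0_soma
  f0[dend] <- pmax(kin$f0_soma * (1 - kin$f0_distal_slope * dist_px[dend]),
                   0.05 * kin$f0_soma)

  amp <- matrix(0, nr, nc)
  if (kin$responder) {
    amp[label == "soma"] <- kin$soma_amplitude_frac * kin$amplitude_a
    amp[dend] <- pmax(kin$amplitude_a *
                        (1 + kin$distal_amplitude_slope *
                           (dist_px[dend] - kin$reference_offset)), 0)
  }
  list(f0 = f0, amp = amp, label = label, dist_px = dist_px)
}

#' Simulate a fluorescence image stack
#'
#' Renders the dF/F0 model of [kinetics_params()] onto the pixel grid of a
#' [make_geometry()] object and converts it to camera counts:
#' `dark_offset + read noise + Poisson(photon_scale * F0(x) * (1 + dFF(x,t)))`.
#' Also emits `n_dark` shutter-closed frames (offset + read noise only).
#' Identical seeds give bit-identical stacks.
#'
#' @param geom a [make_geometry()] object.
#' @param kin a [kinetics_params()] object.
#' @param protocol a [stimulus_protocol()]; all pulses must fall inside the
#'   stack duration.
#' @param noise a [noise_params()] object.
#' @param frame_interval frame interval in s (default 0.01, i.e. 100
#'   frames/s).
#' @param duration total recording length (s); default
#'   `protocol$pre_window + span of pulses + protocol$post_window`.
#' @param n_dark number of dark frames (>= 20 by convention).
#' @return An object of class `image_stack`: `data` (frames x rows x cols
#'   counts), `dark_frames`, `frame_interval`, `pixel_size`, `time`, and a
#'   `ground_truth` list (F0/amplitude maps, kinetics, labels, peak mode)
#'   used by tests and sidecar files.
#' @export
simulate_stack <- function(geom, kin, protocol, noise = noise_params(),
                           frame_interval = 0.01, duration = NULL,
                           n_dark = 20) {
  duration <- duration %||%
    (protocol$pre_window + diff(range(protocol$pulse_times)) + protocol$post_window)
  nf <- round(duration / frame_interval)
  time <- (seq_len(nf) - 1) * frame_interval
  if (any(protocol$pulse_times < 0 | protocol$pulse_times > time[nf]))
    stopf("protocol error: pulse outside the stack duration [0, %.2f]", time[nf])

  maps <- intensity_maps(geom, kin)
  g <- unit_train(time, protocol$pulse_times, kin$tau, kin$tau_schedule,
                  kin$peak_mode)
  nr <- geom$dims[1]; nc <- geom$dims[2]; npix <- nr * nc

  ## frames x pixels intensity; dff factorizes as g(t) * amp(x) in both modes
  lam <- noise$photon_scale *
    (rep(as.vector(maps$f0), each = nf) *
       (1 + outer(g, as.vector(maps$amp))))

  with_seed(noise$seed, {
    counts <- if (noise$shot_noise) {
      matrix(rpois(nf * npix, lam), nf, npix)
    } else lam
    counts <- counts + noise$dark_offset
    if (noise$read_noise_sd > 0)
      counts <- counts + rnorm(nf * npix, 0, noise$read_noise_sd)
    dark <- matrix(noise$dark_offset, n_dark, npix)
    if (noise$read_noise_sd > 0)
      dark <- dark + rnorm(n_dark * npix, 0, noise$read_noise_sd)

    structure(
      list(data = array(counts, c(nf, nr, nc)),
           dark_frames = array(dark, c(n_dark, nr, nc)),
           frame_interval = frame_interval,
           pixel_size = geom$pixel_size,
           time = time,
           ground_truth = list(f0 = maps$f0, amp = maps$amp,
                               label = maps$label, dist_px = maps$dist_px,
                               kinetics = kin, protocol = protocol,
                               noise = noise, unit_response = g,
                               peak_mode = kin$peak_mode)),
      class = "image_stack")
  })
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frames of %dx%d px at %.0f frames/s, %d dark frame(s)\n",
              d[1], d[2], d[3], 1 / x$frame_interval, dim(x$dark_frames)[1]))
  invisible(x)
}

#' Simulate a dendritic dF/F0 trace directly
#'
#' Produces the trace that the full image pipeline would extract at the
#' reference dendritic position, without rendering an image stack:
#' the analytic transient train plus additive Gaussian noise (representing
#' residual noise after 12-pixel spatial averaging). Used for large
#' trace-level simulation studies where rendering stacks is unnecessary.
#'
#' @param kin a [kinetics_params()] object.
#' @param protocol a [stimulus_protocol()].
#' @param frame_interval frame interval (s).
#' @param duration recording length (s); defaults as in [simulate_stack()].
#' @param noise_sd additive Gaussian noise SD in dF/F0 units.
#' @param seed integer seed.
#' @return A [dff_trace()] whose `f0_value` is the model F0 at the
#'   reference position.
#' @export
simulate_trace <- function(kin, protocol, frame_interval = 0.01,
                           duration = NULL, noise_sd = 0, seed = NULL) {
  duration <- duration %||%
    (protocol$pre_window + diff(range(protocol$pulse_times)) + protocol$post_window)
  nf <- round(duration / frame_interval)
  time <- (seq_len(nf) - 1) * frame_interval
  if (any(protocol$pulse_times < 0 | protocol$pulse_times > time[nf]))
    stopf("protocol error: pulse outside the trace duration")
  a <- if (kin$responder) kin$amplitude_a else 0
  v <- a * unit_train(time, protocol$pulse_times, kin$tau, kin$tau_schedule,
                      kin$peak_mode)
  if (noise_sd > 0)
    v <- v + with_seed(seed, rnorm(nf, 0, noise_sd))
  f0_ref <- kin$f0_soma * (1 - kin$f0_distal_slope * kin$reference_offset)
  dff_trace(v, time, f0_value = f0_ref, source = "synthetic")
}

#' Reference dendritic pixel of a geometry
#'
#' The centerline pixel `offset` pixels beyond the soma-dendrite border,
#' i.e. the position at which [kinetics_params()]`$amplitude_a` applies and
#' where the proximal analysis ROI starts.
#'
#' @param geom a [make_geometry()] object.
#' @param dendrite_id which dendrite.
#' @param offset pixels beyond the border (default 6).
#' @return Integer vector `c(row, col)`.
#' @export
reference_pixel <- function(geom, dendrite_id = 1, offset = 6) {
  den <- geom$dendrites[[dendrite_id]]
  idx <- den$border + offset
  if (idx > nrow(den$path)) stopf("dendrite too short for offset %d", offset)
  c(row = den$path[idx, 1], col = den$path[idx, 2])
}
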