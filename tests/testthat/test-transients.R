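test_that("RMS noise is the root-mean-square about the window mean", {
  prot <- tiny_protocol()
  t <- seq(0, 4, by = 0.01)

  ## flat baseline
  expect_equal(as.numeric(compute_rms(dff_trace(rep(0.3, length(t)), t), prot)), 0)

  ## alternating +/- c about an offset: RMS = c exactly
  alt <- 0.1 + 0.05 * rep_len(c(1, -1), length(t))
  expect_equal(as.numeric(compute_rms(dff_trace(alt, t), prot)), 0.05,
               tolerance = 1e-9)

  ## unit-variance white noise: RMS -> 1 within 3 sigma of the estimator
  set.seed(3)
  rmss <- replicate(50, as.numeric(
    compute_rms(dff_trace(rnorm(length(t)), t), prot)))
  expect_lt(abs(mean(rmss) - 1), 3 * sd(rmss) / sqrt(50))

  expect_error(compute_rms(dff_trace(1:5 / 10, seq(1.8, 2.2, by = 0.1)), prot),
               "window")
})

test_that("peak detection recovers noiseless transients and flags non-responders", {
  prot <- tiny_protocol()
  tr <- simulate_trace(kinetics_params(amplitude_a = 0.5, tau = 2), prot)
  rms <- compute_rms(tr, prot)
  pk <- detect_peaks(tr, prot, rms)
  ## first sample in the (pulse, end] window is one frame after the pulse
  expect_true(pk$detected[1])
  expect_equal(pk$amplitude[1], 0.5 * exp(-0.01 / 2), tolerance = 1e-12)
  expect_equal(pk$baseline[1], 0)
  expect_true(attr(pk, "responder"))

  silent <- simulate_trace(kinetics_params(responder = FALSE), prot,
                           noise_sd = 0.02, seed = 4)
  s15 <- filter_trace(silent, 15)
  pk0 <- detect_peaks(s15, prot, compute_rms(s15, prot))
  expect_equal(sum(pk0$detected), 0)
  expect_false(attr(pk0, "responder"))
})

test_that("detection equals a brute-force window scan on random traces", {
  prot <- stimulus_protocol(5, 1, pre_window = 2, post_window = 1.5)
  t <- seq(0, prot$duration, by = 0.01)
  set.seed(7)
  for (i in 1:40) {
    v <- rnorm(length(t), 0, 0.02)
    if (i %% 2 == 0) {  # add random transients on some pulses
      for (k in sample(1:5, 3)) {
        tk <- prot$pulse_times[k]
        on <- t >= tk
        v[on] <- v[on] + runif(1, 0, 0.6) * exp(-(t[on] - tk) / runif(1, 0.3, 2))
      }
    }
    tr <- filter_trace(dff_trace(v, t), 15)
    rms <- compute_rms(tr, prot)
    got <- detect_peaks(tr, prot, rms)

    ## independent oracle: exhaustive scan of every sample in each window
    ref <- attr(rms, "baseline_mean")
    thr <- ref + 5 * as.numeric(rms)
    ends <- c(prot$pulse_times[-1], prot$pulse_times[5] + 1)
    for (k in 1:5) {
      best <- -Inf; best_t <- NA
      for (j in seq_along(t)) {
        in_win <- t[j] > prot$pulse_times[k] &&
          (if (k < 5) t[j] < ends[k] - 1e-9 else t[j] <= ends[k] + 1e-9)
        if (in_win && tr$values[j] > best) {
          best <- tr$values[j]; best_t <- t[j]
        }
      }
      jb <- max(which(t <= prot$pulse_times[k] - 0.104 + 1e-9))
      expect_equal(got$peak_value[k], best)
      expect_equal(got$peak_time[k], best_t)
      expect_equal(got$amplitude[k], best - tr$values[jb])
      expect_equal(got$detected[k], best >= thr)
    }
  }
})

test_that("the fixed-window amplitude measure matches the model and blockade", {
  prot <- tiny_protocol()
  tr <- simulate_trace(kinetics_params(amplitude_a = 0.8, tau = 2), prot)
  ## highest point in (10, 70] ms; first sampled frame is at +20 ms
  amp <- peak_amplitude_simple(tr, prot$pulse_times[1])
  expect_equal(amp$amplitude, 0.8 * exp(-0.02 / 2), tolerance = 1e-12)

  ## simulated channel blockade: amplitude indistinguishable from baseline
  set.seed(9)
  blocked <- vapply(1:30, function(i) {
    trb <- filter_trace(simulate_trace(kinetics_params(responder = FALSE),
                                       prot, noise_sd = 0.02), 15)
    peak_amplitude_simple(trb, prot$pulse_times[1])$amplitude
  }, numeric(1))
  control <- 0.8 * exp(-0.02 / 2)
  expect_lt(mean(blocked) / control, 0.05)

  expect_error(peak_amplitude_simple(tr, prot$duration + 5), "window")
})

test_that("decay fitting recovers noiseless parameters to 1e-6", {
  for (a in c(0.3, 0.8, 1.5)) {
    for (tau in c(0.4, 1, 3)) {
      prot <- stimulus_protocol(1, pre_window = 2,
                                post_window = max(4, 6 * tau))
      tr <- simulate_trace(kinetics_params(amplitude_a = a, tau = tau), prot)
      pk <- detect_peaks(tr, prot, compute_rms(tr, prot))
      fit <- fit_decay(tr, pk[1, ])
      expect_true(fit$tau_valid)
      expect_lt(abs(fit$tau - tau) / tau, 1e-6)
      ## ground-truth amplitude at the sampled peak time
      a_peak <- a * exp(-(pk$peak_time[1] - prot$pulse_times[1]) / tau)
      expect_lt(abs(fit$fit_a - a_peak) / a_peak, 1e-6)
      expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    }
  }
})

test_that("poor fits are rejected by the r-squared rule, not silently kept", {
  prot <- tiny_protocol(post = 6)
  set.seed(15)
  tr <- simulate_trace(kinetics_params(amplitude_a = 0.15, tau = 2), prot,
                       noise_sd = 0.05)
  tr5 <- filter_trace(tr, 5)
  pk <- detect_peaks(tr5, prot, compute_rms(tr5, prot))
  fit <- fit_decay(tr5, pk[1, ])
  expect_lt(fit$r_squared, 0.990)
  expect_false(fit$tau_valid)

  ## truncation flag when the decay cannot reach 20% before the limit
  tr_long <- simulate_trace(kinetics_params(amplitude_a = 0.5, tau = 5),
                            tiny_protocol(post = 2))
  pk2 <- detect_peaks(tr_long, tiny_protocol(post = 2),
                      compute_rms(tr_long, tiny_protocol(post = 2)))
  fit2 <- fit_decay(tr_long, pk2[1, ])
  expect_true(fit2$truncated)
  expect_true(fit2$tau_valid)      # noiseless: still an exact fit
  expect_lt(abs(fit2$tau - 5) / 5, 1e-6)
})

test_that("cumulative load integrates |dF/F0| from stimulus onset", {
  prot <- stimulus_protocol(3, 1, pre_window = 2, post_window = 1.5)
  t <- seq(0, prot$duration, by = 0.01)

  expect_equal(cumulative_load(dff_trace(rep(0, length(t)), t), prot),
               rep(0, 3))

  ## brute-force sample-sum oracle, exact equality
  set.seed(4)
  v <- abs(rnorm(length(t), 0, 0.1))
  tr <- dff_trace(v, t)
  got <- cumulative_load(tr, prot)
  for (k in 1:3) {
    idx <- which(t >= prot$pulse_times[1] & t <= prot$pulse_times[k] + 1)
    expect_equal(got[k], sum(abs(v[idx])) * 0.01)
  }
  expect_true(all(diff(got) >= 0))

  ## Area(inf) identity: long-tailed single transient integrates to ~ a*tau
  protL <- stimulus_protocol(1, pre_window = 2, post_window = 3)
  trL <- simulate_trace(kinetics_params(amplitude_a = 1, tau = 0.2), protL,
                        duration = 5)
  loadL <- cumulative_load(trL, protL, tail = 2.9)
  expect_equal(loadL, 1 * 0.2, tolerance = 0.03)

  expect_error(cumulative_load(dff_trace(v[1:200], t[1:200]), prot), "ends")
})

test_that("decay-impact closed forms hold and scale linearly in tau", {
  expect_equal(decay_impact(2, exp(-1))$time_above, 2)
  expect_equal(decay_impact(3, 0.5)$time_above, 3 * log(2))
  expect_equal(decay_impact(1.7, 0.1)$area_total, 1.7)

  ## quadrature oracle within 0.1%
  for (tau in c(0.2, 1, 4)) {
    q <- integrate(function(x) exp(-x / tau), 0, 50 * tau)$value
    expect_equal(decay_impact(tau)$area_total, q, tolerance = 1e-3)
  }
  ## ratio property: area and supra-threshold time ratios equal tau ratios
  d1 <- decay_impact(1.2, 0.3); d2 <- decay_impact(3.6, 0.3)
  expect_equal(d2$area_total / d1$area_total, 3)
  expect_equal(d2$time_above / d1$time_above, 3)

  expect_error(decay_impact(-1, 0.5), "tau")
  expect_error(decay_impact(2, 1.5), "threshold")
})

test_that("transient_metrics ties the whole group-1 analysis together", {
  ## 2-s pulse spacing so the 80-20% segment clears the 5 Hz kernel smear
  prot <- stimulus_protocol(3, 0.5, pre_window = 2, post_window = 2)
  set.seed(21)
  tr <- simulate_trace(kinetics_params(amplitude_a = 0.5, tau = 0.8), prot,
                       noise_sd = 0.01)
  m <- transient_metrics(tr, prot)
  expect_equal(nrow(m), 3)
  expect_true(all(m$detected))
  expect_true(attr(m, "responder"))
  expect_true(all(m$cumulative_load == cumulative_load(tr, prot)))
  ## the first pulse decays from a clean baseline: tau near truth
  expect_true(m$tau_valid[1])
  expect_lt(abs(m$tau[1] - 0.8) / 0.8, 0.05)
  ## later pulses ride on the preceding tail: the local-baseline fit makes
  ## their apparent tau faster, the acceleration seen in train analyses
  expect_true(all(m$tau[-1] < m$tau[1], na.rm = TRUE))
})
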