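test_that("geometry generation is deterministic and honors its invariants", {
  for (s in 1:5) {
    g <- make_geometry(area_range = c(158, 537), seed = s)
    expect_gte(g$soma_area, 158)
    expect_lte(g$soma_area, 537)
    for (den in g$dendrites) {
      expect_gte(nrow(den$path) - den$border + 1, 13)
      expect_true(all(den$width_um > 0))
      # 8-connected contiguity of the centerline
      steps <- abs(diff(den$path))
      expect_true(all(steps <= 1) && all(rowSums(steps) >= 1))
    }
  }
  expect_identical(make_geometry(seed = 42), make_geometry(seed = 42))
  g2 <- make_geometry(n_dendrites = 2, seed = 7)
  expect_length(g2$dendrites, 2)
  expect_error(make_geometry(area_range = c(500, 200)), "degenerate")
})

test_that("noise-free stacks conserve the analytic dF/F0 model", {
  geom <- tiny_geometry(seed = 3)
  kin <- kinetics_params(amplitude_a = 0.5, tau = 2)
  prot <- tiny_protocol()
  st <- simulate_stack(geom, kin, prot, clean_noise())
  dff <- stack_to_dff(st, prot)

  gt <- st$ground_truth
  g <- gt$unit_response
  valid <- which(dff$valid)
  m <- matrix(dff$dff, length(g), prod(dim(dff$dff)[2:3]))
  model <- outer(g, as.vector(gt$amp)[valid])
  expect_lt(max(abs(m[, valid] - model)), 1e-9)

  # reference pixel carries exactly a * exp(-(t - t1)/tau)
  rp <- reference_pixel(geom, 1)
  tr <- dff$dff[, rp[1], rp[2]]
  t1 <- prot$pulse_times[1]
  model <- ifelse(st$time >= t1, 0.5 * exp(-(st$time - t1) / 2), 0)
  expect_lt(max(abs(tr - model)), 1e-9)
})

test_that("identical seeds give bit-identical stacks", {
  geom <- tiny_geometry(seed = 4)
  kin <- kinetics_params()
  prot <- tiny_protocol()
  noisy <- noise_params(read_noise_sd = 2, shot_noise = TRUE, seed = 99)
  s1 <- simulate_stack(geom, kin, prot, noisy)
  s2 <- simulate_stack(geom, kin, prot, noisy)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$dark_frames, s2$dark_frames)
})

test_that("non-responders are silent and dark frames average to the offset", {
  geom <- tiny_geometry(seed = 5)
  prot <- tiny_protocol()
  noisy <- noise_params(dark_offset = 100, read_noise_sd = 2, seed = 12)
  st <- simulate_stack(geom, kinetics_params(responder = FALSE), prot, noisy)
  rp <- reference_pixel(geom, 1)
  v <- st$data[, rp[1], rp[2]]
  pre <- v[st$time < prot$pulse_times[1]]
  post <- v[st$time >= prot$pulse_times[1]]
  ## no stimulus-locked change beyond noise
  tt <- t.test(pre, post)
  expect_gt(tt$p.value, 0.001)

  dk <- st$dark_frames
  n <- length(dk)
  expect_lt(abs(mean(dk) - 100), 3 * 2 / sqrt(n))
})

test_that("a 1-Hz train produces one stimulus-locked maximum per pulse", {
  prot <- stimulus_protocol(10, 1, pre_window = 2, post_window = 2)
  tr <- simulate_trace(kinetics_params(tau = 0.5), prot)
  v <- tr$values
  ## direct scan for local maxima
  imax <- which(v[2:(length(v) - 1)] > v[1:(length(v) - 2)] &
                  v[2:(length(v) - 1)] >= v[3:length(v)]) + 1
  expect_length(imax, 10)
  ## each maximum within one frame of a pulse
  expect_true(all(abs(tr$time[imax] - prot$pulse_times) <= 0.011))
})

test_that("immuno simulation draws the configured mixture deterministically", {
  p <- immuno_population_params(n_cells = 1000,
                                fractions = c(msn = 0.95,
                                              gaba_interneuron = 0.04,
                                              cholinergic = 0.01),
                                n_controls = 50, seed = 21)
  cells <- simulate_immuno(p)
  expect_identical(cells, simulate_immuno(p))
  stained <- cells[cells$primary_antibody_present, ]
  expect_equal(nrow(stained), 1000)
  cnt <- table(factor(stained$true_class,
                      levels = c("msn", "gaba_interneuron", "cholinergic")))
  for (i in seq_len(3)) {
    expected <- c(950, 40, 10)[i]
    sd3 <- 3 * sqrt(1000 * expected / 1000 * (1 - expected / 1000))
    expect_lt(abs(cnt[i] - expected), sd3 + 1)
  }
  expect_error(simulate_immuno(immuno_population_params(
    fractions = c(0.9, 0.2, 0.1))), "sum")
})

test_that("control intensity follows the background-vs-area model", {
  p <- immuno_population_params(n_cells = 50, n_controls = 400,
                                background_intercept = -200,
                                background_slope = 150,
                                background_sd = 30, seed = 8)
  cells <- simulate_immuno(p)
  ctl <- cells[!cells$primary_antibody_present, ]
  fit <- lm(gad65 ~ log10(somatic_area), data = ctl)
  expect_lt(abs(coef(fit)[2] - 150), 3 * summary(fit)$coefficients[2, 2])
  expect_lt(abs(sd(fit$residuals) - 30), 6)
})

test_that("a unit positive multiplier removes the stained/control contrast", {
  p <- immuno_population_params(n_cells = 300, n_controls = 300,
                                positive_multiplier = 1 + 1e-12, seed = 31)
  cells <- simulate_immuno(p)
  msn_gad <- cells$gad65[cells$primary_antibody_present &
                           cells$true_class == "msn"]
  ctl_gad <- cells$gad65[!cells$primary_antibody_present]
  expect_gt(t.test(msn_gad, ctl_gad)$p.value, 0.01)
})
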