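test_that("somatic line intensity is the max of the 7-pixel running average", {
  img <- matrix(4.2, 20, 20)
  line <- data.frame(row = 5, col = 3:17)
  expect_equal(somatic_intensity(img, line), 4.2)

  ## an isolated hot pixel is diluted by the 7-point kernel
  img2 <- matrix(0, 20, 20)
  img2[5, 10] <- 14
  expect_equal(somatic_intensity(img2, line), 2)

  ## random profile vs a hand-computed running mean
  set.seed(6)
  img3 <- matrix(runif(400, 0, 100), 20, 20)
  prof <- img3[cbind(5, 3:17)]
  want <- max(vapply(4:12, function(i) mean(prof[(i - 3):(i + 3)]), numeric(1)))
  expect_equal(somatic_intensity(img3, line), want)

  expect_error(somatic_intensity(img, data.frame(row = 5, col = 1:5)),
               "shorter")
})

test_that("the simultaneous band collapses on exact data and widens at the edges", {
  x <- seq(100, 600, length.out = 30)
  exact <- data.frame(somatic_area = x, intensity = -200 + 150 * log10(x))
  band <- fit_band(exact)
  expect_lt(max(band_halfwidth(band, x)), 1e-8)
  expect_equal(band_upper(band, 300), -200 + 150 * log10(300),
               tolerance = 1e-6)

  set.seed(2)
  noisy <- data.frame(somatic_area = x,
                      intensity = -200 + 150 * log10(x) + rnorm(30, 0, 30))
  bn <- fit_band(noisy)
  hw <- band_halfwidth(bn, c(100, 10^bn$x_mean, 600))
  expect_lt(hw[2], hw[1])
  expect_lt(hw[2], hw[3])
  expect_true(all(band_upper(bn, x) > bn$intercept + bn$slope * log10(x)))

  expect_error(fit_band(noisy[1:5, ]), ">= 10")
  expect_error(fit_band(data.frame(somatic_area = rep(200, 20),
                                   intensity = rnorm(20))), "variance")
})

test_that("the band covers the true mean line at its nominal rate", {
  set.seed(17)
  n <- 100
  hits <- replicate(600, {
    a <- 10^runif(n, log10(100), log10(600))
    y <- -200 + 150 * log10(a) + rnorm(n, 0, 30)
    band <- fit_band(data.frame(somatic_area = a, intensity = y))
    band_contains_line(band, -200, 150)
  })
  expect_gt(mean(hits), 0.93)
  expect_lt(mean(hits), 0.97)
})

test_that("classification is strict at the threshold and monotone in intensity", {
  x <- seq(100, 600, length.out = 40)
  set.seed(3)
  band <- fit_band(data.frame(somatic_area = x,
                              intensity = -200 + 150 * log10(x) +
                                rnorm(40, 0, 30)))
  bands <- list(gad65 = band, darpp32 = band)
  thr <- band_upper(band, 300)
  rec <- data.frame(somatic_area = rep(300, 3),
                    gad65 = c(thr, thr + 1e-9, thr - 1e-9),
                    darpp32 = rep(thr + 10, 3))
  calls <- classify_cells(rec, bands)
  ## exactly at the threshold counts as negative
  expect_equal(calls$gad65_pos, c(FALSE, TRUE, FALSE))

  ## monotonicity: raising intensity never flips positive -> negative
  grid <- seq(thr - 50, thr + 50, length.out = 200)
  pos <- classify_cells(data.frame(somatic_area = 300, gad65 = grid,
                                   darpp32 = 0), bands)$gad65_pos
  expect_true(all(diff(pos) >= 0))

  ## a missing required channel leaves the cell unclassified
  calls2 <- classify_cells(data.frame(somatic_area = 300, gad65 = thr + 100),
                           list(gad65 = band, darpp32 = band))
  expect_equal(as.character(calls2$cell_type), "unclassified")
})

test_that("bright positives are called correctly and fractions are recovered", {
  p <- immuno_population_params(n_cells = 120, positive_multiplier = 5,
                                n_controls = 100, seed = 19)
  cells <- simulate_immuno(p)
  ctl <- cells[!cells$primary_antibody_present, ]
  markers <- c("gad65", "darpp32", "vacht", "vgat")
  bands <- lapply(markers, function(m)
    fit_band(data.frame(somatic_area = ctl$somatic_area,
                        intensity = ctl[[m]])))
  names(bands) <- markers
  stained <- cells[cells$primary_antibody_present, ]
  calls <- classify_cells(stained, bands)

  ## every truly antigen-positive channel must be called positive
  for (m in markers) {
    truly <- vapply(stained$true_class,
                    function(l) m %in% calcitrace:::marker_truth[[l]],
                    logical(1))
    expect_gte(mean(calls[[paste0(m, "_pos")]][truly]), 0.99)
  }
  ## overall class agreement at the level the band threshold supports
  expect_gte(mean(as.character(calls$cell_type) == calls$true_class), 0.90)

  ## recovered fractions within binomial 95% CIs of the mixture
  n <- nrow(calls)
  for (cl in c("msn", "gaba_interneuron", "cholinergic")) {
    pr <- p$fractions[[cl]]
    cnt <- sum(calls$cell_type == cl)
    expect_gte(cnt, qbinom(0.025, n, pr))
    expect_lte(cnt, qbinom(0.975, n, pr))
  }
})

test_that("population summaries reproduce tabulated percentages", {
  calls <- data.frame(
    somatic_area = 300,
    cell_type = rep(c("msn", "gaba_interneuron", "unclassified"),
                    c(114, 3, 3)))
  s <- population_summary(calls, area_gate = c(158, 537))
  expect_equal(s$pct[s$cell_type == "msn"], 95.0)
  expect_equal(s$pct[s$cell_type == "gaba_interneuron"], 2.5)
  expect_equal(s$total[1], 120)

  het <- data.frame(somatic_area = 300,
                    cell_type = rep(c("msn", "gaba_interneuron", "unclassified"),
                                    c(89, 5, 2)))
  sh <- population_summary(het, area_gate = NULL)
  expect_equal(round(sh$pct[sh$cell_type == "msn"], 1), 92.7)
  expect_equal(round(sh$pct[sh$cell_type == "gaba_interneuron"], 1), 5.2)

  ## single class and gating behavior
  one <- data.frame(somatic_area = c(300, 50), cell_type = "msn")
  s1 <- population_summary(one, area_gate = c(158, 537))
  expect_equal(s1$pct[s1$cell_type == "msn"], 100)
  expect_equal(s1$total[1], 1)
  expect_warning(population_summary(one, area_gate = c(1000, 2000)), "gate")
})

test_that("responder fractions use the reference-derived size gate", {
  wt <- data.frame(
    somatic_area = c(seq(158.03, 536.68, length.out = 37),   # responders
                     seq(160, 500, length.out = 6),          # gated non-resp
                     seq(60, 150, length.out = 10)),         # below the gate
    responded = rep(c(TRUE, FALSE, FALSE), c(37, 6, 10)))
  rf <- responder_fraction(wt)
  expect_equal(rf$gate_lower, 158.03)
  expect_equal(rf$n_gated, 43)
  expect_equal(round(rf$pct), 86)

  het <- data.frame(
    somatic_area = c(seq(170, 520, length.out = 37),
                     seq(160, 500, length.out = 9),
                     seq(60, 150, length.out = 12)),
    responded = rep(c(TRUE, FALSE, FALSE), c(37, 9, 12)))
  rf2 <- responder_fraction(het, reference = wt)
  expect_equal(rf2$n_gated, 46)
  expect_equal(round(rf2$pct), 80)

  ## gate invariance: adding small non-responders changes nothing
  het_more <- rbind(het, data.frame(somatic_area = runif(20, 50, 150),
                                    responded = FALSE))
  expect_equal(responder_fraction(het_more, reference = wt)$pct, rf2$pct)

  all_resp <- data.frame(somatic_area = c(200, 300), responded = TRUE)
  expect_equal(responder_fraction(all_resp)$pct, 100)
  expect_error(responder_fraction(data.frame(somatic_area = 200,
                                             responded = FALSE)),
               "undefined")
})
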