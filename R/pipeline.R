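#' Default run configuration
#'
#' Assembles the configuration used by the orchestration commands, echoing
#' every analysis threshold (5 x RMS detection, r^2 >= 0.990 fit
#' acceptance, 95% band confidence, 158-537 um^2 area gate) so that output
#' metadata fully documents a run.
#'
#' @param ... overrides of the defaults.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_neurons = 3,
    area_range = c(158, 537),
    n_dendrites = 2,
    dendrite_length_px = c(20, 30),
    protocol = list(n_pulses = 10, frequency = 1, pre_window = 2,
                    post_window = 2),
    kinetics = list(amplitude_a = 0.5, tau = 2),
    noise = list(dark_offset = 100, read_noise_sd = 2, photon_scale = 1),
    dims = c(96, 96),
    frame_interval = 0.01,
    rms_multiplier = 5,
    r2_min = 0.990,
    filter_detect_hz = 15,
    filter_fit_hz = 5,
    band_confidence = 0.95,
    area_gate = c(158, 537),
    group = "wildtype")
  utils::modifyList(cfg, list(...))
}

#' Simulate a set of neurons to disk
#'
#' Generates `n_neurons` seeded geometries and image stacks and writes each
#' as 16-bit TIFF + dark TIFF + YAML sidecar. The sidecar stores the full
#' generator parameters and per-neuron seed, so a run is reproducible
#' bit-identically from its output directory alone.
#'
#' @param config list from [default_config()].
#' @param out_dir output directory (created if needed).
#' @param seed mandatory integer seed.
#' @return Data frame of written stack paths, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir, seed) {
  if (missing(seed) || is.null(seed))
    stopf("a seed is required for simulation runs")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  protocol <- do.call(stimulus_protocol, config$protocol)
  paths <- character(config$n_neurons)
  for (i in seq_len(config$n_neurons)) {
    seed_i <- as.integer(seed) + i
    geom <- make_geometry(area_range = config$area_range,
                          n_dendrites = config$n_dendrites,
                          dendrite_length_px = config$dendrite_length_px,
                          dims = config$dims, seed = seed_i)
    kin <- do.call(kinetics_params, config$kinetics)
    noise <- do.call(noise_params, c(config$noise, list(seed = seed_i)))
    stack <- simulate_stack(geom, kin, protocol, noise,
                            frame_interval = config$frame_interval)
    paths[i] <- file.path(out_dir, sprintf("neuron_%03d.tif", i))
    write_stack_tiff(stack, paths[i], sidecar = list(
      neuron = i, seed = seed_i, group = config$group,
      geometry_params = list(area_range = config$area_range,
                             n_dendrites = config$n_dendrites,
                             dendrite_length_px = config$dendrite_length_px,
                             dims = config$dims),
      kinetics = config$kinetics,
      noise = config$noise,
      peak_mode = kin$peak_mode,
      protocol = config$protocol))
  }
  yaml::write_yaml(c(config, list(seed = seed,
                                  package_version = as.character(utils::packageVersion("calcitrace")))),
                   file.path(out_dir, "provenance.yaml"))
  invisible(data.frame(neuron = seq_along(paths), path = paths))
}

#' Analyze a directory of simulated/recorded stacks
#'
#' For every stack + sidecar pair: dark subtraction, F0, dF/F0, geometry
#' regeneration from the sidecar seed, ROI placement on each dendrite,
#' trace extraction, and full transient metrics. Writes `metrics.csv` (one
#' row per dendrite x pulse) and `analysis.yaml` (thresholds echoed).
#'
#' @param stacks_dir directory produced by [run_simulate()].
#' @param out_dir output directory.
#' @param config analysis thresholds ([default_config()]).
#' @return The metrics data frame, invisibly.
#' @export
run_analyze <- function(stacks_dir, out_dir = stacks_dir,
                        config = default_config()) {
  tifs <- list.files(stacks_dir, pattern = "^neuron_[0-9]+\\.tiff?$",
                     full.names = TRUE)
  if (!length(tifs)) stopf("no stacks found in %s", stacks_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (tif in tifs) {
    stack <- read_stack_tiff(tif)
    meta <- stack$sidecar
    if (is.null(meta$dark_tiff)) stopf("missing dark frames for %s", tif)
    protocol <- do.call(stimulus_protocol, meta$protocol)
    gp <- meta$geometry_params
    geom <- make_geometry(area_range = unlist(gp$area_range),
                          n_dendrites = gp$n_dendrites,
                          dendrite_length_px = unlist(gp$dendrite_length_px),
                          dims = unlist(gp$dims), seed = meta$seed)
    sub <- subtract_dark(stack)
    f0 <- compute_f0(sub, protocol)
    dff <- compute_dff(sub, f0)
    for (d in seq_along(geom$dendrites)) {
      rois <- place_rois(geom, d)
      if (!isTRUE(rois$accepted)) {
        rows[[length(rows) + 1]] <- data.frame(
          neuron = meta$neuron, group = meta$group %||% NA, dendrite = d,
          rejected = rois$reason, pulse = NA, detected = NA,
          amplitude = NA, tau = NA, r_squared = NA, tau_valid = NA,
          cumulative_load = NA, rms_noise = NA, f0 = NA,
          dendrite_width = NA)
        next
      }
      trace <- extract_roi_trace(dff, rois)
      m <- transient_metrics(trace, protocol,
                             filter_detect = config$filter_detect_hz,
                             filter_fit = config$filter_fit_hz,
                             rms_mult = config$rms_multiplier,
                             r2_min = config$r2_min)
      rows[[length(rows) + 1]] <- data.frame(
        neuron = meta$neuron, group = meta$group %||% NA, dendrite = d,
        rejected = NA_character_, pulse = m$pulse, detected = m$detected,
        amplitude = m$amplitude, tau = m$tau, r_squared = m$r_squared,
        tau_valid = m$tau_valid, cumulative_load = m$cumulative_load,
        rms_noise = m$rms_noise, f0 = m$f0,
        dendrite_width = rois$dendrite_width)
    }
  }
  metrics <- do.call(rbind, rows)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  yaml::write_yaml(list(rms_multiplier = config$rms_multiplier,
                        r2_min = config$r2_min,
                        filter_detect_hz = config$filter_detect_hz,
                        filter_fit_hz = config$filter_fit_hz,
                        photobleach_correction = FALSE),
                   file.path(out_dir, "analysis.yaml"))
  invisible(metrics)
}

#' Classify an immunostained cell table
#'
#' Reads a per-cell CSV (columns `cell_id`, `somatic_area`,
#' `primary_antibody_present`, marker intensity columns, optional `group`),
#' fits one negative-control band per marker, classifies the stained
#' cells, and writes `calls.csv`, `bands.json` and the gated `summary.csv`.
#'
#' @param cells_csv input CSV path or a data frame.
#' @param out_dir output directory.
#' @param markers marker channels to band-fit and classify.
#' @param config thresholds ([default_config()]); uses `band_confidence`
#'   and `area_gate`.
#' @return List with `calls`, `bands`, `summary`, invisibly.
#' @export
run_classify <- function(cells_csv, out_dir,
                         markers = c("gad65", "darpp32", "vacht", "vgat"),
                         config = default_config()) {
  cells <- if (is.character(cells_csv)) read.csv(cells_csv) else cells_csv
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  controls <- cells[!cells$primary_antibody_present, ]
  if (!nrow(controls)) stopf("fit error: no negative-control records")
  markers <- intersect(markers, names(cells))
  bands <- lapply(markers, function(m)
    fit_band(data.frame(somatic_area = controls$somatic_area,
                        intensity = controls[[m]]),
             confidence = config$band_confidence))
  names(bands) <- markers
  stained <- cells[cells$primary_antibody_present, ]
  calls <- classify_cells(stained, bands)
  summary <- population_summary(calls, area_gate = config$area_gate)
  write.csv(calls, file.path(out_dir, "calls.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(bands, function(b) b[c("intercept", "slope", "residual_sd",
                                  "n_control", "confidence")]),
    file.path(out_dir, "bands.json"), auto_unbox = TRUE, digits = NA)
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  invisible(list(calls = calls, bands = bands, summary = summary))
}

#' Group comparison report over an analyzed metrics table
#'
#' Per-pulse two-group comparisons (log t-test) of peak amplitude and
#' cumulative load, using the `group` column of `metrics.csv`.
#'
#' @param metrics data frame or path to a `metrics.csv` from
#'   [run_analyze()].
#' @param out_dir optional directory to write `comparisons.csv` into.
#' @return Data frame of comparisons, invisibly.
#' @export
run_report <- function(metrics, out_dir = NULL) {
  m <- if (is.character(metrics)) read.csv(metrics) else metrics
  m <- m[!is.na(m$pulse) & m$detected %in% TRUE, ]
  groups <- unique(m$group)
  if (length(groups) != 2)
    stopf("report needs exactly 2 groups, found %d", length(groups))
  out <- do.call(rbind, lapply(sort(unique(m$pulse)), function(k) {
    mk <- m[m$pulse == k, ]
    one <- function(metric) {
      a <- mk[[metric]][mk$group == groups[1]]
      b <- mk[[metric]][mk$group == groups[2]]
      a <- a[is.finite(a) & a > 0]; b <- b[is.finite(b) & b > 0]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      cmp <- log_t_test(a, b)
      data.frame(metric = metric, pulse = k,
                 group_a = groups[1], group_b = groups[2],
                 n_a = cmp$n_a, n_b = cmp$n_b,
                 mean_a = cmp$mean_a, sem_a = cmp$sem_a,
                 mean_b = cmp$mean_b, sem_b = cmp$sem_b,
                 t = cmp$t, p = cmp$p, percent_diff = cmp$percent_diff)
    }
    rbind(one("amplitude"), one("cumulative_load"))
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(out_dir, "comparisons.csv"), row.names = FALSE)
  }
  invisible(out)
}
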