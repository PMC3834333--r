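#' Immunostaining population parameters
#'
#' Describes a synthetic population of immunostained striatal cells: a
#' mixture of medium spiny neurons (MSN), GABAergic interneurons and
#' cholinergic interneurons, plus negative-control cells stained without
#' primary antibody. Cellular background intensity grows linearly with
#' log10 somatic area (as negative controls do in these preparations) and
#' channels for which a cell truly carries the antigen are brighter by
#' `positive_multiplier`.
#'
#' @param n_cells number of antibody-stained cells.
#' @param fractions named or ordered proportions of (msn,
#'   gaba_interneuron, cholinergic); must sum to 1.
#' @param area_log10_range range of log10 somatic area (um^2) for the
#'   GABAergic classes.
#' @param chol_area_log10_range log10 area range for cholinergic cells
#'   (these somata are distinctly larger).
#' @param background_intercept,background_slope negative-control intensity
#'   model: `intercept + slope * log10(area)` a.u.
#' @param background_sd Gaussian SD of intensity around the background line
#'   (a.u., > 0).
#' @param positive_multiplier fold-intensity of antigen-positive channels
#'   over background (> 1).
#' @param n_controls number of negative-control (no primary antibody) cells.
#' @param seed integer seed.
#' @return An object of class `immuno_population_params`.
#' @export
immuno_population_params <- function(n_cells = 120,
                                     fractions = c(msn = 0.95,
                                                   gaba_interneuron = 0.04,
                                                   cholinergic = 0.01),
                                     area_log10_range = log10(c(100, 600)),
                                     chol_area_log10_range = log10(c(600, 850)),
                                     background_intercept = -200,
                                     background_slope = 150,
                                     background_sd = 30,
                                     positive_multiplier = 5,
                                     n_controls = 100,
                                     seed = NULL) {
  if (length(fractions) != 3)
    stopf("fractions must give proportions for 3 classes")
  if (abs(sum(fractions) - 1) > 1e-8)
    stopf("parameter error: fractions sum to %.4f, not 1", sum(fractions))
  if (background_sd <= 0) stopf("background_sd must be > 0")
  if (positive_multiplier <= 1) stopf("positive_multiplier must be > 1")
  if (is.null(names(fractions)))
    names(fractions) <- c("msn", "gaba_interneuron", "cholinergic")
  structure(list(n_cells = n_cells, fractions = fractions,
                 area_log10_range = area_log10_range,
                 chol_area_log10_range = chol_area_log10_range,
                 background_intercept = background_intercept,
                 background_slope = background_slope,
                 background_sd = background_sd,
                 positive_multiplier = positive_multiplier,
                 n_controls = n_controls, seed = seed),
            class = "immuno_population_params")
}

## which marker channels are truly antigen-positive for each class
marker_truth <- list(
  msn              = c("gad65", "darpp32", "vgat"),
  gaba_interneuron = c("gad65", "vgat"),
  cholinergic      = c("vacht"))

#' Simulate an immunostained cell population
#'
#' Draws class labels from the configured mixture, somatic areas uniform in
#' log10 within the class range, and four marker-channel intensities
#' (GAD65, DARPP-32, VAChT, VGAT). Every channel starts from the background
#' model `intercept + slope * log10(area) + N(0, sd)` (floored at 0);
#' antigen-positive channels are multiplied by `positive_multiplier`.
#' Negative-control cells (no primary antibody) carry pure background in
#' every channel. Deterministic per seed.
#'
#' @param params an [immuno_population_params()] object.
#' @return A data frame with one row per cell: `cell_id`, `true_class`
#'   (NA for controls), `somatic_area` (um^2), `primary_antibody_present`,
#'   and intensity columns `gad65`, `darpp32`, `vacht`, `vgat`.
#' @examples
#' cells <- simulate_immuno(immuno_population_params(seed = 1))
#' table(cells$true_class)
#' @export
simulate_immuno <- function(params) {
  stopifnot(inherits(params, "immuno_population_params"))
  classes <- names(params$fractions)
  markers <- c("gad65", "darpp32", "vacht", "vgat")
  with_seed(params$seed, {
    lab <- sample(classes, params$n_cells, replace = TRUE,
                  prob = params$fractions)
    rng <- function(n, r) 10^runif(n, r[1], r[2])
    area <- ifelse(lab == "cholinergic",
                   rng(params$n_cells, params$chol_area_log10_range),
                   rng(params$n_cells, params$area_log10_range))
    area_ctl <- rng(params$n_controls, params$area_log10_range)

    background <- function(a, n) {
      pmax(params$background_intercept +
             params$background_slope * log10(a) +
             rnorm(n, 0, params$background_sd), 0)
    }
    cells <- data.frame(cell_id = sprintf("cell_%03d", seq_len(params$n_cells)),
                        true_class = lab, somatic_area = area,
                        primary_antibody_present = TRUE)
    for (m in markers) {
      v <- background(area, params$n_cells)
      pos <- vapply(lab, function(l) m %in% marker_truth[[l]], logical(1))
      v[pos] <- v[pos] * params$positive_multiplier
      cells[[m]] <- v
    }
    ctl <- data.frame(cell_id = sprintf("ctrl_%03d", seq_len(params$n_controls)),
                      true_class = NA_character_, somatic_area = area_ctl,
                      primary_antibody_present = FALSE)
    for (m in markers) ctl[[m]] <- background(area_ctl, params$n_controls)
    rbind(cells, ctl)
  })
}
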