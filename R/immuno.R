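#' Somatic line intensity
#'
#' The somatic staining intensity of a cell: the peak value of the
#' intensity profile along a line drawn through the center of the soma,
#' after the profile is smoothed with a 7-pixel running average.
#'
#' @param image 2-D numeric matrix of fluorescence intensity.
#' @param line matrix or data frame of ordered pixel coordinates
#'   (columns `row`, `col`), at least `window` pixels long.
#' @param window running-average length in pixels (default 7).
#' @return Somatic intensity (a.u.).
#' @export
somatic_intensity <- function(image, line, window = 7) {
  line <- as.matrix(line[, c("row", "col")])
  if (nrow(line) < window)
    stopf("input error: line of %d pixels is shorter than the %d-pixel window",
          nrow(line), window)
  if (any(line[, 1] < 1 | line[, 1] > nrow(image) |
            line[, 2] < 1 | line[, 2] > ncol(image)))
    stopf("input error: line pixel outside the image")
  profile <- image[line]
  smoothed <- stats::filter(profile, rep(1 / window, window), sides = 2)
  max(smoothed, na.rm = TRUE)
}

#' Fit the negative-control intensity band
#'
#' Ordinary least squares of intensity on log10 somatic area over
#' negative-control cells (stained without primary antibody), with the 95%
#' uniform (simultaneous) confidence band realized as the
#' Working-Hotelling-Scheffe two-parameter band:
#' `halfwidth(x) = sqrt(2 F_{conf}(2, n-2)) * SE(fitted value at x)`.
#' Whatever the somatic area, the band covers the mean control intensity
#' line with the stated probability; its upper limit is the
#' marker-positivity threshold.
#'
#' @param controls data frame of negative-control cells with columns
#'   `somatic_area` (um^2) and `intensity` (a.u.); at least 10 records
#'   with non-degenerate area spread.
#' @param confidence simultaneous coverage probability (default 0.95).
#' @return An object of class `band_model`: `intercept`, `slope` (on the
#'   log10-area scale), `residual_sd`, `n_control`, `confidence`, and the
#'   internals needed to evaluate the band (`x_mean`, `sxx`, `xtx`, `s2`,
#'   `df`, `x_range`).
#' @export
fit_band <- function(controls, confidence = 0.95) {
  if (!all(c("somatic_area", "intensity") %in% names(controls)))
    stopf("controls need columns somatic_area and intensity")
  controls <- controls[is.finite(controls$somatic_area) &
                         is.finite(controls$intensity), ]
  n <- nrow(controls)
  if (n < 10) stopf("fit error: need >= 10 control records, got %d", n)
  x <- log10(controls$somatic_area)
  if (var(x) == 0) stopf("fit error: zero variance in somatic area")
  fit <- lm(controls$intensity ~ x)
  s2 <- sum(fit$residuals^2) / (n - 2)
  structure(
    list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
         residual_sd = sqrt(s2), n_control = n, confidence = confidence,
         x_mean = mean(x), sxx = sum((x - mean(x))^2),
         xtx = crossprod(cbind(1, x)), s2 = s2, df = n - 2,
         x_range = range(x)),
    class = "band_model")
}

#' @export
print.band_model <- function(x, ...) {
  cat(sprintf(paste0("<band_model> intensity = %.1f + %.1f * log10(area), ",
                     "residual SD %.1f (n = %d, %.0f%% simultaneous band)\n"),
              x$intercept, x$slope, x$residual_sd, x$n_control,
              100 * x$confidence))
  invisible(x)
}

#' Band half-width and threshold of a fitted band model
#'
#' `band_halfwidth()` evaluates the simultaneous-band half-width at given
#' somatic areas; `band_upper()` (fitted line + half-width) is the
#' intensity threshold used for positivity calls; `band_lower()` is
#' computed for completeness but unused by classification.
#'
#' @param band a [fit_band()] model.
#' @param area somatic areas (um^2).
#' @return Numeric vector of a.u. values.
#' @export
band_halfwidth <- function(band, area) {
  x <- log10(area)
  se_fit <- sqrt(band$s2 * (1 / band$n_control + (x - band$x_mean)^2 / band$sxx))
  sqrt(2 * qf(band$confidence, 2, band$df)) * se_fit
}

#' @rdname band_halfwidth
#' @export
band_upper <- function(band, area) {
  band$intercept + band$slope * log10(area) + band_halfwidth(band, area)
}

#' @rdname band_halfwidth
#' @export
band_lower <- function(band, area) {
  band$intercept + band$slope * log10(area) - band_halfwidth(band, area)
}

#' Does the band contain a given true line?
#'
#' Exact test of whether the entire line `intercept + slope * x` lies
#' inside the simultaneous band for all x, via the equivalent quadratic
#' form in the regression coefficients (the Scheffe construction):
#' `(b - beta)' X'X (b - beta) <= 2 s^2 F_conf(2, n-2)`. Used by coverage
#' simulations.
#'
#' @param band a [fit_band()] model.
#' @param intercept,slope the candidate true line (log10-area scale).
#' @return Logical.
#' @export
band_contains_line <- function(band, intercept, slope) {
  d <- c(band$intercept - intercept, band$slope - slope)
  q <- drop(t(d) %*% band$xtx %*% d)
  q <= 2 * band$s2 * qf(band$confidence, 2, band$df)
}

#' Classify cells as marker-positive/negative and assign cell types
#'
#' A cell is positive for a marker when its channel intensity strictly
#' exceeds the upper band limit at its somatic area (ties are negative).
#' Cell types follow the marker logic of these cultures: medium spiny
#' neuron = GAD65+ and DARPP-32+; GABAergic interneuron = GAD65+ and
#' DARPP-32-; cholinergic interneuron = (GAD65- or VGAT-) and VAChT+;
#' anything else (or a cell with a missing required channel) is
#' unclassified.
#'
#' @param records data frame with `somatic_area` and marker intensity
#'   columns named as in `bands`.
#' @param bands named list of [fit_band()] models, one per marker channel
#'   (e.g. `gad65`, `darpp32`, `vacht`, `vgat`).
#' @return `records` with added logical columns `<marker>_pos` and a
#'   `cell_type` factor in (msn, gaba_interneuron, cholinergic,
#'   unclassified).
#' @export
classify_cells <- function(records, bands) {
  stopifnot(is.list(bands), length(names(bands)) == length(bands))
  for (m in names(bands)) {
    if (!m %in% names(records)) {
      records[[paste0(m, "_pos")]] <- NA
      next
    }
    records[[paste0(m, "_pos")]] <-
      records[[m]] > band_upper(bands[[m]], records$somatic_area)
  }
  g <- records$gad65_pos
  d <- records$darpp32_pos
  va <- if ("vacht_pos" %in% names(records)) records$vacht_pos else NA
  vg <- if ("vgat_pos" %in% names(records)) records$vgat_pos else NA

  type <- rep("unclassified", nrow(records))
  gaba_like <- !is.na(g) & g & !is.na(d)
  type[gaba_like & d] <- "msn"
  type[gaba_like & !d] <- "gaba_interneuron"
  chol <- !is.na(va) & va &
    ((!is.na(g) & !g) | (!is.na(vg) & !vg)) & type == "unclassified"
  type[chol] <- "cholinergic"
  records$cell_type <- factor(type, levels = c("msn", "gaba_interneuron",
                                               "cholinergic", "unclassified"))
  records
}

#' Cell-type proportions within an area gate
#'
#' Counts and percentages of each cell type among cells whose somatic area
#' falls inside the gate (the range of somatic areas over which calcium
#' responders are observed, 158-537 um^2, by default). When a `group`
#' column is present, one block of rows per group is produced.
#'
#' @param calls output of [classify_cells()] (or any data frame with
#'   `somatic_area` and `cell_type`).
#' @param area_gate inclusive area interval in um^2, or `NULL` for no gate.
#' @return A data frame: `group`, `cell_type`, `count`, `total`, `pct`.
#'   Empty after gating gives a zero-row table with a warning.
#' @export
population_summary <- function(calls, area_gate = c(158, 537)) {
  if (!nrow(calls)) stopf("input error: no cells supplied")
  if (!is.null(area_gate))
    calls <- calls[calls$somatic_area >= area_gate[1] &
                     calls$somatic_area <= area_gate[2], ]
  if (!nrow(calls)) {
    warning("no cells inside the area gate", call. = FALSE)
    return(data.frame(group = character(0), cell_type = character(0),
                      count = integer(0), total = integer(0), pct = numeric(0)))
  }
  groups <- if ("group" %in% names(calls)) split(calls, calls$group)
            else list(all = calls)
  out <- do.call(rbind, lapply(names(groups), function(gn) {
    gc <- groups[[gn]]
    lv <- levels(factor(gc$cell_type,
                        levels = c("msn", "gaba_interneuron", "cholinergic",
                                   "unclassified")))
    tab <- table(factor(gc$cell_type, levels = lv))
    data.frame(group = gn, cell_type = names(tab),
               count = as.integer(tab), total = nrow(gc),
               pct = 100 * as.integer(tab) / nrow(gc))
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of neurons responding to stimulation, within a size gate
#'
#' The responder fraction after excluding the small neurons in which no
#' response is ever observed: the gate's lower bound defaults to the
#' smallest somatic area among responders of the reference group (158 um^2
#' in the wild-type reference), and the fraction is responders / all
#' neurons at or above the gate.
#'
#' @param neurons data frame with columns `somatic_area` (um^2) and
#'   `responded` (logical).
#' @param gate_lower explicit lower area bound; default derives it from
#'   `reference` (or from `neurons` itself).
#' @param reference optional reference data frame (same columns) whose
#'   responders define the gate.
#' @return A list: `fraction`, `pct`, `n_responders`, `n_gated`,
#'   `gate_lower`.
#' @export
responder_fraction <- function(neurons, gate_lower = NULL, reference = NULL) {
  if (!nrow(neurons)) stopf("input error: no neurons supplied")
  if (is.null(gate_lower)) {
    ref <- reference %||% neurons
    if (!any(ref$responded))
      stopf("no responders in the reference group: the gate is undefined")
    gate_lower <- min(ref$somatic_area[ref$responded])
  }
  gated <- neurons[neurons$somatic_area >= gate_lower, ]
  n_resp <- sum(gated$responded)
  list(fraction = n_resp / nrow(gated), pct = 100 * n_resp / nrow(gated),
       n_responders = n_resp, n_gated = nrow(gated), gate_lower = gate_lower)
}
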