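#' Generate a synthetic neuron geometry
#'
#' Draws a soma (disc), a nucleus and straight dendrites on a pixel grid.
#' Dendrite centerlines start at the nucleus center, cross the soma and
#' extend outward; the index of the first centerline point outside the soma
#' is recorded as the soma-dendrite border. The somatic area is drawn
#' uniformly from `area_range` (the default range covers the somatic areas
#' over which responding neurons are observed in these cultures).
#'
#' @param area_range somatic area range in um^2 (min, max).
#' @param n_dendrites number of dendrites.
#' @param dendrite_length_px range (min, max) of dendrite length in pixels
#'   beyond the soma-dendrite border; every dendrite has at least 13 pixels
#'   beyond the border so the short-dendrite exclusion rule is exercisable.
#' @param dendrite_width_um range (min, max) of dendrite width at the border
#'   (um); widths taper linearly to 80% at the tip.
#' @param pixel_size pixel pitch in um (camera default 1.18).
#' @param dims image dimensions (rows, cols) in pixels.
#' @param branch_at optional list (one element per dendrite) of centerline
#'   indices, counted from the border, annotated as branch points.
#' @param seed integer seed; identical seeds give identical geometries.
#' @return An object of class `neuron_geometry` with fields `soma_outline`
#'   (closed polygon, pixel coords), `soma_area` (um^2), `soma_radius_px`,
#'   `nucleus_center`, `nucleus_radius_px`, `dendrites` (list of paths with
#'   per-point widths and border index), `pixel_size`, `dims`.
#' @examples
#' geom <- make_geometry(seed = 1)
#' geom$soma_area
#' @export
make_geometry <- function(area_range = c(158, 537),
                          n_dendrites = 2,
                          dendrite_length_px = c(20, 30),
                          dendrite_width_um = c(2.8, 3.6),
                          pixel_size = 1.18,
                          dims = c(96, 96),
                          branch_at = NULL,
                          seed = NULL) {
  if (area_range[1] >= area_range[2])
    stopf("degenerate area_range: min (%g) >= max (%g)", area_range[1], area_range[2])
  if (dendrite_length_px[1] > dendrite_length_px[2] ||
      dendrite_width_um[1] > dendrite_width_um[2])
    stopf("degenerate dendrite length/width range")
  if (dendrite_length_px[1] < 13)
    stopf("dendrite_length_px must allow >= 13 pixels beyond the border")
  if (n_dendrites < 1) stopf("need at least one dendrite")

  with_seed(seed, {
    area <- runif(1, area_range[1], area_range[2])
    r_px <- sqrt(area / pi) / pixel_size
    center <- floor(dims / 2) + 0.5       # between-pixel center keeps discs symmetric
    max_len <- max(dendrite_length_px)
    if (r_px + max_len + 2 > min(dims) / 2)
      stopf("geometry does not fit in a %dx%d image (soma radius %.1f px + dendrite %d px)",
            dims[1], dims[2], r_px, max_len)

    angles <- 2 * pi * (seq_len(n_dendrites) - 1) / n_dendrites +
      runif(n_dendrites, -0.3, 0.3) + runif(1, 0, 2 * pi)
    lengths <- round(runif(n_dendrites, dendrite_length_px[1], dendrite_length_px[2]))
    base_w <- runif(n_dendrites, dendrite_width_um[1], dendrite_width_um[2])

    dendrites <- vector("list", n_dendrites)
    for (j in seq_len(n_dendrites)) {
      total <- ceiling(r_px) + lengths[j] + 2
      target <- center + total * c(sin(angles[j]), cos(angles[j]))  # (row, col)
      path <- bresenham(round(center - 0.5), round(target))
      d_center <- sqrt((path[, 1] - center[1])^2 + (path[, 2] - center[2])^2)
      border <- which(d_center > r_px)[1]
      if (is.na(border)) stopf("internal: dendrite %d never leaves the soma", j)
      keep <- min(nrow(path), border + lengths[j] - 1)
      path <- path[seq_len(keep), , drop = FALSE]
      n_out <- keep - border + 1
      ## width: soma portion carries the border width; taper to 80% at the tip
      w <- rep(base_w[j], keep)
      if (n_out > 1)
        w[border:keep] <- base_w[j] * (1 - 0.2 * (seq_len(n_out) - 1) / (n_out - 1))
      bp <- if (is.null(branch_at) || length(branch_at) < j) integer(0) else branch_at[[j]]
      dendrites[[j]] <- list(path = path, width_um = w, border = border,
                             angle = angles[j], branch_at = bp %||% integer(0))
    }

    theta <- seq(0, 2 * pi, length.out = 25)
    outline <- cbind(row = center[1] + r_px * sin(theta),
                     col = center[2] + r_px * cos(theta))

    structure(
      list(soma_outline = outline,
           soma_area = area,
           soma_radius_px = r_px,
           soma_center = center,
           nucleus_center = center,
           nucleus_radius_px = 0.45 * r_px,
           dendrites = dendrites,
           pixel_size = pixel_size,
           dims = as.integer(dims)),
      class = "neuron_geometry")
  })
}

#' @export
print.neuron_geometry <- function(x, ...) {
  cat(sprintf("<neuron_geometry> soma %.1f um^2 (r = %.1f px), %d dendrite(s), %dx%d px grid\n",
              x$soma_area, x$soma_radius_px, length(x$dendrites),
              x$dims[1], x$dims[2]))
  invisible(x)
}

## 8-connected integer line walk from p0 to p1 (inclusive), (row, col)
bresenham <- function(p0, p1) {
  d <- p1 - p0
  n <- max(abs(d))
  steps <- round(outer(0:n, d / n))
  cbind(row = p0[1] + steps[, 1], col = p0[2] + steps[, 2])
}

#' Extract the nucleus-to-dendrite pixel path of a geometry
#'
#' Returns the ordered centerline pixels of one dendrite, starting at the
#' nucleus center, with an anatomical label per pixel (`nucleus`, `soma`, or
#' `dendrite`) and a 0-based position index.
#'
#' @param geom a [make_geometry()] object.
#' @param dendrite_id which dendrite (1-based).
#' @return A data frame with columns `row`, `col`, `label`, `position`.
#' @export
pixel_path <- function(geom, dendrite_id = 1) {
  if (dendrite_id < 1 || dendrite_id > length(geom$dendrites))
    stopf("dendrite %s does not exist", dendrite_id)
  den <- geom$dendrites[[dendrite_id]]
  p <- den$path
  d <- sqrt((p[, 1] - geom$soma_center[1])^2 + (p[, 2] - geom$soma_center[2])^2)
  label <- ifelse(d <= geom$nucleus_radius_px, "nucleus",
                  ifelse(d <= geom$soma_radius_px, "soma", "dendrite"))
  data.frame(row = p[, 1], col = p[, 2], label = label,
             position = seq_len(nrow(p)) - 1L)
}
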