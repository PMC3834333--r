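#' Place the standard three-ROI set on a dendrite
#'
#' Places three contiguous 2x2-pixel ROIs end-to-end along the dendrite
#' centerline, with the most proximal pixel 6 pixels (about 7 um at
#' 1.18 um/pixel) from the soma-dendrite border. A dendrite is rejected --
#' a result, not an error -- when it is 12 pixels long or shorter
#' (`too_short`), when the 2-pixel ROI extent exceeds the dendritic width
#' (`too_narrow`), or when a ROI lands on an annotated branch point
#' (`branch_point`).
#'
#' @param geom a [make_geometry()] object (or any list with compatible
#'   `dendrites` entries and `pixel_size`).
#' @param dendrite_id which dendrite.
#' @param roi_distance centerline distance (pixels) from the border to the
#'   most proximal ROI pixel; default 6.
#' @param n_rois number of contiguous ROIs; default 3.
#' @param roi_px ROI edge length in pixels; default 2.
#' @return An object of class `roi_set`. When accepted: `rois` (list of
#'   `list(rows = c(r0, r1), cols = c(c0, c1))`), `dendrite_id`,
#'   `distance_to_soma`, `dendrite_width` (um at the proximal ROI) and
#'   `accepted = TRUE`. When rejected: `accepted = FALSE` and `reason` in
#'   `too_short`, `too_narrow`, `branch_point`.
#' @export
place_rois <- function(geom, dendrite_id = 1, roi_distance = 6,
                       n_rois = 3, roi_px = 2) {
  if (dendrite_id < 1 || dendrite_id > length(geom$dendrites))
    stopf("dendrite %s does not exist in the geometry", dendrite_id)
  den <- geom$dendrites[[dendrite_id]]
  n_out <- nrow(den$path) - den$border + 1     # pixels beyond the border

  reject <- function(reason)
    structure(list(accepted = FALSE, reason = reason,
                   dendrite_id = dendrite_id), class = "roi_set")

  if (n_out <= 12) return(reject("too_short"))
  need <- roi_distance + n_rois * roi_px       # centerline pixels consumed
  if (n_out < need + 1) return(reject("too_short"))

  idx0 <- den$border + roi_distance            # most proximal ROI pixel
  used <- idx0 + seq_len(n_rois * roi_px) - 1
  width_um <- den$width_um[idx0]
  if (width_um < roi_px * geom$pixel_size) return(reject("too_narrow"))
  if (length(den$branch_at) &&
      any((used - den$border) %in% den$branch_at)) return(reject("branch_point"))

  rois <- vector("list", n_rois)
  for (k in seq_len(n_rois)) {
    p1 <- den$path[idx0 + (k - 1) * roi_px, ]
    p2 <- den$path[idx0 + k * roi_px - 1, ]
    rows <- range(p1[1], p2[1]); cols <- range(p1[2], p2[2])
    if (diff(rows) == 0) rows[2] <- rows[1] + 1   # expand degenerate axis
    if (diff(cols) == 0) cols[2] <- cols[1] + 1
    rois[[k]] <- list(rows = as.integer(rows), cols = as.integer(cols))
  }
  structure(list(accepted = TRUE, rois = rois, dendrite_id = dendrite_id,
                 distance_to_soma = roi_distance,
                 dendrite_width = width_um),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  if (isTRUE(x$accepted)) {
    cat(sprintf("<roi_set> %d ROI(s) on dendrite %d, %d px from border, width %.2f um\n",
                length(x$rois), x$dendrite_id, x$distance_to_soma,
                x$dendrite_width))
  } else {
    cat(sprintf("<roi_set> dendrite %d rejected: %s\n", x$dendrite_id, x$reason))
  }
  invisible(x)
}

## linear pixel indices (into a rows-major matrix slice) of an roi_set
roi_pixels <- function(rois, nr, nc) {
  px <- integer(0)
  for (roi in rois$rois) {
    if (roi$rows[1] < 1 || roi$rows[2] > nr || roi$cols[1] < 1 || roi$cols[2] > nc)
      stopf("input error: ROI [%d-%d, %d-%d] outside the %dx%d image",
            roi$rows[1], roi$rows[2], roi$cols[1], roi$cols[2], nr, nc)
    g <- expand.grid(r = roi$rows[1]:roi$rows[2], c = roi$cols[1]:roi$cols[2])
    px <- c(px, g$r + (g$c - 1L) * nr)
  }
  px
}

#' Extract the averaged dF/F0 trace of a ROI set
#'
#' Per-frame mean of dF/F0 over the 12 member pixels (3 ROIs x 4 pixels);
#' since all ROIs have equal pixel counts, averaging ROIs or averaging
#' pixels is identical. The trace carries the mean F0 of the same pixels.
#'
#' @param dff a `dff_stack` from [compute_dff()].
#' @param rois an accepted [place_rois()] result.
#' @return A [dff_trace()] with `source = "roi"`.
#' @export
extract_roi_trace <- function(dff, rois) {
  stopifnot(inherits(dff, "dff_stack"))
  if (!isTRUE(rois$accepted))
    stopf("input error: rejected roi_set (%s) has no trace", rois$reason)
  d <- dim(dff$dff)
  px <- roi_pixels(rois, d[2], d[3])
  m <- matrix(dff$dff, d[1], d[2] * d[3])
  dff_trace(rowMeans(m[, px, drop = FALSE]), dff$time,
            f0_value = mean(dff$f0[px]), source = "roi")
}

#' Extract unaveraged single-pixel traces along a path
#'
#' One dF/F0 trace per path pixel, ordered along the path; each trace
#' carries its anatomical label and 0-based position index as attributes.
#'
#' @param dff a `dff_stack`.
#' @param path a data frame from [pixel_path()] (columns `row`, `col`, and
#'   optionally `label`, `position`).
#' @return A list of [dff_trace()] objects (`source = "pixel"`).
#' @export
extract_path_traces <- function(dff, path) {
  stopifnot(inherits(dff, "dff_stack"))
  if (NROW(path) < 1) stopf("input error: empty pixel path")
  d <- dim(dff$dff)
  if (any(path$row < 1 | path$row > d[2] | path$col < 1 | path$col > d[3]))
    stopf("input error: path pixel outside the image")
  m <- matrix(dff$dff, d[1], d[2] * d[3])
  lapply(seq_len(nrow(path)), function(i) {
    px <- path$row[i] + (path$col[i] - 1L) * d[2]
    tr <- dff_trace(m[, px], dff$time, f0_value = dff$f0[px], source = "pixel")
    attr(tr, "label") <- if ("label" %in% names(path)) path$label[i] else NA
    attr(tr, "position") <- if ("position" %in% names(path)) path$position[i] else i - 1L
    tr
  })
}
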