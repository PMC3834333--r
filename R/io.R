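#' Write an image stack to multi-page TIFF with a sidecar
#'
#' Counts are rounded and written as 16-bit multi-page TIFF (one page per
#' frame); dark frames go to a companion `*_dark.tif`. A YAML sidecar
#' records the frame interval, pixel size, protocol and any generator
#' parameters needed to reproduce the stack.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path (the sidecar is `path` with extension
#'   `.yaml`, the dark stack `_dark.tif`).
#' @param sidecar named list of extra metadata merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, sidecar = list()) {
  stopifnot(inherits(stack, "image_stack"))
  to_pages <- function(arr) {
    nf <- dim(arr)[1]
    lapply(seq_len(nf), function(i)
      pmin(pmax(round(arr[i, , ]), 0), 65535) / 65535)
  }
  tiff::writeTIFF(to_pages(stack$data), path, bits.per.sample = 16,
                  compression = "none")
  dark_path <- sub("\\.tiff?$", "_dark.tif", path)
  tiff::writeTIFF(to_pages(stack$dark_frames), dark_path,
                  bits.per.sample = 16, compression = "none")
  meta <- c(list(frame_interval = stack$frame_interval,
                 pixel_size = stack$pixel_size,
                 n_frames = dim(stack$data)[1],
                 dims = as.integer(dim(stack$data)[2:3]),
                 dark_tiff = basename(dark_path)),
            sidecar)
  yaml::write_yaml(meta, sub("\\.tiff?$", ".yaml", path))
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param path TIFF path (sidecar and dark stack found alongside).
#' @return An `image_stack`.
#' @export
read_stack_tiff <- function(path) {
  meta <- yaml::read_yaml(sub("\\.tiff?$", ".yaml", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  dark_pages <- tiff::readTIFF(file.path(dirname(path), meta$dark_tiff),
                               all = TRUE)
  to_array <- function(pages) {
    nf <- length(pages)
    arr <- array(0, c(nf, dim(pages[[1]])[1], dim(pages[[1]])[2]))
    for (i in seq_len(nf)) arr[i, , ] <- round(pages[[i]] * 65535)
    arr
  }
  data <- to_array(pages)
  structure(list(data = data,
                 dark_frames = to_array(dark_pages),
                 frame_interval = meta$frame_interval,
                 pixel_size = meta$pixel_size,
                 time = (seq_len(dim(data)[1]) - 1) * meta$frame_interval,
                 sidecar = meta),
            class = "image_stack")
}

#' Serialize ROI sets / pixel paths as JSON, traces as CSV
#'
#' ROI coordinates are written 1-based in row/col order with inclusive
#' extents; traces as `time, value, f0` CSV.
#'
#' @param rois an accepted `roi_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois_json <- function(rois, path) {
  jsonlite::write_json(unclass(rois), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois_json
#' @param trace a [dff_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time = trace$time, value = trace$values,
                       f0 = trace$f0_value),
            path, row.names = FALSE)
  invisible(path)
}
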