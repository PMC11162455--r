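# On-disk containers for synthetic study artifacts: epochs as a flat binary
# array with a JSON sidecar, behaviour as CSV, mask sets as JSON, images as
# PNG (when the png package is available).

#' Write / read an epoch set
#'
#' Epochs are stored as little-endian doubles in trial-major order
#' (`data.bin`) next to a JSON sidecar (`meta.json`) carrying channel names,
#' the time axis, labels, sampling rate and subject id.
#'
#' @param epochs An `eeg_epochs`.
#' @param dir Directory (created if missing).
#' @return `write_epochs` returns `dir` invisibly; `read_epochs` the
#'   reconstructed `eeg_epochs`.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(dim = dim(epochs$data), channel_names = epochs$channel_names,
         times_ms = epochs$times_ms, labels = epochs$labels,
         sfreq = epochs$sfreq, subject_id = epochs$subject_id),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(meta$dim), size = 8,
                  endian = "little")
  eeg_epochs(array(vals, meta$dim), meta$times_ms, meta$labels,
             meta$channel_names, meta$sfreq, meta$subject_id)
}

#' Write a mask set to JSON
#'
#' @param masks A `mask_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "mask_set"))
  jsonlite::write_json(
    list(image_id = masks$image_id,
         masks = lapply(masks$masks, function(m) {
           list(area_px = m$area_px, centroid = as.list(m$centroid),
                quality = m$quality,
                rle = if (!is.null(m$rle)) unname(apply(m$rle, 1, as.list)))
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic image as PNG
#'
#' Requires the `png` package.
#'
#' @param image An `image_record` with pixels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the png package is required to write PNG files", call. = FALSE)
  }
  px <- as_pixel_array(image)
  png::writePNG(px / 255, path)
  invisible(path)
}
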