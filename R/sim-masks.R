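# Segmentation-mask synthesis. Masks are axis-aligned rectangles: only the
# quantities consumed downstream (area, centroid, quality) matter, and
# rectangles make run-length encodings and moments exact.

rect_rle <- function(x0, y0, w, h, height) {
  # Runs over the column-major flattening of an H x W logical image.
  starts <- (x0:(x0 + w - 1L) - 1L) * height + y0
  cbind(start = starts, length = rep.int(h, w))
}

#' Decode a run-length-encoded mask
#'
#' @param rle Two-column matrix of `start`/`length` runs over the
#'   column-major flattening of the image.
#' @param image_size `c(width, height)` in pixels.
#' @return Logical height x width matrix.
#' @export
render_mask <- function(rle, image_size) {
  m <- matrix(FALSE, image_size[2], image_size[1])
  idx <- sequence(rle[, "length"], from = rle[, "start"])
  m[idx] <- TRUE
  m
}

rle_area <- function(rle) sum(rle[, "length"])

make_mask <- function(x0, y0, w, h, quality, height) {
  x0 <- unname(x0); y0 <- unname(y0); w <- unname(w); h <- unname(h)
  list(
    area_px = as.integer(w) * as.integer(h),
    centroid = c(x = x0 + (w - 1) / 2, y = y0 + (h - 1) / 2),
    quality = quality,
    bbox = c(x0 = x0, y0 = y0, w = w, h = h),
    rle = rect_rle(as.integer(x0), as.integer(y0), as.integer(w),
                   as.integer(h), as.integer(height))
  )
}

#' Generate a synthetic segmentation-mask set for one image
#'
#' Emulates the output of an automatic segment-everything model: between
#' `config$n_masks_range[1]` and `[2]` masks per image, one of which
#' coincides with the target patch (with a high quality score), the rest
#' random background segments. Areas, centroids and run-length encodings are
#' mutually consistent by construction.
#'
#' @param image An `image_record`.
#' @param config The [sim_config()] used to generate the image.
#' @return A `mask_set`: list with `image_id` and `masks`, each mask holding
#'   `area_px`, `centroid` (x, y), `quality` in \[0, 1\] and an `rle`.
#' @export
#' @examples
#' cfg <- sim_config(image_size = c(90, 60), n_masks_range = c(5, 5))
#' ms <- generate_masks(generate_image(cfg, 1, render = FALSE), cfg)
#' length(ms$masks)
generate_masks <- function(image, config) {
  stopifnot(inherits(image, "image_record"), inherits(config, "sim_config"))
  W <- config$image_size[1]; H <- config$image_size[2]
  rng <- config$n_masks_range
  with_seed(child_seed(config$seed, 2L, image$image_index), {
    n <- if (rng[1] == rng[2]) rng[1] else
      rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    b <- image$target_bbox
    masks <- vector("list", n)
    masks[[1]] <- make_mask(b["x0"], b["y0"], b["w"], b["h"],
                            quality = runif(1, 0.85, 0.99), height = H)
    if (n > 1L) {
      for (i in 2:n) {
        w <- max(2L, round(runif(1, 0.03, 0.25) * W))
        h <- max(2L, round(runif(1, 0.03, 0.25) * H))
        x0 <- sample.int(W - w + 1L, 1L)
        y0 <- sample.int(H - h + 1L, 1L)
        masks[[i]] <- make_mask(x0, y0, w, h,
                                quality = runif(1, 0.5, 0.99), height = H)
      }
    }
    structure(list(image_id = image$image_id, masks = masks),
              class = "mask_set")
  })
}

#' Assemble a mask set from explicit per-mask quantities
#'
#' Escape hatch for feeding externally produced segmentations (or hand-built
#' test cases) into [mask_relational_features()].
#'
#' @param image_id Image identifier.
#' @param area_px,quality Numeric vectors, one entry per mask.
#' @param centroid_x,centroid_y Centroid coordinates in pixels.
#' @return A `mask_set`.
#' @export
mask_set <- function(image_id, area_px, centroid_x, centroid_y, quality) {
  n <- length(area_px)
  stopifnot(length(centroid_x) == n, length(centroid_y) == n,
            length(quality) == n)
  if (n && (any(area_px <= 0) || any(quality < 0 | quality > 1))) {
    stop("areas must be positive and qualities in [0, 1]", call. = FALSE)
  }
  masks <- lapply(seq_len(n), function(i) {
    list(area_px = area_px[i],
         centroid = c(x = centroid_x[i], y = centroid_y[i]),
         quality = quality[i], rle = NULL)
  })
  structure(list(image_id = image_id, masks = masks), class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set %s> %d masks, total area %d px\n", x$image_id,
              length(x$masks),
              sum(vapply(x$masks, `[[`, 0, "area_px"))))
  invisible(x)
}
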