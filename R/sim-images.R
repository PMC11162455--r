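# Stimulus image synthesis: textured backgrounds with a low-contrast
# (camouflaged) rectangular target confined to one of six grid sub-regions.

# Bilinearly upsample a coarse Gaussian grid to h x w: cheap smooth texture.
smooth_field <- function(h, w, grid_h = 12, grid_w = 18, sd = 1) {
  g <- matrix(rnorm(grid_h * grid_w, sd = sd), grid_h, grid_w)
  interp <- function(n, gn) {
    # n x gn weight matrix for piecewise-linear interpolation of grid nodes
    pos <- seq(1, gn, length.out = n)
    lo <- pmin(floor(pos), gn - 1L)
    frac <- pos - lo
    m <- matrix(0, n, gn)
    m[cbind(seq_len(n), lo)] <- 1 - frac
    m[cbind(seq_len(n), lo + 1L)] <- frac
    m
  }
  interp(h, grid_h) %*% g %*% t(interp(w, grid_w))
}

# Pixel-boundary box of sub-region `r` (1..3 top row, 4..6 bottom row) as
# c(x0, x1, y0, y1), 1-based inclusive column/row indices.
subregion_box <- function(r, width, height) {
  if (!r %in% 1:6) stop("`target_subregion` must be in 1..6", call. = FALSE)
  col <- (r - 1L) %% 3L
  row <- (r - 1L) %/% 3L
  c(x0 = floor(col * width / 3) + 1L, x1 = floor((col + 1) * width / 3),
    y0 = floor(row * height / 2) + 1L, y1 = floor((row + 1) * height / 2))
}

size_bin_ratio_range <- function(bin) {
  switch(as.character(bin),
         "0" = c(1 / 96, 1 / 48),
         "1" = c(1 / 48, 1 / 24),
         "2" = c(1 / 24, 1 / 12),
         "3" = c(1 / 12, 1 / 6))
}

species_pool <- c("moth", "gecko", "flounder", "owl", "mantis", "frog",
                  "seahorse", "spider", "toad", "katydid")

# Generate the i-th stimulus image of a configuration. All metadata and
# geometry draws happen before any pixel noise, so records are reproducible.
generate_image <- function(config, index, render = TRUE) {
  W <- config$image_size[1]; H <- config$image_size[2]
  with_seed(child_seed(config$seed, 1L, index), {
    size_bin <- sample(0:3, 1L, prob = config$size_bin_probs)
    ratio <- if (!is.null(config$target_size_ratio)) {
      config$target_size_ratio
    } else {
      rr <- size_bin_ratio_range(size_bin)
      runif(1, rr[1], rr[2])
    }
    if (ratio > 1 / 6 || ratio <= 0) {
      stop("target_size_ratio must lie in (0, 1/6]", call. = FALSE)
    }
    subregion <- sample(1:6, 1L)
    occluded <- as.integer(runif(1) < config$occlusion_rate)
    species <- sample(species_pool, 1L)
    bg <- runif(3, 70, 170)
    gains <- runif(3, 0.7, 1.3)
    delta <- runif(3, 6, 14) * sample(c(-1, 1), 3, replace = TRUE)

    box <- subregion_box(subregion, W, H)
    sw <- box["x1"] - box["x0"] + 1; sh <- box["y1"] - box["y0"] + 1
    area <- ratio * W * H
    amin <- area / sh^2; amax <- sw^2 / area
    lo <- max(amin, 0.5); hi <- min(amax, 2)
    aspect <- if (lo <= hi) runif(1, lo, hi) else max(amin, min(amax, 1))
    tw <- max(2L, round(sqrt(area * aspect)))
    th <- max(2L, round(area / tw))
    tw <- min(tw, sw); th <- min(th, sh)
    x0 <- box["x0"] + sample.int(sw - tw + 1L, 1L) - 1L
    y0 <- box["y0"] + sample.int(sh - th + 1L, 1L) - 1L
    bbox <- c(x0 = unname(x0), y0 = unname(y0), w = tw, h = th)

    occ_bbox <- NULL
    if (occluded) {
      ow <- max(2L, round(tw * runif(1, 0.4, 0.7)))
      oh <- max(2L, round(th * runif(1, 0.4, 0.7)))
      ox <- max(1L, min(W - ow + 1L, x0 + sample.int(tw, 1L) - ow %/% 2L))
      oy <- max(1L, min(H - oh + 1L, y0 + sample.int(th, 1L) - oh %/% 2L))
      occ_bbox <- c(x0 = unname(ox), y0 = unname(oy), w = ow, h = oh)
      occ_delta <- runif(3, 8, 18) * sample(c(-1, 1), 3, replace = TRUE)
    }

    pixels <- NULL
    if (render) {
      field <- smooth_field(H, W, sd = 18)
      fine <- matrix(rnorm(H * W, sd = 5), H, W)
      px <- array(0, c(H, W, 3))
      ys <- y0:(y0 + th - 1L); xs <- x0:(x0 + tw - 1L)
      for (c in 1:3) {
        ch <- bg[c] + gains[c] * field + fine
        ch[ys, xs] <- ch[ys, xs] + delta[c]
        if (occluded) {
          oys <- occ_bbox["y0"]:(occ_bbox["y0"] + occ_bbox["h"] - 1L)
          oxs <- occ_bbox["x0"]:(occ_bbox["x0"] + occ_bbox["w"] - 1L)
          ch[oys, oxs] <- bg[c] + occ_delta[c] + 0.3 * gains[c] * field[oys, oxs]
        }
        px[, , c] <- ch
      }
      pixels <- round(pmin(pmax(px, 0), 255))
      storage.mode(pixels) <- "integer"
    }

    structure(list(
      pixels = pixels,
      image_id = sprintf("img%04d", index),
      image_index = as.integer(index),
      target_subregion = subregion,
      target_size_ratio = ratio,
      occluded = occluded,
      species_hint = species,
      target_bbox = bbox,
      occluder_bbox = occ_bbox,
      image_size = config$image_size
    ), class = "image_record")
  })
}

#' Generate synthetic camouflage stimulus images
#'
#' Renders `n` RGB images with a smoothly textured background and a
#' low-contrast rectangular target patch placed wholly inside one of six
#' equal grid sub-regions (numbered 1-3 across the top row, 4-6 across the
#' bottom, so 2 and 5 are the central columns). The patch occupies the
#' image-area fraction drawn for its size level; occluded images carry an
#' occluder patch overlapping the target. Output is deterministic for a
#' fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @param n Number of images; defaults to `config$n_trials_per_subject`
#'   (every subject sees the same image set, one image per trial).
#' @param render If `FALSE`, skip pixel rendering and return metadata-only
#'   records (geometry and difficulty covariates are unchanged).
#' @return A list of `image_record` objects with fields `pixels`
#'   (height x width x 3 integer array, 0-255, `NULL` when `render = FALSE`),
#'   `image_id`, `target_subregion`, `target_size_ratio`, `occluded`,
#'   `species_hint` and the target bounding box.
#' @export
#' @examples
#' imgs <- generate_images(sim_config(image_size = c(90, 60)), n = 3)
#' sapply(imgs, function(x) x$target_subregion)
generate_images <- function(config, n = NULL, render = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n <- n %||% config$n_trials_per_subject
  lapply(seq_len(n), function(i) generate_image(config, i, render = render))
}

#' Logical mask of the target patch of a synthetic image
#'
#' @param image An `image_record`.
#' @return A height x width logical matrix, `TRUE` on target pixels.
#' @export
target_mask <- function(image) {
  stopifnot(inherits(image, "image_record"))
  W <- image$image_size[1]; H <- image$image_size[2]
  b <- image$target_bbox
  m <- matrix(FALSE, H, W)
  m[b["y0"]:(b["y0"] + b["h"] - 1L), b["x0"]:(b["x0"] + b["w"] - 1L)] <- TRUE
  m
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record %s> %dx%d px, target in sub-region %d (%.4f of area)%s\n",
              x$image_id, x$image_size[1], x$image_size[2],
              x$target_subregion, x$target_size_ratio,
              if (x$occluded) ", occluded" else ""))
  invisible(x)
}

# Metadata data frame from a list of image records (or pass-through for a
# data frame that already has the metadata columns).
as_image_meta <- function(images) {
  if (is.data.frame(images)) {
    need <- c("image_id", "target_subregion", "target_size_ratio", "occluded")
    if (!all(need %in% names(images))) {
      stop("image metadata needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    return(images)
  }
  data.frame(
    image_id = vapply(images, `[[`, "", "image_id"),
    target_subregion = vapply(images, `[[`, 0L, "target_subregion"),
    target_size_ratio = vapply(images, `[[`, 0, "target_size_ratio"),
    occluded = vapply(images, `[[`, 0L, "occluded"),
    species_hint = vapply(images, function(x) x$species_hint %||% "", ""),
    stringsAsFactors = FALSE
  )
}
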