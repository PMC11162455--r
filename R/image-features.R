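# Image feature families: basic colour/contrast/quality statistics,
# target-object covariates, and relational summaries of segmentation-mask
# sets. All operate on plain arrays / mask sets so the segmentation backend
# stays pluggable.

as_pixel_array <- function(image) {
  px <- if (inherits(image, "image_record")) image$pixels else image
  if (is.null(px) || length(dim(px)) != 3L || dim(px)[3] != 3L) {
    stop("need a height x width x 3 RGB array (0-255)", call. = FALSE)
  }
  px
}

# Rec. 709 luma on the 0-255 scale.
grey_matrix <- function(px) {
  0.2125 * px[, , 1] + 0.7154 * px[, , 2] + 0.0721 * px[, , 3]
}

#' Mean hue, saturation and brightness of an image
#'
#' Per-pixel hexcone HSV conversion followed by plain arithmetic means over
#' all pixels. Saturation is `(max - min) / max` (0 for black pixels),
#' brightness is `max(R, G, B)` scaled to \[0, 1\], and hue is reported in
#' degrees with achromatic pixels contributing hue 0 to the mean. The mean
#' hue is deliberately a linear, not circular, mean.
#'
#' @param image An `image_record` or RGB array (0-255).
#' @return Named vector `mean_hue` (degrees), `mean_saturation`,
#'   `mean_brightness`.
#' @export
hsv_means <- function(image) {
  px <- as_pixel_array(image)
  hsv <- rgb2hsv(r = as.vector(px[, , 1]), g = as.vector(px[, , 2]),
                 b = as.vector(px[, , 3]), maxColorValue = 255)
  c(mean_hue = mean(hsv["h", ]) * 360,
    mean_saturation = mean(hsv["s", ]),
    mean_brightness = mean(hsv["v", ]))
}

#' Dominant-colour ratios via k-means in RGB space
#'
#' Clusters pixel RGB values into `k` groups (k-means, fixed seed, 10
#' restarts) and reports the pixel share of the largest cluster and of the
#' three largest clusters. When the image has fewer distinct colours than
#' `k`, `k` is reduced to the distinct-colour count with a message. For
#' speed, at most `max_pixels` pixels are clustered (a seeded subsample);
#' shares are computed on the clustered sample.
#'
#' @param image An `image_record` or RGB array.
#' @param k Number of colour clusters (default 10).
#' @param seed Seed for the subsample and k-means restarts.
#' @param max_pixels Pixel budget for clustering.
#' @return Named vector `top_dominant_ratio`, `top3_dominant_ratio`.
#' @export
dominant_color_ratios <- function(image, k = 10, seed = 42,
                                  max_pixels = 20000) {
  px <- as_pixel_array(image)
  if (k < 3) stop("`k` must be >= 3", call. = FALSE)
  pix <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
               as.vector(px[, , 3]))
  with_seed(child_seed(seed, 6L), {
    if (nrow(pix) > max_pixels) {
      pix <- pix[sample.int(nrow(pix), max_pixels), , drop = FALSE]
    }
    distinct <- unique(pix)
    k_eff <- min(k, nrow(distinct))
    if (k_eff < k) {
      message("fewer distinct colours than k; using k = ", k_eff)
    }
    if (k_eff == 1L) {
      c(top_dominant_ratio = 1, top3_dominant_ratio = 1)
    } else {
      km <- suppressWarnings(
        kmeans(pix, centers = distinct[sample.int(nrow(distinct), k_eff), ,
                                       drop = FALSE],
               iter.max = 50)
      )
      shares <- sort(tabulate(km$cluster, nbins = k_eff) / nrow(pix),
                     decreasing = TRUE)
      c(top_dominant_ratio = shares[[1]],
        top3_dominant_ratio = sum(shares[seq_len(min(3L, k_eff))]))
    }
  })
}

#' Binary contrast flags
#'
#' The contrast value is the spread between the 1st and 99th percentile of
#' the grey-level intensities, as a fraction of the full 8-bit range; the
#' flag at a threshold is 1 when the contrast value reaches it ("not low
#' contrast"), 0 otherwise.
#'
#' @param image An `image_record` or RGB array.
#' @param thresholds Two contrast thresholds (default 0.75 and 0.85).
#' @return Named integer vector, one flag per threshold, plus an attribute
#'   `contrast_value`.
#' @export
contrast_flags <- function(image, thresholds = c(0.75, 0.85)) {
  grey <- grey_matrix(as_pixel_array(image))
  qs <- quantile(grey, c(0.01, 0.99), names = FALSE)
  value <- (qs[2] - qs[1]) / 255
  out <- as.integer(value >= thresholds)
  names(out) <- sprintf("contrast_threshold_%03d", round(thresholds * 100))
  attr(out, "contrast_value") <- value
  out
}

# Separable Gaussian blur with edge replication (7-tap, sd = 7/6), the
# local-mean filter under the MSCN transform.
gauss_blur <- function(m, radius = 3L, sigma = 7 / 6) {
  w <- exp(-0.5 * ((-radius):radius / sigma)^2)
  w <- w / sum(w)
  pass <- function(x, along_rows) {
    n <- if (along_rows) nrow(x) else ncol(x)
    acc <- 0
    for (o in (-radius):radius) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      acc <- acc + w[o + radius + 1L] *
        (if (along_rows) x[idx, , drop = FALSE] else x[, idx, drop = FALSE])
    }
    acc
  }
  pass(pass(m, TRUE), FALSE)
}

ggd_shape_from_moments <- function(x) {
  # Moment-matched shape parameter of a generalised Gaussian:
  # r(alpha) = Gamma(2/alpha)^2 / (Gamma(1/alpha) Gamma(3/alpha)) is
  # monotone in alpha; invert on a grid.
  m1 <- mean(abs(x)); m2 <- mean(x^2)
  if (m2 < 1e-12) return(NA_real_)
  r <- m1^2 / m2
  grid <- seq(0.2, 5, by = 0.001)
  rg <- exp(2 * lgamma(2 / grid) - lgamma(1 / grid) - lgamma(3 / grid))
  grid[which.min(abs(rg - r))]
}

#' No-reference image quality score
#'
#' A blind quality proxy on the \[0, 100\] scale (lower = cleaner), built
#' from mean-subtracted contrast-normalised (MSCN) luminance coefficients:
#' the generalised-Gaussian scale (standard deviation) of the MSCN
#' distribution is mapped monotonically to \[0, 100\]. Because the MSCN
#' transform divides by a stabilised local contrast, broadband noise pushes
#' the coefficient spread towards its saturation value, so the score rises
#' monotonically with added white noise; smooth, noise-free scenes sit well
#' below it. The moment-matched GGD shape estimate used alongside it is
#' exposed via the `ggd_shape` attribute.
#'
#' @param image An `image_record` or RGB array.
#' @param backend Optional replacement scorer: a `function(grey_matrix)`
#'   returning a score in \[0, 100\] (so a trained evaluator can be plugged
#'   in).
#' @return Scalar in \[0, 100\].
#' @export
image_quality <- function(image, backend = NULL) {
  grey <- grey_matrix(as_pixel_array(image))
  if (is.function(backend)) {
    return(backend(grey))
  }
  mu <- gauss_blur(grey)
  sigma <- sqrt(pmax(gauss_blur(grey^2) - mu^2, 0))
  mscn <- (grey - mu) / (sigma + 1)
  score <- min(100, max(0, 100 * sd(mscn)))
  attr(score, "ggd_shape") <- ggd_shape_from_moments(mscn)
  score
}

#' Target-object size level
#'
#' Grades the target/image area ratio into four levels: very small (0) below
#' 1/48, small (1) in \[1/48, 1/24), large (2) in \[1/24, 1/12), very large
#' (3) in \[1/12, 1/6\]. Boundaries are left-closed.
#'
#' @param ratio Area fraction in (0, 1/6\].
#' @return Integer 0-3.
#' @export
#' @examples
#' object_size_bin(1 / 48)  # 1
object_size_bin <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) ||
      ratio <= 0 || ratio > 1 / 6) {
    stop("`ratio` must lie in (0, 1/6]", call. = FALSE)
  }
  if (ratio < 1 / 48) 0 else if (ratio < 1 / 24) 1 else if (ratio < 1 / 12) 2 else 3
}

#' Occlusion and central-bias flags
#'
#' `occlusion_flag` is 1 iff the target is partially covered by another
#' object. `central_bias_flag` is 1 iff the target lies in one of the two
#' central sub-regions (2 = top centre, 5 = bottom centre of the 2 x 3
#' grid); side regions 1, 3, 4, 6 give 0.
#'
#' @param occluded Logical or 0/1.
#' @return 0 or 1.
#' @export
occlusion_flag <- function(occluded) {
  as.integer(as.logical(occluded))
}

#' @rdname occlusion_flag
#' @param region Sub-region index 1-6.
#' @export
central_bias_flag <- function(region) {
  if (!region %in% 1:6) stop("`region` must be in 1..6", call. = FALSE)
  as.integer(region %in% c(2L, 5L))
}

#' Relational features of a segmentation-mask set
#'
#' Five scalar summaries of scene clutter: the mask count; the summed mask
#' area; the dominance of the biggest mask (its share of the total area);
#' the segment density, defined as the sum of Euclidean distances between
#' all unordered centroid pairs divided by the number of masks; and the mean
#' mask quality. An empty mask set returns all zeros with attribute
#' `degenerate = TRUE` (dominance and quality are undefined there).
#'
#' @param masks A `mask_set`.
#' @return Named vector `n_segments`, `sum_segment_area`,
#'   `biggest_dominance`, `density`, `quality`.
#' @export
#' @examples
#' ms <- mask_set("x", area_px = c(10, 10), centroid_x = c(0, 100),
#'                centroid_y = c(0, 0), quality = c(1, 0.5))
#' mask_relational_features(ms)["density"]  # 100 / 2 = 50
mask_relational_features <- function(masks) {
  stopifnot(inherits(masks, "mask_set"))
  n <- length(masks$masks)
  if (n == 0L) {
    message("empty mask set: dominance and quality encoded as 0")
    out <- c(n_segments = 0, sum_segment_area = 0, biggest_dominance = 0,
             density = 0, quality = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  areas <- vapply(masks$masks, `[[`, 0, "area_px")
  quality <- vapply(masks$masks, `[[`, 0, "quality")
  cents <- t(vapply(masks$masks, `[[`, c(x = 0, y = 0), "centroid"))
  dens <- if (n < 2L) 0 else sum(dist(cents)) / n
  c(n_segments = n,
    sum_segment_area = sum(areas),
    biggest_dominance = max(areas) / sum(areas),
    density = dens,
    quality = sum(quality) / n)
}

image_feature_names <- function() {
  c("Basic_mean_hue", "Basic_mean_saturation", "Basic_mean_brightness",
    "Basic_top_dominant_color_ratio", "Basic_top_3_dominant_color_ratio",
    "Basic_contrast_threshold_075", "Basic_contrast_threshold_085",
    "Basic_image_quality",
    "Target_object_size_ratio", "Target_object_occlusion",
    "Target_object_central_bias",
    "SAM_number_of_segment", "SAM_sum_of_segment_area",
    "SAM_the_biggest_segment_dominance", "SAM_segment_density",
    "SAM_segment_quality")
}

# All sixteen image features of one image as a named numeric vector.
image_features_one <- function(image, masks, seed = 42,
                               quality_backend = NULL) {
  stopifnot(inherits(image, "image_record"))
  hsv <- hsv_means(image)
  dom <- dominant_color_ratios(image, seed = child_seed(seed, 7L,
                                                        image$image_index))
  con <- contrast_flags(image)
  rel <- mask_relational_features(masks)
  out <- c(hsv["mean_hue"], hsv["mean_saturation"], hsv["mean_brightness"],
           dom["top_dominant_ratio"], dom["top3_dominant_ratio"],
           con[1], con[2],
           image_quality(image, backend = quality_backend),
           object_size_bin(image$target_size_ratio),
           occlusion_flag(image$occluded),
           central_bias_flag(image$target_subregion),
           rel["n_segments"], rel["sum_segment_area"],
           rel["biggest_dominance"], rel["density"], rel["quality"])
  setNames(out, image_feature_names())
}

#' Per-image feature table
#'
#' Computes the three feature families (basic, target-object,
#' mask-relational) for every image, one row per image.
#'
#' @param images List of `image_record`s (with pixels).
#' @param masksets List of `mask_set`s aligned with `images` by `image_id`.
#' @param seed Seed driving the k-means clustering.
#' @param quality_backend Optional scorer passed to [image_quality()].
#' @return Data frame with `image_id` plus the 16 feature columns.
#' @seealso [trial_image_features()] to expand per-image rows to trials.
#' @export
image_feature_table <- function(images, masksets, seed = 42,
                                quality_backend = NULL) {
  mask_ids <- vapply(masksets, `[[`, "", "image_id")
  rows <- lapply(images, function(img) {
    mi <- match(img$image_id, mask_ids)
    if (is.na(mi)) stop("missing mask set for image ", img$image_id,
                        call. = FALSE)
    image_features_one(img, masksets[[mi]], seed = seed,
                       quality_backend = quality_backend)
  })
  out <- as.data.frame(do.call(rbind, rows))
  if (anyNA(out) || any(!is.finite(as.matrix(out)))) {
    stop("non-finite image feature computed", call. = FALSE)
  }
  cbind(data.frame(image_id = vapply(images, `[[`, "", "image_id"),
                   stringsAsFactors = FALSE),
        out)
}

#' Expand per-image features to per-trial rows
#'
#' Joins an image feature table to a behaviour table via `image_id`,
#' yielding a trial-aligned `feature_table` with modality `"image"`.
#'
#' @param image_features Data frame from [image_feature_table()].
#' @param behavior Behaviour table (see [generate_behavior()]).
#' @return A `feature_table` whose rows follow the behaviour-table order.
#' @export
trial_image_features <- function(image_features, behavior) {
  idx <- match(behavior$image_id, image_features$image_id)
  if (anyNA(idx)) stop("behaviour references image(s) missing from the feature table",
                       call. = FALSE)
  mat <- as.matrix(image_features[idx, image_feature_names(), drop = FALSE])
  rownames(mat) <- NULL
  feature_table(mat, "image", behavior$label, behavior$subject_id)
}
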