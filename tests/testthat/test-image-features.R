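# Image feature families: colour statistics, dominant colours, contrast,
# the blind quality proxy, target-object covariates and mask-relational
# summaries.

solid_image <- function(r, g, b, h = 20, w = 30) {
  px <- array(0L, c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  px
}

# Independent per-pixel hexcone HSV oracle.
oracle_hsv <- function(px) {
  H <- S <- V <- matrix(0, dim(px)[1], dim(px)[2])
  for (i in seq_len(dim(px)[1])) {
    for (j in seq_len(dim(px)[2])) {
      r <- px[i, j, 1] / 255; g <- px[i, j, 2] / 255; b <- px[i, j, 3] / 255
      mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
      h <- if (d == 0) 0
      else if (mx == r) ((g - b) / d) %% 6
      else if (mx == g) (b - r) / d + 2
      else (r - g) / d + 4
      H[i, j] <- 60 * h
      S[i, j] <- if (mx == 0) 0 else d / mx
      V[i, j] <- mx
    }
  }
  c(mean_hue = mean(H), mean_saturation = mean(S), mean_brightness = mean(V))
}

test_that("HSV means follow the hexcone definition", {
  # uniform mid-grey: no saturation, half brightness
  grey <- hsv_means(solid_image(128, 128, 128))
  expect_equal(unname(grey["mean_saturation"]), 0)
  expect_equal(unname(grey["mean_brightness"]), 128 / 255, tolerance = 1e-12)

  # pure red: hue 0, full saturation and brightness
  red <- hsv_means(solid_image(255, 0, 0))
  expect_equal(unname(red), c(0, 1, 1))

  # pixelwise oracle on a random image
  set.seed(50)
  px <- array(sample(0:255, 12 * 18 * 3, replace = TRUE), c(12, 18, 3))
  expect_equal(hsv_means(px), oracle_hsv(px), tolerance = 1e-9)
})

test_that("dominant-colour ratios recover planted colour shares", {
  # 60% / 30% / 10% of three well-separated colours
  n <- 1000
  px <- array(0L, c(20, 50, 3))
  cols <- rbind(c(250, 10, 10), c(10, 250, 10), c(10, 10, 250))
  assign_to <- rep(1:3, times = c(600, 300, 100))
  for (c in 1:3) {
    ch <- matrix(cols[assign_to, c], 20, 50)
    px[, , c] <- ch
  }
  shares <- dominant_color_ratios(px, k = 10, seed = 1)
  expect_lt(abs(shares["top_dominant_ratio"] - 0.6), 0.02)
  expect_lt(abs(shares["top3_dominant_ratio"] - 1.0), 0.02)

  # single-colour image collapses to one cluster
  expect_message(one <- dominant_color_ratios(solid_image(7, 7, 7)),
                 "distinct")
  expect_equal(unname(one), c(1, 1))

  # ordering invariant on random images
  set.seed(51)
  for (i in 1:5) {
    px_r <- array(sample(0:255, 15 * 15 * 3, replace = TRUE), c(15, 15, 3))
    s <- suppressMessages(dominant_color_ratios(px_r, seed = i))
    expect_lte(s["top_dominant_ratio"], s["top3_dominant_ratio"])
    expect_lte(s["top3_dominant_ratio"], 1)
  }

  expect_error(dominant_color_ratios(px, k = 2), ">= 3")
})

test_that("contrast flags encode the percentile spread against both thresholds", {
  # constant image: zero contrast
  expect_equal(unname(contrast_flags(solid_image(100, 100, 100))),
               c(0L, 0L), ignore_attr = TRUE)

  # >1% pure black and pure white pixels: full contrast
  px <- solid_image(128, 128, 128, h = 10, w = 100)
  px[, 1:2, ] <- 0L
  px[, 99:100, ] <- 255L
  expect_equal(unname(contrast_flags(px)), c(1L, 1L), ignore_attr = TRUE)

  # constructed spread of 80% of the range: passes 0.75, fails 0.85
  px2 <- solid_image(102, 102, 102, h = 10, w = 100)
  px2[, 1:2, ] <- 0L
  px2[, 99:100, ] <- 204L
  flags <- contrast_flags(px2)
  expect_equal(unname(flags), c(1L, 0L), ignore_attr = TRUE)
  expect_equal(attr(flags, "contrast_value"), 0.8, tolerance = 0.01)

  # monotone in the threshold: passing 0.85 implies passing 0.75
  set.seed(52)
  for (i in 1:10) {
    px_r <- array(sample(0:255, 300, replace = TRUE), c(10, 10, 3))
    f <- contrast_flags(px_r)
    expect_true(f[2] <= f[1])
  }
})

test_that("the blind quality score is bounded, deterministic and noise-monotone", {
  cfg <- sim_config(image_size = c(200, 120), seed = 9)
  for (i in 1:3) {
    img <- decifuse:::generate_image(cfg, i)
    q <- image_quality(img)
    expect_gte(as.numeric(q), 0); expect_lte(as.numeric(q), 100)
    expect_equal(as.numeric(image_quality(img)), as.numeric(q))

    # a ladder of increasing white noise raises the score at every rung
    prev <- -Inf
    for (ns in c(0, 15, 40, 80)) {
      set.seed(1000 * i + ns)
      noisy <- pmin(pmax(img$pixels +
                           array(rnorm(length(img$pixels), sd = ns),
                                 dim(img$pixels)), 0), 255)
      sc <- as.numeric(image_quality(noisy))
      expect_gt(sc, prev)
      prev <- sc
    }
  }
})

test_that("object size binning matches the boundary definition exactly", {
  expect_identical(object_size_bin(1 / 100), 0)
  expect_identical(object_size_bin(1 / 48), 1)   # left-closed boundary
  expect_identical(object_size_bin(1 / 24), 2)
  expect_identical(object_size_bin(1 / 12), 3)
  expect_identical(object_size_bin(1 / 6), 3)    # top bin closed at 1/6
  expect_error(object_size_bin(0.2), "1/6")
  expect_error(object_size_bin(0), "1/6")

  # brute-force interval oracle on many random ratios
  set.seed(53)
  ratios <- runif(10000, 1e-6, 1 / 6)
  bins <- vapply(ratios, object_size_bin, 0)
  oracle <- findInterval(ratios, c(0, 1 / 48, 1 / 24, 1 / 12, 1 / 6 + 1e-15)) - 1
  expect_identical(bins, as.numeric(oracle))
})

test_that("occlusion and central-bias flags follow the sub-region layout", {
  expect_identical(central_bias_flag(2), 1L)
  expect_identical(central_bias_flag(5), 1L)
  for (r in c(1, 3, 4, 6)) expect_identical(central_bias_flag(r), 0L)
  expect_error(central_bias_flag(7), "1..6")

  expect_identical(occlusion_flag(TRUE), 1L)
  expect_identical(occlusion_flag(0), 0L)
})

test_that("mask-relational features match a double-loop oracle", {
  # two masks 100 px apart: one pair, density = 100 / 2
  ms <- mask_set("x", area_px = c(10, 10), centroid_x = c(0, 100),
                 centroid_y = c(0, 0), quality = c(1, 0.5))
  f <- mask_relational_features(ms)
  expect_equal(unname(f["density"]), 50)
  expect_equal(unname(f["quality"]), 0.75)

  # n equal-area masks: dominance 1/n
  for (n in c(2, 5, 9)) {
    ms_n <- mask_set("x", rep(20, n), seq_len(n), rep(1, n), rep(0.9, n))
    expect_equal(unname(mask_relational_features(ms_n)["biggest_dominance"]),
                 1 / n)
  }

  # single mask: no pairs
  ms1 <- mask_set("x", 42, 5, 7, 0.66)
  f1 <- mask_relational_features(ms1)
  expect_equal(unname(f1["density"]), 0)
  expect_equal(unname(f1["biggest_dominance"]), 1)
  expect_equal(unname(f1["quality"]), 0.66)

  # empty set: degenerate zeros
  expect_message(f0 <- mask_relational_features(
    mask_set("x", numeric(), numeric(), numeric(), numeric())), "empty")
  expect_true(all(f0 == 0))

  # randomised oracle, including linear scaling of the density
  set.seed(54)
  for (r in 1:100) {
    n <- sample(1:12, 1)
    cx <- runif(n, 0, 500); cy <- runif(n, 0, 300)
    areas <- sample(1:5000, n, replace = TRUE)
    qual <- runif(n)
    ms_r <- mask_set("x", areas, cx, cy, qual)
    f_r <- mask_relational_features(ms_r)
    dens <- 0
    if (n > 1) {
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          dens <- dens + sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2)
        }
      }
    }
    expect_equal(unname(f_r["n_segments"]), n)
    expect_equal(unname(f_r["sum_segment_area"]), sum(areas))
    expect_equal(unname(f_r["biggest_dominance"]), max(areas) / sum(areas),
                 tolerance = 1e-12)
    expect_equal(unname(f_r["density"]), dens / n, tolerance = 1e-9)
    expect_equal(unname(f_r["quality"]), mean(qual), tolerance = 1e-12)

    ms_s <- mask_set("x", areas, 3 * cx, 3 * cy, qual)
    expect_equal(unname(mask_relational_features(ms_s)["density"]),
                 3 * unname(f_r["density"]), tolerance = 1e-9)
  }
})

test_that("the per-image feature table carries the standard feature names", {
  cfg <- tiny_config()
  imgs <- generate_images(cfg, n = 4)
  masks <- lapply(imgs, generate_masks, config = cfg)
  tab <- image_feature_table(imgs, masks, seed = 2)

  expect_identical(nrow(tab), 4L)
  expect_true(all(c("SAM_segment_density", "Target_object_occlusion",
                    "Target_object_size_ratio", "SAM_number_of_segment",
                    "Basic_image_quality") %in% names(tab)))
  expect_true(all(is.finite(as.matrix(tab[, -1]))))

  # missing mask set is an error
  expect_error(image_feature_table(imgs, masks[-2]), "missing mask set")

  # expansion to trials follows the behaviour table order
  beh <- generate_behavior(tiny_config(n_trials_per_subject = 4), imgs)
  trial_tab <- trial_image_features(tab, beh)
  expect_identical(nrow(trial_tab$matrix), nrow(beh))
  expect_identical(trial_tab$labels, beh$label)
  i <- match(beh$image_id[3], tab$image_id)
  expect_equal(unname(trial_tab$matrix[3, "SAM_segment_density"]),
               tab$SAM_segment_density[i])
})
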