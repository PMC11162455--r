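# Synthetic study generators: determinism, geometry, logistic behaviour
# model, and label-dependent ERP injection.

test_that("image generation is deterministic and respects the declared geometry", {
  cfg <- tiny_config()
  imgs <- generate_images(cfg, n = 10)
  expect_length(imgs, 10)
  expect_true(all(vapply(imgs, `[[`, 0L, "target_subregion") %in% 1:6))

  # byte-identical pixels on a second call with the same seed
  again <- generate_images(tiny_config(), n = 3)
  for (i in 1:3) expect_identical(imgs[[i]]$pixels, again[[i]]$pixels)

  # the target lies wholly inside its declared sub-region
  for (img in imgs) {
    b <- img$target_bbox
    box <- decifuse:::subregion_box(img$target_subregion,
                                    cfg$image_size[1], cfg$image_size[2])
    expect_gte(b["x0"], box["x0"])
    expect_lte(b["x0"] + b["w"] - 1L, box["x1"])
    expect_gte(b["y0"], box["y0"])
    expect_lte(b["y0"] + b["h"] - 1L, box["y1"])
  }
})

test_that("a fixed target size ratio is realised in the rendered image", {
  cfg <- tiny_config(target_size_ratio = 1 / 10)
  for (img in generate_images(cfg, n = 5)) {
    frac <- sum(target_mask(img)) / prod(cfg$image_size)
    expect_lt(abs(frac - 1 / 10) / (1 / 10), 0.05)
  }
  expect_error(sim_config(target_size_ratio = 1 / 5), "1/6")
})

test_that("mask sets are internally consistent", {
  cfg <- tiny_config(n_masks_range = c(5, 5))
  img <- generate_images(cfg, n = 1)[[1]]
  ms <- generate_masks(img, cfg)
  expect_length(ms$masks, 5)

  for (m in ms$masks) {
    expect_gt(m$area_px, 0)
    expect_gte(m$quality, 0); expect_lte(m$quality, 1)
    # RLE decodes to the stored area and the moments of the rendered
    # rectangle match the stored centroid
    rendered <- render_mask(m$rle, cfg$image_size)
    expect_identical(sum(rendered), as.integer(m$area_px))
    px <- which(rendered, arr.ind = TRUE)
    expect_lt(abs(mean(px[, 2]) - m$centroid["x"]), 0.5)
    expect_lt(abs(mean(px[, 1]) - m$centroid["y"]), 0.5)
    # centroid inside image bounds
    expect_true(m$centroid["x"] >= 1 && m$centroid["x"] <= cfg$image_size[1])
    expect_true(m$centroid["y"] >= 1 && m$centroid["y"] <= cfg$image_size[2])
  }
  # the first mask coincides with the target patch
  expect_identical(unname(ms$masks[[1]]$area_px),
                   as.integer(sum(target_mask(img))))
  # determinism
  ms2 <- generate_masks(img, cfg)
  expect_identical(ms, ms2)
})

test_that("behaviour follows the logistic link and the 1/6 chance structure", {
  meta <- as_image_meta(generate_images(tiny_config(), n = 50,
                                        render = FALSE))

  # pure guessing: skill -> -Inf drives accuracy to the 1/6 chance level
  cfg_lo <- sim_config(n_subjects = 1, n_trials_per_subject = 2000,
                       base_logit = -50, subject_skill_sd = 0,
                       difficulty_weights = c(size_bin = 0), seed = 3)
  beh <- generate_behavior(cfg_lo, meta)
  expect_lt(abs(mean(beh$label) - 1 / 6),
            3 * sqrt((1 / 6) * (5 / 6) / nrow(beh)))
  # wrong responses spread over all five non-target regions
  wrong <- beh[beh$label == 0L, ]
  expect_true(all(wrong$response != wrong$correct_location))
  expect_true(all(1:6 %in% wrong$response))

  # ceiling: skill -> +Inf gives perfect accuracy
  cfg_hi <- sim_config(n_subjects = 1, n_trials_per_subject = 500,
                       base_logit = 50, subject_skill_sd = 0, seed = 3)
  expect_identical(mean(generate_behavior(cfg_hi, meta)$label), 1)

  # label = 1 exactly when response matches the target
  cfg <- tiny_config()
  beh <- generate_behavior(cfg, meta)
  expect_identical(beh$label, as.integer(beh$response == beh$correct_location))

  # label balance converges to the implied logistic rate
  cfg_b <- sim_config(n_subjects = 1, n_trials_per_subject = 2000,
                      subject_skill_sd = 0, seed = 11)
  beh_b <- generate_behavior(cfg_b, meta)
  X <- decifuse:::image_difficulty_covariates(meta)
  eta <- cfg_b$base_logit +
    as.matrix(X[, names(cfg_b$difficulty_weights)]) %*% cfg_b$difficulty_weights
  idx <- match(beh_b$image_id, meta$image_id)
  p_implied <- mean(1 / 6 + (5 / 6) * plogis(eta[idx]))
  expect_lt(abs(mean(beh_b$label) - p_implied),
            3 * sqrt(p_implied * (1 - p_implied) / 2000))
})

test_that("the logistic slope on image difficulty is recoverable by refitting", {
  meta <- as_image_meta(generate_images(tiny_config(seed = 5), n = 200,
                                        render = FALSE))
  w <- 1.2
  cfg <- sim_config(n_subjects = 1, n_trials_per_subject = 4000,
                    base_logit = 0, subject_skill_sd = 0,
                    difficulty_weights = c(size_bin = w), seed = 21)
  beh <- generate_behavior(cfg, meta)
  size_bin <- vapply(meta$target_size_ratio[match(beh$image_id, meta$image_id)],
                     object_size_bin, 0)
  # maximum-likelihood refit of the guessing-corrected logistic link
  nll <- function(par) {
    p <- 1 / 6 + (5 / 6) * plogis(par[1] + par[2] * size_bin)
    -sum(beh$label * log(p) + (1 - beh$label) * log(1 - p))
  }
  fit <- optim(c(0, 1), nll, hessian = TRUE)
  est <- fit$par[2]
  se <- sqrt(diag(solve(fit$hessian)))[2]
  expect_lt(abs(est - w), 3 * se)
})

test_that("epoch generation injects label-dependent deflections", {
  meta_beh <- function(labels) {
    data.frame(subject_id = "S01", trial_index = seq_along(labels),
               image_id = "img0001", response = 1, correct_location = 1,
               label = labels)
  }
  eff <- function(ac, ai) {
    data.frame(region = "parietal", center_ms = 300, width_ms = 25,
               amp_correct = ac, amp_incorrect = ai)
  }
  base_cfg <- function(...) {
    args <- list(n_subjects = 1, n_trials_per_subject = 8,
                 channels = region_channels("parietal"))
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(sim_config, args)
  }

  # equal amplitudes, zero noise: condition means coincide
  cfg0 <- base_cfg(erp_effects = eff(3, 3), noise_sd = 0)
  ep0 <- generate_epochs(cfg0, meta_beh(rep_len(c(0L, 1L), 8)), "S01")
  expect_equal(condition_average(ep0, 1), condition_average(ep0, 0),
               tolerance = 1e-12)

  # 5 uV vs 0 uV, zero noise: the condition difference peaks at the effect
  # centre with the peak amplitude
  cfg5 <- base_cfg(erp_effects = eff(5, 0), noise_sd = 0)
  ep5 <- generate_epochs(cfg5, meta_beh(rep_len(c(0L, 1L), 8)), "S01")
  d <- condition_average(ep5, 1) - condition_average(ep5, 0)
  peak <- which.max(d[1, ])
  expect_equal(ep5$times_ms[peak], 300)
  expect_equal(max(d), 5, tolerance = 1e-9)

  # with noise, the empirical condition difference at the centre is within
  # 3 standard errors of the injected 2 uV gap
  cfg_n <- base_cfg(erp_effects = eff(4, 2), noise_sd = 5,
                    n_trials_per_subject = 200)
  labels <- rep_len(c(0L, 1L), 200)
  ep_n <- generate_epochs(cfg_n, meta_beh(labels), "S01")
  w <- region_waveforms(ep_n, region_channels("parietal"))
  ctr <- which.min(abs(ep_n$times_ms - 300))
  dd <- mean(w[labels == 1, ctr]) - mean(w[labels == 0, ctr])
  se <- sqrt(var(w[labels == 1, ctr]) / 100 + var(w[labels == 0, ctr]) / 100)
  expect_lt(abs(dd - 2), 3 * se)

  # determinism
  expect_identical(generate_epochs(cfg5, meta_beh(rep_len(c(0L, 1L), 8)), "S01"),
                   ep5)
})

test_that("an injected ERP effect is recovered as a significant segment", {
  # effect well above the 3 * noise_sd / sqrt(n_trials) recoverability bound
  cfg <- sim_config(n_subjects = 1, n_trials_per_subject = 100,
                    channels = region_channels("parietal"),
                    erp_effects = data.frame(region = "parietal",
                                             center_ms = 325, width_ms = 25,
                                             amp_correct = 5,
                                             amp_incorrect = 0),
                    noise_sd = 5, seed = 1)
  labels <- rep_len(c(0L, 1L), 100)
  beh <- data.frame(subject_id = "S01", trial_index = 1:100,
                    image_id = "x", response = 1, correct_location = 1,
                    label = labels)
  hits <- 0L
  for (r in 1:20) {
    cfg$seed <- 1000L + r
    ep <- baseline_correct(generate_epochs(cfg, beh, "S01"))
    wv <- region_waveforms(ep, region_channels("parietal"))
    res <- pointwise_permutation_test(wv, labels, n_permutations = 10000,
                                      seed = r)
    seg <- extract_segments(res, min_len_ms = 20, region = "parietal")
    overlap <- nrow(seg) > 0 &&
      any(seg$onset_ms <= 350 & seg$offset_ms >= 300)
    hits <- hits + overlap
  }
  expect_gte(hits, 19)
})

test_that("epoch containers round-trip through the on-disk format", {
  ep <- random_epochs(n_trials = 6)
  dir <- withr::local_tempdir()
  write_epochs(ep, dir)
  back <- read_epochs(dir)
  expect_equal(back$data, ep$data, tolerance = 0)
  expect_identical(back$labels, ep$labels)
  expect_equal(back$times_ms, ep$times_ms)
  expect_identical(back$channel_names, ep$channel_names)
})
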