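# Random-forest evaluation, importance ranking, fusion, reference-accuracy
# comparison and the paired subject test.

test_that("a perfectly separable table is classified almost perfectly", {
  set.seed(60)
  x <- rnorm(200)
  tab <- table_from_matrix(cbind(signal = x, noise = rnorm(200)),
                           labels = as.integer(x > 0))
  ev <- train_eval(tab, model_config())
  expect_gte(ev$mean["accuracy"], 0.99)
  expect_true(all(ev$folds$accuracy >= 0.9))
})

test_that("evaluation is deterministic for a fixed seed", {
  set.seed(61)
  tab <- table_from_matrix(matrix(rnorm(120 * 8), 120, 8))
  a <- train_eval(tab, model_config(), seed = 11)
  b <- train_eval(tab, model_config(), seed = 11)
  expect_identical(a$folds, b$folds)
  expect_identical(a$importances, b$importances)
  c <- train_eval(tab, model_config(), seed = 12)
  expect_false(identical(a$folds, c$folds))
})

test_that("label-shuffled features score at the chance level", {
  set.seed(62)
  accs <- replicate(20, {
    tab <- table_from_matrix(matrix(rnorm(120 * 6), 120, 6),
                             labels = sample(rep(0:1, 60)))
    unname(train_eval(tab, model_config())$mean["accuracy"])
  })
  # balanced classes, independent features: accuracy within the binomial
  # envelope of 0.5 (averaged over 20 seeds)
  expect_lt(abs(mean(accs) - 0.5), 4 * sqrt(0.25 / (20 * 120)))
})

test_that("importance ranking recovers a planted signal deterministically", {
  hits <- 0L
  for (r in 1:20) {
    set.seed(200 + r)
    m <- matrix(rnorm(150 * 21), 150, 21)
    colnames(m) <- c("planted", sprintf("noise%02d", 1:20))
    labels <- as.integer(m[, "planted"] + rnorm(150, sd = 0.3) > 0)
    if (min(table(labels)) < 5) next
    ev <- train_eval(feature_table(m, "eeg", labels, rep("S01", 150)),
                     model_config())
    hits <- hits + (importance_ranking(ev, 1) == "planted")
  }
  expect_gte(hits, 19)

  # the full ranking is a permutation with non-increasing importances
  set.seed(63)
  tab <- table_from_matrix(matrix(rnorm(80 * 6), 80, 6))
  ev <- train_eval(tab, model_config())
  rk <- importance_ranking(ev, 6)
  expect_setequal(rk, colnames(tab$matrix))
  expect_true(all(diff(ev$importances[rk]) <= 1e-12))
  expect_error(importance_ranking(ev, 7), "exceeds")
})

test_that("fusion concatenates the top features of each modality", {
  set.seed(64)
  n <- 100
  labels <- rep_len(c(0L, 1L), n)
  eeg <- feature_table(matrix(rnorm(n * 12), n,
                              dimnames = list(NULL, sprintf("E%02d", 1:12))),
                       "eeg", labels, rep("S01", n))
  img <- feature_table(matrix(rnorm(n * 8), n,
                              dimnames = list(NULL, sprintf("I%02d", 1:8))),
                       "image", labels, rep("S01", n))
  fused <- fuse(eeg, img, k_each = 5)
  expect_identical(ncol(fused$matrix), 10L)
  expect_identical(sum(fused$modality == "eeg"), 5L)
  expect_identical(sum(fused$modality == "image"), 5L)

  # explicit rankings are honoured verbatim
  fused2 <- fuse(eeg, img, k_each = 2,
                 eeg_ranking = c("E03", "E07"),
                 image_ranking = c("I01", "I05"))
  expect_identical(colnames(fused2$matrix), c("E03", "E07", "I01", "I05"))

  expect_error(fuse(eeg, img, k_each = 0), ">= 1")
  img_short <- feature_table(img$matrix[1:50, ], "image", labels[1:50],
                             rep("S01", 50))
  expect_error(fuse(eeg, img_short, k_each = 2,
                    eeg_ranking = colnames(eeg$matrix),
                    image_ranking = colnames(img$matrix)), "aligned")
})

test_that("reference accuracy is the subject's own correct fraction", {
  beh <- data.frame(subject_id = rep(c("S01", "S02"), c(200, 100)),
                    label = c(rep(1L, 168), rep(0L, 32), rep(1L, 100)))
  expect_equal(reference_accuracy(beh, "S01"), 0.84)
  expect_equal(reference_accuracy(beh, "S02"), 1)
  expect_equal(reference_accuracy(beh), mean(beh$label))
  expect_error(reference_accuracy(beh, "S99"), "no behaviour rows")
})

test_that("the reference comparison uses a strict inequality", {
  stub <- structure(list(mean = c(accuracy = 0.85)), class = "rf_eval")
  res <- compare_to_reference(stub, 0.80)
  expect_true(res$passes_reference)
  expect_equal(res$margin, 0.05)

  stub$mean["accuracy"] <- 0.75
  expect_false(compare_to_reference(stub, 0.80)$passes_reference)

  stub$mean["accuracy"] <- 0.80
  expect_false(compare_to_reference(stub, 0.80)$passes_reference)
})

test_that("the paired subject test matches the closed-form t statistic", {
  a <- c(0.85, 0.93, 0.85, 0.80, 0.85)
  b <- c(0.84, 0.90, 0.87, 0.75, 0.83)
  res <- paired_subject_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_identical(res$degrees_of_freedom, 4)

  # identical vectors: degenerate zero
  res0 <- paired_subject_test(a, a)
  expect_true(res0$degenerate)
  expect_identical(res0$t_statistic, 0)
  expect_identical(res0$p_value, 1)

  # constant non-zero difference: degenerate infinite separation
  resc <- paired_subject_test(a + 0.1, a)
  expect_true(resc$degenerate)
  expect_identical(resc$t_statistic, Inf)

  # near-constant difference with tiny jitter: decisive
  set.seed(65)
  resj <- paired_subject_test(a + 0.1 + rnorm(5, sd = 1e-4), a)
  expect_gt(abs(resj$t_statistic), 100)
  expect_lt(resj$p_value, 0.001)

  expect_error(paired_subject_test(1, 1), "n >= 2")
})

test_that("the pipeline report has the full design grid shape", {
  cfg <- tiny_config(n_subjects = 3, n_trials_per_subject = 40,
                     image_size = c(100, 60))
  rep_ <- run_pipeline(cfg)

  # subject tables: one row per subject plus the mean row
  expect_identical(nrow(rep_$table_all), 4L)
  expect_identical(nrow(rep_$table_selected), 4L)
  expect_identical(rep_$table_all$subject, c("S01", "S02", "S03", "Mean"))
  cols <- c("image_acc", "image_pre", "image_f1", "eeg_acc", "eeg_pre",
            "eeg_f1", "multimodal_acc", "multimodal_pre", "multimodal_f1",
            "ref_acc")
  expect_true(all(cols %in% names(rep_$table_all)))

  # six group-level cells, metrics bounded in [0, 1]
  expect_identical(nrow(rep_$group_summary), 6L)
  metr <- as.matrix(rep_$group_summary[, c("acc", "pre", "f1")])
  expect_true(all(metr >= 0 & metr <= 1))

  # the fused set has 2 * k_each = 10 features
  expect_identical(rep_$n_fused_features, 10L)
  expect_identical(rep_$n_eeg_features_total, 540L)

  # F1 is consistent with precision and recall on every stored fold
  for (cell in rep_$group_all) {
    with(cell$report$folds, {
      f1_check <- ifelse(precision + recall == 0, 0,
                         2 * precision * recall / (precision + recall))
      expect_equal(f1, f1_check, tolerance = 1e-12)
    })
  }

  # written artifacts round-trip
  out <- withr::local_tempdir()
  decifuse:::write_report(rep_, out)
  expect_true(file.exists(file.path(out, "subject_all_features.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  js <- jsonlite::read_json(file.path(out, "summary.json"),
                            simplifyVector = TRUE)
  expect_identical(js$n_fused_features, 10L)
})
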