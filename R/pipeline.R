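# End-to-end orchestration: simulate a study, build the three feature sets,
# and evaluate the classifier over the full design grid
# {all, selected} x {eeg, image, multimodal} x {group, subject}.

#' Simulate a complete synthetic study
#'
#' Generates the image set (streamed one image at a time, so full-resolution
#' studies stay memory-bounded), mask sets, per-image features, the behaviour
#' table, and per-subject epochs with baseline correction and temporal EEG
#' feature extraction already applied. EEG feature rows follow the behaviour
#' table order.
#'
#' @param config A [sim_config()].
#' @param segments Segment table for EEG features (default
#'   [reference_segments()]).
#' @param keep_epochs Keep the raw `eeg_epochs` objects in the result
#'   (memory-heavy for large studies; default `FALSE`).
#' @param verbose Print progress.
#' @return List with `behavior`, `image_meta`, `image_features` (per-image
#'   data frame), `masksets`, `eeg_features` (trial-aligned `feature_table`),
#'   `skills`, `config`, and optionally `epochs`.
#' @export
simulate_study <- function(config = sim_config(),
                           segments = reference_segments(),
                           keep_epochs = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n_img <- config$n_trials_per_subject
  say <- function(...) if (verbose) message(sprintf(...))

  say("rendering %d images and mask sets ...", n_img)
  meta_rows <- vector("list", n_img)
  feat_rows <- vector("list", n_img)
  masksets <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    img <- generate_image(config, i)
    masksets[[i]] <- generate_masks(img, config)
    meta_rows[[i]] <- as_image_meta(list(img))
    feat_rows[[i]] <- image_features_one(img, masksets[[i]],
                                         seed = config$seed)
  }
  image_meta <- do.call(rbind, meta_rows)
  image_features <- cbind(data.frame(image_id = image_meta$image_id,
                                     stringsAsFactors = FALSE),
                          as.data.frame(do.call(rbind, feat_rows)))

  say("generating behaviour for %d subjects ...", config$n_subjects)
  behavior <- generate_behavior(config, image_meta)

  say("generating epochs and EEG features ...")
  subjects <- unique(behavior$subject_id)
  eeg_tabs <- vector("list", length(subjects))
  epochs_list <- if (keep_epochs) vector("list", length(subjects)) else NULL
  for (k in seq_along(subjects)) {
    ep <- generate_epochs(config, behavior, subjects[k])
    ep <- baseline_correct(ep)
    eeg_tabs[[k]] <- extract_segment_features(ep, segments = segments)
    if (keep_epochs) epochs_list[[k]] <- ep
  }
  eeg_features <- Reduce(function(a, b) {
    feature_table(rbind(a$matrix, b$matrix), unname(a$modality),
                  c(a$labels, b$labels), c(a$subject_ids, b$subject_ids))
  }, eeg_tabs)
  if (keep_epochs) names(epochs_list) <- subjects

  out <- list(behavior = behavior, image_meta = image_meta,
              image_features = image_features, masksets = masksets,
              eeg_features = eeg_features, skills = subject_skills(config),
              config = config)
  if (keep_epochs) out$epochs <- epochs_list
  out
}

eval_cell <- function(table, model, behavior, subject_id = NULL) {
  tab <- if (is.null(subject_id)) table else
    subset_trials(table, table$subject_ids == subject_id)
  rep_ <- train_eval(tab, model)
  ref <- reference_accuracy(behavior, subject_id)
  cmp <- compare_to_reference(rep_, ref)
  list(report = rep_, reference = ref, passes = cmp$passes_reference,
       margin = cmp$margin)
}

cell_row <- function(cell) {
  c(acc = unname(cell$report$mean["accuracy"]),
    pre = unname(cell$report$mean["precision"]),
    f1 = unname(cell$report$mean["f1"]))
}

#' Run the full evaluation pipeline
#'
#' Executes the whole design on a (simulated) study: group-level and
#' subject-level random-forest evaluations of the EEG, image and multimodal
#' feature sets, both with all features and with the importance-selected
#' top-`k_top` (respectively fused top-`k_each` + `k_each`) features.
#' Feature rankings are computed once on the group-level evaluations and
#' reused everywhere (set `rerank_per_subject = TRUE` for leakage-safe
#' per-subject re-ranking). Results include per-subject tables in the shape
#' of the study's two results tables, a group summary, paired t-tests of the
#' fused set against each unimodal set and against reference accuracy, and
#' pass counts versus reference accuracy.
#'
#' @param config A [sim_config()] describing the synthetic study.
#' @param model A [model_config()].
#' @param k_top Features kept in the selected unimodal sets.
#' @param k_each Features per modality in the fused set.
#' @param study Optional pre-computed [simulate_study()] result (must match
#'   `config`); simulated when `NULL`.
#' @param rerank_per_subject Recompute rankings inside each subject's data.
#' @param out_dir Optional directory to write CSV tables and a JSON summary.
#' @param verbose Print progress.
#' @return A `decision_report` list; see Details.
#' @export
run_pipeline <- function(config = sim_config(), model = model_config(),
                         k_top = 10, k_each = 5, study = NULL,
                         rerank_per_subject = FALSE, out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  study <- study %||% simulate_study(config, verbose = verbose)
  behavior <- study$behavior

  say("pruning EEG features ...")
  pruned <- correlation_prune(study$eeg_features, 0.80)
  eeg_tab <- pruned$table
  img_tab <- trial_image_features(study$image_features, behavior)
  multi_tab <- bind_features(eeg_tab, img_tab)

  say("group-level evaluation (all features) ...")
  g_all <- list(image = eval_cell(img_tab, model, behavior),
                eeg = eval_cell(eeg_tab, model, behavior),
                multimodal = eval_cell(multi_tab, model, behavior))

  rank_eeg <- importance_ranking(g_all$eeg$report,
                                 min(k_top, ncol(eeg_tab$matrix)))
  rank_img <- importance_ranking(g_all$image$report,
                                 min(k_top, ncol(img_tab$matrix)))
  eeg_top <- select_features(eeg_tab, rank_eeg)
  img_top <- select_features(img_tab, rank_img)
  fused <- bind_features(select_features(eeg_tab, rank_eeg[seq_len(k_each)]),
                         select_features(img_tab, rank_img[seq_len(k_each)]))

  say("group-level evaluation (selected features) ...")
  g_sel <- list(image = eval_cell(img_top, model, behavior),
                eeg = eval_cell(eeg_top, model, behavior),
                multimodal = eval_cell(fused, model, behavior))

  say("subject-level evaluations ...")
  subjects <- unique(behavior$subject_id)
  subj_eval <- function(all_tab, top_names, s) {
    tab <- subset_trials(all_tab, all_tab$subject_ids == s)
    if (rerank_per_subject) {
      top_names <- importance_ranking(train_eval(tab, model),
                                      length(top_names))
    }
    list(all = eval_cell(all_tab, model, behavior, s),
         sel = eval_cell(select_features(all_tab, top_names), model,
                         behavior, s))
  }
  per_subject <- lapply(subjects, function(s) {
    img <- subj_eval(img_tab, rank_img, s)
    eeg <- subj_eval(eeg_tab, rank_eeg, s)
    mul_all <- eval_cell(multi_tab, model, behavior, s)
    mul_sel <- eval_cell(fused, model, behavior, s)
    list(subject = s, image = img, eeg = eeg,
         multimodal = list(all = mul_all, sel = mul_sel))
  })
  names(per_subject) <- subjects

  subject_table <- function(which) {
    rows <- lapply(per_subject, function(ps) {
      data.frame(subject = ps$subject,
                 t(setNames(cell_row(ps$image[[which]]),
                            paste0("image_", c("acc", "pre", "f1")))),
                 t(setNames(cell_row(ps$eeg[[which]]),
                            paste0("eeg_", c("acc", "pre", "f1")))),
                 t(setNames(cell_row(ps$multimodal[[which]]),
                            paste0("multimodal_", c("acc", "pre", "f1")))),
                 ref_acc = ps$image[[which]]$reference)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    mean_row <- tab[1, ]
    mean_row$subject <- "Mean"
    mean_row[, -1] <- colMeans(tab[, -1])
    rbind(tab, mean_row)
  }
  table_all <- subject_table("all")
  table_selected <- subject_table("sel")

  acc_of <- function(modality, which) {
    vapply(per_subject, function(ps)
      unname(ps[[modality]][[which]]$report$mean["accuracy"]), 0)
  }
  refs <- vapply(per_subject, function(ps) ps$image$sel$reference, 0)
  comparisons <- list(
    fused_vs_eeg = paired_subject_test(acc_of("multimodal", "sel"),
                                       acc_of("eeg", "sel"),
                                       "multimodal vs eeg (selected)"),
    fused_vs_image = paired_subject_test(acc_of("multimodal", "sel"),
                                         acc_of("image", "sel"),
                                         "multimodal vs image (selected)"),
    fused_vs_reference = paired_subject_test(acc_of("multimodal", "sel"),
                                             refs,
                                             "multimodal (selected) vs reference")
  )
  pass_counts <- vapply(c("image", "eeg", "multimodal"), function(md) {
    c(all = sum(vapply(per_subject, function(ps) ps[[md]]$all$passes, TRUE)),
      sel = sum(vapply(per_subject, function(ps) ps[[md]]$sel$passes, TRUE)))
  }, c(all = 0, sel = 0))

  group_summary <- do.call(rbind, lapply(c("all", "sel"), function(w) {
    cells <- if (w == "all") g_all else g_sel
    do.call(rbind, lapply(names(cells), function(md) {
      data.frame(feature_set = w, modality = md,
                 t(cell_row(cells[[md]])),
                 acc_sd = unname(cells[[md]]$report$sd["accuracy"]),
                 ref_acc = cells[[md]]$reference,
                 passes = cells[[md]]$passes)
    }))
  }))

  report <- structure(list(
    group_all = g_all, group_selected = g_sel,
    group_summary = group_summary,
    per_subject = per_subject,
    table_all = table_all, table_selected = table_selected,
    comparisons = comparisons,
    pass_counts = pass_counts,
    rankings = list(eeg = rank_eeg, image = rank_img),
    n_eeg_features_total = ncol(study$eeg_features$matrix),
    n_eeg_features_pruned = ncol(eeg_tab$matrix),
    dropped_features = pruned$dropped,
    n_fused_features = ncol(fused$matrix),
    config = config, model = model
  ), class = "decision_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.decision_report <- function(x, ...) {
  cat("<decision_report>\n")
  cat(sprintf("  EEG features: %d extracted, %d after pruning; fused set width %d\n",
              x$n_eeg_features_total, x$n_eeg_features_pruned,
              x$n_fused_features))
  cat("  group-level results:\n")
  gs <- x$group_summary
  for (i in seq_len(nrow(gs))) {
    cat(sprintf("    [%s/%s] acc %.3f (sd %.3f), pre %.3f, F1 %.3f, ref %.3f%s\n",
                gs$feature_set[i], gs$modality[i], gs$acc[i], gs$acc_sd[i],
                gs$pre[i], gs$f1[i], gs$ref_acc[i],
                if (gs$passes[i]) " PASS" else ""))
  }
  n_sub <- length(x$per_subject)
  cat(sprintf("  subject-level pass counts vs reference (of %d):\n", n_sub))
  for (md in colnames(x$pass_counts)) {
    cat(sprintf("    %-10s all %d, selected %d\n", md,
                x$pass_counts["all", md], x$pass_counts["sel", md]))
  }
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$table_all, file.path(out_dir, "subject_all_features.csv"),
            row.names = FALSE)
  write.csv(report$table_selected,
            file.path(out_dir, "subject_selected_features.csv"),
            row.names = FALSE)
  write.csv(report$group_summary, file.path(out_dir, "group_summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(group_summary = report$group_summary,
         pass_counts = as.data.frame(t(report$pass_counts)),
         comparisons = lapply(report$comparisons, function(cmp) {
           list(contrast = cmp$contrast, t = cmp$t_statistic,
                df = cmp$degrees_of_freedom, p = cmp$p_value)
         }),
         rankings = report$rankings,
         n_eeg_features_total = report$n_eeg_features_total,
         n_eeg_features_pruned = report$n_eeg_features_pruned,
         n_fused_features = report$n_fused_features),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
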