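# Behaviour table synthesis: a logistic model links image difficulty and
# per-subject skill to the probability of a correct localisation response.

# Difficulty covariates of each image, matching the names accepted by
# `difficulty_weights`: size_bin (0-3), occlusion (0/1), central_bias (0/1).
image_difficulty_covariates <- function(meta) {
  data.frame(
    size_bin = vapply(meta$target_size_ratio, object_size_bin, 0),
    occlusion = as.numeric(meta$occluded),
    central_bias = as.numeric(meta$target_subregion %in% c(2L, 5L))
  )
}

#' Per-subject skill offsets of a configuration
#'
#' Skills are drawn once per subject from `N(0, subject_skill_sd)` on the
#' logit scale, from a dedicated seed stream, so behaviour and EEG generation
#' can be rerun independently without changing who is good at the task.
#'
#' @param config A [sim_config()].
#' @return Named numeric vector of logit offsets, one per subject.
#' @export
subject_skills <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 3L),
            setNames(rnorm(config$n_subjects, 0, config$subject_skill_sd),
                     sprintf("S%02d", seq_len(config$n_subjects))))
}

#' Generate a synthetic behaviour table
#'
#' A knowledge-plus-guessing response model: on each trial the subject
#' locates the target with probability
#' `plogis(base_logit + skill + sum(difficulty_weights * covariates))` and
#' responds with its sub-region; otherwise the response is a uniform guess
#' over all six sub-regions. The probability of a correct response is
#' therefore `1/6 + 5/6 * plogis(eta)` — floored at the 1/6 chance level of
#' the six-alternative task — and wrong responses are uniform over the five
#' non-target sub-regions. Each subject sees every image once, in an
#' independently shuffled order, when the number of images equals
#' `n_trials_per_subject`.
#'
#' @param config A [sim_config()].
#' @param images List of `image_record`s (pixels not required) or a metadata
#'   data frame with columns `image_id`, `target_subregion`,
#'   `target_size_ratio`, `occluded`.
#' @return Data frame with one row per (subject, trial): `subject_id`,
#'   `trial_index`, `image_id`, `response`, `correct_location`, `label`
#'   (1 exactly when `response == correct_location`).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, n_trials_per_subject = 12,
#'                   image_size = c(90, 60))
#' beh <- generate_behavior(cfg, generate_images(cfg, render = FALSE))
#' mean(beh$label)
generate_behavior <- function(config, images) {
  stopifnot(inherits(config, "sim_config"))
  meta <- as_image_meta(images)
  if (!nrow(meta)) stop("`images` must be non-empty", call. = FALSE)
  X <- image_difficulty_covariates(meta)
  w <- config$difficulty_weights
  eta_img <- config$base_logit +
    as.vector(as.matrix(X[, names(w), drop = FALSE]) %*% w)
  skills <- subject_skills(config)
  n_tr <- config$n_trials_per_subject

  rows <- lapply(seq_len(config$n_subjects), function(s) {
    with_seed(child_seed(config$seed, 4L, s), {
      img_idx <- if (nrow(meta) == n_tr) sample.int(n_tr) else
        sample.int(nrow(meta), n_tr, replace = TRUE)
      know <- rbinom(n_tr, 1L, plogis(eta_img[img_idx] + skills[s]))
      loc <- meta$target_subregion[img_idx]
      response <- loc
      guessing <- which(know == 0L)
      if (length(guessing)) {
        response[guessing] <- sample(1:6, length(guessing), replace = TRUE)
      }
      data.frame(subject_id = names(skills)[s],
                 trial_index = seq_len(n_tr),
                 image_id = meta$image_id[img_idx],
                 response = response,
                 correct_location = loc,
                 label = as.integer(response == loc),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}
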