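#' Channel triples for the five midline scalp regions
#'
#' The analysis works on five three-channel regions along the scalp midline:
#' occipital, parietal, central-parietal, central and frontocentral. Feature
#' extraction uses the twelve channels of the four posterior/central regions;
#' the frontocentral triple is carried through preprocessing but contributes
#' no features (it shows no condition difference in this paradigm).
#'
#' @param region Optional region name; if given, returns that region's three
#'   channel names instead of the full list.
#' @return A named list of character vectors, or a character vector of three
#'   channel names when `region` is supplied.
#' @export
#' @examples
#' region_channels("parietal")
region_channels <- function(region = NULL) {
  map <- list(
    occipital        = c("O1", "Oz", "O2"),
    parietal         = c("P1", "Pz", "P2"),
    central_parietal = c("CP1", "CPz", "CP2"),
    central          = c("C1", "Cz", "C2"),
    frontocentral    = c("FC1", "FCz", "FC2")
  )
  if (is.null(region)) {
    return(map)
  }
  region <- match.arg(region, names(map))
  map[[region]]
}

default_montage <- function() unname(unlist(region_channels()))

# The twelve channels actually used for EEG features: the four regions with
# significant condition differences (frontocentral excluded).
feature_channels <- function() {
  unname(unlist(region_channels()[c("occipital", "parietal",
                                    "central_parietal", "central")]))
}

default_erp_effects <- function(amp_correct = 5.5, amp_incorrect = 0.75) {
  seg <- reference_segments()
  data.frame(
    region        = seg$region,
    center_ms     = (seg$onset_ms + seg$offset_ms) / 2,
    width_ms      = (seg$offset_ms - seg$onset_ms) / 4,
    amp_correct   = amp_correct,
    amp_incorrect = amp_incorrect,
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic visual-search study
#'
#' Bundles every knob of the synthetic data generator: the study layout
#' (subjects, trials, EEG sampling), the injected event-related potential
#' (ERP) effects that make correct and incorrect trials separable in the EEG,
#' the stimulus-image geometry, and the logistic behaviour model that links
#' image difficulty and subject skill to response correctness.
#'
#' The defaults emulate the study conditions the package targets: 14 subjects
#' performing 200 trials each, 64-channel-style EEG reduced to a 15-channel
#' midline montage sampled at 250 Hz over a \[-100, 1000\] ms epoch, stimulus
#' images of 1000 x 600 pixels divided into six equal sub-regions, and nine
#' ERP effects placed at the canonical segment latencies (see
#' [reference_segments()]) with correct-trial amplitudes consistently above
#' incorrect-trial amplitudes.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_subject Trials per subject (one image per trial).
#' @param sfreq EEG sampling rate in Hz.
#' @param epoch_window Epoch limits in ms relative to image onset,
#'   `c(start, end)` with `start < 0 < end`.
#' @param channels Channel names of the montage; must contain every channel
#'   referenced by `erp_effects` via its region.
#' @param erp_effects Data frame with columns `region`, `center_ms`,
#'   `width_ms` (Gaussian sd of the deflection), `amp_correct` and
#'   `amp_incorrect` (peak amplitudes in microvolt). Each effect is added to
#'   the three channels of its region. `amp_correct >= amp_incorrect` is
#'   required for every effect.
#' @param noise_sd Total noise standard deviation per channel sample in
#'   microvolt (split internally into a 1/f and a white component).
#' @param image_size `c(width, height)` of stimulus images in pixels.
#' @param n_masks_range `c(min, max)` segmentation masks per image.
#' @param base_logit Population mean of the correctness logit; `plogis(base_logit)`
#'   is roughly the average behavioural accuracy of an average subject on an
#'   average image.
#' @param subject_skill_sd SD (logit units) of the per-subject skill offset.
#' @param difficulty_weights Named numeric vector of logit coefficients on the
#'   image difficulty covariates `size_bin` (0-3), `occlusion` (0/1) and
#'   `central_bias` (0/1).
#' @param occlusion_rate Fraction of images with an occluder over the target.
#' @param size_bin_probs Sampling probabilities of the four target-size levels
#'   (very small .. very large).
#' @param target_size_ratio Optional fixed target area fraction in (0, 1/6\];
#'   when set, every image uses it instead of sampling a size level.
#' @param seed Base seed; every generator derives its own stream from it.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_images()], [generate_masks()], [generate_behavior()],
#'   [generate_epochs()], [simulate_study()]
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, n_trials_per_subject = 20,
#'                   image_size = c(120, 72))
#' cfg$sfreq
sim_config <- function(n_subjects = 14,
                       n_trials_per_subject = 200,
                       sfreq = 250,
                       epoch_window = c(-100, 1000),
                       channels = default_montage(),
                       erp_effects = default_erp_effects(),
                       noise_sd = 5,
                       image_size = c(1000, 600),
                       n_masks_range = c(8, 24),
                       base_logit = -0.2,
                       subject_skill_sd = 0.4,
                       difficulty_weights = c(size_bin = 1.6,
                                              occlusion = -2.0,
                                              central_bias = 0.8),
                       occlusion_rate = 0.3,
                       size_bin_probs = c(0.35, 0.30, 0.25, 0.10),
                       target_size_ratio = NULL,
                       seed = 1L) {
  stopifnot_scalar(n_subjects, "n_subjects", lower = 1)
  stopifnot_scalar(n_trials_per_subject, "n_trials_per_subject", lower = 1)
  stopifnot_scalar(sfreq, "sfreq", lower = 1e-9)
  stopifnot_scalar(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar(subject_skill_sd, "subject_skill_sd", lower = 0)
  stopifnot_scalar(occlusion_rate, "occlusion_rate", lower = 0, upper = 1)
  if (length(epoch_window) != 2L || !(epoch_window[1] < 0 && 0 < epoch_window[2])) {
    stop("`epoch_window` must satisfy start < 0 < end", call. = FALSE)
  }
  if (length(image_size) != 2L || any(image_size < 12)) {
    stop("`image_size` must be c(width, height), both >= 12 px", call. = FALSE)
  }
  if (length(n_masks_range) != 2L || n_masks_range[1] < 1 ||
      n_masks_range[2] < n_masks_range[1]) {
    stop("`n_masks_range` must be c(min, max) with 1 <= min <= max", call. = FALSE)
  }
  need <- c("region", "center_ms", "width_ms", "amp_correct", "amp_incorrect")
  if (!is.data.frame(erp_effects) || !all(need %in% names(erp_effects))) {
    stop("`erp_effects` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(erp_effects$amp_correct < erp_effects$amp_incorrect)) {
    stop("every ERP effect must have amp_correct >= amp_incorrect", call. = FALSE)
  }
  bad_region <- setdiff(erp_effects$region, names(region_channels()))
  if (length(bad_region)) {
    stop("unknown region(s) in erp_effects: ", paste(bad_region, collapse = ", "),
         call. = FALSE)
  }
  eff_channels <- unique(unlist(region_channels()[unique(erp_effects$region)]))
  missing_ch <- setdiff(eff_channels, channels)
  if (length(missing_ch)) {
    stop("`channels` is missing channels required by erp_effects: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(difficulty_weights)) && length(difficulty_weights)) {
    stop("`difficulty_weights` must be a named vector", call. = FALSE)
  }
  bad_w <- setdiff(names(difficulty_weights),
                   c("size_bin", "occlusion", "central_bias"))
  if (length(bad_w)) {
    stop("unknown difficulty covariate(s): ", paste(bad_w, collapse = ", "),
         call. = FALSE)
  }
  if (length(size_bin_probs) != 4L || any(size_bin_probs < 0) ||
      sum(size_bin_probs) <= 0) {
    stop("`size_bin_probs` must be 4 non-negative weights", call. = FALSE)
  }
  if (!is.null(target_size_ratio)) {
    if (target_size_ratio > 1 / 6 || target_size_ratio <= 0) {
      stop("`target_size_ratio` must lie in (0, 1/6]: larger targets cannot fit one sub-region",
           call. = FALSE)
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_subject = as.integer(n_trials_per_subject),
    sfreq = sfreq,
    epoch_window = as.numeric(epoch_window),
    channels = as.character(channels),
    erp_effects = erp_effects,
    noise_sd = noise_sd,
    image_size = as.integer(image_size),
    n_masks_range = as.integer(n_masks_range),
    base_logit = base_logit,
    subject_skill_sd = subject_skill_sd,
    difficulty_weights = difficulty_weights,
    occlusion_rate = occlusion_rate,
    size_bin_probs = size_bin_probs / sum(size_bin_probs),
    target_size_ratio = target_size_ratio,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic visual-search study configuration\n")
  cat(sprintf("  %d subjects x %d trials, %g Hz, window [%g, %g] ms, %d channels\n",
              x$n_subjects, x$n_trials_per_subject, x$sfreq,
              x$epoch_window[1], x$epoch_window[2], length(x$channels)))
  cat(sprintf("  %d ERP effects, noise sd %g uV; images %d x %d px; masks %d-%d\n",
              nrow(x$erp_effects), x$noise_sd, x$image_size[1], x$image_size[2],
              x$n_masks_range[1], x$n_masks_range[2]))
  cat(sprintf("  behaviour: base logit %g, skill sd %g, weights [%s]\n",
              x$base_logit, x$subject_skill_sd,
              paste(sprintf("%s=%g", names(x$difficulty_weights),
                            x$difficulty_weights), collapse = ", ")))
  invisible(x)
}
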