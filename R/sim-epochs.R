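# Epoched EEG synthesis: pink + white Gaussian background noise plus
# Gaussian-windowed ERP deflections whose peak amplitude depends on whether
# the trial was answered correctly.

# Matrix of 1/f ("pink") noise columns with unit expected variance per
# sample. Spectral shaping of white noise: amplitude ~ f^(-1/2), flat below
# one cycle per window so the DC/drift end stays bounded.
pink_noise <- function(n, m) {
  if (n < 2 || m < 1) return(matrix(0, n, m))
  white <- matrix(rnorm(n * m), n, m)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)           # two-sided frequency index
  g <- 1 / sqrt(pmax(f, 1))
  spec <- mvfft(white) * g
  out <- Re(mvfft(spec, inverse = TRUE)) / n
  out / sqrt(mean(g^2))  # unit variance per sample
}

epoch_times <- function(epoch_window, sfreq) {
  o1 <- round(epoch_window[1] * sfreq / 1000)
  o2 <- round(epoch_window[2] * sfreq / 1000)
  (o1:o2) * 1000 / sfreq
}

#' Generate label-dependent synthetic EEG epochs
#'
#' Builds one epoch per behaviour row: background noise (80% pink, 60% white
#' in sd, combining to `noise_sd`) plus, for every configured ERP effect, a
#' Gaussian-windowed deflection on the three channels of the effect's region
#' whose peak amplitude is `amp_correct` or `amp_incorrect` according to the
#' trial label. Correct-trial deflections are never smaller, which is what
#' makes decision correctness decodable from the EEG.
#'
#' @param config A [sim_config()].
#' @param behavior Behaviour table from [generate_behavior()].
#' @param subject_id Subject to generate; `NULL` generates every subject in
#'   `behavior` and returns a named list.
#' @return An `eeg_epochs` object (or named list of them): trials x channels
#'   x samples array plus `times_ms`, `labels`, `channel_names`, `sfreq`,
#'   `subject_id`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 1, n_trials_per_subject = 8,
#'                   image_size = c(90, 60))
#' beh <- generate_behavior(cfg, generate_images(cfg, render = FALSE))
#' ep <- generate_epochs(cfg, beh, "S01")
#' dim(ep$data)
generate_epochs <- function(config, behavior, subject_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(subject_id)) {
    subjects <- unique(behavior$subject_id)
    out <- lapply(subjects, function(s) generate_epochs(config, behavior, s))
    names(out) <- subjects
    return(out)
  }
  beh <- behavior[behavior$subject_id == subject_id, , drop = FALSE]
  if (!nrow(beh)) stop("no behaviour rows for subject ", subject_id, call. = FALSE)
  beh <- beh[order(beh$trial_index), , drop = FALSE]

  chans <- config$channels
  eff <- config$erp_effects
  missing_ch <- setdiff(unlist(region_channels()[unique(eff$region)]), chans)
  if (length(missing_ch)) {
    stop("channel list is missing effect channels: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  times <- epoch_times(config$epoch_window, config$sfreq)
  ns <- length(times); ntr <- nrow(beh); nch <- length(chans)
  labels <- beh$label

  snum <- as.integer(sub("^S", "", subject_id))
  arr <- with_seed(child_seed(config$seed, 5L, snum), {
    noise <- if (config$noise_sd > 0) {
      0.8 * config$noise_sd * pink_noise(ns, ntr * nch) +
        0.6 * config$noise_sd * matrix(rnorm(ns * ntr * nch), ns, ntr * nch)
    } else {
      matrix(0, ns, ntr * nch)
    }
    aperm(array(noise, c(ns, ntr, nch)), c(2, 3, 1))
  })
  dimnames(arr) <- list(NULL, chans, NULL)

  for (k in seq_len(nrow(eff))) {
    bump <- exp(-0.5 * ((times - eff$center_ms[k]) / eff$width_ms[k])^2)
    amp <- ifelse(labels == 1L, eff$amp_correct[k], eff$amp_incorrect[k])
    contribution <- outer(amp, bump)
    for (ch in region_channels(eff$region[k])) {
      arr[, ch, ] <- arr[, ch, ] + contribution
    }
  }
  eeg_epochs(arr, times, labels, chans, config$sfreq, subject_id)
}
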