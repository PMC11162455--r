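# Shared fixtures, all built in code.

# A small, fast study configuration for structural tests; overrides win.
tiny_config <- function(...) {
  args <- list(n_subjects = 2, n_trials_per_subject = 24,
               image_size = c(120, 72), n_masks_range = c(4, 8), seed = 7)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Random epochs with a given geometry (no injected structure).
random_epochs <- function(n_trials = 20, channels = feature_channels(),
                          sfreq = 250, window = c(-100, 1000), seed = 1,
                          labels = NULL, subject_id = "S01") {
  set.seed(seed)
  times <- seq(round(window[1] * sfreq / 1000),
               round(window[2] * sfreq / 1000)) * 1000 / sfreq
  arr <- array(rnorm(n_trials * length(channels) * length(times)),
               c(n_trials, length(channels), length(times)))
  labels <- labels %||% rep_len(c(0L, 1L), n_trials)
  eeg_epochs(arr, times, labels, channels, sfreq, subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal permutation-result stub for segment extraction tests.
perm_stub <- function(times_ms, mask, diff = rep(1, length(times_ms))) {
  structure(list(times_ms = times_ms, observed_diff = diff,
                 p_values = ifelse(mask, 1e-6, 0.5), alpha = 0.05,
                 alpha_adjusted = 1e-4, significant_mask = mask,
                 n_permutations = 1000L, n_correct = 10L, n_incorrect = 10L,
                 seed = 1),
            class = "erp_permutation")
}

# A feature table built from a plain matrix with balanced labels.
table_from_matrix <- function(m, labels = NULL, subjects = "S01") {
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%02d", seq_len(ncol(m)))
  labels <- labels %||% rep_len(c(0L, 1L), nrow(m))
  feature_table(m, "eeg", labels, rep_len(subjects, nrow(m)))
}

# Amplitude of frequency `f` (Hz) in a signal via the discrete Fourier
# transform (assumes an integer number of cycles in the window).
fft_amplitude <- function(x, f, sfreq) {
  n <- length(x)
  bin <- round(f * n / sfreq) + 1L
  2 * Mod(fft(x)[bin]) / n
}

# Independent loop-style implementations of the five statistics.
oracle_stat <- function(x, method) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v / n
  switch(method,
         mean = m,
         median = sort(x)[if (n %% 2 == 1) (n + 1) / 2 else c(n / 2, n / 2 + 1)] |>
           mean(),
         std = {
           s <- 0; for (v in x) s <- s + (v - m)^2
           sqrt(s / (n - 1))
         },
         mean_square = {
           s <- 0; for (v in x) s <- s + (v - m)^2
           s / n
         },
         rms = {
           s <- 0; for (v in x) s <- s + v^2
           sqrt(s / n)
         })
}
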