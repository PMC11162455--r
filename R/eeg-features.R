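# Temporal EEG features: five summary statistics per (segment x channel)
# pair over the full cross-product of segments and channels, then greedy
# correlation pruning.

temporal_stat_methods <- c("mean", "median", "std", "mean_square", "rms")

#' Temporal summary statistic of a sample vector
#'
#' The five statistics used for EEG features, with the exact conventions of
#' the analysis: `std` uses the 1/(n-1) denominator, `mean_square` is the
#' central second moment with 1/n (so `n * mean_square = (n-1) * std^2`),
#' and `rms` is the uncentred root mean square.
#'
#' @param x Numeric vector of amplitude samples (microvolt).
#' @param method One of "mean", "median", "std", "mean_square", "rms".
#' @return A scalar.
#' @export
#' @examples
#' temporal_stat(c(1, 2, 3), "mean_square")  # 2/3
temporal_stat <- function(x, method = temporal_stat_methods) {
  method <- match.arg(method)
  n <- length(x)
  if (n == 0L) stop("`x` must be non-empty", call. = FALSE)
  if (method == "std" && n < 2L) stop("std needs n >= 2", call. = FALSE)
  switch(method,
         mean = sum(x) / n,
         median = median(x),
         std = sqrt(sum((x - mean(x))^2) / (n - 1)),
         mean_square = sum((x - mean(x))^2) / n,
         rms = sqrt(sum(x^2) / n))
}

#' Extract the temporal EEG feature table
#'
#' Applies every statistic to every (channel, segment) pair — the full
#' cross-product, not just each segment's home region, which is what makes
#' 9 segments x 12 channels x 5 methods = 540 features. The samples entering
#' a feature are those with `onset_ms <= t <= offset_ms` in the given
#' channel's epoch. Feature names follow `CHANNEL_SEGMENT_STAT`
#' (e.g. `PZ_P8p_median`), with the channel upper-cased and the segment's
#' `alias` used when present. Column order is channels outer, segments
#' middle, statistics inner; this is also the precedence order of
#' [correlation_prune()].
#'
#' @param epochs An `eeg_epochs`.
#' @param segments Segment table with `onset_ms`, `offset_ms` and `name`
#'   (optionally `alias`); defaults to [reference_segments()].
#' @param channels Channels to use; defaults to the twelve feature channels.
#' @param methods Statistics to apply (default all five).
#' @return A `feature_table` with modality `"eeg"`.
#' @export
extract_segment_features <- function(epochs, segments = reference_segments(),
                                     channels = feature_channels(),
                                     methods = temporal_stat_methods) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  methods <- match.arg(methods, temporal_stat_methods, several.ok = TRUE)
  missing_ch <- setdiff(channels, epochs$channel_names)
  if (length(missing_ch)) {
    stop("unknown channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  tmin <- min(epochs$times_ms); tmax <- max(epochs$times_ms)
  if (any(segments$onset_ms < tmin | segments$offset_ms > tmax)) {
    stop("segment outside the epoch window", call. = FALSE)
  }
  seg_names <- if ("alias" %in% names(segments)) segments$alias else segments$name
  ntr <- dim(epochs$data)[1]
  cols <- vector("list", length(channels) * nrow(segments) * length(methods))
  col_names <- character(length(cols))
  j <- 0L
  for (ch in channels) {
    ch_idx <- match(ch, epochs$channel_names)
    for (s in seq_len(nrow(segments))) {
      idx <- which(epochs$times_ms >= segments$onset_ms[s] &
                     epochs$times_ms <= segments$offset_ms[s])
      mat <- epochs$data[, ch_idx, idx, drop = TRUE]
      if (is.null(dim(mat))) mat <- matrix(mat, nrow = ntr)
      k <- ncol(mat)
      rm_ <- rowMeans(mat)
      css <- rowSums((mat - rm_)^2)
      for (m in methods) {
        j <- j + 1L
        cols[[j]] <- switch(m,
                            mean = rm_,
                            median = apply(mat, 1L, median),
                            std = sqrt(css / (k - 1)),
                            mean_square = css / k,
                            rms = sqrt(rowSums(mat^2) / k))
        col_names[j] <- paste(toupper(ch), seg_names[s], m, sep = "_")
      }
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- col_names
  feature_table(out, "eeg", epochs$labels,
                rep(epochs$subject_id %||% "S01", ntr))
}

#' Greedy correlation pruning of a feature table
#'
#' Scans columns left to right in their canonical order; a feature is dropped
#' iff its absolute Pearson correlation with any earlier *kept* feature
#' exceeds `threshold`. The surviving table therefore has no pair with
#' `|r| > threshold`. Zero-variance columns (undefined correlation) are
#' treated as correlation 0 and kept, with a message.
#'
#' @param table A `feature_table` with at least two rows.
#' @param threshold Absolute-correlation threshold in (0, 1].
#' @return List with the pruned `table` and `dropped` (character vector of
#'   removed feature names).
#' @export
#' @examples
#' m <- cbind(a = rnorm(50), b = rnorm(50))
#' m <- cbind(m, c = m[, "a"])  # duplicate of a
#' ft <- feature_table(m, "eeg", rbinom(50, 1, 0.5), rep("S01", 50))
#' correlation_prune(ft, 0.8)$dropped
correlation_prune <- function(table, threshold = 0.80) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$matrix) < 2L) stop("need >= 2 trials", call. = FALSE)
  stopifnot_scalar(threshold, "threshold", lower = 1e-12, upper = 1)
  p <- ncol(table$matrix)
  sds <- apply(table$matrix, 2L, sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " zero-variance feature(s) kept (correlation treated as 0)")
  }
  C <- suppressWarnings(abs(cor(table$matrix)))
  C[is.na(C)] <- 0
  kept <- logical(p)
  for (j in seq_len(p)) {
    kept[j] <- !any(C[which(kept), j] > threshold)
  }
  dropped <- colnames(table$matrix)[!kept]
  list(table = select_features(table, colnames(table$matrix)[kept]),
       dropped = dropped)
}
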