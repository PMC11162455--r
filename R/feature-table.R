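# Trial x feature container shared by the EEG and image feature extractors
# and the classifier front end.

#' Construct a feature table
#'
#' A thin container holding a trials x features numeric matrix with unique
#' column names, a per-feature modality tag ("eeg" or "image"), binary trial
#' labels and per-trial subject ids. Rows align with the behaviour-table
#' order.
#'
#' @param matrix Numeric trials x features matrix with column names.
#' @param modality Single tag or per-feature vector, values "eeg" / "image".
#' @param labels Binary labels, one per row.
#' @param subject_ids Subject id per row.
#' @return A `feature_table` object.
#' @export
feature_table <- function(matrix, modality, labels, subject_ids) {
  matrix <- as.matrix(matrix)
  if (is.null(colnames(matrix)) || anyDuplicated(colnames(matrix))) {
    stop("feature matrix needs unique column names", call. = FALSE)
  }
  if (length(modality) == 1L) modality <- rep(modality, ncol(matrix))
  stopifnot(length(modality) == ncol(matrix),
            all(modality %in% c("eeg", "image")),
            length(labels) == nrow(matrix),
            length(subject_ids) == nrow(matrix))
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (anyNA(matrix)) stop("feature matrix must not contain missing values",
                          call. = FALSE)
  structure(list(matrix = matrix,
                 modality = setNames(modality, colnames(matrix)),
                 labels = as.integer(labels),
                 subject_ids = as.character(subject_ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$modality)
  cat(sprintf("<feature_table> %d trials x %d features (%s), %d subject(s), %.2f correct\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              length(unique(x$subject_ids)), mean(x$labels)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$matrix)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  cbind(data.frame(subject_id = x$subject_ids, label = x$labels,
                   stringsAsFactors = FALSE),
        as.data.frame(x$matrix))
}

# Column subset preserving metadata.
select_features <- function(table, names) {
  missing <- setdiff(names, colnames(table$matrix))
  if (length(missing)) {
    stop("unknown feature(s): ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  feature_table(table$matrix[, names, drop = FALSE],
                unname(table$modality[names]),
                table$labels, table$subject_ids)
}

# Row subset (e.g. one subject) preserving metadata.
subset_trials <- function(table, keep) {
  feature_table(table$matrix[keep, , drop = FALSE], unname(table$modality),
                table$labels[keep], table$subject_ids[keep])
}

# Column-bind two aligned tables (same trials, same order).
bind_features <- function(a, b) {
  if (nrow(a$matrix) != nrow(b$matrix) ||
      !identical(a$labels, b$labels) ||
      !identical(a$subject_ids, b$subject_ids)) {
    stop("feature tables are not row-aligned", call. = FALSE)
  }
  feature_table(cbind(a$matrix, b$matrix),
                c(unname(a$modality), unname(b$modality)),
                a$labels, a$subject_ids)
}

#' Write / read a feature table as CSV
#'
#' The CSV carries `subject_id`, `trial_index` (row order), `label`, then the
#' features; modality tags go to a JSON manifest next to it.
#'
#' @param table A `feature_table`.
#' @param path CSV path; the manifest is written to `<path>.manifest.json`.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` the reconstructed `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  df <- cbind(data.frame(subject_id = table$subject_ids,
                         trial_index = seq_len(nrow(table$matrix)),
                         label = table$labels),
              as.data.frame(table$matrix, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(modality = as.list(table$modality)),
                       paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param path CSV path written by `write_feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  manifest <- jsonlite::read_json(paste0(path, ".manifest.json"),
                                  simplifyVector = TRUE)
  feats <- setdiff(names(df), c("subject_id", "trial_index", "label"))
  feature_table(as.matrix(df[, feats, drop = FALSE]),
                unname(unlist(manifest$modality)[feats]),
                df$label, df$subject_id)
}
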