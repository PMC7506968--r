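#' EEG signal containers
#'
#' Lightweight containers for single-channel and paired-channel EEG records.
#' `eeg_signal()` holds one channel of samples plus its sampling rate;
#' `paired_signal()` holds the x/y channel pair of one intracranial record.
#' Class labels follow the focal-epilepsy convention: `"FC"` (focal, recorded
#' at channels that first show ictal activity) versus `"NFC"` (non-focal).
#'
#' @param samples numeric vector of samples (microvolts for real recordings).
#' @param fs sampling rate in Hz.
#' @param label optional class tag, one of `"NFC"`, `"FC"` or `NA`.
#' @param source_id identifier of the originating record.
#' @return An object of class `eeg_signal`.
#' @examples
#' s <- eeg_signal(sin(seq_len(256) / 10), fs = 173.61)
#' length(s$samples)
#' @export
eeg_signal <- function(samples, fs, label = NA_character_, source_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("'samples' must be non-empty", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("'samples' must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number", call. = FALSE)
  label <- as.character(label)
  if (!is.na(label) && !label %in% c("NFC", "FC"))
    stop("'label' must be \"NFC\", \"FC\" or NA", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, label = label,
         source_id = as.character(source_id)),
    class = "eeg_signal"
  )
}

#' @param x,y `eeg_signal` objects of equal length and sampling rate.
#' @rdname eeg_signal
#' @export
paired_signal <- function(x, y, label = NA_character_, source_id = "") {
  stopifnot(inherits(x, "eeg_signal"), inherits(y, "eeg_signal"))
  if (length(x$samples) != length(y$samples))
    stop("x and y channels must have the same length", call. = FALSE)
  if (x$fs != y$fs)
    stop("x and y channels must share one sampling rate", call. = FALSE)
  label <- as.character(label)
  if (!is.na(label) && !label %in% c("NFC", "FC"))
    stop("'label' must be \"NFC\", \"FC\" or NA", call. = FALSE)
  structure(
    list(x = x, y = y, label = label, source_id = as.character(source_id)),
    class = "eeg_paired"
  )
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> %d samples @ %.4g Hz (%.1f s)%s%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.na(x$label)) "" else paste0(", label ", x$label),
              if (nzchar(x$source_id)) paste0(", ", x$source_id) else ""))
  invisible(x)
}

#' @export
print.eeg_paired <- function(x, ...) {
  cat(sprintf("<eeg_paired> x/y channels, %d samples @ %.4g Hz%s%s\n",
              length(x$x$samples), x$x$fs,
              if (is.na(x$label)) "" else paste0(", label ", x$label),
              if (nzchar(x$source_id)) paste0(", ", x$source_id) else ""))
  invisible(x)
}

parse_numeric_lines <- function(lines, path) {
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  bad <- which(is.na(vals))
  if (length(bad))
    stop(sprintf("cannot parse line %d of '%s' as a number: \"%s\"",
                 idx[bad[1L]], path, trimws(lines[idx[bad[1L]]])),
         call. = FALSE)
  vals
}

#' Read a single-channel EEG record
#'
#' Reads the one-value-per-line ASCII dialect used by the Bonn scalp/depth
#' EEG distribution (4096 samples at 173.61 Hz per record). Blank lines are
#' ignored; every other line must parse as one number. No filtering or
#' resampling is applied: records are consumed as distributed.
#'
#' @param path file to read.
#' @param fs sampling rate in Hz (the Bonn records are 173.61 Hz).
#' @inheritParams eeg_signal
#' @return An [eeg_signal()].
#' @export
read_single_channel_record <- function(path, fs = 173.61,
                                       label = NA_character_,
                                       source_id = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  vals <- parse_numeric_lines(readLines(path, warn = FALSE), path)
  if (length(vals) == 0L)
    stop(sprintf("file '%s' contains no samples", path), call. = FALSE)
  eeg_signal(vals, fs = fs, label = label, source_id = source_id)
}

#' Read a paired-channel EEG record
#'
#' Reads the two-column ASCII dialect of the Bern-Barcelona intracranial
#' distribution (10,240 samples per channel at 512 Hz): each line holds the
#' x-channel and y-channel sample separated by `delimiter`.
#'
#' @inheritParams read_single_channel_record
#' @param fs sampling rate in Hz (the Bern-Barcelona records are 512 Hz).
#' @param delimiter single-character field separator, default `","`.
#' @return A [paired_signal()].
#' @export
read_paired_record <- function(path, fs = 512, delimiter = ",",
                               label = NA_character_,
                               source_id = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L)
    stop(sprintf("file '%s' contains no samples", path), call. = FALSE)
  fields <- strsplit(trimws(lines[keep]), delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop(sprintf("row %d of '%s' has %d fields, expected 2",
                 idx[bad], path, nf[bad]), call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(trimws(unlist(fields)))),
              ncol = 2L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0L)[1L]
    stop(sprintf("cannot parse row %d of '%s' as two numbers",
                 idx[bad], path), call. = FALSE)
  }
  paired_signal(eeg_signal(m[, 1L], fs = fs),
                eeg_signal(m[, 2L], fs = fs),
                label = label, source_id = source_id)
}

#' Write and read per-record feature tables
#'
#' Persists the feature vectors of a set of records as a plain CSV with
#' columns `source_id`, `label`, then one column per named feature. Values
#' survive a write/read cycle to better than 1e-12 relative error. All rows
#' must share one feature ordering.
#'
#' @param rows a list of feature vectors as returned by
#'   [extract_feature_vector()] (each carries `source_id` and `label`
#'   attributes), or a data.frame already in table layout.
#' @param path output CSV file.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a data.frame with `source_id` and `label`
#'   character columns and numeric feature columns.
#' @export
write_feature_table <- function(rows, path) {
  df <- if (is.data.frame(rows)) rows else feature_rows_to_df(rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

feature_rows_to_df <- function(rows) {
  if (length(rows) == 0L)
    stop("'rows' must contain at least one feature vector; ",
         "pass a data.frame for an empty table", call. = FALSE)
  nm <- names(rows[[1L]])
  for (r in rows) {
    if (!identical(names(r), nm))
      stop("all feature vectors must share one feature ordering",
           call. = FALSE)
  }
  vals <- do.call(rbind, lapply(rows, as.numeric))
  colnames(vals) <- nm
  data.frame(
    source_id = vapply(rows, function(r)
      as.character(attr(r, "source_id") %||% ""), character(1L)),
    label = vapply(rows, function(r)
      as.character(attr(r, "label") %||% NA_character_), character(1L)),
    vals,
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(source_id = "character",
                                       label = "character"))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a signal back to its on-disk dialect
#'
#' Inverse of the readers: one value per line for an [eeg_signal()], two
#' delimited columns for a [paired_signal()]. Values are written with 15
#' significant digits so a read-back reproduces samples to 1e-12.
#'
#' @param record an `eeg_signal` or `eeg_paired` object.
#' @param path output file.
#' @param delimiter field separator for paired records.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, delimiter = ",") {
  if (inherits(record, "eeg_signal")) {
    writeLines(sprintf("%.15g", record$samples), path)
  } else if (inherits(record, "eeg_paired")) {
    writeLines(sprintf("%.15g%s%.15g",
                       record$x$samples, delimiter, record$y$samples), path)
  } else {
    stop("'record' must be an eeg_signal or eeg_paired object", call. = FALSE)
  }
  invisible(path)
}
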