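#' Synthetic two-class EEG dataset configuration
#'
#' The generator emulates the structure of paired intracranial recordings:
#' two correlated channels per record and two classes whose temporal
#' regularity differs. Each x channel is a stationary AR(1) process with
#' Gaussian innovations; the focal-like (FC) class uses a high
#' autoregressive coefficient (more regular, lower entropy — mirroring the
#' reduced complexity of epileptogenic-zone recordings), the non-focal-like
#' (NFC) class a low one (closer to white noise). The y channel is a 0.7/0.3
#' mixture of x and an independent AR(1), imitating a correlated neighbouring
#' electrode. Records are deterministic functions of `(seed, class, index)`.
#'
#' @param n_pairs records per class.
#' @param length samples per channel (default 1024; set 10240 for the
#'   dialect-faithful record length).
#' @param fs sampling rate tag carried on the generated signals, Hz.
#' @param fc_ar_phi AR(1) coefficient of the focal-like class.
#' @param nfc_ar_phi AR(1) coefficient of the non-focal-like class.
#' @param noise_sd innovation standard deviation.
#' @param seed base seed; every record derives its own stream from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_pairs = 100L, length = 1024L, fs = 512,
                         fc_ar_phi = 0.95, nfc_ar_phi = 0.4,
                         noise_sd = 1, seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs), length = as.integer(length),
              fs = fs, fc_ar_phi = fc_ar_phi, nfc_ar_phi = nfc_ar_phi,
              noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(cfg$n_pairs >= 1L, cfg$length >= 64L, cfg$fs > 0,
            cfg$fc_ar_phi >= 0, cfg$fc_ar_phi < 1,
            cfg$nfc_ar_phi >= 0, cfg$nfc_ar_phi < 1, cfg$noise_sd > 0)
  class(cfg) <- "synth_config"
  cfg
}

ar1_series <- function(n, phi, sd) {
  innov <- stats::rnorm(n, sd = sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Generate one synthetic paired record
#'
#' @param class `"FC"` or `"NFC"`.
#' @param cfg a [synth_config()].
#' @param index record index within the class (1-based); part of the
#'   per-record seed so records are independent but reproducible.
#' @return A [paired_signal()] labelled with `class`.
#' @export
generate_class_signal <- function(class, cfg, index = 1L) {
  stopifnot(inherits(cfg, "synth_config"), class %in% c("FC", "NFC"))
  phi <- if (class == "FC") cfg$fc_ar_phi else cfg$nfc_ar_phi
  # distinct sub-stream per (seed, class, index); kept well below 2^31
  rec_seed <- (cfg$seed * 977L + index * 2L +
                 (class == "FC")) %% 2147483629L
  rs <- local_rng(rec_seed)
  on.exit(restore_rng(rs))
  x <- ar1_series(cfg$length, phi, cfg$noise_sd)
  y <- 0.7 * x + 0.3 * ar1_series(cfg$length, phi, cfg$noise_sd)
  sid <- sprintf("synth_%s_%04d", class, index)
  paired_signal(eeg_signal(x, fs = cfg$fs),
                eeg_signal(y, fs = cfg$fs),
                label = class, source_id = sid)
}

#' Generate a labelled synthetic dataset
#'
#' Produces `2 * n_pairs` paired records (classes alternating by index) and
#' a manifest recording the full configuration, sufficient to regenerate the
#' dataset exactly.
#'
#' @param cfg a [synth_config()].
#' @return A list with `records` (list of [paired_signal()]) and `manifest`
#'   (config echo plus record ids and labels).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  records <- vector("list", 2L * cfg$n_pairs)
  for (i in seq_len(cfg$n_pairs)) {
    records[[2L * i - 1L]] <- generate_class_signal("NFC", cfg, i)
    records[[2L * i]] <- generate_class_signal("FC", cfg, i)
  }
  manifest <- list(
    config = unclass(cfg),
    n_records = length(records),
    source_id = vapply(records, function(r) r$source_id, character(1L)),
    label = vapply(records, function(r) r$label, character(1L)))
  list(records = records, manifest = manifest)
}

#' Write a synthetic dataset to disk in a reader dialect
#'
#' Emits one file per record — two-column paired dialect (`"bb"`) or one
#' one-column file per channel (`"bonn"`, x channel only) — plus
#' `manifest.json`. Files written in the paired dialect round-trip through
#' [read_paired_record()].
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param dialect `"bb"` (two delimited columns) or `"bonn"` (one value per
#'   line, x channel).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, dialect = c("bb", "bonn")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in dataset$records) {
    path <- file.path(dir, paste0(rec$source_id, ".txt"))
    if (dialect == "bb") write_record(rec, path)
    else write_record(rec$x, path)
  }
  jsonlite::write_json(dataset$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @param dialect dialect the files were written in.
#' @return A list of labelled records ([paired_signal()] or [eeg_signal()]).
#' @export
read_dataset <- function(dir, dialect = c("bb", "bonn")) {
  dialect <- match.arg(dialect)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  fs <- man$config$fs
  mapply(function(sid, lab) {
    path <- file.path(dir, paste0(sid, ".txt"))
    if (dialect == "bb")
      read_paired_record(path, fs = fs, label = lab, source_id = sid)
    else
      read_single_channel_record(path, fs = fs, label = lab, source_id = sid)
  }, man$source_id, man$label, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
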