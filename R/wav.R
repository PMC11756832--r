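# Minimal mono 16-bit PCM WAV reader/writer (RIFF/WAVE, canonical 44-byte
# header). Only the subset of the format this package emits is supported.

#' Write a recording to a mono 16-bit PCM WAV file
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_domain("cannot open WAV for writing: ", path))
  on.exit(close(con))
  pcm <- as.integer(round(pmax(-1, pmin(1, rec$samples)) * 32767))
  n <- length(pcm)
  sr <- rec$sample_rate
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @param participant_id optional identifier attached to the recording.
#' @return a [recording()].
#' @export
read_wav <- function(path, participant_id = NA_character_) {
  if (!file.exists(path)) stop_domain("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop_domain("not a RIFF/WAVE file: ", path)
  }
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop_domain("no data chunk in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) {
        stop_domain("only mono PCM WAV is supported: ", path)
      }
      sr <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop_domain("only 16-bit PCM WAV is supported: ", path)
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2, endian = "little",
                     signed = TRUE)
      break
    } else {
      readBin(con, raw(), n = sz)
    }
  }
  recording(pcm / 32767, sr, participant_id)
}

#' Write a cohort to disk as WAV files plus a manifest CSV
#'
#' Synthesizes one recording per participant (with a per-participant seed
#' derived from the cohort spec's seed) and writes a UTF-8 manifest CSV with
#' columns `participant_id`, `age`, `sex`, the five K-FRAIL item indicators,
#' `kfrail_score`, `category`, `label`, `wav_path`. Round-trips losslessly
#' through [read_cohort()].
#'
#' @param cohort a `frailty_cohort` from [generate_cohort()].
#' @param directory output directory (created if needed).
#' @return path of the manifest CSV, invisibly the updated cohort as
#'   attribute `"cohort"`.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "frailty_cohort"))
  spec <- attr(cohort, "spec")
  if (is.null(spec)) stop_domain("cohort has no attached cohort_spec")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop_domain("cannot create directory: ", directory)
  for (i in seq_len(nrow(cohort))) {
    rec <- synthesize_speech(cohort[i, ], spec$audio_baseline,
                             spec$audio_severe,
                             seed = derive_seed(spec$seed, 101L, i))
    wav <- file.path(directory, paste0(cohort$participant_id[i], ".wav"))
    write_wav(rec, wav)
    cohort$wav_path[i] <- wav
  }
  manifest <- file.path(directory, "manifest.csv")
  utils::write.csv(as.data.frame(cohort), manifest, row.names = FALSE,
                   fileEncoding = "UTF-8")
  out <- manifest
  attr(out, "cohort") <- cohort
  invisible(out)
}

#' Read a cohort manifest written by [write_cohort()]
#'
#' @param manifest path to the manifest CSV (or a directory containing
#'   `manifest.csv`).
#' @return a `frailty_cohort` data frame; audio stays on disk and is loaded
#'   per participant with [read_wav()].
#' @export
read_cohort <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  if (!file.exists(manifest)) stop_domain("manifest not found: ", manifest)
  cohort <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  required <- c("participant_id", "age", "sex", kfrail_item_names(),
                "kfrail_score", "category", "label", "wav_path")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    stop_domain("manifest is missing columns: ", paste(missing, collapse = ", "))
  }
  # recompute invariant fields to catch corrupted manifests
  resum <- rowSums(cohort[, kfrail_item_names()])
  if (any(resum != cohort$kfrail_score)) {
    stop_domain("manifest kfrail_score inconsistent with item indicators")
  }
  class(cohort) <- c("frailty_cohort", "data.frame")
  cohort
}
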