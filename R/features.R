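#' Acoustic feature extraction configuration
#'
#' Framing and filterbank parameters for MFCC extraction. Defaults follow
#' standard speech practice: 25 ms Hann windows with a 10 ms hop at a 16 kHz
#' analysis rate, 64 mel bands from 20 Hz to Nyquist, 20 retained cepstral
#' coefficients (including the log-energy-like coefficient 0), and
#' width-9 regression deltas.
#'
#' @param target_sample_rate analysis sampling rate in Hz; recordings at
#'   other rates are resampled internally.
#' @param frame_length_ms,hop_ms analysis window length and hop in ms.
#' @param n_mels number of mel filterbank bands.
#' @param fmin,fmax filterbank edges in Hz (`fmax = NULL` means Nyquist).
#' @param n_coeff number of cepstral coefficients kept ("n"); the feature
#'   matrix has `3 * n_coeff` columns (coefficients, deltas, delta-deltas).
#' @param delta_width odd number of frames in the delta regression window.
#' @param log_floor floor applied before the log of the mel spectrum.
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(target_sample_rate = 16000,
                           frame_length_ms = 25,
                           hop_ms = 10,
                           n_mels = 64,
                           fmin = 20,
                           fmax = NULL,
                           n_coeff = 20,
                           delta_width = 9,
                           log_floor = 1e-10) {
  fmax <- fmax %||% (target_sample_rate / 2)
  if (n_coeff > n_mels) stop_domain("n_coeff must not exceed n_mels")
  if (delta_width %% 2 == 0 || delta_width < 3) {
    stop_domain("delta_width must be odd and at least 3")
  }
  if (fmax > target_sample_rate / 2) stop_domain("fmax above Nyquist")
  structure(list(target_sample_rate = target_sample_rate,
                 frame_length_ms = frame_length_ms, hop_ms = hop_ms,
                 n_mels = n_mels, fmin = fmin, fmax = fmax,
                 n_coeff = n_coeff, delta_width = delta_width,
                 log_floor = log_floor),
            class = "feature_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank matrix (n_mels x n_bins).
mel_filterbank <- function(n_mels, nfft, sample_rate, fmin, fmax) {
  n_bins <- nfft / 2 + 1
  freqs <- (0:(n_bins - 1)) * sample_rate / nfft
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                         length.out = n_mels + 2))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in).
dct_matrix <- function(n_out, n_in) {
  k <- 0:(n_out - 1)
  m <- 0:(n_in - 1)
  mat <- sqrt(2 / n_in) * cos(pi * outer(k, 2 * m + 1) / (2 * n_in))
  mat[1, ] <- mat[1, ] / sqrt(2)
  mat
}

# Slice a signal into a (frame_length x T) matrix of hop-spaced frames.
frame_signal <- function(x, nwin, nhop) {
  n_frames <- 1 + floor((length(x) - nwin) / nhop)
  if (n_frames < 1) stop_domain("clip shorter than one analysis frame")
  starts <- (0:(n_frames - 1)) * nhop
  idx <- outer(seq_len(nwin), starts, `+`)
  matrix(x[idx], nrow = nwin)
}

resample_to <- function(samples, from_rate, to_rate) {
  if (from_rate == to_rate) return(samples)
  g <- gcd_int(from_rate, to_rate)
  as.numeric(signal::resample(samples, to_rate / g, from_rate / g))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Windowed frames and their magnitude spectrum; shared by MFCC and
# functional extraction so both see identical framing.
stft_frames <- function(rec, config) {
  x <- resample_to(rec$samples, rec$sample_rate, config$target_sample_rate)
  sr <- config$target_sample_rate
  nwin <- round(config$frame_length_ms * sr / 1000)
  nhop <- round(config$hop_ms * sr / 1000)
  frames <- frame_signal(x, nwin, nhop)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))
  wf <- frames * win
  nfft <- 2^ceiling(log2(nwin))
  padded <- rbind(wf, matrix(0, nfft - nwin, ncol(wf)))
  spec <- stats::mvfft(padded)
  list(x = x, sr = sr, nwin = nwin, nhop = nhop, nfft = nfft,
       frames = frames, windowed = wf,
       mag = Mod(spec[seq_len(nfft / 2 + 1), , drop = FALSE]),
       rms = sqrt(colMeans(frames^2)),
       times = ((0:(ncol(frames) - 1)) * nhop + nwin / 2) / sr)
}

#' Extract the 60-dimensional MFCC feature matrix of a recording
#'
#' Short-time Fourier magnitudes are mapped through a triangular mel
#' filterbank, floored and log-compressed, and projected with an orthonormal
#' DCT-II; the first `n_coeff` cepstral coefficients are kept and first- and
#' second-order regression deltas are appended, giving `3 * n_coeff` columns
#' (60 with the default `n_coeff = 20`).
#'
#' @param rec a [recording()].
#' @param config a [feature_config()].
#' @return a `T x 3*n_coeff` matrix of class `acoustic_features` with
#'   attributes `frame_times` (seconds) and `layout`.
#' @export
extract_mfcc_features <- function(rec, config = feature_config()) {
  s <- stft_frames(rec, config)
  fb <- mel_filterbank(config$n_mels, s$nfft, s$sr, config$fmin, config$fmax)
  logmel <- log(pmax(fb %*% s$mag, config$log_floor))
  dct <- dct_matrix(config$n_coeff, config$n_mels)
  mfcc <- t(dct %*% logmel)                       # T x n_coeff
  d1 <- compute_deltas(mfcc, order = 1, width = config$delta_width)
  d2 <- compute_deltas(mfcc, order = 2, width = config$delta_width)
  out <- cbind(mfcc, d1, d2)
  colnames(out) <- c(paste0("mfcc", 0:(config$n_coeff - 1)),
                     paste0("d1_", 0:(config$n_coeff - 1)),
                     paste0("d2_", 0:(config$n_coeff - 1)))
  structure(out, frame_times = s$times,
            layout = c(mfcc = config$n_coeff, delta = config$n_coeff,
                       delta2 = config$n_coeff),
            config_hash = config_hash(unclass(config)),
            class = c("acoustic_features", class(out)))
}

#' Local least-squares regression deltas of a frame-feature matrix
#'
#' The standard delta operator of speech front ends: for each column, the
#' slope of a least-squares line over a centered window of `width` frames
#' (weights `k / sum(k^2)`, `k = -(width-1)/2 .. (width-1)/2`) with edge
#' frames replicated. `order = 2` applies the operator twice.
#'
#' @param mat numeric `T x d` matrix.
#' @param order 1 (delta) or 2 (delta-delta).
#' @param width odd window length in frames.
#' @return matrix of the same shape.
#' @export
compute_deltas <- function(mat, order = 1, width = 9) {
  if (width %% 2 == 0) stop_domain("delta window width must be odd")
  if (!order %in% 1:2) stop_domain("order must be 1 or 2")
  mat <- as.matrix(mat)
  h <- (width - 1) / 2
  denom <- 2 * sum((1:h)^2)
  delta1 <- function(m) {
    tt <- nrow(m)
    padded <- m[c(rep(1, h), seq_len(tt), rep(tt, h)), , drop = FALSE]
    out <- matrix(0, tt, ncol(m))
    for (k in 1:h) {
      out <- out + k * (padded[(h + k) + seq_len(tt), , drop = FALSE] -
                        padded[(h - k) + seq_len(tt), , drop = FALSE])
    }
    out / denom
  }
  res <- delta1(mat)
  if (order == 2) res <- delta1(res)
  dimnames(res) <- NULL
  res
}

#' Fixed-length functional (summary-statistic) vector of a recording
#'
#' Per-clip statistics used by the classical baselines: mean and SD of each
#' of the 60 MFCC-based feature columns (120 values) plus six prosodic
#' functionals - F0 mean and SD over voiced frames (Hz), voiced fraction,
#' RMS-loudness mean and SD, and pause fraction. F0 is estimated per frame
#' as the autocorrelation peak in the 60-400 Hz lag range; pauses are frames
#' whose RMS falls below an adaptive threshold (10% of the 95th-percentile
#' frame RMS). A fully silent clip gets voiced fraction 0 and F0 statistics
#' 0, and is flagged via the `silent` attribute.
#'
#' @param rec a [recording()].
#' @param config a [feature_config()].
#' @return named numeric vector of length 126 with attribute `silent`.
#' @export
extract_functionals <- function(rec, config = feature_config()) {
  feats <- extract_mfcc_features(rec, config)
  s <- stft_frames(rec, config)
  rms <- s$rms
  thr <- max(1e-4, 0.1 * stats::quantile(rms, 0.95, names = FALSE))
  pause <- rms < thr
  silent <- all(pause) || max(rms) < 1e-7

  # autocorrelation F0 tracker on non-pause frames
  f0 <- rep(NA_real_, ncol(s$frames))
  voiced <- rep(FALSE, ncol(s$frames))
  lag_min <- max(2L, floor(s$sr / 400))
  lag_max <- min(s$nwin - 1L, ceiling(s$sr / 60))
  if (!silent && lag_max > lag_min) {
    nfft2 <- 2^ceiling(log2(2 * s$nwin))
    padded <- rbind(s$frames, matrix(0, nfft2 - s$nwin, ncol(s$frames)))
    pw <- Mod(stats::mvfft(padded))^2
    ac <- Re(stats::mvfft(pw, inverse = TRUE)) / nfft2
    for (t in which(!pause)) {
      a0 <- ac[1, t]
      if (a0 <= 0) next
      seg <- ac[(lag_min + 1):(lag_max + 1), t] / a0
      pk <- which.max(seg)
      if (seg[pk] > 0.3) {
        voiced[t] <- TRUE
        f0[t] <- s$sr / (lag_min + pk - 1)
      }
    }
  }
  col_sd <- function(m) {
    v <- apply(m, 2, stats::sd)
    ifelse(is.na(v), 0, v)
  }
  f0v <- f0[voiced]
  out <- c(
    stats::setNames(colMeans(feats), paste0(colnames(feats), "_mean")),
    stats::setNames(col_sd(feats), paste0(colnames(feats), "_sd")),
    f0_mean = if (length(f0v)) mean(f0v) else 0,
    f0_sd = if (length(f0v) > 1) stats::sd(f0v) else 0,
    voiced_fraction = mean(voiced),
    rms_mean = mean(rms),
    rms_sd = if (length(rms) > 1) stats::sd(rms) else 0,
    pause_fraction = mean(pause))
  attr(out, "silent") <- silent
  out
}

#' Extract features for every participant of a written cohort
#'
#' @param cohort a `frailty_cohort` whose `wav_path` entries exist on disk
#'   (see [write_cohort()]).
#' @param config a [feature_config()].
#' @param what `"mfcc"` for frame matrices, `"functionals"` for the
#'   fixed-length summary vectors.
#' @return a named list of feature matrices, or a matrix of functional rows.
#' @export
extract_cohort_features <- function(cohort, config = feature_config(),
                                    what = c("mfcc", "functionals")) {
  what <- match.arg(what)
  recs <- lapply(seq_len(nrow(cohort)), function(i) {
    read_wav(cohort$wav_path[i], cohort$participant_id[i])
  })
  if (what == "mfcc") {
    out <- lapply(recs, extract_mfcc_features, config = config)
    names(out) <- cohort$participant_id
    out
  } else {
    out <- t(vapply(recs, extract_functionals, numeric(126), config = config))
    rownames(out) <- cohort$participant_id
    out
  }
}
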