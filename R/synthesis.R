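#' Construct a recording object
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz.
#' @param participant_id identifier string.
#' @return an object of class `recording`.
#' @export
recording <- function(samples, sample_rate, participant_id = NA_character_) {
  if (any(!is.finite(samples))) stop_domain("recording contains non-finite samples")
  if (length(samples) && max(abs(samples)) > 1 + 1e-9) {
    stop_domain("recording amplitudes must lie in [-1, 1]")
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.integer(sample_rate),
                 participant_id = participant_id),
            class = "recording")
}

#' @exportS3Method base::print
print.recording <- function(x, ...) {
  cat(sprintf("recording: %s, %.2f s at %d Hz (%d samples)\n",
              x$participant_id, length(x$samples) / x$sample_rate,
              x$sample_rate, length(x$samples)))
  invisible(x)
}

# Cascade of two-pole resonators emulating vocal-tract formants.
formant_filter <- function(x, formants, sample_rate) {
  for (i in seq_len(nrow(formants))) {
    r <- exp(-pi * formants$bw[i] / sample_rate)
    theta <- 2 * pi * formants$freq[i] / sample_rate
    a <- c(1, -2 * r * cos(theta), r^2)
    # unity DC gain per stage so the cascade keeps amplitudes commensurate
    b <- 1 - 2 * r * cos(theta) + r^2
    x <- as.numeric(signal::filter(b, a, x))
  }
  x
}

#' Synthesize speech-like audio for one participant
#'
#' Source-filter synthesis standing in for picture-description-task
#' recordings: a glottal pulse train at a sex-dependent fundamental frequency
#' with jitter (period) and shimmer (amplitude) perturbations is passed
#' through a cascade of formant resonators and organized into voiced bursts
#' separated by silent pauses. Severity (K-FRAIL score / 5) linearly
#' interpolates the synthesis parameters between the `baseline` and `severe`
#' endpoints, so higher scores give more pausing, a slower burst rate,
#' rougher voicing and a flatter pitch contour.
#'
#' @param participant one row of a `frailty_cohort` (or a list with
#'   `kfrail_score`, `sex`, `participant_id`).
#' @param baseline [audio_class_params()] for severity 0.
#' @param severe [audio_class_params()] for severity 5; `NULL` disables
#'   severity scaling and uses `baseline` as-is.
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @param speaker_variability scale of seeded between-speaker variation
#'   around the severity-interpolated parameters (habitual pitch, pausing,
#'   rate, roughness); 1 is the default inter-speaker spread, 0 disables it.
#' @return a [recording()].
#' @export
synthesize_speech <- function(participant, baseline = audio_class_params(),
                              severe = severe_audio_params(
                                sample_rate = baseline$sample_rate,
                                duration = baseline$duration),
                              seed = 1L, speaker_variability = 1) {
  score <- participant$kfrail_score %||% 0L
  params <- if (is.null(severe)) baseline else {
    interpolate_audio_params(baseline, severe, score / 5)
  }
  if (params$duration <= 0) stop_domain("requested duration must be positive")
  sr <- params$sample_rate
  n_total <- round(params$duration * sr)
  f0 <- params$f0_base[[as.character(participant$sex %||% "male")]]

  with_seed(seed, {
    # idiosyncratic speaker traits: habitual pitch, pausing, rate, roughness
    v <- speaker_variability
    f0 <- max(70, f0 + stats::rnorm(1, 0, 15 * v))
    params$pause_fraction <- min(0.8, max(0, params$pause_fraction +
                                            stats::rnorm(1, 0, 0.06 * v)))
    params$speech_rate <- params$speech_rate * exp(stats::rnorm(1, 0, 0.15 * v))
    params$jitter <- params$jitter * exp(stats::rnorm(1, 0, 0.25 * v))
    params$shimmer <- params$shimmer * exp(stats::rnorm(1, 0, 0.25 * v))
    params$f0_sd <- params$f0_sd * exp(stats::rnorm(1, 0, 0.2 * v))
    n_bursts <- max(1L, round(params$speech_rate * params$duration))
    voiced_total <- (1 - params$pause_fraction) * params$duration
    pause_total <- params$pause_fraction * params$duration
    wb <- stats::runif(n_bursts, 0.7, 1.3)
    burst_len <- voiced_total * wb / sum(wb)
    wp <- stats::runif(n_bursts, 0.7, 1.3)
    pause_len <- if (pause_total > 0) pause_total * wp / sum(wp) else rep(0, n_bursts)

    x <- numeric(n_total)
    pos <- 1L
    for (b in seq_len(n_bursts)) {
      nb <- round(burst_len[b] * sr)
      if (nb >= 2 && pos <= n_total) {
        f0_b <- max(60, f0 + stats::rnorm(1, 0, params$f0_sd))
        # glottal pulse train with jitter/shimmer
        n_pulse_max <- ceiling(burst_len[b] * f0_b * 1.5) + 2
        periods <- (1 / f0_b) * (1 + params$jitter * stats::rnorm(n_pulse_max))
        t_pulse <- cumsum(pmax(periods, 1 / (4 * f0_b)))
        t_pulse <- t_pulse[t_pulse < burst_len[b]]
        amps <- 1 + params$shimmer * stats::rnorm(length(t_pulse))
        exc <- numeric(nb)
        idx <- pmin(nb, 1L + round(t_pulse * sr))
        exc[idx] <- exc[idx] + amps
        exc <- exc + stats::rnorm(nb, 0, 0.01)   # aspiration noise
        y <- formant_filter(exc, params$formants, sr)
        # 20 ms attack/decay ramps avoid clicks at burst edges
        nr <- min(round(0.02 * sr), floor(nb / 2))
        if (nr > 0) {
          env <- c(seq(0, 1, length.out = nr), rep(1, nb - 2 * nr),
                   seq(1, 0, length.out = nr))
          y <- y * env
        }
        iend <- min(n_total, pos + nb - 1L)
        x[pos:iend] <- y[seq_len(iend - pos + 1L)]
        pos <- iend + 1L
      }
      pos <- pos + round(pause_len[b] * sr)
      if (pos > n_total) break
    }
    x <- x + stats::rnorm(n_total, 0, 1e-4)     # recording noise floor
    peak <- max(abs(x))
    if (peak > 0) x <- 0.9 * x / peak
    recording(x, sr, participant$participant_id %||% NA_character_)
  })
}
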