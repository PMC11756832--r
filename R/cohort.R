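#' Audio synthesis parameters for a severity endpoint
#'
#' Parameters of the source-filter voice synthesizer. A cohort specification
#' carries two endpoints, `baseline` (K-FRAIL score 0) and `severe` (score 5);
#' a participant's effective parameters are linear interpolations between the
#' endpoints at severity `score / 5`. Frail-like speech is emulated with more
#' and longer pauses, a slower burst rate, stronger jitter/shimmer and a
#' flatter pitch contour.
#'
#' @param f0_base named numeric, fundamental frequency in Hz by sex
#'   (`female`, `male`).
#' @param f0_sd Hz, slow random variation of F0 across bursts.
#' @param jitter fraction, cycle-to-cycle period perturbation.
#' @param shimmer fraction, cycle-to-cycle amplitude perturbation.
#' @param speech_rate syllable-like voiced bursts per second.
#' @param pause_fraction fraction of the clip spent in silent pauses,
#'   in `[0, 1)`.
#' @param formants data frame with columns `freq` and `bw` (Hz): resonator
#'   center frequencies and bandwidths of the vocal-tract filter.
#' @param duration clip duration in seconds.
#' @param sample_rate sampling rate in Hz.
#' @return an object of class `audio_class_params`.
#' @export
audio_class_params <- function(f0_base = c(female = 210, male = 120),
                               f0_sd = 12,
                               jitter = 0.006,
                               shimmer = 0.04,
                               speech_rate = 2.8,
                               pause_fraction = 0.15,
                               formants = data.frame(
                                 freq = c(500, 1500, 2500),
                                 bw = c(80, 120, 160)),
                               duration = 10,
                               sample_rate = 48000) {
  stopifnot(all(c("female", "male") %in% names(f0_base)))
  if (pause_fraction < 0 || pause_fraction >= 1) {
    stop_domain("pause_fraction must be in [0, 1)")
  }
  if (sample_rate <= 0) stop_domain("sample_rate must be positive")
  if (any(formants$freq >= sample_rate / 2)) {
    stop_domain("formant frequencies must be below the Nyquist frequency")
  }
  structure(list(f0_base = f0_base, f0_sd = f0_sd, jitter = jitter,
                 shimmer = shimmer, speech_rate = speech_rate,
                 pause_fraction = pause_fraction, formants = formants,
                 duration = duration, sample_rate = sample_rate),
            class = "audio_class_params")
}

#' Default severity-5 synthesis endpoint
#'
#' Slower, more halting, rougher voice: lower burst rate, more pausing,
#' stronger jitter/shimmer, flatter pitch than [audio_class_params()].
#'
#' @param sample_rate,duration as in [audio_class_params()].
#' @return an `audio_class_params` object.
#' @export
severe_audio_params <- function(sample_rate = 48000, duration = 10) {
  audio_class_params(f0_sd = 4, jitter = 0.030, shimmer = 0.14,
                     speech_rate = 1.6, pause_fraction = 0.45,
                     duration = duration, sample_rate = sample_rate)
}

# Interpolate synthesis parameters at severity in [0, 1].
interpolate_audio_params <- function(baseline, severe, severity) {
  stopifnot(severity >= 0, severity <= 1)
  lerp <- function(a, b) a + severity * (b - a)
  p <- baseline
  for (f in c("f0_sd", "jitter", "shimmer", "speech_rate", "pause_fraction")) {
    p[[f]] <- lerp(baseline[[f]], severe[[f]])
  }
  p$f0_base <- lerp(baseline$f0_base, severe$f0_base)
  p$formants$freq <- lerp(baseline$formants$freq, severe$formants$freq)
  p$formants$bw <- lerp(baseline$formants$bw, severe$formants$bw)
  p
}

#' Specification of a synthetic frailty cohort
#'
#' Defaults emulate the demographic structure of a 127-participant clinical
#' cohort of adults aged 50 and over: roughly half the cohort is
#' prefrail-or-frail (the positive class), the positive class is about 8.5
#' years older on average, and has a higher proportion of women.
#'
#' @param n cohort size (at least 2).
#' @param positive_prevalence fraction of prefrail-or-frail participants,
#'   in (0, 1).
#' @param prefrail_fraction_within_positive fraction of the positive class
#'   that is prefrail (score 1-2) rather than frail (score 3-5).
#' @param age_params list with elements `robust` and `positive`, each
#'   `c(mean, sd)` in years; ages are drawn from normals truncated to
#'   `[50, 95]`.
#' @param female_fraction named numeric: probability of female sex per class.
#' @param audio_baseline,audio_severe `audio_class_params` endpoints for
#'   severity 0 and severity 5 speech.
#' @param seed integer master seed for the cohort draw.
#' @return an object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n = 40, seed = 1)
#' cohort <- generate_cohort(spec)
#' table(cohort$category)
#' @export
cohort_spec <- function(n = 127,
                        positive_prevalence = 65 / 127,
                        prefrail_fraction_within_positive = 0.7,
                        age_params = list(robust = c(mean = 64.9, sd = 9.26),
                                          positive = c(mean = 73.4, sd = 10.84)),
                        female_fraction = c(robust = 0.274, positive = 0.40),
                        audio_baseline = audio_class_params(),
                        audio_severe = severe_audio_params(),
                        seed = 1L) {
  if (n < 2) stop_domain("cohort size n must be at least 2")
  if (positive_prevalence <= 0 || positive_prevalence >= 1) {
    stop_domain("positive_prevalence must be in (0, 1)")
  }
  if (any(vapply(age_params, function(p) p[["sd"]], numeric(1)) <= 0)) {
    stop_domain("age SDs must be positive")
  }
  structure(list(n = as.integer(n),
                 positive_prevalence = positive_prevalence,
                 prefrail_fraction_within_positive =
                   prefrail_fraction_within_positive,
                 age_params = age_params,
                 female_fraction = female_fraction,
                 audio_baseline = audio_baseline,
                 audio_severe = audio_severe,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Truncated-normal draw by rejection; bounds are wide relative to the SDs
# used here so rejection is cheap. The underlying location is adjusted so
# the truncated distribution's mean equals the requested mean (truncation
# would otherwise bias the realized class means).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  mu <- mean
  for (i in 1:25) {
    a <- (lower - mu) / sd
    b <- (upper - mu) / sd
    bias <- sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
    mu <- mu - (mu + bias - mean)
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mu, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort (demographics and K-FRAIL labels)
#'
#' Draws participants with class-conditional age and sex distributions and
#' K-FRAIL item patterns consistent with the drawn category. Audio is not
#' synthesized here; see [synthesize_speech()] and [write_cohort()].
#'
#' @param spec a [cohort_spec()].
#' @return a `frailty_cohort` data frame with one row per participant:
#'   `participant_id`, `age`, `sex`, the five K-FRAIL items, `kfrail_score`,
#'   `category`, `label` and `wav_path` (`NA` until written).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_pos <- round(spec$n * spec$positive_prevalence)
  if (n_pos == 0 || n_pos == spec$n) {
    stop_domain("degenerate cohort: both classes must be non-empty ",
                "(round(n * prevalence) = ", n_pos, " of ", spec$n, ")")
  }
  n_rob <- spec$n - n_pos
  with_seed(spec$seed, {
    # categories: robust score 0; positives split prefrail / frail
    n_pre <- round(n_pos * spec$prefrail_fraction_within_positive)
    n_fra <- n_pos - n_pre
    score <- c(rep(0L, n_rob),
               sample(1:2, n_pre, replace = TRUE),
               sample(3:5, n_fra, replace = TRUE, prob = c(0.6, 0.3, 0.1)))
    label <- as.integer(score >= 1)
    age <- numeric(spec$n)
    age[label == 0] <- round(rtruncnorm(n_rob,
                                        spec$age_params$robust[["mean"]],
                                        spec$age_params$robust[["sd"]],
                                        50, 95))
    age[label == 1] <- round(rtruncnorm(n_pos,
                                        spec$age_params$positive[["mean"]],
                                        spec$age_params$positive[["sd"]],
                                        50, 95))
    sex <- character(spec$n)
    sex[label == 0] <- ifelse(
      stats::runif(n_rob) < spec$female_fraction[["robust"]],
      "female", "male")
    sex[label == 1] <- ifelse(
      stats::runif(n_pos) < spec$female_fraction[["positive"]],
      "female", "male")
    # item patterns: pick `score` of the 5 items uniformly at random
    items <- t(vapply(score, function(s) {
      v <- integer(5)
      if (s > 0) v[sample.int(5, s)] <- 1L
      v
    }, integer(5)))
    colnames(items) <- kfrail_item_names()
    ord <- sample.int(spec$n)
    cohort <- data.frame(
      participant_id = sprintf("P%04d", seq_len(spec$n)),
      age = as.integer(age[ord]),
      sex = sex[ord],
      items[ord, , drop = FALSE],
      kfrail_score = score[ord],
      stringsAsFactors = FALSE)
  })
  cohort$category <- as.character(kfrail_categorize(cohort$kfrail_score))
  cohort$label <- binary_label(cohort$category)
  cohort$wav_path <- NA_character_
  attr(cohort, "spec") <- spec
  class(cohort) <- c("frailty_cohort", "data.frame")
  cohort
}

#' @exportS3Method base::print
print.frailty_cohort <- function(x, ...) {
  cat(sprintf("Synthetic frailty cohort: %d participants (%d robust, %d prefrail/frail)\n",
              nrow(x), sum(x$label == 0), sum(x$label == 1)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
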