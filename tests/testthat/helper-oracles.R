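# Independent oracles and small fixtures shared across tests.

# Direct (loop-based) implementation of the windowed-regression delta:
# slope of a least-squares line over a centered window, edges replicated.
oracle_delta <- function(mat, width) {
  h <- (width - 1) / 2
  denom <- 2 * sum((1:h)^2)
  n <- nrow(mat)
  out <- matrix(0, n, ncol(mat))
  for (t in seq_len(n)) {
    for (k in 1:h) {
      hi <- min(n, t + k)
      lo <- max(1, t - k)
      out[t, ] <- out[t, ] + k * (mat[hi, ] - mat[lo, ])
    }
  }
  out / denom
}

# Brute-force all-pairs Mann-Whitney concordance (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Energy-based pause fraction: share of 25 ms frames whose RMS falls below
# 10% of the loudest frame's RMS.
oracle_pause_fraction <- function(samples, sample_rate) {
  nwin <- round(0.025 * sample_rate)
  n_frames <- floor(length(samples) / nwin)
  rms <- vapply(seq_len(n_frames), function(i) {
    seg <- samples[((i - 1) * nwin + 1):(i * nwin)]
    sqrt(mean(seg^2))
  }, numeric(1))
  mean(rms < 0.1 * max(rms))
}

# Tiny encoder for fast structural tests.
tiny_speech_config <- function(chunk_frames = 50) {
  speech_embedding_config(input_dim = 60, model_dim = 16, n_heads = 2,
                          ffn_dim = 32, n_layers = 2,
                          chunk_frames = chunk_frames)
}

# Feature-like random matrices with smooth temporal structure (AR(1) rows)
# so masked-frame reconstruction has signal to learn.
make_feature_matrices <- function(n_clips, n_frames = 40, d = 60, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n_clips), function(i) {
      x <- matrix(rnorm(n_frames * d), n_frames, d)
      for (t in 2:n_frames) x[t, ] <- 0.9 * x[t - 1, ] + 0.1 * x[t, ]
      x
    })
  })
}

test_audio_params <- function(duration = 1.5, sample_rate = 16000) {
  list(baseline = audio_class_params(duration = duration,
                                     sample_rate = sample_rate),
       severe = severe_audio_params(sample_rate = sample_rate,
                                    duration = duration))
}

quick_ft_config <- function(seed = 1L) {
  finetune_config(patience = 8, max_epochs = 200, seed = seed)
}
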