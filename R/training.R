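#' Self-supervised pretraining configuration
#'
#' Masked-frame reconstruction: a fraction of input frames is replaced by a
#' learned mask vector and the encoder is trained (with a linear
#' reconstruction head that is discarded afterwards) to reconstruct the
#' original 60-dimensional frames at the masked positions under mean squared
#' error.
#'
#' @param mask_fraction fraction of frames masked per clip, in (0, 1).
#' @param epochs training epochs.
#' @param batch_size clips per optimizer step.
#' @param lr Adam learning rate.
#' @param holdout_fraction fraction of clips held out for the loss trace.
#' @param seed integer seed.
#' @return an object of class `ssl_config`.
#' @export
ssl_config <- function(mask_fraction = 0.15, epochs = 10, batch_size = 16,
                       lr = 1e-3, holdout_fraction = 0.1, seed = 1L) {
  if (mask_fraction <= 0 || mask_fraction >= 1) {
    stop_domain("mask_fraction must be in (0, 1); an empty mask set is degenerate")
  }
  structure(list(mask_fraction = mask_fraction, epochs = epochs,
                 batch_size = batch_size, lr = lr,
                 holdout_fraction = holdout_fraction, seed = as.integer(seed)),
            class = "ssl_config")
}

# Per-feature standardization statistics estimated from a corpus;
# applied before the encoder so all feature columns are commensurate.
feature_norm_stats <- function(feature_list) {
  all <- do.call(rbind, feature_list)
  list(mean = colMeans(all), sd = pmax(apply(all, 2, stats::sd), 1e-6))
}

normalize_features <- function(norm, X) {
  if (is.null(norm)) return(X)
  (X - rep(norm$mean, each = nrow(X))) / rep(norm$sd, each = nrow(X))
}

# Masked-frame reconstruction loss and gradients for one clip.
ssl_clip_grads <- function(enc, ssl_params, Xn, mask_rows) {
  X_in <- Xn
  X_in[mask_rows, ] <- rep(ssl_params$mask_token, each = length(mask_rows))
  fw <- encoder_forward(enc, X_in, keep_cache = TRUE)
  Hm <- fw$H[mask_rows, , drop = FALSE]
  Yhat <- add_bias(Hm %*% ssl_params$head$W, ssl_params$head$b)
  E <- Yhat - Xn[mask_rows, , drop = FALSE]
  loss <- mean(E^2)
  dYhat <- 2 * E / length(E)
  dH <- matrix(0, nrow(Xn), ncol(fw$H))
  dH[mask_rows, ] <- dYhat %*% t(ssl_params$head$W)
  bw <- encoder_backward(enc, fw$cache, dH)
  gmask <- colSums(bw$dX[mask_rows, , drop = FALSE])
  list(loss = loss,
       grads = list(enc = bw$grads,
                    mask_token = gmask,
                    head = list(W = crossprod(Hm, dYhat),
                                b = colSums(dYhat))))
}

ssl_clip_loss <- function(enc, ssl_params, Xn, mask_rows) {
  X_in <- Xn
  X_in[mask_rows, ] <- rep(ssl_params$mask_token, each = length(mask_rows))
  fw <- encoder_forward(enc, X_in)
  Yhat <- add_bias(fw$H[mask_rows, , drop = FALSE] %*% ssl_params$head$W,
                   ssl_params$head$b)
  mean((Yhat - Xn[mask_rows, , drop = FALSE])^2)
}

sample_mask_rows <- function(n_frames, mask_fraction) {
  n_mask <- max(1L, round(mask_fraction * n_frames))
  sort(sample.int(n_frames, n_mask))
}

#' Pretrain the speech encoder by masked-frame reconstruction
#'
#' Trains all encoder parameters (plus the mask vector and a linear
#' reconstruction head, both discarded downstream) on an unlabeled corpus of
#' acoustic feature matrices. Per-feature standardization statistics are
#' estimated from the corpus and stored with the encoder. Deterministic
#' given the config seed.
#'
#' @param corpus_features non-empty list of `T x input_dim` feature matrices
#'   (see [extract_mfcc_features()]).
#' @param speech_config a [speech_embedding_config()].
#' @param config an [ssl_config()].
#' @return list with `encoder` (trained, with `$norm` set), `trace`
#'   (data frame: epoch, train_loss, holdout_loss) and `ssl`
#'   (mask token and reconstruction head, kept for inspection only).
#' @export
pretrain_speech_embedding <- function(corpus_features,
                                      speech_config = speech_embedding_config(),
                                      config = ssl_config()) {
  if (length(corpus_features) == 0) stop_domain("pretraining corpus is empty")
  enc <- init_speech_encoder(speech_config, seed = derive_seed(config$seed, 11L))
  enc$norm <- feature_norm_stats(corpus_features)
  d <- speech_config$model_dim
  with_seed(derive_seed(config$seed, 12L), {
    ssl_params <- list(mask_token = stats::rnorm(speech_config$input_dim, 0, 0.1),
                       head = init_linear(d, speech_config$input_dim))
    n <- length(corpus_features)
    n_hold <- max(1L, min(n - 1L, round(config$holdout_fraction * n)))
    hold_idx <- if (n > 1) sample.int(n, n_hold) else integer(0)
    train_idx <- setdiff(seq_len(n), hold_idx)
    norm_clip <- function(X) {
      X <- normalize_features(enc$norm, X)
      cf <- speech_config$chunk_frames
      if (nrow(X) > cf) {
        s <- sample.int(nrow(X) - cf + 1L, 1L)
        X <- X[s:(s + cf - 1L), , drop = FALSE]
      }
      X
    }
    clips <- lapply(corpus_features, norm_clip)
    # fixed holdout masks so the loss trace is comparable across epochs
    hold_masks <- lapply(hold_idx, function(i) {
      sample_mask_rows(nrow(clips[[i]]), config$mask_fraction)
    })
    holdout_loss <- function() {
      if (!length(hold_idx)) return(NA_real_)
      mean(vapply(seq_along(hold_idx), function(j) {
        ssl_clip_loss(enc, ssl_params, clips[[hold_idx[j]]], hold_masks[[j]])
      }, numeric(1)))
    }
    all_params <- list(enc = enc$params, mask_token = ssl_params$mask_token,
                       head = ssl_params$head)
    opt <- adam_init(all_params)
    trace <- data.frame(epoch = 0L, train_loss = NA_real_,
                        holdout_loss = holdout_loss())
    for (epoch in seq_len(config$epochs)) {
      order <- sample(train_idx)
      batches <- split(order, ceiling(seq_along(order) / config$batch_size))
      epoch_losses <- numeric(0)
      for (batch in batches) {
        acc <- NULL
        bl <- numeric(length(batch))
        for (j in seq_along(batch)) {
          Xn <- clips[[batch[j]]]
          res <- ssl_clip_grads(enc, ssl_params, Xn,
                                sample_mask_rows(nrow(Xn), config$mask_fraction))
          bl[j] <- res$loss
          acc <- if (is.null(acc)) res$grads else {
            tree_map(`+`, acc, res$grads)
          }
        }
        acc <- tree_map(function(g) g / length(batch), acc)
        step <- adam_step(all_params, acc, opt, lr = config$lr)
        all_params <- step$params
        opt <- step$state
        enc$params <- all_params$enc
        ssl_params$mask_token <- all_params$mask_token
        ssl_params$head <- all_params$head
        epoch_losses <- c(epoch_losses, mean(bl))
      }
      trace <- rbind(trace, data.frame(epoch = epoch,
                                       train_loss = mean(epoch_losses),
                                       holdout_loss = holdout_loss()))
    }
    list(encoder = enc, trace = trace, ssl = ssl_params)
  })
}

#' Undersample the majority class to a balanced training set
#'
#' @param indices candidate indices.
#' @param labels 0/1 labels aligned with `indices`.
#' @param seed integer seed for the undersampling draw.
#' @return sorted subset of `indices` with equal class counts.
#' @export
balance_training_set <- function(indices, labels, seed = 1L) {
  stopifnot(length(indices) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_domain("both classes must be present to balance")
  m <- min(n0, n1)
  with_seed(seed, {
    keep0 <- sample(indices[labels == 0], m)
    keep1 <- sample(indices[labels == 1], m)
  })
  sort(c(keep0, keep1))
}

# Stratified train/validation split of positions 1..n.
split_stratified <- function(labels, val_fraction, seed) {
  with_seed(seed, {
    val <- unlist(lapply(unique(labels), function(l) {
      pos <- which(labels == l)
      n_val <- max(1L, round(val_fraction * length(pos)))
      sample(pos, n_val)
    }))
  })
  list(train = setdiff(seq_along(labels), val), val = sort(val))
}

#' Fine-tuning configuration
#'
#' @param patience epochs without inner-validation improvement before
#'   stopping; the best-epoch weights are restored.
#' @param max_epochs upper bound on epochs.
#' @param inner_val_fraction fraction of the (balanced) training set held
#'   out, stratified by label, to monitor early stopping.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param balance undersample the majority class before training.
#' @param seed integer seed.
#' @return an object of class `finetune_config`.
#' @export
finetune_config <- function(patience = 10, max_epochs = 200,
                            inner_val_fraction = 0.2, lr = 1e-3,
                            batch_size = 16, balance = TRUE, seed = 1L) {
  stopifnot(patience >= 1)
  structure(list(patience = patience, max_epochs = max_epochs,
                 inner_val_fraction = inner_val_fraction, lr = lr,
                 batch_size = batch_size, balance = balance,
                 seed = as.integer(seed)),
            class = "finetune_config")
}

# Trainable-head parameters of an assembly (classifier + demographic tables).
head_params <- function(assembly) {
  p <- list(clf = assembly$classifier)
  if (!is.null(assembly$demo)) p$demo <- assembly$demo
  p
}

set_head_params <- function(assembly, p) {
  assembly$classifier <- p$clf
  if (!is.null(p$demo)) assembly$demo <- p$demo
  assembly
}

# Forward/backward of the trainable head on a batch given fixed speech
# embeddings; demographic-table gradients are accumulated by lookup row.
head_batch <- function(assembly, speech_emb, age_bin, sex_idx, labels,
                       want_grads = TRUE) {
  parts <- list()
  if (assembly$kind != "DemoAI") parts <- c(parts, list(speech_emb))
  a_dim <- 0L
  if (assembly$kind != "SpeechAI") {
    a_dim <- ncol(assembly$demo$age_table)
    parts <- c(parts, list(cbind(
      assembly$demo$age_table[age_bin, , drop = FALSE],
      assembly$demo$sex_table[sex_idx, , drop = FALSE])))
  }
  X <- do.call(cbind, parts)
  fw <- classifier_forward(assembly$classifier, X)
  loss <- cross_entropy(fw$P, labels)
  if (!want_grads) return(list(loss = loss, P = fw$P))
  bw <- classifier_backward(assembly$classifier, fw$cache, fw$P, labels)
  grads <- list(clf = bw$grads)
  if (assembly$kind != "SpeechAI") {
    sp_dim <- if (assembly$kind == "DemoAI") 0L else ncol(speech_emb)
    dA <- bw$dX[, sp_dim + seq_len(a_dim), drop = FALSE]
    dS <- bw$dX[, (sp_dim + a_dim + 1):ncol(bw$dX), drop = FALSE]
    gA <- assembly$demo$age_table * 0
    gS <- assembly$demo$sex_table * 0
    ra <- rowsum(dA, age_bin)
    gA[as.integer(rownames(ra)), ] <- ra
    rs <- rowsum(dS, sex_idx)
    gS[as.integer(rownames(rs)), ] <- rs
    grads$demo <- list(age_table = gA, sex_table = gS)
  }
  list(loss = loss, P = fw$P, grads = grads)
}

#' Fine-tune an assembly with a frozen speech encoder
#'
#' Only the classifier and (when present) the demographic embedding tables
#' are updated; the speech encoder's weights are bit-identical before and
#' after. Speech embeddings are computed once up front through the frozen
#' encoder, which is numerically equivalent to running the full forward pass
#' at every step. The training set is balanced by majority-class
#' undersampling, then split 80/20 (stratified) into an inner training and
#' early-stopping monitor set.
#'
#' @param assembly a [build_assembly()] model (encoder already loaded with
#'   pretrained weights where applicable).
#' @param features named list of acoustic feature matrices (speech-bearing
#'   kinds; ignored for DemoAI), or a precomputed embedding matrix via
#'   `speech_emb`.
#' @param age,sex,labels per-participant demographics and 0/1 labels.
#' @param config a [finetune_config()].
#' @param speech_emb optional precomputed `n x model_dim` embedding matrix.
#' @return list with the trained `assembly`, the training `log` (data frame:
#'   epoch, train_loss, val_loss, stopped), `best_epoch` and `n_train`.
#' @export
finetune <- function(assembly, features = NULL, age = NULL, sex = NULL,
                     labels, config = finetune_config(), speech_emb = NULL) {
  if (length(unique(labels)) < 2) {
    stop_domain("training data must contain both classes")
  }
  if (assembly$kind != "DemoAI" && is.null(speech_emb)) {
    if (is.null(features)) stop_domain(assembly$kind, " requires speech input")
    speech_emb <- embed_speech_batch(assembly$encoder, features)
  }
  n <- length(labels)
  keep <- if (config$balance) {
    balance_training_set(seq_len(n), labels, derive_seed(config$seed, 21L))
  } else seq_len(n)
  lab <- labels[keep]
  if (length(unique(lab)) < 2) {
    stop_domain("training fold has a single class after balancing")
  }
  emb <- if (!is.null(speech_emb)) speech_emb[keep, , drop = FALSE]
  a_bin <- if (assembly$kind != "SpeechAI") age_decade_bin(age[keep])
  s_idx <- if (assembly$kind != "SpeechAI") sex_index(sex[keep])
  sp <- split_stratified(lab, config$inner_val_fraction,
                         derive_seed(config$seed, 22L))
  frozen_before <- if (!is.null(assembly$encoder)) assembly$encoder$params

  sel <- function(x, i) if (is.null(x)) NULL else {
    if (is.matrix(x)) x[i, , drop = FALSE] else x[i]
  }
  params <- head_params(assembly)
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), stopped = logical())
  with_seed(derive_seed(config$seed, 23L), {
    for (epoch in seq_len(config$max_epochs)) {
      order <- sample(sp$train)
      batches <- split(order, ceiling(seq_along(order) / config$batch_size))
      tl <- numeric(0)
      for (batch in batches) {
        res <- head_batch(assembly, sel(emb, batch), sel(a_bin, batch),
                          sel(s_idx, batch), lab[batch])
        step <- adam_step(params, res$grads, opt, lr = config$lr)
        params <- step$params
        opt <- step$state
        assembly <- set_head_params(assembly, params)
        tl <- c(tl, res$loss)
      }
      vl <- head_batch(assembly, sel(emb, sp$val), sel(a_bin, sp$val),
                       sel(s_idx, sp$val), lab[sp$val],
                       want_grads = FALSE)$loss
      improved <- vl < best$loss - 1e-8
      if (improved) {
        best <- list(loss = vl, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
      stopped <- wait >= config$patience
      log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(tl),
                                   val_loss = vl, stopped = stopped))
      if (stopped) break
    }
  })
  assembly <- set_head_params(assembly, best$params)
  if (!is.null(assembly$encoder)) {
    stopifnot(tree_max_abs_diff(frozen_before, assembly$encoder$params) == 0)
  }
  list(assembly = assembly, log = log, best_epoch = best$epoch,
       n_train = length(keep))
}

#' Synthesize an unlabeled pretraining corpus
#'
#' Stands in for a large public speech corpus: clips are synthesized at a
#' severity-neutral midpoint between the baseline and severe parameter
#' endpoints, with random sex per clip, so the corpus carries no class
#' structure.
#'
#' @param n_clips number of clips.
#' @param baseline,severe [audio_class_params()] endpoints.
#' @param seed integer seed.
#' @return list of [recording()] objects.
#' @export
make_pretraining_corpus <- function(n_clips = 200,
                                    baseline = audio_class_params(),
                                    severe = severe_audio_params(
                                      sample_rate = baseline$sample_rate,
                                      duration = baseline$duration),
                                    seed = 1L) {
  neutral <- interpolate_audio_params(baseline, severe, 0.5)
  lapply(seq_len(n_clips), function(i) {
    sex <- if (derive_seed(seed, 31L, i) %% 2 == 0) "female" else "male"
    synthesize_speech(list(kfrail_score = 0L, sex = sex,
                           participant_id = sprintf("U%04d", i)),
                      baseline = neutral, severe = NULL,
                      seed = derive_seed(seed, 32L, i))
  })
}
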