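test_that("majority-class undersampling balances the training set", {
  labels <- c(rep(1, 40), rep(0, 60))
  kept <- balance_training_set(seq_along(labels), labels, seed = 1)
  expect_equal(sum(labels[kept] == 1), 40)
  expect_equal(sum(labels[kept] == 0), 40)
  # already balanced -> unchanged set
  lab2 <- rep(c(0, 1), 25)
  expect_setequal(balance_training_set(1:50, lab2, seed = 1), 1:50)
  # seeded determinism
  expect_identical(balance_training_set(seq_along(labels), labels, seed = 3),
                   balance_training_set(seq_along(labels), labels, seed = 3))
  expect_error(balance_training_set(1:10, rep(1, 10)), "both classes")
})

test_that("an empty mask fraction is rejected as degenerate", {
  expect_error(ssl_config(mask_fraction = 0), "degenerate")
  expect_error(ssl_config(mask_fraction = 1), "degenerate")
  expect_error(pretrain_speech_embedding(list(), tiny_speech_config()),
               "empty")
})

test_that("masked-frame pretraining reduces held-out reconstruction loss", {
  corpus <- make_feature_matrices(14, n_frames = 30, seed = 21)
  fit <- pretrain_speech_embedding(
    corpus, tiny_speech_config(),
    ssl_config(epochs = 6, batch_size = 4, holdout_fraction = 0.15, seed = 2))
  trace <- fit$trace
  expect_equal(trace$epoch, 0:6)
  expect_lt(trace$holdout_loss[nrow(trace)], trace$holdout_loss[1])
  expect_false(is.null(fit$encoder$norm))
})

test_that("pretraining is seed-deterministic", {
  corpus <- make_feature_matrices(6, n_frames = 20, seed = 22)
  cfg <- ssl_config(epochs = 2, batch_size = 3, seed = 5)
  a <- pretrain_speech_embedding(corpus, tiny_speech_config(), cfg)
  b <- pretrain_speech_embedding(corpus, tiny_speech_config(), cfg)
  expect_equal(frailvoice:::tree_max_abs_diff(a$encoder$params,
                                              b$encoder$params), 0)
  expect_identical(a$trace, b$trace)
})

make_separable_data <- function(n = 80, d = 16, gap = 2.5, seed = 31) {
  withr::with_seed(seed, {
    labels <- rep(c(0L, 1L), length.out = n)
    emb <- matrix(rnorm(n * d), n, d)
    emb[, 1] <- emb[, 1] + gap * labels
    list(emb = emb, labels = labels,
         age = sample(50:95, n, replace = TRUE),
         sex = sample(c("female", "male"), n, replace = TRUE))
  })
}

test_that("fine-tuning freezes the speech encoder bit-for-bit", {
  dat <- make_separable_data()
  m <- build_assembly("SpeechAI", tiny_speech_config(), hidden_dim = 8,
                      seed = 2)
  before <- m$encoder$params
  fit <- finetune(m, speech_emb = dat$emb, labels = dat$labels,
                  config = quick_ft_config(seed = 4))
  expect_equal(frailvoice:::tree_max_abs_diff(before,
                                              fit$assembly$encoder$params), 0)
  # classifier did move
  expect_gt(frailvoice:::tree_max_abs_diff(m$classifier,
                                           fit$assembly$classifier), 0)
})

test_that("fine-tuning learns a strongly separated problem", {
  dat <- make_separable_data(gap = 4)
  m <- build_assembly("SpeechAI", tiny_speech_config(), hidden_dim = 8,
                      seed = 2)
  fit <- finetune(m, speech_emb = dat$emb, labels = dat$labels,
                  config = quick_ft_config(seed = 4))
  p <- predict(fit$assembly, speech_emb = dat$emb)
  expect_gt(mean((p >= 0.5) == (dat$labels == 1)), 0.9)
})

test_that("early stopping respects patience and restores the best epoch", {
  dat <- make_separable_data(n = 40, gap = 1)
  m <- build_assembly("DemoSpeechAI", tiny_speech_config(), hidden_dim = 8,
                      seed = 3)
  cfg <- finetune_config(patience = 3, max_epochs = 25, seed = 9)
  fit <- finetune(m, speech_emb = dat$emb, age = dat$age, sex = dat$sex,
                  labels = dat$labels, config = cfg)
  expect_lte(nrow(fit$log), 25)
  expect_equal(fit$best_epoch, fit$log$epoch[which.min(fit$log$val_loss)])
  if (any(fit$log$stopped)) {
    expect_equal(sum(fit$log$stopped), 1)
    expect_equal(fit$log$epoch[fit$log$stopped], nrow(fit$log))
  }
})

test_that("fine-tuning is seed-deterministic and rejects single-class data", {
  dat <- make_separable_data(n = 30)
  m <- build_assembly("SpeechAI", tiny_speech_config(), hidden_dim = 8,
                      seed = 2)
  cfg <- quick_ft_config(seed = 12)
  a <- finetune(m, speech_emb = dat$emb, labels = dat$labels, config = cfg)
  b <- finetune(m, speech_emb = dat$emb, labels = dat$labels, config = cfg)
  expect_equal(frailvoice:::tree_max_abs_diff(
    frailvoice:::head_params(a$assembly),
    frailvoice:::head_params(b$assembly)), 0)
  expect_error(finetune(m, speech_emb = dat$emb, labels = rep(1, 30),
                        config = cfg), "both classes")
})

test_that("precomputed embeddings are equivalent to end-to-end forwards", {
  feats <- make_feature_matrices(6, n_frames = 25, seed = 41)
  names(feats) <- sprintf("P%d", 1:6)
  m <- build_assembly("SpeechAI", tiny_speech_config(), hidden_dim = 8,
                      seed = 5)
  emb <- frailvoice:::embed_speech_batch(m$encoder, feats)
  expect_equal(predict(m, features = feats), predict(m, speech_emb = emb),
               tolerance = 1e-9)
})

test_that("the pretraining corpus is seeded and class-neutral", {
  ap <- test_audio_params(duration = 0.5, sample_rate = 8000)
  a <- make_pretraining_corpus(3, ap$baseline, ap$severe, seed = 7)
  b <- make_pretraining_corpus(3, ap$baseline, ap$severe, seed = 7)
  expect_identical(a[[1]]$samples, b[[1]]$samples)
  expect_length(a, 3)
})
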