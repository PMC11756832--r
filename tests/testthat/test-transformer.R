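test_that("analytic encoder gradients match finite differences", {
  cfg <- speech_embedding_config(input_dim = 6, model_dim = 8, n_heads = 2,
                                 ffn_dim = 12, n_layers = 2,
                                 chunk_frames = 100)
  enc <- init_speech_encoder(cfg, seed = 5)
  withr::with_seed(42, {
    X <- matrix(rnorm(7 * 6), 7, 6)
    ssl <- list(mask_token = rnorm(6, 0, 0.1),
                head = frailvoice:::init_linear(8, 6))
  })
  mask <- c(2L, 5L)
  res <- frailvoice:::ssl_clip_grads(enc, ssl, X, mask)
  loss_at <- function(e, s) frailvoice:::ssl_clip_loss(e, s, X, mask)
  fd <- function(mutate) {
    eps <- 1e-5
    up <- mutate(enc, ssl, eps)
    dn <- mutate(enc, ssl, -eps)
    (loss_at(up$enc, up$ssl) - loss_at(dn$enc, dn$ssl)) / (2 * eps)
  }
  checks <- list(
    list(res$grads$enc$input$W[1, 1], function(e, s, d) {
      e$params$input$W[1, 1] <- e$params$input$W[1, 1] + d
      list(enc = e, ssl = s)
    }),
    list(res$grads$enc$layers[[1]]$Wq$W[3, 2], function(e, s, d) {
      e$params$layers[[1]]$Wq$W[3, 2] <- e$params$layers[[1]]$Wq$W[3, 2] + d
      list(enc = e, ssl = s)
    }),
    list(res$grads$enc$layers[[1]]$ln1$g[4], function(e, s, d) {
      e$params$layers[[1]]$ln1$g[4] <- e$params$layers[[1]]$ln1$g[4] + d
      list(enc = e, ssl = s)
    }),
    list(res$grads$enc$layers[[2]]$ffn2$W[5, 3], function(e, s, d) {
      e$params$layers[[2]]$ffn2$W[5, 3] <- e$params$layers[[2]]$ffn2$W[5, 3] + d
      list(enc = e, ssl = s)
    }),
    list(res$grads$enc$layers[[2]]$Wo$b[2], function(e, s, d) {
      e$params$layers[[2]]$Wo$b[2] <- e$params$layers[[2]]$Wo$b[2] + d
      list(enc = e, ssl = s)
    }),
    list(res$grads$mask_token[3], function(e, s, d) {
      s$mask_token[3] <- s$mask_token[3] + d
      list(enc = e, ssl = s)
    }),
    list(res$grads$head$W[2, 4], function(e, s, d) {
      s$head$W[2, 4] <- s$head$W[2, 4] + d
      list(enc = e, ssl = s)
    }))
  for (chk in checks) {
    numeric_grad <- fd(chk[[2]])
    expect_lt(abs(chk[[1]] - numeric_grad) / max(1e-6, abs(numeric_grad)),
              1e-4)
  }
})

test_that("speech embeddings have the configured length", {
  cfg <- tiny_speech_config()
  enc <- init_speech_encoder(cfg, seed = 2)
  f <- make_feature_matrices(1, n_frames = 30)[[1]]
  emb <- embed_speech(enc, f)
  expect_length(emb, 16)
  expect_true(all(is.finite(emb)))
})

test_that("chunk pooling averages ceiling(T / chunk_frames) chunks and is order-invariant", {
  cfg <- tiny_speech_config(chunk_frames = 10)
  enc <- init_speech_encoder(cfg, seed = 2)
  X <- make_feature_matrices(1, n_frames = 30)[[1]]
  chunks <- list(X[1:10, ], X[11:20, ], X[21:30, ])
  per_chunk <- vapply(chunks, function(ch) {
    colMeans(frailvoice:::encoder_forward(enc, ch)$H)
  }, numeric(16))
  expect_equal(embed_speech(enc, X), rowMeans(per_chunk), tolerance = 1e-12)
  # permuting the chunk order leaves the pooled embedding unchanged
  X_perm <- rbind(X[21:30, ], X[1:10, ], X[11:20, ])
  expect_equal(embed_speech(enc, X), embed_speech(enc, X_perm),
               tolerance = 1e-6)
  # 25 frames with chunk 10 -> 3 chunks, the last partial
  X25 <- X[1:25, ]
  manual <- rowMeans(cbind(
    colMeans(frailvoice:::encoder_forward(enc, X25[1:10, ])$H),
    colMeans(frailvoice:::encoder_forward(enc, X25[11:20, ])$H),
    colMeans(frailvoice:::encoder_forward(enc, X25[21:25, ])$H)))
  expect_equal(embed_speech(enc, X25), manual, tolerance = 1e-12)
})

test_that("encoder rejects mismatched feature dimensionality", {
  enc <- init_speech_encoder(tiny_speech_config(), seed = 1)
  expect_error(embed_speech(enc, matrix(0, 10, 40)), "expects")
  expect_error(speech_embedding_config(model_dim = 30, n_heads = 4),
               "divisible")
})

test_that("encoder initialization is seed-deterministic", {
  cfg <- tiny_speech_config()
  a <- init_speech_encoder(cfg, seed = 9)
  b <- init_speech_encoder(cfg, seed = 9)
  c <- init_speech_encoder(cfg, seed = 10)
  expect_equal(frailvoice:::tree_max_abs_diff(a$params, b$params), 0)
  expect_gt(frailvoice:::tree_max_abs_diff(a$params, c$params), 0)
})
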