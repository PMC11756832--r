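# Dense neural-network primitives: initialization, softmax classifier head,
# and the Adam optimizer over nested parameter lists ("trees").

# Glorot-uniform initialized dense layer.
init_linear <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  list(W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
       b = numeric(fan_out))
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

relu <- function(x) pmax(x, 0)

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  params <- tree_map(function(p, m, v) p - lr * (m * c1) / (sqrt(v * c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

# --- two-logit softmax classifier with one hidden layer ---------------------

init_classifier <- function(input_dim, hidden_dim) {
  list(h = init_linear(input_dim, hidden_dim),
       out = init_linear(hidden_dim, 2L))
}

classifier_forward <- function(clf, X) {
  U <- X %*% clf$h$W + matrix(clf$h$b, nrow(X), length(clf$h$b), byrow = TRUE)
  Z <- relu(U)
  logits <- Z %*% clf$out$W +
    matrix(clf$out$b, nrow(X), 2L, byrow = TRUE)
  P <- softmax_rows(logits)
  list(P = P, cache = list(X = X, U = U, Z = Z))
}

# Cross-entropy gradient; labels are 0/1 (column 2 is the positive class).
classifier_backward <- function(clf, cache, P, labels) {
  n <- nrow(P)
  Y <- cbind(1 - labels, labels)
  dlogits <- (P - Y) / n
  dZ <- dlogits %*% t(clf$out$W)
  dU <- dZ * (cache$U > 0)
  list(grads = list(h = list(W = t(cache$X) %*% dU, b = colSums(dU)),
                    out = list(W = t(cache$Z) %*% dlogits,
                               b = colSums(dlogits))),
       dX = dU %*% t(clf$h$W))
}

cross_entropy <- function(P, labels) {
  p_true <- ifelse(labels == 1, P[, 2], P[, 1])
  -mean(log(pmax(p_true, 1e-12)))
}
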