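# Internal utilities: seed plumbing, nested parameter-list algebra, hashing.

#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from a single master seed; each stage
#' and repetition derives its own child seed with this function so that
#' stages are reproducible independently of execution order.
#'
#' @param seed master seed (integer).
#' @param ... integer offsets identifying the stage/repetition.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  offs <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (o in offs) {
    h <- (h * 48271 + as.double(o) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% 2147483647), expr)
}

# Map a function elementwise over parallel nested lists of numeric arrays.
# Used for optimizer state and gradient accumulation over parameter trees.
tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- vector("list", length(t1))
    names(out) <- names(t1)
    for (i in seq_along(t1)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

# Sum all elements of |a - b| over a parameter tree; used for freeze checks.
tree_max_abs_diff <- function(a, b) {
  if (is.list(a)) {
    max(vapply(seq_along(a), function(i) tree_max_abs_diff(a[[i]], b[[i]]),
               numeric(1)))
  } else {
    if (length(a) == 0) 0 else max(abs(a - b))
  }
}

# Total number of scalar entries in a parameter tree.
tree_count <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_count, numeric(1))) else length(a)
}

# FNV-1a hash of a character scalar, returned as 8 hex digits. Used to stamp
# artifacts with a configuration fingerprint.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

# Stable fingerprint of an R configuration object (lists/atomics only).
config_hash <- function(x) {
  fnv1a_hash(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                              force = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
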