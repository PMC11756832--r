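#' Demographic embedding configuration
#'
#' Age is categorized into decade bins (50s through 90s, from
#' `floor(age / 10)` clamped to that range) and looked up in a 2-dimensional
#' embedding table; sex is looked up in a 4-dimensional table; the joint
#' demographic vector is their concatenation (6 dimensions).
#'
#' @param age_embed_dim,sex_embed_dim embedding widths.
#' @return an object of class `demographic_embedding_config`.
#' @export
demographic_embedding_config <- function(age_embed_dim = 2L,
                                         sex_embed_dim = 4L) {
  structure(list(age_bins = c("50s", "60s", "70s", "80s", "90s"),
                 sexes = c("female", "male"),
                 age_embed_dim = as.integer(age_embed_dim),
                 sex_embed_dim = as.integer(sex_embed_dim),
                 joint_dim = as.integer(age_embed_dim + sex_embed_dim)),
            class = "demographic_embedding_config")
}

init_demo_embedding <- function(config = demographic_embedding_config(),
                                seed = 1L) {
  with_seed(seed, {
    list(age_table = matrix(stats::rnorm(5 * config$age_embed_dim, 0, 0.5),
                            5, config$age_embed_dim),
         sex_table = matrix(stats::rnorm(2 * config$sex_embed_dim, 0, 0.5),
                            2, config$sex_embed_dim))
  })
}

# Decade bin index 1..5 for ages 50s..90s; younger ages clamp to bin 1
# with a warning, older ages clamp to bin 5.
age_decade_bin <- function(age) {
  if (any(age < 50)) {
    warning("age below 50 clamped to the lowest decade bin", call. = FALSE)
  }
  pmin(pmax(floor(age / 10) - 4L, 1L), 5L)
}

sex_index <- function(sex) {
  sex <- as.character(sex)
  if (!all(sex %in% c("female", "male"))) {
    stop_domain("sex must be 'female' or 'male'")
  }
  ifelse(sex == "female", 1L, 2L)
}

#' Embed demographics into the 6-dimensional joint vector
#'
#' @param age age in years (vectorized).
#' @param sex `"female"` or `"male"` (vectorized).
#' @param demo_params embedding tables from a model assembly (or
#'   [init_demo_embedding()]).
#' @return an `n x 6` matrix (a vector input gives a 1-row matrix).
#' @export
embed_demographics <- function(age, sex, demo_params) {
  cbind(demo_params$age_table[age_decade_bin(age), , drop = FALSE],
        demo_params$sex_table[sex_index(sex), , drop = FALSE])
}

model_kinds <- function() c("SpeechAI", "DemoAI", "DemoSpeechAI")

# Conformance-profile classifier hidden widths, back-solved from the
# published per-model parameter budgets (~25K / ~26K / ~34K classifiers).
conformance_hidden_dim <- function(kind) {
  switch(kind, SpeechAI = 373L, DemoAI = 2889L, DemoSpeechAI = 466L)
}

#' Build a frailty model assembly
#'
#' Constructs one of the three model assemblies: `SpeechAI` (speech
#' embedding + classifier), `DemoAI` (demographic embedding + classifier) or
#' `DemoSpeechAI` (both embeddings concatenated before the classifier). The
#' classifier has exactly one hidden layer and two output logits mapped to
#' class probabilities by the softmax. For speech-bearing assemblies the
#' speech encoder belongs to the frozen set: fine-tuning never updates it.
#'
#' @param kind `"SpeechAI"`, `"DemoAI"` or `"DemoSpeechAI"`.
#' @param speech_config a [speech_embedding_config()] (ignored for DemoAI).
#' @param demo_config a [demographic_embedding_config()] (ignored for
#'   SpeechAI).
#' @param hidden_dim classifier hidden width; `NULL` selects the
#'   conformance default for the kind (373 / 2889 / 466).
#' @param encoder optional pre-initialized (e.g. pretrained)
#'   [init_speech_encoder()]; a fresh one is drawn when omitted.
#' @param seed integer seed for weight initialization.
#' @return an object of class `frailty_model`.
#' @examples
#' m <- build_assembly("DemoAI", seed = 1)
#' predict(m, age = 72, sex = "female")
#' @export
build_assembly <- function(kind = model_kinds(),
                           speech_config = speech_embedding_config(),
                           demo_config = demographic_embedding_config(),
                           hidden_dim = NULL,
                           encoder = NULL,
                           seed = 1L) {
  kind <- match.arg(kind)
  hidden_dim <- hidden_dim %||% conformance_hidden_dim(kind)
  has_speech <- kind != "DemoAI"
  has_demo <- kind != "SpeechAI"
  if (has_speech && is.null(encoder)) {
    encoder <- init_speech_encoder(speech_config, seed = derive_seed(seed, 1L))
  }
  input_dim <- (if (has_speech) encoder$config$model_dim else 0L) +
    (if (has_demo) demo_config$joint_dim else 0L)
  with_seed(derive_seed(seed, 2L), {
    clf <- init_classifier(input_dim, hidden_dim)
  })
  demo <- if (has_demo) init_demo_embedding(demo_config,
                                            seed = derive_seed(seed, 3L))
  structure(list(kind = kind,
                 encoder = if (has_speech) encoder,
                 demo = demo,
                 demo_config = if (has_demo) demo_config,
                 classifier = clf,
                 hidden_dim = hidden_dim,
                 frozen_set = if (has_speech) "encoder" else character(0)),
            class = "frailty_model")
}

#' @exportS3Method base::print
print.frailty_model <- function(x, ...) {
  rep <- count_parameters(x)
  cat(sprintf("%s assembly: %s trainable parameters (%s)\n", x$kind,
              format(rep$total, big.mark = ","),
              paste(sprintf("%s %s", names(rep$components),
                            format(unlist(rep$components), big.mark = ",")),
                    collapse = ", ")))
  invisible(x)
}

# Pre-classifier joint vector(s) for a batch; speech_emb is an n x model_dim
# matrix of precomputed embeddings (or NULL for DemoAI).
joint_input <- function(assembly, speech_emb = NULL, age = NULL, sex = NULL) {
  parts <- list()
  if (assembly$kind != "DemoAI") {
    if (is.null(speech_emb)) stop_domain(assembly$kind, " requires speech input")
    parts <- c(parts, list(speech_emb))
  }
  if (assembly$kind != "SpeechAI") {
    if (is.null(age) || is.null(sex)) {
      stop_domain(assembly$kind, " requires demographic input (age, sex)")
    }
    parts <- c(parts, list(embed_demographics(age, sex, assembly$demo)))
  }
  do.call(cbind, parts)
}

#' Predict the probability of the prefrail/frail class
#'
#' @param object a [build_assembly()] model.
#' @param features an acoustic feature matrix (speech-bearing kinds), or a
#'   precomputed embedding via `speech_emb`.
#' @param age,sex demographics (DemoAI / DemoSpeechAI).
#' @param speech_emb optional precomputed speech embedding matrix
#'   (`n x model_dim`), bypassing the encoder forward pass.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]` for the positive
#'   (prefrail-or-frail) class; the two class probabilities sum to one.
#' @export
predict.frailty_model <- function(object, features = NULL, age = NULL,
                                  sex = NULL, speech_emb = NULL, ...) {
  if (object$kind != "DemoAI" && is.null(speech_emb)) {
    if (is.null(features)) stop_domain(object$kind, " requires speech input")
    if (is.list(features) && !is.matrix(features)) {
      speech_emb <- embed_speech_batch(object$encoder, features)
    } else {
      speech_emb <- matrix(embed_speech(object$encoder, features), nrow = 1)
    }
  }
  X <- joint_input(object, speech_emb, age, sex)
  classifier_forward(object$classifier, X)$P[, 2]
}

#' Count trainable parameters of an assembly
#'
#' Exact integer counts per component, the total, the share of the total
#' held by the speech-embedding (transformer) module, and the fraction that
#' is actually updated during frozen-backbone fine-tuning (classifier plus
#' demographic embedding).
#'
#' @param assembly a [build_assembly()] model.
#' @return an object of class `param_report` with fields `components`
#'   (named integer list), `total`, `embedding_share` (percent) and
#'   `trained_fraction_finetune`.
#' @export
count_parameters <- function(assembly) {
  comp <- list()
  if (!is.null(assembly$encoder)) {
    comp$speech_embedding <- tree_count(assembly$encoder$params)
  }
  if (!is.null(assembly$demo)) {
    comp$demographic_embedding <- tree_count(assembly$demo)
  }
  comp$classifier <- tree_count(assembly$classifier)
  total <- sum(unlist(comp))
  trained <- total - (comp$speech_embedding %||% 0)
  structure(list(kind = assembly$kind,
                 components = comp,
                 total = total,
                 embedding_share =
                   round(100 * (comp$speech_embedding %||% 0) / total),
                 trained_fraction_finetune = trained / total),
            class = "param_report")
}

#' @exportS3Method base::print
print.param_report <- function(x, ...) {
  cat(sprintf("%s parameter report: total %s\n", x$kind,
              format(x$total, big.mark = ",")))
  for (nm in names(x$components)) {
    cat(sprintf("  %-24s %s\n", nm,
                format(x$components[[nm]], big.mark = ",")))
  }
  cat(sprintf("  speech-embedding share:  %d%%\n", x$embedding_share))
  cat(sprintf("  fine-tuned fraction:     %.3f\n", x$trained_fraction_finetune))
  invisible(x)
}
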