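#' Balanced (stratified) k-fold split
#'
#' Shuffles each class independently (seeded) and deals members round-robin
#' across folds, continuing the dealing pointer across classes so that fold
#' sizes differ by at most one and per-fold class counts are within one of
#' perfect stratification.
#'
#' @param labels 0/1 label vector.
#' @param k fold count.
#' @param seed integer seed.
#' @return an object of class `fold_split` with `k`, `assignments`
#'   (fold index per observation) and `counts` (k x 2 class-count matrix).
#' @export
make_balanced_folds <- function(labels, k = 5, seed = 1L) {
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab < k)) {
    stop_domain("each class needs at least k = ", k, " members ",
                "(have ", tab[1], " / ", tab[2], ")")
  }
  assignments <- integer(length(labels))
  with_seed(seed, {
    pointer <- 0L
    for (cls in c(0, 1)) {
      idx <- sample(which(labels == cls))
      assignments[idx] <- ((pointer + seq_along(idx) - 1L) %% k) + 1L
      pointer <- (pointer + length(idx)) %% k
    }
  })
  counts <- t(vapply(seq_len(k), function(f) {
    c(robust = sum(labels == 0 & assignments == f),
      positive = sum(labels == 1 & assignments == f))
  }, numeric(2)))
  structure(list(k = as.integer(k), assignments = assignments,
                 counts = counts),
            class = "fold_split")
}

#' @exportS3Method base::print
print.fold_split <- function(x, ...) {
  cat(sprintf("Stratified %d-fold split of %d observations\n", x$k,
              length(x$assignments)))
  print(x$counts)
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the probability
#' that a randomly chosen positive is scored above a randomly chosen
#' negative, with ties counted one half. Implemented with midranks, which is
#' exactly the all-pairs count.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
compute_roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_domain("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at a decision threshold
#'
#' Predictions are positive iff `score >= threshold`. Accuracy is reported
#' in percent; sensitivity (recall on the prefrail/frail class) and
#' specificity (recall on the robust class) as fractions.
#'
#' @param scores numeric scores (probability of the positive class).
#' @param labels 0/1 labels.
#' @param threshold decision threshold, default 0.5.
#' @return an object of class `metric_set`: accuracy, auc, sensitivity,
#'   specificity and the confusion counts tp, fp, tn, fn.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  structure(list(accuracy = 100 * (tp + tn) / length(labels),
                 auc = compute_roc_auc(scores, labels),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 threshold = threshold),
            class = "metric_set")
}

#' Summarize a per-fold metric vector
#'
#' Mean, sample SD, a 95% normal-approximation confidence interval
#' (`mean +/- 1.96 * SD / sqrt(k)`), minimum and maximum. The normal
#' half-width (rather than a t quantile) matches the convention used in the
#' cross-validated performance tables this layer reproduces.
#'
#' @param values numeric vector of per-fold values (length k >= 2).
#' @return list with `mean`, `sd`, `ci_lower`, `ci_upper`, `min`, `max`.
#' @export
summarize_folds <- function(values) {
  k <- length(values)
  if (k < 2) stop_domain("need at least 2 fold values to summarize")
  m <- mean(values)
  s <- stats::sd(values)
  half <- 1.96 * s / sqrt(k)
  list(mean = m, sd = s, ci_lower = m - half, ci_upper = m + half,
       min = min(values), max = max(values))
}

#' Paired fold-level t-test on AUCs
#'
#' Two-sided paired t-test on per-fold AUC differences between two models
#' evaluated on the same folds: `t = mean(d) / (SD(d) / sqrt(k))` with
#' `k - 1` degrees of freedom. All-zero differences give t = 0, p = 1; zero
#' SD with a nonzero mean is a degenerate case reported with p = 0 and
#' `degenerate = TRUE`.
#'
#' @param aucs_a,aucs_b per-fold AUC vectors of equal length (same folds).
#' @return an object of class `paired_fold_test`: `t`, `df`, `p`,
#'   `mean_difference`, `differences`, `degenerate`.
#' @export
paired_auc_ttest <- function(aucs_a, aucs_b) {
  if (length(aucs_a) != length(aucs_b)) {
    stop_domain("fold AUC vectors must have equal length")
  }
  k <- length(aucs_a)
  if (k < 2) stop_domain("need at least 2 folds")
  d <- aucs_a - aucs_b
  md <- mean(d)
  s <- stats::sd(d)
  degenerate <- FALSE
  if (s == 0) {
    if (md == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(md) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    t_stat <- md / (s / sqrt(k))
    p <- 2 * stats::pt(-abs(t_stat), df = k - 1)
  }
  structure(list(t = t_stat, df = k - 1L, p = p, mean_difference = md,
                 differences = d, degenerate = degenerate),
            class = "paired_fold_test")
}

#' @exportS3Method base::print
print.paired_fold_test <- function(x, ...) {
  cat(sprintf("paired fold-level t-test: t(%d) = %.3f, two-sided p = %.4g\n",
              x$df, x$t, x$p))
  invisible(x)
}

per_fold_frame <- function(metric_list) {
  data.frame(fold = seq_along(metric_list),
             accuracy = vapply(metric_list, `[[`, numeric(1), "accuracy"),
             auc = vapply(metric_list, `[[`, numeric(1), "auc"),
             sensitivity = vapply(metric_list, `[[`, numeric(1), "sensitivity"),
             specificity = vapply(metric_list, `[[`, numeric(1), "specificity"))
}

new_cv_result <- function(model, metric_list, folds, oof_scores = NULL) {
  pf <- per_fold_frame(metric_list)
  structure(list(model = model,
                 per_fold = pf,
                 summary = lapply(pf[, -1], summarize_folds),
                 fold_split = folds,
                 oof_scores = oof_scores,
                 per_fold_metrics = metric_list),
            class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, digits = 2, ...) {
  cat(sprintf("%s: %d-fold cross-validation\n", x$model, x$fold_split$k))
  for (m in names(x$summary)) {
    s <- x$summary[[m]]
    cat(sprintf("  %-12s mean %.*f (95%% CI %.*f-%.*f), min %.*f, max %.*f\n",
                m, digits, s$mean, digits, s$ci_lower, digits, s$ci_upper,
                digits, s$min, digits, s$max))
  }
  invisible(x)
}

#' Cross-validate a deep model assembly
#'
#' For each fold, a fresh assembly head is fine-tuned (frozen speech
#' encoder, balanced training set, inner early-stopping split) on the other
#' folds and scored on the held-out fold; a participant's score is therefore
#' always out-of-fold. Speech embeddings are precomputed once through the
#' frozen encoder.
#'
#' @param kind `"SpeechAI"`, `"DemoAI"` or `"DemoSpeechAI"`.
#' @param labels,age,sex per-participant outcome and demographics.
#' @param folds a [make_balanced_folds()] split.
#' @param speech_emb `n x model_dim` matrix of precomputed embeddings
#'   (required unless `kind == "DemoAI"`).
#' @param encoder the frozen [init_speech_encoder()] used for `speech_emb`
#'   (stored in the per-fold assemblies).
#' @param speech_config,demo_config,hidden_dim assembly configuration;
#'   see [build_assembly()].
#' @param ft_config a [finetune_config()] template (its seed is re-derived
#'   per fold).
#' @param threshold decision threshold for the confusion counts.
#' @param seed integer seed.
#' @return an object of class `cv_result` with per-fold metric sets, summary
#'   statistics and out-of-fold scores.
#' @export
cross_validate <- function(kind, labels, age = NULL, sex = NULL, folds,
                           speech_emb = NULL, encoder = NULL,
                           speech_config = fast_speech_config(),
                           demo_config = demographic_embedding_config(),
                           hidden_dim = NULL,
                           ft_config = finetune_config(),
                           threshold = 0.5, seed = 1L) {
  kind <- match.arg(kind, model_kinds())
  if (kind != "DemoAI" && is.null(speech_emb)) {
    stop_domain(kind, " needs precomputed speech embeddings")
  }
  oof <- rep(NA_real_, length(labels))
  metric_list <- vector("list", folds$k)
  sel <- function(x, i) if (is.null(x)) NULL else {
    if (is.matrix(x)) x[i, , drop = FALSE] else x[i]
  }
  for (f in seq_len(folds$k)) {
    val <- which(folds$assignments == f)
    trn <- which(folds$assignments != f)
    assembly <- build_assembly(kind, speech_config, demo_config,
                               hidden_dim = hidden_dim, encoder = encoder,
                               seed = derive_seed(seed, 41L, f))
    cfg <- ft_config
    cfg$seed <- derive_seed(seed, 42L, f)
    fit <- finetune(assembly, speech_emb = sel(speech_emb, trn),
                    age = sel(age, trn), sex = sel(sex, trn),
                    labels = labels[trn], config = cfg)
    scores <- predict(fit$assembly, speech_emb = sel(speech_emb, val),
                      age = sel(age, val), sex = sel(sex, val))
    oof[val] <- scores
    metric_list[[f]] <- compute_metrics(scores, labels[val], threshold)
  }
  new_cv_result(kind, metric_list, folds, oof)
}

#' Prevalence-shifted (imbalanced) sensitivity evaluation
#'
#' Rebuilds validation sets with the positive class at a target real-world
#' prevalence (default 20%): all robust participants are kept and positives
#' are subsampled without replacement to the count whose resulting
#' prevalence is closest to the target. Because a single subsample is
#' high-variance, metrics are averaged over repeated seeded resamples.
#'
#' @param scores out-of-fold prediction scores for the full pool.
#' @param labels 0/1 labels for the pool.
#' @param target_prevalence target positive fraction, in (0, 1).
#' @param repeats number of resamples averaged.
#' @param seed integer master seed.
#' @param threshold decision threshold.
#' @return list with averaged `metrics` (accuracy %, auc, sensitivity,
#'   specificity), `n_positive`, `n_robust`, `attained_prevalence`,
#'   `exact` (whether the target is attainable exactly) and `repeats`.
#' @export
evaluate_imbalanced <- function(scores, labels, target_prevalence = 0.20,
                                repeats = 20, seed = 1L, threshold = 0.5) {
  stopifnot(target_prevalence > 0, target_prevalence < 1)
  neg <- which(labels == 0)
  pos <- which(labels == 1)
  m <- round(length(neg) * target_prevalence / (1 - target_prevalence))
  if (m < 1 || m > length(pos)) {
    stop_domain("target prevalence ", target_prevalence,
                " unattainable with ", length(pos), " positives and ",
                length(neg), " robust participants")
  }
  attained <- m / (m + length(neg))
  reps <- lapply(seq_len(repeats), function(r) {
    take <- with_seed(derive_seed(seed, 51L, r), sample(pos, m))
    idx <- c(neg, take)
    compute_metrics(scores[idx], labels[idx], threshold)
  })
  avg <- function(field) mean(vapply(reps, `[[`, numeric(1), field))
  list(metrics = list(accuracy = avg("accuracy"), auc = avg("auc"),
                      sensitivity = avg("sensitivity"),
                      specificity = avg("specificity")),
       n_positive = m, n_robust = length(neg),
       attained_prevalence = attained,
       exact = isTRUE(all.equal(attained, target_prevalence)),
       repeats = repeats)
}

#' Cross-validate a classical baseline on functional features
#'
#' Fits one of the classical models used for comparison - ridge logistic
#' regression, a depth-limited decision tree, or a 100-tree random forest -
#' on the per-clip functional vectors, with the same fold split, training
#' balancing and metric definitions as the deep models. Features are
#' standardized with training-fold statistics.
#'
#' @param kind `"logistic_regression"`, `"decision_tree"` or
#'   `"random_forest"`.
#' @param functionals `n x p` matrix of per-clip functionals
#'   (see [extract_functionals()]).
#' @param labels 0/1 labels.
#' @param folds a [make_balanced_folds()] split.
#' @param seed integer seed.
#' @param balance undersample the majority class in training folds.
#' @param threshold decision threshold.
#' @return an object of class `cv_result`.
#' @export
train_baseline <- function(kind = c("logistic_regression", "decision_tree",
                                    "random_forest"),
                           functionals, labels, folds, seed = 1L,
                           balance = TRUE, threshold = 0.5) {
  kind <- match.arg(kind)
  metric_list <- vector("list", folds$k)
  oof <- rep(NA_real_, length(labels))
  for (f in seq_len(folds$k)) {
    val <- which(folds$assignments == f)
    trn <- which(folds$assignments != f)
    if (balance) {
      trn <- balance_training_set(trn, labels[trn], derive_seed(seed, 61L, f))
    }
    mu <- colMeans(functionals[trn, , drop = FALSE])
    sdv <- pmax(apply(functionals[trn, , drop = FALSE], 2, stats::sd), 1e-8)
    std <- function(X) sweep(sweep(X, 2, mu), 2, sdv, `/`)
    Xtr <- std(functionals[trn, , drop = FALSE])
    Xva <- std(functionals[val, , drop = FALSE])
    ytr <- labels[trn]
    scores <- with_seed(derive_seed(seed, 62L, f), {
      switch(kind,
        logistic_regression = {
          lam <- 1 / length(ytr)
          fit <- glmnet::glmnet(Xtr, factor(ytr), family = "binomial",
                                alpha = 0, lambda = lam, standardize = FALSE)
          as.numeric(stats::predict(fit, Xva, s = lam, type = "response"))
        },
        decision_tree = {
          df <- data.frame(y = factor(ytr), Xtr)
          fit <- rpart::rpart(y ~ ., data = df, method = "class",
                              control = rpart::rpart.control(
                                maxdepth = 5, xval = 0, cp = 0.01))
          stats::predict(fit, data.frame(Xva))[, "1"]
        },
        random_forest = {
          fit <- randomForest::randomForest(Xtr, factor(ytr), ntree = 100)
          stats::predict(fit, Xva, type = "prob")[, "1"]
        })
    })
    oof[val] <- scores
    metric_list[[f]] <- compute_metrics(scores, labels[val], threshold)
  }
  new_cv_result(kind, metric_list, folds, oof)
}

# ROC step-curve points (FPR, TPR) for plotting/export.
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  data.frame(fpr = c(0, fp / sum(labels == 0)),
             tpr = c(0, tp / sum(labels == 1)))
}
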