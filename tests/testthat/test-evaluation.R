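test_that("balanced folds stratify a 50/50 cohort perfectly", {
  labels <- rep(c(0, 1), 50)
  fs <- make_balanced_folds(labels, k = 5, seed = 1)
  expect_true(all(table(fs$assignments) == 20))
  expect_true(all(fs$counts == 10))
})

test_that("fold splits partition the cohort with near-ideal stratification", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(30:250, 1)
      prev <- runif(1, 0.2, 0.8)
      labels <- rbinom(n, 1, prev)
      if (min(table(factor(labels, levels = 0:1))) < 5) next
      fs <- make_balanced_folds(labels, k = 5, seed = i)
      # disjoint and exhaustive by construction of an assignment vector
      expect_length(fs$assignments, n)
      expect_setequal(unique(fs$assignments), 1:5)
      sizes <- tabulate(fs$assignments, 5)
      expect_lte(max(sizes) - min(sizes), 1)
      for (cls in c(1, 2)) {
        ideal <- sum(fs$counts[, cls]) / 5
        expect_lte(max(abs(fs$counts[, cls] - ideal)), 1)
      }
      # each fold holds about 20% of samples
      expect_true(all(abs(sizes / n - 0.2) < 0.2 / 5 + 1 / n))
    }
  })
})

test_that("a 127-participant 65/62 cohort splits into folds of 25-26", {
  labels <- c(rep(1, 65), rep(0, 62))
  fs <- make_balanced_folds(labels, k = 5, seed = 2)
  expect_true(all(tabulate(fs$assignments, 5) %in% c(25, 26)))
  expect_true(all(abs(fs$counts[, "positive"] - 13) <= 1))
  expect_true(all(abs(fs$counts[, "robust"] - 12.4) <= 1))
  expect_error(make_balanced_folds(c(rep(0, 3), rep(1, 20)), k = 5),
               "at least k")
})

test_that("AUC matches perfect, inverted and the pair-counting oracle", {
  expect_equal(compute_roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_roc_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0.0)
  withr::with_seed(5, {
    for (i in 1:25) {
      n <- sample(10:200, 1)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
      expect_equal(compute_roc_auc(scores, labels),
                   oracle_auc(scores, labels), tolerance = 1e-12)
    }
  })
  expect_error(compute_roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(6, {
    scores <- runif(50)
    labels <- rbinom(50, 1, 0.5)
  })
  base <- compute_roc_auc(scores, labels)
  expect_equal(compute_roc_auc(exp(3 * scores), labels), base)
  expect_equal(compute_roc_auc(rank(scores), labels), base)
  expect_equal(compute_roc_auc(scores^3 + 10, labels), base)
})

test_that("confusion-matrix metrics follow their defining ratios", {
  scores <- c(rep(0.9, 28), rep(0.1, 4), rep(0.2, 20), rep(0.8, 12))
  labels <- c(rep(1, 32), rep(0, 32))
  m <- compute_metrics(scores, labels)
  expect_equal(m$tp, 28); expect_equal(m$fn, 4)
  expect_equal(m$tn, 20); expect_equal(m$fp, 12)
  expect_equal(m$sensitivity, 0.875)
  expect_equal(m$specificity, 0.625)
  expect_equal(m$accuracy, 100 * 48 / 64)
  perfect <- compute_metrics(labels, labels)
  expect_equal(perfect$accuracy, 100)
})

test_that("scores exactly at the threshold count as positive", {
  scores <- c(0.5, 0.9, 0.1)
  labels <- c(1, 1, 0)
  eps <- 1e-9
  at <- compute_metrics(scores, labels, threshold = 0.5)
  below <- compute_metrics(scores, labels, threshold = 0.5 - eps)
  above <- compute_metrics(scores, labels, threshold = 0.5 + eps)
  expect_equal(at$tp, 2)
  expect_equal(below$tp, 2)
  expect_equal(above$tp, 1)
})

# five values with exact mean m and sample SD s
five_with <- function(m, s) {
  a <- s * sqrt(2)
  c(m - a, m, m, m, m + a)
}

test_that("fold summaries reproduce printed normal-approximation CIs", {
  cases <- list(
    list(mean = 85.60, sd = 6.35, ci = c(80.03, 91.17)),
    list(mean = 0.93, sd = 0.05, ci = c(0.89, 0.97)),
    list(mean = 0.89, sd = 0.07, ci = c(0.83, 0.95)),
    list(mean = 0.83, sd = 0.07, ci = c(0.77, 0.89)))
  for (cs in cases) {
    s <- summarize_folds(five_with(cs$mean, cs$sd))
    expect_equal(s$mean, cs$mean, tolerance = 1e-12)
    expect_equal(s$sd, cs$sd, tolerance = 1e-12)
    expect_equal(round(c(s$ci_lower, s$ci_upper), 2), cs$ci)
  }
  same <- summarize_folds(rep(0.8, 5))
  expect_equal(c(same$ci_lower, same$ci_upper), c(0.8, 0.8))
  expect_true(same$min <= same$mean && same$mean <= same$max)
  expect_error(summarize_folds(0.5), "at least 2")
})

test_that("paired fold t-test matches the closed form and handles degeneracy", {
  expect_equal(paired_auc_ttest(rep(0.8, 5), rep(0.8, 5))[c("t", "p")],
               list(t = 0, p = 1))
  d <- c(0.10, 0.12, 0.15, 0.20, 0.18)
  a <- 0.7 + d; b <- rep(0.7, 5)
  tt <- paired_auc_ttest(a, b)
  t_expected <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(tt$t, t_expected, tolerance = 1e-12)
  expect_equal(tt$df, 4L)
  expect_equal(tt$p, 2 * pt(-abs(t_expected), 4), tolerance = 1e-12)
  # base R paired t-test as an independent cross-check
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-10)
  deg <- paired_auc_ttest(c(0.9, 0.9, 0.9), c(0.8, 0.8, 0.8))
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
  expect_error(paired_auc_ttest(1:4 / 10, 1:5 / 10), "equal length")
})

test_that("prevalence-shifted evaluation hits the target or nearest count", {
  withr::with_seed(7, {
    labels <- c(rep(0, 40), rep(1, 60))
    scores <- ifelse(labels == 1, runif(100, 0.5, 1), runif(100, 0, 0.5))
  })
  res <- evaluate_imbalanced(scores, labels, target_prevalence = 0.2,
                             repeats = 5, seed = 3)
  expect_equal(res$n_positive, 10)
  expect_equal(res$n_robust, 40)
  expect_true(res$exact)
  expect_equal(res$attained_prevalence, 0.2)
  # a perfect scorer keeps AUC 1.0 in every resample
  perf <- evaluate_imbalanced(labels, labels, 0.2, repeats = 5, seed = 3)
  expect_equal(perf$metrics$auc, 1.0)
  # determinism
  res2 <- evaluate_imbalanced(scores, labels, 0.2, repeats = 5, seed = 3)
  expect_identical(res, res2)
  expect_error(evaluate_imbalanced(scores[1:41], labels[1:41], 0.2),
               "unattainable")
})

test_that("baselines score near chance on permuted labels and are seeded", {
  withr::with_seed(8, {
    X <- matrix(rnorm(200 * 12), 200, 12)
    labels <- sample(rep(c(0, 1), 100))
  })
  fs <- make_balanced_folds(labels, 5, seed = 1)
  for (kind in c("logistic_regression", "random_forest")) {
    cv <- train_baseline(kind, X, labels, fs, seed = 2)
    expect_lt(abs(cv$summary$auc$mean - 0.5), 0.1)
    cv2 <- train_baseline(kind, X, labels, fs, seed = 2)
    expect_identical(cv$per_fold, cv2$per_fold)
  }
})

test_that("cross-validation scores every participant exactly once out-of-fold", {
  dat <- withr::with_seed(9, {
    n <- 60
    labels <- rep(c(0L, 1L), n / 2)
    emb <- matrix(rnorm(n * 16), n, 16)
    emb[, 2] <- emb[, 2] + 1.5 * labels
    list(emb = emb, labels = labels,
         age = sample(50:95, n, replace = TRUE),
         sex = sample(c("female", "male"), n, replace = TRUE))
  })
  fs <- make_balanced_folds(dat$labels, 5, seed = 4)
  cv <- cross_validate("DemoSpeechAI", dat$labels, dat$age, dat$sex, fs,
                       speech_emb = dat$emb,
                       encoder = init_speech_encoder(tiny_speech_config(),
                                                     seed = 1),
                       speech_config = tiny_speech_config(), hidden_dim = 8,
                       ft_config = quick_ft_config(), seed = 6)
  expect_false(any(is.na(cv$oof_scores)))
  expect_length(cv$oof_scores, 60)
  expect_equal(nrow(cv$per_fold), 5)
  # every id is validated in exactly the fold it was assigned to
  expect_setequal(unique(cv$fold_split$assignments), 1:5)
  for (m in c("accuracy", "auc", "sensitivity", "specificity")) {
    s <- cv$summary[[m]]
    expect_true(s$min <= s$mean && s$mean <= s$max)
    expect_true(s$ci_lower <= s$mean && s$mean <= s$ci_upper)
  }
})
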