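separable_dataset <- function(n = 40, n_fp = 8, seed = 21) {
  set.seed(seed)
  m <- matrix(rbinom(n * n_fp, 1, 0.5), nrow = n,
              dimnames = list(paste0("m", seq_len(n)),
                              paste0("FP", seq_len(n_fp))))
  labels <- rep(c("active", "inactive"), length.out = n)
  m[, 1] <- as.integer(labels == "active")  # one bit equals the label
  labeled_dataset(m, labels)
}

test_that("the margin scorer separates a separable set and is reproducible", {
  ds <- separable_dataset()
  model <- train_margin_scorer(ds, seed = 1)
  scores <- margin_scores(model, ds)
  pred <- classify_potency(scores, 0)
  expect_equal(as.character(pred), as.character(ds$labels))  # 100 % training
  expect_true(all(scores[ds$labels == "active"] > 0))

  model2 <- train_margin_scorer(ds, seed = 1)
  expect_identical(margin_scores(model2, ds), scores)

  one_class <- labeled_dataset(ds$matrix, rep("active", nrow(ds$matrix)))
  expect_error(train_margin_scorer(one_class), "per class")
})

test_that("scoring refuses tables missing a training fingerprint", {
  ds <- separable_dataset()
  model <- train_margin_scorer(ds)
  crippled <- ds$matrix[, -3, drop = FALSE]
  expect_error(margin_scores(model, crippled), "FP3")
  # reordered columns are fine
  shuffled <- ds$matrix[, rev(colnames(ds$matrix))]
  expect_equal(margin_scores(model, shuffled), margin_scores(model, ds))
})

test_that("normalization maps the training range onto [-1, 1] with clipping", {
  cal <- score_calibration(c(0, 5, 10))
  expect_equal(normalize_scores(c(0, 5, 10), cal), c(-1, 0, 1))
  expect_equal(normalize_scores(12, cal), 1)
  expect_equal(normalize_scores(-3, cal), -1)

  idcal <- score_calibration(c(-1, 0.2, 1))
  expect_equal(normalize_scores(c(-1, 0.2, 1), idcal), c(-1, 0.2, 1))

  deg <- score_calibration(rep(4, 3))
  expect_true(deg$degenerate)
  expect_equal(normalize_scores(c(1, 9), deg), c(0, 0))
})

test_that("normalization is monotone and preserves training-score ranks", {
  set.seed(606)
  raw <- rnorm(200, sd = 4)
  cal <- score_calibration(raw)
  norm <- normalize_scores(raw, cal)
  expect_true(all(diff(norm[order(raw)]) >= 0))
  expect_equal(rank(norm), rank(raw))
  labels <- rbinom(200, 1, 0.5)
  labels[1] <- 1; labels[2] <- 0
  expect_equal(roc_auc(norm, labels)$auc, roc_auc(raw, labels)$auc)
})

test_that("hybrid score is the exact symmetric mean on [-1, 1]", {
  expect_equal(hybrid_score(0.6, 0.8)$hybrid, 0.7)
  expect_equal(hybrid_score(0.4, -0.4)$hybrid, 0)
  expect_equal(hybrid_score(-1, -1)$hybrid, -1)
  expect_equal(hybrid_score(0.3, 0.9)$hybrid, hybrid_score(0.9, 0.3)$hybrid)
  expect_error(hybrid_score(1.5, 0), "\\[-1, 1\\]")
  expect_error(hybrid_score(c(0, 1), 0), "equal length")
})

test_that("the fitted pipeline scores new molecules end to end", {
  g <- generate_dataset(sim_config(n_active = 150, n_inactive = 150,
                                   n_fingerprints = 30, n_informative = 6,
                                   p_active = 0.85, p_inactive = 0.15,
                                   duplicate_fraction = 0.2, seed = 31))
  hm <- fit_hybrid(g$dataset, seed = 1)
  expect_true(all(g$informative %in% hm$fingerprints))
  pred <- predict(hm, g$dataset)
  expect_true(all(abs(pred$hybrid) <= 1))
  acc <- mean(as.character(pred$label) == as.character(g$dataset$labels))
  expect_gt(acc, 0.8)
  keep <- setdiff(colnames(g$dataset$matrix), hm$fingerprints[1])
  expect_error(predict(hm, g$dataset$matrix[, keep, drop = FALSE]),
               "missing training fingerprint")
})

test_that("hybrid cross-validation is no worse than its weaker component", {
  g <- generate_dataset(sim_config(n_active = 150, n_inactive = 150,
                                   n_fingerprints = 24, n_informative = 4,
                                   p_active = 0.8, p_inactive = 0.2,
                                   duplicate_fraction = 0.25, n_xor_pairs = 3,
                                   seed = 41))
  all_fp <- colnames(g$dataset$matrix)
  pot <- cross_validate(g$dataset, "potency", repeats = 2, seed = 9,
                        fixed_fingerprints = all_fp)
  mar <- cross_validate(g$dataset, "margin", repeats = 2, seed = 9,
                        fixed_fingerprints = all_fp)
  hyb <- cross_validate(g$dataset, "hybrid", repeats = 2, seed = 9,
                        fixed_fingerprints = all_fp)
  mcc0 <- function(cv) cv_metrics_at(cv, 0)$mcc
  expect_gte(mcc0(hyb) + 0.02, min(mcc0(pot), mcc0(mar)))
})
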