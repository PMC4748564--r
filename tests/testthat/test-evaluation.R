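test_that("confusion metrics follow the count formulas and conventions", {
  m <- confusion_metrics(tp = 50, fp = 50, tn = 50, fn = 50)
  expect_equal(m$mcc, 0)
  expect_equal(m$accuracy, 50)

  p <- confusion_metrics(tp = 30, fp = 0, tn = 70, fn = 0)
  expect_equal(p$mcc, 1)
  expect_equal(p$accuracy, 100)

  cc <- confusion_counts(c("active", "active", "inactive", "inactive"),
                         c("active", "inactive", "active", "inactive"))
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_error(confusion_metrics(tp = 0, fp = 0, tn = 0, fn = 0), "zero")
})

test_that("MCC from counts equals the Pearson correlation of the labels", {
  set.seed(707)
  for (k in 1:100) {
    n <- sample(10:80, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(truth)) < 2 || length(unique(pred)) < 2) next
    m <- confusion_metrics(tp = sum(truth & pred), fp = sum(!truth & pred),
                           tn = sum(!truth & !pred), fn = sum(truth & !pred))
    expect_equal(m$mcc, cor(truth, pred), tolerance = 1e-12)
  }
})

test_that("accuracy is the class-size weighted mix of sensitivity and specificity", {
  set.seed(708)
  for (k in 1:50) {
    tp <- sample(0:50, 1); fn <- sample(1:50, 1)
    fp <- sample(0:50, 1); tn <- sample(1:50, 1)
    m <- confusion_metrics(tp = tp, fp = fp, tn = tn, fn = fn)
    na <- tp + fn; ni <- tn + fp
    expect_equal(m$accuracy,
                 (m$sensitivity * na + m$specificity * ni) / (na + ni))
  }
})

test_that("rank AUC matches the worked examples and the trapezoid oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(808)
  for (k in 1:100) {
    n <- sample(10:60, 1)
    scores <- round(rnorm(n), 1)           # rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    res <- roc_auc(scores, labels)
    expect_equal(res$auc, trapezoid_auc(res$roc$fpr, res$roc$tpr),
                 tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(810)
  for (k in 1:20) {
    n <- sample(20:80, 1)
    scores <- round(rnorm(n), 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ours <- roc_auc(scores, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<",
                                          quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("ROC points start at (0,0), end at (1,1) and are monotone", {
  set.seed(809)
  res <- roc_auc(rnorm(40), rbinom(40, 1, 0.5))
  expect_equal(res$roc$fpr[1], 0)
  expect_equal(res$roc$tpr[1], 0)
  expect_equal(res$roc$fpr[nrow(res$roc)], 1)
  expect_equal(res$roc$tpr[nrow(res$roc)], 1)
  expect_true(all(diff(res$roc$fpr) >= 0))
  expect_true(all(diff(res$roc$tpr) >= 0))
})

test_that("stratified folds partition every molecule exactly once", {
  labels <- rep(c("active", "inactive"), c(37, 53))
  set.seed(1)
  f <- stratified_folds(labels, folds = 5)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 90)
  # per-fold class counts as equal as arithmetic allows
  for (k in 1:5) {
    expect_lte(abs(sum(f == k & labels == "active") - 37 / 5), 1)
    expect_lte(abs(sum(f == k & labels == "inactive") - 53 / 5), 1)
  }
  expect_error(stratified_folds(rep(c("active", "inactive"), c(3, 50)),
                                folds = 5), "fewer")
})

test_that("cross-validation is perfect on a separable set and well-formed", {
  set.seed(33)
  m <- matrix(rbinom(600, 1, 0.5), nrow = 60,
              dimnames = list(paste0("m", 1:60), paste0("FP", 1:10)))
  labels <- rep(c("active", "inactive"), 30)
  m[, 1] <- as.integer(labels == "active")
  ds <- labeled_dataset(m, labels)
  cv <- cross_validate(ds, "potency", repeats = 2, seed = 4)
  at0 <- cv_metrics_at(cv, 0)
  expect_equal(at0$accuracy, 100)
  expect_equal(at0$mcc, 1)
  expect_equal(cv$auc, 1)

  # partition invariant: each molecule in exactly one test fold per repeat
  for (part in cv$partitions) {
    expect_equal(length(part), 60)
    expect_true(all(table(part) > 0))
    expect_equal(sum(table(part)), 60)
  }
})

test_that("raising the threshold never helps sensitivity nor hurts specificity", {
  g <- generate_dataset(sim_config(n_active = 100, n_inactive = 100,
                                   n_fingerprints = 20, n_informative = 3,
                                   p_active = 0.8, p_inactive = 0.2,
                                   seed = 17))
  cv <- cross_validate(g$dataset, "potency", repeats = 2, seed = 2)
  expect_true(all(diff(cv$metrics$sensitivity) <= 1e-9))
  expect_true(all(diff(cv$metrics$specificity) >= -1e-9))
  expect_true(all(diff(cv$metrics$fpr) <= 1e-9))
})

test_that("sweep_report keeps input order and handles the empty case", {
  empty <- sweep_report(list())
  expect_equal(nrow(empty), 0)
  expect_equal(colnames(empty),
               c("configuration", "sensitivity", "specificity", "accuracy",
                 "mcc", "fpr", "auc"))

  g <- generate_dataset(sim_config(n_active = 60, n_inactive = 60,
                                   n_fingerprints = 15, n_informative = 3,
                                   p_active = 0.85, p_inactive = 0.15,
                                   seed = 23))
  cv1 <- cross_validate(g$dataset, "potency", repeats = 1, seed = 1)
  one <- sweep_report(list(top5 = cv1))
  expect_equal(nrow(one), 1)
  expect_equal(one$configuration, "top5")

  reps <- list(a = cv1, b = cv1, c = cv1, d = cv1, e = cv1)
  five <- sweep_report(reps)
  expect_equal(five$configuration, c("a", "b", "c", "d", "e"))
})
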