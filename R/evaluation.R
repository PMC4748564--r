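#' Confusion counts from true and predicted labels
#'
#' @param truth,predicted vectors coercible to `active`/`inactive` labels
#'   (see [normalize_labels()]), same length.
#' @return A `confusion_counts` list: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- normalize_labels(truth); predicted <- normalize_labels(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  structure(list(tp = sum(truth == "active" & predicted == "active"),
                 fp = sum(truth == "inactive" & predicted == "active"),
                 tn = sum(truth == "inactive" & predicted == "inactive"),
                 fn = sum(truth == "active" & predicted == "inactive")),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `100*tp/(tp+fn)`, specificity `100*tn/(tn+fp)`, accuracy
#' `100*(tp+tn)/total`, Matthews correlation coefficient (0 when a
#' denominator factor vanishes), and false-positive rate `fp/(fp+tn)`.
#' Counts may be non-integer, which supports reconstructing metrics from
#' rounded published sensitivity/specificity pairs.
#'
#' @param cc a `confusion_counts` object, or `NULL` when passing counts
#'   directly.
#' @param tp,fp,tn,fn counts, used when `cc` is `NULL`.
#' @return A `metric_set` list: `sensitivity`, `specificity`, `accuracy`
#'   (percent), `mcc`, `fpr`, and the counts.
#' @export
confusion_metrics <- function(cc = NULL, tp = NULL, fp = NULL, tn = NULL,
                              fn = NULL) {
  if (!is.null(cc)) {
    stopifnot(inherits(cc, "confusion_counts"))
    tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  }
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  total <- tp + fp + tn + fn
  if (total <= 0) stop("all counts are zero")
  structure(list(
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    accuracy = 100 * (tp + tn) / total,
    mcc = .mcc_from_counts(tp, fp, tn, fn),
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%  MCC %.3f  FPR %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$mcc, x$fpr))
  invisible(x)
}

#' Rank-based AUC and ROC points
#'
#' AUC is computed as the Wilcoxon rank statistic (ties averaged), which
#' equals the trapezoidal area under the full-threshold-sweep ROC curve.
#' ROC points (one per distinct score, plus the two endpoints) are emitted
#' for plotting.
#'
#' @param scores numeric scores, higher = more active-like.
#' @param labels class labels (see [normalize_labels()]).
#' @return List with `auc` and `roc`, a data frame of `threshold`, `fpr`,
#'   `tpr` rows ordered from the strictest threshold to the most permissive.
#' @export
roc_auc <- function(scores, labels) {
  labels <- normalize_labels(labels)
  act <- labels == "active"
  if (!any(act) || all(act)) stop("both classes must be present")
  auc <- .rank_auc(scores, act)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(act); n0 <- sum(!act)
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !act) / n0, tpr = sum(pred & act) / n1)
  }, c(fpr = 0, tpr = 0)))
  list(auc = auc,
       roc = data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"]))
}

#' Stratified cross-validation fold assignment
#'
#' Randomly partitions molecules into `folds` parts; with `stratified =
#' TRUE` (default) each class is partitioned separately so per-fold class
#' proportions match the whole set as closely as possible. Every molecule
#' lands in exactly one fold.
#'
#' @param labels class labels.
#' @param folds number of folds (>= 2).
#' @param stratified preserve class proportions per fold.
#' @return Integer vector of fold ids in `1:folds`, one per molecule.
#' @export
stratified_folds <- function(labels, folds = 5, stratified = TRUE) {
  labels <- normalize_labels(labels)
  n <- length(labels)
  if (folds < 2) stop("need at least 2 folds")
  assign_group <- function(idx) {
    f <- rep(seq_len(folds), length.out = length(idx))
    sample(f, length(idx))
  }
  out <- integer(n)
  if (stratified) {
    if (min(table(labels)) < folds)
      stop("a class has fewer molecules than folds; cannot stratify")
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      out[idx] <- assign_group(idx)
    }
  } else {
    out <- assign_group(seq_len(n))
  }
  out
}

# Vectorized potency scores of the rows of Q against a reference dataset.
# With exclude_self = TRUE, reference molecules whose id equals the query's
# id are masked out before taking the maxima.
.potency_scores <- function(Q, refs, exclude_self = FALSE) {
  act <- refs$labels == "active"
  highest <- function(R) {
    s1 <- .tanimoto_cross(Q, R)
    s0 <- .tanimoto_cross(1L - Q, 1L - R)
    if (exclude_self) {
      mask <- outer(rownames(Q), rownames(R), "==")
      s1[mask] <- -Inf
      s0[mask] <- -Inf
    }
    rowmax <- function(M)
      M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
    pmax(rowmax(s1), rowmax(s0))
  }
  ha <- highest(refs$matrix[act, , drop = FALSE])
  hn <- highest(refs$matrix[!act, , drop = FALSE])
  if (any(!is.finite(ha)) || any(!is.finite(hn)))
    stop("a reference class is empty after self-exclusion")
  ha - hn
}

# Train on ds_tr, score ds_te; returns per-method normalized (or natural
# [-1,1]) test scores. Potency raw scores are already in [-1,1]; margin and
# hybrid components are min-max normalized on training-set scores.
.fit_and_score <- function(ds_tr, ds_te, method, selection_cutoff, top_k,
                           fixed_fingerprints, g, c, j) {
  if (is.null(fixed_fingerprints)) {
    stats <- single_fingerprint_performance(ds_tr)
    sel <- select_fingerprints(stats, mcc_cutoff = selection_cutoff,
                               top_k = top_k)
    if (!length(sel)) sel <- colnames(ds_tr$matrix)  # nothing passes: keep all
  } else {
    sel <- fixed_fingerprints
  }
  tr <- subset_fingerprints(ds_tr, sel)
  te <- subset_fingerprints(ds_te, sel)
  out <- list(selected = sel)

  if (method == "potency") {
    out$score <- .potency_scores(te$matrix, tr)
    out$cal <- NULL                        # raw potency is already in [-1, 1]
  } else if (method == "margin") {
    model <- train_margin_scorer(tr, g = g, c = c, j = j)
    cal <- score_calibration(margin_scores(model, tr))
    out$score <- normalize_scores(margin_scores(model, te), cal)
    out$cal <- cal
  } else {
    hm <- fit_hybrid(ds_tr, fixed_fingerprints = sel, g = g, c = c, j = j)
    out$score <- predict(hm, te)$hybrid
    out$cal <- list(potency = hm$cal_potency, margin = hm$cal_margin)
  }
  out
}

#' Repeated stratified cross-validation of a screening method
#'
#' Runs the full evaluation protocol: per repeat, molecules are randomly
#' split into `folds` stratified parts; inside each training portion the
#' fingerprint selection, the potency reference set, the margin model and
#' the score calibrations are refit from scratch, and the held-out part is
#' scored. The five folds' test scores are pooled per repeat, metrics are
#' computed at each threshold of a fixed grid plus AUC, and the final
#' report averages over repeats (with standard deviations).
#'
#' @param ds a `labeled_dataset`.
#' @param method `"potency"` (dual-Tanimoto nearest-reference score),
#'   `"margin"` (normalized RBF SVM decision score) or `"hybrid"` (mean of
#'   the two normalized scores).
#' @param folds number of CV folds (default 5).
#' @param repeats number of independent CV repetitions (default 20).
#' @param seed integer seed governing all partitions.
#' @param stratified preserve class proportions per fold (default `TRUE`).
#' @param selection_cutoff MCC cutoff for per-fold fingerprint selection
#'   (default 0.2). If no fingerprint passes in some fold, all are kept.
#' @param top_k optional cap on the number of selected fingerprints.
#' @param fixed_fingerprints optional fixed fingerprint list; bypasses
#'   per-fold selection (reproduces a single global selection).
#' @param thresholds decision-threshold grid (default `-1` to `1` by `0.2`).
#' @param g,c,j margin-scorer hyperparameters (see
#'   [train_margin_scorer()]).
#' @return A `cv_result` list: `metrics` (per-threshold means and sds over
#'   repeats), `auc`/`auc_sd`, `partitions` (fold assignment per repeat),
#'   `selected` (per repeat x fold selected fingerprints), `calibrations`
#'   (per repeat x fold score calibrations), `scores`
#'   (pooled test scores per repeat) and the configuration.
#' @export
cross_validate <- function(ds, method = c("potency", "margin", "hybrid"),
                           folds = 5, repeats = 20, seed = 1,
                           stratified = TRUE, selection_cutoff = 0.2,
                           top_k = NULL, fixed_fingerprints = NULL,
                           thresholds = seq(-1, 1, by = 0.2),
                           g = 0.1, c = 6, j = 1) {
  stopifnot(inherits(ds, "labeled_dataset"))
  method <- match.arg(method)
  if (min(n_active(ds), n_inactive(ds)) < folds)
    stop("each class needs at least `folds` molecules")
  set.seed(seed)
  n <- nrow(ds$matrix)
  partitions <- vector("list", repeats)
  selected <- vector("list", repeats)
  calibrations <- vector("list", repeats)
  scores_by_repeat <- vector("list", repeats)
  per_repeat <- vector("list", repeats)
  aucs <- numeric(repeats)

  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(ds$labels, folds = folds,
                                stratified = stratified)
    partitions[[r]] <- fold_id
    scores <- numeric(n)
    sel_r <- vector("list", folds)
    cal_r <- vector("list", folds)
    for (f in seq_len(folds)) {
      te_idx <- which(fold_id == f)
      fit <- .fit_and_score(subset_molecules(ds, -te_idx),
                            subset_molecules(ds, te_idx),
                            method, selection_cutoff, top_k,
                            fixed_fingerprints, g, c, j)
      scores[te_idx] <- fit$score
      sel_r[[f]] <- fit$selected
      cal_r[[f]] <- fit$cal
    }
    selected[[r]] <- sel_r
    calibrations[[r]] <- cal_r
    scores_by_repeat[[r]] <- scores
    aucs[r] <- roc_auc(scores, ds$labels)$auc
    per_repeat[[r]] <- t(vapply(thresholds, function(t) {
      m <- confusion_metrics(confusion_counts(ds$labels,
                                              classify_potency(scores, t)))
      c(sensitivity = m$sensitivity, specificity = m$specificity,
        accuracy = m$accuracy, mcc = m$mcc, fpr = m$fpr)
    }, c(sensitivity = 0, specificity = 0, accuracy = 0, mcc = 0, fpr = 0)))
  }

  arr <- simplify2array(per_repeat)            # thresholds x metrics x repeats
  mean_m <- apply(arr, c(1, 2), mean)
  sd_m <- apply(arr, c(1, 2), stats::sd)
  metrics <- data.frame(threshold = thresholds, mean_m,
                        sd_m[, c("sensitivity", "specificity", "accuracy",
                                 "mcc", "fpr")])
  colnames(metrics) <- c("threshold", "sensitivity", "specificity",
                         "accuracy", "mcc", "fpr",
                         paste0(c("sensitivity", "specificity", "accuracy",
                                  "mcc", "fpr"), "_sd"))
  structure(list(method = method, folds = folds, repeats = repeats,
                 seed = seed, thresholds = thresholds, metrics = metrics,
                 auc = mean(aucs), auc_sd = stats::sd(aucs),
                 partitions = partitions, selected = selected,
                 calibrations = calibrations,
                 scores = scores_by_repeat, labels = ds$labels,
                 n = n), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  at0 <- x$metrics[which.min(abs(x$metrics$threshold)), ]
  cat(sprintf("cv_result: %s, %d-fold x %d repeats, n = %d\n",
              x$method, x$folds, x$repeats, x$n))
  cat(sprintf("  at threshold %.1f: sensitivity %.2f%%, specificity %.2f%%, accuracy %.2f%%, MCC %.3f, FPR %.3f\n",
              at0$threshold, at0$sensitivity, at0$specificity, at0$accuracy,
              at0$mcc, at0$fpr))
  cat(sprintf("  AUC %.3f (sd %.3f)\n", x$auc, x$auc_sd))
  invisible(x)
}

#' Metrics of a cross-validation result at one threshold
#'
#' @param cv a `cv_result`.
#' @param threshold a threshold present in the result's grid.
#' @return One-row data frame of averaged metrics plus AUC.
#' @export
cv_metrics_at <- function(cv, threshold = 0) {
  stopifnot(inherits(cv, "cv_result"))
  i <- which(abs(cv$metrics$threshold - threshold) < 1e-9)
  if (!length(i)) stop("threshold not in the evaluated grid")
  cbind(cv$metrics[i, c("threshold", "sensitivity", "specificity",
                        "accuracy", "mcc", "fpr")],
        auc = cv$auc, row.names = NULL)
}

#' Summary table over several evaluated configurations
#'
#' Assembles one row of averaged metrics per configuration (e.g. per
#' fingerprint-count setting or per method), in input order — the shape of
#' a published comparison table.
#'
#' @param results named list of `cv_result` objects (may be empty).
#' @param threshold threshold at which each row is reported (default 0).
#' @return Data frame with columns `configuration`, `sensitivity`,
#'   `specificity`, `accuracy`, `mcc`, `fpr`, `auc`; zero rows if
#'   `results` is empty.
#' @export
sweep_report <- function(results, threshold = 0) {
  cols <- c("configuration", "sensitivity", "specificity", "accuracy",
            "mcc", "fpr", "auc")
  if (!length(results)) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    colnames(out) <- cols
    return(out)
  }
  if (is.null(names(results))) names(results) <- seq_along(results)
  rows <- lapply(names(results), function(nm) {
    cbind(configuration = nm, cv_metrics_at(results[[nm]], threshold)[
      , c("sensitivity", "specificity", "accuracy", "mcc", "fpr", "auc")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
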