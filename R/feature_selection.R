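#' Per-class mean of each fingerprint bit
#'
#' For every fingerprint, the fraction of active molecules carrying the bit
#' (`mean_active`) and the fraction of inactive molecules carrying it
#' (`mean_inactive`): exact sums of bits divided by class sizes.
#'
#' @param ds a `labeled_dataset` with at least one molecule in each class.
#' @return Data frame with columns `fingerprint`, `mean_active`,
#'   `mean_inactive`.
#' @export
class_bit_means <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  na <- n_active(ds); ni <- n_inactive(ds)
  if (na < 1 || ni < 1) stop("both classes must be non-empty")
  act <- ds$labels == "active"
  data.frame(fingerprint = colnames(ds$matrix),
             mean_active = colSums(ds$matrix[act, , drop = FALSE]) / na,
             mean_inactive = colSums(ds$matrix[!act, , drop = FALSE]) / ni,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compound score of a bit value
#'
#' The per-molecule, per-fingerprint separation score: `mean_active -
#' mean_inactive` when the molecule carries the bit, `mean_inactive -
#' mean_active` when it does not. A molecule whose bits tend to agree with
#' the active class profile accumulates positive scores.
#'
#' @param bit 0/1 value(s) of the fingerprint in the molecule.
#' @param mean_active,mean_inactive class-wise bit frequencies in `[0, 1]`.
#' @return Numeric score(s) in `[-1, 1]`.
#' @export
compound_score <- function(bit, mean_active, mean_inactive) {
  if (!all(bit %in% c(0, 1))) stop("`bit` must be 0 or 1")
  if (any(mean_active < 0 | mean_active > 1 | mean_inactive < 0 | mean_inactive > 1))
    stop("class means must lie in [0, 1]")
  ifelse(bit == 1, mean_active - mean_inactive, mean_inactive - mean_active)
}

# Rank-statistic AUC of a score vector against active/inactive labels,
# ties handled by midranks (equivalent to trapezoidal ROC area).
.rank_auc <- function(scores, active) {
  n1 <- sum(active); n0 <- sum(!active)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[active]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.mcc_from_counts <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  num <- tp * tn - fp * fn
  ifelse(den <= 0, 0, num / sqrt(den))
}

#' Standalone classification performance of single fingerprints
#'
#' Evaluates each fingerprint as a one-bit classifier. The compound score of
#' a single bit takes at most two values, so the full threshold sweep runs
#' over the midpoints of the distinct observed scores plus `-Inf`/`+Inf`
#' sentinels; a molecule is called active when its score exceeds the
#' threshold. The threshold (and hence orientation) maximizing MCC is kept;
#' ties are broken toward higher sensitivity, then lower threshold. AUC is
#' the rank-based area under the ROC of the compound score.
#'
#' @param ds a `labeled_dataset`.
#' @param names fingerprints to evaluate (default: all columns).
#' @return A `feature_stats` data frame with one row per fingerprint:
#'   `fingerprint`, `mean_active`, `mean_inactive`, `best_threshold`,
#'   `orientation` (bit value predicting active; `NA` when degenerate),
#'   `sensitivity`, `specificity`, `accuracy` (percent), `mcc`, `fpr`,
#'   `auc`, `degenerate`.
#' @export
single_fingerprint_performance <- function(ds, names = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.null(names)) names <- colnames(ds$matrix)
  missing <- setdiff(names, colnames(ds$matrix))
  if (length(missing))
    stop("unknown fingerprint name(s): ", paste(missing, collapse = ", "))
  act <- ds$labels == "active"
  na <- sum(act); ni <- sum(!act)
  if (na < 1 || ni < 1) stop("both classes must be non-empty")
  m <- ds$matrix[, names, drop = FALSE]
  a1 <- colSums(m[act, , drop = FALSE])   # actives with bit set
  i1 <- colSums(m[!act, , drop = FALSE])  # inactives with bit set
  fa <- a1 / na; fi <- i1 / ni

  one <- function(k) {
    s1 <- fa[k] - fi[k]          # score when bit = 1
    s0 <- -s1                    # score when bit = 0
    scores <- ifelse(m[, k] == 1, s1, s0)
    uniq <- sort(unique(scores))
    degenerate <- length(unique(m[, k])) < 2 || length(uniq) < 2
    auc <- .rank_auc(scores, act)
    if (degenerate) {
      return(data.frame(fingerprint = names[k], mean_active = fa[k],
                        mean_inactive = fi[k], best_threshold = NA_real_,
                        orientation = NA_integer_, sensitivity = 100 * 1,
                        specificity = 0, accuracy = 100 * na / (na + ni),
                        mcc = 0, fpr = 1, auc = if (length(uniq) < 2) 0.5 else auc,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    thr <- c(-Inf, (uniq[-length(uniq)] + uniq[-1]) / 2, Inf)
    best <- NULL
    for (t in thr) {
      pred_active <- scores > t
      tp <- sum(pred_active & act); fp <- sum(pred_active & !act)
      fn <- na - tp; tn <- ni - fp
      cand <- list(threshold = t, tp = tp, fp = fp, tn = tn, fn = fn,
                   mcc = .mcc_from_counts(tp, fp, tn, fn),
                   sens = tp / na)
      if (is.null(best) || cand$mcc > best$mcc + 1e-15 ||
          (abs(cand$mcc - best$mcc) <= 1e-15 &&
           (cand$sens > best$sens + 1e-15 ||
            (abs(cand$sens - best$sens) <= 1e-15 && cand$threshold < best$threshold))))
        best <- cand
    }
    # which bit value is called active at the chosen threshold
    orientation <- if (s1 > best$threshold && s0 > best$threshold) NA_integer_
                   else if (s1 > best$threshold) 1L
                   else if (s0 > best$threshold) 0L
                   else NA_integer_
    data.frame(fingerprint = names[k], mean_active = fa[k],
               mean_inactive = fi[k], best_threshold = best$threshold,
               orientation = orientation,
               sensitivity = 100 * best$tp / na,
               specificity = 100 * best$tn / ni,
               accuracy = 100 * (best$tp + best$tn) / (na + ni),
               mcc = best$mcc, fpr = best$fp / ni, auc = auc,
               degenerate = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(names), one))
  rownames(out) <- NULL
  class(out) <- c("feature_stats", class(out))
  out
}

#' Rank and select fingerprints by MCC
#'
#' Sorts fingerprint statistics by MCC (descending; ties by accuracy
#' descending, then name ascending) and keeps those with MCC strictly above
#' the cutoff; `top_k`, if given, truncates the ranked list after filtering.
#'
#' @param stats a `feature_stats` data frame
#'   (from [single_fingerprint_performance()]).
#' @param mcc_cutoff keep fingerprints with `mcc > mcc_cutoff` (default 0.2).
#' @param top_k optional maximum number of fingerprints to return.
#' @return Character vector of selected fingerprint names, best first.
#' @export
select_fingerprints <- function(stats, mcc_cutoff = 0.2, top_k = NULL) {
  stopifnot(is.data.frame(stats), nrow(stats) >= 1)
  keep <- stats[stats$mcc > mcc_cutoff, , drop = FALSE]
  ord <- order(-keep$mcc, -keep$accuracy, keep$fingerprint)
  out <- keep$fingerprint[ord]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}
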