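#' Fit the full hybrid screening pipeline
#'
#' Trains every component on one reference/training set: fingerprint
#' selection by MCC, the dual-Tanimoto potency reference set, the RBF
#' margin scorer, and the min-max calibrations that map both raw scores to
#' `[-1, 1]`. The result scores new molecules with [predict()] and refuses
#' query tables missing any training fingerprint.
#'
#' @param ds a `labeled_dataset` of reference molecules.
#' @param selection_cutoff MCC cutoff for fingerprint selection (default
#'   0.2); if nothing passes, all fingerprints are kept.
#' @param top_k optional cap on the number of selected fingerprints.
#' @param fixed_fingerprints optional explicit fingerprint list, bypassing
#'   selection.
#' @param g,c,j margin-scorer hyperparameters ([train_margin_scorer()]).
#' @param seed optional seed fixed before training.
#' @return A `hybrid_model`: selected fingerprint names, reference
#'   dataset, fitted `margin_model`, and the two score calibrations.
#' @export
fit_hybrid <- function(ds, selection_cutoff = 0.2, top_k = NULL,
                       fixed_fingerprints = NULL, g = 0.1, c = 6, j = 1,
                       seed = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.null(fixed_fingerprints)) {
    stats <- single_fingerprint_performance(ds)
    sel <- select_fingerprints(stats, mcc_cutoff = selection_cutoff,
                               top_k = top_k)
    if (!length(sel)) sel <- colnames(ds$matrix)
  } else {
    sel <- fixed_fingerprints
  }
  refs <- subset_fingerprints(ds, sel)
  margin <- train_margin_scorer(refs, g = g, c = c, j = j, seed = seed)
  cal_margin <- score_calibration(margin_scores(margin, refs))
  cal_potency <- score_calibration(
    .potency_scores(refs$matrix, refs, exclude_self = TRUE))
  structure(list(fingerprints = sel, refs = refs, margin = margin,
                 cal_margin = cal_margin, cal_potency = cal_potency),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("hybrid_model: %d selected fingerprints, %d reference molecules (%d active, %d inactive)\n",
              length(x$fingerprints), nrow(x$refs$matrix),
              n_active(x$refs), n_inactive(x$refs)))
  invisible(x)
}

#' Score new molecules with a fitted hybrid model
#'
#' @param object a `hybrid_model` from [fit_hybrid()].
#' @param newdata a 0/1 matrix (rows = queries, named) or
#'   `labeled_dataset`; must contain every training fingerprint.
#' @param threshold decision threshold on the hybrid score (default 0;
#'   a score exactly at the threshold is called inactive).
#' @param exclude_id reference ids to mask during similarity search.
#' @param ... unused.
#' @return Data frame, one row per query: the four highest similarities
#'   and nearest reference ids, raw `potency` and `margin` scores, their
#'   normalized versions, `hybrid`, and the predicted `label`.
#' @export
predict.hybrid_model <- function(object, newdata, threshold = 0,
                                 exclude_id = NULL, ...) {
  m <- if (inherits(newdata, "labeled_dataset")) newdata$matrix else newdata
  if (is.null(dim(m)))
    m <- matrix(as.integer(m), nrow = 1,
                dimnames = list("query", object$fingerprints))
  missing <- setdiff(object$fingerprints, colnames(m))
  if (length(missing))
    stop("query table is missing training fingerprint(s): ",
         paste(missing, collapse = ", "))
  m <- m[, object$fingerprints, drop = FALSE]
  ps <- nearest_similarities(m, object$refs, exclude_id = exclude_id)
  margin_raw <- margin_scores(object$margin, m)
  hs <- hybrid_score(normalize_scores(ps$potency, object$cal_potency),
                     normalize_scores(margin_raw, object$cal_margin))
  cbind(ps, margin = margin_raw, hs,
        label = classify_potency(hs$hybrid, threshold))
}
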