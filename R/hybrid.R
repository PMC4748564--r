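#' Train the RBF max-margin scorer
#'
#' Fits a C-classification support vector machine with a radial-basis-
#' function kernel on the binary fingerprint matrix. Defaults follow the
#' kernel width `g = 0.1`, cost `c = 6` and class-cost ratio `j = 1` that
#' perform best for anticancer/non-anticancer discrimination on selected
#' fingerprint bits. Decision scores are oriented so that positive means
#' active.
#'
#' @param ds a `labeled_dataset` with at least two molecules per class.
#' @param g RBF kernel width (libsvm `gamma`).
#' @param c soft-margin cost.
#' @param j cost ratio applied to the active class (class weight
#'   `active = j`, `inactive = 1`).
#' @param seed optional integer seed fixed before training, making the
#'   fitted model reproducible.
#' @return A `margin_model`: list with the fitted svm, the training
#'   fingerprint names, the parameters and the score sign convention.
#' @export
train_margin_scorer <- function(ds, g = 0.1, c = 6, j = 1, seed = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (n_active(ds) < 2 || n_inactive(ds) < 2)
    stop("need at least two molecules per class")
  if (!is.null(seed)) set.seed(seed)
  fit <- e1071::svm(x = ds$matrix, y = ds$labels, type = "C-classification",
                    kernel = "radial", gamma = g, cost = c,
                    class.weights = c(active = j, inactive = 1),
                    scale = FALSE)
  # libsvm orients decision values toward the first training label it sees;
  # detect and store the flip needed for "positive = active"
  dv <- attr(stats::predict(fit, ds$matrix[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- if (grepl("^active/", colnames(dv)[1])) 1 else -1
  structure(list(svm = fit, fingerprints = colnames(ds$matrix),
                 g = g, c = c, j = j, seed = seed, flip = flip),
            class = "margin_model")
}

#' @export
print.margin_model <- function(x, ...) {
  cat(sprintf("margin_model: RBF SVM (g = %g, c = %g, j = %g) on %d fingerprints, %d support vectors\n",
              x$g, x$c, x$j, length(x$fingerprints), x$svm$tot.nSV))
  invisible(x)
}

#' Decision scores of a margin model
#'
#' @param model a `margin_model`.
#' @param newdata a 0/1 matrix or `labeled_dataset`; must contain every
#'   fingerprint the model was trained on (columns are reordered to the
#'   training order).
#' @return Numeric decision scores, positive = active.
#' @export
margin_scores <- function(model, newdata) {
  stopifnot(inherits(model, "margin_model"))
  m <- if (inherits(newdata, "labeled_dataset")) newdata$matrix else newdata
  missing <- setdiff(model$fingerprints, colnames(m))
  if (length(missing))
    stop("newdata is missing training fingerprint(s): ",
         paste(missing, collapse = ", "))
  m <- m[, model$fingerprints, drop = FALSE]
  dv <- attr(stats::predict(model$svm, m, decision.values = TRUE),
             "decision.values")
  as.numeric(dv[, 1]) * model$flip
}

#' Score calibration from training scores
#'
#' Records the observed minimum and maximum of raw scores on the training
#' set, the anchors of the `[-1, 1]` normalization.
#'
#' @param raw numeric vector of raw training scores.
#' @return A `score_calibration`: list `min`, `max`, `degenerate`.
#' @export
score_calibration <- function(raw) {
  raw <- raw[is.finite(raw)]
  if (!length(raw)) stop("no finite scores to calibrate on")
  structure(list(min = min(raw), max = max(raw),
                 degenerate = isTRUE(all.equal(min(raw), max(raw))) ||
                   min(raw) == max(raw)),
            class = "score_calibration")
}

#' Normalize raw scores to \[-1, 1\]
#'
#' Affine map sending the calibration interval `[min, max]` to `[-1, 1]`;
#' out-of-range scores (e.g. test scores beyond the training range) are
#' clipped to the endpoints. A degenerate calibration (`min == max`) maps
#' everything to 0.
#'
#' @param raw numeric scores.
#' @param cal a `score_calibration` fitted on training scores.
#' @return Numeric vector in `[-1, 1]`, same length and order as `raw`.
#' @export
normalize_scores <- function(raw, cal) {
  stopifnot(inherits(cal, "score_calibration"))
  if (cal$degenerate) return(rep(0, length(raw)))
  pmin(1, pmax(-1, -1 + 2 * (raw - cal$min) / (cal$max - cal$min)))
}

#' Hybrid score: average of the two normalized scores
#'
#' @param norm_potency,norm_margin normalized potency and margin scores in
#'   `[-1, 1]` (same length).
#' @return A `hybrid_score` data frame with columns `norm_potency`,
#'   `norm_margin`, `hybrid` (their arithmetic mean). Classify with
#'   [classify_potency()]: active iff `hybrid` exceeds the threshold.
#' @export
hybrid_score <- function(norm_potency, norm_margin) {
  if (length(norm_potency) != length(norm_margin))
    stop("score vectors must have equal length")
  if (any(abs(norm_potency) > 1 + 1e-12) || any(abs(norm_margin) > 1 + 1e-12))
    stop("normalized scores must lie in [-1, 1]")
  out <- data.frame(norm_potency = norm_potency, norm_margin = norm_margin,
                    hybrid = (norm_potency + norm_margin) / 2)
  class(out) <- c("hybrid_score", class(out))
  out
}
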