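#' Tanimoto similarity over present and absent bits
#'
#' `tanimoto_present` is the classical Tanimoto (Jaccard) coefficient on set
#' bits, `|x AND y| / |x OR y|`. `tanimoto_absent` applies the same
#' coefficient to the complemented vectors, measuring agreement on which
#' bits are absent. When the denominator is empty (both vectors all-zero,
#' or all-one for the absent variant) the similarity is defined as 0 and the
#' result carries a `degenerate` attribute.
#'
#' @param x,y binary vectors of equal length (>= 1).
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto_present(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' tanimoto_absent(c(1, 1, 0, 0), c(1, 0, 1, 0))   # 1/3
#' @export
tanimoto_present <- function(x, y) {
  if (length(x) != length(y)) stop("bit vectors must have equal length")
  if (length(x) < 1) stop("bit vectors must be non-empty")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("bit vectors must be binary")
  u <- sum(x | y)
  if (u == 0) return(structure(0, degenerate = TRUE))
  sum(x & y) / u
}

#' @rdname tanimoto_present
#' @export
tanimoto_absent <- function(x, y) {
  tanimoto_present(1 - x, 1 - y)
}

# Cross Tanimoto-on-set-bits between the rows of two 0/1 matrices.
# Returns an nrow(Q) x nrow(R) matrix; empty-union pairs get similarity 0.
.tanimoto_cross <- function(Q, R) {
  inter <- Q %*% t(R)
  un <- outer(rowSums(Q), rowSums(R), "+") - inter
  s <- inter / un
  s[un == 0] <- 0
  s
}

#' Highest similarities of queries to active and inactive references
#'
#' For each query, computes its best Tanimoto similarity to any active
#' reference and to any inactive reference, for both the present-bit (Ts1)
#' and absent-bit (Ts0) variants, records the nearest neighbours, and
#' derives the potency score.
#'
#' @param query a binary vector, a 0/1 matrix (rows = queries, named), or a
#'   `labeled_dataset` whose matrix supplies the queries.
#' @param refs a `labeled_dataset` of reference molecules with at least one
#'   active and one inactive (after exclusion).
#' @param exclude_id optional molecule ids removed from the reference set
#'   before taking maxima (guards self-matching when a query is also a
#'   reference).
#' @return A `potency_result` data frame, one row per query: `query_id`,
#'   `ha_ts1`, `ha_ts0`, `hn_ts1`, `hn_ts0`, `nearest_active_id`,
#'   `nearest_inactive_id`, `potency`. The nearest id of each class comes
#'   from the variant (Ts1 or Ts0) achieving the larger maximum; on a tie
#'   the Ts1 neighbour is reported.
#' @export
nearest_similarities <- function(query, refs, exclude_id = NULL) {
  stopifnot(inherits(refs, "labeled_dataset"))
  if (inherits(query, "labeled_dataset")) query <- query$matrix
  if (is.null(dim(query))) {
    query <- matrix(as.integer(query), nrow = 1,
                    dimnames = list("query", colnames(refs$matrix)))
  }
  if (ncol(query) != ncol(refs$matrix))
    stop("query and reference fingerprint lengths differ")
  keep <- !(rownames(refs$matrix) %in% exclude_id)
  act <- refs$labels == "active" & keep
  ina <- refs$labels == "inactive" & keep
  if (!any(act)) stop("no active reference molecules after exclusion")
  if (!any(ina)) stop("no inactive reference molecules after exclusion")

  best <- function(R) {
    s1 <- .tanimoto_cross(query, R)
    s0 <- .tanimoto_cross(1L - query, 1L - R)
    i1 <- max.col(s1, ties.method = "first")
    i0 <- max.col(s0, ties.method = "first")
    h1 <- s1[cbind(seq_len(nrow(s1)), i1)]
    h0 <- s0[cbind(seq_len(nrow(s0)), i0)]
    nn <- ifelse(h0 > h1, rownames(R)[i0], rownames(R)[i1])
    list(h1 = h1, h0 = h0, nn = nn)
  }
  A <- best(refs$matrix[act, , drop = FALSE])
  I <- best(refs$matrix[ina, , drop = FALSE])
  out <- data.frame(query_id = rownames(query),
                    ha_ts1 = A$h1, ha_ts0 = A$h0,
                    hn_ts1 = I$h1, hn_ts0 = I$h0,
                    nearest_active_id = A$nn,
                    nearest_inactive_id = I$nn,
                    potency = potency(A$h1, A$h0, I$h1, I$h0),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("potency_result", class(out))
  out
}

#' Potency score from the four highest similarities
#'
#' `max(ha_ts1, ha_ts0) - max(hn_ts1, hn_ts0)`: the query's best similarity
#' to any active reference minus its best similarity to any inactive
#' reference, each taken over both Tanimoto variants.
#'
#' @param ha_ts1,ha_ts0 highest present-/absent-bit similarity to an active.
#' @param hn_ts1,hn_ts0 highest present-/absent-bit similarity to an
#'   inactive.
#' @return Potency score(s) in `[-1, 1]`.
#' @export
potency <- function(ha_ts1, ha_ts0, hn_ts1, hn_ts0) {
  vals <- c(ha_ts1, ha_ts0, hn_ts1, hn_ts0)
  if (any(vals < 0 | vals > 1)) stop("similarities must lie in [0, 1]")
  pmax(ha_ts1, ha_ts0) - pmax(hn_ts1, hn_ts0)
}

#' Classify by thresholding a score
#'
#' Active if and only if the score strictly exceeds the threshold; a score
#' exactly at the threshold is called inactive.
#'
#' @param score numeric score(s), e.g. potency or hybrid scores.
#' @param threshold decision threshold (default 0).
#' @return Factor with levels `c("active", "inactive")`.
#' @export
classify_potency <- function(score, threshold = 0) {
  factor(ifelse(score > threshold, "active", "inactive"),
         levels = c("active", "inactive"))
}
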