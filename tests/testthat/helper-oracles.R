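# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's vectorized code paths.

# set-bit Tanimoto by direct counting
brute_ts1 <- function(x, y) {
  inter <- sum(x == 1 & y == 1)
  un <- sum(x == 1 | y == 1)
  if (un == 0) 0 else inter / un
}

brute_ts0 <- function(x, y) brute_ts1(1 - x, 1 - y)

# exhaustive nearest-reference similarities for one query
brute_nearest <- function(q, ref_matrix, labels) {
  act <- which(labels == "active")
  ina <- which(labels == "inactive")
  s1 <- apply(ref_matrix, 1, brute_ts1, x = q)
  s0 <- apply(ref_matrix, 1, brute_ts0, x = q)
  list(ha_ts1 = max(s1[act]), ha_ts0 = max(s0[act]),
       hn_ts1 = max(s1[ina]), hn_ts0 = max(s0[ina]),
       potency = max(max(s1[act]), max(s0[act])) -
                 max(max(s1[ina]), max(s0[ina])))
}

# trapezoidal area under an ROC curve given as (fpr, tpr) points
trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# random binary labeled dataset with no planted structure
random_dataset <- function(n_active, n_inactive, n_fp, p = 0.5) {
  n <- n_active + n_inactive
  m <- matrix(rbinom(n * n_fp, 1, p), nrow = n,
              dimnames = list(paste0("m", seq_len(n)),
                              paste0("FP", seq_len(n_fp))))
  labeled_dataset(m, rep(c("active", "inactive"), c(n_active, n_inactive)))
}

# dataset whose bit k is present in exactly a1 of the actives and i1 of the
# inactives (deterministic counts, not sampled)
counted_bit_dataset <- function(n_active, n_inactive, a1, i1) {
  bits <- c(rep(1, a1), rep(0, n_active - a1), rep(1, i1),
            rep(0, n_inactive - i1))
  m <- cbind(FP1 = bits)
  rownames(m) <- paste0("m", seq_along(bits))
  labeled_dataset(m, rep(c("active", "inactive"), c(n_active, n_inactive)))
}
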