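#' Configuration for the synthetic fingerprint generator
#'
#' Describes a labeled binary fingerprint dataset with planted structure:
#' `n_informative` bits whose per-class presence probabilities differ
#' (`p_active` vs `p_inactive`), the remainder drawn at `p_background` in
#' both classes, and optionally a fraction of actives generated as noisy
#' clones of other actives (bitwise flips at rate `epsilon`), emulating the
#' chemical-series redundancy that nearest-neighbour similarity methods
#' exploit in screening benchmarks. Optionally, `n_xor_pairs` bit pairs
#' carry a purely pairwise signal (actives have unequal bits in the pair,
#' inactives equal, each marginal at 1/2), invisible to single-bit ranking
#' but learnable by a kernel classifier.
#'
#' @param n_active,n_inactive class sizes.
#' @param n_fingerprints total number of bits.
#' @param n_informative number of planted single-bit signals.
#' @param p_active,p_inactive presence probabilities of informative bits in
#'   each class.
#' @param p_background presence probability of uninformative bits (both
#'   classes).
#' @param duplicate_fraction fraction of actives replaced by noisy clones
#'   of other actives.
#' @param epsilon per-bit flip rate used when cloning.
#' @param n_xor_pairs number of XOR-style informative bit pairs.
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_active = 1000, n_inactive = 1000,
                       n_fingerprints = 100, n_informative = 1,
                       p_active = 0.9, p_inactive = 0.1,
                       p_background = 0.3, duplicate_fraction = 0,
                       epsilon = 0.05, n_xor_pairs = 0, seed = 1) {
  probs <- c(p_active, p_inactive, p_background, epsilon,
             duplicate_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities and fractions must lie in [0, 1]")
  if (n_informative + 2 * n_xor_pairs > n_fingerprints)
    stop("more informative bits than fingerprints")
  if (n_active < 1 || n_inactive < 1) stop("class sizes must be >= 1")
  structure(list(n_active = n_active, n_inactive = n_inactive,
                 n_fingerprints = n_fingerprints,
                 n_informative = n_informative, p_active = p_active,
                 p_inactive = p_inactive, p_background = p_background,
                 duplicate_fraction = duplicate_fraction,
                 epsilon = epsilon, n_xor_pairs = n_xor_pairs,
                 seed = seed), class = "sim_config")
}

#' Generate a synthetic labeled fingerprint dataset
#'
#' Draws independent Bernoulli bits per the configuration, plants the
#' informative bits (and XOR pairs), clones the configured fraction of
#' actives with flip noise, and shuffles the row order. Deterministic for a
#' fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return List with `dataset` (a `labeled_dataset`), `informative`
#'   (names of the planted single bits), `xor_pairs` (list of name pairs)
#'   and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- cfg$n_fingerprints
  fp_names <- sprintf("FP%03d", seq_len(p))
  special <- sample(p, cfg$n_informative + 2 * cfg$n_xor_pairs)
  inf_idx <- special[seq_len(cfg$n_informative)]
  xor_idx <- if (cfg$n_xor_pairs > 0)
    matrix(special[cfg$n_informative + seq_len(2 * cfg$n_xor_pairs)],
           ncol = 2) else matrix(integer(), ncol = 2)

  draw_class <- function(n, p_inf) {
    m <- matrix(stats::rbinom(n * p, 1, cfg$p_background), nrow = n)
    if (cfg$n_informative > 0)
      m[, inf_idx] <- stats::rbinom(n * cfg$n_informative, 1, p_inf)
    m
  }
  A <- draw_class(cfg$n_active, cfg$p_active)
  I <- draw_class(cfg$n_inactive, cfg$p_inactive)
  if (nrow(xor_idx) > 0) {
    for (k in seq_len(nrow(xor_idx))) {
      u_a <- stats::rbinom(cfg$n_active, 1, 0.5)
      A[, xor_idx[k, 1]] <- u_a
      A[, xor_idx[k, 2]] <- 1L - u_a          # actives: bits disagree
      u_i <- stats::rbinom(cfg$n_inactive, 1, 0.5)
      I[, xor_idx[k, 1]] <- u_i
      I[, xor_idx[k, 2]] <- u_i               # inactives: bits agree
    }
  }
  n_dup <- round(cfg$duplicate_fraction * cfg$n_active)
  if (n_dup > 0) {
    if (n_dup >= cfg$n_active)
      stop("duplicate_fraction leaves no seed actives to clone from")
    clones <- seq_len(n_dup)                       # rows replaced by clones
    donors <- sample((n_dup + 1):cfg$n_active, n_dup, replace = TRUE)
    flips <- matrix(stats::rbinom(n_dup * p, 1, cfg$epsilon), nrow = n_dup)
    A[clones, ] <- (A[donors, , drop = FALSE] + flips) %% 2L
  }
  m <- rbind(A, I)
  rownames(m) <- c(sprintf("A%04d", seq_len(cfg$n_active)),
                   sprintf("I%04d", seq_len(cfg$n_inactive)))
  colnames(m) <- fp_names
  labels <- rep(c("active", "inactive"), c(cfg$n_active, cfg$n_inactive))
  ord <- sample(nrow(m))
  ds <- labeled_dataset(m[ord, , drop = FALSE], labels[ord])
  list(dataset = ds, informative = fp_names[inf_idx],
       xor_pairs = lapply(seq_len(nrow(xor_idx)), function(k)
         fp_names[xor_idx[k, ]]),
       config = cfg)
}

#' Closed-form MCC of a single planted bit
#'
#' Expected MCC of the rule "predict active iff the bit is set" when the
#' bit is present with probability `p_active` in actives and `p_inactive`
#' in inactives, computed from expected confusion counts.
#'
#' @param p_active,p_inactive per-class presence probabilities.
#' @param n_active,n_inactive class sizes (default equal).
#' @return Expected MCC in `[-1, 1]`.
#' @examples
#' analytic_single_bit_mcc(0.9, 0.1)  # 0.8
#' @export
analytic_single_bit_mcc <- function(p_active, p_inactive,
                                    n_active = 1, n_inactive = 1) {
  if (any(c(p_active, p_inactive) < 0 | c(p_active, p_inactive) > 1))
    stop("probabilities must lie in [0, 1]")
  tp <- p_active * n_active
  fn <- (1 - p_active) * n_active
  fp <- p_inactive * n_inactive
  tn <- (1 - p_inactive) * n_inactive
  .mcc_from_counts(tp, fp, tn, fn)
}
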