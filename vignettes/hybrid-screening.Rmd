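---
title: "Hybrid similarity and max-margin screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid similarity and max-margin screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potencyscreen)
```

## The problem and the model

Given a reference panel of molecules labeled active (anticancer) or
inactive, each described by a fixed-length binary fingerprint vector, we
want to score new molecules for likely activity. The package combines two
complementary signals:

* a **similarity signal** — active molecules often belong to chemical
  series, so a query resembling a known active (and not resembling any
  known inactive) is likely active;
* a **margin signal** — an RBF-kernel SVM can combine many weakly
  informative bits, including interactions, and is unaffected by whether
  the query is close to any single reference.

The potency score captures the first:
$P_s = \max(H^aT_{s1}, H^aT_{s0}) - \max(H^nT_{s1}, H^nT_{s0})$, where
$T_{s1}$ is the Tanimoto coefficient on set bits, $T_{s0}$ the same
coefficient on the complemented vectors (agreement on absent features),
and $H^a$/$H^n$ denote the best similarity to any active/inactive
reference. $P_s$ lies in $[-1,1]$ by construction; swapping the roles of
the two reference classes negates it. The hybrid score is the arithmetic
mean of the normalized potency and SVM scores.

Both scorers operate on a *selected* subset of fingerprints: each bit is
assessed as a standalone classifier via its compound score (the
class-mean difference, signed by bit presence), and bits whose best MCC
exceeds a cutoff are kept. This univariate filter assumes the useful
signal is visible marginally; purely interactive signals (e.g. an
XOR-style bit pair, which the synthetic generator can plant) are
invisible to it and survive only via `fixed_fingerprints` or a lowered
cutoff.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `mcc_cutoff` | 0.2 | keep fingerprints with standalone MCC strictly above this; strict `>` follows the selection rule's wording |
| `top_k` | unset | optional cap after ranking (MCC desc, accuracy desc, name asc) |
| `g` | 0.1 | RBF kernel width; the value at which the SVM performs best on the anticancer benchmark |
| `c` | 6 | soft-margin cost, same provenance |
| `j` | 1 | cost ratio of the active class (class weight) |
| `threshold` | 0 | decision threshold on potency/hybrid scores; equality is called inactive |
| `folds`, `repeats` | 5, 20 | stratified cross-validation protocol |

The margin scorer is specified by contract — an RBF max-margin binary
scorer with these parameters — and implemented with libsvm (`e1071`);
numeric equality with any particular SVM binary is not part of the
contract.

## Numerical choices and edge cases

* **Single-bit threshold sweep.** A bit's compound score takes at most
  two values, so the "sweep over all thresholds" is exact: midpoints of
  the distinct observed scores plus $\pm\infty$ sentinels. Ties in MCC
  are broken toward higher sensitivity, then lower threshold, for
  reproducibility. A constant column is flagged degenerate with MCC 0 and
  AUC 0.5.
* **Degenerate Tanimoto.** An all-zero pair (or all-one pair for
  $T_{s0}$) has an empty union; the similarity is defined as 0 — absence
  of shared evidence is not similarity — and flagged.
* **Boundary classification.** A score exactly at the threshold is
  inactive ("more than threshold" reads as strict).
* **MCC.** When a denominator factor is zero, MCC is 0 (the standard
  convention); on counts it equals the Pearson correlation of the binary
  label vectors, which the tests verify on random instances.
* **AUC.** Computed as the Wilcoxon rank statistic with midrank ties,
  identical to the trapezoidal area under the full-sweep ROC; `pROC`
  serves as an independent cross-check in the tests, not as the
  implementation.
* **Normalization.** Raw potency and SVM scores live on different
  scales, so each is affinely mapped from its observed training-set
  `[min, max]` to `[-1, 1]`; test scores outside the range are clipped
  and a degenerate calibration maps to 0. Min–max was chosen over rank or
  z-scaling because it is bounded, monotone (rank- and AUC-preserving)
  and cheap; the calibration is always fit inside the training fold, the
  only leakage-free choice.
* **Empty selection.** If no fingerprint clears the cutoff in some
  training fold (typical under label permutation), all fingerprints are
  kept rather than failing — the honest behaviour for null data.
* **Label sign convention.** libsvm orients decision values toward the
  first label it encounters; the trained model detects and stores the
  flip so positive always means active.

## Cross-validation protocol

Molecules are partitioned per repeat into five stratified folds
(stratification stabilizes per-fold class balance for the similarity
scorer; each molecule is in exactly one test fold per repeat, which the
tests assert). Inside every training portion the fingerprint selection,
the potency reference set, the SVM and both calibrations are refit from
scratch; the held-out fold only ever contributes query vectors. Test
scores are pooled per repeat, metrics are computed on a fixed threshold
grid ($-1$ to $1$ in steps of $0.2$) plus AUC, and the final report
averages repeats with standard deviations. The protocol description we
follow says both "repeated 20 times" and "average of 25-fold
cross-validations"; these cannot both be literal, so the default is 5
folds × 20 repeats with `repeats` configurable. Selection refit per fold
is the default (a single global selection inflates estimates slightly);
`fixed_fingerprints` reproduces the global-list variant.

## The synthetic generator

`generate_dataset()` emulates the statistical structure a screening
benchmark presents to this method: a minority of informative bits whose
presence probability differs between classes (`p_active` vs
`p_inactive`), a background of uninformative bits at `p_background`, and
— crucial for the similarity scorer — a fraction of actives generated as
noisy clones of other actives (`duplicate_fraction`, flip rate
`epsilon = 0.05`), mimicking chemical-series redundancy. Optional
XOR-style bit pairs supply a margin-only signal. It does **not** emulate
real fingerprint bit correlations induced by chemistry (nested
substructure keys are strongly dependent), class imbalance drift, or
assay noise in the labels; green tests on synthetic data therefore
demonstrate correctness of the machinery and sane statistical behaviour,
not performance on real screening data.

Closed-form expectations back the recovery tests:
`analytic_single_bit_mcc(0.9, 0.1)` is exactly 0.8, and with 1000
molecules per class the empirical estimate of a planted 0.9/0.1 bit lands
within a few binomial standard errors of it.

## Problem sizes

The test suite and the acceptance script run at sizes chosen to exercise
every code path while completing in minutes on one core: oracle
equivalences on ~1000 random instances each, recovery at 1000 molecules
per class, and the full pipeline (selection → potency + SVM → hybrid,
5-fold × 5 repeats) at 2000 molecules × 100 bits, where the
cross-validated hybrid MCC at threshold 0 exceeds 0.7 by a wide margin
and collapses to ~0 (AUC ~0.5) under label permutation.

## Scope and limitations

* Native fingerprint computation covers a MACCS-type key set (166 keys)
  and a substructure key set (307 functional-group patterns) via Open
  Babel. The original benchmark's 9365 bits came from PaDEL's ten
  fingerprint families; those are treated as *data* — any named binary
  columns can be imported with `read_fingerprint_table()` — so full-scale
  replication requires regenerating PaDEL output for the external
  benchmark (the 8565/9804 NCI-60-derived set), which is an optional,
  download-gated workflow, not part of the test suite. Which 126 bits
  pass the 0.2 cutoff there is only checkable with that dataset.
* Count-valued fingerprint families are out of scope; all equations
  assume bits.
* The functional-group vocabulary ships as an editable SMARTS file; the
  exact definitions used by any particular perception toolkit are not
  reproduced, so per-group frequencies are comparable within this
  package, not across toolkits.
* Whether $T_{s0}$ means Tanimoto on complemented vectors is a reading;
  it is the natural one and is implemented bit-exactly as such
  (`tanimoto_absent(x, y) == tanimoto_present(1-x, 1-y)` is a tested
  identity).
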