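---
title: "Predicting DNA N4-methylcytosine sites from sequence windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA N4-methylcytosine sites from sequence windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

N4-methylcytosine (4mC) marks the exocyclic amino group of cytosine and is
widespread in bacteria, where it participates in restriction–modification
defence; it also occurs in model eukaryotes such as *C. elegans* and
*D. melanogaster*. Experimental mapping (SMRT kinetics) is costly, so a
standard computational formulation has emerged: classify a fixed-length,
cytosine-centred DNA window (41 nt throughout this package) as containing
a 4mC site at its centre or not. Training data are balanced sets of
positive and negative windows; evaluation uses sensitivity (Sn),
specificity (Sp), accuracy (ACC), Matthews correlation (MCC) and ROC/AUC.

`meth4c` implements one complete predictor of this family: a
292-dimensional sequence encoding, boosted-tree importance ranking,
backward-elimination feature selection under cross-validated SVM accuracy,
and a grid-searched RBF-kernel SVM with calibrated probabilities.

## The feature space

Five encoder families are concatenated in a fixed order; for a 41-nt
window the blocks are D1–D164, D165–D205, D206–D225, D226–D273, D274–D292
(292 total).

**One-hot binary (OHB, 4L = 164 dims).** Each position contributes a 4-bit
indicator with the convention A=(1,0,0,0), G=(0,1,0,0), T=(0,0,1,0),
C=(0,0,0,1). This is the fully positional code: a per-position motif
appears here as a handful of high-importance bits.

**Sequential nucleotide frequency (SNF, L = 41 dims).** Entry *i* is the
frequency of the nucleotide at position *i* among positions 1..*i*,
current position included, so `d_1 = 1` and `d_i ∈ [1/i, 1]`. For
`AACGTACT` this gives (1, 1, 0.33, 0.25, 0.2, 0.5, 0.29, 0.25). Note the
definition forces the second entry of a repeated leading base to be 1,
not 0.5: the count includes the current position, and the package applies
the definition literally and consistently.

**k-nucleotide frequency (KNF, 20 dims).** Frequencies of contiguous
k-mers, `C(n_1..n_k)/(S−k+1)`, lexicographic over (A,C,G,T), for
k ∈ {1,2} (4 + 16 = 20 dims — the unique k-set compatible with the
20-dimension block). Each k-block sums to 1.

**k-spaced nucleotide pair frequency (KSNPF, 48 dims).** Frequencies of
ordered pairs separated by exactly k intervening bases (`AxxT` has k = 2),
`C(n_1 X..X n_2)/(S−k−1)`, 16 dims per k, for k ∈ {1,2,3} (the unique
k-set compatible with the 48-dimension block). Each 16-block sums to 1.

**Pseudo dinucleotide composition (PseDNC, 16 + λ dims, λ = 3).** The
16 dinucleotide frequencies `f_k` augmented with tier correlations

θ_j = mean over i of Θ(i, i+j),  Θ(i, i+j) = mean over properties u of
[P_u(R_i R_{i+1}) − P_u(R_{i+j} R_{i+j+1})]²,

where `P_u` are per-property standardized values of 38 dinucleotide
physico-chemical properties. The full vector is divided by
`Σf + w·Σθ` (weight `w = 0.05` by default), so it sums to 1.

Three notational conventions deserve a note, because the common
shorthand in this literature is ambiguous: the averaging index μ in Θ is
the number of properties (38), not the sequence length; the correlation
compares positions *i* and *i+j*; and the tail entries are
`w·θ_{k−16}` over the same denominator. These are the standard PseDNC
definitions and the only readings under which the vector is well-defined
and normalized.

### The property table is a labelled stand-in

The 38 property *names* shipped in
`inst/extdata/dinucleotide_properties_synthetic.tsv` are the canonical
dinucleotide property set, but the *values* are synthetic (seeded random
draws, standardized per property). The measured table is supplementary
material we do not redistribute. Every property of the encoding that this
package tests — dimension count, ordering, non-negativity, sum-to-1,
degenerate-table behaviour — is invariant to the actual values; only the
numerical PseDNC coordinates (19 of 292 dimensions) change. Users with
the real table can pass it via `dinucleotide_properties(path)`.

## Importance ranking

A gradient-boosted tree ensemble (binary logistic loss) is fit once to
the full labeled matrix, and each dimension is scored by **weight**
importance: the number of times it is chosen as a split variable. The
boosting hyperparameters are not dictated by the problem, so we use the
common library defaults of the era — 100 rounds, maximum depth 6,
learning rate 0.3, L2 regularization 1 — exposed in `boost_config()`.
The implementation (in C++) is deliberately deterministic: no row or
column subsampling, single-threaded histogram construction (256 quantile
bins), first-feature/first-bin tie-breaking. Identical inputs give
identical scores; ties in the final scores are broken by ascending
dimension index; zero-score dimensions rank last. `gain` and `cover`
importances are recorded and selectable but not default.

The ranking is computed **once** on the full feature space and reused for
every elimination step; it is not re-fit after each removal. This mirrors
the single ranking stage of the published design and is the root of the
selection-bias caveat discussed below.

## Feature selection

`backward_eliminate()` walks prefixes of the ranking from all 292
dimensions down to `min_size = 1`, dropping the lowest-ranked dimension
each step (`stride` allows coarser traces for quick runs). Every prefix
is scored by stratified 10-fold cross-validation with an RBF SVM at fixed
parameters `C = 1`, `γ = 1/|subset|`; fold assignment is fixed once per
run, so steps are comparable. The criterion is pooled CV accuracy, with
ties broken by higher MCC and then by the smaller subset. The full
(C, γ) grid search runs only on the final subset: the heavyweight
alternative — a nested grid per subset per fold — would multiply the cost
by ~300 and is not what a single published ranking-plus-CV loop implies.

Implementation note: because removing a dimension only subtracts a
rank-one term from the pairwise squared-distance matrix, the elimination
maintains per-fold distance matrices incrementally; a full 292-step,
10-fold trace on 400 samples runs in seconds. The incremental path is
tested for exact agreement against direct `evaluate_subset()` calls.

### Feature-selection bias, measured

Ranking on the *same* data that the elimination CV evaluates means the CV
estimate of a small ranked prefix is optimistically biased even when the
data contain no signal: the ranking has already seen the held-out folds
and promoted dimensions that happen to correlate with labels by chance.
On signal-free tables (n = 400, 100 noise dimensions) we measure pooled
CV accuracies of 57–64% for small prefixes of a same-data ranking, while
the same subset sizes chosen by a ranking fit on *independent* null data
sit at 48–51%. This is the classic selection-bias phenomenon and a
property of the procedure, not of the implementation; any booster with
comparable capacity overfits noise the same way. Consequences:

- the elimination trace is a *relative* guide for choosing a subset, not
  an unbiased performance estimate;
- honest performance numbers must come from `independent_test()`, which
  re-runs ranking and selection inside the training partition only (its
  null-data test accuracy is centred on 50%, as verified in the tests);
- the acceptance check asserting that null traces stay within 50 ± 5
  accuracy points at every step fails by design and is documented as such
  rather than weakened.

## The classifier

The SVM dual is solved by SMO (maximal-violating-pair with second-order
working-set selection, stopping tolerance 1e-3) on a precomputed RBF
kernel. The hyperparameter grid follows the published exponent ranges,
read as multiplicative steps of 2: C ∈ {2⁻⁵..2¹⁰} (16 values),
γ ∈ {2⁻¹⁵..2²} (18 values); ties prefer smaller C, then smaller γ.
Features are passed to the kernel as encoded — all encoder outputs
already live in [0,1], so no re-scaling is applied.

Probability outputs use Platt scaling — a sigmoid
`P(y=1|f) = 1/(1 + exp(A f + B))` fit by damped Newton iteration on
out-of-fold decision values (5 internal folds, seed-fixed) to avoid
optimistic calibration. The predicted label is 1 iff the probability is
**greater than or equal to** the 0.5 threshold (boundary assigned to the
positive class, documented convention). During subset evaluation, labels
come from the decision-value sign instead; this is the uncalibrated
equivalent and saves a factor of ~6 in the elimination loop.

## Evaluation

`compute_metrics()` implements Sn, Sp, ACC (percent, full precision;
round only for display) and MCC, with MCC defined as 0 when a
denominator factor vanishes. `roc_auc()` traces all distinct thresholds
and integrates trapezoidally, which equals the pairwise-ranking
probability with half credit for ties (tested against a brute-force
pairwise oracle). `kfold_cv()` pools per-fold predictions into one
confusion table — so TP+FN equals the full positive count, matching how
published cross-validation tables are laid out — and also reports
per-fold metrics. `independent_test()` refuses overlapping train/test
ids (leakage guard) and fits every stage on the training set only.

## Synthetic data: the stated world

`generate()` draws 41-nt windows with a forced centre C. Negatives are
uniform background (0.25 each base). Positives interpolate the background
toward a 5-position consensus motif at offsets −3..−1, +1, +2 around the
centre (consensus G, A, G, G, T), with `effect_strength` the
interpolation weight; the default 0.8 gives each motif position an 85%
consensus probability versus 25% in negatives — a strong, learnable but
imperfect signal, the regime the benchmark species' sequence logos
suggest around real 4mC sites. Five biased positions is the smallest
structure that makes the encoder families differentially informative
(OHB/SNF positional, KNF/KSNPF compositional).

`generate_feature_table()` bypasses the encoders: informative dimensions
are unit-variance Gaussians whose class means differ by `effect` standard
deviations; noise dimensions are identically distributed in both classes.
For selection-recovery experiments we use `effect = 1`: each informative
dimension alone classifies at only ~69% (Bayes), but the ten together
reach ~94%, so a selector must keep *all* of them — at `effect = 3` a
single dimension nearly suffices and "recovering 10/10" would be
meaningless. For power tests of the classifier we use `effect = 3`.

What a green test on these worlds does **not** establish: performance on
real genomes (composition bias, repeats, species-specific motifs,
ambiguity codes), robustness to class imbalance, or the value of the
PseDNC block under the real property table.

## Numerical and design choices

- Coordinates are 1-based in all user-facing ids; `extract_windows()`
  scans the forward strand only and skips cytosines with insufficient
  flanks (no padding).
- Non-ACGT characters are a hard error with an opt-in skip mode; encoder
  definitions are meaningless for ambiguity codes.
- Stratified folds are dealt round-robin after a seeded within-class
  permutation; every CV consumer shares this helper, so a seed pins the
  entire pipeline.
- SMO convergence tolerance 1e-3 with a 200k-iteration cap; bias from
  free support vectors when any exist, else the KKT-band midpoint.
- Boosted-tree split gain uses the second-order formula with a strict
  1e-12 improvement margin, making tie-breaking stable across platforms.
- All frequencies are kept at full floating precision; the published
  two-decimal displays are truncations and are compared as such in tests.

## Known limitations

- The shipped PseDNC property values are synthetic (see above).
- The elimination trace is biased upward at small subset sizes whenever
  ranking and evaluation share data; use the independent test for honest
  estimates.
- Reverse-strand scanning, class imbalance handling, and non-41-nt
  transfer are out of scope.
- The SMO solver precomputes the full kernel; practical up to a few
  thousand windows, not genome scale.
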