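---
title: "Library-free peptide detection in DIA data: model and methods"
author: "diadetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Library-free peptide detection in DIA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The detection model

Data-independent acquisition fragments everything inside a wide
isolation window at once, so an MS2 spectrum is a superposition of
several peptides' fragment ions plus background. `diadetect` treats
detection as scoring the edges of a bipartite graph between the MS2
spectra of one run and the charged peptides of a sequence database: an
edge exists when the peptide's theoretical precursor m/z lies inside the
spectrum's isolation window (a closed interval — a boundary precursor
belongs to both adjacent windows), and carries all the evidence relating
that spectrum to that peptide. A conventional one-peptide-per-spectrum
search would keep only the best match; here the top `top_k = 5` matches
per spectrum *and per charge state* (charges 1–5) are kept, because a
wide window genuinely contains several detectable peptides.

### Primary score and its calibration

The primary score is the SEQUEST cross-correlation in its fast
formulation: square-root intensities are binned on a 1.0005079 Th grid
(offset 0.4; 0.02 Th is appropriate for high-resolution fragment
spectra), ten equal m/z regions are normalized to a common maximum of
50, and each bin has the mean of its ±75 neighboring bins subtracted, so
that the dot product with the unit-intensity theoretical b/y-ion bins
equals corr(0) minus the mean of corr(τ) over τ = ±1..±75. The test
suite verifies this identity against a direct cross-correlation oracle
to 1e-9.

Raw XCorr is spectrum-dependent, so each edge is calibrated by the
spectrum- and charge-specific score at sorted position [N/100] (N = all
candidates scored for that spectrum and charge, before top-k
truncation; [·] rounds half away from zero and is floored at position
1). This "divide by the 99th-percentile score" calibration makes scores
comparable across spectra; when N < 100 the divisor clamps to the top
score and calibrated scores are ≤ 1. Candidates are counted per charge
state, matching the per-charge candidate lists of the search; the
divisor therefore reflects the same score distribution the edge competed
in. Two rank-gap features (`delta_cn`, `delta_lcn`, the relative score
drop to the next and to the last retained candidate) and the charge
complete the search-engine feature block.

### Auxiliary evidence features

Four additional features each quantify one independent line of
evidence. Natural logarithms are used throughout; the base only rescales
features linearly and is absorbed by the aggregate weights and the
reranker.

**Precursor isotope intensity rank (w^P ≤ 0).** For the monoisotopic,
M+1 and M+2 m/z values (spacing 1.00335483/charge, the ¹³C–¹²C mass
difference; configurable to exactly 1 for a literal unit-spacing model),
the maximum MS1 intensity within tolerance is converted to its rank
among all peak intensities of the survey scan, counting with ≥ so tied
intensities share the worst rank of the tie group. The score is minus
the sum of the three log-ranks. A query with no matching peak takes
intensity 0 and hence the worst possible rank: undetectable precursor
signal is a finite penalty, never a veto — this is what lets peptides
with suppressed MS1 signal survive to the reranker on the strength of
their fragment evidence.

**Fragment-matching P-value (w^F ≥ 0).** The spectrum's m/z range is
split into 10 equal segments keeping the 10 most intense peaks each
(half-open segments, the last closed; this peak picking exists only
inside this feature). The chance of one theoretical fragment matching by
luck, p_u, is the length of the union of ±τ intervals around the picked
peaks divided by the padded observed range (overlaps merged, capped at
1). With N_v theoretical fragments of which N_{u,v} match, the score is
the negative log upper tail of Binomial(N_v, p_u) at N_{u,v}, computed
in log space. Degenerate inputs (fewer than two picked peaks, no
fragments, p_u = 1, no matches) score 0 — uninformative, not negative
evidence.

**Retention-time agreement (w^R ∈ [−1, 0]).** The observed proxy is the
scan cycle; both it and the predicted retention time are converted to
normalized ranks (fraction of values ≤ the query) within their
populations — observed ranks pooled over all MS2 spectra of the run,
predicted ranks over all precursors with predictions — and the score is
minus their absolute difference. The default predictor is a
residue-coefficient hydrophobicity sum (Krokhin-style C18 scale) that
understands oxidized methionine; a two-column TSV predictor can replace
it. Peptides the predictor cannot handle fall back to −0.5, the
midpoint penalty. Decoys are predicted on their own shuffled sequence:
the decoy must be treated exactly like a plausible target, and its
hydrophobicity genuinely differs from its target's after shuffling.

**Precursor/fragment coelution (w^E ∈ [0, 1]).** Elution profiles are
extracted over ±2 scan cycles: the precursor's from the MS1 scans at its
m/z, each fragment's from the same-window MS2 scans at the fragment m/z
(per-scan value = maximum intensity within tolerance; cycles outside the
run contribute 0). The score is the mean of the 3 largest inner products
between the L2-normalized precursor profile and the L2-normalized
fragment profiles (mean of all when fewer than 3 fragments; a zero-norm
profile contributes 0). The precursor profile is taken from the full MS1
scans rather than any window restriction — survey scans are not
window-multiplexed, so there is nothing to restrict.

### Aggregation, filtering and reranking

All five features (including the calibrated XCorr) are linearly rescaled
so their empirical 1st and 99th quantiles (linear interpolation between
order statistics, R type 7) map to 0 and 1, without clamping; a
degenerate feature maps to the constant 0.5. The scaler is fitted on all
edges, targets and decoys alike, keeping the transform label-blind. The
aggregate score is w = w^T + α^P w^P + α^F w^F + α^R w^R + α^E w^E with
non-negative weights; within each spectrum-charge group, edges whose
aggregate score is below that of the group's top-XCorr edge are
discarded (the reference edge always survives, so no group empties).
Shipped default weights are (α^P, α^F, α^R, α^E) = (0.8, 0.1, 0.8, 0.8);
`grid_search_alphas()` re-derives weights on labeled data over the grid
{0, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4, 12.8} per weight, by
exhaustive or coordinate search with a lexicographic-smallest tie-break.
Masking weights to zero (`feature_mask`) supports ablation experiments.

Surviving edges go to a semi-supervised reranker that follows the
Percolator protocol: target/decoy pairs are hashed into 3
cross-validation folds — a pair's edges never span folds, closing the
leakage channel where a decoy trains the model that scores its own
target — and per fold the model is initialized with the single best
feature direction, then iterated 10 times taking as positives the target
edges at internal q ≤ 0.01 and as negatives all decoy edges. The
classifier is an L2-regularized squared-hinge linear SVM solved exactly
in the primal by active-set Newton iterations; with eight standardized
features the solve is direct, deterministic and fast, and its
regularization cost is chosen from {0.1, 1, 10} by nested validation
between the two training folds. Held-out scores are rank-normalized
within each fold before merging. A fold with no identifiable positives
falls back to ranking by the calibrated XCorr and is flagged.

### Competition and error control

Because spectrum-level competition is meaningless when one spectrum
legitimately matches several peptides, competition happens at the
precursor-pair level: among all edges of a target peptide and its paired
decoy — across all charge states and spectra — only the best-scoring
edge survives, and its label decides whether the pair contributes a
target or a decoy. A pair is a (sequence, modification set) unit;
charge remains a feature, and the output is one record per pair. Score
ties break toward the decoy, the conservative direction. FDR at
threshold τ is min(1, #decoys > τ / max(1, #targets > τ)); a peptide's
q-value is the minimum FDR over thresholds accepting it. The
implementation is checked exactly against a brute-force
enumerate-all-thresholds oracle.

Decoys are built by shuffling each target's internal residues with the
terminal residues fixed, preserving mass, composition and the enzymatic
terminus; collisions with target sequences are reshuffled a bounded
number of times and then fall back to internal reversal, and
modifications travel with their residues. Targets too short to shuffle
yield flagged self-identical decoys.

For method evaluation the package also implements pseudo-target
(entrapment) calibration: the target database is doubled with disguised
decoys generated from an independent seed, the pipeline runs normally
(building its own internal decoys), and FDR is re-estimated from the
hidden labels with the same formula. Nominal and pseudo-target q-values
are returned side by side.

## The synthetic-data generator

`simulate_run()` exists so that every stage is testable without
downloads. It emulates: repeated scan cycles of one MS1 scan plus a
sweep of wide windows (default 24 × 25 m/z over 400–1000); a random
present subset of the digested database (default ~15%) with log-normal
abundances; Gaussian elution profiles (σ = 2 cycles) with apex cycles
that follow the default retention predictor plus Gaussian noise of σ =
3% of the gradient — informative but deliberately imperfect, so w^R
helps without deciding; isotope envelopes M/M+1/M+2 with
Poisson-in-mass (averagine-style) ratios, since only their relative
ranks matter to w^P; per-fragment random efficiencies; uniform-m/z
log-normal noise peaks in every scan; Gaussian m/z jitter (3 ppm); and
an optional fraction of present peptides with fully suppressed MS1
signal. Runs can be serialized to standard mzML together with the FASTA
and a ground-truth table.

It does **not** emulate chimeric structured noise, overlapping
charge-state envelopes, interference between co-eluting isobaric
peptides, intensity-dependent mass error, or instrument-specific peak
shapes. Passing tests on these simulations therefore demonstrate the
correctness and calibration of the machinery under idealized,
known-truth conditions — not detection performance on real instrument
data.

One consequence of simulating from a digested database: missed-cleavage
and modification relatives of a present peptide share most of their
fragment ions with it, and the pipeline can legitimately detect them.
Evaluation against ground truth therefore uses a sequence-overlap
convention — a detection is counted true when its sequence equals,
contains, or is contained in a planted sequence. Measured this way, the
empirical false discovery proportion at q ≤ 0.01 stays below the
nominal level in the test suite, and runs with no planted peptides
accept ~1% of targets or fewer.

## Numerical choices and conventions

- [N/100] uses round-half-away-from-zero (so N = 250 gives position 3),
  with position floored at 1; a non-positive divisor flags the edge and
  sets w^T = 0.
- Top-k ties break by higher XCorr, then lexicographically smaller
  peptide, then target before decoy — full determinism under a fixed
  seed is asserted in the tests.
- The aggregate uses the *rescaled* w^T, consistent with all five scores
  being quantile-rescaled before weighting.
- Noise reduction (off by default; intended for noisier
  quadrupole-TOF-style data) removes an MS2 peak unless the same-window
  scan of a neighboring cycle has a peak within tolerance; the match
  interval [q(1−t), q/(1−t)] is symmetric in the two peaks, which makes
  the operation provably idempotent. Its tolerance defaults to the
  fragment tolerance. First and last cycles use their single neighbor.
- Tolerances are ppm everywhere by default (10 ppm; 30 ppm is the
  sensible choice for TripleTOF-class data), with Th-based tolerances
  supported in the fragment-matching feature.
- Digestion cleaves after K/R including before proline by default
  (configurable), bounds peptides to length 7–50 and mass 200–6000 Da,
  and deduplicates across proteins.
- b/y ions only, singly charged, plus doubly charged when the precursor
  charge is ≥ 3; no neutral losses or a-ions.

## Problem sizes

The test suite and the acceptance script run entirely on simulated
data: the end-to-end checks use a ~2000-peptide database (14 proteins of
300 residues) over 24 × 25 m/z windows and 40 cycles with ~15% of
peptides present, the null-calibration checks use 20 smaller runs
(~450 competed pairs each) with nothing present, and the oracle checks
sweep 200 random spectra × 20 fragment sets (XCorr), the full binomial
grid up to N_v = 30, and 1000 random score lists (q-values). These sizes
were chosen so the whole suite completes in a few minutes while keeping
every estimate's Monte-Carlo error well inside the asserted bounds.

## Known limitations

- The reranker reproduces the Percolator *protocol*, not its exact
  solver or its hyperparameter schedule; absolute scores differ, the
  semantics (semi-supervised CV reranking with pair-atomic folds) do
  not.
- The default retention predictor is a deliberately simple
  hydrophobicity sum; for real chromatography a learned predictor
  (supplied as a TSV table) is strictly better.
- Protein-level inference, quantification, and spectrum-level reporting
  are out of scope; the output is a ranked peptide list.
- XCorr binning replicates the standard fast formulation but not any
  specific engine's flanking-peak heuristics byte for byte.
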