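---
title: "Predicting sumoylation sites: model, data handling, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sumoylation sites: model, data handling, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The problem and the model

Sumoylation attaches a SUMO protein to specific lysines. The recognition
signal is partly local sequence: a large hydrophobic residue immediately
upstream of the lysine and a glutamate two positions downstream (the ψKxE
consensus) mark most known sites, but a substantial minority of real sites
lack the consensus and many consensus matches are never modified. We
therefore treat site prediction as binary classification of
lysine-centered sequence windows.

A window is the 25-mer centered on the candidate lysine (half-width
n = 12, wide enough to cover the ~10-residue acidic stretch that extends
the core motif in one of its known variants). Positions that fall outside
the protein are padded with the artificial letter `O`, giving a 21-letter
alphabet. Eight encoders map a window to a numeric vector; their
dimensions are fixed contracts asserted in the tests (one-hot 504, CKSAAP
2205, reduced alphabets 144/216, Z-scales 120, hydrophobicity-augmented
one-hot 508, profile rows 500, nearest-neighbour ratios 6).

The classifier is a soft-margin SVM with RBF kernel. The decision function
is the raw margin, so fixed cutoffs are meaningful operating points; we
use −0.2 / 0 / +0.2 (low/medium/high), which produce nested positive call
sets by construction.

## Parameters that matter

* **C** (regularization) and **gamma** (RBF width): no published values
  exist for this task, so `grid_search()` offers exhaustive selection by
  mean cross-validated MCC over a libsvm-style grid
  (C ∈ 2^{−5..15}, γ ∈ 2^{−15..3}, odd powers), with deterministic
  smaller-C-then-smaller-γ tie-breaks. Where a fixed default is needed
  (CLI, acceptance benchmarks) we use C = 8 and γ = 1/d (d the feature
  dimension), the scale at which RBF distances on one-hot features are
  neither saturated nor flat; the synthetic-recovery benchmark is
  insensitive to ±2 octaves around this point.
* **Negative:positive training ratio** (default 1:10): curated corpora run
  near 1:25; subsampling to 1:10 is the published operating choice this
  package reproduces, and `ratio_sweep()` regenerates the selection curve.
* **Identity threshold** (default 0.40): greedy single-pass filtering in
  dataset order, positives listed first so they are preferentially
  retained. "Identity" is ungapped positional identity over the aligned
  25-mers — the windows are equal-length and centered, so no alignment is
  needed; `O` matching `O` counts as a match.
* **Hydrophobicity tail**: the four extra features cover offsets −1..+2
  around the lysine — the hydrophobic recognition region — and are used on
  their raw scale (kcal/mol vacuum-to-water transfer values) by default,
  since nothing in the method's description implies rescaling. A
  `scale = TRUE` flag divides by the largest absolute scale value for
  users who want the tail bounded like the one-hot block.

## Numerical choices

* **SMO solver**: maximal-violating-pair working-set selection with the
  second-order refinement used by libsvm, stopping at KKT gap < 1e-3, full
  precomputed kernel matrix (training sets here are a few thousand rows).
  `rho` is averaged over free support vectors, with the bound-midpoint
  fallback. The two-point problem has a closed-form dual solution
  (α = 1/(1−k), ρ = 0) that the tests assert; determinism is bitwise.
* **Normalized BLOSUM62**: the 20×20 integer matrix min–max rescaled to
  [0,1] globally (not per-row), then extended by sim(O,O) = 1,
  sim(O,x) = 0. A consequence worth knowing: a fragment's distance to
  itself is not 0, because BLOSUM62 diagonal entries are not all the
  global maximum. Nearest-neighbour features remain well-behaved (the
  self-match is still each fragment's minimum), and reference-set
  encodings exclude the query fragment by index, never by string equality.
* **Degenerate MCC**: when any factor of the denominator is zero the MCC
  is reported as 0 with a `degenerate` flag rather than NaN.
* **ROC**: one point per distinct score; trapezoidal AUC, which equals the
  Mann–Whitney pair-ordering statistic with half-credit ties (property
  tested against an O(n²) oracle).
* **Cross-validation**: folds are stratified within class (ratio preserved
  to ±1 sample); metrics come from pooled out-of-fold scores at cutoff 0.
  For the KNN encoding, reference sets are restricted to the training fold
  so no label information leaks into held-out features.
* **LOO granularity**: leave-one-out removes one *sample* per round.
  Grouped (per-protein) leave-out is a different estimator and is out of
  scope here; site-level LOO is what the reported protocol describes.

## The synthetic world

`generate_proteome()` draws protein sequences (uniform background by
default; a Swiss-Prot-like composition preset is included) and plants
positive lysines with the ψKxE context: ψ sampled uniformly from
{V,I,L,M,F}, any +1 residue, E at +2. Defaults encode the stated world of
the curated corpora: ~1:25 lysine imbalance and 26% of positives planted
*without* the consensus context, mirroring the observed non-consensus
share of real sites.

Two deliberate design choices:

* **`clean_negatives = TRUE`**: background lysines that acquire the
  consensus context by chance (~1.2% of negatives under a uniform
  background) are rewritten (the +2 glutamate becomes glutamine). With
  random backgrounds the planted labels would otherwise be irreducibly
  ambiguous — a chance-consensus negative is statistically identical to a
  planted positive — and no classifier could reach the separability bar
  the recovery benchmark sets. Disable it for a harder, more honest-to-
  biology world.
* **Separability benchmarks use `nonconsensus_frac = 0`**: non-consensus
  positives carry no learnable signal by construction, capping achievable
  sensitivity near 74% under the default. The recovery criterion is a
  check that the pipeline finds a planted signal, so its world plants the
  signal in every positive. The default stays 0.26 because every *other*
  use of the generator benefits from the realistic hard fraction.

What a green recovery test establishes: windows → features → SMO →
cross-validation plumbing is correct end to end, with no label leakage.
What it does not establish: performance on real proteomes — real negatives
are not consensus-free, real positives share evolutionary correlations
that random backgrounds lack, and redundancy structure is absent.
Published-corpus reproduction is implemented separately and runs only when
the original corpus files are supplied (they are not redistributable with
the package; see the acceptance test file's header).

## Known limitations

* The profile (`pssm`) encoder consumes precomputed PSI-BLAST ASCII
  profiles; running the profile search is out of scope, and the CLI cannot
  train or predict with this scheme from fragment lists alone.
* The exact removal order of the published 40% redundancy filter is
  unrecoverable from its description, so filtered counts on the published
  corpus need not match 358/8071 exactly; the filter here is deterministic
  (greedy keep-first, positives first) and idempotent.
* Kernel matrices are held in memory; practical ceiling is roughly
  10–15k training fragments — ample for this task's corpora.
* The model archive is an RDS bundle with a format-version tag, not a
  cross-language format.
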