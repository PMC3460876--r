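---
title: "Physicochemical distance transformation: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physicochemical distance transformation: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdtransform)
```

## The problem and the model

Remote homologs — proteins related at the superfamily level — typically
share too little sequence identity for alignment to find them, while their
fold, and with it the *arrangement* of physicochemical character along the
chain, is conserved. Composition-based vectorizations (k-mer spectra,
amino-acid frequencies) are cheap but discard sequence order entirely;
alignment and profile kernels keep order but at a large computational cost.

The physicochemical distance transformation (PDT) sits between the two.
For a protein $A_1 A_2 \dots A_L$, an amino-acid property scale $j$ and a
lag $\lambda$, define

$$\mathrm{PDT}(j,\lambda) \;=\; \frac{1}{L-\lambda}\sum_{i=1}^{L-\lambda}
\bigl(I_j(A_i) - I_j(A_{i+\lambda})\bigr)^2 ,$$

where $I_j$ is the scale z-normalized over the 20 standard residues with
the *population* standard deviation (the mean runs over exactly those 20
values, so the divisor is 20; this is a fixed per-scale rescaling chosen
for reproducibility). The feature vector stacks $\mathrm{PDT}(j,\lambda)$
for every retained scale and $\lambda = 1 \dots \beta$. Its length is
$N\beta$ regardless of $L$ — which is the point: variable-length chains
become comparable fixed-length vectors, yet unlike composition features the
value at lag $\lambda$ reacts to the *order* of residues. A property
arranged with period $p$ produces a large component at $\lambda = p$ (pairs
$p$ apart straddle the high/low phases) and a depressed component at
$\lambda = 2p$ (pairs match in phase). Every component is a mean of squares,
hence finite and non-negative, and zero exactly when the property is
constant across all pairs at that lag.

Assumptions worth keeping in mind: the transform sees only *pairwise*
property contrast at fixed lags (no triplet or gapped patterns); averaging
over the whole chain means a signal confined to a short segment is diluted
in long proteins; and all scales contribute equally — no scale selection is
performed, discrimination between scales is left to the classifier.

## Parameters

* **`beta`** (maximum lag, default 8): lags $1\dots\beta$ are included.
  $\beta$ must not exceed $L-1$ for the shortest sequence transformed.
  On the standard SCOP 1.53 remote-homology benchmark, performance rises
  steeply up to $\beta \approx 4$ and plateaus; 8 is the published optimum
  and our default. Units: residues.
* **Index set**: any AAIndex1 flat file. Scales with missing values or
  all-zero entries are unusable and dropped by `filter_indices()` (544
  entries → 531 usable in AAIndex1 v9; the exact survivor set depends on
  the database version, the filtering rules are authoritative). Feature
  layout is index-major, λ-minor in surviving *file order* — the order is
  part of the vector definition, so models and feature files record it.
* **`n_max`** (profile mode, 1 or 2): how many frequency ranks of the
  profile are turned into sequences and transformed; vector length becomes
  $N\beta n_{\max}$. Ranks beyond 2 carry little signal.
* **Pseudo-count weight** $\beta_{pc} = 10$ (the PSI-BLAST constant) and
  the observed-frequency weight $\alpha = (\text{distinct residues in the
  column}) - 1$: a single-residue column ($\alpha = 0$) draws its target
  frequencies entirely from the pseudo-counts.
* **SVM cost `C`** (default 10) and kernel: quadratic $(1 + x\cdot y)^2$ or
  RBF with median-pairwise-distance width by default. Per-family kernel
  choice uses 5-fold cross-validated ROC on training data only — the
  original study reports the outcome of its per-family selection but not
  the procedure, so the procedure is pinned here.

## Numerical and design choices

**Squared-difference pairing term.** The pairwise factor is pinned as
$(I_j(a)-I_j(b))^2$ — the standard sequence-order-correlation factor. Any
fixed positive rescaling of it would be absorbed by feature
standardization and kernel scaling and cannot change ROC; only worked
example values depend on the choice.

**Cosine normalization of inputs, not of the kernel matrix.** Features are
standardized (z-score fitted on the training split — index blocks have
heterogeneous scales) and then scaled to unit length before the kernel
applies. For a linear kernel this equals the usual
$K_{ij}/\sqrt{K_{ii}K_{jj}}$ matrix normalization. For the quadratic
kernel the two are *not* equivalent: $(1 + x\cdot y)^2$ is non-monotone in
$x\cdot y$ below $-1$, so post-hoc matrix normalization lets strongly
dissimilar pairs masquerade as similar ones — in our planted-signal
benchmark this costs roughly 0.08 mean ROC. Normalizing the inputs keeps
the base inner product in $[-1,1]$ where the quadratic map is monotone.

**Exact dual instead of an approximate solver.** The soft-margin SVM dual
is a small convex QP; it is solved exactly with `quadprog` (ridge
$10^{-8}$ on the Hessian diagonal for strict positive definiteness). The
fit is therefore deterministic — identical data give bitwise-identical
decision scores — and the only randomness in the pipeline is in data
generation, fold assignment and chopping, all funneled through explicit
seeds. Dual coefficients are stored label-signed, so the discriminant
weight vector is $w = \sum_n \alpha_n M_n$ with $M$ the (standardized,
unit-scaled) training representatives. The signs in per-family feature
tables are meaningful: positive means family members show *more* property
contrast at that (scale, λ) than non-members. $w$ reproduces the decision
function exactly only for a linear kernel (asserted in the tests); for
quadratic/RBF kernels it is the conventional linear projection used for
feature ranking.

**Pseudo-count pairing term $q_{ij}$.** The profile smoothing formula
blends observed column frequencies $f$ with pseudo-counts
$g_i = \sum_j (f_j/p_j)\, q_{ij}$. The literature description calls
$q_{ij}$ "the score of amino acid $i$ aligned to $j$ in BLOSUM62", but raw
log-odds scores are negative for most pairs and a frequency cannot be
negative. Default mode therefore uses the BLOSUM62-implied joint target
frequencies, reconstructed from the half-bit scores as
$q_{ij} \propto p_i p_j 2^{s_{ij}/2}$ (symmetric, renormalized) with the
published BLOSUM62 marginals as background $p$; a literal `"score"` mode
is provided, clamping negative blends at zero before renormalization.
Either way the final target frequencies are renormalized to sum exactly
to 1. Frequency ties in the n-th-rank sequence are broken alphabetically —
arbitrary but deterministic.

**Degenerate inputs.** Constant property scales have zero variance and are
rejected rather than silently zeroed. Non-standard residues (X, B, Z, U,
O) sit at the index mean (normalized value 0) with a warning — a neutral
contribution instead of a hard failure on real-world FASTA. Sequences
shorter than $\beta + 1$ abort a strict batch naming the offender, or are
skipped with a log line in lenient mode. All-gap alignment columns (only
possible without the query row) fall back to the background distribution
with a warning. ROC ties are averaged (trapezoid through tied blocks);
ROC50 is normalized by $P \cdot \min(50, N)$ so that perfect early
retrieval scores 1 and it coincides with ROC whenever there are at most 50
negatives — the truncation point is standard, the normalization constant
is a convention and absolute ROC50 values under other conventions differ
by a fixed factor.

## What the synthetic generator emulates — and what it does not

`make_family_dataset()` builds a family whose members carry a *periodic*
physicochemical signal: blocks of length $\lambda^*$ alternate between the
six highest- and six lowest-scoring residues of a chosen scale, so pairs at
lag $\lambda^*$ almost always straddle a phase boundary and the PDT
component there is large (with the characteristic depressed harmonic at
$2\lambda^*$). Negatives are within-sequence shuffles of independently
generated family-style sequences — *composition-matched by construction*,
so any separation must come from sequence order. This isolates exactly the
claim the transform embodies: order information, not composition, drives
the discrimination. A `weights`-style ranking on these families should
(and in tests does) put the planted (scale, $\lambda^*$) feature at the
top, mirroring the family-specific λ structure reported for real SCOP
families (e.g. the all-λ=2 signature of a β-sandwich domain family).

Frozen defaults, chosen once as a plausible stated world: 40 positives and
40 negatives per family (half train / half test), lengths 60–120 residues
(single-domain scale), `effect = 0.9` (each residue follows the planted
periodic arrangement with probability 0.9, else is uniform — roughly a
"one mutation in ten" corruption), $\lambda^* = 2$ by default, five toy
scales with $\beta = 5$ in tests. `effect = 0` is the negative control and
is explicitly allowed (test ROC ≈ 0.5).

What the generator does **not** emulate: evolutionary divergence
(substitutions correlated with a phylogeny), real superfamily/family
nesting, length and composition biases of real SCOP sets, or profiles
derived from real alignments (profile code is tested on degenerate and toy
profiles). A green synthetic benchmark therefore establishes that the
machinery — transform, classifier, scoring, ranking — is correct and
sensitive to planted order signals at realistic noise; it does *not*
establish the absolute ROC levels reported on SCOP 1.53, which depend on
external data deliberately out of scope here.

## Known limitations

* The SVM back end is an exact QP solve: fine for per-family problems of a
  few hundred vectors (the remote-homology setting), cubic beyond that.
* Only the alignment-consuming half of profile generation is implemented;
  running PSI-BLAST is left to the user (`psiblast_command()` emits the
  canonical invocation, untested by design).
* ROC50 absolute values are convention-dependent (see above); comparisons
  across methods are only meaningful under a fixed convention.
* The transform is blind to signals expressed as k-mer identities rather
  than property contrast, and to correlations *between* different scales
  (the autocross-covariance family of methods covers those).
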