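---
title: "Walsh–Hadamard entropy features for focal EEG discrimination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walsh-Hadamard entropy features for focal EEG discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwhteeg)
```

## The problem and the model

Intracranial EEG channels recorded inside the epileptogenic zone ("focal",
FC) tend to be *more regular* — lower-complexity, more self-similar — than
channels recorded elsewhere ("non-focal", NFC). The pipeline in this
package turns that observation into a classifier in three steps:
an orthogonal transform that concentrates the signal's structure, a bank of
entropy statistics that quantify the residual irregularity, and a small
neural network that learns the decision boundary in entropy space.

### The transform

The Walsh–Hadamard transform projects a length-`N = 2^n` signal onto
rectangular ±1 basis functions. We use the **orthonormal** convention
generated by the doubling recursion

$$W_n = \frac{1}{\sqrt 2}\begin{pmatrix}W_{n-1} & W_{n-1}\\ W_{n-1} &
-W_{n-1}\end{pmatrix},\qquad W_0 = (1),$$

computed by the standard add/subtract butterfly in `fwht()` rather than by
matrix multiplication. Records whose length is not a power of two are
zero-padded up to the next power (`pad_to_next_pow2()`): the common
10,240-sample paired-record length becomes 16,384 coefficients, while
4096-sample records transform as-is. The `1/\sqrt 2` reading of the
recursion's scale factor is a deliberate choice — with it `W_n` is
symmetric *and* orthonormal, so the transform is exactly its own inverse
and conserves energy, and both properties are cheap, sharp test oracles.
The alternative `1/2` (averaging) convention differs only by an overall
factor per stage; because every entropy tolerance downstream is tied to the
coefficient standard deviation, the classification pipeline is insensitive
to this choice, which is why fixing one convention is safe.

Coefficients are produced in **natural (Hadamard) ordering**, the order the
recursion generates. Sequency ordering (rows sorted by sign-change count)
is the Walsh analogue of a frequency axis and is exposed via
`to_sequency_order()` / `to_natural_order()` for inspection, but the
pipeline itself consumes the full coefficient set, and of the five
entropies only the ordinal one is sensitive to coefficient order — so one
convention has to be fixed and documented, and natural is the one the
recursion gives for free.

### The entropy bank

All five statistics are computed on the Hadamard coefficients of each
channel, in the fixed order ApEn, SampEn, PermEn, FuzzyEn, LogEn
(per channel; x-channel block first for paired records).

* **Approximate entropy** (`approximate_entropy()`): with `N − m + 1`
  templates of length `m`, Chebyshev distance and tolerance `r`,
  `φ_m(r)` is the mean log fraction of templates within `r` (self-matches
  included, the classic biased-but-always-defined form), and
  `ApEn = φ_m − φ_{m+1}`.
* **Sample entropy** (`sample_entropy()`): `−ln(A/B)` over the `N − m`
  template start points, self-matches excluded. When no pairs match
  (`B = 0`) or no pair continues to match (`A = 0`) the statistic is
  infinite/undefined; we return the finite cap `ln(N−m) + ln(N−m−1)` — the
  value a single matching pair would produce — with attribute
  `degenerate = TRUE`, so feature tables never contain infinities while the
  condition remains detectable.
* **Permutation entropy** (`permutation_entropy()`): Shannon entropy of
  ordinal patterns of `k` consecutive (delay-`τ`) values, normalized by
  `ln(k!)` into [0, 1]. Ties are ranked by time index (stable ranking),
  the deterministic standard for ordinal methods.
* **Fuzzy entropy** (`fuzzy_entropy()`): a sample-entropy variant where the
  hard threshold is replaced by the membership `exp(−d^n/p)` computed on
  baseline-removed templates (each window minus its own mean);
  `FuzzyEn = ln φ_m − ln φ_{m+1}` with `φ` the mean pairwise membership
  excluding `j = i`.
* **Log-energy entropy** (`log_energy_entropy()`):
  `Σ ln(max(y_i², ε))`. The floor `ε` keeps exact zeros finite — relevant
  because zero-padding can produce exactly-zero coefficients for special
  inputs; an all-zero series returns `N·ln ε` by construction.

Natural logarithms are used throughout. The quadratic-time kernels
(ApEn, SampEn, FuzzyEn) are implemented in C++ with O(N) memory (explicit
pair loops, no N×N distance matrix), so full 16,384-coefficient vectors are
feasible; `entropy_params(max_series_len =)` optionally decimates longer
vectors for speed and is off by default.

**Parameter defaults** (all exposed in `entropy_params()`): embedding
dimension `m = 2` and tolerance `r = 0.2·SD` for ApEn/SampEn; ordinal order
`k = 3`, delay `τ = 1`; fuzzy `m = 2`, exponent `n = 2`, width
`p = 0.2·SD`; LogEn floor `1e-12`. These are the community-standard
settings for biomedical series of this length; no published parameter set
exists for this exact pipeline, so reported benchmark accuracies cannot be
pinned to specific values — a replication caveat worth stating plainly.
Because `r` and `p` are resolved per channel as fractions of the
*coefficient* standard deviation, ApEn, SampEn and PermEn are exactly
invariant to amplitude rescaling of a record; FuzzyEn is not (its distances
enter to the power `n` while `p` scales linearly), and LogEn deliberately
measures absolute energy spread.

### The classifier

`mlp_lm()` fits a `p`–10–1 feed-forward network — tanh hidden layer,
logistic output — by **Levenberg–Marquardt damped least squares** on the
residuals `e_i = y_i − p(x_i)`, `y_i ∈ {0, 1}` with FC coded 1. Each step
solves `(JᵀJ + μI)δ = Jᵀe` with the analytic Jacobian; accepted steps must
strictly decrease the sum-of-squares loss (`μ` relaxed ×0.1), rejected
steps escalate `μ` ×10 and retry, and a singular normal matrix is handled
by the same escalation rather than an error. Stopping: 200 accepted epochs,
gradient infinity-norm below `1e-7`, loss below `1e-10`, or `μ` exceeding
`1e10`. Sum-of-squares with a logistic output (rather than cross-entropy)
is the classic `trainlm`-style pairing — LM is intrinsically a
least-squares method. Ten hidden units is the default width; inputs are
z-scored on *training* statistics only (the entropies span orders of
magnitude — LogEn is O(−10³) while PermEn is O(1)), and weights start
uniform on (−0.5, 0.5) from a caller-supplied seed, so training is
bit-reproducible. No early-stopping validation split is used by default
since the evaluation protocol is k-fold CV; the hard 0.5 threshold, with
ties to FC, is the documented decision rule.

### Evaluation

`t_screen()` applies a pooled-variance two-sample Student's *t*-test per
feature (Welch variant behind a flag) at α = 0.01. In both the synthetic
experiments and typical real-data use all entropy features pass, so the
screen certifies significance rather than prunes; dropping screened-out
features before CV is opt-in (`screen = TRUE`).
`stratified_kfold_cv()` shuffles within class from the seed, assigns folds
so per-fold class counts differ from the global proportion by at most one
record, trains one network per fold (fold-specific seed `seed + fold`) and
predicts its held-out records, so each record is tested exactly once.
Headline metrics are **pooled** (micro-averaged) over the summed confusion
counts — with per-fold tables alongside — because pooling is the aggregation
that makes the counts, not the folds, the unit of evidence; a
zero-denominator metric is reported as `NaN` and flagged, never as 0.

## The synthetic generator

`synth_config()` / `generate_dataset()` emulate the *structure* of paired
intracranial records: two channels per record, a focal-like class that is
more regular than the non-focal-like class. Channel `x` is a stationary
AR(1) process (`φ = 0.95` for FC-like, `φ = 0.4` for NFC-like, unit-SD
Gaussian innovations); channel `y = 0.7·x + 0.3·(independent AR(1))`
imitates a correlated neighbouring electrode. Records are pure functions of
`(seed, class, index)`. The default length is 1024 samples — long enough
for stable entropy estimates yet fast under the quadratic kernels; a
dialect-faithful 10,240-sample mode is one argument away. The φ gap is the
effect size: it was chosen once to give a clear but not degenerate contrast
(AR(1) autocorrelation 0.95 vs 0.4 spans the range reported for within- vs
outside-zone regularity differences) and is configurable for
harder-or-easier benchmarks.

What the generator does **not** emulate: 1/f spectral shape, seizure
morphology, artifacts, non-stationarity, inter-subject variability. Passing
the end-to-end tests therefore demonstrates that the pipeline is correctly
wired and genuinely discriminative for complexity-separated classes — not
that it attains any particular accuracy on clinical recordings.

## Test and acceptance problem sizes

The suite verifies each quadratic kernel against an independent naive
reference on 50 random series of length ≤ 300 at 1e-12, the fast transform
against explicit Walsh-matrix multiplication for N ≤ 64 (20 random vectors
each, 1e-10) plus involution/Parseval/linearity at 1e-9, the LM Jacobian
against central differences at 1e-6 relative, and the full synthetic
experiment at 100 record pairs per class × 1024 samples — sizes chosen so
the whole suite runs in about a minute while every numerical claim is
exercised at full precision. `scripts/acceptance.R` re-runs the
dialect-length padding checks, the feature arities and the complete
100-pair experiment from a single `--seed`.

## Known limitations

* Benchmark accuracies published for FWHT-entropy pipelines on the public
  Bonn and Bern-Barcelona datasets are not reproduced here: they require
  the datasets themselves (thousands of records), unreported entropy and
  training hyperparameters, and hours of quadratic-kernel computation on
  16,384-point coefficient vectors. The package reports what it computes.
* ApEn's self-match bias makes it length-dependent; SampEn is the
  length-robust member of the pair and, consistently, the single most
  discriminative feature in our synthetic runs.
* The SampEn degeneracy cap, PermEn tie rule and LogEn floor are
  conventions; all are documented above and surfaced in the API so a user
  can detect (attribute, flag) rather than silently absorb them.
* The LM trainer optimises a non-convex loss; different seeds reach
  different minima. The CV protocol averages over ten seeded fits, and all
  seeds are recorded in the run report, so any reported number is exactly
  recomputable.
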