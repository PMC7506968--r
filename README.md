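# fwhteeg

Automated discrimination of **focal (FC)** and **non-focal (NFC)** EEG
records. Localising the epileptogenic zone before resective surgery
requires deciding which intracranial channels sit in seizure-generating
tissue; visual review of long recordings is slow and error-prone. This
package implements a frequency-domain screening pipeline for that decision,
aimed at biomedical-signal researchers who want a reproducible, testable
reference implementation:

1. **Fast Walsh–Hadamard transform (FWHT).** Each channel
   `x(1), …, x(N)` is zero-padded to the next power of two and decomposed
   onto the orthonormal Walsh basis, `X = W_n x` with
   `W_n = 2^{-1/2} [[W_{n-1}, W_{n-1}], [W_{n-1}, -W_{n-1}]]`, `W_0 = (1)`,
   computed by the O(N log N) add/subtract butterfly. A 10,240-sample
   paired record yields 16,384 coefficients; a 4096-sample single-channel
   record yields 4096.
2. **Entropy feature bank.** Five nonlinear regularity measures are
   computed on the Hadamard coefficients of each channel, in fixed order:
   approximate entropy `ApEn = φ_m(r) − φ_{m+1}(r)`, sample entropy
   `SampEn = −ln(A_m(r)/B_m(r))` (self-matches excluded, Chebyshev
   distance), normalized permutation entropy
   `−Σ p_j ln p_j / ln(k!)` over ordinal patterns, fuzzy entropy
   `ln φ_m − ln φ_{m+1}` with exponential membership `exp(−d^n/p)` on
   baseline-removed templates, and log-energy entropy `Σ ln(y_i²)`.
   Paired records give 10 features (5 per channel), single-channel records 5.
3. **Classification.** Features are screened by a pooled-variance
   Student's *t*-test (*p* < 0.01) and fed to a single-hidden-layer
   feed-forward network (10 tanh hidden units, logistic output) trained by
   Levenberg–Marquardt least squares, evaluated by stratified 10-fold
   cross-validation with pooled confusion counts and the five standard
   metrics (accuracy, sensitivity, specificity, PPV, NPV, in percent).

Readers for the two common plain-text record dialects (one value per line;
two delimited columns per line) and a seeded synthetic AR(1)-based
two-class generator make the whole pipeline runnable and testable without
any data download.

## Worked example

```r
library(fwhteeg)

## one synthetic focal-like paired record (two correlated AR(1) channels)
rec <- generate_class_signal("FC", synth_config(length = 1024, seed = 42), 1)
rec
#> <eeg_paired> x/y channels, 1024 samples @ 512 Hz, label FC, synth_FC_0001

## Hadamard coefficients and the per-channel entropy block
length(fwht(rec$x))
#> [1] 1024
round(extract_feature_vector(rec)[1:5], 4)
#>    ApEn_x  SampEn_x  PermEn_x FuzzyEn_x   LogEn_x
#>    1.4305    1.4244    0.9961    1.1540 -830.8861

## full experiment: generate 50 record pairs per class, extract features,
## t-screen, stratified 10-fold CV of the LM-trained network
res <- run_experiment(experiment_config(
  data = list(synthetic = TRUE, n_pairs = 50, length = 1024), seed = 42))
res
#> fwhteeg run: 100 records, 10 features, seed 42
#> Stratified 10-fold cross-validation (seed 42)
#> Pooled confusion counts:
#>      predicted
#> truth FC NFC
#>   FC  50   0
#>   NFC  0  50
#> accuracy 100.00%  sensitivity 100.00%  specificity 100.00%  ppv 100.00%  npv 100.00%
```

The entropy block already tells the story: focal-like records are more
regular, so their coefficient entropies sit systematically below the
non-focal ones, and the cross-validated network separates the two synthetic
classes perfectly. On real recordings the five metrics in the last line are
the clinically relevant outputs: sensitivity is the fraction of focal
channels correctly flagged, specificity the fraction of non-focal channels
correctly cleared.

A thin command-line front end mirrors the stages
(`inst/cli/fwht-eeg simulate|transform|extract|evaluate|run`); see the
header of that script for flags.

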