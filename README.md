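# cvte — complex-valued transfer entropy for directed connectivity

Complex-valued fMRI acquisitions yield a magnitude *and* a phase time
series for every region of interest, but directed-connectivity analyses
almost always use the magnitude alone. `cvte` implements a
complex-valued transfer entropy (CTE) that uses both channels: for two
signals `z1 = a·e^{jθ}` and `z2 = b·e^{jφ}` it sums four symbolic
plug-in information terms at a shared data-driven delay τ,

    C(z1→z2) = R(a→b) + R(θ→φ) + R(a→b | θ) + R(θ→φ | a)

— magnitude–magnitude and phase–phase transfer entropy
(`I(b_t; a_{t−τ} | b_{t−τ})` and its phase analogue) plus two *partial*
transfer entropy cross terms that condition on the source's
complementary channel and capture magnitude–phase interplay. The
forward–reverse difference is calibrated against time-shuffled
surrogates, and a t-test over `R = 100` shuffle repetitions turns it
into a three-way verdict: `forward`, `reverse`, or `none`.

The package is for researchers analysing complex-valued (or any
two-channel) time series who want directed coupling estimates with a
significance gate, together with the standard baselines to compare
against: simplified CTE without the cross terms (sCTE), symbolic and
histogram transfer entropy on magnitudes only (STE/HTE), and a nested
OLS Granger F-test. A six-family autoregressive simulation benchmark
with known ground-truth directions, ROI extraction from 4D volumes, and
edge-wise two-group comparison with Benjamini–Hochberg FDR round out the
toolkit.

## A worked example

```r
library(cvte)

p <- simulate_cpair("N1", T = 146, seed = 1)   # quadratic coupling z1 -> z2
ct <- causality(p$z1, p$z2, estimator = "cte", R = 100, seed = 1)
summary(ct)
#> Directed causality test (cte)
#>   time delay tau:    1
#>   C(1->2):           0.69593
#>   C(2->1):           0.44103
#>   Delta-C mean:     0.28969 (sd 0.09032, R = 100)
#>   p-value:           4.192e-54
#>   verdict:           forward
```

The delay scan found the true one-sample lag, the forward causality
value (in bits) exceeds the reverse one, and the surrogate-corrected
difference `Delta-C` is positive and significant: the verdict recovers
the planted direction z1 → z2. A `none` verdict would mean the
difference is not distinguishable from the surrogate distribution.

Running the benchmark at reduced scale reproduces the qualitative
story — the complex-valued estimator detects non-linear coupling that
defeats the linear Granger test:

```r
b <- run_benchmark(c("cte", "granger"), c("L1", "N1"),
                   n_pairs = 100, n_groups = 5, R = 100, seed = 1)
print(b)
#> <cvte_benchmark> accuracy of direction inference (% , mean +/- sd)
#>   method family snr_db   T      accuracy
#>      cte     L1     NA 146  91.0 +/- 8.2
#>  granger     L1     NA 146  86.0 +/- 9.6
#>      cte     N1     NA 146 100.0 +/- 0.0
#>  granger     N1     NA 146   6.0 +/- 6.5
```

For pairs of real series use `complex_series(magnitude, phase)` directly
(any aligned pair of real channels works), or `decompose_complex()` for
data given as real/imaginary parts. `connectivity_matrix()` maps a set
of ROI series to an antisymmetric Delta-C matrix with an FDR-gated
significance mask, and `group_edge_test()` compares two groups of such
matrices edge-wise.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "cvte", load_package = "installed")'
```

The suite contains unit tests per module (estimators are verified
against exhaustive brute-force oracles on short inputs) and a
benchmark-level acceptance file that re-runs the simulation study at
reduced scale.
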