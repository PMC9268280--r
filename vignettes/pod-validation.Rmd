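---
title: "Threshold-based SERS screening and its POD-model validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based SERS screening and its POD-model validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podscreen)
```

## The screening problem

Regulatory screening of a finite contaminant such as carbendazim in apple
does not need a concentration estimate: it needs two binary answers — does
the sample contain the analyte, and is the residue at or above the maximum
residue limit (MRL, 5 mg/kg for carbendazim in apple)? SERS is attractive
for this because characteristic Raman shifts give a molecular fingerprint
within minutes; it is problematic because absolute SERS intensities are
unstable (nanoparticle aggregation, matrix effects), so conventional
calibration-curve quantification is unreliable. `podscreen` implements a
workflow that leans only on what SERS does reliably: peak *positions*
(qualitative call), a *distributional* treatment of peak intensity at a
single decision concentration (semi-quantitative call), and a binary-output
validation framework (the POD model) for both.

## Qualitative call

A characteristic-peak library holds 2–6 shifts that are present in the
analyte standard and spiked matrix but absent in blank matrix, plus a
matching tolerance (3–10 cm⁻¹; default 5 cm⁻¹, the midpoint of the
acceptable range). Peak detection smooths the trace with a Savitzky–Golay
filter (window 9 points, order 2 — standard for Raman line widths of a few
cm⁻¹ on a 1 cm⁻¹ grid), takes the first derivative, and keeps downward zero
crossings whose topographic prominence clears **two floors**:

- a *relative* floor, 2% of the spectrum's dynamic range, and
- a *signal-to-noise* floor, 5 times the noise level estimated robustly as
  `mad(diff(intensity))/sqrt(2)`.

The second floor is a design decision worth explaining. A purely relative
floor is self-defeating on blanks: a blank's dynamic range *is* noise, so
noise maxima clear 2% of it everywhere and, with a ±5 cm⁻¹ tolerance on a
1 cm⁻¹ grid, some noise maximum always sits near every library position —
blanks would be called positive. The SNR floor removes this failure mode.
Both floors scale linearly with the spectrum, so the qualitative call is
invariant under uniform intensity scaling (laser power, integration time),
a property the test suite checks. Apex intensities are always read from
the raw, unsmoothed trace so that the later threshold comparison does not
depend on smoothing strength.

Matching is greedy nearest-first within the tolerance, each detected peak
used at most once; when two detected peaks lie within tolerance of one
library peak the nearer wins and the other remains available. The sample
is positive only if *all* library peaks match — the strictest reading of
the fingerprint rule; partial matches are negative. No baseline correction
is applied by default (a rolling-minimum subtraction is available behind a
flag): prominence is already a local measure and the validation data this
package mirrors were processed without one.

## Semi-quantitative call

At the decision concentration (typically the MRL) the replicate-to-replicate
scatter of a characteristic peak's intensity is treated as Gaussian — the
empirical premise of intensity-threshold screening. For each library peak,
a training set (recommended > 50 replicates; smaller sets warn rather than
fail so reduced-scale studies can run) gives `mean` and `sd`, Shapiro–Wilk
tests normality at α = 0.05, and the threshold is the one-sided lower
population bound

```
threshold = mean − z·sd,   z = qnorm(confidence), 1.645 at the default 95%.
```

The population bound (not the confidence bound of the *mean*,
`mean − z·sd/√n`, available via `mean_ci = TRUE`) is the right default
because the decision is about an individual blind sample: a sample truly
at the MRL then exceeds the threshold with probability ≈ confidence. The
direct consequence — visible in the test suite — is that the exceedance
rate at the MRL converges to ≈ 0.95, not 1: about one MRL-level sample in
twenty falls below the threshold by construction. Raising `confidence`
lowers the threshold and trades false negatives at the MRL against false
positives below it.

Candidates (one per library peak) are scored on three test sets — low
concentration, half the decision concentration, and the decision
concentration (recommended > 20 each) — by the exceedance fractions
POD₁, POD₂, POD₃:

```
S = 2 (POD₃ − POD₂ − POD₁) × 50
```

so a perfectly separating threshold (0, 0, 1) scores 100 and the score
falls by one point per percentage point of false exceedance below the
decision level or missed exceedance at it. Selection filters to
normality-passing candidates and takes the highest score; ties break by
lower POD₂, then lower POD₁, then lower shift. A candidate that scores
well but fails normality is rejected — the threshold formula is meaningless
for a non-Gaussian intensity distribution.

The final call gates on the qualitative result: a qualitative negative
leaves the exceeds-MRL question *indeterminate* (`NA`), never "below" —
absence of the fingerprint is not evidence about concentration. Intensity
exactly equal to the threshold does not exceed (strict `>`).

## POD validation

Both calls are binary, so one validation framework covers them. From `x`
positives in `N` replicates at each spiked concentration:

- `POD = x/N` with the score-type 95% interval in count form,
  `(x + 1.9207 ∓ 1.9600·√(x − x²/N + 0.9604))/(N + 3.8415)`; at the
  boundaries, `LCL = 0, UCL = 3.8415/(N + 3.8415)` (x = 0) and
  `LCL = N/(N + 3.8415), UCL = 1` (x = N). The constants bake in z = 1.96;
  there is deliberately no generic-z mode, keeping reported limits
  bit-compatible with published validation tables. (The printed constants
  are internally inconsistent at the fourth decimal — 1.9600·0.98 =
  1.9208 ≠ 1.9207 — so the boundary branches differ from the raw Wilson
  limits by ~10⁻⁴/N; the test suite pins the interior equations to an
  independently coded Wilson oracle at 10⁻⁹ and the boundaries at 10⁻⁴.)
  Values are never rounded or capped internally; report writers round to
  three decimals.
- **LOD**: the smallest non-zero tested concentration with POD > 0.95
  (the sensitivity requirement of rapid-screening guidelines). If the
  empirical curve dips back below the threshold at a higher concentration
  the smallest qualifying level is still returned, with a warning — the
  model assumes monotonicity and non-monotone data deserve scrutiny, not
  silence.
- **Rates**: at concentration zero POD is the false positive rate
  (specificity its complement); elsewhere POD is the sensitivity (false
  negative rate its complement). Each is reported only where defined.
- **Consistency**: `dPOD = POD_I − POD_II` per shared concentration, with
  95% limits from the component interval half-widths combined in
  quadrature. The verdict uses the *point estimate* (`|dPOD| ≤ tol`,
  default `tol = 0`) — the convention of published consistency tables,
  which never consult the dPOD interval; requiring the CI to cover zero
  (AOAC-style) is available via `use_ci = TRUE` and is necessarily more
  permissive. The signed value is kept internally (antisymmetry is
  tested); reports print the conventional absolute value.

## The simulator: what it emulates, and what it does not

`simulate_spectrum()` emulates a spiked-matrix SERS acquisition: a
polynomial baseline in normalised shift, six Lorentzian lines (the natural
Raman line shape) at the carbendazim shifts, additive Gaussian detector
noise, and — the scientifically load-bearing part — apex amplitudes drawn
per replicate from a Gaussian with mean `base_mean·(c/c_ref)^exponent`
and SD `rel_sd` times that mean. Defaults: grid 200–2000 cm⁻¹ at 1 cm⁻¹
(covers all library peaks; the full 200–4000 cm⁻¹ acquisition range adds
nothing to testing), reference concentration 5 mg/kg, linear response
(`exponent = 1`; sublinearity is configurable since only rank order
matters to the method), `rel_sd = 0.1` and a 630 cm⁻¹ base mean of 16 000
counts — chosen once so the trained threshold lands near 1.4 × 10⁴ counts,
the scale reported for carbendazim screening at the MRL. Amplitude draws
are truncated at zero (counts cannot be negative), a negligible departure
from exact normality below `rel_sd ≈ 0.3`.

The simulator reproduces the *statistical* structure the method relies on
— Gaussian amplitude scatter, monotone concentration response, seeded
determinism — and deliberately omits what it does not rely on: hot-spot
physics, aggregation kinetics, matrix chemistry, cosmic rays, wavenumber
drift. Passing tests therefore certify the decision logic and the
statistics, not instrument robustness on real extracts.

`simulate_counts()` drives binomial detection counts from a logistic POD
in log concentration (exactly zero at concentration zero — a blank cannot
contain the analyte), for testing the validation layer independently of
spectra.

## Numerical and degenerate-input choices

- Derivative values below 10⁻¹⁰ of the trace scale are treated as zero
  slope, so constant traces yield no peaks (filter round-off is not
  slope).
- Zero-variance training intensities give `sd = 0`, `threshold = mean`,
  normality "not assessable" (Shapiro–Wilk is undefined), and a warning.
- An undetected peak in a test spectrum contributes intensity `NA`, which
  counts as *not exceeding* — the conservative direction.
- Count inputs must be whole numbers with `0 ≤ x ≤ N`, `N ≥ 1`;
  concentrations unique and non-negative; mismatched consistency grids
  are input errors, not silent alignments.

## Problem sizes in the shipped tests

The suite exercises the formula layer exhaustively (all interior count
pairs to N = 200 against the Wilson oracle), interval coverage with 5 000
binomial draws per (p, N) combination, parameter recovery at n = 200, and
the end-to-end pipeline at the study scale the method recommends (train
n = 60 at the MRL, three test sets of 40, 100 seeded replicates on a
550–1400 cm⁻¹ grid). These sizes were chosen as the smallest that make the
statistical assertions sharp.

## Known limitations

- The package validates binary outputs; it does not quantify
  concentration (no PLS/PLS-DA-style calibration) and does not model
  inter-laboratory variance components (ISO 5725-type analyses).
- The qualitative rule is strict all-peaks matching; highly concentrated
  samples with saturated or shifted lines can fail it.
- The semi-quantitative threshold presumes Gaussian intensity scatter at
  the decision concentration; the normality gate rejects peaks where that
  fails, but a passing test at n ≈ 60 has limited power against modest
  departures.
- By construction of the population bound, `POD₃ = 1` over a 40-sample
  test set at the decision concentration is the exception, not the rule
  (expected exceedance ≈ 0.95 per sample); perfect separation scores
  require either larger margins between tested concentrations or a higher
  configured confidence.
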