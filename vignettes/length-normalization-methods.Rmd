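---
title: "Descriptor encoding and length normalization: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor encoding and length normalization: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aainterp)
```

## The problem

Most classifiers and regressors require inputs of fixed dimension, while
protein sequences vary in length through insertions and deletions. A second,
independent observation is that numerically encoded residues (hydropathy, net
charge, molecular weight, ...) often outperform the sparse orthonormal
representation of twenty indicator variables per position. aainterp combines
the two ideas into a preprocessing pipeline:

1. **encode** each residue with a descriptor scale, giving one real value per
   position;
2. **normalize** the encoded vector to a chosen length by interpolation,
   giving a fixed-width feature matrix any learner can consume.

The motivating use case is classification of HIV-1 V3 loop sequences
(33–38 residues, the main determinant of CCR5/CXCR4 coreceptor usage), but
nothing in the package is specific to that system.

## The descriptor database

The database holds 532 scales: the 531 complete (all-numeric) AAindex1
scales, in accession order as shipped in seqinr's `aaindex` snapshot, plus
one *empirical* scale at index 532. Thirteen AAindex1 entries contain `NA`
values and are excluded — this is why 531, not 544, scales are usable.
Index 151 is the Kyte–Doolittle hydropathy scale (`KYTJ820101`), the default
descriptor throughout the package.

The 532nd scale deserves a caveat: earlier tools in this space advertised an
additional empirical descriptor alongside the AAindex scales without ever
defining its values. Our stand-in is the alphabet-rank scale (A=1 ... V=20 in canonical residue
order), clearly flagged `empirical` in `list_descriptors()`. It carries no
physicochemical meaning; it exists so the documented index range 1–532 is
fully populated. Index-for-index agreement with historical tools beyond
index 151 is not claimed, since their ordering conventions are not published.

`parse_aaindex1()` reads the AAindex1 flat-file format directly (records
with `H`/`D`/`I` lines; the two ten-value rows follow the `A/L R/K N/M D/F
C/P Q/S E/T G/W H/Y I/V` column order), skipping and reporting `NA` records,
so users can load their own scale collections.

### Interval normalization

`normalize` rescales the *scale*, not the encoded sequence: the affine map
sending the scale's 20-value minimum and maximum onto the interval endpoints
(`[0,1]` for mode 2/`"unit"`, `[-1,1]` for mode 1/`"symmetric_unit"`).
Normalizing per sequence would make the same residue encode differently in
different sequences and destroy comparability across a dataset, which is the
entire point of a fixed descriptor. A constant scale has no defined affine
map and is rejected. The map is idempotent and order-preserving, and its
endpoints are exact (both are asserted in the test suite).

## Encoding

`encode_sequence()` maps residue *i* to the (possibly rescaled) scale value
of residue *i*. Input is uppercased. The default residue policy is
**strict** — only the 20 canonical codes, anything else is an error naming
the character and position. The **lenient** policy must be opted into
because imputation changes feature values: it strips gap characters (`-`,
`.`) and imputes `B` as mean(D, N), `Z` as mean(E, Q), and `X` as the mean
of all 20 scale values, warning with counts.

## Length normalization

`resample(values, dims, method)` treats the encoded vector as knots
$(i, y_i)$, $i = 1..L$, fits an interpolant, and evaluates it on the uniform
target grid

$$x_j = 1 + (j - 1)\frac{L - 1}{D - 1}, \qquad j = 1..D,$$

which spans $[1, L]$ inclusively. Endpoint preservation
(`out[1] == values[1]`, `out[D] == values[L]`) is the contract we consider
defensible for a resampling grid; grids of the form `seq(1, L, L/D)` seen in
older plotting code do not hit the right endpoint and are treated here as
plot cosmetics, so bit-compatibility with historical implementations of the
normalization grid is not claimed. Extrapolation is never performed;
evaluation outside $[1, L]$ is an error.

Five method names are accepted:

* **linear** (default): straight segments between neighboring knots. Output
  is always inside `[min(y), max(y)]`.
* **natural**: cubic spline with zero second derivative at both ends.
* **periodic**: cubic spline with equal first and second derivatives at its
  endpoints; requires `y[1] == y[L]`. By default unequal endpoints are an
  error; `coerce = TRUE` replaces the last value with the first (with a
  warning) for users porting data from implementations that warn-and-coerce.
* **fmm**: the Forsythe–Malcolm–Moler end condition — at each end the
  spline's third derivative matches that of the single cubic passing exactly
  through the outermost four points. Consequently data sampled from one
  cubic polynomial is reproduced exactly (a test asserts this).
* **spline**: an alias for `fmm`. Generic "cubic spline interpolation" and
  the Forsythe variant describe the same construction here; the alias keeps
  all five public names valid while defining exactly three distinct cubic
  boundary treatments.

### Numerical construction

The splines use the second-derivative formulation: with unit knot spacing,
C2 continuity yields
$M_{i-1} + 4M_i + M_{i+1} = 6(y_{i+1} - 2y_i + y_{i-1})$ for interior knots.
Natural and fmm boundaries close the system into a tridiagonal matrix solved
with the Thomas algorithm; the periodic wrap-around produces a cyclic
tridiagonal matrix solved by a Sherman–Morrison rank-one update. All solves
are direct (no iteration); the solutions are verified in the test suite
against (a) a dense solve of the full $4(L-1)$-equation piecewise-cubic
system assembled from scratch, to $10^{-9}$ on 200 random vectors, and
(b) `stats::splinefun`, an independent implementation of the same three
boundary types, to $10^{-10}$.

Degenerate inputs: fmm needs four points per end, so $L = 3$ falls back to
natural and $L = 2$ to the (linear) natural spline, each with a warning.
$L = 2$ periodic input is a constant function.

### Overshoot and clamping

Cubic interpolants can overshoot the knot range, so with `normalize = 2` a
resampled row may leave $[0,1]$ slightly. The default is **no clamping** —
the interpolant is reported faithfully. `build_feature_matrix(clamp = TRUE)`
truncates to the interval for consumers that require hard bounds; clamping
is opt-in because it silently distorts the interpolant.

## The dataset pipeline

`build_feature_matrix()` applies encode-then-resample to every record,
preserving row order, and returns a tibble `id, p1..pD` (plus carried
columns such as `label`). When `dims` is omitted it defaults to the rounded
median input length: squeezing below half the original length loses
information, and stretching inflates dimension and overfitting risk, so a
central default is the sensible compromise; a warning fires when any
stretch/squeeze ratio exceeds 2. Per-record failures abort with the record
id, or are collected with `skip_errors = TRUE`.

`demo_classification()` exists to demonstrate that preprocessing preserves
class signal, not to be a production learner: stratified k-fold
cross-validation (default 5 folds, fold assignment seeded) of a pluggable
classifier — any `function(x_train, y_train, x_test)` returning scores —
with AUC computed from out-of-fold scores by the Mann–Whitney rank
estimator, which equals the trapezoidal area under the empirical ROC curve.
Resubstitution AUC (train = test) overestimates performance, which is why
the demo insists on cross-validation. The default classifier is nearest
centroid: on features with approximately isotropic per-position noise it is
close to the optimal linear rule and has no tuning parameters.

## The synthetic generator

`generate_synthetic()` provides a fully self-contained stand-in for a
V3-like dataset, so every pipeline stage is testable without external data.
What it emulates:

* **class imbalance** — defaults of 1151 class-0 and 200 class-1 sequences;
* **length variation** — each sequence starts as a 35-residue template and
  is brought by random indels to a length drawn uniformly from 33–38;
* **a composition signal** — class 0 draws residues i.i.d. from the uniform
  composition; class 1 from the mixture
  $(1-s)\,\text{base} + s\,\text{shifted}$, where the shifted composition
  multiplies the probability mass of the hydrophobic residues
  {I, V, L, F, C, M, A} by 5 and renormalizes, and $s$ is `class_signal`
  (default 0.6).

The shift multiplier was calibrated once, in closed form, against the
nearest-centroid baseline: with multiplier $k$ the class-1 hydrophobic mass
at $s = 0.6$ is $0.4\cdot 0.35 + 0.6\cdot 7k/(13+7k)$, and the resulting
per-position mean hydropathy shift, against a per-position standard
deviation of about 2.9 over 35 positions, gives a linear-classifier
separation $d' \approx 2.3$ at $k = 5$ (cross-validated AUC $\approx$ 0.95).
A doubling ($k = 2$) caps even the Bayes-optimal AUC near 0.81, too weak for
a clearly positive control; $k = 5$ leaves the task non-trivial while
cleanly separable from the null. At `class_signal = 0` the classes are
identically distributed by construction and cross-validated AUC stays at
chance.

What the generator does **not** emulate: positional conservation motifs,
phylogenetic correlation between sequences, realistic amino-acid background
frequencies, or any linkage between length and class. Passing tests
therefore show the pipeline's mechanics are correct and that a planted
composition signal survives preprocessing — they do not certify performance
on real sequence data. `indel_rate` adds composition-neutral delete–insert
churn only; under an i.i.d. composition model it has no distributional
effect and exists for API completeness.

## Known limitations

* Normalizing to below ~50% of the original length in general loses
  information; prefer stretching short sequences over squeezing long ones,
  at the cost of a higher-dimensional (more overfitting-prone) feature
  space.
* Length itself can be informative (e.g. disease-associated repeat
  expansions such as the huntingtin glutamine tract); normalization
  partially erases that signal. Keep length as an extra feature if it may
  matter.
* Only single-scale encodings are produced; k-mer, window-averaged, and
  profile encodings are out of scope, as are AAindex2/AAindex3 matrices.

## Problem sizes used in the checks

The test suite exercises the spline solvers on 200 random vectors of
lengths 4–12 per boundary type against the dense oracle, property checks on
random vectors up to length 40, and the full pipeline on the default
1151 + 200 synthetic configuration, with the null calibration averaged over
20 seeds. These sizes were chosen to exercise every code path (including
boundary fallbacks) while keeping the whole suite around twenty seconds on
one core.
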