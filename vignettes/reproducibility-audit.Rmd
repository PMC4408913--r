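---
title: "Auditing numerical reproducibility of neuroimaging pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing numerical reproducibility of neuroimaging pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reprotrace)
```

## The problem

A neuroimaging pipeline run twice on the same data, with the same binaries
and parameters, can still produce different tissue classifications, different
ICA decompositions and measurably different cortical-thickness maps when the
two runs happen on different operating systems or builds. The root cause is
rarely the pipeline itself: dynamically linked mathematical libraries change
between OS releases, and a single-precision `expf()` or `cosf()` that returns
a value one unit in the last place (ULP) away from its old self, millions of
times per subject, is enough to move tissue boundaries and flip loop bounds.

`reprotrace` implements the measurement layer of such an audit. It does not
run FSL, Freesurfer or CIVET, and it does not generate traces; it consumes
their outputs (call logs, label volumes, transform files, component maps,
thickness matrices) and quantifies how and where two executions disagree.
A seeded synthetic-data module generates paired inputs with known ground
truth for every stage, so the whole toolkit is testable at desk scale
without clinical MRI data.

## Trace difference taxonomy

Two executions that produce identical results are assumed to perform the
same library calls in the same order, so paired trace lines are compared
positionally. Each pair receives exactly one class:

| class     | arguments | return value | reading                                   |
|-----------|-----------|--------------|-------------------------------------------|
| identical | equal     | equal        | no difference                             |
| type-1    | differ    | equal        | non-injective call (`floor`, `ceil`) absorbed an upstream drift |
| type-2    | differ    | differ       | cascading drift                           |
| type-3    | equal     | differ       | the library implementation itself changed |
| mismatch  | —         | —            | different functions: control flow diverged |

Mismatch is evaluated first — comparing arguments across different functions
is meaningless. Type-3 is the root-cause class; type-1/2 are its downstream
signatures; mismatches mark the transition from numerical to structural
divergence.

Design choices worth stating:

* **Token equality is exact-string** (after trimming), because trace
  formatting is fixed within a run; a numeric mode is unnecessary for the
  synthetic dialect since the generator perturbs the last *printed* digit,
  making both readings agree.
* **Unequal trace lengths**: each unpaired trailing line counts as a
  mismatch, so diverging control flow lengthens the mismatch series instead
  of aborting the comparison.
* **Interleaved children**: the default compares file order ignoring pids;
  `per_pid = TRUE` splits into per-pid streams, since the serialization of
  child output by a tracer is not well defined.
* **Memory**: `diff_trace_files()` streams both logs in checkpoint-sized
  chunks (default 10^4 lines) and keeps only difference rows, so traces of
  tens of millions of calls fit in constant memory per chunk.

```{r trace}
tp <- gen_trace_pair(2000, list(type3 = 500L, type1 = 0.005), seed = 7)
diff_traces(parse_trace(tp$a), parse_trace(tp$b))
```

## IEEE-754 forensics

`float32_from_hex()` decodes the little-endian byte dumps that debuggers
print for single-precision values. `ulp_distance()` maps each 32-bit pattern
to a monotone integer rank (sign-magnitude folded onto a signed offset, so
+0 and −0 coincide) and reports the difference in representable values;
`hamming_bits()` counts XOR bits. The distinction matters: the three libm
results that changed between glibc 2.5 and 2.18 each moved exactly one ULP,
but their patterns differ in 1, 4 and 2 bits — "one bit flipped" is a value
statement, not a pattern statement.

```{r float}
libm_drift_examples()
```

`format_30dec()` prints the exact decimal expansion of a binary32 value to
30 fractional digits. Every finite binary32 has a terminating expansion (at
most 149 fractional digits), so this is implemented as exact digit-vector
arithmetic (repeated halving of a decimal representation) and **truncates**
at the 30th digit rather than rounding: the printed string is a prefix of
the exact value, which is the property one wants when comparing dumps.
Numbers-to-text via `sprintf("%.30f")` would round instead, and the two
conventions disagree for magnitudes below 2^-30.

Conventions: `ulp_distance(+0, −0) = 0` (value semantics) while
`hamming_bits` reports 1 (bit semantics); infinities rank adjacent to the
largest finite floats; NaN is always an error.

## Segmentation overlap

Per-structure agreement uses the Dice index `2|A∩B|/(|A|+|B|)`; the global
figure for a multi-label map is the generalized (label-summed) Dice over
non-zero labels, which weights structures by size and equals 1 iff the two
labelings agree on every non-background voxel. Localization uses binarized
difference masks summed across subjects. Comparisons are strictly
voxel-for-voxel: inputs must be pre-aligned, and the package never
resamples — a resampler's own interpolation choices would contaminate
exactly the differences being measured. Checksum screening (SHA-256, raw
bytes or NIfTI voxel payload only) comes first so identical outputs cost
one hash, not one analysis.

Two edge conventions: a label absent from both volumes is reported absent
(`NA`), not 0; two empty masks score 1 by default (agreement on absence,
with a warning), configurable to 0 or an error.

## Rigid-transform residuals and stage attribution

Motion correction yields one rigid transform per timepoint. Agreement
between two runs is the residual `T1 ∘ T2⁻¹` (column-vector convention,
`T1 %*% solve(T2)`), summarized by the Euclidean norm of its translation
(mm) and its rotation angle `θ = arccos((tr R − 1)/2)` in degrees, the
argument clamped to [−1, 1] against rounding. Rigidity is validated at
tolerance 1e-6 on orthonormality and determinant; near-rigid matrices are
rejected, never re-orthogonalized, because silent repair would hide real
differences. Matrices round-trip through FLIRT-style ASCII files at 17
significant digits, which is lossless for doubles.

Stage attribution computes the mean absolute difference (MAD) between the
two runs' images after each pre-processing stage and divides by the final
stage's MAD. 4D series pool voxels and timepoints (the per-volume reading is
available through masking); the profile is invariant under common positive
scaling of all images, so it isolates *where* divergence is amplified, not
overall intensity. A reference stage with zero MAD is an error — there is no
difference to attribute.

## ICA component matching

Component order and sign are arbitrary between ICA runs. Each component in
A is matched to the maximally correlated component in B; the matching is
per-component, many-to-one allowed, and not symmetric, so both directions
are reported. Signed correlation is the default because it reproduces the
observed failure mode honestly: a sign-flipped component does *not* match
its counterpart at r = 1 and surfaces as positive-part Dice 0, the
inversion mode seen in real run-to-run histograms. Absolute-value matching
(`signed = FALSE`) is available when inverted components should be paired.

Agreement per match is Dice on thresholded positive parts and negative
parts separately (default threshold 0, i.e. any non-zero activation, since
mixture-model thresholding belongs to the ICA tool, not the audit).
Histogram summaries use 0.1-wide bins with the final bin closed at
`[0.9, 1.0]` so a perfect Dice of 1 is countable; the mode is the center of
the most populated bin, ties broken toward the lowest bin.

## Vertex-wise thickness statistics

The per-vertex comparison of two processing conditions is an intercept-only
GLM on the paired difference scores `d = A − B`, i.e. a one-sample t test:
`t = mean(d)/(sd(d)/√n)` with `df = n − 1`, two-sided throughout. Vertices
with zero variance are flagged undefined rather than ±∞ so summaries stay
finite. `threshold_tmap()` applies an uncorrected two-sided threshold;
random-field-theory peak/cluster correction is deliberately out of scope, as
it requires surface geometry this package does not consume.

## What the synthetic generators emulate — and what they do not

Each generator plants its ground truth by construction:

* `gen_trace_pair`: baseline lines are real evaluations of
  `expf/logf/cosf/sinf/ceilf/floorf` printed at 6 decimals; injections
  perturb the last printed digit (type-3/2), use floor's non-injectivity
  (type-1), or rename the function (mismatch). Rates resolve to
  `round(rate · n)` positions sampled without replacement.
* `gen_label_volume_pair`: equal-size label supports laid out as runs in the
  flattened grid with overlap `k = d·s`, so any target Dice with `d·s`
  integral is realized *exactly*; unrealizable targets are rejected with the
  nearest realizable value.
* `gen_rigid_pair`: `T2 = G⁻¹∘T1` for a random rigid `T1`, so the residual
  is `G` exactly; defaults exercise the empirically interesting scale
  (rotations ≤ 0.096°, translations ≤ 1e-5 mm).
* `gen_component_sets`: disjoint unit-amplitude truncated-Gaussian blobs on
  a cell lattice; B is a permuted, optionally sign-flipped, noise-added
  copy. With disjoint supports, signed matching recovers the permutation
  exactly for noise well below the unit amplitude (the suite exercises
  sd 0.3).
* `gen_stage_series`: B = A + (random sign) × (constant magnitude), so the
  stage MAD equals its target to machine precision.
* `gen_thickness_pair`: baseline 2.5 mm plus subject and vertex offsets;
  condition B adds the effect inside the region plus iid Gaussian noise, so
  the null case is exactly calibrated and the planted case has the
  closed-form noncentrality `δ/(σ/√n)`.

These generators are stand-ins, not phantoms: label supports are runs, not
anatomy; component blobs are spherical; thickness noise is iid rather than
spatially correlated; traces contain no genuine cascade from a type-3 seed
to later type-2s. Passing tests therefore demonstrate that the *measurement*
machinery is exact and calibrated under controlled conditions — they say
nothing about any particular pipeline's reproducibility, which requires the
pipeline's own outputs.

## Problem sizes and determinism

The test suite and analysis scripts run at deliberately modest sizes —
traces of 10^4 lines (1% injection rates per class), 64³ label grids with
1000-voxel structures, 30-timepoint transform series, 20-component sets on
a 30×30×12 grid, and thickness panels up to 50 subjects × 10^4 vertices —
sizes at which every recovery check is exact and the null-calibration check
has standard error below 0.3 percentage points at α = 0.05. All generators
take explicit integer seeds and record them in their ground-truth blocks;
identical seeds reproduce identical outputs byte for byte.

## Known limitations

* Trace comparison is positional; a single inserted call early in one trace
  shifts all later pairings into mismatches (by design — that is what
  diverged control flow looks like to a positional comparator), and the
  streaming variant requires such length divergence to occur only as a
  trailing tail.
* The generalized global Dice is one of several defensible "global"
  definitions; all-voxel agreement would weight background, which we avoid.
* Component matching assumes maps on a common grid; no spatial registration
  is attempted.
* Uncorrected vertex thresholds control per-vertex error only; users
  needing family-wise control must take the t map into a geometry-aware
  tool.
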