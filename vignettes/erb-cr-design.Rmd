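---
title: "ERB-based design of coordinated reset tone alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ERB-based design of coordinated reset tone alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erbcr)
```

## The model

Acoustic coordinated reset (CR) therapy for tonal tinnitus plays sequences
of pure tones grouped around the patient's tinnitus pitch match `f_T`. The
working hypothesis is spatial: the tonotopically organized neural
population that sustains the tinnitus percept is desynchronized by
stimulating neighboring sub-populations at staggered times, and the
sub-population a tone recruits scales with the bandwidth of the auditory
filter centered on it. `erbcr` therefore treats every tone `f` as carrying
the ERB-wide band `[f - ERB/2, f + ERB/2]` and quantifies tone alignments
by how those bands overlap.

Two empirical relations drive everything:

* **Bandwidth:** `ERB_N(f) = 24.7 (0.00437 f + 1)` Hz, the average
  auditory-filter bandwidth of young normal-hearing listeners at moderate
  level. It is well supported for center frequencies from roughly 50 Hz to
  15 kHz; outside that range the package still computes but emits a
  warning (`erb_formula_range`), since the formula extrapolates smoothly
  and a hard failure would be wrong for, say, a 16-kHz design probe.
* **Loss widening:** `ERB(h) = ERB_N (1 + h/50)`, with `h` the hearing
  loss in dB HL at that frequency. The linear widening is supported by
  filter-width data for losses between 0 and 50 dB HL; beyond 50 dB the
  data show no clear relationship, so the package clamps `h` into
  `[0, 50]` and flags the clamp (`loss_clamped_50dB` / `loss_clamped_0dB`)
  rather than refusing to compute. Negative thresholds (better than
  normal) are clamped to 0 for the same reason: the relation was fitted
  for `h >= 0`.

Audiogram thresholds are interpolated **linearly on a logarithmic
frequency axis** between measured points; outside the measured range the
nearest endpoint's threshold is held constant. Constant extrapolation is a
deliberate choice: the interpolation contract only covers the measured
span, and inventing slopes beyond it would manufacture hearing loss (or
recovery) with no data behind it. The log base is immaterial — a function
linear in `log2(f)` is linear in `ln(f)`.

## Overlap statistics

With band edges `a = f - ERB/2`, `b = f + ERB/2`, two families of
dimensionless overlap measures are used (positive = overlap, negative =
gap, zero = coinciding edges):

* **Tinnitus-relative** (`rd_erb_tinnitus`): normalized by the tinnitus
  band width `b_T - a_T`, using the tone's upper edge below `f_T` and its
  lower edge above. The normalization is always the tinnitus band, even
  when the tone band is narrower — the tinnitus ERB is the target of the
  intervention, so overlap is expressed as a fraction of *it*.
* **Pairwise** (`rd_erb_pair`): normalized by the `min` (default) or
  `max` of the two adjacent band widths. Min-normalization bounds the
  overlap relative to the narrower filter and is the conservative choice;
  max-normalization suits designs that deliberately seek large overlaps.

A tone exactly at `f_T` is reported with tinnitus-relative overlap 1
(complete self-overlap); the defining ratio is not evaluated there because
numerator and denominator coincide. Classification into
overlap/gap/coincident uses a tolerance of `1e-9` — effectively "exact
zero up to floating point", since the analysis otherwise treats
coincidence exactly.

## The legacy tone set and its asymmetry

The original therapy used four tones at fixed ratios
`(0.766, 0.9, 1.1, 1.4) x f_T`. Because `ERB_N` grows with frequency, this
set is asymmetric on the ERB scale: the upper flanking tone's band
overlaps the tinnitus band more than the lower one at every `f_T`, and the
outer tones sit behind gaps that themselves depend on `f_T`.
`sweep_standard()` tabulates these quantities over a tinnitus-frequency
grid (default 500 log-spaced points over 250–10000 Hz, the plotted domain
of interest; the grid is configurable), and `overlap_threshold()` finds
the largest `f_T` at which an adjacent pair's bands still touch by
bisection on the edge residual `b_j - a_k` (reported at 10-Hz resolution
by default). Under normal hearing the residual is affine in `f_T`, so
these roots have closed forms — the test suite exploits that as an
independent oracle. Pair 3–4's residual does cross zero near 150 Hz,
below the 250-Hz floor of the domain of interest; over 250–10000 Hz those
bands never touch, and `overlap_threshold()` reports "no crossing" there
rather than raising an error.

## Constructive alignment design

`design_spec()` captures the open design choices: style, tone count,
target relative overlap `r` (|r| < 1), and pairwise normalization.

* **Tinnitus-centered** (`design_centered`, odd `n`): middle tone pinned
  at `f_T`; the rest placed outward one at a time by
  `place_neighbor()`.
* **Enclosing, edge-pinned** (`design_enclosing_edge`, even `n`): the
  inner pair solves `b(f_lo) = f_T` and `a(f_hi) = f_T`, so the two inner
  edges coincide *at* `f_T` and the inner pair's mutual overlap is 0 by
  construction. `r` then governs only the remaining pairs — for `r != 0`
  this is an extrapolated convention (the reference designs show all
  edges coinciding), recorded in the result's `governed_by_r` flags.
* **Enclosing, ERB-balanced** (`design_enclosing_balanced`, even `n`):
  the inner pair `(f_lo, f_hi)` solves the two-equation system
  `rd(lo, hi) = r` and `f_T = (a_lo + b_hi)/2`, which centers the
  tinnitus band in the interval spanned by the inner pair whether the
  inner bands coincide, overlap or gap. Balancing shifts the whole
  alignment slightly below the edge-pinned variant. For `n > 4` the
  balancing condition is applied to the innermost pair only — the
  obvious generalization, since outer pairs are already determined by
  the recursion.

### Numerics

Every placement is an implicit 1-D equation because the new tone's band
width depends on the audiogram at the unknown frequency.
`place_neighbor()` seeds a bracket from the local ERB width, expands it
geometrically away from the known tone until the overlap residual changes
sign (failing with a solver error carrying the bracket history if none is
found within `[f/4, 4f]`), then runs `stats::uniroot` (Brent: bracketed,
derivative-free — the interpolated audiogram has kinks at measured
frequencies, so derivative-based methods are unattractive) to an absolute
frequency tolerance of 1e-9 Hz. Near the known tone the residual is
`~ 1 - r > 0`, which guarantees the bracket orientation. Before the root
find, a 65-point scan of the bracket checks for multiple sign changes —
possible in principle with steep audiogram notches — and, if found, picks
the root nearest the known tone and emits a multiplicity warning.

The balanced inner pair is solved as nested 1-D root finds rather than a
2-D Newton iteration: the outer variable is the upper inner tone `f_hi`;
for each candidate, the balancing equation fixes the lower inner tone via
another monotone 1-D solve (`a(f_lo) = 2 f_T - b(f_hi)`), and the outer
residual is the inner-pair overlap minus `r`. Each sub-problem is monotone
and bracketable for audiograms within the supported loss range, which
makes the nesting robust where a joint iteration could stall on the
audiogram's kinks.

With a flat 0-dB audiogram all edges are affine in frequency, so every
design has an exact closed-form solution; the test suite solves those
linear recursions independently and requires agreement to 1e-9 relative.
Under a notched audiogram, solver roots are cross-checked against a
0.01-Hz brute-force grid scan of the same residual.

## The synthetic audiogram generator

No individual patient audiogram ships with the package; `synth_audiogram()`
generates the study conditions on the standard extended audiometric grid
(250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000, 10000,
12500 Hz — deliberately past the usual 8-kHz limit, because tone placement
above a high-frequency tinnitus needs thresholds there):

* `flat` — constant threshold (0 dB for normal hearing, 40–50 dB for the
  widening limit cases);
* `sloping` — flat at `start` up to a `corner` frequency, then rising
  linearly in log-frequency to `end` at 12.5 kHz, the typical presbycusis
  shape;
* `notch` — a Gaussian (in octaves) elevation of `depth` dB over a flat
  `base`, centered by default at 4 kHz with 0.75-octave width, emulating
  a noise-induced notch.

Thresholds are clipped to [-10, 90] dB HL before any downstream clamping.
Optional Gaussian jitter (default 0 dB, so fixtures are exactly
reproducible; seeded when enabled) roughens the shapes. These fixtures
emulate the *shapes* of clinical audiograms, not their measurement
process: no test–retest variability, no air–bone gaps, no
frequency-dependent measurement floors. Passing tests on them demonstrates
that the solvers honor their contracts on realistic threshold profiles —
not that any particular clinical population's numbers are reproduced,
which would require the (unpublished) individual audiograms behind the
reference figures.

## Parameter defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `c1`, `c2` | 24.7, 0.00437 | Hz, 1/Hz | standard ERB_N constants |
| `h_scale` | 50 | dB HL | widening doubles the band at 50 dB HL |
| `f_valid` | (50, 15000) | Hz | advisory support of the ERB_N formula |
| `r` | 0 | — | coinciding edges, the baseline alignment |
| `normalization` | `"min"` | — | conservative pairwise normalization |
| `n_tones` | 4 (enclosing), 5 (centered) | — | reference designs |
| sweep grid | 500 log points, 250–10000 Hz | Hz | plotted tinnitus range |
| coincidence `tol` | 1e-9 | — | exact-zero semantics up to float |
| solver `tol` | 1e-9 | Hz | oracle agreement to 1e-9 relative |

## Problem sizes

The shipped tests run the full 500-point sweep for the asymmetry
properties, 15-point sweeps for design-ratio monotonicity, the
design/re-analysis round trip over 3 styles x 3 overlap targets x 3
audiograms (27 design runs at 3 kHz) plus closed-form oracle cases at 5
tinnitus frequencies and 3 targets per style, and
0.01-Hz grid scans spanning six ERB widths for the brute-force
cross-checks — sizes chosen so the whole suite exercises every code path
in well under a minute while the oracles remain exhaustive at their
stated tolerances.

## Known limitations

* The loss-widening relation is best supported between 2 and 6 kHz and
  for losses up to 50 dB HL; the package extrapolates the same linear
  form elsewhere (with warnings), as the model intends, but individual
  filter widths vary markedly around the average.
* Everything is computed at moderate sound level; level-dependent filter
  asymmetry, roex filter shapes, and the ERB-number (Cam) scale are out
  of scope.
* The package prescribes tone *frequencies* only — no stimulus levels
  (dB SL), delivery schedules, or sequence randomization.
* Choosing the best `r`, tone count, or alignment style is an empirical
  question the package deliberately leaves open; it supplies the
  candidates and their overlap statistics.
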