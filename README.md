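# erbcr

Design and analysis of acoustic **coordinated reset (CR)** therapy tones for
tonal tinnitus on the **equivalent rectangular bandwidth (ERB)** scale.

Acoustic CR therapy delivers sequences of pure tones grouped around a
patient's tinnitus pitch match f_T, aiming to desynchronize the
pathologically synchronized neural population in the tonotopic map. Because
constant steps on the ERB scale correspond to approximately constant
cortical distances, the ERB-wide band around each tone is a useful proxy
for the spatial extent of the neural sub-population it activates. `erbcr`
is for audiology researchers and therapy-app developers who need to place
CR tones with controlled overlap between those bands, taking the patient's
audiogram into account.

## Model

The normal-hearing auditory-filter bandwidth at center frequency *f* (Hz) is

    ERB_N(f) = 24.7 (0.00437 f + 1)

and sensorineural hearing loss *h* (dB HL, audiogram-interpolated on a
log-frequency axis and clamped to [0, 50]) widens it:

    ERB(h) = ERB_N (1 + h / 50)

Each tone f_j carries the band [a_j, b_j] = [f_j − ERB/2, f_j + ERB/2].
Alignment quality is quantified by relative overlaps: against the tinnitus
band, rdERB(j, f_T) = (b_j − a_T)/(b_T − a_T) for tones below f_T (and
mirrored above); between adjacent tones,
rdERB(j, k) = (b_j − a_k) / min[(b_j − a_j), (b_k − a_k)] (or `max`).
Positive values are overlaps, negative are gaps, zero means coinciding
edges.

The package provides:

- **Audiograms** — `read_audiogram()`, `threshold_at()` (linear in log f,
  constant extrapolation), `effective_loss()`, `synth_audiogram()`
  fixtures (flat / sloping / noise-notch).
- **ERB statistics** — `erb_n()`, `erb_at()`, `band_at()`,
  `rd_erb_pair()`, `rd_erb_tinnitus()`, `classify_rd()`.
- **Legacy tone analysis** — `standard_tones()` (0.766, 0.9, 1.1, 1.4 ×
  f_T), `analyze_alignment()`, `sweep_standard()`, `overlap_threshold()`.
- **Constructive design** — `design_centered()` (middle tone at f_T),
  `design_enclosing_edge()` (inner band edges pinned to f_T),
  `design_enclosing_balanced()` (f_T centered in the inner-pair interval,
  f_T = (a₂ + b₃)/2), all placing tones by bracketed root finding so every
  governed adjacent pair meets a target relative overlap *r*;
  `verify_alignment()` re-checks any result from scratch.
- **Orchestration** — `run_sweep()`, `export_result()` (CSV/JSON), and a
  CLI (`erbcr_cli()`, wrapper in `inst/cli/erbcr.R`).

## Worked example

Analyze the legacy fixed-ratio tones for a 5.5-kHz tinnitus against a
noise-notch audiogram, then design a tinnitus-centered set with coinciding
band edges:

```r
library(erbcr)
ag <- synth_audiogram("notch", center = 4000, depth = 40, base = 5)
analyze_alignment(standard_tones(5500), 5500, ag)
#> ERB overlap report: f_T = 5500 Hz, 4 tones (min-normalized pairs)
#>  tone    f       a       b rd_tinnitus
#>     1 4213 3763.96 4662.04     -0.2810
#>     2 4950 4449.77 5450.23      0.4536
#>     3 6050 5479.81 6620.19      0.5188
#>     4 7700 7073.70 8326.30     -0.9666
#> adjacent pairs:
#>  pair      rd   class
#>   1-2  0.2364 overlap
#>   2-3 -0.0296     gap
#>   3-4 -0.3977     gap

design_centered(design_spec("centered", 5, r = 0, f_T = 5500), ag)
#> CR tone alignment (centered, n = 5, r = 0, min-normalized), f_T = 5500 Hz
#>  tone       f  ratio       a       b
#>     1 3636.99 0.6613 3248.42 4025.57
#>     2 4494.53 0.8172 4025.57 4963.50
#>     3 5500.00 1.0000 4963.50 6036.50
#>     4 6628.53 1.2052 6036.50 7220.56
#>     5 7851.10 1.4275 7220.56 8481.64
#> achieved adjacent rd: 0, 0, 0, 0
```

In the first report the legacy tones are asymmetric around the tinnitus
band (tone 2 overlaps it by 45 % of its width, tone 4 sits behind a gap of
almost a full tinnitus bandwidth), and bands 2–3 and 3–4 leave gaps. The
designed set instead tiles the frequency axis with exactly coinciding ERB
edges (`rd = 0` for every adjacent pair), the middle tone pinned at f_T.

Same numbers from the shell:

```sh
Rscript inst/cli/erbcr.R synth-audiogram --kind notch --center 4000 --depth 40 --out notch.csv
Rscript inst/cli/erbcr.R design --audiogram notch.csv --ft 5500 --style centered --n 5 --r 0 --out design.json
```

## Vignette

`vignettes/erb-cr-design.Rmd` documents the model assumptions, the solver
architecture, parameter defaults, and known limitations.
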