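# cbiqus

High-frequency quantitative ultrasound (QUS) analysis of the cartilage–bone
interface (CBI) in osteochondral explants, built as a fully testable R
pipeline around a synthetic pulse-echo phantom.

## The problem

The junction between articular cartilage and the mineralized tissue beneath
it — the tidemark, or mineral front — remodels early in osteoarthritis, but
there are few non-destructive ways to watch that remodeling happen. A
focused 35 MHz transducer raster-scanned over an explant records one
A-mode radio-frequency (RF) line per position; the echo from the articular
cartilage (AC) surface and the echo from the CBI carry enough information
to measure cartilage thickness, the sharpness of the acoustic-impedance
rise at the mineral front, and the CBI's echogenicity — and to track how
all three change when the mineral front is displaced (for example by
surface-directed EDTA decalcification, a controllable mimetic of tidemark
remodeling).

`cbiqus` implements that analysis end to end for simulated acquisitions
with known ground truth:

* **phantom** — seeded synthetic RF volumes of a cylindrical explant
  (default: 3 mm explant, 6 mm × 6 mm raster at 100 µm steps = 61 × 61
  lines, 500 MHz sampling over a 10 µs window), with operators for
  surface-directed decalcification and PBS swelling;
* **envelope** — analytic-signal envelope per RF line, dB normalization to
  the volume maximum, detection of the two most prominent peaks per line
  with a 50 mV noise floor and QC verdicts;
* **qus** — the three per-line QUS parameters;
* **reconstruct** — transverse B-mode slices, en face segmented AC/CBI
  images, and maximum intensity projections (MIP), with `autoplot()`
  methods;
* **stats** — matched paired *t*-test, one-way ANOVA, Monte-Carlo
  Dunnett-type many-to-one comparisons, and Pearson correlation, with
  broom-style `tidy()`/`glance()` methods;
* **workflow** — `run_experiment()` orchestrates the full repeated-scan
  design (baseline, re-scan, condition, re-scan) and writes tables,
  images, a statistics report, and a hashed manifest.

## The three QUS parameters

For each accepted scan line with AC peak time `t_AC` and CBI peak time
`t_CBI` (round-trip):

* **Delta (mm)** — ultrasound cartilage thickness,
  `Delta = c_cartilage (t_CBI − t_AC) / 2` with a constant
  `c_cartilage = 1600 m/s`;
* **Alpha (dB/mm)** — the backscatter upswing at the mineral front,
  `Alpha = [env_dB(t_CBI) − env_dB(t_CBI − Δt_200µm)] / 0.2 mm`, where
  `Δt_200µm = 0.25 µs` is the round-trip time across 200 µm of cartilage;
* **CBI backscatter intensity (dB)** — `env_dB(t_CBI)`, the CBI peak
  amplitude relative to the volume-wide envelope maximum (0 dB).

Depth and time interconvert by `depth = c·TOF/2`; axial resolution is
`c/2f` (≈ 23 µm at 35 MHz, ≈ 53 µm at 15 MHz in cartilage).

## Worked example

```r
library(cbiqus)

spec  <- phantom_spec(seed = 7)            # default acquisition, known truth
vol   <- simulate_volume(spec)
env   <- compute_envelope(vol)
peaks <- detect_volume_peaks(env)          # 50 mV floor, 1 µs merge window
qus   <- compute_qus(env, peaks)
summarize_explant(qus, "baseline")
#> # A tibble: 1 × 8
#>   scan_label n_lines delta_mean delta_sd alpha_mean alpha_sd cbi_mean cbi_sd
#> 1 baseline       705       1.07  0.00292       150.     28.0    -10.7  0.423
```

705 of the 3721 scan lines pass QC (the explant covers about a fifth of
the field); the per-line thickness Delta averages 1.07 mm, and the CBI
echoes sit about 10.7 dB below the AC reflection — the echogenicity regime
this phantom is built to emulate. Displace the mineral front 100 µm deeper
and scan again:

```r
post  <- apply_decalcification(spec, front_shift = 100, mode = "brief")
vol2  <- simulate_volume(post, seed = 8)   # fresh noise, same explant
env2  <- compute_envelope(vol2)
qus2  <- compute_qus(env2, detect_volume_peaks(env2))
d     <- pair_qus_records(qus, qus2)       # per-line pairing by position
mean(d$d_delta_mm) * 1000; sd(d$d_delta_mm) * 1000
#> [1] 99.9
#> [1] 4.14
```

The programmed 100 µm shift is recovered as 99.9 ± 4.1 µm across the 705
paired lines — well inside one 23 µm axial resolution. The full
matched-pair study (several explants per arm, two baseline scans, paired
*t*-tests per arm and re-scan precision) is one call:

```r
res <- run_experiment(demo_design(seed = 1), "demo_out")
res$stats$arms$`EDTA-brief`$p      # paired t across explants
baseline_precision(res)            # re-scan precision, µm
```

Images come from `autoplot()` on `enface_segment()`, `transverse_slice()`
and `mip_project()` results.

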