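---
title: "Methods: quantitative ultrasound of the cartilage–bone interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative ultrasound of the cartilage–bone interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbiqus)
```

`cbiqus` analyzes raster-scanned pulse-echo RF volumes of osteochondral
explants: per scan line it finds the articular-surface (AC) and
cartilage–bone-interface (CBI) echoes and derives cartilage thickness
(Delta), the backscatter upswing at the mineral front (Alpha), and the CBI
backscatter intensity. Because no public acquisitions of this kind exist,
the package ships a first-class synthetic phantom with known ground truth;
every downstream stage is tested against that truth. This vignette records
the model, its assumptions, the defaults, and the numerical choices.

## The phantom model

Each scan line at lateral position $(x, y)$ is a sum of echoes plus white
Gaussian noise:

$$ s(t) = A_{AC}\, p(t - t_{AC}) + A_{CBI}\, p(t - t_{CBI})
        + \sum_j A_j\, p(t - t_j) + \varepsilon(t), $$

where $p$ is the transmit pulse, $t_{AC} = 2 z_s / c_{PBS}$ is the
round-trip time to the (optionally tilted) articular surface at one-way
depth $z_s$, and $t_{CBI} = t_{AC} + 2 h / c_{cart}$ adds the round trip
through cartilage of thickness $h$. The third term is an optional train of
sub-CBI bone scatterers. Positions outside the circular explant mask carry
only noise.

**Pulse.** A Gaussian-enveloped cosine at the center frequency, with the
envelope width chosen so the −6 dB spectral band spans
`fractional_bandwidth × center_frequency` (default 16/35 at 35 MHz, i.e. a
27–43 MHz band). This shape was chosen because its envelope is available
in closed form, which gives the test suite exact oracles for envelope
extraction and echo arrival times.

**Focal sensitivity.** A single Gaussian weight in one-way depth,
$w(z) = \exp[-(z - z_f)^2 / 2\,d^2]$ with focal distance $z_f$ = 12.7 mm
and depth-of-field scale $d$ = 2 mm. This is the simplest model that
reproduces the qualitative behavior of a fixed-focus transducer — echo
strength migrates between the surface and the CBI as the focus is moved —
without modeling diffraction. The default standoff places the *CBI* at the
focus (the configuration that favors CBI measurements), which is why the
default standoff is `focal_distance − mean(thickness)`.

**Amplitudes.** $A_{AC} = R_{AC}\, w(z_s)$ and
$A_{CBI} = R_{CBI}(x, y)\, w(z_s + h)\, 10^{-\alpha \cdot 2h/20}$ with a
frequency-independent one-way attenuation $\alpha$ = 1 dB/mm in cartilage.
$R_{CBI}(x, y)$ is a spatially correlated log-normal field (correlation
length 0.4 mm, marginal spread 0.5 dB), reflecting the punctate, laterally
heterogeneous en face appearance of real CBI backscatter; it is drawn once
per phantom from the spec seed, so one spec *is* one explant and repeated
simulations with fresh noise seeds are re-scans of it.

**Default scales.** The defaults are anchored to the tissue regime the
phantom emulates: mean cartilage thickness 1.072 mm (cohort scale, with
explant-to-explant sd 0.209 mm in `run_experiment()`), sound speeds
1500 m/s (PBS) and 1600 m/s (cartilage), AC reflectivity 1 V, and a CBI
geometric-mean reflectivity of 0.331 V — the value at which, after the
round-trip attenuation through 1.072 mm and the focal weights, the CBI
envelope sits ≈ 10.5 dB below the volume maximum. Noise sd is 8 mV so
that the 50 mV QC floor sits at ≈ 6σ: out-of-mask lines essentially never
produce candidates, while both tissue echoes clear it comfortably.

**Operators.** `apply_decalcification()` raises the thickness map by
`front_shift` everywhere in the mask (the mineral front recedes; the
apparent cartilage deepens). In `mode = "full"` it also scales the CBI
reflectivity field by `−amplitude_drop` dB and enables bone scatterers:
once the calcified layer has lost its impedance contrast, deeper
structures become visible. `apply_swelling()` raises thickness only. Both
return new specs; both are exactly additive, which the tests exploit.

**What the phantom does not emulate.** No diffraction or lateral beam
width (each line is independent), no refraction, no speckle beyond the
scatterer sum, no frequency-dependent attenuation, no electronic ring-down
beyond a guard interval. Passing tests therefore demonstrate correctness
of the *analysis* under a controlled echo model — not robustness to every
artifact of real acquisitions.

## Envelope and peak detection

The envelope is the magnitude of the analytic signal, computed per line by
the FFT construction (positive frequencies doubled, negative zeroed). The
dB twin is normalized to the **volume-wide** maximum, not per line: with
one shared reference the strongest reflector in the volume defines 0 dB,
and CBI intensities from different positions and scans are comparable.

Peak detection per line:

1. local maxima of the envelope are candidates, excluding a 0.1 µs
   ring-down guard at the window start (plateaus count once, at their
   first sample);
2. candidates below the 50 mV floor are dropped — the floor applies to the
   linear envelope, since it is an instrument-level threshold in mV;
3. one echo complex can carry several local maxima once noise rides on
   it, so candidates are collapsed by non-maximum suppression within half
   the 1 µs merge window; the representative of a complex is its envelope
   maximum;
4. each representative is scored by the mean amplitude of all candidates
   within its window — a local-mean prominence that ranks echo complexes
   above isolated mid-zone spikes — and the two top-scoring
   representatives, ordered in time, become (AC, CBI). Score ties resolve
   toward the earlier arrival, which is stable and depth-ordered.

QC failures are data, not errors: `qc_reason` distinguishes `no_peaks`,
`below_floor` (maxima exist but none reach the floor), and `single_peak`.
Lines pass QC only with two peaks at or above the floor, and downstream
QUS functions refuse QC-failed lines explicitly.

Two readings of the 1 µs averaging rule were possible: replace peak
amplitudes by window means, or use the window mean only to *rank*
candidates. Ranking was chosen: it leaves the reported amplitudes as true
envelope peaks (so CBI intensity is the actual peak height) while still
suppressing isolated spikes, and it is the reading the exhaustive
pair-search oracle in the tests pins down.

## QUS parameters

* `compute_delta()`: $\Delta = c_{cart}(t_{CBI} - t_{AC})/2$ with
  $c_{cart}$ = 1600 m/s.
* `compute_alpha()`: the pre-point 200 µm shallower than the CBI is
  converted to time with the *cartilage* speed (the zone above the CBI is
  cartilage), giving 0.25 µs round trip = 125 samples at 500 MHz; the
  pre-point intensity is the single-sample dB envelope at the rounded
  index — the plainest reading of "200 µm prior to the peak", and the
  resampling test shows the rounding costs < 1 dB/mm. Alpha is computed on
  the dB-normalized envelope (its units are dB/mm). Lines whose pre-point
  falls before the AC peak are excluded from Alpha (recorded as `NA`),
  never raised.
* `compute_cbi_intensity()`: the dB envelope at the CBI peak.

Per-explant summaries use the arithmetic mean and sample sd (n−1); the sd
of a single record is 0 by convention so summaries are total. Per-line
pairing across scans joins by grid position — the scan holders fix the
explant orientation between scans, so positions correspond — and a line
failing QC in either scan drops out of the pair.

## Image reconstruction

`normalize_full_thickness()` min–max rescales the whole volume to [0, 1]
before segmentation. En face slabs are tied to the detected peaks:
`[t_AC, t_AC + 0.25 µs]` for the AC layer and `t_CBI ± 0.25 µs` for the
CBI (200 µm at 1600 m/s). Slab aggregation defaults to the maximum —
consistent with the MIP convention used for the projections — with mean
behind a flag; whether the original en face images used max or mean is not
determinable, and max makes the en face CBI image track the reflectivity
field most directly. QC-failed positions are missing (`NA`) and excluded
from image statistics; slabs reaching past the window are clipped and
counted. Transverse slices default to the middle row, with a piecewise
depth axis: coupling-bath speed above the row's median detected AC time,
cartilage speed below. `mip_project()` is the element-wise maximum along
depth, x, or y.

## Statistics

All tests are implemented from their formulas; base R supplies only the
reference distributions. Tests are two-sided throughout. The paired
*t*-test rejects zero-variance differences rather than returning a
meaningless statistic. ANOVA requires every group to have at least two
observations and nonzero variance.

The Dunnett-type many-to-one adjustment is computed by seeded Monte Carlo:
under the joint null, group means and the pooled variance are drawn from
their exact sampling distributions (the shared control induces the
correct correlation between comparisons), and the adjusted p of each
comparison is the tail probability of $\max_j |T_j|$. This is transparent,
testable by calibration, and reproducible from the recorded seed; with the
default 200 000 draws the Monte-Carlo error of an adjusted p near 0.05 is
about ±0.0015. The post-hoc Student's *t* uses the pooled variance,
matching the classical ANOVA post-hoc convention. A test cross-checks the
Monte-Carlo adjustment against the single-step parametric implementation
in `multcomp` to 0.02.

## Problem sizes and seeds

Checks that need only one volume run at the full default acquisition
(61 × 61 × 5000 samples). Replicate-heavy checks — matched-pair recovery
arms, the 100-replicate no-op false-positive rate, the 30-explant
precision cohort — run on reduced rasters (11 × 11 over 1 mm with a 4 µs
window, or 7 × 7 over 0.6 mm with 3 µs) chosen so an arm of six explants
simulates in seconds; the explant mask still covers dozens of accepted
lines per scan, which is what the paired per-line statistics need.
Calibration simulations use 5000 replicates (paired-*t* type-I error),
2000 (Dunnett family-wise error, with 20 000 Monte-Carlo draws per call),
and 2000 (power). Every stochastic step takes an explicit seed;
`run_experiment()` derives per-explant seeds deterministically from the
master seed, so identical designs reproduce byte-identical QUS tables and
manifest hashes.

## Known limitations

* A constant cartilage sound speed is assumed; real speeds vary with
  composition, so absolute Delta carries a proportional bias that the
  matched-pair design cancels only partially.
* Alpha's absolute scale depends on the pulse bandwidth and the noise
  floor at the pre-point; it is comparable within an acquisition
  configuration, not across instruments.
* The Gaussian focal model and the absence of lateral coupling mean the
  phantom cannot probe lateral-resolution artifacts (e.g. surface tilt
  interacting with beam width).
* Volume containers use R's native serialization with validated metadata;
  they are not portable to non-R tools (phantom configs, peak and QUS
  tables, summaries and reports are plain text).
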