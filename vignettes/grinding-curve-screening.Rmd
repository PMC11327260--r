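---
title: "Grinding-curve screening of tooth enamel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grinding-curve screening of tooth enamel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grindcurve)
```

## The problem

Electron spin resonance combined with uranium-series analysis (ESR/U-series)
is the workhorse for dating Pleistocene fossil teeth beyond the radiocarbon
limit, but its accuracy degrades when the enamel has taken up (or leached)
uranium during burial. Diagenetic dissolution–reprecipitation makes carbonate
hydroxyapatite crystals larger and more ordered (Ostwald ripening), and that
increase in atomic order correlates with uranium content. Transmission FTIR
offers a fast, cheap proxy for atomic order — if one can get around the fact
that infrared band shapes of powdered apatite depend on *particle size* as
well as on atomic order.

The grinding-curve method does exactly that. Two statistics are measured on
a KBr-pellet transmission spectrum:

* **FWHM(ν3)** — the full width at half maximum (cm⁻¹) of the ν3 phosphate
  band near 1034 cm⁻¹, measured on the baseline-corrected band (straight
  baseline anchored at 2000 and 400 cm⁻¹);
* **IRSF** — the infrared splitting factor of the ν4 phosphate doublet:
  `(h604 + h565) / hvalley`, all three heights measured from a straight
  baseline anchored at 820 and 400 cm⁻¹.

A single (IRSF, FWHM) point confounds order and particle size. Regrinding
the same pellet more and more vigorously and re-measuring traces a
*grinding curve* in the (IRSF, FWHM) plane; the curve's **position** (not
any single point on it) indexes atomic order. A fossil whose grinding curve
overlaps the reference curve of its species is well preserved; a curve
offset towards lower FWHM at matched IRSF indicates recrystallisation and
likely uranium uptake, and the specimen should not have priority for dating.

## Pipeline

`read_spectrum_csv()` / `read_jcamp()` load two-column spectra (stored
wavenumber-descending); `compute_band_metrics()` produces both statistics;
`fit_grinding_curve()` fits FWHM on IRSF by ordinary least squares;
`pool_reference()` pools replicate curves of one species into a reference
with a between-replicate dispersion; `assess_offset()` and
`screen_assemblage()` classify and rank test specimens. The bundled
`species_registry()` carries the 15 African ungulate reference species
(Equidae, Rhinocerotidae, Giraffidae, Hippopotamidae and 11 Bovidae), whose
deposited library follows the `Species<curve>_<grinding>` file naming that
`parse_library_filename()` decodes.

### Numerical choices in the metrics

* **Peak finding** is a direct maximum of the baseline-corrected absorbance
  inside a search window — 1100–950 cm⁻¹ for ν3, 615–595 and 580–550 cm⁻¹
  for the two ν4 peaks. The windows are wide enough for biological
  variation but exclude the carbonate ν2 band at 872 cm⁻¹. Ties go to the
  highest wavenumber, for determinism.
* **Half-maximum crossings** are found by scanning outward from the peak to
  the first bracketing sample pair and interpolating linearly. Taking the
  *first* crossing makes the measure robust to shoulder side-lobes that
  re-cross further out.
* **The ν4 valley** is located (not fixed at a nominal wavenumber) as the
  corrected minimum strictly between the two located peaks, and measured
  from the same 820–400 cm⁻¹ baseline as the peaks, following the standard
  splitting-factor literature. A valley at or below the baseline, or a
  merged doublet with no interior minimum below both peaks, is a metric
  error rather than a number.
* **No smoothing** is applied before the metrics: smoothing biases FWHM.
* **Discretisation error.** At the 4 cm⁻¹ acquisition spacing, both
  statistics agree with brute-force evaluation of the same analytic band
  models on a 0.01 cm⁻¹ grid to within 0.5 % for band widths in the range
  the doublet actually shows after particle-size broadening (Gaussian
  σ ≳ 12 cm⁻¹). The error grows for sharper bands (about 0.6 % at
  σ = 10 cm⁻¹), driven mostly by sampling the 565 cm⁻¹ peak and the valley
  off-grid; this is a property of the acquisition grid itself, not of the
  implementation.

### Curve fitting and the offset score

IRSF is the predictor and FWHM the response; offsets are therefore vertical
and in cm⁻¹. R² is the squared Pearson correlation, so the choice of axes
does not affect it. The reference's `replicate_spread` is the standard
deviation, across replicate curves, of each curve's mean vertical residual
from the pooled line.

`assess_offset()` computes the mean vertical offset of the test points that
fall inside the reference's IRSF range — point-to-line, never line-to-line,
because real curves overlap only partially, and never extrapolated beyond
the sampled particle-size range (insufficient overlap is reported instead;
default minimum overlap, 25 % of the reference range). The score divides
the offset by `max(replicate_spread, 0.5 cm⁻¹)`; the floor guards against
near-zero spread estimates from small replicate numbers. The label
threshold defaults to a score of 2 — roughly a two-sigma rule; no numeric
criterion exists in the field for "the curves overlap", so the threshold is
exposed everywhere and recorded in all outputs. Negative scores (lower
FWHM at matched IRSF) are labelled `offset_ordered`, the direction
associated with recrystallisation and uranium uptake.

## The synthetic generator

`synth_params()` / `synth_grinding_series()` emulate enamel spectra so the
entire pipeline can be exercised and validated without any external data.
A spectrum is a sum of Gaussian bands — ν3 main (1034 cm⁻¹) plus shoulder
(1096), the ν4 doublet (604, 565), carbonate bands (1455, 1415, 872) and a
broad OH feature (~3400) — convolved with a Gaussian particle-size kernel
of width *k* (done analytically: variances add, area is conserved), plus a
scattering baseline that shrinks as *k* does, plus white noise
(sd 0.002 absorbance).

Atomic order enters as a latent straight line in the (IRSF, FWHM) plane:
at crystallinity *c* ∈ (0, 1] the line passes through
`fwhm_anchor / c` (default anchor 52 cm⁻¹) at IRSF 3.4 with slope
−7 cm⁻¹ per IRSF unit. For each grinding level the generator *solves* the
kernel width against that level's IRSF target (defaults 2.7, 3.4, 4.1; the
solved widths come out strictly decreasing, i.e. finer particles with more
vigorous grinding) and then solves the ν3 width scale against the line's
FWHM at that IRSF. Noise-free, the measured statistics of the emitted
4 cm⁻¹ spectrum therefore sit *exactly* on the latent line: grinding moves
points along the curve, crystallinity moves the curve, and the two effects
are decoupled by construction — the operational core of the method, made
literal. A forward mode (`grinding_kernel_widths =`) skips the calibration
when explicit kernel widths are wanted; collinearity is then only
approximate.

Randomness, all derived from one integer seed: a per-replicate vertical
jitter of the latent line (sd 0.4 cm⁻¹, a within-operator reproducibility
scale deliberately kept below the 0.5 cm⁻¹ score floor — with only five
replicate curves, a spread estimate far above the floor would make the
nominal two-sigma rule heavy-tailed), a per-grinding jitter of the IRSF
target (sd 0.05; grinding vigour is subjective, and this moves points
*along* the line, not off it), and white measurement noise. Identical
parameters and seed give bit-identical spectra.

Default crystallinities in the simulated 15-species library span
0.78–0.98, fanning the curves out as real inter-species differences do;
assemblage simulations use a reference at 0.82 so that strongly
recrystallised fossils (offsets to −10 cm⁻¹) remain representable within
crystallinity ≤ 1.

**What the generator does not emulate:** the asymmetric shape of real
enamel ν3, Voigt/instrument line shapes, Mie scattering physics,
carbonate-content variation, and any relation between offset magnitude and
actual uranium concentration. Passing tests show the *pipeline* is correct
and the *decision rule* well calibrated under the stated noise model; they
are not biological claims, and synthetic absolute values must not be
compared against real spectra.

## Validation design and problem sizes

The test-suite and the acceptance script rerun, per invocation:

* the full simulated design — 15 species × 5 replicate curves × 3
  grindings = 225 spectra, written in both CSV and JCAMP-DX (450 files) and
  rebuilt into 15 references;
* closed-form checks (Gaussian FWHM = 2√(2 ln 2) σ; a piecewise-linear ν4
  triplet with heights 1, 1 and valley 0.5 giving IRSF exactly 4);
* dense-grid (0.01 cm⁻¹) brute-force agreement for multi-band analytic
  models; a normal-equations check of the least-squares fit to 1e−10;
* 200 seeded grinding series at default noise, all with r² > 0.9, echoing
  the r² range (0.94–0.98) reported for the real library, which can only be
  reproduced exactly from the deposited archive;
* full-pipeline Monte-Carlo operating characteristics: 500 null
  repetitions (false-offset rate ≤ 5 % at threshold 2), 500 repetitions
  with an injected offset of 4× the floored reference spread (detection
  ≥ 95 %), and 200 assemblages of 9 fossils of which 3 carry offsets of
  −6 to −10 cm⁻¹ (the recrystallised trio must rank last).

These sizes keep a full run in the low minutes on a single core while
leaving all rates several Monte-Carlo standard errors clear of their
bounds.

## Known limitations

* The offset score is one defensible formalisation of "the curves
  overlap"; field practice has so far been visual, and the published
  record does not fix a quantitative criterion. The threshold, floor and
  minimum-overlap fraction are all explicit parameters.
* References built from a *single* replicate curve have no internal
  dispersion estimate (spread 0, floored in scoring, flagged in the
  object).
* The OMNIC `.spa` binary format is not parsed; every deposited spectrum
  also exists as CSV, which is the supported path (with JCAMP-DX as the
  interchange format).
* Screening says nothing about uranium *leaching* that leaves
  crystallinity unchanged; it is a pre-screening tool, not a substitute
  for U-series measurement.
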