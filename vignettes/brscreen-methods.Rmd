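---
title: "Methods: bromine-contaminant screening by full-scan HRMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bromine-contaminant screening by full-scan HRMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brscreen)
```

`brscreen` implements an accurate-mass strategy for identifying and
quantifying brominated contaminants — worked out on the three
mono-modified byproducts of tetrabromobisphenol-S
bis(2,3-dibromopropyl ether): TBBPS-MAE (Br₄), TBBPS-MBAE (Br₅) and
TBBPS-MDBPE (Br₆) — in centroided full-scan Orbitrap-class data. This
vignette records the models, the defaults and why they are set the way
they are, and what the synthetic-data tests do and do not demonstrate.

## Exact-mass arithmetic

All masses derive from a pinned table (AME2020 isotope masses, IUPAC
2021 representative abundances, CODATA 2018 electron mass) shipped as a
versioned CSV. An ion's m/z is the sum of its atoms' exact isotope
masses, minus `charge × m_e` (anions gain electrons), divided by
|charge|. The `[M−H]⁻` convention is *neutral − H atom + electron*: this
is required to reproduce vendor-calculated values — e.g. the two-⁸¹Br
isotopologue of deprotonated TBBPS-MAE computes to 604.69196, matching
the published Orbitrap value to the fifth decimal — and is therefore
fixed, not configurable. Isotopologues are expressed as explicit
substitution counts (`c("81Br" = 2)`), validated against the ion's
element counts.

Mass errors are reported as absolute ppm with the theoretical value in
the denominator, matching how screening tolerances are stated
(identification gate: 5 ppm).

## Isotope envelopes

Two predictors are provided, with provenance tags so the caller always
knows which approximation produced a pattern:

* `binomial_br_envelope()` — bromine only: n_br + 1 peaks spaced by
  m(⁸¹Br) − m(⁷⁹Br) = 1.99795 Da with binomial abundances. With
  p(⁸¹Br) = 0.5 the ratios are exactly the Pascal rows (1:4:6:4:1 …)
  printed in reference tables; with the natural p(⁸¹Br) = 0.4931 they
  are slightly asymmetric (the Br₆ central/monoisotopic ratio is 18.4,
  not 20).
* `fine_structure_envelope()` — exact multinomial expansion over every
  element's isotopes, convolved element by element with pruning
  (default 1e-4 relative abundance), then merged into centroids
  wherever two exact peaks are closer than the Gaussian FWHM
  (m/z / resolving power; default 60000, an Orbitrap-class setting).

At resolving power 60000 the ¹³C₂ and ³⁴S satellites of each bromine
isotopologue (about +2.0067 and +1.9958 Da) are unresolvable from the
next ⁸¹Br centroid (+1.9980 Da) and merge into it, while the single-¹³C
satellites stay resolved between the bromine peaks. The merged bromine
centroids therefore deviate from the idealized integer pattern by up to
about +16% on the heaviest peak. This is physically correct behaviour,
and it is why envelope comparisons throughout the package use a default
per-peak relative-abundance tolerance of **20%** (the integer ratio
string is derived output via `ratio_string()`, never the comparison
basis). `envelope_match_score()` pairs predicted to observed peaks
greedily by nearest m/z within a ppm tolerance and returns
`1 − mean(|obs − pred|/pred)` over matched peaks, clamped to [0, 1] and
zero when fewer than two predicted peaks match — one peak carries no
pattern evidence.

## Chromatography: EICs and peak integration

Extracted ion chromatograms sum centroid intensities within a ppm
window per scan. Peak integration searches `expected RT ± rt_tol`
(default ±0.10 min; retention times are known to 0.01 min precision but
no window is standardized, so a generous ±0.10 min was fixed) for local
maxima, picks the one nearest the expected RT (ties to the higher
intensity), requires apex S/N ≥ 3 (the conventional detection
threshold), and integrates by trapezoid between the points where the
trace falls below `max(3 × noise, 0.5% of apex)`. Baseline noise is the
scaled MAD of the trace outside the search window — a robust estimate
that ignores the peak itself. On noiseless Gaussian peaks the
integrated area is within 1% of the analytic A·σ·√(2π).

## Targeted identification

`identify_target()` reports a detection only when all four criteria
hold: quantifier peak present (S/N ≥ 3, within the RT window), mass
error of the intensity-weighted observed m/z against the *theoretical*
isotopologue m/z ≤ 5 ppm, qualifier peak co-eluting within half the RT
tolerance (same chromatographic peak), and qualifier/quantifier area
ratio within ±20% (relative) of the fine-structure prediction. Failed
criteria are recorded in `flags`, so every rejection is auditable.
Relaxing any tolerance can only turn non-detections into detections
(monotonicity, covered by a property test).

## Untargeted bromine-compound discovery

`discover_br_unknowns()` chains centroids spaced by the Br isotope
spacing (±0.01 Da default), then infers the bromine count by
least-squares fit of the sum-normalized intensities against natural
binomial envelopes for candidate counts bracketing the cluster size
(±1, tolerating one missing edge peak). Two design choices matter:

* clusters must contain at least two chained peaks *and* pass a
  binomial-shape gate (mean absolute deviation of normalized
  intensities ≤ 0.15). The spacing alone is not rare enough in dense
  spectra; the shape gate is what keeps halogen-free spectra at zero
  false hits.
* the decimal-part ("mass defect decreases with ⁸¹Br count") heuristic
  is implicit in the spacing chain and not enforced as a hard gate.

Hits are deduplicated across adjacent scans by monoisotopic m/z
(±0.02 Da) and RT (±0.2 min), keeping the most intense occurrence.
Optionally each hit's monoisotopic peak is decomposed into candidate
formulas.

`decompose_formula()` searches all C/H/N/O/S/Br compositions within
user bounds (default C≤20, H≤20, N≤2, O≤6, S≤2, Br≤8 — sized for
bromophenol-class unknowns), keeps |Δppm| ≤ tolerance, filters by ring
double-bond equivalents computed on the re-protonated neutral
(RDBE = C − (H+Br)/2 + N/2 + 1 ≥ 0; electron-parity rules beyond RDBE
are deliberately not enforced), and ranks by ppm error. It is verified
against a naive nested-loop oracle.

## Quantification and method validation

* Calibration: unweighted OLS on ≥ 5 distinct levels (reference series:
  7 points, 0.05–100 ng/mL), accepted when R² > 0.99. Unweighted fitting
  follows the plain linear calibration convention of the underlying
  method; a weighted variant was considered and left out of v1.
* Quantification: `conc = (area − intercept)/slope`, converted to ng/g
  dry weight via `× extract volume / dry mass`; negative
  back-calculations floor at 0 with a flag, extrapolations are flagged.
* Recovery: 100 × measured/spiked, aggregated with the sample SD (n−1).
* Matrix effect: post-extraction matrix-spike area over solvent-standard
  area; 1 means no effect.
* IDL: smallest injected mass whose 5 replicates are all detected with
  RSD ≤ 20%.
* MDL: `t(0.99, n−1) × SD` of n ≥ 7 replicate spiked measurements
  (t(0.99, 9) = 2.821 at the reference n = 10). The exact literature
  variant behind replicate-spike MDLs is not uniquely specified; the
  one-sided 99% Student-t convention is an explicit, documented choice,
  and MDL scales linearly with the replicate SD by construction.
* Cohort summaries: a sample counts as detected when identification
  passed *and* the quantified concentration is ≥ the compound MDL;
  ranges/means/medians are computed over detected samples only, with no
  ½-MDL substitution for non-detects (matching how biota surveys report
  detected ranges).
* Blank policy: any target quantified in a procedural blank at or above
  its MDL voids the batch.
* `bioaccumulation_flag()` applies the strict log K_ow > 5 and
  BCF > 5000 rule to property values supplied as inputs (e.g. EPI Suite
  estimates); the package never estimates these properties itself.

## The synthetic-data generator

The simulator exists so every stage is testable without instrument
files; its defaults *are* the study conditions and are not tuned per
test:

* retention times 4.20 / 4.56 / 4.80 min, Gaussian peaks with
  σ = 0.05 min, scans every 0.01 min (a 6-min run = 600 scans);
* per-centroid mass noise Normal(0, 1.0 ppm) — conservative relative to
  the sub-0.4 ppm errors of the real instrument — and unit-mean
  log-normal intensity noise with CV 5%;
* response factors equal to the published calibration slopes
  (519149 / 421073 / 363618 counts per ng/mL), so the quantifier peak
  area equals `slope × conc` by construction;
* an exponential chemical baseline (mean 50 counts, Poisson 20
  centroids/scan over 100–1000 Da);
* cohort scenario: 38 samples, 11 mollusk species cycled over sampling
  years 2009–2013, per-compound two-part concentration model —
  Bernoulli detect probabilities (0.05, 0.39, 0.95) × log-normal
  rejection-sampled into the detected ranges (0.1–0.2, 0.1–1.6,
  0.3–4.1 ng/g dw) with medians near 0.14 / 0.18 / 1.1 ng/g — plus
  extraction recovery 0.85 and matrix factor 0.95; species/year
  covariate effects are deliberately absent (none were observed in the
  underlying survey data the scenario emulates).

What the generator does *not* emulate: realistic biological matrix
background (the baseline is sparse and unstructured), chromatographic
tailing, correlated drift in mass accuracy, and ion-suppression that
varies across the run. Passing closed-loop tests therefore demonstrates
the correctness of the algorithms under the stated noise model, not
instrument-grade performance on real extracts.

## Problem sizes and numerical choices

Test and acceptance workloads use desk-scale sizes chosen as the
package's own defaults: 38-sample cohorts, 100-seed noise replicates,
200 single-scan spectra for discovery sensitivity, and calibration
windows of ~1.2 min around each analyte. Concentration-recovery
properties are asserted at 10× MDL with < 5% bias, detection
frequencies against the generator's realized ground truth within ±10
percentage points (binomial spread at n = 38). Fine-structure pruning
(1e-4), centroid-merge criterion (FWHM), the S/N = 3 gate and the
integration-bound rule (3σ of baseline or 0.5% of apex, whichever is
larger) are fixed constants; degenerate inputs (empty formulas,
prune = 1, non-ascending calibration levels, all-equal areas, zero
spikes) raise errors rather than returning silent results.

## Known limitations

* Bromine-only halogen logic: chlorine and mixed Br/Cl envelope
  classification is out of scope in v1.
* mzML support is read-only, centroided MS1, via `mzR`; vendor raw
  files and profile-mode centroiding are not handled.
* MS² information is not used beyond exact-mass checks of listed
  fragment compositions; no structure elucidation.
* The published "minimum isotope" observed values differ from
  first-principles calculation by ~0.5 ppm; they are treated as
  observations, never as calibration constants.
* No censored-data statistics for non-detects (Kaplan–Meier etc.);
  summaries follow the detected-samples-only convention.
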