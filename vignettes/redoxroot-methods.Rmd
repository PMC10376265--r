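---
title: "Methods: ratiometric redox imaging, cell-cycle gating and growth analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric redox imaging, cell-cycle gating and growth analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxroot)
```

## Scope and model

`redoxroot` quantifies the glutathione redox state of nuclei and cytosol in
proliferating root-meristem cells from ratiometric roGFP2 fluorescence, the
distribution of cells over the G1/S/G2 phases from DNA-content flow
cytometry, and root growth rates under redox-active treatments (hydrogen
cyanamide, HC, 1.5 mM; hydroxyurea, HU, 3 mM; untreated control).  Because
the emulated study deposited no raw data, the package ships a first-class
synthetic-data generator whose ground truth is set to the study's reported
values; every analysis stage is validated as a parameter-recovery problem
against that truth.

### Ratiometric model

roGFP2 is excited at 405 nm (favouring the oxidised chromophore) and
488 nm (favouring the reduced one).  For a compartment with excitation
ratio $R = I_{405}/I_{488}$ and calibration endpoints $R_{red}$ (fully
reduced, DTT-treated) and $R_{ox}$ (fully oxidised, H2O2-treated), the
degree of oxidation is

$$OxD = \frac{R - R_{red}}{k\,(R_{ox} - R) + (R - R_{red})}, \qquad
  k = \frac{I_{488}^{min}}{I_{488}^{max}},$$

the unique reading of the calibrated two-state mixing model that satisfies
$OxD(R_{red}) = 0$ and $OxD(R_{ox}) = 1$.  A point worth making explicit:
488-nm fluorescence is *minimal* for the oxidised probe, so $I_{488}^{min}$
is measured on the oxidised reference and $I_{488}^{max}$ on the reduced
one, and $k < 1$ on a typical instrument.  (Descriptions that attach "min"
to the reduced state circulate in the literature; with that attribution the
boundary identities above fail, so the package pins the consistent one with
unit tests.)

The probe potential follows the two-electron Nernst equation

$$E = E^{0'}_{probe} - \frac{RT}{zF}\,\ln\frac{1-OxD}{OxD},$$

with $R = 8.315\,$J K$^{-1}$ mol$^{-1}$, $T = 298.15\,$K, $z = 2$,
$F = 9.648\times 10^4\,$C mol$^{-1}$, so $RT/zF = 12.848\,$mV.  Assuming
probe-glutathione equilibration, the couple potential additionally uses the
total glutathione concentration:

$$E_{GSH} = E^{0'}_{GSH} - \frac{RT}{zF}\,
  \ln\frac{2\,[GSH]_{tot}\,(1-OxD)^2}{OxD}.$$

Both are reported per replicate; no attempt is made to reconcile them into
one "true" potential.

### Choice of the probe midpoint potential

$E^{0'}_{probe}$ is not measurable from the data the package emulates, and
published roGFP2 values cluster around $-280\,$mV.  The scenario anchors
(mean OxD / mean E pairs, and the 2 h OxD/E pairs of the treated cytosol)
are only jointly consistent with a single midpoint near the upper end of
that cluster; the package default is $E^{0'}_{probe} = -279.2\,$mV, shared
by the generator and the analysis so that simulated scenarios are
self-consistent.  It is a plain config field
(`nernst_constants(e0_probe_mV = )`) for instruments calibrated
differently.  The glutathione defaults are $E^{0'}_{GSH} = -240\,$mV and
$[GSH]_{tot} = 2.5\,$mM, typical literature values for plant cells, also
overridable.

### Averaging order

Mean potentials are computed per replicate and then averaged (never as the
potential of the mean OxD).  The two orders differ by a Jensen gap — the
Nernst transform is nonlinear — of the order of 1 mV at the observed
between-timepoint dispersion, which is larger than the reporting precision,
so the order is fixed and tested.

## The synthetic-data generator

### Truth trajectories

Each scenario defines a per-compartment OxD time course on the canonical
2-hourly 0–24 h grid as a two-parameter logit-linear family
$OxD_t = \mathrm{logit}^{-1}(a + b\,s_t)$, where $s_t$ is a fixed
qualitative shape (control: mid-window excursion, reduced at 2 h and in the
final hours; HC: flat early phase, saturating oxidation after ~12 h; HU:
early oxidation burst around 4–8 h, later reduction).  Because $E$ is
affine in the logit, $a$ is fixed by the target *mean potential* and $b$ is
solved by one root-find so the *mean OxD* matches its target
simultaneously; the treated scenarios additionally pin the 2 h cytosolic
OxD (HC 37%, HU 32%) exactly and solve the remaining points.  The
between-timepoint dispersion this induces is not decorative: it is exactly
the dispersion required for the pair (mean OxD, mean E) to be mutually
consistent, and it stays within the potential ranges the emulated study
reports.  Configurations requesting other timepoints sample this canonical
trajectory (logit-interpolated).

### Images

A frame holds ~20 elliptical cells on a jittered grid, each a cytosol ring
(even mask id $2i$) with a nested nucleus (odd id $2i-1$); ≥1% of pixels
remain background.  Per-cell 488 brightness is lognormal
(`i488_base = 3000` AU, sdlog 0.25).  The 488 signal scales with oxidation
as $(1-OxD) + k\,OxD$ and the 405 signal is the inverted calibrated ratio
times the 488 signal, so the noiseless pixel ratio is exact by
construction.  Noise: Poisson shot noise at a gain of 4 AU/photon, uniform
background of 100 AU, Gaussian read noise (SD 10 AU), clipped to the
16-bit cap.  Biological replicate variability is a Gaussian jitter of the
true OxD on the logit scale (SD 0.05, keeping OxD in (0,1) and leaving the
replicate-mean potential unbiased); the value was chosen once so that a
5-replicate mean recovers truth within ±1.5 OxD points with ~3σ margin,
and yields per-timepoint SEMs comparable to the emulated study's.
Calibration pairs share one cell layout and brightness field between the
reduced and oxidised frame (the references are the same roots imaged in
both states); without this, between-frame brightness differences bias
$\hat k$ by several percent and drag recovered OxD down by 1–2 points.

What the generator does *not* emulate: optical sectioning and PSF blur,
photobleaching, pH sensitivity, chromatic registration error, or
heterogeneity of oxidation within a compartment.  Passing recovery tests
therefore demonstrate the correctness of the calibration algebra and the
estimation pipeline, not robustness to those instrument effects.

### Flow cytometry

Events carry forward/side scatter and a DNA-fluorescence channel.  G1
events are Normal($\mu$, CV$\,\mu$) with $\mu = 200$ and CV 5%; G2 events
Normal($2\mu$, CV$\,2\mu$); S-phase events come from a uniform bridge over
the central 80% of $(\mu, 2\mu)$ convolved with the G1 width.  The interior
bridge keeps the noiseless limit exactly separable (used by the
oracle-equivalence test) while the broadening restores full-range coverage
at the default CV; a Dean–Jett–Fox S model is an explicit non-goal.  Debris
(2% by default) has exponentially decaying DNA signal and low scatter.
Phase counts are apportioned to the requested fractions exactly
(largest-remainder), so the generated composition *is* the truth, before
any classification.

### Root growth

Seedling lengths accumulate rate × elapsed days over the measured 0–24 h
and 24–48 h windows (control 1.4 and 1.7 mm/d; post-release HC 45% then
100% of control, HU 72% then 65%), with a per-seedling rate multiplier
(CV 10%) and a 0.05 mm measurement SD; 10 seedlings × 3 biological
replicates per treatment.

### Seeding

All randomness flows from one master seed through a documented splitting
scheme: stream (images / calibration / flow / growth), timepoint,
replicate and treatment are mixed into a 31-bit sub-seed, so any single
output is regenerable in isolation, bit-identically, independent of call
order, and different treatments never share draws.

## Analysis pipeline choices

**ROI measurement.** Compartment value = mean over the compartment's
labelled pixels minus the mean over background pixels, per channel, floored
at a small epsilon; saturated pixels are excluded and counted.  Ratios are
computed from ROI-mean intensities (ImageJ-style); a pixelwise-ratio mode
exists behind a flag (`pixelwise = TRUE`).  No rolling-ball background
estimation is attempted.

**Calibration.** Pooled over all labelled pixels of the reference frames.
An estimated $R_{ox} \le R_{red}$ raises a calibration-inversion error
(swapped inputs or failed reference treatments) rather than silently
producing negative oxidation degrees.

**Clamping.** Noise routinely pushes ratios slightly outside
$[R_{red}, R_{ox}]$; they are clamped to the endpoints with a warning.
OxD is clamped to $[10^{-4}, 1-10^{-4}]$ (configurable) before the Nernst
step, which is undefined at the boundaries.

**Phase gating.** The emulated study gated manually; the package replaces
that with a deterministic rule whose thresholds live in `gating_params()`:
rectangular scatter gate, low-DNA threshold at 25% of the provisional G1
mode, 512-bin histogram, G1 peak = smoothed mode in the searched range
(global-mode fallback for degenerate histograms), G2 peak = highest mode at
1.8–2.2× the G1 position, per-peak σ from the half-width at half maximum
of the smoothed histogram (robust against the S bridge, degrading
gracefully to sub-bin widths for near-delta peaks), cores = peak ± 2σ,
S = strictly between the cores, boundary ties to the peaks, and events
below the G1 core or above the G2 core reassigned to the nearest peak.
The known systematic of rectangular gating — the ~2.3% of each Gaussian
core beyond 2σ trades against bridge leakage — biases recovered fractions
by ≲1.5 points at the default CV, well inside the ±3-point recovery band;
fitting a mixture model instead is out of scope.  The DNA axis is linear,
as conventional for propidium-iodide content data.

**Growth and statistics.** Per-seedling rates are plain interval
arithmetic.  Group comparison is classical one-way ANOVA with Tukey HSD:
studentized-range probabilities via the numerically integrated CDF
(`stats::ptukey`), Tukey–Kramer harmonic-n for unbalanced designs, and a
compact letter display built by insert-and-absorb, so sharing a letter is
provably equivalent to pairwise non-significance.  "Recovery to control
levels" after release is operationalised as Tukey non-significance versus
control at α = 0.01 on the matching interval.  With zero within-group
variance and distinct means the exact-separation path reports all pairs
significant with a warning.

## Problem sizes and determinism

The recovery experiments run at the emulated study's design sizes: 5
replicates × 13 timepoints for imaging grand means, 5 replicates at a
single timepoint for the 2 h contrasts, 100,000 events per flow sample,
and 30 seedlings per treatment for growth — a full acceptance run takes a
few seconds.  `run_report()` executes all three scenarios end to end and
writes a CSV bundle plus a JSON manifest; identical seeds reproduce every
CSV byte-identically (figures are advisory and excluded from that
contract).

## Known limitations

- The generator's realism limits are listed above; in particular,
  recovered calibration error is ~0.5% at default noise, which is
  flattering compared to real day-to-day instrument drift.
- The S-phase model is a gating convention, not a biological model; S
  fractions far from the ~8% regime would deserve a deconvolution method.
- Technical/biological replicate nesting is collapsed to a single
  replicate level (nested means), as the emulated design's pooling rule
  is unspecified.
- The glutathione-couple potential inherits any error in the assumed
  total glutathione concentration logarithmically.
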