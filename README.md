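# redoxroot

Quantitative analysis of subcellular redox state and cell-cycle dynamics
in plant root meristems, built around the redox-sensitive fluorescent
protein roGFP2.

## The problem

In proliferating root-tip cells, the glutathione redox potential of the
nucleus and cytosol is tightly coupled to cell-cycle progression, and
redox-active agrochemicals (hydrogen cyanamide, HC; hydroxyurea, HU)
perturb both.  Measuring this requires stitching together three
quantitative workflows that are usually done ad hoc in spreadsheets:

1. **Ratiometric redox imaging** — roGFP2 is excited at 405 nm and 488 nm;
   the ratio `R = I405/I488` of background-subtracted ROI intensities,
   calibrated against fully reduced (DTT) and fully oxidised (H2O2)
   references, gives the probe's degree of oxidation

   `OxD = (R − R_red) / (k·(R_ox − R) + (R − R_red))`,  `k = I488min/I488max`,

   and the Nernst equation converts OxD into redox potentials (mV) of the
   probe, `E = E0' − (RT/zF)·ln((1 − OxD)/OxD)`, and of the glutathione
   couple, `E_GSH = E0'_GSH − (RT/zF)·ln(2·GSH_tot·(1 − OxD)²/OxD)`.
2. **DNA-content cell-cycle analysis** — gating debris from flow-cytometry
   event tables and classifying nuclei into G1/S/G2 from the 2C/4C
   histogram.
3. **Root growth** — per-seedling growth rates, treatment-relative growth,
   and recovery after release, compared with one-way ANOVA + Tukey HSD and
   compact letter displays.

`redoxroot` implements all three as a tested, pipeable R package.  Since
studies of this design typically publish summary values rather than raw
images, the package also ships a **synthetic-data generator** with known
ground truth (two-channel image sets with label masks, flow event tables,
root-length tables) so the whole pipeline is validated by parameter
recovery: simulate at the published values, analyse, and check the
round trip.

## Worked example

Simulate the HC scenario at its defaults (5 replicates x 13 timepoints,
0–24 h), calibrate, and run the redox pipeline:

```r
library(redoxroot)

cfg <- scenario_config("hc", seed = 1)
cal_sets <- generate_calibration_sets(cfg)
calib <- estimate_calibration(cal_sets$reduced, cal_sets$oxidized)
calib
#> <calibration_state>
#>   r_red = 0.199307, r_ox = 2.00121, k = 0.499385
#>   i488_min (oxidised) = 1582.18, i488_max (reduced) = 3168.27

imgs <- list()
for (tp in cfg$timepoints_h)
  for (r in seq_len(cfg$n_replicates))
    imgs[[length(imgs) + 1]] <- generate_image_set(cfg, tp, r)

tc <- run_redox_timecourse(imgs, calib, cfg$constants)
tc
#> <redox_timecourse>
#>   130 measurements over 13 timepoint(s)
#>   grand means over the window:
#>     cytosol  OxD 32.45 +/- 1.70 %, E -289.7 +/- 1.1 mV (n=65)
#>     nucleus  OxD 31.36 +/- 2.28 %, E -291.3 +/- 1.5 mV (n=65)
```

The estimated calibration sits on the generator truth (`r_red` 0.2,
`r_ox` 2.0, `k` 0.5) to within half a percent, and the recovered grand
means reproduce the scenario's configured truth (nuclear OxD 31.22%,
E −291.4 mV) within fractions of their replicate SEMs.  `tidy(tc)` returns
the per-replicate measurement tibble, `glance(tc)` the grand means, and
`autoplot(tc)` the OxD time course.

Cell-cycle phases at 24 h of HC (G1 has collapsed towards 55% as G2/M
cells accumulate):

```r
ev <- generate_flow_events(cfg, timepoint = 24, n_events = 1e5)
fit_phases(gate_debris(ev))
#> <phase_fit>
#>   G1 54.4%  S 8.1%  G2 37.5%  (n = 98000 gated, 2000 debris)
#>   peaks: G1 at 200.8, G2 at 399.2 (CV 0.051 / 0.052)
```

Post-release growth relative to control, with the Tukey-based recovery
call:

```r
tab <- dplyr::bind_rows(
  generate_root_lengths(scenario_config("control", seed = 1)),
  generate_root_lengths(cfg))
growth_rate(tab, interval = c(0, 24))
#> # A tibble: 2 x 6
#>   treatment     n rate_mean_mm_d rate_sem_mm_d relative_to_control_pct recovered
#> 1 control      30          1.41         0.0267                   100   TRUE
#> 2 hc           30          0.658        0.0184                    46.7 FALSE
```

HC-released roots grow at ~45% of the control rate over the first 24 h and
are statistically distinguishable from control (no recovery yet); on the
24–48 h interval the same call flags them as recovered.

`run_report(out_dir, seed = 1)` runs all three scenarios end to end and
writes `summary_table1.csv`, `redox_timecourse.csv`, `phases.csv`,
`growth.csv`, figures, and a JSON manifest; identical seeds reproduce the
CSVs byte-identically.

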