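# aidkit

Simulation and single-cell analysis of auxin-inducible degron (AID)
kinetics in budding yeast.

The AID system couples a degron-tagged protein to auxin-triggered,
TIR1-mediated proteasomal degradation, making targeted protein depletion
switchable by a medium change. In time-lapse microfluidics a degron-tagged
GFP reporter shows three regimes that this package models and quantifies:
a division-cycle sawtooth baseline, a fast dose-dependent collapse to the
cellular autofluorescence floor after auxin arrives, and — after auxin
removal — a slow multi-generation recovery in which synthesis refills the
cell each cycle and every division dilutes the protein.

`aidkit` is aimed at yeast researchers planning or analyzing single-cell
AID experiments: it provides a calibrated forward simulator of single-cell
fluorescence trajectories under arbitrary auxin schedules, and the
estimators used to summarize real or simulated cohorts.

## The quantities at the core

* Protein dynamics between divisions:
  `dC/dt = k_syn_max (1 − C/c_cap) − k_deg(A_eff) · C`, with a Hill dose
  response `k_deg(A) = k_deg_max A^h / (EC50^h + A^h)`, pH-corrected
  effective dose (Henderson–Hasselbalch protonated fraction), per-cell
  Gamma-distributed onset delays (newborn daughters +20 min), and an
  instantaneous drop `C → C/DIL` at each division.
* Measured signal: `S = (a + (1 − a) C) · noise`, autofluorescence floor
  `a = 0.288` of the pre-depletion level, lognormal noise (CV 5%).
* Depletion summaries: minimum slope ΔS/Δt after auxin addition, time to
  the floor band, completeness ratio (signal 500–740 min over 0–240 min),
  two-phase exponential decay and constrained log-dose–response fits.
* Dilution factor from the recovery sawtooth: per division cycle the peak
  MAX and following trough MIN give DIFF = MAX − MIN; the
  origin-constrained regression of DIFF on MAX yields SLOPE = DIFF/MAX and
  `DIL = 1/(1 − SLOPE)`, with a bootstrap CI over oscillations.
* Growth: per-cycle `GR_sc = ln(2)/DT_sc` from consecutive budding events,
  Kruskal–Wallis + Dunn group comparisons, and one-phase exponential
  association fits `GR(t) = plateau + (y0 − plateau) e^(−K t)` for the
  recovery of growth after auxin removal.

## Worked example

Simulate a depletion experiment (20 mother cells, 0.5 mM IAA added at
240 min) and summarize it per cell:

```r
library(aidkit)
cfg <- sim_config()

sch <- schedule_step(0.5, t_on = 240, horizon = 480)
pop <- normalize_baseline(simulate_experiment(cfg, sch, n_mothers = 20, seed = 1))
ds <- depletion_summary(pop, t_add = 240, after = c(400, 480))
head(ds, 3)
#>   cell_id   role   min_slope t_min_slope time_to_floor completeness_ratio
#> 1     m01 mother -0.04929353         250      19.75411          0.2959502
#> 2     m02 mother -0.04071282         250      22.62181          0.3015435
#> 3     m03 mother -0.03826028         245      19.31480          0.3037101
mean(ds$time_to_floor)
#> [1] 27.95383
```

Each cell's signal crosses into the autofluorescence floor band roughly
25–30 min after auxin addition (the per-cell onset delay plus the
exponential collapse), and the completeness ratio lands at the floor level
0.288–0.30: depletion is complete at this dose.

Now a recovery experiment — a 120-min saturating pulse, then five division
cycles of sawtooth recovery — and the dilution-factor estimate:

```r
schp <- schedule_pulse(0.5, t_on = 240, duration = 120, horizon = 1100)
rec <- normalize_baseline(simulate_experiment(cfg, schp, n_mothers = 19, seed = 1))
cyc <- cohort_cycles(protein_component(rec, cfg$af_floor), t_removal = 360)
fit_max_diff_regression(cyc, n_boot = 1000)
#> DIFF-vs-MAX regression (through origin): slope 0.1736 (95% CI 0.1584-0.1892), 99 oscillations from 19 cells
#>   dilution factor DIL = 1/(1-SLOPE) = 1.210
```

The slope says each division drops about 17% of the peak protein signal,
i.e. a per-division dilution factor of ~1.2 — the concentration cost of
cell growth and division that makes full recovery take several generations.

A thin command-line front end over the same functions is available in
`scripts/aidkit.R` (`simulate`, `deplete`, `recover`, `growth`, `report`
subcommands; trajectory CSVs plus flat key = value schedule sidecars).

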