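# poredirection

Quantification of **directionally asymmetric small-molecule uptake into
electropermeabilized cells** from time-lapse fluorescence microscopy.

When cells are exposed to pulsed electric fields, impermeant dyes enter
through the transiently permeabilized membrane, preferentially at the poles
facing the electrodes. Whether the anode- or the cathode-facing pole
dominates depends on the pulse regimen (a single 220 µs pulse versus trains
of 6 ns pulses) and on the molecule (the intercalating cations YO-PRO-1 and
propidium versus the anionic, natively fluorescent calcein). This package
implements the measurement chain that turns raw image stacks into that
asymmetry statistic and its kinetics:

* **Regional photometry** — each cell mask is divided into 1-px rows
  parallel to the electrodes; rows are grouped into anode-facing, middle and
  cathode-facing thirds (equal polar groups, remainder to the middle; a
  ~50-row cell partitions 16/18/16) and each group reports the average of
  its row means.
* **Calibration** — fluorescence → µM via lysate standard curves
  (OLS line through replicate means), or via the 200 µM bath anchor for
  calcein.
* **Kinetics** — population anode−cathode difference traces,
  decaying-exponential fits Δ(t) = A·exp(−(t−t₀)/τ) with the window anchored
  at the dominant-sign post-pulse extremum, and middle-region crossover
  times with a 5-frame persistence rule.
* **Physics** — Einstein–Smoluchowski diffusion times (t = d²/(2nD), the
  dimensionality factor always explicit), Stokes–Einstein D = k_BT/(6πηr),
  and dye mobility ratios from the bundled molecular property table.
* **Simulator** — a ground-truthed reaction–diffusion model of dye influx
  through angular membrane caps into a 12 µm disc cell (free + bound pools,
  exact mass balance, camera noise, 16-bit TIFF rendering) emulating the
  microsecond-bipolar, nanosecond-anode-dominant and symmetric regimens, so
  the pipeline is testable end-to-end without microscope data.

## Worked example

```r
library(poredirection)

# one full-protocol recording: 12 um cell, 1200 frames at 100 ms,
# 220 us-class pulse at t = 5 s, YO-PRO-1
cfg <- scenario_config("microsecond_bipolar", dye_name = "YP1",
                       seed = 1, duration = 120)
summary <- run_end_to_end(cfg, "run_micro")
#> poredirection 0.1.0 | scenario microsecond_bipolar | seed 1
#>   tau = 34.5 s, asymmetry sign -1, crossovers 80.4 / NA s
```

Reading: the anode−cathode concentration difference is **negative**
(cathode-dominant entry, the signature of this pulse regimen) after a brief
anode-positive transient, and relaxes with **τ ≈ 34 s** (the corresponding
published fit for this regimen is 40 s). The middle region overtakes the
anode-side region at ~80 s and never overtakes the cathode side within the
2-minute recording — in the simulator's uniform-binding world crossovers are
late; their *ordering* (anode first, under cathode-dominant influx) is the
meaningful observable. `run_micro/` now holds `stack.tif` + `stack.json`,
`calibration.csv`, `truth.csv`/`params.json` (simulator ground truth),
`traces.csv`, `fits.csv`, `crossovers.csv` and `summary.json`.

The diffusion arithmetic used to interpret such traces:

```r
diffusion_time(12e-6, 1e-10, msd_factor = 4)   # 0.36  -> "about 400 ms"
diffusion_time(12e-6, 5e-12, msd_factor = 4)   # 7.2   -> "about 7 s"
mobility_ratio(dye_geometry("YP1"), dye_geometry("Pr"))  # 1.3
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/poredirection.R", package = "poredirection"))')
Rscript $CLI simulate --scenario nanosecond_multi_anode --seed 1 --out sim_out
Rscript $CLI analyze --stack sim_out/stack.tif --meta sim_out/stack.json \
        --calib sim_out/calibration.csv --roi rois.tif --out traces.csv
Rscript $CLI fit --traces traces.csv --pulse-time 5 --out fits.csv
Rscript $CLI physics difftime --distance-um 12 --D 1e-10 --factor 4
```

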