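# batlipid

Dynamic fat-water MRI analysis of brown adipose tissue (BAT) lipid
content during personalized cold exposure — as a reusable, tested R
pipeline built around a digital phantom.

## The problem

Cold-activated brown adipose tissue burns intracellular lipid. Multi-echo
gradient-echo (fat-water) MRI measures each voxel's fat-signal fraction

FSF = 100 · F / (F + W)  [%],

where W and F are the water and fat signal magnitudes obtained by fitting
the complex signal model

S(TE) = (W + F · Σₚ αₚ e^{i2πΔfₚTE}) · e^{i2πψTE} · e^{−R₂*TE}

with a seven-peak spectral fat model, per-voxel field-map offset ψ and
common R₂*. BAT lipid is heterogeneous, so voxels are grouped by their
thermoneutral FSF into decades {0–10%}, …, {90–100%}, membership is
frozen, and each decade's mean FSF is tracked across a ~1 h individualized
cooling session. Cold stress is standardized as the normalized cooling
dose

NCD(t) = ∫ (T₀ − T(t)) dt / BSA  [°C·min·m⁻²],

the area under the relative blanket water-temperature curve divided by
the DuBois body surface area. Lipid-rich decades lose fat under cold
while lipid-poor decades gain it; the package reproduces this analysis
end to end — multi-peak fat-water separation, demons nonrigid
registration with fiducial validation, eroded bilateral ROIs, decade
tracking with a 60-voxel stability rule, dose/sensation synchronization,
and the exact nonparametric statistical battery (signed-rank enumeration,
bootstrap percentile CIs, Spearman correlation, noncentral-t power
analysis).

Raw human MRI for this design is not publicly available, so the package
ships a first-class synthetic-subject generator (`make_phantom`,
`simulate_cooling_protocol`, `simulate_cooling_response`,
`synthesize_echoes`, `apply_motion`) whose ground truth encodes the
measured tissue statistics; every stage is validated against that truth.

## Worked example

```r
library(batlipid)

# a short simulated cooling session on the default 64 x 64 x 15 phantom
cfg <- bat_pipeline_config(n_acquisitions = 8)
run <- run_pipeline(cfg, seed = 42, outdir = "report")
print(run)
```

```
BAT cooling run: 8 acquisitions, endpoint 8, seed 42
  normalized dose at endpoint: 419.7 degC min m^-2 (BSA 1.82 m^2)
  fiducial median error 0.84 -> 0.19 px
  BAT decade endpoint changes (pp):
    0:+7.7 10:+5.7 20:+3.7 30:+1.4 40:+0.6 50:-0.7 60:-3.9 70:-7.7 80:-11.3 90:-14.5
```

Reading the output: the session delivered ≈ 420 °C·min·m⁻² of normalized
cooling dose; registration reduced the median in-plane fiducial error
from 0.84 to 0.19 pixels; and the tracked decade means recover the
generated differential response — the lipid-poorest decade gained ≈ 8 pp
of fat fraction while the lipid-richest lost ≈ 14.5 pp. `summary(run)`
additionally prints the ROI threshold comparison (0–100 / 40–100 /
50–100%) and the per-decade Spearman correlations with dose and thermal
sensation; `report/` contains tidy CSV tables, figures and a manifest
with file hashes. `inst/scripts/batlipid.R` wraps the same call for the
shell.

The statistical battery is usable on its own, e.g.

```r
wilcoxon_exact_paired(c(2, 4, 6, 8, 10, 12, 14), c(1, 2, 3, 4, 5, 6, 7))
#> Exact paired Wilcoxon signed rank (n = 7)
#>   statistic: 0
#>   two-sided p: 0.01562 (exact)
paired_sample_size(1.45, alpha = 0.05, power = 0.85)
#> [1] 7
round(dubois_bsa(70.8, 170.6), 2)
#> [1] 1.82
```

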