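# actidiary

Agreement analysis between wearable-accelerometer physical-activity
intensity and diary-derived energy expenditure, on 15-minute daytime
epochs.

Body-worn inertial sensors summarize movement as **ENMO** — the Euclidean
norm of tri-axial acceleration minus 1 g, low-pass filtered (4th-order
Butterworth, 20 Hz, zero-phase) and truncated at zero — while structured
activity diaries yield **MET** values (multiples of resting metabolic rate)
via Compendium-style lookup from the activity label and self-reported
intensity (mild/moderate/vigorous). `actidiary` aligns both on the 36-slot
09:00–18:00 grid, applies day- and participant-level inclusion rules
(≥ 4 simultaneously valid slots/day, ≥ 9 h recorded sensor time, recording
spanning the window, ≥ 3 included days/participant), Min-Max normalizes
both arms (ENMO per sensor position; the three parallel-activity MET levels
low/average/high jointly), fits the one-parameter calibration

```
MET = alpha * ENMO
```

per sensor position × MET level by Nelder-Mead on the group-mean profiles
(the closed-form least-squares minimizer `alpha* = Σ(M·E)/Σ(E²)` ships as
an independent oracle), and reports per-participant RMSE distributions
(median/min/max), optionally stratified by tremor severity (MDS-UPDRS
items 3.15–3.17 sum ≤ 1 vs. > 1). Because the motivating study's clinical
data are not publicly deposited, the package includes a fully synthetic
cohort generator with known ground truth (true correction factors, latent
activity schedules, wear gaps, wrist tremor contamination), against which
every pipeline stage is tested. Intended users: researchers validating
sensor placement and calibration pipelines for free-living physical
activity assessment, particularly in movement disorders.

## Worked example

Simulate a small cohort under the generator's default world (epoch noise
0.05, 5 % wear gaps, wrist response gain 1.25, 44 % stronger-tremor
participants) and run the full pipeline:

```r
library(actidiary)
cfg    <- synth_config(n_participants = 8, days_per_participant = 4, seed = 11)
bundle <- synthesize_cohort(cfg)
run    <- run_agreement(bundle, pipeline_config())
print(run)
#> <actidiary_run>
#>   days: 96 records, 90 included
#>   correction factors:
#>     ankle      low  alpha = 0.7226 (fit RMSE 0.0012)
#>     ankle      avg  alpha = 0.8775 (fit RMSE 0.0015)
#>     ankle      high alpha = 1.0323 (fit RMSE 0.0018)
#>     wrist      low  alpha = 0.6221 (fit RMSE 0.0217)
#>     wrist      avg  alpha = 0.7554 (fit RMSE 0.0263)
#>     wrist      high alpha = 0.8887 (fit RMSE 0.0310)
#>     lower_back low  alpha = 0.7208 (fit RMSE 0.0012)
#>     lower_back avg  alpha = 0.8752 (fit RMSE 0.0014)
#>     lower_back high alpha = 1.0297 (fit RMSE 0.0017)
```

Six of 96 days fell to the inclusion rules (wear gaps), and one participant
dropped below 3 included days. The wrist needs a clearly stronger downward
correction than ankle/lower back (0.62–0.89 vs 0.72–1.03): its concave
amplitude response inflates normalized ENMO at light activities. The true
per-level factors of this world are 0.7 / 0.85 / 1.0; the matched-response
sensors recover them to within the noise-induced ~3 % Min-Max bias.

```r
print(subset(run$tremor_summary, sensor_position == "wrist"), digits = 3)
#>         group met_level sensor_position median   min   max n
#> 1  no_minimal       low           wrist  0.117 0.089 0.144 4
#> 3  no_minimal       avg           wrist  0.142 0.108 0.175 4
#> 5  no_minimal      high           wrist  0.167 0.127 0.206 4
#> 7    stronger       low           wrist  0.142 0.111 0.168 3
#> 9    stronger       avg           wrist  0.172 0.134 0.204 3
#> 11   stronger      high           wrist  0.202 0.158 0.239 3
```

Stronger-tremor participants show higher wrist RMSE at every MET level —
tremor adds wrist ENMO with no corresponding diary energy expenditure.

`run_agreement(bundle, pipeline_config(out_dir = "out"))` additionally
writes `scaling_results.csv`, `subject_rmse.csv`, `summary_table1.csv`,
`tremor_summary.csv`, `group_profiles.csv`, `qc_report.csv`,
`run_summary.json` and the resolved `config.yaml`.

### Command line

```sh
cli=$(Rscript -e 'cat(system.file("cli", "actidiary.R", package = "actidiary"))')
Rscript "$cli" simulate --config sim.yaml --out bundle/
Rscript "$cli" run --config run.yaml
```

Exit codes: 0 ok, 2 configuration error, 3 data error, 4 empty cohort.

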