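# ctriage

Weakly supervised anomaly detection and triage for head CT, built around
a voxel-wise Gaussian **normative atlas**: learn what normal brains look
like at every voxel, flag everything that deviates, and sort the
worklist so pathology gets read first.

The package is aimed at methods researchers in medical image analysis
who want a complete, testable reference implementation of the
normative-triage pipeline — including the statistics used to evaluate it
in a reader study — without needing clinical data: a built-in phantom
generator produces co-registerable brain-shaped CT volumes with
controlled lesions.

## The model

Training scans (globally labelled "normal", no voxel annotations) are
registered to a template. At each brain voxel *v* the intensities are
modelled as Gaussian with mean μ<sub>v</sub> and SD σ<sub>v</sub>,
giving normative bounds

&nbsp;&nbsp;&nbsp;&nbsp;L<sub>v</sub> = μ<sub>v</sub> − k·σ<sub>v</sub>,&nbsp;&nbsp;
U<sub>v</sub> = μ<sub>v</sub> + k·σ<sub>v</sub>&nbsp;&nbsp;(default k = 2.576, 99% coverage).

A scored scan's **anomaly score** is

&nbsp;&nbsp;&nbsp;&nbsp;s = (# in-brain voxels strictly outside [L, U]) / (# brain voxels) ∈ [0, 1].

Two thresholds, calibrated on a labelled validation set to **minimize
the false positive rate under a false omission rate of 0**
(T<sub>upper</sub> = highest normal score, T<sub>lower</sub> = lowest
pathological score), map scores to triage labels:
s < T<sub>lower</sub> → *normal* (green), s > T<sub>upper</sub> →
*pathological* (red), otherwise *inconclusive* (white).

## Worked example

```r
library(ctriage)

spec <- phantom_spec(seed = 1)          # 32^3 head phantom, 1 mm voxels
ph   <- make_template(spec)

# fit the atlas on 60 synthetic normal scans
train <- lapply(1:60, function(i) simulate_normal_scan(ph, spec, seed = i))
atlas <- fit_atlas(train, ph$brain_mask, k = 2.576)

# score a normal scan and a 5%-volume hyperdense lesion scan
v0 <- simulate_normal_scan(ph, spec, seed = 991)
les <- lesion_spec(count = 2, target_volume_fraction = 0.05,
                   contrast = 50, seed = 7)
v1 <- simulate_pathological_scan(ph, spec, les)$scan

score_scan(v0, atlas, scan_id = "normal-991")
#> <anomaly_result> scan normal-991: score 0.0128 (69 / 5384 voxels)
score_scan(v1, atlas, scan_id = "lesion-7")
#> <anomaly_result> scan lesion-7: score 0.0581 (313 / 5384 voxels)
```

The normal scan flags ≈1% of brain voxels — the expected two-sided tail
mass outside μ ± 2.576σ — while the lesion scan scores ≈ lesion fraction
plus that baseline. Calibrating thresholds on a small labelled cohort
and triaging:

```r
cal_scores <- c(0.0120, 0.0098, 0.0135, 0.0128, 0.0421)
cal_labels <- c("normal", "normal", "normal",
                "pathological", "pathological")
thr <- calibrate_thresholds(cal_scores, cal_labels)
thr
#> <triage_thresholds> t_lower = 0.0128, t_upper = 0.0135 (3 normal, 2 pathological)
triage(c(0.010, 0.013, 0.080), thr)
#> [1] "normal"       "inconclusive" "pathological"
```

The overlap between the worst normal (0.0135) and the best pathological
(0.0128) calibration scores becomes the inconclusive band; scores below
it are safely normal (false omission rate 0 on the calibration set),
scores above it safely pathological (false positive rate 0). When the
classes separate the band collapses instead of inverting, and optional
margins widen it for unseen data — see `?calibrate_thresholds`.

Reader-study statistics work on plain record tables:

```r
scans <- simulate_scan_table(seed = 1)           # 40 normal / 40 path, 89 findings
rec   <- simulate_reader_study(scans, seed = 2)  # 4 readers x 80 scans x 2 runs
confusion_metrics(rec, scans, run = "ai")
#> <confusion_metrics> tp 160 fp 1 tn 159 fn 0 (n = 320)
#>   sensitivity 100.0%  specificity 99.4%  PPV 99.4%  NPV 100.0%
reporting_time_summary(rec, scans)[1, c("mean_no_ai", "mean_ai", "delta_rt_pct")]
#>   mean_no_ai  mean_ai delta_rt_pct
#> 1   64.05073 54.81701     14.41626
```

A thin command-line interface over these functions ships in
`inst/cli/ctriage` (subcommands `simulate`, `build-atlas`, `score`,
`calibrate`, `triage`, `evaluate`).

## Package layout

| Area | Files |
| --- | --- |
| Volumes, NIfTI/worklist I/O, config | `R/volume.R`, `R/config.R` |
| Phantom + reader-study simulators | `R/phantom.R`, `R/reader_sim.R` |
| Registration and resampling | `R/registration.R` |
| Normative atlas | `R/atlas.R` |
| Outlier scoring and heatmaps | `R/scoring.R` |
| Threshold calibration and triage | `R/triage.R` |
| Evaluation statistics | `R/evaluation.R` |

The methods vignette (`vignettes/ctriage-methods.Rmd`) documents the
model assumptions, parameter defaults, numerical conventions and the
limits of what the synthetic studies demonstrate.
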