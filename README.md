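# cardiobcg

Closed-loop lumped-parameter (0D) modelling of the human cardiovascular
system as a virtual laboratory for **sex-difference experiments**, with
**ballistocardiogram (BCG) synthesis** from simulated blood-volume
redistribution and a complete ECG/BCG **signal-processing chain**.

## Who this is for

Computational physiologists and biomedical-signals researchers who want
to (i) quantify how documented male/female differences in heart rate,
ventricular elastance and arterial geometry propagate to ventricular
volumes, ventricular-arterial coupling and cardiac output, and (ii)
explore the BCG — the recoil force of the body caused by blood-mass
redistribution at each heartbeat — as a noninvasive window on those
differences.

## The model in brief

Two time-varying-elastance ventricles (pressure generator `U·a(t)` in
series with elastance `E(t) = E_D + E_S·a(t)`) drive a closed loop:
six named systemic arterial segments (ascending aorta → arch → {carotid,
thoracic} → abdominal → iliac) as RLC compartments derived from geometry

    R = 128 l η / (π d⁴),  L = 4 ρ l / (π d²),
    C = 3 l π d² (d+2h)² / (16 E h (d+h)),

upper/lower-body microcirculations, a venous pool, and a pulmonary loop.
Eight parameterizations are built in: an idealized male baseline, six
single-change versions (HR +5%, ELS +15%, ELD +30%, ERS +17%, all
arterial diameters −10%, all lengths −10%) and the idealized female
(all six at once). Shared parameters not fixed by the presets are
calibrated once against male anchor values and frozen
(`inst/extdata/calibrated-params.json`); all female outputs are genuine
predictions. The BCG force is `F = M ÿ_cm` with
`y_cm = (ρ/M) Σ_j y_j V_j(t)`, reported in the 1.25–15 Hz measurement
band. Cardiovascular indexes follow the standard definitions
`SV = EDV − ESV`, `CO = HR·SV`, `EF = SV/EDV`, `Ea = ESP/SV`,
`Ees = ESP/ESV`, `VAC = Ea/Ees` (LV), `Ees/Ea` (RV).

## Worked example

```r
library(cardiobcg)

shared <- calibrated_params()
sim_m <- simulate_circuit(cv_config("idealized_male", shared))
sim_f <- simulate_circuit(cv_config("idealized_female", shared))

cardiac_metrics(sim_f, "left")
#> <cardiac_metrics> left ventricle (idealized_female)
#>   EDV 137.8 mL  ESV 55.9 mL  SV 81.9 mL  CO 6.4 L/min  EF 59.4%
#>   ESP 139.4 mmHg  Ea 1.70  Ees 2.49  VAC (Ea/Ees) 0.68

bcg_waveform(sim_f, scale = shared$bcg_scale)
#> <bcg_waveform> idealized_female: amplitude 1.7 x 10^5 dyne, systolic peak at 53 ms
```

(Output shown from the shipped calibration; EDV/ESV are the extrema of
the last simulated cycle, ESP the peak ventricular pressure, and the BCG
amplitude is peak-to-valley force within the 0–0.3 s systolic window.
The shared parameters were calibrated against idealized-male anchors
only, so these female values are model predictions.)

The full eight-version suite with ±5% sensitivity envelopes and the
male/female comparison table:

```r
suite <- run_all_versions(shared)
report_tables(suite, dir = "results")
sensitivity_pm5("ELS", shared)$envelope
```

Synthetic paired ECG+BCG recordings with known ground truth, and the
processing pipeline (Butterworth band-passes 0.7–40 / 1.25–15 Hz, R-peak
detection, beat segmentation, ensemble averaging):

```r
fx <- make_fixture("female", seed = 7)
rec <- read.csv(fx$recording)
ecg_f <- bandpass_filter(rec$ecg, 1000, c(0.7, 40))
bcg_f <- bandpass_filter(rec$bcg, 1000, c(1.25, 15))
peaks <- detect_r_peaks(ecg_f, 1000)
beats <- segment_beats(bcg_f, peaks, 1000)
mean_beat <- ensemble_average(beats)
```

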