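---
title: "Modelling cardiovascular sex differences and the ballistocardiogram with cardiobcg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cardiovascular sex differences and the ballistocardiogram with cardiobcg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`cardiobcg` implements a closed-loop, lumped-parameter (0D) model of the
human circulation built on the electric-hydraulic analogy: pressures are
voltages, flows are currents, vessel compliance is capacitance, viscous
loss is resistance, and blood inertia is inductance.

Each ventricle is a pressure generator in series with a time-varying
elastance,

$$P_v(t) = U_{\max}\,a(t) + \big(E_D + E_S\,a(t)\big)\,(V_v - V_0),$$

where the activation $a(t)$ is periodic with the cardiac period
$T_c = 60/\mathrm{HR}$, zero in diastole, and rises as
$\sin^2(\pi t/T_{act})$ over the active window. The left ventricle feeds a
systemic arterial tree of six named segments (ascending aorta, aortic
arch, thoracic aorta, abdominal aorta, iliac and carotid arteries) whose
resistance, inertance and compliance derive from geometry and wall
properties,

$$R = \frac{128\,l\,\eta}{\pi d^4},\qquad
  L = \frac{4\rho_b\,l}{\pi d^2},\qquad
  C = \frac{3\,l\,\pi d^2 (d+2h)^2}{16\,E\,h\,(d+h)},$$

with the wall thickness fixed at $h = 0.1\,d$ and Young moduli of
$4\times10^6$ dyn/cm$^2$ for the aortic segments and $8\times10^6$
dyn/cm$^2$ for the stiffer muscular carotid and iliac. The carotid
branches off the aortic arch toward the upper-body microcirculation,
which is also fed directly from the arch by the subclavian (arm) supply;
the lower-body bed receives the visceral branches leaving the abdominal
aorta (celiac, mesenteric, renal — about half of resting cardiac output)
and the legs' supply through the iliac; both beds drain into a common
systemic venous compartment, and a pulmonary loop (artery,
microcirculation, veins) closes the circuit through the right ventricle.
Valves are regularized ideal diodes, $Q = \Delta P/R \cdot
\sigma(\Delta P/\varepsilon)$ with $\varepsilon = 0.05$ mmHg, which keeps
the right-hand side smooth for the implicit solver. The states are the 14
compartment volumes plus 5 arterial inertial flows; summing the volume
derivatives gives exactly zero, so total blood volume is conserved by
construction.

### Effective-tree homogenization

The six named segments stand in for the entire arterial tree they feed.
Taken literally, their wall compliance (fractions of mL/mmHg) could not
buffer a 90 mL stroke volume, and their series inertances would isolate
the periphery within a beat — neither is true of the real, richly
branched tree. The package therefore carries homogenization factors in
the shared parameter set: segment compliances are scaled up
(`C_art_scale = 15`), segment inertances scaled down
(`L_art_scale = 0.03`), and the carotid and iliac segments — each of
which lumps several parallel supply arteries (two carotids plus
vertebrals; two iliacs) — have their resistance and inertance divided by
parallel-path counts (4 and 2.5). All factors are shared by every model
version, so sex differences act only through the tabulated $d$ and $l$.
A light viscous wave-damping resistance, a fixed multiple (0.4) of each
edge's characteristic impedance $\sqrt{L/C}$, suppresses the unphysical
ringing a discrete LC ladder otherwise exhibits. Sex-invariant distal
arterial-bed compliances at the branch points — the arch (subclavian),
the carotid outlet, the abdominal aorta (visceral) and the iliac outlet —
complete the Windkessel: they stabilize pulse pressure when the named
segments shrink, which is what keeps the female end-systolic pressure
within about 2% of the male value while the smaller, stiffer segments
transmit and store less pulsatile volume per beat.

### Right ventricular filling and tricuspid leak

The tabulated male/female parameter set fixes both ventricles' systolic
elastance amplitudes and the left diastolic elastance, but not the right
diastolic elastance; it is held at 0.025 mmHg/mL for both sexes (reported
sex differences in right-ventricular diastolic stiffness are not
significant). The male anchor volumes imply a right-ventricular volume
excursion about 8 mL larger than the left (97.1 vs 89.3 mL). In a
strictly periodic closed loop both ventricles pass the same net volume
per beat, so unequal excursions require backflow somewhere; the model
realizes it as a small tricuspid regurgitant conductance (calibrated,
physiologically a trace-to-mild regurgitation), which inflates the RV
excursion above its net output without affecting the systemic loop.

## The eight versions and calibration

The idealized male preset carries the tabulated baseline (HR 75, left
systolic/diastolic elastance 1.375/0.04 mmHg/mL, right systolic 0.23, the
six segment diameters and lengths). Six single-change versions alter one
group at a time — HR +5% (78.75), ELS +15% (1.581), ELD +30% (0.05), ERS
+17% (0.27), all diameters −10%, all lengths −10% — and the idealized
female applies all six at once.

Parameters the presets do not fix (the LV pressure generator, both
ventricles' unstressed volumes, initial venous pressures, and scale
factors on the systemic and pulmonary resistances and the peripheral-bed
compliances, plus the tricuspid leak) are determined once, by a bounded
Levenberg–Marquardt least-squares fit of the *male* model to six anchors:
the male LV/RV end-diastolic and end-systolic volumes and the two peak
ventricular pressures implied by the male elastance indexes. Volume
residuals carry triple weight (the coupling-ratio predictions ride on
them), and a weak ridge toward the physiological starting values
regularizes directions the six anchors cannot identify. The search runs
two stages, a coarse Jacobian step (`epsfcn = 1e-4`, well above the ODE
solver tolerance — finer steps stall on solver noise) followed by a fine
polish. Because the anchors must hold on the periodic orbit rather than
on a transient, calibration alternates with settling: each round stores
every version's 24-cycle settled state and the next round calibrates
starting from those orbits. The BCG position scale is then fixed exactly
by linearity against the male BCG amplitude anchor. The resulting set is
frozen in `inst/extdata/calibrated-params.json` and reused unchanged by
all eight versions; every female-model output, the coupling ratios,
ejection fractions, percent differences and the BCG amplitude ratio are
therefore genuine predictions, not fitted quantities.

Anchor choice deliberately excludes all female values. Because the male
anchors cannot identify the split between a ventricle's pressure
generator amplitude and its elastance volume intercept ($U_{\max}$ vs
$V_0$), nor how much congestion feedback the pulmonary venous pool
provides, those structural defaults (a mildly negative LV volume
intercept; the RV generator pinned at $U_{\max} = 24$ mmHg rather than
fitted; a large pulmonary venous compliance of 35 mL/mmHg) were chosen on
physiological grounds: linearized end-systolic pressure–volume relations
routinely extrapolate to intercepts below the operating range, the RV
develops a substantial fraction of its systolic pressure isovolumically,
and the pulmonary venous pool is the most distensible part of the
pulmonary circuit.

## Numerical choices

Simulations integrate 8 cardiac cycles with `deSolve::lsoda` at relative
and absolute tolerance $10^{-6}$, sampled at 1 ms; the final cycle is the
analysis window. The valve regularization scale (0.05 mmHg) trades a
sub-mL/s reverse leak for a smooth right-hand side. Initial volumes place
each passive compartment at its configured starting pressure and the
ventricles at their diastolic operating points, so the orbit settles
within the 8 cycles; the cycle-7 versus cycle-8 volume discrepancy is
reported and warned about above 0.5%. Determinism: the circuit chain has
no randomness; re-running any version reproduces waveforms bitwise.

## BCG synthesis

The ballistocardiogram is computed from blood-volume redistribution: with
compartment centroid coordinates $y_j$ (head-to-foot, cm) the
center-of-mass displacement is $y_{cm}(t) = (\rho_b/M)\sum_j y_j V_j(t)$
and the recorded force is $F = M\,\ddot y_{cm} = \rho_b \sum_j y_j
\ddot V_j$ — body mass cancels exactly. The second derivative is taken by
a five-point central stencil after zero-phase low-pass smoothing at 25 Hz,
evaluated over the last three cycles so filter transients stay outside
the reported cycle. Amplitude is peak-to-valley inside the 0–0.3 s
systolic window. The coordinates are anatomical defaults; only one global
scale factor is calibrated (to the male amplitude), and every male/female
comparison is invariant to it. The post-systolic portion of the waveform
is not a modelling goal here: a lumped model without atria cannot be
expected to reproduce the secondary oscillations seen in measured
recordings.

## Synthetic recordings and what the pipeline tests show

The recording pipeline (band-pass filtering, R-peak detection, beat
segmentation, ensemble averaging) is exercised end-to-end on synthetic
paired ECG+BCG recordings with known ground truth: QRS-like Gaussian
pulses at jittered R times, a per-beat BCG template (either the
model-generated beat or a parametric tri-phasic wavelet), i.i.d. Gaussian
noise scaled to the template peak-to-peak, and a 0.25 Hz respiration
sinusoid deliberately placed inside the stop band of the 1.25–15 Hz BCG
filter. Default noise (0.3 × peak-to-peak) and respiration (1 ×
peak-to-peak) stress the filters without overwhelming them. All
randomness flows from a single mandatory seed. These fixtures emulate the
statistical structure the pipeline assumes — they do not contain motion
artifacts, heart-rate autocorrelation, arrhythmia, or subject-specific
morphology, so passing tests demonstrate correct signal processing, not
robustness to all real-world recordings. Filters are applied
forward-backward (zero phase) because beat-timing comparisons cannot
tolerate group delay; the band-pass "order" names the overall band-pass
order (an order-6 band-pass has an order-3 low-pass prototype). Beat
windows are fixed at 0.7 s after each R peak rather than RR-normalized;
beats whose window overruns their RR interval are flagged, not padded.

## Problem sizes

Shipped analyses use 8-cycle simulations (6 400 one-millisecond samples),
60-beat synthetic recordings at 1 kHz, and the ±5% sensitivity sweeps
re-run each version three times. A full eight-version suite completes in
well under a minute; the one-off calibration search takes a few minutes
and its frozen result ships with the package.

## Known limitations

No atria, no valve dynamics beyond the regularized diode, no baroreflex,
no autoregulation; a single systemic venous compartment; sex differences
enter only through the tabulated parameter groups. Clinical reference
values embedded in the report tables are population literature means and
serve only as labelled context columns.

Two BCG-specific limitations deserve emphasis. First, with the
homogenized inertances the pulse reaches the periphery almost
instantaneously, so the synthesized force is dominated by the early
ejection acceleration–deceleration couple and its systolic peak falls
earlier in the cycle than the J waves of measured recordings; the
post-systolic morphology is not reproduced at all (a known weakness of
lumped BCG models without atria). Second, the male-to-female amplitude
reduction predicted by the model (about 12% under the shipped
calibration) understates the sex difference reported for measured BCG
amplitudes (tens of percent): in this topology the amplitude-forming
proximal flow couple scales mainly with stroke volume, and only the
transmitted, geometry-sensitive part of the wave — which a
six-segment lumped chain carries imperfectly — responds to the smaller
arterial diameters. Comparisons of amplitude ratios across versions are
therefore qualitative (ordering and sign), not quantitative.
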