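---
title: "Simulating and analyzing opto-Pavlovian fiber-photometry experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing opto-Pavlovian fiber-photometry experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optopav)
```

## The experiment this package models

In an opto-Pavlovian conditioning task, a 7 s compound cue predicts
optogenetic stimulation of midbrain dopamine neurons: 2 s after the onset of
the laser-predictive cue, a 5 s laser train (20 Hz, 10 ms pulses) is
delivered, while a second cue predicts nothing. Each training session
presents 30 laser-paired and 30 non-laser cues in a pseudorandom order (no
trial type more than three times in a row) separated by uniform 45--75 s
inter-trial intervals. After about ten sessions the animal has learned the
association; in *omission* sessions one third of the laser-paired cues (10
of 30) are presented without the laser, which elicits a transient *dip* in
extracellular dopamine — the signature of a negative reward-prediction
error riding on a detectable tonic dopamine level.

Fluorescent sensors (dLight for dopamine, GCaMP6s for calcium in orexin
neurons) are recorded through an implanted fiber with two excitation
wavelengths: the 470 nm signal channel and the 405 nm isosbestic control,
which sees motion and bleaching artifacts but is insensitive to the analyte.

`optopav` implements every stage of this workflow on synthetic data: a
schedule generator, a two-channel trace simulator with ground truth, the
isosbestic ΔF/F₀ correction, peri-event AUC analyses, derivative
zero-crossing kinetics, and the matching statistical layer.

## The forward model

A session's latent sensor signal is

$$ s(t) \;=\; \text{tonic} \; + \; \sum_e A_e \, k(t - t_e), \qquad
   k(t) = \bigl(1 - e^{-t/\tau_r}\bigr)\, e^{-t/\tau_d}, \quad t \ge 0 , $$

with the kernel peaking at $\tau_r \log(1 + \tau_d/\tau_r)$. The two
channels share multiplicative artifacts:

$$ F_{470}(t) = g_s\,B(t)\,\bigl(1 + m(t)\bigr)\bigl(1 + s(t)\bigr) + \varepsilon_s(t),
 \qquad
   F_{405}(t) = g_c\,B(t)\,\bigl(1 + m(t)\bigr) + \varepsilon_c(t), $$

where $B(t)$ is double-exponential photobleaching, $m(t)$ a shared
band-limited (0.1--1 Hz) motion term and $\varepsilon$ iid Gaussian channel
noise. Because both artifacts are shared multiplicatively, regressing the
control onto the signal channel and using the fitted control as $F_0$ in
$(F - F_0)/F_0$ removes them, which is exactly what `compute_dff()` does.

Three event kinds place kernels on the time axis:

* **Cue transients** are phasic: brief bursts that decay well before the
  expected laser onset (`cue_tau_rise_s`/`cue_tau_decay_s`, e.g.
  0.15 / 0.5 s in the accumbens preset). Their amplitude grows across
  sessions following a saturating-exponential acquisition curve
  $A(s) = A_{\max}\,(1 - e^{-s/\lambda})$ (defaults $A_{\max} = 0.05$
  ΔF/F, $\lambda = 3$ sessions); the non-laser cue elicits a small constant
  response (0.005). The saturating form is the simplest monotone
  two-parameter model of the gradual growth of cue responses.
* **Stimulation responses** are sustained: the 5 s train drives a slow
  deflection with region-specific time constants. In the accumbens preset
  (τ = 3.5 / 12 s) the response keeps rising until just after the train
  ends (peak ≈ 5.2 s after laser onset); in the lateral-hypothalamus
  dopamine preset (0.6 / 2.5 s) it plateaus early (peak ≈ 1.0 s); the
  orexin-GCaMP6s preset (1.5 / 20 s) is slow and sustained. The decay
  ordering LH-dopamine < NAc-dopamine < LH-orexin is what makes the
  regional kinetics analysis meaningful.
* **Omission dips** are negative kernels at the expected laser onset with
  their own free time constants (0.3 / 1.0 s), slower than the phasic
  transient because they track clearance of tonic dopamine. The simulator
  refuses configurations whose dip would drive fluorescence non-positive.

Separating the phasic and sustained regimes is not cosmetic: with a single
slow kernel the cue response is still rising at the expected laser onset,
and any dip estimate is hopelessly confounded — the null calibration below
would fail. Real cue-evoked dopamine transients are sub-second events,
while the sustained rise under continuous stimulation reflects ongoing
release; the model encodes both.

Per-trial response amplitudes are multiplied by a condition scale factor in
$[0,1]$ (drug and anesthesia conditions: raclopride 0.35, SCH 23390 0.95,
anesthesia 0.85, vehicle 1), and by a per-subject factor (lognormal-like,
CV 0.15) so cohorts show realistic between-animal spread.

Sequencing uses exact-count allocation (never independent draws) followed
by rejection resampling of shuffles until the run-length cap holds, with an
explicit feasibility check and retry bound. Event times are rounded to
1 ms — acquisition-hardware resolution — which also makes the CSV schedule
round trip lossless.

## Analysis choices and their defaults

* **Isosbestic fit**: one global OLS fit per recording (the plainest
  reading of the standard procedure); per-window fits are not implemented.
* **Low-pass**: optional zero-phase 2nd-order Butterworth
  (forward–backward), unit DC gain, so event latencies used by the
  kinetics stage are not shifted. Simulated traces are already
  band-limited, so the pipeline default applies no extra filter.
* **Alignment**: half-open windows $[lo, hi)$ on a common relative grid
  (linear interpolation), each trial minus its own baseline-window mean.
  Default baseline $[-2, 0]$ s before the alignment event. For
  omission-dip quantification the baseline is shifted to precede the
  **cue** ($[-4, -2]$ s relative to the expected laser with the 2 s
  delay): a baseline between cue and expected laser would contain the cue
  transient and leak it into the dip estimate.
* **AUC**: trapezoidal, over a closed window, reported in ΔF/F·s. Cue
  responses use 0--1.5 s after cue onset; dips 0--2 s after the expected
  laser; terminal-stimulation experiments 0--20 s (locomotion control) and
  0--5 s (drug comparison). The dip window is a surfaced configuration
  parameter because regional kinetics differ.
* **Kinetics**: moving-average smoothing (default 0.5 s) then a central
  finite difference; point A is the first positive→negative derivative
  zero crossing after the reference (sub-sample by linear interpolation;
  zero samples bridged), point B the next negative→positive one. Crossings
  are detected on the subject-mean trace. The smoothing window is the main
  bias knob — for noiseless kernels the bias stays below half the window —
  and under noise a first-crossing estimator reports early when the true
  derivative hovers near zero (the accumbal plateau approach), so absolute
  crossing times are conservative; the between-region *ordering* is robust
  across smoothing choices.
* **Statistics**: two-sided at α = 0.05 throughout. Student (pooled)
  unpaired t; RM ANOVAs via within-subject error strata with **no
  sphericity correction** (matching the uncorrected df convention of the
  source analyses; a known limitation). Tukey HSD uses the studentized
  range on the within-subject error stratum. Degenerate inputs
  (zero-variance samples, identically constant tables) are flagged rather
  than erroring. The condition experiment uses 4 conditions × 3 subjects,
  the design consistent with a (3, 6) df report.

## What the simulation studies show — and what they do not

The package validates itself with cohort-level recovery studies
(`recovery_region_ordering()`, `recovery_omission_dip()`,
`recovery_learning_interaction()`, `type1_calibration()`), run at the study
conditions: 4 subjects, 30 + 30 trial sessions, 20/10/30 omission sessions,
10 training sessions, default noise, 25 Hz sampling (the hardware
low-passes at 12 Hz, so 25 Hz respects Nyquist while keeping a hundred
replicates tractable; single-trace examples use 100--1000 Hz where
precision matters). Typical results: the hypothalamic point A precedes the
accumbal point A in ≈100/100 cohorts; dip cohorts give negative subject
AUCs with a significant one-sample t in ≈100/100 while zero-dip cohorts
reject at ≈5/100; the session × cue interaction at df (9, 27) is detected
in ≈100/100 cohorts; and every test's null rejection rate sits inside the
binomial band around 0.05 over 2000 replicates.

These studies establish that the analysis code recovers the structure its
generator puts in. They do **not** establish anything about real
recordings: the generator has no hemodynamic or pH artifacts, no sensor
nonlinearity or saturation, no behavioral covariates (licking, locomotion),
perfectly Gaussian noise, and cue kinetics shared across dopamine regions —
so omission-trial crossing-point differences between regions are close to
zero here even though real data show them. Lock-in modulation and
demodulation are upstream of the model entirely; the simulator emits
already-demodulated traces.

## A worked run

```{r, eval = FALSE}
library(optopav)

cfg <- pipeline_config(seed = 7)
res <- run_pipeline(cfg, out_dir = "results/")
res
```

The bundle contains the learning curve and its RM ANOVA, per-subject
omission AUCs with the one-sample t, per-subject zero-crossing points with
the region comparison, and the condition experiment (paired t for freely
moving vs anesthetized; one-way RM ANOVA + Tukey across drug conditions).
All outputs are stamped with the master seed and a configuration hash, and
rerunning with the same seed reproduces them byte for byte.
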