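---
title: "Temporal gait parameters from windowed IMU classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal gait parameters from windowed IMU classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 7, fig.height = 4)
set.seed(1)
```

```{r setup, message = FALSE}
library(gaitwin)
library(dplyr)
```

## The problem

Clinically useful temporal gait parameters — stride, stance, swing and
double-support time — are defined by two kinds of events: *heel strike* (HS,
the foot touches the ground) and *toe-off* (TO, the foot leaves it).
Laboratory systems derive these events from optical markers on the foot; a
worn or carried IMU (accelerometer + gyroscope) must infer them from
movement signatures that vary with where the device is carried.

`gaitwin` implements both measurement chains and the agreement battery
between them:

* **M1 (experimental)** — events from vertical marker trajectories of the
  calcaneus (heel) and fifth metatarsal (toe).
* **M2 (predicted)** — events from IMU windows classified by small
  convolutional + recurrent networks, one per event stream
  (`HS_L`, `HS_R`, `TO_L`, `TO_R`).

Because real recordings of this kind are not redistributable, the package
ships a synthetic cohort generator with exact, analytically known ground
truth, which also makes every stage of the pipeline testable against an
oracle.

## The synthetic cohort

Each subject carries a gait signature: base stride time (normal, truncated
to 0.90–1.40 s), stance fraction, double-support fraction (constrained so
double-support duration stays in the physiological 0.1–0.2 s band at every
simulated speed), cycle-to-cycle stride variability, an impact amplitude and
a mild left/right asymmetry. Stride time scales with treadmill speed as a
power law. Trials are generated *events-first*: the right heel-strike
sequence is drawn, left events are placed half a cycle later, and toe-offs
at the stance fraction of each stride — so the truth events and all derived
cycle parameters are exact by construction.

```{r simulate}
cfg <- sim_config(fs_imu = 400, seed = 42)
profile <- draw_subject_profiles(1, cfg)
trial <- simulate_trial(profile, speed = 1.25, placement = "trouser", cfg,
                        duration = 20)
trial
```

From the event skeleton, two observation channels are rendered:

* **Markers (100 Hz)**: each vertical trajectory is a flat stance baseline
  plus one smooth swing bump per stride; a symmetric cosine valley is
  centred exactly on the event (HS on the calcaneus, TO on the metatarsal),
  so the local minimum *is* the event and survives zero-phase low-pass
  filtering without bias.
* **IMU (1259 Hz by default)**: gravity projection under slow orientation
  drift, stride- and step-frequency harmonics phase-locked to the actual
  heel-strike sequence (the periodicity and the impacts come from the same
  strides, so they cannot drift apart), and a damped impact transient at
  each event whose low-frequency component survives the 10 Hz filter. Each
  event stream has a fixed propagation direction, and the whole set is
  rotated by one shared per-trial rotation — the device has a single
  orientation per trial. Placement changes the coupling: broadband artifact
  grows from hand to trouser to jacket, and the jacket adds a slow pendulum
  artifact.

```{r plot-trial}
library(ggplot2)
autoplot(trial, window = c(8, 12))
```

## M1: marker events

Heel strikes and toe-offs are extracted per side from the filtered marker
trajectories:

1. find the *foot motion peaks* (swing apexes) of the calcaneus trajectory —
   local maxima with ≥ 10 mm topographic prominence and ≥ 0.4 s separation;
2. between each pair of successive peaks, the heel strike is the minimum of
   the calcaneus trajectory within the **first 30%** of the interval, and
   the toe-off is the minimum of the metatarsal trajectory between **40%
   and 80%** of it.

Local minima of the trajectory are preferred over band-boundary fallbacks
(a sample is judged a local minimum against its full-series neighbours, so
a genuine valley minimum falling on the band's edge sample still counts),
and with noise-free markers the recovered events match the generator's
truth within one 100 Hz sample.

```{r marker-events}
ev_m1 <- marker_events(trial)
head(ev_m1)
```

## Preprocessing and window labeling

The IMU stream is downsampled to the 100 Hz analysis rate (with
anti-aliasing), low-pass filtered with a **4th-order zero-phase Butterworth
at 10 Hz**, robust-scaled per channel (median/IQR, limiting the influence of
impact spikes), and segmented into **200 ms windows with 100 ms hop**.

Zero-phase (forward–backward) filtering is deliberate: a causal filter
delays every event signature by tens of milliseconds and would bias all
event times. The price is that the amplitude response is applied twice —
the gain at the 10 Hz cutoff is 1/2, not 1/√2.

A window is a *positive* training example for a stream only if an event
falls in a central band of the window, which forces the classifier to
localise events rather than merely notice their vicinity. The band must be
chosen with care relative to the hop. `label_windows()` defaults to the
central **45–55%** band; writing the event time as $t$ and the hop as
$h = 0.1$ s, a window starting at $s$ is then positive iff
$t - s \in [0.09, 0.11]$, and since windows start every $h$, an event yields
a positive window iff $t \bmod h \in [0, 0.01] \cup [0.09, 0.1)$ — a 20%
chance for an arbitrarily placed event. A classifier trained on such labels
is taught that off-centre events are *negatives* and consequently cannot
detect the events that never produced a positive window. The experiment
pipeline therefore defaults to the band $[0.25, 0.75]$ — the event within
half a hop of the window centre — the unique width at which every event
labels a window (and at most one, except exactly on the half-hop boundary).

```{r windows}
ws <- prep_windows(trial, ev_m1)
ws
colSums(ws$labels[-1])
```

## M2: window classifiers and event reconstruction

One detector per event stream: two 1-D convolution blocks (kernel 5,
widths 16/32, max-pool by 2) feeding an LSTM (32 units) and a sigmoid head,
trained with class-weighted binary cross-entropy (positives are upweighted
by the negative/positive ratio) and Adam. The implementation is a compact,
dependency-free set of numerical kernels whose gradients are verified
against central differences in the development tests.

At inference, window probabilities are turned back into event times:
adjacent supra-threshold windows form a run, each run becomes one event at
the confidence-weighted mean of the run's window centres, and a 0.4 s
refractory interval keeps only the most confident event — 0.4 s being below
any plausible stride time at walking speeds.

The cohort is split **by subject** (80/20), so no subject contributes to
both training and evaluation.

## Cycle parameters and the quality filter

For each pair of consecutive ipsilateral heel strikes: stride = the
interval; stance = HS to next ipsilateral TO; swing = the remainder
(stance + swing = stride holds to machine precision); double support = the
interval intersection of the cycle's stance with the contralateral stance
set. Cycles are excluded when any duration is negative, when they span a
condition transition, or when the stride is implausible (outside
0.4–2.5 s), with that order of precedence.

## Agreement battery

Condition-level means (per subject × speed × placement) from the two
pipelines are compared with:

* **rRMSE** $= 100\sqrt{\mathrm{mean}((m_2-m_1)^2)}/\mathrm{mean}(m_1)$,
  summarised per condition by median, IQR and a percentile bootstrap 95% CI
  of the *mean* (1000 seeded draws) — under right skew the median can fall
  below that CI, which is a property of the statistic, not an error;
* **Pearson correlation** with the conventional tiers
  weak ($r<0.3$), moderate ($0.3\le r<0.6$), strong ($r\ge 0.6$);
* **Bland–Altman** differences oriented $M_1-M_2$, bias ± 1.96 SD limits of
  agreement, and the percentage of points within the limits. One analysis
  per parameter × placement (mirroring one plot per parameter per sensor
  location, with one point per subject × speed); the report also carries
  pooled per-parameter rows for reference. The headline coverage figure in
  `glance()` judges every point against the limits of its own
  parameter × placement analysis, so a noisier placement is compared
  against its own, appropriately wider, limits rather than against limits
  dominated by cleaner placements.

A small-magnitude parameter assembled from four event times (double
support, ~0.15 s) necessarily shows larger *relative* error than a long
parameter assembled from two (stride, ~1.1 s) under the same absolute
event-time noise; the test suite asserts this ordering.

## Running the full experiment

```{r experiment, eval = FALSE}
ex <- run_experiment(experiment_config(seed = 20201), out_dir = "results")
ex
glance(ex$report)
autoplot(ex$report)
```

A single master seed drives everything: the cohort draw, per-trial
generation, the subject split, the four detector initialisations and the
bootstrap, each through a fixed offset, so the whole experiment is exactly
reproducible. On one CPU the default run (10 subjects × 3 speeds × 3
placements, ~90 s trials) takes on the order of ten minutes.

## Design choices, briefly

* **Events-first generation** makes truth exact and the valley/transient
  rendering testable; valleys are wide enough (150 ms) to survive the
  10 Hz filter with the minimum still on the event.
* **Per-trial robust scaling** (rather than global statistics) mirrors
  deployment, where each recording is normalised on its own.
* **Threshold 0.5 / refractory 0.4 s** for reconstruction; the refractory
  removes double-fires at run fragmentation without suppressing true
  events at walking cadence.
* **Analysis rate 100 Hz** (the marker rate): a common grid for both
  pipelines, with the 10 Hz band of interest far below Nyquist.
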