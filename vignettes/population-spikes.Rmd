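---
title: "Resolving overlapping stimuli with population spikes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving overlapping stimuli with population spikes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(cannstd)
```

## The model

`cannstd` simulates a rate-based continuous attractor neural network
(CANN) on a ring of preferred stimuli — the classic description of
direction-tuned populations such as those in cortical area MT — extended
with short-term synaptic depression (STD).  The state is the synaptic
current field $\tilde u(x,t)$ and the available neurotransmitter
fraction $p(x,t)$ at $N$ preferred directions $x$ on a periodic range of
$360^\circ$.  In rescaled, dimensionless form the dynamics integrated by
`simulate_cann()` are

$$
\tau_s \frac{d\tilde u_i}{dt} = -\tilde u_i + \tilde I_i
  + \sum_j W_{ij}\, p_j\, \tilde r_j,
\qquad
\tau_d \frac{dp_i}{dt} = -p_i + 1 - \tilde\beta\, p_i\, \tilde r_i,
$$

with Gaussian recurrent weights
$W_{ij} = \frac{dx}{\sqrt{2\pi}a}\exp\!\big(-d(x_i,x_j)^2/2a^2\big)$
(minimal-image periodic distance $d$), and a divisively inhibited firing
rate

$$
\tilde r_i = \frac{\Theta(\tilde u_i)\,\tilde u_i^2}{B},
\qquad
B = 1 + \frac{\tilde k}{8\sqrt{2\pi}a}\sum_j dx\,\tilde u_j^2 .
$$

All quantities are parameter-closed after rescaling: the neuron density
$\rho$ and raw coupling $J_0$ never appear, only $\tilde k$ (inhibition
relative to the bump-existence boundary), $\tilde\beta$ (depression
strength), $\tilde A$ (input strength) and $\tau_d/\tau_s$.  We adopt
the discretization convention $\rho\,dx = 1$ so that density integrals
become plain sums; its correctness is checked against the closed-form
stationary bump height $\tilde u_0 = 2\sqrt 2\,(1+\sqrt{1-\tilde k})/\tilde k$
(`bump_heights()`), which the discretized network reproduces to 0.3%.

Without input and without depression the network holds a continuous
family of Gaussian bumps of current SD $\sqrt 2 a$ (rate SD $a$) for
$\tilde k \le 1$.  The *tuning width* (TW) is $2a$; the reference
configuration uses $a = 48^\circ$, i.e. TW $= 96^\circ$, on $N = 80$
units.

### Stimuli

The input is a sum of Gaussian components of width $a_I$ (default $a$)
whose amplitudes fluctuate independently: each refresh interval
(50 $\tau_s$) the relative amplitudes $1+\delta_c$ are redrawn with
$\delta_c \sim \mathcal N(0,\sigma^2)$ and held constant in between
(zero-order hold).  The combined profile is then max-normalized to a
fixed peak strength $\tilde A$ (`normalize_input()`), so only the ratio
$\sigma$ matters.  Fluctuations are deliberately not clipped at zero —
clipping would bias the mean input upward; a negative single-component
amplitude (probability $\approx 4\times10^{-4}$ per draw at
$\sigma = 0.3$) is harmless after normalization, and only an everywhere
non-positive profile raises an error.

### Integration

The input is piecewise constant, so `simulate_cann()` integrates
segment-by-segment between refresh instants with an adaptive
Dormand–Prince 5(4) pair (`deSolve::rkMethod("rk45dp7")`) at local
tolerance $10^{-6}$, restarting at each refresh so the discontinuity
never crosses a step.  Halving the tolerances changes a 1000 $\tau_s$
trajectory by less than $10^{-4}$ (sup-norm), so results are
integrator-independent at this setting; `method = "rk78f"` is available
for a higher-order check.  Initial conditions are $\tilde u = 0$,
$p = 1$; the first 20 $\tau_d$ (1000 $\tau_s$) are excluded from every
statistic.  States are sampled every $\tau_s$, at least 50 samples per
population-spike cycle.  A run is exactly reproducible from its seed, or
bit-for-bit from its serialized fluctuation log (`replay()`).

## Population spikes and the readout

With depression, a sufficiently strong stimulus destabilizes the
stationary response: activity surges, depletes neurotransmitter locally,
collapses, and recurs once $p$ recovers — a *population spike* every
$\mathcal O(\tau_d)$:

```{r raster}
sim <- simulate_cann(cann_params(), cann_stimulus(0, A = 0.8, sigma = 0),
                     duration = 2000, transient = 1000, seed = 1)
plot(sim)
```

The readout mimics the analysis of tuning experiments: at every sample
the peak position $\arg\max_x \tilde r$ and height $\max_x \tilde r$ are
recorded (`detect_peaks()`), heights below a threshold are discarded,
and positions are histogrammed at grid resolution (80 bins;
`peak_histogram()`).  Peak positions are kept at grid resolution —
sub-grid interpolation would scatter mass between the grid-aligned bins.
The reference threshold is 6.2 for the recurrent model (0.45 for the
feedforward variant); both are plain arguments, and
`threshold_resolution_grid()` maps the consequences of the choice rather
than auto-selecting one.

For two stimuli at $\pm\Delta z/2$, `mean_peak_separation()` reports the
distance between the two cluster means and the within-cluster spreads.
Peaks are assigned to clusters by the side of the known stimulus
midpoint (the default; a 1-D 2-means rule is available via
`rule = "kmeans"` — on cleanly separated clusters the two agree, and
both are reported by the tests since no canonical rule exists for this
statistic).  One peak sample per sample time (time occupancy) is the
default statistic; `mode = "event"` keeps only spike apexes.

Bimodality of a histogram is decided by a two-sided mode test
(`two_mode_structure()`): the largest mode on each side of the midpoint
must exceed the valley between them by 20% of the histogram maximum
after a ±1-bin circular smoothing.  For smooth time-averaged profiles
(`split_separation()`) the prominence tolerance is 2% of the profile
maximum, enough to suppress discretization ripple on 80 units.  When a
histogram test is used as evidence that the *stimuli* are resolved, the
detected modes must additionally lie within half their expected offset
(never less than two grid cells) of the true component positions;
without this tracking condition, the turning points of a sloshing bump
— which sit at a stimulus-independent amplitude — masquerade as
resolution at small separations.

## Dynamical regimes

`classify_regime()` labels runs silent / static bump / population spikes
/ moving bump / slosher from the post-transient peak-height and
peak-position series, and `phase_diagram()` sweeps the
$(\tilde A, \tilde\beta)$ plane.  The thresholds operationalize
raster-plot phenomenology that has no printed quantitative definition,
so they were fixed against the deterministic reference exemplars and are
exposed as arguments:

* **silent** — `max h` below 10% of the analytic attractor rate height
  $\tilde r_0(\tilde k)$ (for $\tilde k=0.5$: $13.66$).  The weak-input
  exemplar ($\tilde A=0.4$) sits at $h\approx0.36$, two orders below the
  spike scale; an input-proportional criterion would misclassify it.
* **moving bump** — unwrapped peak position drifts by more than half the
  ring.
* **population spikes** — height-modulation index
  $(h_{\max}-h_{\min})/(h_{\max}+h_{\min}) \ge 0.25$.  The measured
  exemplar indices are 0.45 (spiking, $\tilde A=0.8$), 0.03 (slosher)
  and 0.00 (static), so 0.25 separates the classes with a wide margin
  on both sides.
* **slosher** — modulation below 0.25 but detrended position oscillation
  of amplitude $\ge 0.25a$.

## What the statistics reproduce

At the reference spiking parameters ($\tilde k = 0.5$,
$\tilde\beta = 0.24$, $\tilde A = 0.8$, $\sigma = 0.3$) the package
reproduces, at desk scale (20,000 $\tau_s$ per condition, about 5 s
each; the test suite and the acceptance script state the exact problem
sizes they run):

* the silent → population-spike → static-bump progression with input
  strength;
* thresholded spike-position clusters that over-estimate the stimulus
  separation for $\Delta z$ between roughly one-third and three-halves
  TW (motion repulsion) and converge to the true separation above;
* within-cluster spreads of 0.1–0.16 TW (roughly 12–15°) once two
  clusters have formed;
* two-mode structure down to $\Delta z\approx0.35$ TW from pooling 100
  windows of 500 $\tau_s$ each — the duration scale of a perceptual
  decision;
* the need for thresholding: with no threshold the distribution stays
  merged until $\Delta z$ exceeds a tuning width, while an intermediate
  threshold band resolves a few tenths of a TW even in the weak-STD
  sloshing regime;
* the control variants: no STD pins the response to one stimulus; no
  fluctuations leave overlapping stimuli merged; the purely feedforward
  network (depression driven by the input, linear rate, kernel scaled by
  $dx$ so the printed 0.45 threshold applies) stays single-clustered at
  $\Delta z = 0.5$ TW.

Two statistics come out quantitatively different from the published
account, and we report them as measured rather than adjust the analysis:

* **Time-averaged split.**  With the 2%-prominence rule the
  time-averaged profile first splits at 1.2–1.3 TW, not 1.0; the dip
  near 1.0–1.2 TW is 0–3% of the profile maximum, i.e. at the edge of
  both the prominence tolerance and the Monte-Carlo error of a 20,000
  $\tau_s$ average, and the result is stable across seeds and a 50,000
  $\tau_s$ check.  A contour-based visual reading naturally places the
  split earlier than a ridge-dip criterion.
* **Three-stimulus cluster centers.**  For equal stimuli at
  $-50^\circ/0^\circ/+50^\circ$ the above-threshold distribution does
  merge into exactly two groups, but at threshold 6.2 their centers
  track the outermost stimuli ($\approx\pm50^\circ$) instead of
  contracting to $\pm40^\circ$.  The statistic is extremely sensitive to
  the threshold relative to the spike-height distribution: samples with
  heights between 5 and 6.2 lie mostly near the center, so a threshold
  near 5.5 yields $\pm40^\circ$.  We keep the stated threshold and
  report the measured value.

## The synthetic stimulus generator vs. real data

The fluctuating-stimulus generator *is* the study's stimulus model: it
emulates the unbalanced moment-to-moment motion energy of transparent
random-dot displays after direction filtering — independent
per-component amplitude jitter on a 50 $\tau_s$ hold, with the total
drive max-normalized.  It does not emulate dot-level spatial structure,
direction-tuned filter dynamics, feedback from higher areas, or
intrinsic spiking noise (the only stochasticity is the input amplitude).
Passing tests therefore demonstrate properties of this idealized drive,
not of raw psychophysical stimuli.

## Numerical choices and degenerate inputs

* Kernel wrap-around uses the minimal image only; at $a = 48^\circ$ on a
  $360^\circ$ ring the next image carries relative weight
  $e^{-7}\approx10^{-3}$, and the relaxed bump reproduces the
  closed-form height to 0.3%.  Gaussian-shape checks fit the bump core
  ($|x - z| \le 2a$): the wrapped tail lifts the far side of the ring to
  about 6% of peak, which would bias a full-ring fit.
* $\tilde r = 0$ at exactly $\tilde u = 0$ (measure-zero; dynamically
  equivalent either way).
* The local-inhibition variant shares the global prefactor
  $\tilde k/(8\sqrt{2\pi}a)$; its kernel normalization is genuinely
  unspecified in the model definition, so `b_prefactor` chooses between
  a flat kernel (maximum 1, recovering the global model as
  $b\to\infty$) and a $1/(\sqrt{2\pi}b)$-normalized one.
* Argmax ties break to the smallest grid index; `p` stays in $[0,1]$ up
  to the integrator tolerance and is asserted, not clamped.
* Runs whose duration is not a refresh multiple are truncated to whole
  sample intervals; a NaN or stalled step aborts with the failure time.

## Limitations

The classifier thresholds, mode-prominence tolerances and the
intermediate-threshold band definition are operationalizations of
qualitative descriptions; all are exposed as arguments and their
sensitivity can be mapped with `threshold_resolution_grid()`.  The phase
diagram reports per-cell labels only — no analytic boundaries.  The
model is one-dimensional and rate-based; spiking implementations,
facilitation, and 2-D feature spaces are out of scope.
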