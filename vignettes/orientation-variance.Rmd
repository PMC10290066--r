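---
title: "Orientation variance in V1: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation variance in V1: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orivar)
```

## The scientific problem

Neurons in primary visual cortex (V1) are classically characterised with
single oriented gratings, but natural scenes deliver *distributions* of
orientations. The width of that distribution — the orientation variance
$B_\theta$ — is itself a meaningful sensory quantity. This package implements
a complete analysis chain for asking how single neurons and populations cope
with increasing $B_\theta$: some cells lose orientation tuning abruptly as
variance grows (*vulnerable*), others degrade gracefully and keep responding
across a broad variance range (*resilient*), and a recurrent ring network
with excitatory/inhibitory von Mises connectivity can produce both behaviours.

The chain has five stages, each usable on its own:

1. **Stimuli** — band-pass filtered noise textures ("Motion Clouds") whose
   Fourier orientation envelope
   $O(\theta, B_\theta) = \exp\{\cos(2(\theta_f-\theta))/(4B_\theta^2)\}$
   fixes a mean orientation and a variance.
2. **Synthetic data** — ground-truth archetype populations and
   inhomogeneous-Poisson spike trains for the full trial design.
3. **Tuning** — per-neuron tuning curves, von Mises fits, circular variance
   (CV), Naka–Rushton variance-tuning functions (VTFs), tuning significance
   and response-dynamics features.
4. **Clustering** — PCA + K-means archetype separation and a continuous
   vulnerability score.
5. **Decoding & ring model** — sliding-window multinomial logistic decoders of
   $\theta$, $B_\theta$ and their joint value, and the recurrent ring network
   with its connectivity-plane scan.

## The stimulus model

A stimulus is the inverse Fourier transform of white noise shaped by the
orientation envelope above times a log-Gaussian radial envelope (default one
octave, peak 0.9 cycles/degree). Drift at 10 deg/s orthogonal to the mean
orientation is a per-frame Fourier phase advance, so the per-frame mean
luminance is exactly constant; frames are rescaled to $[0,1]$ per stimulus
(the full-contrast convention). The experimental design crosses 12 mean
orientations (15 degrees apart) with 8 variances evenly spaced up to 35
degrees; the "zero-variance" point is implemented as 0.5 degrees because the
envelope divides by $B_\theta^2$. With two drift directions and 15 trials the
design has $96 \times 2 \times 15 = 2880$ trials.

Two caveats are deliberate. First, the envelope's $4B_\theta^2$ denominator
does not equal the von Mises rule $\kappa = 1/B_\theta^2$; it is kept as
printed in the stimulus family's definition. Second, the exact
bandwidth–concentration relation used by the ring model,
$B_\theta = \sqrt{0.5\arccos((\log 0.5+\kappa)/\kappa)/(2\log 2)}$, and the
small-angle rule $B_\theta \approx 1/\sqrt{\kappa}$ *cross* near
$B_\theta \approx 24.5$ degrees ($\kappa \approx 5.5$) and diverge away from
the crossing (at $\kappa = 20$ they differ by almost 40%). The package
implements the exact relation and treats the rule of thumb as exactly that.

## What the synthetic generator emulates — and what it does not

The downstream analyses consume only condition labels, so spikes are
generated from condition-level rate functions rather than rendered pixels.
Each model neuron has

* a VTF $(f_0, f_{max}, \log n, B_{\theta 50})$ drawn from
  archetype-conditional distributions centred on the two published exemplar
  cells (resilient: $\log n \sim 2.4$, $B_{\theta 50} \sim 31^\circ$,
  $f_0 \sim 0.30$; vulnerable: $\log n \sim 7$, $B_{\theta 50} \sim 14.5^\circ$,
  $f_0 \sim 0.42$), truncated to the fitting bounds;
* a rate model
  $r(t,\theta) = r_{base} + A(B_\theta)\, g_{\kappa_{eff}(B_\theta)}(\theta)\,k(t)$
  in which $\kappa_{eff}(B_\theta)$ is found by root-finding so that the
  circular variance of the 300-ms mean-rate tuning curve on the 12-point
  orientation grid **equals the neuron's VTF exactly** (to $10^{-3}$; in
  practice to machine precision). The amplitude decay
  $A(B) = r_{max}e^{-(B-0.5)/26.3}$ gives a $\sim$73% peak-rate loss at
  $B_\theta = 35^\circ$, matching the reported mean amplitude decrease;
* a difference-of-exponentials temporal kernel: transient for vulnerable
  neurons (latency 30 ms, rise 5 ms, decay 40 ms; peak $<$ 100 ms) and
  ramping for resilient ones (latency 50 ms, rise 100 ms, decay 400 ms; peak
  $>$ 200 ms), with mild per-neuron jitter and a 50-ms decay after stimulus
  offset;
* a laminar depth drawn supragranular ($<800\,\mu m$) with probability 0.8
  for resilient neurons.

Spikes are sampled by thinning a homogeneous Poisson stream at the rate
ceiling, which is exact for the stepless rate functions used here. The
generator is Poisson only: no trial-to-trial gain fluctuations, no noise
correlations between neurons, no LFP. Passing tests therefore demonstrate
that the analysis chain recovers the structure the generator puts in — they
do not show robustness to correlated variability or non-Poisson dispersion,
which real recordings certainly contain.

Default population conditions mirror the reference dataset where stated:
resilient fraction $85/249 \approx 0.34$, 15 trials per condition, recording
window $[-200, 450]$ ms. Rate scales ($r_{max} \sim$ log-normal around 28 Hz,
baseline 0.5–4 Hz) are the package's own choice of typical anesthetized-V1
values.

## Single-neuron analysis choices

* **Analysis window**: the 300-ms window (10-ms steps over $[0,450]$ ms)
  maximizing the across-condition variance of trial-averaged spike counts;
  ties go to the earliest window; all-zero neurons default to $[0,300]$ ms
  with a warning.
* **Baseline**: mean rate in $[-200, 0)$ ms, subtracted before all tuning
  metrics. For CV only, negative baseline-subtracted rates are clipped at
  zero, because the resultant-vector weights must be non-negative; an
  all-zero curve is flagged and reported as CV = 1.
* **Drift handling**: tuning curves average the two drift directions, except
  when the direction-selectivity index exceeds 0.5, in which case only the
  preferred direction is used.
* **von Mises exclusion**: neurons whose lowest-variance tuning curve fits
  with $R^2 < 0.75$ are flagged excluded, mirroring the standard recording
  quality criterion.
* **Naka–Rushton fitting**: bounded least squares with $f_0, f_{max} \in
  [0,1]$, $\log n \in [0.1, 10]$, $B_{\theta 50} \in [0.01, 44]$ degrees.
  The curve is always evaluated in the logistic form
  $f_0 + f_{max}/(1+e^{-n(\log B - \log B_{50})})$ so that near-step VTFs
  ($n$ in the thousands) do not overflow. Initialisation estimates the
  plateaus, then linearises the interior points with a logit transform —
  the transform is linear in $\log B$ with slope $n$ — and refines with
  bounded L-BFGS-B, keeping the initial point when refinement cannot
  strictly improve the fit. This matters for saturated VTFs, where the sum
  of squares is flat in $n$ above some value: the linearisation extracts
  the exponent from points one grid step from the changepoint, where the
  residual signal is of order $10^{-13}$ but still informative.
* **Tuning significance**: two-sided Wilcoxon signed-rank (continuity
  corrected, zeros discarded) between paired per-trial rates at the
  preferred and orthogonal grid orientations; fewer than 6 informative pairs
  counts as not tuned. $B_{\theta max}$ is the largest grid variance with
  $p < 0.05$.
* **Dynamics**: early/late log ratio $\log((late+1)/(early+1))$ with early
  $<$ 100 ms and late $>$ 200 ms (1-spike additive smoothing); delay to peak
  is the centre of the 100-ms window maximizing the tuning-curve peak
  amplitude.

## Clustering and the vulnerability score

Ten features per neuron enter in a fixed order ($\log n$, $B_{\theta 50}$,
$f_0$, $B_{\theta max}$, CV and early/late ratio and delay at the lowest and
highest variances), median-imputed and z-scored; more than 20% missing in a
column is an error. K-means (50 restarts, fixed seed) runs on the first two
principal components; the cluster with the larger mean $B_{\theta max}$ is
labelled resilient — a deterministic identity rule.

The continuous score combines seven of those variables. Each is min–max
normalised, oriented so that larger means more resilient ($B_{\theta 50}$,
$B_{\theta max}$, early/late ratio and delay directly; $\log n$, $f_0$ and CV
flipped), weighted by the normalised mean absolute PC-1/PC-2 loading of the
matching feature, summed, subtracted from one and affinely rescaled to
$[0,1]$ (0 = most resilient, 1 = most vulnerable). The published score
formula lists the weights only as "mean principal component parameters" and
mixes signs typographically; this interpretation is the one that actually
produces a $[0,1]$ score with the stated orientation, and min–max
normalisation makes the score invariant to affine rescaling of any input
variable. The delay term enters positively toward resilience as printed,
although the empirical delay contrast at low variance runs the other way;
the weights are configurable for users who prefer the empirical direction.

## Decoding choices

Spike counts in 100-ms windows slid from $-200$ to $+400$ ms in 10-ms steps
(61 windows) feed independent multinomial logistic decoders per window
(ridge penalty, $C = 1$ in the scikit-learn convention, i.e.
$\lambda = 1/(C\,n_{train})$; stratified 15% held-out split per window;
balanced accuracy = unweighted mean of per-class recall). The solver is
glmnet with a warm-started descending lambda path — a single small ridge
lambda makes its coordinate descent diverge — and an explicit flag records
any window where the solver hit its iteration cap. Population tuning curves
average held-out posteriors re-centred on the true class and are summarised
by their circular variance; the joint $\theta \times B_\theta$ decoder can be
marginalised over $B_\theta$, which can only increase the mass on the correct
orientation. Time courses over $[0,300]$ ms are fitted with
$\sigma(t) = max_{acc}/(1+e^{-k(t-\tau)}) + min_{acc}$; the printed form of
this sigmoid omits the time variable, and this is the standard form
consistent with calling $\tau$ the time constant. When the accuracy curve
does not rise inside the fit range, the Levenberg–Marquardt gradient is
singular and a bounded quasi-Newton fallback is used, flagged accordingly.

Group comparisons resample 100 neurons with replacement per group (5
resamples by default, as in the reference design) and test per-window
differences with a paired signed-rank test, reporting significance only for
runs of at least two consecutive windows. Note an arithmetic consequence:
with only 5 resamples an exact two-sided signed-rank test cannot go below
$p = 0.0625$, so the default configuration can never clear a 0.01 threshold
— the constructed-contrast test uses 10 resamples, and users wanting
significance at 0.01 should too. Score-sorted decoding forms 7 overlapping
groups of 100 along the descending score ranking with an even stride; with
249 neurons the printed "overlap of 20" is arithmetically impossible, so the
stride is configurable and defaults to even coverage of the ranking.

## The ring model

$N$ units tile $[-\pi, \pi)$; each obeys
$\tau\,dV/dt + V = V_{ff} + V_{exc} - V_{inh}$ with rate
$R = \alpha\max(V, 0)$, feedforward drive
$J_{ff}\,e^{\kappa_{ff}\cos(2(\theta-\theta_{pref}))}/(2\pi I_0(\kappa_{ff}))$
and recurrent drive equal to the spacing-weighted ring sum of the
difference-of-von-Mises kernel with the rates. Gains and time constant follow
the published cat-V1 parameterisation ($\tau = 10.8$ ms, $\alpha = 10.6$
Hz/mV, $J_{ff} = 9.57$, $J_{exc} = 1.71$, $J_{inh} = 2.0178$); the printed
unit labels are internally inconsistent (e.g. mV/Hz vs Hz/mV), and the gains
are applied exactly as the equations compose. Numerical choices, each made
once and verified by convergence tests:

* **Integration**: exponential Euler, $dt = 0.5$ ms, 300 ms span, steady
  state = mean over the last 50 ms. For constant input this integrator is
  exact, so the feedforward-only mode reproduces the closed-form first-order
  relaxation to machine precision; halving $dt$ moves steady rates by
  $< 10^{-3}$ relative.
* **Ring size**: $N = 256$ by default ($N$ is not printed in the source
  description); spacing-weighted sums make results insensitive to $N$
  (checked at 64/96/128/256), and the scans use $N = 96$–128.
* **Stimulus grids**: 20 variances spanning the experimental 0.5–35 degrees,
  each with 32 orientations tiling $[-75, 75)$ degrees in half-open even
  steps *including zero*. The inclusion of zero matters: at low variance the
  exact bandwidth relation yields $\kappa_{ff}$ in the $10^4$–$10^7$ range,
  a feedforward profile far narrower than any plausible sample spacing, and
  a grid without the centre angle would never sample the tuning peak. On
  this 32-point sub-span the circular variance of a perfectly flat curve is
  0.809, not 1 — the untuned ceiling of the model's VTFs.
* **Symmetry**: `model_vtf()` simulates one stimulus per variance at
  $\theta = 0$ and reads the readout unit's tuning curve from the steady
  population profile at the negated stimulus offsets, which is exact up to
  circular interpolation by the network's rotational symmetry (a test checks
  agreement with direct per-condition simulation in the feedforward case).
* **Stability**: strongly excitation-dominated kernels
  ($\kappa_{exc} \gg \kappa_{inh}$ with the published gains) make the
  linearised mode-2 gain exceed one and the simulation diverges; such cells
  are detected (membrane excursions beyond $10^6$), frozen and reported as
  missing rather than failing a scan. Mildly excitation-dominated cells
  remain bounded by rectification — the marginal regime in which the network
  sharpens any input into a near-invariant bump, producing near-zero CV at
  every variance.

On a coarse scan of the $(\kappa_{exc}, \kappa_{inh})$ plane, near-identity
(balanced) cells produce smoothly rising, resilient-like VTFs with lower
fitted $n$ and higher $B_{\theta 50}$, whereas stable cells above the
identity line produce higher $n$ and lower $B_{\theta 50}$ — the same
direction of effects as the published phase diagrams. The $f_0$ contrast
between those regions is weak in this implementation because both regimes
drive CV near zero at the lowest variances; $f_0$ is instead controlled by
the receptive-field bandwidth in the feedforward mode, where broadening the
RF raises $f_0$ while leaving $n$ and $B_{\theta 50}$ essentially unchanged.

## Problem sizes used by the tests and the acceptance script

The packaged checks run a 60-neuron population under the default generator
conditions (full 96-condition design, 15 trials), 20 label shuffles per
decoding task on a single informative window, an $8\times8$ coarse
connectivity scan at $N = 96$ with 12 variances, and a $10\times10$ scan for
the timing check. These sizes were chosen as the smallest at which every
quantity of interest is stable across seeds; all of them scale up through
function arguments (population size, shuffle count, scan resolution,
`n_units`, `b_grid`).

## Known limitations

* The generator's archetype-conditional parameter distributions reproduce
  the *direction* of every published group contrast, not the exact medians
  of the reference population, which depend on the deposited recordings.
* Poisson-only variability makes decoding accuracies optimistic relative to
  real data at matched population size.
* The recurrent scan's unstable wedge means some of the published plane is
  reported as missing here; whether the original implementation bounded
  those cells differently (shorter integration, implicit saturation) is not
  stated in the source description.
* HDF5 export is not provided; all artifacts are CSV/JSON.

```{r session}
sessionInfo()
```
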