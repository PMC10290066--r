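# orivar

Analysis chain for studying how primary visual cortex (V1) handles the
**orientation variance** of its input. Natural images deliver distributions
of orientations, not single gratings; as the spread of that distribution
(B<sub>θ</sub>, degrees) grows, some V1 neurons lose orientation tuning
abruptly (*vulnerable*) while others degrade gracefully and keep co-encoding
orientation and its variance (*resilient*). `orivar` implements every stage
needed to study this at the desk:

- **Motion Cloud stimuli** — band-pass filtered white noise with a von Mises
  orientation envelope O(θ, B<sub>θ</sub>) = exp{cos(2(θ<sub>f</sub>−θ)) / 4B<sub>θ</sub>²}
  in the Fourier plane, drifting orthogonally to the mean orientation, plus
  the 12 θ × 8 B<sub>θ</sub> experimental grid (96 conditions, 2880 trials).
- **Synthetic spike data** — ground-truth populations of the two archetypes
  and inhomogeneous-Poisson spike trains whose tuning-curve circular variance
  matches each neuron's variance-tuning function exactly.
- **Single-neuron analysis** — von Mises tuning fits
  f(θ) = R₀ + (R<sub>max</sub>−R₀)·exp{κ(cos 2(θ−θ<sub>pref</sub>)−1)},
  circular variance CV = 1 − |Σ R(θ<sub>k</sub>)e<sup>2iθ<sub>k</sub></sup> / Σ R(θ<sub>k</sub>)|,
  Naka–Rushton variance-tuning functions
  f(B) = f₀ + f<sub>max</sub>·Bⁿ/(Bⁿ + B₅₀ⁿ), Wilcoxon tuning significance
  (B<sub>θmax</sub>), direction selectivity, and response-dynamics features.
- **Archetype clustering** — PCA + K-means on ten tuning/dynamics features,
  and a continuous vulnerability score in [0, 1] weighted by the principal
  component loadings.
- **Population decoding** — sliding-window (100 ms, 61 windows) multinomial
  logistic decoders of θ (K = 12, per-variance), B<sub>θ</sub> (K = 8) and
  the joint θ × B<sub>θ</sub> (K = 96) with balanced accuracy, population
  tuning curves, marginalization, sigmoid time-course fits, group
  comparisons and score-sorted decoding.
- **Recurrent ring model** — rate units tiling orientation space,
  τ dV/dt + V = V<sub>ff</sub> + V<sub>exc</sub> − V<sub>inh</sub>,
  R = α·max(V, 0), Mexican-hat difference-of-von-Mises connectivity, a
  feedforward receptive-field mode, and the 200 × 200
  (κ<sub>exc</sub>, κ<sub>inh</sub>) connectivity scan (40,000 configurations).

## Worked example

```r
library(orivar)

pop <- sample_population(n_neurons = 40, seed = 1)   # 85/249 resilient fraction
ds  <- simulate_trials(pop, seed = 2)                # full 2880-trial design
sm  <- analyze_tuning(ds)                            # per-neuron summaries
cm  <- cluster_archetypes(assemble_features(sm), seed = 3)
score <- vulnerability_score(sm, cm)

print(pop); print(ds); print(sm); print(cm)
round(tapply(score, pop$archetype, mean), 2)
```

```
Ground-truth population: 40 neurons (14 resilient, 26 vulnerable)
Spike dataset: 40 neurons, 2880 trials/neuron, 439103 spikes, window [-200, 450] ms
Neuron summaries: 40 neurons (0 excluded by von Mises R^2 < 0.75)
  median log(n) = 3.64, median B50 = 18.0 deg, median f0 = 0.39
Archetype clustering (k = 2): 26 vulnerable, 14 resilient
  PC1 + PC2 explain 80.5% of the feature variance
 resilient vulnerable
      0.12       0.76
```

The clustering recovers the 26/14 ground-truth split exactly, and the
vulnerability score separates the archetypes by ~0.6: resilient neurons sit
near 0, vulnerable near 1.

Decoding orientation from the population at the lowest variance, and a ring
model with balanced recurrent connectivity:

```r
scm <- windowed_counts(ds, task = "theta", b_theta = 0.5, onsets = seq(0, 200, 50))
decode_timecourse(scm, seed = 4)
model_vtf(ring_config(n_units = 128, kappa_exc = 3, kappa_inh = 3))
```

```
Decoder run (theta task): max balanced accuracy 0.750 (9.0x chance 0.0833) at 0 ms
Model VTF over 20 bandwidths (20 stable):
Naka-Rushton VTF: f0 = 0.003, fmax = 1.000, log(n) = 2.08, B50 = 39.07 deg (R^2 = 0.997)
```

Orientation is read out at 9× the 1/12 chance level from 40 synthetic
neurons, and the balanced-connectivity ring produces a resilient-like VTF:
near-linear (low log n) with a high changepoint. Excitation-dominated
connectivity raises the fitted nonlinearity and lowers the changepoint —
the vulnerable direction. `run_pipeline(outdir, seed)` chains all stages and
writes CSV/JSON artifacts plus a run manifest.

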