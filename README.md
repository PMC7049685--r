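# mtscrunch

Quantitative analysis of transcription initiation by the yeast
mitochondrial RNA polymerase (Rpo41) and its initiation factor Mtf1,
built around two data streams:

* **single-molecule FRET traces** of promoter DNA labeled at −16/+16,
  which report the closed → open → scrunched conformational pathway of
  the initiation complex, and
* **ensemble titrations and gel assays** — fluorescence anisotropy
  (complex stability), 2-aminopurine fluorescence (promoter melting and
  initiating-nucleotide binding), radiometric 2-mer synthesis kinetics
  and abortive/runoff product quantification.

The package is aimed at single-molecule biophysicists who want the whole
chain — simulation, trace correction and QC, histogram mixture fits,
hidden-Markov kinetics, binding/kinetics fits — as tested, seeded,
scriptable R functions rather than GUI steps.

## Models at the core

**FRET correction.** Detected donor/acceptor intensities are corrected
as `E = (I_A − 0.08·I_D)/(I_D + I_A)` (background-subtracted channels,
0.08 donor→acceptor leakage); traces are five-frame averaged and pooled
into density histograms.

**Three-state kinetics.** Corrected traces are modeled by a
Gaussian-emission hidden Markov model with states closed/open/scrunched,
fit by pooled Baum–Welch EM. Per-frame transition probabilities are
converted to rate constants via the matrix logarithm (`k = logm(P)/Δt`),
and the scrunching equilibrium constant is
`Keq = k(open→scrunched)/k(scrunched→open)`.

**Binding and kinetics.** Anisotropy titrations use the quadratic
tight-binding isotherm

```
r_obs = r_f + (r_b − r_f) · [(K_d+P_t+D_t) − sqrt((K_d+P_t+D_t)² − 4·P_t·D_t)] / (2·D_t)
```

(required because the labeled DNA is at concentrations comparable to
K_d); nucleotide binding uses the hyperbola `F0 + ΔF·x/(K_d + x)`; 2-mer
synthesis uses Michaelis–Menten `v = k_cat·S/(K_m + S)` with catalytic
efficiency `k_cat/K_m`; gel bands convert to molar RNA via
`R/(R + A)·[ATP]`.

A seeded synthetic-data generator (exact-jump Markov trajectories +
leakage/background/noise/photobleaching photophysics, and closed-form
titration curves) produces every input the pipeline consumes, so each
stage is testable end to end without instrument data.

## Worked example

Simulate a wild-type-like +2 initiation complex (Keq = 0.6/0.1 = 6),
process the traces, and recover populations and kinetics:

```r
library(mtscrunch)

model <- three_state_model(k_open = 0.2, k_close = 0.4,
                           k_scrunch = 0.6, k_unscrunch = 0.1)
phys  <- photophysics(leakage = 0.08, frame_interval = 0.1)
traces <- simulate_trace_set(model, phys, n_traces = 50, n_frames = 600,
                             seed = 42)

fret <- lapply(traces, compute_fret, leakage = 0.08)
h    <- build_histogram(fret, window = 5)
fit_gaussian_mixture(h, n_components = 3, seed = 1)
#> Gaussian mixture fit (em backend, 3 components, n = 6000)
#>    mean     sd weight fixed
#>  0.1437 0.0294 0.2562 FALSE
#>  0.3811 0.0576 0.1258 FALSE
#>  0.5585 0.0277 0.6180 FALSE

fit <- fit_hmm(fret, n_states = 3, seed = 1)
rates_from_hmm(fit, frame_interval = 0.1)
#> Rate constants (s^-1, exact_log conversion):
#>           closed   open scrunched
#> closed    0.0000 0.1753  0.001384
#> open      0.4153 0.0000  0.576800
#> scrunched 0.0000 0.1024  0.000000
#>   Keq (scrunch) = 5.631668
```

The mixture recovers the three FRET populations near their true means
(0.14/0.38/0.56) with the scrunched state dominant, and the HMM recovers
the generating rates (truth: 0.2, 0.4, 0.6, 0.1 s⁻¹) and a scrunching
Keq close to the true value of 6.

Ensemble example — noiseless Michaelis–Menten data regenerate their
truth exactly:

```r
titr <- generate_titration("michaelis_menten",
                           list(k_cat = 0.4, K_m = 165),
                           x = seq(0, 4000, length.out = 10))
fit_michaelis_menten(titr)
#> Nonlinear fit: Michaelis-Menten (n = 10 points)
#>               estimate std_error
#> k_cat      4.00000e-01         0
#> K_m        1.65000e+02         0
#> efficiency 2.42424e-03         0
```

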