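---
title: "Models and methods: smFRET and ensemble kinetics of mitochondrial transcription initiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtscrunch)
```

## The system and what the package computes

Yeast mitochondrial RNA polymerase (Rpo41) initiates promoter-specific
transcription only with its initiation factor Mtf1. During initiation the
enzyme keeps its upstream promoter contacts and pulls downstream DNA into
the complex — *DNA scrunching* — so a promoter labeled with a FRET pair at
positions −16 and +16 reports initiation progress as increasing FRET
efficiency. Single-molecule TIRF recordings of stalled initiation
complexes show three conformations: a *closed* (low-FRET) state, an
*open* (mid-FRET) state with the −4…+2 bubble melted, and a *scrunched*
(high-FRET) state characteristic of the +2 complex. The balance between
scrunching and unscrunching, summarized by the equilibrium constant
$K_{eq} = k_{scrunch}/k_{unscrunch}$, measures how well a given Mtf1
variant stabilizes the scrunched conformation.

`mtscrunch` implements the full quantitative chain for this system:

1. a seeded **synthetic-data generator** (continuous-time Markov chain +
   detection photophysics) that emulates the smFRET recordings and the
   ensemble titrations, so every downstream stage can be validated
   against known ground truth;
2. **trace processing**: leakage/background FRET correction, trace QC,
   five-frame-averaged pooled histograms;
3. **histogram models**: 1–3-component Gaussian mixtures with optional
   fixed peak positions;
4. **HMM kinetics**: a three-state Gaussian-emission hidden Markov model
   fit by pooled Baum–Welch, Viterbi idealization, transition-density
   plots, and conversion of transition probabilities to rate constants;
5. **ensemble assays**: quadratic tight-binding anisotropy fits,
   hyperbolic nucleotide-Kd fits, Michaelis–Menten kinetics,
   2-aminopurine fold changes, gel-band RNA quantification and
   abortive:runoff ratios, and bubble-collapse exponential fits.

## The kinetic model and the simulator

A `kinetic_model` holds state labels, one FRET mean and emission width
per state, and the first-order rate matrix; its generator has diagonal
$-\sum_{j\ne i} k_{ij}$. States are stored sorted by FRET mean, so closed
< open < scrunched by construction. The default three-state means are
0.14 (closed / free DNA), 0.38 (open) and 0.56 (scrunched at +2), the
peak positions observed for the wild-type system, with emission width
0.06; all are per-scenario overridable.

`simulate_state_path()` draws exact-jump (Gillespie) trajectories and
integrates them onto the camera grid as *fractional occupancies* per
frame. This matters: transitions faster than the frame interval produce
frames whose FRET is a dwell-time-weighted average of two states (motion
blur), which is exactly what broadens the histograms of fast-switching
mutant complexes. Snapping jumps to frame boundaries would hide that.

`render_trace()` converts occupancy to detected channels. With total
intensity $T$, leakage $l$ and frame FRET $E$,
$$I_D = \frac{T(1-E)}{1+l}, \qquad I_A = \frac{T(E+l)}{1+l},$$
which is the exact algebraic inverse of the correction
$E = (I_A - l\,I_D)/(I_D + I_A)$ applied by `compute_fret()`. We chose
this parameterization deliberately: it makes "correction undoes the
simulated leakage" an exact (≤ 1e-12) round-trip identity rather than an
approximation, giving the test suite a machine-precision invariant.
Conformational noise is Gaussian on the FRET scale (per-state width),
and optional Gaussian detection noise is added per channel — matching
the Gaussian-emission assumptions of the mixture and HMM stages. Poisson
or EMCCD excess-noise statistics are out of scope. Photobleaching is a
single exponential step per dye: after acceptor bleach the trace
continues at $E = 0$; after donor bleach both channels drop to
background. Short acceptor direct-excitation blocks at the start and end
of each movie let QC discard traces without an active acceptor.

The recordings' frame rate, trace length and noise level are not pinned
down by the experimental description we model, so the generator defaults
to 0.1 s/frame (typical EMCCD smFRET acquisition) and everything scales
with the configurable `frame_interval`.

## Trace processing choices

* **Background**: treated as a per-channel constant supplied to
  `compute_fret()`; simulations default to zero. No spatial background
  model is attempted.
* **Bleach/step detection** (`detect_bleach_steps()`): recursive binary
  segmentation on total intensity with a minimum segment length of 10
  frames and a step threshold of 4× the robust noise scale (MAD of first
  differences / √2). Spots carrying two dye pairs show ≥ 2 downward
  steps and are rejected by the single-pair filter.
* **Mid-FRET visit filter**: the histogram-building convention for
  complexes requires each trace to have visited the open-state band at
  least once; the band defaults to mean ± 2σ of the open component and
  is configurable.
* **Windows**: five-frame, non-overlapping means (trailing partial
  windows dropped). Overlapping windows would correlate pooled points
  and distort apparent populations.
* Corrected FRET outside $[-0.2, 1.2]$ is flagged, not clipped — noise
  legitimately pushes corrected values slightly outside $[0, 1]$, and
  clipping would bias peak fits.

## Mixture fits

`fit_gaussian_mixture()` maximizes the pooled likelihood by EM with a
deterministic quantile-spaced start plus 10 seeded jittered restarts,
per-component variances (floored at σ = 1e-4 to prevent delta-spike
collapse) and exact enforcement of user-fixed means — the
constraint used to fit a new high-FRET population while holding the
closed/open positions at their reference values. The number of
components is always user-specified (2 vs 3 mirrors how the conditions
are analyzed); no BIC-style automatic selection is attempted. Widths are
reported as Gaussian σ, with FWHM provided as a derived field. A
histogram least-squares backend (Levenberg–Marquardt on the binned
density) is kept as an independent cross-check route; the two backends
agree to ±0.01 on well-separated simulations.

## HMM kinetics

`fit_hmm()` is maximum-likelihood Baum–Welch over all traces pooled: one
emission/transition model per condition, per-trace scaled
forward–backward (implemented in C++ for speed; the scaled recursion is
validated against exhaustive path enumeration to 1e-10 on small cases),
and an M-step that pools sufficient statistics across traces. The EM
log-likelihood is asserted non-decreasing at every iteration. Emission
variances carry a floor of 1e-4 to prevent degenerate collapse. The
state count is fixed (three for initiation complexes) rather than
inferred. This is a deliberate replacement of the variational-Bayes
inference used by ebFRET-style tools with plain maximum likelihood: it
is deterministic given seeds, dependency-free, and recovers rates within
the tolerances we target; it does not provide model evidence for state
counts, which we do not need.

Viterbi idealization breaks exact ties toward the lower state index.
Transition-density plots place one point per state change at the
(departing, arriving) emission means.

**Probability → rate conversion** (`rates_from_hmm()`): the default is
the principal matrix logarithm of the transition matrix divided by the
frame interval — exact for a time-homogeneous continuous-time chain
observed at discrete times; small negative off-diagonal entries (finite-
sample artifacts) are floored at zero and flagged. The linear
approximation $k_{ij} = p_{ij}/\Delta t$ is available for comparison and
is adequate when $p_{ij} \ll 1$. Recovery is reliable for
$k\,\Delta t \lesssim 0.3$; beyond $k\,\Delta t \approx 0.5$ missed
transitions bias rates low, which the parameter-recovery tests document.

## Ensemble assays

* **Quadratic tight-binding** (`fit_quadratic_binding()`): observed
  anisotropy versus total protein with the labeled-DNA concentration
  fixed, using the closed-form bound fraction
  $f_b = \big[(K_d{+}P_t{+}D_t) - \sqrt{(K_d{+}P_t{+}D_t)^2 - 4P_tD_t}\big]/2D_t$.
  The printed source equation carries a symbol under the square root
  ("D_b") defined nowhere; the standard closed form requires $D_t$
  there, and that is what we implement. In the stoichiometric regime
  ($K_d \ll D_t$) the RSS profile in $K_d$ is nearly flat with a cliff,
  so the fitter profiles the linearly-entering anisotropies out exactly
  on a log-spaced $K_d$ grid (variable projection) and polishes from the
  profiled optimum — naive starts stall at a bound.
* **Hyperbola / Michaelis–Menten**: standard three- and two-parameter
  least squares; catalytic efficiency $k_{cat}/K_m$ is reported with a
  covariance-propagated standard error. The tight-binding model reduces
  to the hyperbola for $D_t \le K_d/100$ (checked to < 1%).
* **Gel quantification**: RNA (µM) $= R/(R+A)\cdot[\mathrm{ATP}]$. For
  multi-band lanes each band uses $R_{band}/(R_{total}+A)$ so amounts
  are additive and bounded by [ATP]; the per-band alternative is
  available. Abortive RNA sums the 3–7-mer bands only.
* **Bubble collapse**: single-exponential decay, our modeling choice for
  time courses that are displayed but not fit in the source analyses. A
  fitted amplitude smaller than twice its standard error returns a
  no-collapse verdict instead of a rate.
* Fits are unweighted by default (the source data report duplicate-based
  error bars without a weighting scheme); per-point weights can be
  supplied. Concentration units are tags checked at fit time — a nM
  dataset passed to a µM fit errors rather than silently converting.

## Seeds and determinism

Every stochastic operation takes a seed; trace sets derive per-trace
seeds from one master seed, and `run_pipeline()` derives stage seeds from
its config seed. Identical config + seed therefore reproduces every
number bit-for-bit, which the tests assert.

## What the simulations do and do not show

The generator reproduces the features the analysis depends on: state-
dependent Gaussian emissions, exponential dwells, motion blur, leakage,
background, bleaching, check frames. It does not emulate raw movies
(spot finding, drift), non-Gaussian detector noise, dye photophysics
beyond single-step bleaching (blinking, spectral shifts), or baseline
drift. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to every instrument
artifact.

Problem sizes used in the shipped tests and acceptance computations —
e.g. 60–175 traces of 500–600 frames for histogram and Keq recovery,
10⁵ frames for stationarity checks — were chosen to match the scale of
the emulated experiments while keeping full runs fast on a laptop.

## Known limitations

* Pooled HMM assumes all traces of a condition share one model;
  per-trace heterogeneity is averaged over (the pooled fit is the
  analysis convention for per-condition rate comparison).
* Rate recovery degrades in the missed-transition regime
  ($k\,\Delta t > 0.5$).
* No gamma-factor/detection-efficiency correction or ALEX stoichiometry
  filtering; the FRET scale is the corrected proximity ratio.
* Dwell-time survival analysis beyond the transition-matrix conversion
  is out of scope.
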