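---
title: "Quantifying neuronal dynamical instability with neurodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal dynamical instability with neurodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodyn)
```

## Overview

`neurodyn` quantifies how stable a neuron's dynamics are, at four
scales: the kinetics of individual spike onsets, the sequence structure
of those kinetics (Markov state transitions), the divergence of
membrane-potential trajectories (Lyapunov exponents), and the temporal
statistics of field potentials (Ornstein–Uhlenbeck parameters and
stationarity). A fifth branch analyses trial-to-trial noise of
voltage-clamped sodium currents, and a sixth classifies extracellular
spike patterns. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Spike metrics

Spikes are detected as contiguous supra-threshold excursions (strict
`>`; a sample exactly at threshold does not trigger, which makes the
boundary behaviour deterministic), timed at the local extremum, with a
configurable refractory dead time (default 2 ms) and a polarity flag
for negative-going extracellular peaks. The threshold is a required
input: thresholds in practice are set per recording, and inventing an
automatic rule would hide a consequential choice.

Peak onset rapidness is the maximum dV/dt during the depolarizing
segment, computed by central finite differences over a window ending at
the peak (default 2 ms, configurable; one-sided differences at trace
edges). Central differences on a logistic rise underestimate the
analytic slope by a factor that grows with steepness relative to the
sampling interval; the generator tests account for this bound exactly
rather than hiding it in a loose tolerance.

Local variation of an ISI sequence \(T_1,\dots,T_n\) is

\[
Lv = \frac{1}{n-1} \sum_{i=1}^{n-1}
  \frac{3\,(T_i - T_{i+1})^2}{(T_i + T_{i+1})^2}.
\]

It is invariant to uniform time rescaling, 0 for perfectly regular
trains, 1 in expectation for Poisson firing, and \(3/(2\kappa+1)\) for
gamma-renewal ISIs of shape \(\kappa\) — the calibration the test suite
checks at \(\kappa \in \{1, 2, 4\}\) with \(10^4\) ISIs.

## Markov state dynamics

Any per-spike scalar series (onset rapidness, per-spike Lyapunov
values) is discretized into three classes by its own distribution:
class 1 from the minimum to the first quartile, class 2 to the third
quartile, class 3 above. Quartiles use linear interpolation of order
statistics (R's type 7, configurable); values exactly at Q1 belong to
class 1 and exactly at Q3 to class 2 (closed-left convention — the
underlying convention is arbitrary, so it is fixed and recorded).
Quartiles are computed per recording by default; pooling across
recordings is the caller's choice by concatenating before
classification.

One-step transitions are counted and row-normalized. A class never
visited as a source yields an empty row; its probability row is filled
with the uniform placeholder 1/3 but flagged in `empty_rows`, so
downstream summaries can exclude it rather than mistake the placeholder
for data. The persistence index (mean diagonal over non-flagged rows,
1 = frozen, 1/3 = memoryless) is an added summary for group comparisons,
not a standard chain statistic.

## Lyapunov exponents

Membrane dynamics are embedded in the plane of the potential and its
time derivative. Axes are standardized to unit variance before distance
computation because mV and V/s are incommensurate; the exponent itself
is invariant to any common rescaling. For each reference point the
nearest Euclidean neighbour outside a Theiler window (default 10
samples) is tracked forward over an expansion range \(K_{min}..K_{max}\)
(defaults 1..10 samples):

\[
\lambda(i) = \frac{1}{(K_{max}-K_{min}+1)\,dt}
  \sum_{K=K_{min}}^{K_{max}} \frac{1}{K}
  \ln\frac{\lVert Y_{i+K}-Y_{i^*+K}\rVert}{\lVert Y_i-Y_{i^*}\rVert}.
\]

Numerical choices: neighbours must exceed a minimum initial separation
(default \(10^{-6}\) standardized units) — exactly periodic
trajectories otherwise select rounding-level separations whose
log-ratios are pure floating-point noise; expansion distances are
floored at the same value; references whose expansion window crosses
the series end are dropped, and references with no admissible neighbour
are skipped and counted. For long recordings `n_ref` caps the number of
references (taken evenly spaced, deterministically) while neighbour
candidates still span the whole trajectory.

The estimator separates regimes as it should: \(\approx \ln 2\) on the
chaotic logistic map at r = 4, \(\approx 0\) on a sine, and exactly the
planted rate on a constructed exponentially separating pair; a naive
double-loop implementation serves as the oracle for the vectorized
path.

Per-spike exponents come in two flavours. `"within"` estimates each
peri-spike window (default 10 ms) from its own trajectory, yielding the
per-spike series that feeds the Markov stage. `"ensemble"` pools all
other spikes' windows as neighbour candidates: each action potential is
one pass through the same phase-space region, so the ensemble supplies
recurrences a short single pass cannot.

On stochastic (non-chaotic) traces the log-ratio estimator measures the
decorrelation rate of the fluctuations rather than a deterministic
divergence rate — amplitude-only noise differences cancel exactly
because the formula is scale-invariant. This is why the synthetic
"unstable" condition below differs from control in its noise
correlation time, not just amplitude.

## OU modelling and stationarity of field potentials

The LFP model is a mean-reverting Gaussian process. The series is
mean-centered; \(\tau\) is the decay constant of a least-squares fit of
\(e^{-\mathrm{lag}/\tau}\) to the empirical ACF over lags from 0 to the
first lag where the ACF drops below 0.05 (capped at `max_lag`, default
1 s — beyond the first collapse the ACF is mostly estimation noise);
\(\sigma\) is the SD of the linearly detrended signal; \(\mu\) is the
raw mean. The fit is exactly invariant to constant offsets. Simulation
uses the exact discrete transition
\(X_{t+dt} = \mu + (X_t-\mu)e^{-dt/\tau} + \sigma\sqrt{1-e^{-2dt/\tau}}\,\xi\)
by default (its moments are closed-form and testable); a fixed-step
Euler–Maruyama scheme is available to mirror fixed-step simulators.
\(\sigma\) parameterizes the stationary SD, not the diffusion
coefficient, because noise amplitude is measured as a signal SD.

The continuous wavelet transform uses the analytic Morlet wavelet
(centre-frequency parameter 6) on a log-spaced grid, default 0.5–100 Hz
in 32 bands, with energy-preserving (L2) normalization: white-noise
band power is flat, and a pure tone's power ridge lands within one grid
step of the tone (under a noise-flat normalization a tone falling just
above a log-grid midpoint can resolve to the band below; an
amplitude-true normalization would instead tilt the noise spectrum —
one cannot have both, and the flat-noise convention matches how these
spectrograms are read).

The augmented Dickey–Fuller test is the constant/no-trend OLS
regression \(\Delta y_t = \alpha + \rho y_{t-1} + \sum_j \gamma_j
\Delta y_{t-j} + \varepsilon_t\); the statistic is the t-ratio of
\(\rho\) and p-values come from the MacKinnon response-surface
approximation (the implementation agrees with statsmodels' `adfuller`
to six decimals on frozen fixtures). Lag order is selected by AIC up to
the Schwert bound by default, or fixed. The null hypothesis is a unit
root, so *high* p-values mean the non-stationary null cannot be
rejected. The per-band profile runs the test on the real part of each
band's coefficients (magnitude-envelope mode by flag), after decimating
to about 20 samples per wavelet period — CWT output is heavily
oversampled relative to each band's bandwidth, and the regression on
near-duplicate samples would mostly measure interpolation. No
aggregation across bands is performed; the object of interest is the
profile itself. Note that a band can only reject the null if the series
spans many of its periods: the lowest default band (0.5 Hz) of a 10 s
series has five cycles and essentially no power to reject, regardless
of the underlying process.

## Sodium-current noise analysis

The steady-state inactivation protocol conditions the channel at
prepulse voltages (−100..−20 mV in 10 mV steps by default) and reads
availability from the test-pulse peak. Inward currents are negative, so
the peak is the most negative excursion of the repeat-averaged current
in the test window (polarity flag for data exported positive).
Normalized peaks are fitted with the Boltzmann availability
\(1/(1+e^{(V-V_{1/2})/k})\), \(k>0\), by Levenberg–Marquardt least
squares; the fit is exactly equivariant to voltage shifts.

Non-stationary noise is the SD across repeats (divisor n−1) of the
residuals after subtracting the repeat-averaged current, per voltage
and time point; the residuals are by construction invariant to any
waveform common to all repeats. The maximum noise variability is taken
over the test-pulse window by default (`window = "full"` extends it),
since that is where the inactivation process lives. A diagnostic
reports where the residual SD peaks relative to the mean-current peak:
amplitude-scaled (gating-like) noise concentrates near the current
peak, additive instrument noise does not. No decomposition of the
variance into gating versus thermal sources is attempted.

## Spike-pattern classification

Adjacent-ISI pairs \((T_i, T_{i+1})\) form the feature space for
Gaussian-mixture clustering (EM via mclust, full covariances), on log
ISIs by default since ISI distributions are right-skewed. Mixture
weights are the emergence probabilities of the latent firing motifs.
Because picking the component count by eye is not reproducible, it is a
required argument, and a BIC table over k = 1..6 documents the choice.

The probabilistic distance between groups is defined as
\(2\cdot(\text{balanced out-of-bag accuracy} - 0.5)\) of a
bootstrap-aggregated decision-tree ensemble (random forest, 500 trees
by default) classifying non-overlapping windows of 20 consecutive ISIs
(or instantaneous frequencies), clipped to [0, 1]. This choice is
symmetric, bounded, 0 in expectation under exchangeability and 1 under
perfect separability, and is recorded in the result metadata. The
distance matrix feeds average-linkage hierarchical clustering with a
Newick export.

## The synthetic generators: what they emulate, and what not

Every generator is seeded and reproducible, and returns its ground
truth, so each analysis stage can be tested as a parameter-recovery
problem.

- `gen_gamma_train`: gamma-renewal ISIs, rate and shape known; the Lv
  calibration target.
- `gen_membrane_trace`: spikes on a −60 mV baseline with a logistic
  rising phase whose *analytic* maximum slope equals the spike's drawn
  onset-rapidness state mean (states from a known 3-state chain;
  relative jitter around class means), then an exponential
  repolarization. Only the peak dV/dt matters downstream, so the
  waveform is deliberately stereotyped. ISIs are gamma with an absolute
  refractory floor (12 ms default) so that irregular trains cannot
  overlap templates. Membrane noise is white by default or
  OU-correlated (`noise_tau`), emulating band-limited recording noise
  and channel flicker.
- `gen_ou` / `gen_random_walk`: stationary and unit-root series for the
  OU-fit and ADF branches.
- `gen_inactivation_sweeps`: a common kinetic waveform (exponential
  activation times exponential decay) scaled per voltage by a Boltzmann
  availability, plus iid Gaussian trace noise per repeat (optionally
  heteroscedastic across voltages).

Not emulated: conductance-based spike generation, channel-level gating
kinetics, synaptic input structure, electrode drift and line noise,
bursting, multi-unit contamination. Passing recovery tests on these
generators shows the estimators are correct and calibrated, not that
real recordings satisfy their assumptions — in particular real spike
waveforms vary along more dimensions than peak dV/dt, and real LFPs are
only locally OU-like.

### The end-to-end contrast

The two study conditions used in the acceptance analysis are fixed
as: **control** — persistent onset-rapidness states (diagonal 0.90),
class means 60/100/140 V/s with 2% jitter, regular firing (gamma shape
8 at 8 Hz), 0.5 mV membrane noise with 10 ms correlation time;
**unstable** — memoryless state transitions (uniform 1/3), 10% jitter,
Poisson-like firing (shape 1), 0.8 mV noise with 2 ms correlation time.
Twenty 12 s traces per group at 5 kHz. The unstable condition's faster,
larger membrane noise reflects the elevated fast channel noise of the
disease phenotypes; as noted above, the Lyapunov stage is sensitive to
the decorrelation time, while Lv responds to the ISI process and the
Markov off-diagonal mass to the state dynamics. Effect sizes are
qualitative choices (no quantitative targets exist to calibrate
against), fixed once and not tuned.

## Problem sizes and tolerances

The test suite and acceptance script use: \(10^4\) ISIs for Lv
(tolerance ±0.03), \(10^4\)-step chains for Markov recovery (±0.03
per entry), 5000-point trajectories for the logistic/sine
discrimination, 60 s at 1 kHz and 20 seeds per cell for the OU grid
(τ within 10%, σ within 5%, medians), 100 replicates of n = 2000 for
the ADF rates (≥90% in each direction; the random-walk rate sits near
the nominal 93–95% because the 5% test level rejects a true null about
5% of the time), 20 repeats per voltage for noise recovery (±5%), and
20 traces per group for the end-to-end contrast. These sizes keep each
stage's sampling error comfortably below its tolerance.

## Known limitations

- The ADF p-value approximation is least accurate in the far tails
  (values clamped at 0/1 outside MacKinnon's fitted range).
- The Lyapunov estimator reports decorrelation, not chaos, on purely
  stochastic inputs; interpreting its sign requires the phase-space
  structure the embedding assumes.
- The quartile discretization forces 25/50/25 occupancy, which dilutes
  measured persistence when true states are not equally likely.
- NWB input is not supported in this build; convert to delimited text
  first.
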