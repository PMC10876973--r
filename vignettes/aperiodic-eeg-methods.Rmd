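---
title: "Models and methods for aperiodic EEG spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for aperiodic EEG spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aperspectra)
```

# Scope

`aperspectra` implements a biophysical account of the aperiodic (broadband)
component of EEG power spectra and the analysis chain that account
motivates for pharmacological EEG: simulation of single-neuron ("unitary")
EEG spectra from synaptic kinetics, subcritical branching networks and
dipole-coherence machinery, ensemble EEG power on cortical meshes, and a
propofol-induction pipeline (spectral detrending constrained by synaptic
kinetics, effect-site pharmacokinetics, Hill dose-response, detrended band
power around loss of consciousness). A synthetic-cohort generator with
known ground truth makes every stage testable without recordings.

This vignette documents the models, their assumptions, the tunable
parameters, and the numerical and design choices a maintainer would want
to know about. All quantitative statements here are computed by the test
suite or the acceptance script; none are asserted from memory.

# Spectral trend models

The aperiodic trend of a power spectrum is modelled by one of three closed
forms (`trend_params()`, `eval_trend()`):

* **Two Lorentzians** — `A1 / (1 + (2 pi tau1 f)^2) + A2 / (1 + (2 pi tau2
  f)^2)`. The slow timescale `tau1` is governed by GABA-receptor
  deactivation, the fast timescale `tau2` by AMPA-receptor deactivation;
  the amplitudes reflect the inhibitory and excitatory contributions to
  the signal. This is the exact spectrum of shot noise filtered by
  exponentially decaying synaptic currents.
* **Lorentzian plus constant** — `A1 tau1 / (1 + (2 pi tau1 f)^2) + lam`,
  for recordings whose high-frequency behaviour is a flat floor (fast
  excitatory timescales, muscle, amplifier noise) rather than a second
  Lorentzian.
* **Difference-of-exponentials plus constant** —
  `A1 (tau_r - tau1)^2 / ((1 + (2 pi tau_r f)^2)(1 + (2 pi tau1 f)^2)) +
  lam`, the exact power spectrum of a synaptic current with rise time
  `tau_r` and decay `tau1`. The rise time is fixed at 4 ms to keep the
  fit at three parameters. This is the form used on propofol data, with
  `tau1` bounded to 10–75 ms (the physiological range extended by
  propofol's prolongation of inhibitory decay).

The amplitude conventions differ deliberately across forms (`A1` vs
`A1 tau1` vs `A1 (tau_r - tau1)^2`); each amplitude is a free fit
parameter in its own convention, and the package never converts between
them implicitly.

## Trend-plus-peaks fitting

`fit_trend_and_peaks()` is a FOOOF-style iterative decomposition: a robust
trend fit in log10-power space (the dynamic range spans four decades, so a
linear-power loss would see only the lowest bins), Gaussian peak detection
on the dB residual, peak fitting largest-first, and trend refits on the
peak-subtracted spectrum until parameters stabilise (relative change below
1e-4, cap 50 iterations).

Design choices that were genuinely open:

* **Peak height space.** For raw spectra, peaks are parameterised as
  additive spectral density above the trend rather than as dB offsets.
  Rhythmic and broadband sources superpose linearly in power, so an
  independent broadband change then leaves fitted peak heights unchanged —
  which is exactly the separation the confound analysis requires. For
  detrended (already divided) spectra, peaks are fitted in dB.
* **Peak detection** uses the dB residual (homoscedastic across the
  dynamic range) with a threshold of 2 residual standard deviations, a
  minimum height of 5 percent above trend, a width cap of 4 Hz (SD), and
  at most 6 peaks. The width cap keeps broadband misfit from being
  absorbed into pseudo-peaks.
* **Loss.** Least squares on log10 power by default. For noisy window
  spectra the package also implements the Whittle periodogram likelihood
  (`loss = "whittle"`, via deviance residuals weighted by per-bin degrees
  of freedom): log least squares is biased on small-sample spectra because
  the likelihood of a bounded, weakly identified timescale is asymmetric,
  and the Whittle loss removes most of that bias. The pipeline's
  per-window fits use Whittle; one-off fits of well-averaged spectra use
  the log loss.
* **Spectral-window smearing.** Multitaper estimates average the true
  spectrum over the taper bandwidth (1 Hz for 2 s windows at NW = 2),
  which visibly flattens a steep Lorentzian knee. When the smearing
  half-width is known, the model is averaged over the same window before
  comparison (`smear_hw`), by 7-point Gauss-Legendre quadrature per bin.
* **Frequency weighting.** Linearly gridded spectra are averaged into
  log-spaced bins (`log_bin_spectrum()`, 30–40 bins per decade) before
  broadband fits, so each decade contributes comparable weight; the bin
  occupancies travel along as degrees-of-freedom weights.
* Frequencies at exactly 0 Hz are excluded (log undefined); the fitter
  requires at least 20 points in range; an all-zero or non-finite spectrum
  is rejected; failure to converge flags the result rather than erroring.

Divisive versus subtractive detrending (`detrend()`) mirrors the two
confound classes: changes in postsynaptic kinetics multiply the spectrum
and require division by the fitted trend; an added independent aperiodic
source adds to the spectrum and requires subtraction. `fit_slope()`
summarises a spectrum as `10^alpha / f^beta` over 1–40 Hz by log-log
regression.

# Point-dipole neuron

The morphologically detailed neuron of the original account is replaced by
a single-compartment conductance neuron whose synapses carry unit
direction vectors from the soma; each synaptic current contributes to the
dipole moment along its direction (`simulate_dipole()`):

`Cm dV/dt = -gL (V - EL) - sum_E gE sE(t) (V - 0) - sum_I gI sI(t) (V + 80)`

with difference-of-exponentials gates (AMPAR rise 0.3 ms, decay 1–3.5 ms;
GABAR rise 2 ms, decay 5–20 ms), integrated by exponential Euler at 0.1 ms.
The proxy is licensed by the observation that a synapse's evoked dipole
points at the synapse's location; consequently absolute EEG amplitudes are
calibrated (a configurable scalar lead-field gain), not predicted, and the
location average over the head model is replaced by sampling log-normal
scalar gains and uniform projection directions. The membrane area default
(20,000 um^2, a typical pyramidal total) sets the leak and capacitance
scale against the nS-scale synaptic conductances.

Sampling distributions for the eight varied parameters
(`sample_biophys()`): log-uniform for rates and conductances, uniform for
time constants and the leak reversal, over the stated physiological
ranges. The per-synapse input rates are not pinned by the source material;
the package uses log-uniform 0.1–10 Hz with a reference point of
`lamE = 1 Hz`, `lamI = 10 Hz` — sparse pyramidal firing against sustained
fast-spiking interneuron rates. The reference deliberately sits in the
inhibition-dominated regime: the slow-timescale identity (fitted `tau1`
tracking GABAR decay) presumes that inhibitory currents govern the
low-frequency trend, and at balanced drive the excitatory component
contaminates the fit of the slow knee.

Synaptic input (`generate_input()`) is an inhomogeneous Poisson process
per synapse with rate `max(lam (1 + alpha Y(t)), 0)`; the apical
hemisphere (z > 0) receives `Y`, the basal hemisphere the counterphase
copy. For sinusoids the counterphase is the `k = 0` versus `k = pi` phase
pair; for stochastic modulations the package default negates `Y` (keeping
both hemispheres zero-mean) rather than using `1 - Y`, which would shift
the basal mean rate; `counterphase = "one_minus"` restores the literal
variant. Supported modulations: constant, sinusoid, white noise, a damped
second-order system, and an external series such as a branching-network
population rate.

`unitary_spectrum()` averages Welch spectra (2 s Hann segments, 50 percent
overlap) of `gain * (u . Q)` over trials. `tau1_tauI_slope()` packages the
identity experiment: fitted `tau1` against GABAR decay over 5–20 ms; the
slope is 1 under the synaptic-timescale account, and the acceptance suite
asserts it to within 10 percent.

Sensitivity analysis (`slope_sensitivity()`, `sobol_indices()`): Saltelli
sampling with Jansen estimators for first-order and total indices, plus
closed second-order indices for requested pairs (by default the
leak-conductance by input-rate interactions). The estimator is validated
against closed-form indices of analytic test functions; the full
20,000-spectrum analysis is a long-running computation the user invokes
deliberately, while the test suite checks the estimator and the
qualitative stratified-correlation signature (the spectral exponent
correlates negatively with the excitation:inhibition rate ratio when the
leak is small, positively when it is large).

# Branching network

`build_network()` places N binary neurons uniformly in a unit square with
torus distance and samples exactly `d_out = 10` targets per neuron with
probability proportional to `exp(-d / kernel_scale)` (default scale 0.05).
`simulate_branching()` runs the two rules: baseline Poisson drive at
`lam0 (1 - m)` per neuron, and per spike an independent
Bernoulli(`m / d_out`) chance for each target to fire within the following
4 ms (uniform placement). The stationary per-neuron rate is `lam0` for
every `m < 1`; the default `lam0 = 5 Hz` is a typical cortical unit rate
and gives the rate estimate a workable signal-to-noise at 40 s. The
simulation bin (1/32 ms) is purely numerical: coincident arrivals merge
(binary neurons), and near criticality that merging loss is amplified by
`1/(1 - m)`, so the bin must be much finer than the propagation window;
the event-driven kernel makes the fine grid free. Simulations at m = 0.98
still fluctuate strongly across 40 s realisations (avalanche statistics),
so rate checks average several seeds.

Inhibitory units (15 percent of the full network) are attached after the
fact (`attach_inhibitory()`): each is a thinned copy of its 20 nearest
excitatory units' pooled spikes (fraction `m` of its rate, mirroring the
recurrent share of excitatory drive) plus an independent Poisson
remainder, at rate `lamI`. Spike-train correlation uses the spike-time
tiling coefficient (`sttc()`, default window 10 ms), validated against a
brute-force implementation of the published formula.

# Dipole coherence machinery

`embed_on_sphere()` maps a presynaptic population onto the unit sphere so
that correlated units sit at small angles. The contract is checked rather
than an algorithm guaranteed: the Spearman correlation between source
correlation and embedded angle must be negative (below -0.3 on typical
inputs). The implementation is classical multidimensional scaling of
`1 - corr` into three dimensions with radial projection — adequate for the
contract and dependency-free. `perturb_embedding()` displaces each point
along a random bearing by `arccos(1 - 2 alpha (1 - X))`,
`alpha ~ U(0, 1)`: the optimality index `X = 1` is the identity and
`X = 0` re-scatters points uniformly. (The source text carries a `pi`
prefactor inside this displacement whose range would exceed the sphere;
the prefactor-free form is the one consistent with the stated `X = 0`
uniformity, and is what the package implements.)

`assign_synapses()` runs the quoted greedy loop — draw a synapse with
probability proportional to its surface-area weight, connect it to the
nearest embedded unit, repeat until all are mapped — with ties broken to
the lowest index. `minimal_correlated_trains()` realises the minimal
coherence model: binary trains per 1 ms bin whose pairwise correlations
follow `R_max exp(-theta_ij)`, generated by thresholding a latent Gaussian
whose pairwise correlations are obtained by inverting the dichotomised
Gaussian relation (Drezner-Wesolowsky quadrature plus root finding) and
repairing the matrix to the nearest positive semidefinite one by
eigenvalue clipping. The trains are white in time by construction.

`dyad_dipole_correlation()` correlates matched projections of two
neurons' dipoles. The projection axis defaults to the z-axis (the
layout's apical axis) for both neurons rather than each neuron's mean
synapse direction: for approximately uniform layouts the mean direction is
numerically degenerate (norm near zero), whereas a fixed shared axis is
stable and equally valid for a correlation. The shuffle control permutes
synapse directions, destroying geometric alignment while preserving
temporal correlations; controls are averaged over several shuffles because
a single 40 s correlation has a standard error near the 0.02 null band.

`network_dyad_correlation()` composes the whole chain
(network, STTC, embedding, optional perturbation, assignment, dipoles).
The two neurons draw from disjoint halves of the embedded population:
with shared units, a correlation floor of order
`n_synapses / n_units` appears even for an asynchronous network, from the
same axon feeding both neurons at aligned positions. Splitting the
population isolates the quantity of interest — coherence mediated by
network correlations between distinct units — and makes `m = 0` exactly
uncoupled.

# Ensemble EEG power

`ensemble_spectrum()` evaluates the coherence superposition
`S_N = sum_i S_i + 2 sum_{i<j} gamma_ij sqrt(S_i S_j)` pointwise.
`signed_neuron_count()` computes `nu(r) = sum_j mu A_j f_j(r, x) (N_j .
N_i)` on a triangular mesh, with the face-ball fraction `f_j` by adaptive
triangle subdivision (exact resolution of fully inside/outside triangles,
refinement of boundary triangles until the unresolved area is below 1e-3
of the running estimate, depth cap). `mean_pairwise_correlation()`
estimates `rho_bar = (1/(N-1)) integral rho_max exp(-r^2/sigma^2)
d nu_bar(r)` by area-weighted Monte-Carlo over surface points, with
`nu_bar` accumulated on a shared micro-triangulation (edge length sigma/10
by default) and the Stieltjes integral taken by trapezoid out to 5 sigma.
Distances are Euclidean 3D; the cosine factor uses face normals (apical
axes normal to the surface); sampling is area-weighted. On an open mesh a
`point_filter` restricts sample points to the interior when comparing
against infinite-plane closed forms. `ensemble_power()` is
`N sigma0^2 (1 + (N - 1) rho_bar)`.

Shipped meshes are generated in code: a flat square and an icosphere; an
anatomical surface can be supplied as ASCII OFF/PLY but is never required.

# Propofol analysis pipeline

`multitaper_spectrogram()` uses three DPSS tapers (NW = 2) on 2 s windows
with 1.9 s overlap; tapers come from the classic tridiagonal eigenproblem
and are cached per configuration (no R multitaper package is assumed).
`fill_line_noise()` replaces the mains band (60 +/- 2 Hz) by log-linear
interpolation of the flanking bins. `rescale_time()` maps infusion onset
to -1 and loss of consciousness (LOC) to 0.

`track_tau1()` fits the difference-of-exponentials trend per spectrogram
window, yielding the inhibitory-timescale trajectory `tau1(t)` and its
fold change over the pre-infusion baseline. The estimator matters here,
because a 2 s window at `tau1` above 40 ms (knee near 3.5 Hz, at the edge
of the fit range) is weakly identifying, and several refinements are
needed for unbiased tracking; each is a documented option:

* fit range 3–100 Hz: below ~3 Hz the spectrum is coloured by slow
  neural dynamics rather than synaptic kinetics and is excluded; the long
  upper tail (through the filled mains band) pins the noise floor;
* the floor `lam` is estimated once from the averaged pre-infusion
  spectrum and pinned per window (`fix_lam`) — it is a property of the
  recording, and freeing it per window leaves the three trend parameters
  degenerate;
* spectra are averaged over a 10 s moving window (`t_smooth`) before
  fitting — the timescale drifts over minutes, so this suppresses
  single-window noise without distorting the trajectory;
* the alpha/beta band (8–30 Hz) is excluded from the trend fit
  (`exclude_bands`) — the trend is constrained by its flanks, and broad
  rhythm shoulders otherwise leak past Gaussian peak removal;
* Whittle loss and taper-bandwidth smearing as described above;
* no warm starts between windows (chained initial values lag fast
  changes).

With these defaults the synthetic-cohort tests recover the baseline
timescale to a few percent and the dose-response within the stated
tolerances; with plain per-window log-loss free fits the recovered
timescale is biased low by 10–15 percent at large `tau1`.

`detrend_spectrogram()` divides each window by its fitted trend;
`band_power()` integrates delta (0.5–3 Hz), alpha (8–15 Hz) and beta
(15–30 Hz) band power with optional baseline normalisation;
`group_sign_test()` applies exact right-tailed sign tests across subjects
on per-segment medians (segments of 0.05 rescaled-time units; ties
dropped; no multiple-testing correction by default, Benjamini-Hochberg
optional). `marsh_effect_site()` integrates the three-compartment Marsh
plasma model (rate constants are configuration data from the published
adult model: k10 0.119, k12 0.112, k13 0.0419, k21 0.055, k31 0.0033
min^-1, V1 0.228 L/kg) with first-order effect-site equilibration
(keo 1.21 min^-1), reporting concentrations in uM (molar mass 178.27
g/mol). `fit_hill()` fits `baseline + span C^n / (EC50^n + C^n)` by
multi-start least squares. `analyze_subject()` chains everything.

# Synthetic cohort

`synth_cohort()` emulates the statistical structure the analysis assumes,
with jittered per-subject truths (10 percent log-normal on amplitudes and
baseline timescale; infusion-to-LOC latency uniform over 95–285 s;
constant-rate infusion of 1 mg/kg/min at 70 kg from t = 30 s to LOC).
Components per subject:

* an aperiodic synaptic component: white noise shaped in the frequency
  domain to the exact difference-of-exponentials spectrum with the
  instantaneous `tau1(t)`, synthesised by windowed overlap-add of 8 s
  blocks (sine window, squares summing to one) — no time-discretisation
  bias, unlike recursive-filter synthesis;
* `tau1(t)` driven by the Marsh effect-site concentration through a Hill
  dose-response (EC50 3.7 uM, coefficient 1.6, baseline 16.7 ms). The
  maximal fold-change increment (`hill_span` 1.7) is chosen so the
  trajectory saturates near the pre-LOC timescale estimates that motivate
  the generator (about 43 ms), keeping `tau1` inside its 10–75 ms fit
  bounds;
* a low-frequency excess from a small subcritical branching network's
  population rate (m = 0.98), standing in for slow aperiodic dynamics the
  trend fit must not absorb;
* alpha (10 Hz) and beta (20 Hz) narrowband rhythms ramping in 20 s after
  infusion onset and plateauing 30 s before LOC (an optional `rise_fall`
  template lets beta decline again before LOC); oscillations are
  narrowband filtered noise (1 Hz bandwidth, 4th-order Butterworth
  envelope) rather than sinusoids, so they produce realistic
  Gaussian-fittable peaks with compact spectral support;
* a delta rhythm (1.5 Hz) stepping on at LOC with a 0.5 s raised-cosine
  edge. Its default amplitude (35 uV RMS, roughly 100 uV peak-to-peak
  slow waves) makes it dominate the delta band at LOC, as anesthetic slow
  waves do — the generator encodes a detectable step because the sharp
  detrended-delta rise at LOC is the phenomenon the pipeline is built to
  expose;
* a white measurement-noise floor.

Component amplitudes (20, 10, 5, 35, 6, 3 uV RMS) are scene-setting
choices at realistic scalp-EEG magnitudes. What passing tests show is
that the pipeline recovers this structure — stationary-within-window
signals, multiplicative kinetic drift, additive rhythms; what they cannot
show is robustness to artifacts, montage effects, or non-stationarities
the generator does not emulate (eye blinks, electrode drift, state
switches).

# Problem sizes

The test suite and acceptance script run at desk scale, chosen once:
the timescale-identity experiment uses the median of 5 replicate fits per
probed GABAR constant, each replicate averaging 20 trials of 10 s at
0.1 ms steps; rate conservation runs at N = 2000 and T = 40 s averaged
over up to 12 seeds near criticality; dyads of 58 synapses draw from
networks of 800 units over 40 s; end-to-end recovery pools five
14-subject synthetic cohorts with trend fits every 2 s. The
sensitivity analysis at its published scale (20,000 spectra) is available
but deliberately not exercised by the tests; the estimator is validated on
closed-form functions instead.

# Known limitations

* The point-dipole proxy reproduces shapes and identities, not absolute
  uV^2 amplitudes; quantities tied to full morphologies and a real head
  model (single-neuron EEG power distributions, absolute coherence
  requirement bands, the exact dyad correlation at criticality) are
  covered by monotonicity and closed-form properties instead.
* In the stratified E:I analysis, the proxy shows the driving-force
  nonlinearity as a reliable weakening of the slope's anticorrelation
  with the excitation:inhibition rate ratio in the low-leak stratum, but
  not as a sign flip: with every synapse sharing one membrane potential,
  voltage excursions are smaller than in thin dendrites, and the
  composition effect (more excitation flattens the spectrum) keeps the
  upper hand in both strata. The direction of the interaction is
  reproduced; its magnitude is morphology-dependent.
* Coherently modulated (rhythmic) input is carried jointly by excitatory
  and inhibitory currents whose contributions partially cancel in the
  point dipole, so rhythm power does not scale exactly multiplicatively
  in a synaptic conductance; trend-invariance checks under conductance
  changes therefore use Poissonian (incoherent) input.
* EDF input and HDF5 persistence are not provided (no suitable readers in
  the dependency envelope); EEG and spectrograms travel as documented TSV
  with JSON side-cars.
* The embedding backend satisfies a rank-correlation contract; it is not
  a re-implementation of any particular manifold-learning algorithm.
* Sign tests are per-segment and uncorrected by default, matching the
  analysis they reproduce; this inflates family-wise error across
  segments if interpreted jointly.
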