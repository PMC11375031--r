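---
title: "Models and methods behind smmds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smmds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

smmds analyses single-molecule microfluidic diffusional sizing (smMDS)
experiments: a fluorescent analyte stream is flow-focused between buffer
streams in a laminar microchannel, molecules spread diffusively as they
travel downstream, and a scanning confocal detector records either binned
fluorescence intensity (continuous scans) or photon time traces from which
individual molecule transits are counted digitally (step scans). Because
the diffusive spreading at known residence times determines the diffusion
coefficient directly, the hydrodynamic radius follows from the
Stokes–Einstein relation without any calibration standard. This vignette
describes the models implemented in the package, the parameters that
matter, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## Transport model and basis libraries

The steady-state concentration field of a species with diffusion
coefficient $D$ in the observation channel obeys

$$ u(y,z)\,\frac{\partial c}{\partial x}
   = D\left(\frac{\partial^2 c}{\partial y^2}
          + \frac{\partial^2 c}{\partial z^2}\right), $$

with $x$ downstream, $y$ across the 225 µm width, $z$ across the 25 µm
height, and no-flux walls. `simulate_basis()` discretises the $(y,z)$
cross-section (default 151 × 31 nodes) and marches downstream with an
unconditionally stable implicit (backward-Euler) step. The velocity field
is the rectangular-duct Poiseuille series truncated at 11 odd terms, with
the cosh ratios evaluated in log space to avoid overflow; a cheaper
depth-averaged mode replaces $u(y,z)$ by the mean velocity and solves the
one-dimensional problem in $y$. The inlet condition is a centred top-hat
occupying the sample flow fraction of the width (default 1/9, the ~1:8
sample:buffer flow ratio of the sizing chip). Axial diffusion is neglected
(Péclet numbers are of order $10^3$–$10^6$ here), as is the transient
filling of the channel.

Marching in $x$ uses segments between scanned crossings. The first segment
(leaving the sharp inlet) is subdivided into five geometrically growing
blocks of constant step so that one sparse Cholesky factorisation serves a
whole block; later segments use uniform steps. The number of steps per
segment adapts to the segment Fourier number $D\,\Delta t/\Delta y^2$
between 40 and 400. The implicit scheme conserves the advective mass flux
$\int u\,c\,\mathrm{d}y\,\mathrm{d}z$ to round-off; the library records
its worst-case relative mass error (the test suite requires $< 10^{-6}$,
observed $\sim 10^{-13}$).

Scanned crossings are specified as residence times (default 0, 10, 26 and
55 s, a four-crossing trajectory at 60 µL/h) rather than as absolute
downstream distances: in a folded ~90 mm channel the distances of the
scanned segments are chip-specific, and the printed channel length is not
a reliable bound on the travel implied by long residence times, so the
package treats times as authoritative and never infers distances silently.
Explicitly supplied `crossing_distances` are validated against the channel
length.

The readout is the mid-height slice of the solution (the confocal plane,
~12.5 µm above the coverslip), optionally blurred by a Gaussian of 0.3 µm
waist — below half a transverse grid cell at the default resolution, where
the blur is skipped. A `readout = "depth_averaged"` option averages the
same 3-D solution over $z$; it exists mainly for the Taylor-direction
sanity check: the mid-plane fluid is faster than average, so its profile
must be no wider than the depth average of the same solution. Note that
the reduced depth-averaged *model* (plug flow at the mean velocity) is not
an upper bound: once a small species equilibrates across the depth, slow
near-wall fluid adds transverse spread that plug flow lacks.

A basis library holds profiles for 60 log-spaced radii between 0.3 and
300 nm by default (the instrument's working range is roughly 1–100 nm with
margin on both sides). `interpolate_profile()` interpolates linearly in
$\log R_H$; with grids of ~25 nodes per decade the interpolation error
against a fresh simulation is below 2 % in relative $L_2$ (tested).

## Burst search

Step-scan traces are photon arrival-time sequences (16 ps ticks in the
hardware; seconds internally). `find_bursts()` implements the combined
criterion: the inter-photon-time (IPT) sequence is smoothed with a Lee
filter, and a burst is a maximal run of at least `n_min` photons whose
filtered IPTs all stay at or below `ipt_max`. The Lee filter
$\hat s_i = \bar m_i + (s_i - \bar m_i)\,\sigma_i^2/(\sigma_i^2 +
\sigma_0^2)$ flattens constant-signal stretches while leaving sharp
burst edges intact; the global noise scale $\sigma_0$ is the median
windowed standard deviation of the trace's IPT series (recorded in the
burst table's attributes via the producing parameters). Whether the
original instrument software thresholds filtered IPTs or filtered binned
intensity is not public; this package thresholds filtered IPTs, and
`split_trace_by_threshold()` provides the binned-intensity route used for
rare bright species.

Defaults are `ipt_max` = 0.01 ms, `n_min` = 10 photons, `lee_window` = 3 —
midpoints of the ranges customary for confocal single-molecule detection
(0.005–0.02 ms, 5–20 photons, windows of 2–4). One practical rule matters
more than any default: `ipt_max` must comfortably exceed the *in-burst*
mean inter-photon time $1/b$ for brightness $b$, or genuine transits
fragment into several counted bursts. The fragmentation probability per
IPT is $e^{-b\,\mathrm{ipt}_{max}}$, so `ipt_max` $\gtrsim 5/b$ keeps it
negligible; for the 250 photons/ms species of the synthetic studies the
analyses therefore use `ipt_max` = 0.02 ms with a window of 4. Because
$\sigma_0$ is estimated per trace, heavy fragmentation is also
*position-dependent* (busy centre traces smooth less), which distorts
profile shapes — another reason to keep the threshold matched to the
brightness. Burst duration is last-minus-first photon time; single-tick
runs are rejected. Raising `n_min` can only remove bursts, so counts are
monotone in it (asserted as a property); lowering `ipt_max` is monotone
for coherent bursts but can split ragged ones, so the property test uses
constructed, evenly spaced bursts.

## Profile building and the global fit

Step profiles are burst counts per position (normalised by dwell time only
when dwell times differ, to preserve integer Poisson counts); continuous
profiles are photons per 1-ms bin mapped to coordinates through the scan
speed. `rebin_profile()` sums counts (step) or averages intensities
(continuous), conserving total molecule counts exactly.

`global_fit()` minimises

$$ \sum_i w_i\,\bigl(p_i - a\,s_i(R_H) - b\bigr)^2 $$

jointly over all crossings, with a common nonnegative amplitude $a$ and
baseline $b$ profiled out in closed form at each candidate radius. The
radius is found by grid search over the basis followed by a continuous
1-D minimisation (Brent) in $\log R_H$ between the best node's
neighbours, on the log-interpolated basis — the error surface is
piecewise smooth with kinks at grid nodes, so a three-point parabola is
not accurate enough. Ties on the grid break towards the smaller radius,
deterministically. Each scanned crossing is assumed centred on the channel
unless `crossing_offsets` are given (real profiles can sit a few µm off
centre; the global fit tolerates this, and explicit offsets cover the
rest).

Weights are uniform for continuous profiles (after 1-ms binning at high
rates the relative shot noise is nearly flat) and Poisson,
$w_i = 1/\max(p_i, 1)$, for step profiles. Weighting by *observed* counts
biases least squares in low-count bins (the Neyman-χ² effect: empty wing
bins are over-weighted against any model mass placed there, favouring
too-narrow, too-large-radius solutions), so for step profiles the weights
are re-derived from the fitted model, $w_i = 1/\max(\hat p_i, 1)$, for two
Pearson-style iterations. The fit is exactly invariant under uniform
reweighting.

The ± range on $R_H$ comes from the second-order expansion of the error
surface at the minimum, $\mathrm{var}(R_H) = 2\hat\sigma^2 /
(\partial^2 \mathrm{SSE}/\partial R_H^2)$ with
$\hat\sigma^2 = \mathrm{SSE}/(n-3)$ and the curvature measured by central
differences at ±2 % of the fitted radius; a non-positive curvature (flat
minimum) raises an error rather than reporting a number. A coverage
simulation in the test suite checks that the reported range covers the
truth at roughly the 1-σ (~68 %) rate. Per-crossing local radius errors
refit each crossing alone and report the difference from the global
radius; the zero-time crossing carries no size information, so its local
error is essentially unconstrained and is reported as-is.

## Oligomer deconvolution

Burst brightness (photons per ms of burst duration) scales with the number
of labelled monomer units in an assembly, provided the degree of labelling
is at most one dye per monomer. The brightness distribution is modelled as
a skew-normal monomer component — the right skew reflects undersampling of
short transits — plus Gaussian n-mer components whose means are *tied* to
integer multiples of the skew-normal mean and whose standard deviations
equal the skew-normal standard deviation. The model therefore has three
shape parameters plus the component weights, regardless of the number of
species; the "monomer intensity" reported is the distribution mean, not
the mode. Fitting is by maximum likelihood on the unbinned intensities
(histograms are for display only), using BFGS with an analytic gradient
(compiled) and the weights parameterised by softmax. The likelihood has a
spurious mode in which a wide, strongly skewed monomer component swallows
the dimer; cold fits therefore run from three starting shapes and keep the
best likelihood. Non-convergence raises an error with the optimiser code.

The number of species is chosen by BIC over a candidate range
(`select_species_count()`); the full criterion table is returned so AIC or
likelihood-ratio reasoning can be applied instead — which criterion the
original analysis used is not public, and BIC's consistency property suits
a small fixed candidate set.

Abundance uncertainty uses a percentile bootstrap over burst resampling
(default 1000 replicates, 99 % level, seeded). Each replicate refits the
*full* mixture, warm-started at the full-data estimate: at realistic
sample sizes the uncertainty of the monomer brightness calibration
contributes substantially to abundance uncertainty, and refitting only the
weights (available as `refit = "weights"`, an EM on fixed component
densities precomputed once) visibly undercovers for strongly overlapping
components. Species-resolved sizing gates bursts into ±1 σ regions around
each centre (`regions_from_mixture()`, `gate_bursts()`) and feeds each
subset through the step-profile fit; `threshold_sweep()` provides the
complementary analysis of refitting at increasing `n_min`, which rises
with threshold only when brightness correlates with size.

## Mixtures and nanoscale clusters

For mixtures of an abundant small species and rare large assemblies,
`split_trace_by_threshold()` Savitzky–Golay-smooths the 1-ms binned trace
(default window 11 bins, order 3 — the original smoothing parameters are
not public, so they are recorded in the output) and attributes maximal
runs above a count-rate threshold (e.g. 250 kHz for fibrils over a
nanomolar monomer background), padded by one window on each side, to the
large species. Spike counts per position form a step profile for the large
species; the mean of the remaining bulk signal forms a continuous profile
for the small one.

Nanocluster detection uses a mean + 5 σ rule per trace, with mean and σ
estimated robustly (median and 1.4826 × MAD) so the rare events themselves
do not inflate the threshold. Event histograms per crossing are fitted
with independent Gaussians; the diffusion distance at each crossing is
half the fitted FWHM. Net distances are formed by subtracting the
zero-time width in quadrature (a Gaussian-convolution model of the finite
inlet width; linear subtraction is available and recorded), and
$x_{net} = \sqrt{2 D t}$ is fitted by least squares in $x$ over $\log D$
(Brent on $[10^{-18}, 10^{-6}]\,\mathrm{m^2/s}$). When repeat measurements
exist, their distances should be averaged before the single Fick fit — the
net-distance transform is strongly nonlinear in the per-repeat noise, and
fitting averaged distances is both the stabler and the conventional
treatment of repeats.

Counted events convert to a channel flux as
$F = (N/T)/\varepsilon_{det}$. The geometric detection efficiency
$\varepsilon_{det}$ (which fraction of the flowing particles the scanned
confocal volume samples) is chip- and scan-specific and **must** be
supplied explicitly; the package never defaults it. Flux converts to a
particle concentration $c = F/(Q N_A)$ and to a volume fraction
$\phi = c\,N_A\,\tfrac{4}{3}\pi r^3$; monomer occupancy bounds follow from
the cubed radius ratio scaled by a packing fraction (default 10–35 %, the
typical protein volume fraction of biomolecular condensates, with the
packing-1 ceiling reported alongside).

## Binding isotherms

For a labelled antigen titrated with an antibody carrying `stoichiometry`
independent, identical sites (default 2), the free-site concentration
solves the quadratic mass balance
$s^2 + s\,(K_d + A_t - S_t) - K_d S_t = 0$ (evaluated with the
numerically stable root so no cancellation occurs at $S_t \gg K_d$), the
bound fraction of antigen is $f = s/(K_d + s)$, and the measured effective
radius is modelled as the mole-fraction-weighted mean
$(1-f)\,r_{free} + f\,r_{bound}$. This linear weighting is the simplest
reduction consistent with a single-radius fit of a superposed profile and
is isolated in one function so that a diffusion-weighted alternative can
be swapped in; antigen bound to a singly-occupied antibody is assigned
$r_{bound}$, since hydrodynamically the antibody dominates regardless of
the second site. `fit_isotherm()` does weighted least squares over
($\log K_d$, $r_{free}$, $r_{bound}$) via Levenberg–Marquardt, with the
$K_d$ uncertainty from the fit curvature on the log scale. Working at
antigen concentrations comparable to $K_d$ makes ligand depletion
non-negligible: a free-ligand (Langmuir/Hill) approximation shifts the
apparent midpoint, and a regression test asserts that the exact mass
balance recovers the generating $K_d$ where the approximation does not.
A titration whose radius span is smaller than four times the measurement
noise is rejected as unidentifiable rather than fitted.

## The synthetic-data generator

`generate_step_scan()` emulates the digital experiment: at each scan
position, transits of each species arrive as a Poisson process with rate
$\rho\,v\,A_{det}\,c_{norm}(y)$ — number density × mean flow speed ×
effective detection cross-section (default 0.5 µm²) × the simulated local
concentration — each transit lasting $L_{det}/v$ (detection length
default 1 µm) and emitting Poisson photons at brightness × labelled
units, over Poisson background (default 2 kHz). Oligomer species carry a
distribution over labelled-unit counts. Every scan ships a manifest with
the exact per-position rates and realised transit counts, so burst
detection, profile building and fitting can each be checked against
analytic expectations. `generate_continuous_scan()` produces binned
intensities whose expectation is occupancy × brightness × shape;
`generate_oligomer_bursts()` draws brightness values directly from the
mixture model; `generate_spike_scan()` overlays rare fixed-amplitude
spikes on a bulk trace; and `generate_cluster_events()` draws per-crossing
event histograms whose half-FWHM follows
$\sqrt{x_0^2 + 2 D t}$ — the same FWHM-based diffusion-distance
convention the cluster pipeline estimates, so the generator and estimator
agree on what "diffusion distance" means.

What the generator deliberately does not emulate: diffusion *during* a
transit (transits are advection-dominated at these flow rates; at
Péclet ≫ 1 the straight-through approximation is good), detector dead
time and afterpulsing, dye photophysics (blinking, bleaching), the
confocal point-spread function beyond an effective cross-section, and
triplet-state brightness fluctuations. Passing the closure tests therefore
shows that the analysis inverts the stated physical model correctly — not
that it is robust to every instrumental artefact of real hardware. The
single-seed design (`acquisition_spec()` requires a seed; all randomness
flows through R's generator) makes every synthetic result bit-for-bit
reproducible.

All generator defaults describe one fixed study condition: a 25 × 225 µm
channel, 1/9 sample flow fraction, crossings at 0/10/26/55 s, species
brightness 250 photons/ms per labelled unit, 2 kHz background,
50–100 positions per crossing and dwell times of 1–5 s chosen to land in
the 10 pM–1 nM single-molecule regime with a few thousand counted
molecules per scan, matching ordinary step-scan practice.

## Problem sizes used by the test suite

The suite validates parameter recovery at deliberately desk-sized
statistics: sizing at truths of 1–100 nm uses ~5,000 counted molecules
per scan over 400 positions with three seeds per truth (median error
within 10 %); deconvolution recovery uses 10⁴ bursts (±0.03 on
abundances) and the bootstrap-coverage simulation uses 100 replicates of
10⁴ bursts with 100 bootstrap refits each; cluster sizing uses 500 events
per crossing over 20 seeds with distances averaged before the Fick fit
(within 15 % of 120 nm); the isotherm uses 12 titration points (noiseless
recovery < 1 %, 0.05 nm noise bias < 10 %). Reference bases for these
tests use the depth-averaged solver at 121 transverse nodes with 40
radius nodes over 0.5–300 nm; the full 3-D solver is exercised on a
five-radius grid at 61 × 11 nodes.

## Known limitations

The solver's implicit Euler marching is first-order accurate in $x$;
grid-converged absolute accuracy is traded for robustness, which suffices
because measured profiles are fitted against bases produced by the same
discretisation. Radii at the basis-grid boundary are flagged, not
extrapolated. The burst search assumes a single detection channel and no
microtime information. The brightness mixture ties all oligomer widths to
the monomer width, which underfits samples whose oligomer brightness
broadens with size. The flux conversion treats the detection efficiency as
known; in practice it must come from a calibration measurement. The
isotherm model covers independent identical sites only — no
cooperativity, no kinetics.
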