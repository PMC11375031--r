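# smmds

Analysis toolkit for **single-molecule microfluidic diffusional sizing
(smMDS)**: calibration-free measurement of protein hydrodynamic radii —
from sub-nanometre dyes to hundred-nanometre assemblies — by watching
molecules diffuse across a laminar-flow microchannel while counting them
one at a time with a scanning confocal detector.

A fluorescent sample stream is flow-focused between buffer streams
(~1:8 volume ratio) in a 25 µm × 225 µm observation channel. As the
stream travels downstream, species spread sideways by diffusion; scanning
the confocal spot across the channel at several downstream crossings
yields *diffusion profiles* — signal versus transverse position — whose
broadening at known residence times encodes the diffusion coefficient
*D*. Fitting measured profiles against numerically simulated solutions of
the advection–diffusion transport problem gives *D* directly, and the
hydrodynamic radius follows from the Stokes–Einstein relation

$$ R_H = \frac{k_B T}{6 \pi \eta D}, $$

with no calibration standard. At picomolar concentrations the package
builds profiles digitally, by counting single-molecule photon bursts per
scan position; at nanomolar concentrations it uses binned intensity from
continuous scans.

The package covers the full analysis chain, plus a physics-based
synthetic-data generator so every stage can be validated against ground
truth without instrument data:

- **Transport / basis libraries** — `simulate_basis()` solves
  $u(y,z)\,c_x = D (c_{yy} + c_{zz})$ on the channel cross-section
  (rectangular-duct Poiseuille flow, implicit marching, mass-conserving)
  for a grid of radii; `interpolate_profile()` makes the library
  continuous in $R_H$.
- **Burst search** — `find_bursts()` extracts single-molecule events from
  photon timestamp traces with the combined inter-photon-time /
  minimum-photon criterion after Lee filtering; `count_molecules()`
  turns a step scan into digital molecule counts.
- **Profile fitting** — `global_fit()` returns an `smmds_fit` object
  (print/summary/coef/predict/residuals/plot methods) with the radius, a
  curvature-based ± range, and per-crossing local radius errors.
- **Oligomer deconvolution** — `fit_brightness_mixture()` fits burst
  brightness histograms with a skew-normal monomer plus Gaussian n-mers
  constrained to integer multiples of the monomer mean;
  `select_species_count()` (BIC), `gate_bursts()` for species-resolved
  sizing, `abundance_ci()` (bootstrap), `threshold_sweep()`.
- **Mixtures & nanoclusters** — `split_trace_by_threshold()` separates
  rare bright species (fibrils) from bulk signal;
  `detect_cluster_events()`, `fit_position_peaks()`, `fick_fit()` size
  nanoscale condensate clusters via FWHM-based diffusion distances and
  $x \approx \sqrt{2Dt}$; `cluster_flux()`, `cluster_concentration()`,
  `volume_fraction()` convert digital counts to concentrations.
- **Binding isotherms** — `effective_rh()` / `fit_isotherm()` extract
  dissociation constants from size-vs-titrant curves with exact
  mass-balance treatment of a bivalent antibody.
- **Synthetic data** — `generate_step_scan()`,
  `generate_continuous_scan()`, `generate_oligomer_bursts()`,
  `generate_spike_scan()`, `generate_cluster_events()`, all seeded and
  shipped with ground-truth manifests.

A thin command-line wrapper (`smmds_cli()`, installed under
`inst/cli/smmds`) exposes each pipeline stage as a subcommand
(`simulate-basis`, `generate`, `bursts`, `profile`, `fit`, `deconvolve`,
`split`, `clusters`, `isotherm`) with unit-checked configuration files.

## Worked example

Simulate a step scan of a 3.73-nm protein (serum-albumin-sized) at 50 pM,
count molecules, and size it:

```r
library(smmds)

basis <- simulate_basis(chip_geometry(), flow_settings(60),
                        solvent_conditions(),
                        rh_grid = exp(seq(log(0.5), log(300), length.out = 40)),
                        solver = solver_options(ny = 121, mode = "depth_averaged"))

scan <- generate_step_scan(species_spec(r_h = 3.73, concentration = 50e-12),
                           basis,
                           acquisition_spec("step", n_per_crossing = 100,
                                            dwell = 2.5, seed = 1))
prof <- profile_from_step(scan$traces, burst_search_params(0.02, 10, 4),
                          crossing_boundaries = scan$layout$boundaries)
prof
#> Diffusion profile (step mode): 400 points, 4 crossing(s), total signal 5029

fit <- global_fit(prof, basis)
fit
#> smMDS global fit: R_H = 3.702 +/- 0.114 nm (D = 6.627e-11 m^2/s)
#>   amplitude 115.3, baseline -0.1284, SSE 323.1, 400 points, step mode
```

About 5,000 molecules were counted across 400 scan positions; the global
fit against the simulated basis recovers the generating radius within 1 %
(3.70 vs 3.73 nm), and the ± range is the curvature-based uncertainty of
the least-squares surface. Burst-brightness arithmetic and digital
concentration measurements are one-liners:

```r
oligomer_centers(75.33, n_max = 4)    # n-mer brightness centers, photons/ms
#>   2mer   3mer   4mer
#> 150.66 225.99 301.32

cluster_concentration(72606, flow_settings(60))  # clusters/s at 60 uL/h -> pM
#> [1] 7.233906
```

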