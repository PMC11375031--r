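# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# Reference basis for fitting tests: depth-averaged transport, 40 log-spaced
# radius nodes over 0.5-300 nm, four crossings at the nanocluster step-scan
# flow (60 uL/h).
test_basis <- function() {
  .memo("basis60", function() {
    simulate_basis(chip_geometry(), flow_settings(60), solvent_conditions(),
                   rh_grid = exp(seq(log(0.5), log(300), length.out = 40)),
                   solver = solver_options(ny = 121, mode = "depth_averaged"))
  })
}

# Small full-transport basis (duct velocity field, mid-height readout) on the
# physics-invariant radius set.
test_basis_full <- function() {
  .memo("basis_full", function() {
    simulate_basis(chip_geometry(), flow_settings(60), solvent_conditions(),
                   rh_grid = c(1, 3, 10, 30, 100),
                   solver = solver_options(ny = 61, nz = 11, mode = "full"))
  })
}

# Depth-averaged companion of test_basis_full on the same grid.
test_basis_da <- function() {
  .memo("basis_da", function() {
    simulate_basis(chip_geometry(), flow_settings(60), solvent_conditions(),
                   rh_grid = c(1, 3, 10, 30, 100),
                   solver = solver_options(ny = 61, mode = "depth_averaged"))
  })
}

# Burst-search parameters matched to the generator's default brightness
# (250 photons/ms): IPT_max of 0.02 ms is ~5x the in-burst mean inter-photon
# time, so transits are counted whole instead of fragmenting.
test_burst_params <- function() burst_search_params(0.02, 10, 4)

# Noiseless profile equal to a basis grid row laid out across all crossings.
self_profile <- function(basis, i, amplitude = 1, mode = "continuous",
                         gap = 25) {
  lay <- crossing_layout(basis, gap)
  n_cross <- length(basis$crossing_times_s)
  coords <- c(); vals <- c(); crs <- c()
  for (k in seq_len(n_cross)) {
    coords <- c(coords, lay$offsets[k] + basis$y_um)
    vals <- c(vals, amplitude * basis$profiles[i, k, ])
    crs <- c(crs, rep(k, length(basis$y_um)))
  }
  diffusion_profile(coords, vals, mode, crs)
}

# Variance of a profile row about its mean coordinate.
profile_variance <- function(values, y) {
  m0 <- sum(values)
  mu <- sum(values * y) / m0
  sum(values * (y - mu)^2) / m0
}

# Evenly spaced photon trace helper: n photons at `spacing_ms` intervals.
regular_trace <- function(n, spacing_ms, duration = NULL, t0 = 0.001) {
  t <- t0 + (seq_len(n) - 1) * spacing_ms * 1e-3
  if (is.null(duration)) duration <- max(t) + 0.001
  photon_trace(t, duration)
}
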