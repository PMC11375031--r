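# Chip geometry, residence times, and the advection-diffusion basis solver.

test_that("residence_time follows plug-flow kinematics", {
  geom <- chip_geometry()
  expect_equal(residence_time(geom, flow_settings(60), 29630), 10.0,
               tolerance = 1e-3)
  expect_identical(residence_time(geom, flow_settings(60), 0), 0)
  expect_equal(residence_time(geom, flow_settings(120), 20000),
               residence_time(geom, flow_settings(60), 20000) / 2)
  expect_error(residence_time(geom, flow_settings(60), -1), "distance")
  expect_error(residence_time(geom, flow_settings(60), 1e9), "distance")
})

test_that("geometry invariants are enforced", {
  expect_error(chip_geometry(sample_flow_fraction = 0), "sample_flow_fraction")
  expect_error(chip_geometry(sample_flow_fraction = 1), "sample_flow_fraction")
  expect_error(chip_geometry(crossing_distances = c(5, 10)), "start at 0")
  expect_error(chip_geometry(crossing_distances = c(0, 2e5)),
               "channel_length")
  expect_error(flow_settings(0), "positive")
})

test_that("solver conserves mass and spreads profiles monotonically", {
  for (basis in list(test_basis_full(), test_basis_da())) {
    expect_lt(basis$metadata$mass_error, 1e-6)
    ny <- length(basis$y_um)
    for (i in seq_along(basis$rh_nm)) {
      v <- vapply(1:4, function(k) {
        profile_variance(basis$profiles[i, k, ], basis$y_um)
      }, numeric(1))
      # variance nondecreasing in crossing distance
      expect_true(all(diff(v) > -1e-8))
    }
    for (k in 2:4) {
      v_rh <- vapply(seq_along(basis$rh_nm), function(i) {
        profile_variance(basis$profiles[i, k, ], basis$y_um)
      }, numeric(1))
      # at fixed crossing, larger species diffuse less
      expect_true(all(diff(v_rh) < 1e-8))
    }
    expect_true(all(basis$profiles >= -1e-12))
  }
})

test_that("slow-diffusion limit reproduces the inlet top-hat", {
  basis <- simulate_basis(
    chip_geometry(), flow_settings(60), solvent_conditions(),
    rh_grid = c(5e4, 1e5),   # R_H far above the sized range: D ~ 0
    solver = solver_options(ny = 121, mode = "depth_averaged"))
  inlet <- basis$profiles[2, 1, ]
  for (k in 2:4) {
    # all mass remains within one grid cell of the inlet distribution
    moved <- sum(abs(basis$profiles[2, k, ] - inlet))
    expect_lt(moved / sum(inlet), 0.05)
  }
})

test_that("fast-diffusion limit approaches the uniform profile", {
  basis <- test_basis()
  # smallest species at the last crossing: diffusion length sqrt(2 D t)
  # exceeds the channel width, profile must be uniform to < 1%
  d_um <- basis$d[1] * 1e12
  expect_gt(sqrt(2 * d_um * basis$crossing_times_s[4]),
            max(basis$y_um))
  p <- basis$profiles[1, 4, ]
  expect_lt(max(abs(p - mean(p))) / mean(p), 0.01)
})

test_that("mid-height readout is narrower than the depth average of the same solution", {
  # Taylor-direction check: the mid-height fluid is faster than average, so
  # at a given crossing the mid-plane slice has had less time to diffuse
  # than the depth-averaged readout of the same laminar solution
  bf <- test_basis_full()
  bz <- simulate_basis(chip_geometry(), flow_settings(60),
                       solvent_conditions(), rh_grid = bf$rh_nm,
                       solver = solver_options(ny = 61, nz = 11,
                                               mode = "full",
                                               readout = "depth_averaged"))
  for (i in seq_along(bf$rh_nm)) for (k in 2:4) {
    vf <- profile_variance(bf$profiles[i, k, ], bf$y_um)
    vz <- profile_variance(bz$profiles[i, k, ], bz$y_um)
    expect_lte(vf, vz * (1 + 1e-6))
  }
})

test_that("interpolate_profile is exact at nodes and bounded between them", {
  basis <- test_basis()
  i <- 20
  expect_identical(interpolate_profile(basis, basis$rh_nm[i]),
                   basis$profiles[i, , ])
  r_mid <- sqrt(basis$rh_nm[i] * basis$rh_nm[i + 1])
  p <- interpolate_profile(basis, r_mid)
  lo <- pmin(basis$profiles[i, , ], basis$profiles[i + 1, , ])
  hi <- pmax(basis$profiles[i, , ], basis$profiles[i + 1, , ])
  expect_true(all(p >= lo - 1e-12 & p <= hi + 1e-12))
  expect_error(interpolate_profile(basis, 0.01), "outside basis grid")
  expect_error(interpolate_profile(basis, 1e4), "outside basis grid")
})

test_that("interpolation error against re-simulation is below 2 percent", {
  # dense grid over one decade (denser than 40 nodes per decade and a half)
  grid <- exp(seq(log(3), log(30), length.out = 40))
  opts <- solver_options(ny = 91, mode = "depth_averaged")
  basis <- simulate_basis(chip_geometry(), flow_settings(60),
                          solvent_conditions(), grid, solver = opts)
  r_star <- sqrt(grid[20] * grid[21])   # log-midpoint between nodes
  interp <- interpolate_profile(basis, r_star)
  fresh <- simulate_basis(chip_geometry(), flow_settings(60),
                          solvent_conditions(),
                          rh_grid = c(r_star, r_star * 1.01),
                          solver = opts)$profiles[1, , ]
  for (k in 2:4) {
    rel <- sqrt(sum((interp[k, ] - fresh[k, ])^2) / sum(fresh[k, ]^2))
    expect_lt(rel, 0.02)
  }
})

test_that("basis libraries roundtrip through CSV + JSON serialization", {
  basis <- test_basis_full()
  dir <- withr::local_tempdir()
  write_basis_library(basis, dir)
  back <- read_basis_library(dir)
  expect_equal(back$rh_nm, basis$rh_nm)
  expect_equal(back$profiles, basis$profiles, tolerance = 1e-12)
  expect_equal(back$crossing_times_s, basis$crossing_times_s)
  expect_equal(back$metadata$solver$mode, "full")
})
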