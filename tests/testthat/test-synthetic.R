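# Ground-truth generator: determinism, Poisson rates, analytic expectations.

test_that("generation is bit-for-bit reproducible under a fixed seed", {
  basis <- test_basis()
  sp <- species_spec(5, 100e-12)
  acq <- acquisition_spec("step", n_per_crossing = 10, dwell = 1, seed = 99)
  a <- generate_step_scan(sp, basis, acq)
  b <- generate_step_scan(sp, basis, acq)
  expect_identical(lapply(a$traces, `[[`, "t"),
                   lapply(b$traces, `[[`, "t"))
  expect_identical(a$manifest, b$manifest)
  ca <- generate_continuous_scan(sp, basis,
                                 acquisition_spec("continuous",
                                                  scan_speed = 100,
                                                  seed = 7))
  cb <- generate_continuous_scan(sp, basis,
                                 acquisition_spec("continuous",
                                                  scan_speed = 100,
                                                  seed = 7))
  expect_identical(ca$binned, cb$binned)
  expect_error(acquisition_spec("step"), "seed")
})

test_that("zero concentration yields a background-only scan", {
  basis <- test_basis()
  sp <- species_spec(5, 1e-30, brightness = 250)   # effectively none
  acq <- acquisition_spec("step", n_per_crossing = 8, dwell = 1, seed = 3,
                          background_rate = 2)
  scan <- generate_step_scan(sp, basis, acq)
  expect_equal(sum(scan$manifest$n_transits), 0)
  cnt <- count_molecules(scan$traces, test_burst_params())
  expect_lte(sum(cnt$count), 1)
  # background photon totals follow the configured rate
  nph <- sum(vapply(scan$traces, function(tr) length(tr$t), numeric(1)))
  lambda <- acq$background_rate * 1e3 * acq$dwell * length(scan$traces)
  expect_lt(abs(nph - lambda), 4 * sqrt(lambda))
})

test_that("transit counts scale linearly with concentration", {
  basis <- test_basis()
  acq1 <- acquisition_spec("step", n_per_crossing = 25, dwell = 2, seed = 8)
  s1 <- generate_step_scan(species_spec(5, 100e-12), basis, acq1)
  s2 <- generate_step_scan(species_spec(5, 200e-12), basis, acq1)
  n1 <- sum(s1$manifest$n_transits); n2 <- sum(s2$manifest$n_transits)
  expect_equal(sum(s2$manifest$rate), 2 * sum(s1$manifest$rate))
  expect_lt(abs(n2 - 2 * n1), 3 * sqrt(n2 + 4 * n1))
  # out-of-grid species are rejected
  expect_error(generate_step_scan(species_spec(1e4, 1e-12), basis, acq1),
               "outside basis grid")
})

test_that("continuous-scan intensities track the interpolated basis shape", {
  basis <- test_basis()
  # ~1e4 photons per bin at the profile peak so Poisson noise sits well
  # below the 2% shape tolerance
  sp <- species_spec(3.73, 100e-9, brightness = 600)
  acq <- acquisition_spec("continuous", scan_speed = 20, seed = 17,
                          background_rate = 1)
  cs <- generate_continuous_scan(sp, basis, acq)
  shape <- interpolate_profile(basis, 3.73)
  prof <- profile_from_continuous(cs$binned, scan_speed = 20, bin = 1,
                                  crossing_boundaries = cs$layout$boundaries)
  prof <- rebin_profile(prof, 50)        # ~1-um resolution
  for (k in 1:4) {
    idx <- prof$crossing == k
    y <- prof$coordinate[idx] - cs$layout$offsets[k]
    ref <- approx(basis$y_um, shape[k, ], xout = y, rule = 2)$y
    obs <- prof$value[idx] - acq$background_rate
    ref <- ref / sum(ref); obs <- obs / sum(obs)
    expect_lt(sqrt(sum((obs - ref)^2) / sum(ref^2)), 0.02)
  }
})

test_that("oligomer burst draws match their component moments", {
  ab <- c(0.6, 0.3, 0.1)
  x <- generate_oligomer_bursts(80, 30, ab, 2e4, seed = 21)
  expect_equal(nrow(x), 2e4)
  counts <- table(x$species)
  expect_equal(as.numeric(counts / nrow(x)), ab, tolerance = 0.02)
  dimer <- x$normalized_intensity[x$species == 2]
  expect_lt(abs(mean(dimer) - 160), 3 * 30 / sqrt(length(dimer)))
  mono <- x$normalized_intensity[x$species == 1]
  expect_equal(mean(mono), 80, tolerance = 3 * 30 / sqrt(length(mono)) / 80)
  expect_identical(generate_oligomer_bursts(80, 30, ab, 500, seed = 5),
                   generate_oligomer_bursts(80, 30, ab, 500, seed = 5))
  expect_error(generate_oligomer_bursts(80, 30, c(0.5, 0.2), 100, 1),
               "sum to 1")
})

test_that("end-to-end closure: a 3.73-nm species is sized within 10%", {
  basis <- test_basis()
  scan <- generate_step_scan(
    species_spec(3.73, 50e-12), basis,
    acquisition_spec("step", n_per_crossing = 100, dwell = 2.5, seed = 64))
  prof <- profile_from_step(scan$traces, test_burst_params(),
                            crossing_boundaries = scan$layout$boundaries)
  fit <- global_fit(prof, basis)
  expect_lt(abs(fit$r_h / 3.73 - 1), 0.10)
})
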