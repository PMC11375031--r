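# Brightness-histogram deconvolution of oligomeric states.

test_that("oligomer centers are integer multiples of the monomer intensity", {
  centers <- oligomer_centers(75.33, 4)
  expect_equal(unname(centers), c(150.66, 225.99, 301.32))
  expect_equal(unname(oligomer_centers(1, 3)), c(2, 3))
  expect_equal(oligomer_centers(2 * 75.33, 4), 2 * oligomer_centers(75.33, 4))
  expect_error(oligomer_centers(-1, 4), "positive")
  expect_error(oligomer_centers(75, 1), "n_max")
})

test_that("skew-normal sampler matches its moment parameterisation", {
  set.seed(1)
  x <- rskewnorm(2e5, xi = 10, omega = 20, alpha = 4)
  delta <- 4 / sqrt(17)
  expect_equal(mean(x), 10 + 20 * delta * sqrt(2 / pi), tolerance = 0.01)
  expect_equal(sd(x), 20 * sqrt(1 - 2 * delta^2 / pi), tolerance = 0.01)
  # density integrates to one
  expect_equal(integrate(dskewnorm, -50, 150, xi = 10, omega = 20,
                         alpha = 4)$value, 1, tolerance = 1e-6)
})

test_that("burst gating partitions by brightness region", {
  bursts <- data.frame(normalized_intensity = c(10, 70, 80, 150, 160, 300))
  reg <- species_region("monomer", 75, 37)
  expect_equal(gate_bursts(bursts, reg)$normalized_intensity, c(70, 80))
  # exhaustive disjoint regions partition the burst list
  regions <- list(species_region("a", 50, 50 - 1e-9),
                  species_region("b", 150, 50 - 1e-9),
                  species_region("c", 250, 50 - 1e-9))
  gated <- lapply(regions, gate_bursts, bursts = bursts)
  expect_equal(sum(vapply(gated, nrow, integer(1))),
               sum(bursts$normalized_intensity < 300))
  none <- species_region("below", -100, 5)
  expect_identical(nrow(gate_bursts(bursts, none)), 0L)
  # +/- 1 sd gating captures the central mass of a Gaussian species;
  # expected capture = pnorm(1) - pnorm(-1) of draws
  set.seed(8)
  dimers <- data.frame(normalized_intensity = rnorm(4000, 150.66, 37.44))
  cap <- nrow(gate_bursts(dimers, species_region("dimer", 150.66, 37.44)))
  p <- pnorm(1) - pnorm(-1)
  expect_lt(abs(cap / 4000 - p), 3 * sqrt(p * (1 - p) / 4000))
})

test_that("mixture fit recovers a pure monomer and a 4-species sample", {
  x1 <- generate_oligomer_bursts(75.33, 37.44, 1, 2000, seed = 3)
  m1 <- fit_brightness_mixture(x1, 1)
  expect_equal(unname(m1$abundances), 1)
  expect_equal(m1$i_monomer, 75.33, tolerance = 0.05)
  expect_equal(m1$sigma_monomer, 37.44, tolerance = 0.10)

  ab <- c(0.679, 0.207, 0.072, 0.042)
  x4 <- generate_oligomer_bursts(75.33, 37.44, ab, 1e4, seed = 7)
  m4 <- fit_brightness_mixture(x4, 4)
  expect_true(all(abs(m4$abundances - ab) < 0.03))
  expect_equal(sum(m4$abundances), 1, tolerance = 1e-9)
  expect_equal(m4$i_monomer, 75.33, tolerance = 0.05)
  # constraint identity: dimer center is exactly twice the fitted mean
  expect_equal(unname(m4$oligomer_centers[1]), 2 * m4$i_monomer)
  expect_error(fit_brightness_mixture(x4, 0), "positive integer")
  expect_error(fit_brightness_mixture(x4[1:50, ], 2), "at least")
})

test_that("BIC selects the generating number of species", {
  # single species chosen in >= 95% of seeds
  hits1 <- vapply(1:40, function(s) {
    x <- generate_oligomer_bursts(75, 37, 1, 600, seed = s)
    select_species_count(x, 1:3, min_bursts = 100)$k == 1
  }, logical(1))
  expect_gte(mean(hits1), 0.95)

  # four species at realistic abundances chosen in >= 80% of seeds
  ab <- c(0.679, 0.207, 0.072, 0.042)
  hits4 <- vapply(1:15, function(s) {
    x <- generate_oligomer_bursts(75.33, 37.44, ab, 1e4, seed = 100 + s)
    select_species_count(x, 3:5)$k == 4
  }, logical(1))
  expect_gte(mean(hits4), 0.8)

  # degenerate single-candidate range
  x <- generate_oligomer_bursts(75, 37, 1, 600, seed = 1)
  expect_identical(select_species_count(x, 3, min_bursts = 100)$k, 3L)
})

test_that("bootstrap abundance intervals are reproducible and calibrated", {
  ab <- c(0.679, 0.207, 0.072, 0.042)
  x <- generate_oligomer_bursts(75.33, 37.44, ab, 5000, seed = 11)
  mix <- fit_brightness_mixture(x, 4)
  ci_a <- abundance_ci(mix, x, n_boot = 150, seed = 42)
  ci_b <- abundance_ci(mix, x, n_boot = 150, seed = 42)
  expect_identical(ci_a, ci_b)
  expect_true(all(ab >= ci_a[, "lower"] & ab <= ci_a[, "upper"]))

  x1 <- generate_oligomer_bursts(75.33, 37.44, 1, 1000, seed = 12)
  m1 <- fit_brightness_mixture(x1, 1)
  ci1 <- abundance_ci(m1, x1, n_boot = 150, seed = 1)
  expect_true(ci1[1, "lower"] <= 1 & 1 <= ci1[1, "upper"] + 1e-12)
  expect_error(abundance_ci(m1, x1$normalized_intensity[1:3],
                            n_boot = 150), "resample|few")
})

test_that("threshold sweep is flat for monodisperse, rising for oligomers", {
  basis <- test_basis()
  # monodisperse: radius stable across photon thresholds
  scan <- generate_step_scan(
    species_spec(5, 150e-12), basis,
    acquisition_spec("step", n_per_crossing = 60, dwell = 3, seed = 55))
  sw <- threshold_sweep(scan$traces, c(10, 20, 40), ipt_max = 0.02,
                        basis = basis, lee_window = 4,
                        crossing_boundaries = scan$layout$boundaries)
  ok <- !sw$table$undersampled
  expect_gte(sum(ok), 2)
  rh <- sw$table$r_h[ok]
  expect_lt(diff(range(rh)) / median(rh), 0.25)
  # single-threshold sweep equals the plain fit at that threshold
  sw1 <- threshold_sweep(scan$traces, 10, ipt_max = 0.02, basis = basis,
                         lee_window = 4,
                         crossing_boundaries = scan$layout$boundaries)
  prof <- profile_from_step(scan$traces, burst_search_params(0.02, 10, 4),
                            crossing_boundaries = scan$layout$boundaries)
  fit <- global_fit(prof, basis)
  expect_equal(sw1$table$r_h[1], fit$r_h, tolerance = 1e-9)

  # mixture in which brightness scales with assembly size: radius grows
  # with the photon threshold
  mono <- species_spec(4, 120e-12, brightness = 250, labeled_units = 1,
                       label = "monomer")
  olig <- species_spec(12, 25e-12, brightness = 250,
                       labeled_units = setNames(c(0.5, 0.5), c(6, 8)),
                       label = "oligomer")
  scan2 <- generate_step_scan(list(mono, olig), basis,
                              acquisition_spec("step", n_per_crossing = 60,
                                               dwell = 3, seed = 56))
  sw2 <- threshold_sweep(scan2$traces, c(10, 150), ipt_max = 0.02,
                         basis = basis, lee_window = 4,
                         crossing_boundaries = scan2$layout$boundaries)
  expect_false(any(sw2$table$undersampled))
  expect_gt(sw2$table$r_h[2], sw2$table$r_h[1])
})
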