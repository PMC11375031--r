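# Rare-species separation, nanocluster detection, Fick sizing, and the
# digital count -> flux -> concentration -> volume-fraction chain.

test_that("intensity thresholding separates spikes from bulk", {
  set.seed(2)
  flat <- rpois(4000, 100)
  st <- split_trace_by_threshold(flat, 250)
  expect_identical(st$n_spikes, 0L)
  expect_identical(st$bulk_series, flat)

  spiked <- flat
  spiked[1001:1005] <- spiked[1001:1005] + 400      # 5-ms 400-kHz spike
  st2 <- split_trace_by_threshold(spiked, 250)
  expect_identical(st2$n_spikes, 1L)
  expect_lte(st2$spike_segments$start[1], 1001)
  expect_gte(st2$spike_segments$end[1], 1005)
  # bulk mean unaffected by the excised spike
  expect_lt(abs(st2$bulk_mean - 100), 1)
  expect_error(split_trace_by_threshold(flat, 250, smooth_window = 10),
               "odd")
  expect_error(split_trace_by_threshold(flat[1:5], 250), "shorter")
})

test_that("cluster event detection is robust and monotone in k_sd", {
  set.seed(3)
  tr <- rpois(20000, 50)
  ev0 <- detect_cluster_events(tr, 5)
  # normal-tail false-positive control at 5 robust sd
  expect_lt(ev0$n, 5)

  tr[5000] <- 50 + 20 * sqrt(50)                    # one 20-sd spike
  ev1 <- detect_cluster_events(tr, 5)
  expect_gte(ev1$n, 1)
  expect_true(any(ev1$events$start <= 5000 & ev1$events$end >= 5000))

  ns <- vapply(c(3, 5, 8, 12), function(k) {
    detect_cluster_events(tr, k)$n
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(detect_cluster_events(rep(5, 100), 5), "zero variance")

  # robust statistics: rare large events do not inflate the threshold
  many <- tr; many[seq(100, 19000, by = 400)] <- 400
  evm <- detect_cluster_events(many, 5)
  expect_equal(evm$bulk_mean, median(tr), tolerance = 0.05)
})

test_that("Gaussian peak fits recover the FWHM closed form", {
  y <- seq(0.5, 224.5, by = 1)
  sigma <- 14
  counts <- round(600 * dnorm(y, 112.5, sigma) * 1)
  d <- data.frame(coordinate = y, count = counts, crossing = 1)
  pk <- fit_position_peaks(d)
  expect_equal(pk$mean, 112.5, tolerance = 0.01)
  expect_equal(pk$fwhm, 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.01)
  expect_equal(pk$distance, pk$fwhm / 2)

  # Poisson-sampled histograms: fwhm within 10% over 50 seeds
  rels <- vapply(1:50, function(s) {
    set.seed(s)
    cnt <- rpois(length(y), 500 * dnorm(y, 112.5, sigma))
    pks <- fit_position_peaks(
      data.frame(coordinate = y, count = cnt, crossing = 1))
    abs(pks$fwhm / (2 * sqrt(2 * log(2)) * sigma) - 1)
  }, numeric(1))
  expect_lt(median(rels), 0.10)

  # a crossing with too few informative positions is excluded and flagged
  sparse <- data.frame(coordinate = c(1, 2), count = c(3, 1), crossing = 2)
  pk2 <- fit_position_peaks(rbind(d, sparse))
  expect_identical(attr(pk2, "excluded"), 2)
  expect_identical(pk2$crossing, 1)
})

test_that("fick_fit inverts the one-dimensional broadening law", {
  d_true <- 2.045e-12
  times <- c(0, 10, 26, 55)
  x <- c(0, sqrt(2 * d_true * times[-1]) * 1e6)
  ff <- fick_fit(x, times)
  expect_equal(ff$d, d_true, tolerance = 1e-4)
  expect_equal(ff$r_h, 120, tolerance = 1e-3)
  # quadratic law: scaling all net distances by c scales D by c^2
  ff2 <- fick_fit(c(0, 2 * x[-1]), times)
  expect_equal(ff2$d, 4 * d_true, tolerance = 1e-4)
  # quadrature normalisation of a finite zero-time width
  x0 <- 12.5
  xq <- sqrt(x0^2 + 2 * d_true * 1e12 * times)
  ffq <- fick_fit(xq, times)
  expect_equal(ffq$d, d_true, tolerance = 1e-4)
  expect_error(fick_fit(rep(5, 4), times), "no broadening")
  expect_error(fick_fit(x[-1], times[-1]), "t = 0")
})

test_that("flux, concentration, and volume fraction follow the digital chain", {
  expect_equal(cluster_flux(100, 10, 1), 10)
  expect_equal(cluster_flux(100, 10, 0.5), 20)
  expect_error(cluster_flux(100, 10), "detection_efficiency")

  # worked example: 72,606 clusters/s at 60 uL/h -> 7.24 pM
  cc <- cluster_concentration(72606, flow_settings(60))
  expect_equal(cc, 7.24, tolerance = 0.005)
  expect_equal(cluster_concentration(0, flow_settings(60)), 0)
  expect_equal(cluster_concentration(72606, flow_settings(120)), cc / 2)

  # 7.24 pM of 120-nm particles -> phi = 3.16e-5
  phi <- volume_fraction(7.24, 120)
  expect_equal(phi, 3.16e-5, tolerance = 0.01)
  expect_equal(volume_fraction(0, 120), 0)
  expect_equal(volume_fraction(7.24, 240), 8 * phi)

  # c -> phi -> c roundtrip is exact
  c_back <- phi / (.N_A <- 6.02214076e23) / ((4 / 3) * pi * (120e-9)^3) /
    1e3 * 1e12
  expect_equal(c_back, 7.24, tolerance = 1e-9)

  m <- monomers_per_cluster(120, 4.29)
  expect_equal(m$ceiling, (120 / 4.29)^3)
  expect_equal(m$ceiling, 2.19e4, tolerance = 0.01)
  expect_equal(m$lower, 2.19e3, tolerance = 0.01)
  expect_equal(m$upper, 7.66e3, tolerance = 0.01)
  expect_equal(monomers_per_cluster(10, 10, c(1, 1))$ceiling, 1)
})

test_that("cluster pipeline recovers the generating radius end to end", {
  times <- c(0, 10, 26, 55)
  d_true <- 2.045e-12
  # per-seed peak distances, averaged over repeats before the Fick fit
  dist_mat <- vapply(1:6, function(s) {
    ev <- generate_cluster_events(d_true, times, n_events = 500, seed = s)
    pk <- fit_position_peaks(ev)
    pk$distance[match(1:4, pk$crossing)]
  }, numeric(4))
  ff <- fick_fit(rowMeans(dist_mat), times)
  expect_lt(abs(ff$r_h / 120 - 1), 0.15)

  ev <- generate_cluster_events(d_true, times, n_events = 500, seed = 1)
  cp <- cluster_pipeline(ev, times, observation_time = 600,
                         detection_efficiency = 0.5)
  expect_equal(cp$n_events, sum(ev$count))
  expect_equal(cp$flux, sum(ev$count) / 600 / 0.5)
  expect_equal(cp$concentration,
               cluster_concentration(cp$flux, flow_settings(60)))
  expect_equal(cp$volume_fraction, volume_fraction(cp$concentration, cp$r_h))
})

test_that("fibril spikes and monomer bulk are sized from one mixed scan", {
  basis <- test_basis()
  errs <- vapply(1:5, function(s) {
    bulk <- species_spec(3.2, 1e-9, 250, label = "monomer")
    fib <- species_spec(56, 5e-12, 250, label = "fibril")
    acq <- acquisition_spec("step", n_per_crossing = 100, dwell = 2,
                            seed = s)
    scan <- generate_spike_scan(bulk, fib, basis, acq,
                                spike_amplitude = 400, spike_duration = 5)
    splits <- lapply(scan$binned, split_trace_by_threshold,
                     rate_threshold = 250)
    nsp <- vapply(splits, `[[`, integer(1), "n_spikes")
    bm <- vapply(splits, `[[`, numeric(1), "bulk_mean")
    pos <- scan$positions; o <- order(pos$coordinate)
    pf <- diffusion_profile(pos$coordinate[o], nsp[o], "step",
                            pos$crossing[o])
    ff <- global_fit(pf, basis, compute_errors = FALSE)
    pm <- diffusion_profile(pos$coordinate[o],
                            pmax(bm[o] - acq$background_rate, 0),
                            "continuous", pos$crossing[o])
    fm <- global_fit(pm, basis, compute_errors = FALSE)
    c(abs(ff$r_h / 56 - 1), abs(fm$r_h / 3.2 - 1))
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.15)   # fibrils
  expect_lt(median(errs[2, ]), 0.15)   # monomer bulk
})
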