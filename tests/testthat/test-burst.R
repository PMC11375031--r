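# Lee filter and the combined IPT_max / N_min burst search.

test_that("lee_filter keeps constant signal and honours its contracts", {
  expect_identical(lee_filter(rep(4, 50), 3), rep(4, 50))
  x <- rnorm(100)
  expect_identical(lee_filter(x, 1), x)          # window 1 is the identity
  expect_length(lee_filter(x, 5), 100)
  step <- c(rep(0, 30), rep(10, 30))
  f <- lee_filter(step, 5)
  expect_true(all(f >= min(step) - 1e-12 & f <= max(step) + 1e-12))
  # edge preservation: away from the step the signal is untouched, and the
  # transition still happens within one window of the true edge
  expect_equal(f[1:25], step[1:25])
  expect_equal(f[36:60], step[36:60])
  expect_lt(f[28], 5); expect_gt(f[33], 5)
  expect_error(lee_filter(numeric(0), 3), "empty")
})

test_that("find_bursts applies the combined IPT/N_min criterion", {
  p <- burst_search_params(ipt_max = 0.02, n_min = 5, lee_window = 1)
  empty <- photon_trace(numeric(0), 1)
  expect_identical(nrow(find_bursts(empty, p)), 0L)

  tr <- regular_trace(10, 0.01)                  # 10 photons, 0.01 ms apart
  b <- find_bursts(tr, p)
  expect_identical(nrow(b), 1L)
  expect_identical(b$n_photons, 10L)
  expect_equal(b$duration, 0.09)
  expect_equal(b$normalized_intensity, 10 / 0.09)
  expect_identical(nrow(find_bursts(tr, burst_search_params(0.02, 20, 1))),
                   0L)
  # photons spaced wider than ipt_max never form a burst
  slow <- regular_trace(50, 0.5)
  expect_identical(nrow(find_bursts(slow, p)), 0L)
})

test_that("burst search is deterministic and monotone in its thresholds", {
  set.seed(21)
  # bursty trace: background plus clusters of fast photons
  t_bg <- sort(runif(2000, 0, 1))
  t_burst <- unlist(lapply(runif(150, 0, 1), function(t0) {
    t0 + cumsum(rexp(rpois(1, 40), rate = 2.5e5))
  }))
  t_all <- sort(c(t_bg, t_burst)); t_all <- t_all[t_all < 1]
  t_all <- t_all[c(TRUE, diff(t_all) > 0)]
  tr <- photon_trace(t_all, 1)

  p <- burst_search_params(0.02, 10, 3)
  b1 <- find_bursts(tr, p); b2 <- find_bursts(tr, p)
  expect_identical(b1, b2)                       # bit-for-bit determinism

  counts_nmin <- vapply(c(5, 10, 15, 20, 30), function(nm) {
    nrow(find_bursts(tr, burst_search_params(0.02, nm, 3)))
  }, numeric(1))
  expect_true(all(diff(counts_nmin) <= 0))

  # lowering ipt_max never increases the count when bursts are coherent
  # (evenly spaced photons; ragged bursts can fragment, see vignette)
  gaps <- seq(0.05, 0.95, by = 0.05)
  t2 <- sort(unlist(lapply(gaps, function(t0) t0 + (0:19) * 4e-6)))
  tr2 <- photon_trace(t2, 1)
  counts_ipt <- vapply(c(0.03, 0.02, 0.012, 0.008, 0.005, 0.003),
                       function(ipt) {
    nrow(find_bursts(tr2, burst_search_params(ipt, 10, 3)))
  }, numeric(1))
  expect_true(all(diff(counts_ipt) <= 0))
  expect_equal(counts_ipt[1], length(gaps))   # all bursts at loose ipt
  expect_equal(counts_ipt[6], 0)              # none below the spacing
})

test_that("pure background yields essentially no false bursts", {
  # mean inter-photon time 10x the threshold: expected bursts < 1 per 10 s
  set.seed(77)
  ipt_max <- 0.01                                 # ms
  n <- rpois(1, 10 / (10 * ipt_max * 1e-3))       # 10 s at 10 kHz
  t <- sort(runif(n, 0, 10))
  t <- t[c(TRUE, diff(t) > 0)]
  tr <- photon_trace(t, 10)
  b <- find_bursts(tr, burst_search_params(ipt_max, 10, 3))
  expect_lt(nrow(b), 2)
})

test_that("count_molecules is additive and rejects ambiguous positions", {
  p <- burst_search_params(0.02, 5, 1)
  mk <- function(offsets, id, coord = 10) {
    t <- sort(unlist(lapply(offsets, function(o) o + (0:9) * 1e-5)))
    photon_trace(t, 1, id, coord)
  }
  tr3 <- mk(c(0.1, 0.4, 0.8), 1L)
  cnt <- count_molecules(list(tr3), p)
  expect_identical(cnt$count, 3)

  a <- mk(c(0.1, 0.4), 1L); b <- mk(c(0.2, 0.6), 1L)
  both <- concat_traces(a, b)
  expect_identical(count_molecules(list(both), p)$count,
                   count_molecules(list(a), p)$count +
                     count_molecules(list(mk(c(0.2, 0.6), 2L)), p)$count)
  expect_error(count_molecules(list(a, b), p), "duplicate position ids")
})

test_that("burst counts on generator traces match the Poisson ground truth", {
  basis <- test_basis()
  # bright species so every transit is one coherent, unfragmented burst
  sp <- species_spec(10, 200e-12, brightness = 600)
  acq <- acquisition_spec("step", n_per_crossing = 25, dwell = 2, seed = 5)
  scan <- generate_step_scan(sp, basis, acq)
  cnt <- count_molecules(scan$traces, test_burst_params())
  n_expected <- sum(scan$manifest$rate) * acq$dwell
  n_detected <- sum(cnt$count)
  # detected single-molecule events track the generating Poisson process
  expect_lt(abs(n_detected - n_expected), 4 * sqrt(n_expected))
})
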