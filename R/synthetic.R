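## molar concentration -> number density per um^3
.dens_um3 <- function(conc_molar) conc_molar * .N_A / 1e15

#' Species specification for the synthetic-data generator
#'
#' @param r_h Hydrodynamic radius (nm); must lie inside the basis grid used
#'   for generation.
#' @param concentration Molar concentration of the species.
#' @param brightness Photons/ms emitted per labeled monomer unit while in
#'   the confocal volume.
#' @param labeled_units Either a single monomer count or a named probability
#'   vector over monomer counts (names = counts), for oligomer mixtures.
#' @param label Species name.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(r_h, concentration, brightness = 250,
                         labeled_units = 1, label = "species") {
  if (r_h <= 0 || concentration <= 0 || brightness <= 0) {
    stop("`r_h`, `concentration` and `brightness` must be positive")
  }
  if (is.null(names(labeled_units))) {
    if (length(labeled_units) != 1 || labeled_units < 1) {
      stop("unnamed `labeled_units` must be a single count >= 1")
    }
    labeled_units <- setNames(1, as.character(labeled_units))
  }
  if (abs(sum(labeled_units) - 1) > 1e-9) {
    stop("`labeled_units` probabilities must sum to 1")
  }
  structure(list(r_h = r_h, concentration = concentration,
                 brightness = brightness, labeled_units = labeled_units,
                 label = label), class = "species_spec")
}

#' Acquisition specification for the synthetic-data generator
#'
#' @param mode `"step"` or `"continuous"`.
#' @param n_per_crossing Scan positions per channel crossing (step mode).
#' @param dwell Dwell time per position in seconds (step mode).
#' @param bin Bin width in ms.
#' @param background_rate Background photon rate in kHz.
#' @param seed Mandatory integer seed; all generator randomness flows
#'   through it.
#' @param scan_speed Stage speed in um/s (continuous mode).
#' @param detection_length Effective detection length along the flow (um);
#'   sets the transit duration at the local flow speed.
#' @param detection_area Effective detection cross-section (um^2); sets the
#'   molecular flux through the confocal spot.
#' @param detection_volume Effective confocal volume (um^3); sets the mean
#'   occupancy for continuous-mode intensities.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(mode = c("step", "continuous"),
                             n_per_crossing = 50, dwell = 2, bin = 1,
                             background_rate = 2, seed,
                             scan_speed = 50, detection_length = 1,
                             detection_area = 0.5, detection_volume = 0.3) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("`seed` is mandatory")
  if (dwell <= 0 || bin <= 0) stop("`dwell` and `bin` must be positive")
  structure(list(mode = mode, n_per_crossing = as.integer(n_per_crossing),
                 dwell = dwell, bin = bin,
                 background_rate = background_rate,
                 seed = as.integer(seed), scan_speed = scan_speed,
                 detection_length = detection_length,
                 detection_area = detection_area,
                 detection_volume = detection_volume),
            class = "acquisition_spec")
}

#' Chip-coordinate layout of the scanned crossings
#'
#' Lays the scanned crossings out along a single scan axis: crossing k spans
#' `[(k-1)(W + gap), (k-1)(W + gap) + W]` where W is the channel width.
#'
#' @param basis A basis library (supplies the width and crossing count).
#' @param gap Width of the channel wall between crossings (um).
#' @return List with `boundaries` (list of `c(lo, hi)` per crossing) and
#'   `offsets` (left-edge coordinate per crossing).
#' @export
crossing_layout <- function(basis, gap = 25) {
  W <- max(basis$y_um)
  n <- length(basis$crossing_times_s)
  offsets <- (seq_len(n) - 1) * (W + gap)
  list(boundaries = lapply(seq_len(n),
                           function(k) c(offsets[k], offsets[k] + W)),
       offsets = offsets)
}

.basis_velocity <- function(basis) {
  g <- basis$metadata$geometry; f <- basis$metadata$flow
  (f$total_flow_rate * 1e9 / 3600) /
    (g$channel_height * g$observation_width)
}

## expected concentration shape of `sp` at positions (y within crossing)
.shape_at <- function(basis, sp, crossing, y) {
  prof <- interpolate_profile(basis, sp$r_h)
  approx(basis$y_um, prof[crossing, ], xout = y, yleft = 0, yright = 0)$y
}

#' Generate a synthetic single-molecule step scan
#'
#' Emulates a step-scan acquisition over the simulated chip: at every scan
#' position, molecules of each species arrive as a Poisson process with rate
#' proportional to the local simulated concentration, the flow velocity and
#' the effective detection cross-section; each transit emits a Poisson
#' number of photons at `brightness x labeled units` over the transit
#' duration, on top of Poisson background photons. A manifest records the
#' expected and realised transit counts per position and species, so every
#' downstream statistic has an analytic reference.
#'
#' @param species List of [species_spec()] objects (a single spec is
#'   wrapped).
#' @param basis Basis library from [simulate_basis()]; species radii must
#'   lie inside its grid.
#' @param acq An [acquisition_spec()] with `mode = "step"`.
#' @param gap Wall width between crossings (um).
#' @return A list of class `sm_step_scan`: `traces` (list of
#'   [photon_trace()]), `manifest` (per position x species expected rate and
#'   true transit count), `layout`, `acq`.
#' @export
generate_step_scan <- function(species, basis, acq, gap = 25) {
  if (inherits(species, "species_spec")) species <- list(species)
  rng <- range(basis$rh_nm)
  for (sp in species) {
    if (sp$r_h < rng[1] || sp$r_h > rng[2]) {
      stop(sprintf("species r_h = %.3g nm outside basis grid [%.3g, %.3g]",
                   sp$r_h, rng[1], rng[2]))
    }
  }
  set.seed(acq$seed)
  lay <- crossing_layout(basis, gap)
  W <- max(basis$y_um)
  v <- .basis_velocity(basis)
  tau <- acq$detection_length / v                 # transit duration, s
  n_cross <- length(basis$crossing_times_s)
  y_pos <- seq(0, W, length.out = acq$n_per_crossing)

  traces <- list(); manifest <- list(); pid <- 0L
  for (k in seq_len(n_cross)) {
    shapes <- lapply(species, .shape_at, basis = basis, crossing = k,
                     y = y_pos)
    for (j in seq_along(y_pos)) {
      pid <- pid + 1L
      coord <- lay$offsets[k] + y_pos[j]
      t_all <- runif(rpois(1, acq$background_rate * 1e3 * acq$dwell),
                     0, acq$dwell)
      for (si in seq_along(species)) {
        sp <- species[[si]]
        rate <- .dens_um3(sp$concentration) * v * acq$detection_area *
          shapes[[si]][j]
        n_tr <- rpois(1, rate * acq$dwell)
        if (n_tr > 0) {
          t0 <- runif(n_tr, 0, max(acq$dwell - tau, 0))
          units <- as.numeric(names(sp$labeled_units))[
            sample.int(length(sp$labeled_units), n_tr, replace = TRUE,
                       prob = sp$labeled_units)]
          nph <- rpois(n_tr, sp$brightness * units * tau * 1e3)
          if (sum(nph) > 0) {
            t_all <- c(t_all, runif(sum(nph), rep(t0, nph),
                                    rep(t0 + tau, nph)))
          }
        }
        manifest[[length(manifest) + 1L]] <- data.frame(
          position_id = pid, coordinate = coord, crossing = k,
          species = sp$label, rate = rate, n_transits = n_tr)
      }
      t_all <- sort(t_all)
      t_all <- t_all[c(TRUE, diff(t_all) > 0)]
      traces[[pid]] <- photon_trace(t_all, acq$dwell, pid, coord)
    }
  }
  structure(list(traces = traces, manifest = do.call(rbind, manifest),
                 layout = lay, acq = acq),
            class = "sm_step_scan")
}

#' Generate a synthetic continuous scan
#'
#' Bins a constant-speed scan across the laid-out crossings; the expected
#' intensity at each coordinate is the species' simulated concentration
#' shape scaled by mean confocal occupancy and brightness, plus background.
#' Channel walls between crossings contribute background only.
#'
#' @inheritParams generate_step_scan
#' @param acq An [acquisition_spec()] with `mode = "continuous"`.
#' @return A list of class `sm_continuous_scan`: `binned` (photon counts per
#'   bin), `coordinates` (um, bin midpoints), `expected` (kHz), `layout`,
#'   `acq`.
#' @export
generate_continuous_scan <- function(species, basis, acq, gap = 25) {
  if (inherits(species, "species_spec")) species <- list(species)
  set.seed(acq$seed)
  lay <- crossing_layout(basis, gap)
  W <- max(basis$y_um)
  n_cross <- length(basis$crossing_times_s)
  total_len <- n_cross * W + (n_cross - 1) * gap
  n_bins <- floor(total_len / acq$scan_speed * 1e3 / acq$bin)
  mid_s <- (seq_len(n_bins) - 0.5) * acq$bin * 1e-3
  coord <- acq$scan_speed * mid_s
  expected <- rep(acq$background_rate, n_bins)
  for (sp in species) {
    occ <- .dens_um3(sp$concentration) * acq$detection_volume
    units_mean <- sum(as.numeric(names(sp$labeled_units)) *
                        sp$labeled_units)
    prof <- interpolate_profile(basis, sp$r_h)
    for (k in seq_len(n_cross)) {
      idx <- coord >= lay$boundaries[[k]][1] & coord <= lay$boundaries[[k]][2]
      y <- coord[idx] - lay$offsets[k]
      shape <- approx(basis$y_um, prof[k, ], xout = y,
                      yleft = 0, yright = 0)$y
      expected[idx] <- expected[idx] +
        occ * units_mean * sp$brightness * shape
    }
  }
  binned <- rpois(n_bins, expected * acq$bin)
  structure(list(binned = binned, coordinates = coord, expected = expected,
                 layout = lay, acq = acq),
            class = "sm_continuous_scan")
}

#' Generate synthetic burst brightnesses for an oligomer mixture
#'
#' Monomer intensities are drawn from a skew-normal with the given mean and
#' standard deviation; n-mer intensities from Gaussians centred at n times
#' the monomer mean with the monomer standard deviation; species counts are
#' multinomial in the given abundances.
#'
#' @param i_monomer Monomer mean normalized intensity (photons/ms).
#' @param sigma_monomer Monomer standard deviation (photons/ms).
#' @param abundances Species abundances (monomer first), summing to 1.
#' @param n_bursts Number of bursts to draw.
#' @param seed Integer seed.
#' @param alpha Skew-normal shape of the monomer component (default 4,
#'   right-skewed as produced by undersampled short transits).
#' @return Data.frame `normalized_intensity`, `species` (1 = monomer) with
#'   the generating parameters attached as attribute `"truth"`.
#' @export
generate_oligomer_bursts <- function(i_monomer, sigma_monomer, abundances,
                                     n_bursts, seed, alpha = 4) {
  if (abs(sum(abundances) - 1) > 1e-9) stop("`abundances` must sum to 1")
  set.seed(seed)
  k <- length(abundances)
  counts <- as.vector(rmultinom(1, n_bursts, abundances))
  sn <- .sn_from_moments(i_monomer, sigma_monomer, alpha)
  xs <- list()
  for (m in seq_len(k)) {
    if (counts[m] == 0) next
    x <- if (m == 1) rskewnorm(counts[m], sn$xi, sn$omega, alpha)
         else rnorm(counts[m], m * i_monomer, sigma_monomer)
    xs[[m]] <- data.frame(normalized_intensity = x, species = m)
  }
  out <- do.call(rbind, xs)
  out <- out[sample.int(nrow(out)), ]
  rownames(out) <- NULL
  attr(out, "truth") <- list(i_monomer = i_monomer,
                             sigma_monomer = sigma_monomer,
                             abundances = abundances, alpha = alpha,
                             seed = seed)
  out
}

#' Generate synthetic per-position nanocluster event histograms
#'
#' Draws cluster detection events around the channel centre of each
#' crossing. Peak widths follow the FWHM-based diffusion-distance
#' convention: the half-FWHM of the crossing at residence time t equals
#' `sqrt(x0^2 + 2 D t)`, where `x0` is the half-FWHM of the zero-time
#' crossing (set by the finite inlet stream width).
#'
#' @param d Cluster diffusion coefficient (m^2/s).
#' @param crossing_times Residence times (s), first = 0.
#' @param n_events Expected events per crossing (Poisson-sampled per
#'   position).
#' @param x0 Zero-time half-FWHM (um).
#' @param width Channel width (um).
#' @param bin_width Histogram bin width (um).
#' @param seed Integer seed.
#' @return Data.frame `coordinate`, `count`, `crossing` suitable for
#'   [fit_position_peaks()] / [cluster_pipeline()], with the generating
#'   parameters in attribute `"truth"`.
#' @export
generate_cluster_events <- function(d, crossing_times, n_events = 500,
                                    x0 = 12.5, width = 225, bin_width = 1,
                                    seed = 1L) {
  set.seed(seed)
  d_um <- d * 1e12
  center <- width / 2
  g <- 2 * sqrt(2 * log(2)) / 2      # half-FWHM per sigma
  rows <- list()
  for (k in seq_along(crossing_times)) {
    half_fwhm <- sqrt(x0^2 + 2 * d_um * crossing_times[k])
    sigma <- half_fwhm / g
    pos <- rnorm(rpois(1, n_events), center, sigma)
    pos <- pos[pos >= 0 & pos <= width]
    edges <- seq(0, width, by = bin_width)
    cnt <- tabulate(findInterval(pos, edges, rightmost.closed = TRUE),
                    length(edges) - 1)
    rows[[k]] <- data.frame(coordinate = edges[-1] - bin_width / 2,
                            count = cnt, crossing = k)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(d = d, crossing_times = crossing_times,
                             x0 = x0, seed = seed)
  out
}

#' Generate step-scan traces for a bulk species with rare bright spikes
#'
#' Emulates a heterogeneous mixture in which an abundant small species
#' produces a continuous bulk count rate while a rare large species
#' (fibrils, clusters) produces short bright spikes. Returns binned traces
#' per position, ready for [split_trace_by_threshold()] or
#' [detect_cluster_events()].
#'
#' @param bulk A [species_spec()] for the abundant small species.
#' @param spike A [species_spec()] for the rare large species.
#' @param basis Basis library.
#' @param acq An [acquisition_spec()].
#' @param spike_amplitude Added count rate during a spike (kHz).
#' @param spike_duration Spike duration in ms.
#' @param gap Wall width (um).
#' @return List of class `sm_spike_scan`: `binned` (list of per-position
#'   vectors, photons per 1-ms bin), `positions` (data.frame `position_id`,
#'   `coordinate`, `crossing`, `expected_spikes`, `n_spikes`,
#'   `bulk_rate`), `layout`, `acq`.
#' @export
generate_spike_scan <- function(bulk, spike, basis, acq,
                                spike_amplitude = 400, spike_duration = 5,
                                gap = 25) {
  set.seed(acq$seed)
  lay <- crossing_layout(basis, gap)
  W <- max(basis$y_um)
  v <- .basis_velocity(basis)
  n_cross <- length(basis$crossing_times_s)
  y_pos <- seq(0, W, length.out = acq$n_per_crossing)
  n_bins <- floor(acq$dwell * 1e3 / acq$bin)
  dur_bins <- max(1L, round(spike_duration / acq$bin))

  binned <- list(); rows <- list(); pid <- 0L
  for (k in seq_len(n_cross)) {
    bulk_shape <- .shape_at(basis, bulk, k, y_pos)
    spike_shape <- .shape_at(basis, spike, k, y_pos)
    occ <- .dens_um3(bulk$concentration) * acq$detection_volume
    units_mean <- sum(as.numeric(names(bulk$labeled_units)) *
                        bulk$labeled_units)
    for (j in seq_along(y_pos)) {
      pid <- pid + 1L
      bulk_rate <- acq$background_rate +
        occ * units_mean * bulk$brightness * bulk_shape[j]
      tr <- rpois(n_bins, bulk_rate * acq$bin)
      sp_rate <- .dens_um3(spike$concentration) * v *
        acq$detection_area * spike_shape[j]
      n_sp <- rpois(1, sp_rate * acq$dwell)
      if (n_sp > 0) {
        starts <- sample.int(max(n_bins - dur_bins, 1), n_sp, replace = TRUE)
        for (s0 in starts) {
          idx <- s0:(s0 + dur_bins - 1L)
          tr[idx] <- tr[idx] + rpois(dur_bins, spike_amplitude * acq$bin)
        }
      }
      binned[[pid]] <- tr
      rows[[pid]] <- data.frame(
        position_id = pid, coordinate = lay$offsets[k] + y_pos[j],
        crossing = k, expected_spikes = sp_rate * acq$dwell,
        n_spikes = n_sp, bulk_rate = bulk_rate)
    }
  }
  structure(list(binned = binned, positions = do.call(rbind, rows),
                 layout = lay, acq = acq),
            class = "sm_spike_scan")
}
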