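#' Split a binned trace into rare bright spikes and bulk signal
#'
#' Large assemblies (fibrils, clusters) transiting the confocal volume
#' produce count-rate spikes far above the bulk (monomer) level. The binned
#' trace is smoothed with a Savitzky--Golay filter and maximal runs above the
#' rate threshold, padded by one window on each side, are attributed to the
#' large species; the remainder forms the bulk signal.
#'
#' @param binned Numeric vector of photon counts per 1-ms bin (so values are
#'   in photons/ms = kHz).
#' @param rate_threshold Count-rate threshold in kHz (e.g. 250 for fibrils
#'   over a nanomolar monomer background).
#' @param smooth_window Savitzky--Golay window in bins (odd, > order).
#' @param smooth_order Savitzky--Golay polynomial order.
#' @return An object of class `split_trace`: `spike_segments` (data.frame
#'   `start`, `end`, bin indices, disjoint), `n_spikes`, `bulk_series`
#'   (binned values with spike bins removed), `bulk_mean` (kHz),
#'   `threshold`, `smoothing`.
#' @export
split_trace_by_threshold <- function(binned, rate_threshold,
                                     smooth_window = 11, smooth_order = 3) {
  if (rate_threshold <= 0) stop("`rate_threshold` must be positive (kHz)")
  if (smooth_window %% 2 == 0 || smooth_window <= smooth_order) {
    stop("`smooth_window` must be odd and greater than `smooth_order`")
  }
  n <- length(binned)
  if (smooth_window >= n) stop("smoothing window must be shorter than the trace")
  sm <- signal::sgolayfilt(binned, p = smooth_order, n = smooth_window)
  above <- sm > rate_threshold
  segs <- .runs_true(above)
  if (nrow(segs)) {
    segs$start <- pmax(segs$start - smooth_window, 1L)
    segs$end <- pmin(segs$end + smooth_window, n)
    segs <- .merge_runs(segs)
  }
  spike_bins <- if (nrow(segs)) {
    unlist(mapply(seq, segs$start, segs$end, SIMPLIFY = FALSE))
  } else integer(0)
  bulk <- if (length(spike_bins)) binned[-spike_bins] else binned
  structure(list(spike_segments = segs, n_spikes = nrow(segs),
                 bulk_series = bulk,
                 bulk_mean = if (length(bulk)) mean(bulk) else NA_real_,
                 threshold = rate_threshold,
                 smoothing = list(window = smooth_window,
                                  order = smooth_order)),
            class = "split_trace")
}

#' @export
print.split_trace <- function(x, ...) {
  cat(sprintf(
    "Split trace: %d spike segment(s) above %.4g kHz, bulk mean %.4g kHz over %d bins\n",
    x$n_spikes, x$threshold, x$bulk_mean, length(x$bulk_series)))
  invisible(x)
}

## maximal runs of TRUE -> data.frame(start, end)
.runs_true <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

## merge overlapping/adjacent [start, end] runs
.merge_runs <- function(segs) {
  if (nrow(segs) < 2) return(segs)
  segs <- segs[order(segs$start), ]
  out <- segs[1, ]
  for (i in 2:nrow(segs)) {
    j <- nrow(out)
    if (segs$start[i] <= out$end[j] + 1L) {
      out$end[j] <- max(out$end[j], segs$end[i])
    } else {
      out <- rbind(out, segs[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

#' Detect nanocluster events in a binned trace
#'
#' Events are maximal runs of 1-ms bins exceeding the bulk level by `k_sd`
#' standard deviations. Bulk mean and sd are estimated robustly (median and
#' 1.4826 x MAD) so that the rare events themselves do not inflate the
#' threshold.
#'
#' @param binned Photon counts per 1-ms bin.
#' @param k_sd Threshold in robust standard deviations above the bulk
#'   (default 5).
#' @return List: `events` (data.frame `start`, `end` bin indices), `n`
#'   (event count), `threshold` (kHz), `bulk_mean`, `bulk_sd`.
#' @export
detect_cluster_events <- function(binned, k_sd = 5) {
  if (length(binned) < 10) stop("trace too short to estimate bulk statistics")
  m <- median(binned)
  s <- mad(binned)
  if (s == 0) stop("degenerate statistics: zero variance in binned trace")
  thr <- m + k_sd * s
  segs <- .runs_true(binned > thr)
  list(events = segs, n = nrow(segs), threshold = thr,
       bulk_mean = m, bulk_sd = s)
}

#' Gaussian peak fits of per-position event histograms
#'
#' Fits an independent Gaussian to the event-count histogram of each
#' crossing. The diffusion distance of the cluster population at that
#' crossing is half the full width at half maximum of the fitted peak
#' (FWHM = 2 sqrt(2 log 2) sigma).
#'
#' @param events_per_position Data.frame with columns `coordinate` (um),
#'   `count`, `crossing`.
#' @param min_positions Crossings with fewer informative (nonzero) positions
#'   are excluded and flagged.
#' @return Data.frame with one row per fitted crossing: `crossing`, `mean`,
#'   `sigma`, `fwhm`, `distance` (= fwhm/2, um). Excluded crossings are
#'   listed in attribute `"excluded"`.
#' @export
fit_position_peaks <- function(events_per_position, min_positions = 3) {
  stopifnot(all(c("coordinate", "count", "crossing") %in%
                  names(events_per_position)))
  ks <- sort(unique(events_per_position$crossing))
  rows <- list(); excluded <- integer(0)
  for (k in ks) {
    d <- events_per_position[events_per_position$crossing == k, ]
    if (sum(d$count > 0) < min_positions) { excluded <- c(excluded, k); next }
    mu0 <- sum(d$coordinate * d$count) / sum(d$count)
    s0 <- sqrt(sum(d$count * (d$coordinate - mu0)^2) / sum(d$count))
    if (s0 <= 0) { excluded <- c(excluded, k); next }
    fit <- tryCatch(
      minpack.lm::nlsLM(count ~ a * exp(-(coordinate - mu)^2 / (2 * sig^2)),
                        data = d,
                        start = list(a = max(d$count), mu = mu0, sig = s0),
                        lower = c(0, min(d$coordinate), 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) { excluded <- c(excluded, k); next }
    cf <- coef(fit)
    sig <- abs(cf[["sig"]])
    fwhm <- 2 * sqrt(2 * log(2)) * sig
    rows[[length(rows) + 1L]] <- data.frame(
      crossing = k, mean = cf[["mu"]], sigma = sig, fwhm = fwhm,
      distance = fwhm / 2)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(crossing = integer(0), mean = numeric(0), sigma = numeric(0),
               fwhm = numeric(0), distance = numeric(0))
  attr(out, "excluded") <- excluded
  out
}

#' Fit diffusion distances with the one-dimensional Fick broadening law
#'
#' The diffusion distance grows as \eqn{x \approx \sqrt{2 D t}} with
#' residence time. The width at the zero-time crossing is used for
#' normalisation: by default net distances are formed in quadrature,
#' \eqn{x_{net}(t) = \sqrt{x(t)^2 - x(0)^2}} (Gaussian-convolution model of
#' the finite inlet width); linear subtraction is available as an
#' alternative. `D` is then fitted by least squares of
#' \eqn{x_{net} = \sqrt{2 D t}} and converted to a hydrodynamic radius.
#'
#' @param distances Diffusion distances x(t) in um, one per time point
#'   (including the t = 0 reference).
#' @param times Residence times in seconds (same length; one entry must be 0).
#' @param cond A [solvent_conditions()].
#' @param normalization `"quadrature"` (default) or `"linear"`.
#' @return An object of class `fick_fit`: `d` (m^2/s), `r_h` (nm), `x_net`
#'   (um), `times` (s), `normalization`.
#' @export
fick_fit <- function(distances, times, cond = solvent_conditions(),
                     normalization = c("quadrature", "linear")) {
  normalization <- match.arg(normalization)
  cond <- .check_cond(cond)
  if (length(distances) != length(times)) stop("length mismatch")
  if (!any(times == 0)) stop("a t = 0 reference point is required")
  x0 <- distances[times == 0][1]
  sel <- times > 0
  if (sum(sel) < 2) stop("need at least two strictly positive time points")
  t_s <- times[sel]
  x_net <- switch(normalization,
    quadrature = sqrt(pmax(distances[sel]^2 - x0^2, 0)),
    linear = pmax(distances[sel] - x0, 0))
  if (all(x_net <= 0)) {
    stop("no broadening: all distances at or below the zero-time width")
  }
  x_m <- x_net * 1e-6
  obj <- function(logD) sum((x_m - sqrt(2 * exp(logD) * t_s))^2)
  opt <- optimize(obj, interval = log(c(1e-18, 1e-6)))
  d <- exp(opt$minimum)
  structure(list(d = d,
                 r_h = hydrodynamic_radius(d, cond) * 1e9,
                 x_net = x_net, times = t_s,
                 normalization = normalization),
            class = "fick_fit")
}

#' @export
print.fick_fit <- function(x, ...) {
  cat(sprintf("Fick broadening fit: D = %.4g m^2/s, R_H = %.4g nm (%s normalization)\n",
              x$d, x$r_h, x$normalization))
  invisible(x)
}

#' Particle flux from a digital event count
#'
#' @param n_events Number of detected events.
#' @param observation_time Total observation time in seconds.
#' @param detection_efficiency Fraction of particles passing the channel
#'   that are detected by the scanned confocal volume. This geometric
#'   conversion factor is chip- and scan-specific and must be supplied
#'   explicitly; it is never defaulted.
#' @return Flux in particles per second.
#' @export
cluster_flux <- function(n_events, observation_time, detection_efficiency) {
  if (missing(detection_efficiency)) {
    stop("`detection_efficiency` must be supplied explicitly ",
         "(geometric conversion from counted events to channel flux)")
  }
  if (observation_time <= 0) stop("`observation_time` must be positive (s)")
  if (detection_efficiency <= 0 || detection_efficiency > 1) {
    stop("`detection_efficiency` must lie in (0, 1]")
  }
  (n_events / observation_time) / detection_efficiency
}

.N_A <- 6.02214076e23

#' Particle concentration from flux and flow rate
#'
#' `c = F / (Q N_A)`: every particle in the flowing volume passes the
#' detection cross-section, so the number flux divided by the volumetric
#' flow rate gives the number concentration.
#'
#' @param flux Particle flux in 1/s.
#' @param flow A [flow_settings()] (or flow rate in uL/h).
#' @return Concentration in pM.
#' @export
cluster_concentration <- function(flux, flow) {
  if (flux < 0) stop("`flux` must be nonnegative")
  q <- if (inherits(flow, "flow_settings")) flow$total_flow_rate else flow
  if (q <= 0) stop("flow rate must be positive")
  q_l_s <- q * 1e-6 / 3600
  flux / (q_l_s * .N_A) * 1e12
}

#' Volume fraction occupied by spherical particles
#'
#' `phi = c N_A (4/3) pi r^3` in consistent units.
#'
#' @param concentration Particle concentration in pM.
#' @param radius Particle radius in nm.
#' @return Dimensionless volume fraction.
#' @export
volume_fraction <- function(concentration, radius) {
  if (any(concentration < 0)) stop("`concentration` must be nonnegative")
  if (any(radius <= 0)) stop("`radius` must be positive")
  c_m3 <- concentration * 1e-12 * 1e3          # pM -> mol/m^3
  c_m3 * .N_A * (4 / 3) * pi * (radius * 1e-9)^3
}

#' Monomer copies per cluster from volume ratios
#'
#' Bounds the number of monomer units per cluster by the cube of the radius
#' ratio scaled by the protein packing fraction inside the cluster. The
#' pure-protein ceiling (packing fraction 1) is reported alongside; dilute
#' condensates typically pack 10--35% protein by volume.
#'
#' @param r_cluster Cluster radius (nm).
#' @param r_monomer Monomer radius (nm).
#' @param packing_fraction_range Two packing fractions in (0, 1] giving the
#'   lower and upper bound (default `c(0.10, 0.35)`).
#' @return List: `lower`, `upper`, `ceiling` (packing = 1), unrounded.
#' @export
monomers_per_cluster <- function(r_cluster, r_monomer,
                                 packing_fraction_range = c(0.10, 0.35)) {
  if (r_cluster <= 0 || r_monomer <= 0) stop("radii must be positive")
  pf <- sort(packing_fraction_range)
  if (any(pf <= 0) || any(pf > 1)) {
    stop("packing fractions must lie in (0, 1]")
  }
  ratio3 <- (r_cluster / r_monomer)^3
  list(lower = pf[1] * ratio3, upper = pf[2] * ratio3, ceiling = ratio3)
}

#' End-to-end nanocluster characterisation
#'
#' Combines per-position event histograms, Gaussian peak fitting, the Fick
#' broadening fit, and the digital count-to-concentration conversion into a
#' single report.
#'
#' @param events_per_position Data.frame (`coordinate`, `count`, `crossing`).
#' @param crossing_times Residence times (s) of the crossings, first = 0.
#' @param cond A [solvent_conditions()].
#' @param flow A [flow_settings()].
#' @param observation_time Total step-scan observation time (s).
#' @param detection_efficiency See [cluster_flux()].
#' @param normalization Passed to [fick_fit()].
#' @return An object of class `cluster_result`: event counts, per-crossing
#'   peak fits, the x--t table, `d`, `r_h` (nm), `n_events`, `flux` (1/s),
#'   `concentration` (pM), `volume_fraction`.
#' @export
cluster_pipeline <- function(events_per_position, crossing_times,
                             cond = solvent_conditions(),
                             flow = flow_settings(60),
                             observation_time, detection_efficiency,
                             normalization = "quadrature") {
  peaks <- fit_position_peaks(events_per_position)
  if (nrow(peaks) < 3) stop("need >= 3 fitted crossings for the Fick fit")
  times <- crossing_times[peaks$crossing]
  ff <- fick_fit(peaks$distance, times, cond, normalization)
  n_events <- sum(events_per_position$count)
  fl <- cluster_flux(n_events, observation_time, detection_efficiency)
  conc <- cluster_concentration(fl, flow)
  structure(list(
    peak_fits = peaks,
    xt = data.frame(time = times, distance = peaks$distance),
    d = ff$d, r_h = ff$r_h,
    n_events = n_events, flux = fl, concentration = conc,
    volume_fraction = volume_fraction(conc, ff$r_h),
    fick = ff), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Nanocluster analysis: R_H = %.4g nm (D = %.3g m^2/s)\n",
              x$r_h, x$d))
  cat(sprintf("  N = %d events, F = %.4g /s, c = %.4g pM, phi = %.4g\n",
              x$n_events, x$flux, x$concentration, x$volume_fraction))
  invisible(x)
}
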