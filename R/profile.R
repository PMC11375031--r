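#' Diffusion profile
#'
#' Signal versus transverse chip coordinate across the scanned channel
#' crossings: binned fluorescence intensity (continuous mode, photons/ms) or
#' digital molecule counts (step mode).
#'
#' @param coordinates Strictly increasing chip coordinates (um).
#' @param values Nonnegative signal values (photons/ms or counts).
#' @param mode `"continuous"` or `"step"`.
#' @param crossing Integer crossing index per point. Default: single crossing.
#' @return An object of class `diffusion_profile` (a data.frame with columns
#'   `coordinate`, `value`, `crossing` and a `mode` attribute).
#' @export
diffusion_profile <- function(coordinates, values,
                              mode = c("step", "continuous"),
                              crossing = rep(1L, length(coordinates))) {
  mode <- match.arg(mode)
  if (length(coordinates) != length(values) ||
      length(crossing) != length(values)) {
    stop("coordinate, value and crossing lengths differ")
  }
  if (length(coordinates) && is.unsorted(coordinates, strictly = TRUE)) {
    stop("coordinates must be strictly increasing")
  }
  if (any(values < 0)) stop("profile values must be nonnegative")
  df <- data.frame(coordinate = coordinates, value = values,
                   crossing = as.integer(crossing))
  class(df) <- c("diffusion_profile", "data.frame")
  attr(df, "mode") <- mode
  df
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat(sprintf("Diffusion profile (%s mode): %d points, %d crossing(s), total signal %.4g\n",
              attr(x, "mode"), nrow(x), length(unique(x$crossing)),
              sum(x$value)))
  invisible(x)
}

#' @export
plot.diffusion_profile <- function(x, ...) {
  plot(x$coordinate, x$value, type = "h", xlab = "chip coordinate (um)",
       ylab = if (attr(x, "mode") == "step") "molecules" else "photons/ms",
       ...)
  invisible(x)
}

#' Build a diffusion profile from a continuous scan
#'
#' Bins the photon record of a constant-speed scan into time intervals and
#' maps bin midpoints onto chip coordinates.
#'
#' @param trace A [photon_trace()] covering the whole scan, or a numeric
#'   vector of pre-binned photon counts per bin.
#' @param scan_speed Stage speed in um/s.
#' @param bin Bin width in ms (ignored for pre-binned input unless given).
#' @param start_coordinate Chip coordinate at scan start (um).
#' @param crossing_boundaries Optional list of `c(lo, hi)` coordinate ranges
#'   (um) assigning points to crossings; points outside all ranges (channel
#'   walls) are dropped. Default: one crossing covering the scan.
#' @return A `diffusion_profile` in continuous mode, values in photons/ms.
#' @export
profile_from_continuous <- function(trace, scan_speed, bin = 1,
                                    start_coordinate = 0,
                                    crossing_boundaries = NULL) {
  if (scan_speed <= 0) stop("`scan_speed` must be positive (um/s)")
  if (bin <= 0) stop("`bin` must be positive (ms)")
  if (inherits(trace, "photon_trace")) {
    n_bins <- floor(trace$duration * 1e3 / bin)
    if (n_bins < 1) stop("trace shorter than one bin")
    edges <- seq(0, n_bins * bin, by = bin) * 1e-3
    counts <- tabulate(findInterval(trace$t, edges,
                                    rightmost.closed = TRUE), n_bins)
  } else {
    counts <- as.numeric(trace)
    n_bins <- length(counts)
  }
  mid_s <- (seq_len(n_bins) - 0.5) * bin * 1e-3
  coord <- start_coordinate + scan_speed * mid_s
  value <- counts / bin
  .assign_crossings(coord, value, "continuous", crossing_boundaries)
}

#' Build a diffusion profile from a step scan
#'
#' Runs the burst search at every position and plots the number of counted
#' molecules against chip position. When dwell times differ between
#' positions, counts are normalised to the shortest dwell so the profile
#' stays comparable across positions (kept as raw integer counts whenever
#' dwell times are uniform, preserving Poisson statistics for weighting).
#'
#' @param traces List of [photon_trace()] objects with coordinates set, or a
#'   data.frame as returned by [count_molecules()].
#' @param params A [burst_search_params()] (ignored for pre-counted input).
#' @param crossing_boundaries Optional list of coordinate ranges, as in
#'   [profile_from_continuous()].
#' @return A `diffusion_profile` in step mode.
#' @export
profile_from_step <- function(traces, params = burst_search_params(),
                              crossing_boundaries = NULL) {
  counts <- if (is.data.frame(traces)) traces
            else count_molecules(traces, params)
  if (nrow(counts) < 2) stop("need at least two scan positions")
  if (any(is.na(counts$coordinate))) {
    stop("traces must carry chip coordinates")
  }
  o <- order(counts$coordinate)
  counts <- counts[o, ]
  value <- counts$count
  if (length(unique(counts$dwell)) > 1) {
    if (any(is.na(counts$dwell)) || any(counts$dwell <= 0)) {
      stop("dwell times required to normalise unequal dwells")
    }
    value <- counts$count / counts$dwell * min(counts$dwell)
  }
  .assign_crossings(counts$coordinate, value, "step", crossing_boundaries)
}

.assign_crossings <- function(coord, value, mode, crossing_boundaries) {
  if (is.null(crossing_boundaries)) {
    return(diffusion_profile(coord, value, mode))
  }
  cross <- rep(NA_integer_, length(coord))
  for (k in seq_along(crossing_boundaries)) {
    b <- crossing_boundaries[[k]]
    cross[coord >= b[1] & coord <= b[2]] <- k
  }
  keep <- !is.na(cross)
  diffusion_profile(coord[keep], value[keep], mode, cross[keep])
}

#' Rebin a diffusion profile
#'
#' Groups `factor` consecutive points per crossing: step-mode counts are
#' summed (total molecule count is conserved), continuous-mode intensities
#' are averaged. A trailing group shorter than `factor` is kept.
#'
#' @param profile A `diffusion_profile`.
#' @param factor Positive integer grouping factor.
#' @return A rebinned `diffusion_profile`.
#' @export
rebin_profile <- function(profile, factor) {
  if (factor < 1 || factor != round(factor)) {
    stop("`factor` must be a positive integer")
  }
  factor <- as.integer(factor)
  if (factor > nrow(profile)) stop("`factor` exceeds profile length")
  if (factor == 1L) return(profile)
  mode <- attr(profile, "mode")
  pieces <- lapply(split(seq_len(nrow(profile)), profile$crossing),
                   function(idx) {
    g <- (seq_along(idx) - 1L) %/% factor
    co <- tapply(profile$coordinate[idx], g, mean)
    va <- if (mode == "step") tapply(profile$value[idx], g, sum)
          else tapply(profile$value[idx], g, mean)
    data.frame(coordinate = as.numeric(co), value = as.numeric(va),
               crossing = profile$crossing[idx][1])
  })
  df <- do.call(rbind, pieces)
  df <- df[order(df$coordinate), ]
  diffusion_profile(df$coordinate, df$value, mode, df$crossing)
}
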