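#' Photon timestamp trace at one scan position
#'
#' Raw digital signal of a step-scan acquisition: strictly increasing photon
#' arrival times recorded at one confocal position. Timestamps may be given
#' either in seconds or as integer timer ticks (16 ps resolution, the native
#' resolution of time-tagged photon counting hardware).
#'
#' @param timestamps Photon arrival times in seconds (sorted, strictly
#'   increasing), or integer ticks when `unit = "ticks"`.
#' @param duration Trace duration in seconds; all timestamps must lie in
#'   `[0, duration]`.
#' @param position_id Integer index of the scan position.
#' @param coordinate Transverse chip coordinate of the position (um).
#' @param unit `"seconds"` or `"ticks"` (1 tick = 16 ps).
#' @return An object of class `photon_trace`.
#' @export
photon_trace <- function(timestamps, duration, position_id = 1L,
                         coordinate = NA_real_,
                         unit = c("seconds", "ticks")) {
  unit <- match.arg(unit)
  t <- if (unit == "ticks") as.numeric(timestamps) * 16e-12
       else as.numeric(timestamps)
  if (length(t) && (is.unsorted(t, strictly = TRUE))) {
    stop("timestamps must be strictly increasing")
  }
  if (duration <= 0) stop("`duration` must be positive (seconds)")
  if (length(t) && (t[1] < 0 || t[length(t)] > duration)) {
    stop("timestamps must lie within [0, duration]")
  }
  structure(list(t = t, duration = duration,
                 position_id = as.integer(position_id),
                 coordinate = coordinate),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("Photon trace: %d photons over %.3g s at position %d (%.4g um)\n",
              length(x$t), x$duration, x$position_id, x$coordinate))
  invisible(x)
}

#' Burst-search parameters
#'
#' Thresholds of the combined inter-photon-time / minimum-photon-count burst
#' search. Defaults sit at the midpoints of the ranges commonly used for
#' single-molecule confocal detection (IPT_max 0.005--0.02 ms, N_min 5--20
#' photons, Lee filter window 2--4 samples).
#'
#' @param ipt_max Maximum inter-photon time within a burst, in ms.
#' @param n_min Minimum number of photons per burst.
#' @param lee_window Window (samples) of the Lee filter applied to the
#'   inter-photon-time sequence before thresholding; 1 disables filtering.
#' @return An object of class `burst_search_params`.
#' @export
burst_search_params <- function(ipt_max = 0.01, n_min = 10, lee_window = 3) {
  if (ipt_max <= 0) stop("`ipt_max` must be positive (ms)")
  if (n_min < 1) stop("`n_min` must be >= 1")
  if (lee_window < 1) stop("`lee_window` must be >= 1")
  structure(list(ipt_max = ipt_max, n_min = as.integer(n_min),
                 lee_window = as.integer(lee_window)),
            class = "burst_search_params")
}

## rolling mean and variance with window truncation at the edges
.rolling_stats <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (window - 1L - half), n)
  cnt <- hi - lo + 1L
  m <- (cs[hi + 1L] - cs[lo]) / cnt
  v <- pmax((cs2[hi + 1L] - cs2[lo]) / cnt - m^2, 0)
  list(mean = m, var = v)
}

#' Lee filter
#'
#' Local adaptive smoother
#' \eqn{\hat s_i = \bar m_i + (s_i - \bar m_i)\,\sigma_i^2 /
#' (\sigma_i^2 + \sigma_0^2)}
#' with windowed mean \eqn{\bar m} and variance \eqn{\sigma^2}: regions of
#' constant signal are flattened towards the local mean while sharp features
#' (burst edges), where the local variance dominates the noise scale
#' \eqn{\sigma_0}, pass through nearly unchanged. Edges of the series are
#' handled by window truncation.
#'
#' @param series Numeric sequence.
#' @param window Window length in samples; 1 returns the input unchanged.
#' @param sigma0 Global noise scale. Default: median windowed standard
#'   deviation of the full series.
#' @return Filtered sequence, same length as the input.
#' @export
lee_filter <- function(series, window = 3, sigma0 = NULL) {
  if (length(series) == 0) stop("empty series")
  if (window < 1) stop("`window` must be >= 1")
  if (window == 1 || length(series) == 1) return(series)
  rs <- .rolling_stats(series, window)
  if (is.null(sigma0)) sigma0 <- median(sqrt(rs$var))
  if (sigma0 == 0) return(series)
  rs$mean + (series - rs$mean) * rs$var / (rs$var + sigma0^2)
}

#' Find single-molecule bursts in a photon trace
#'
#' A burst is a maximal run of photons whose consecutive inter-photon times,
#' after Lee filtering of the IPT sequence, all stay at or below `ipt_max`,
#' containing at least `n_min` photons. Runs whose first and last photon
#' coincide in time (zero duration) are rejected. The search is fully
#' deterministic.
#'
#' @param trace A [photon_trace()].
#' @param params A [burst_search_params()].
#' @return A data.frame with one row per burst: `start` (s), `duration`
#'   (ms, last minus first photon), `n_photons`, and `normalized_intensity`
#'   (photons/ms, `n_photons / duration`). The producing parameters are
#'   attached as attribute `"params"`.
#' @export
find_bursts <- function(trace, params = burst_search_params()) {
  stopifnot(inherits(trace, "photon_trace"))
  empty <- data.frame(start = numeric(0), duration = numeric(0),
                      n_photons = integer(0),
                      normalized_intensity = numeric(0))
  attr(empty, "params") <- unclass(params)
  n <- length(trace$t)
  if (n < 2) return(empty)
  ipt_ms <- diff(trace$t) * 1e3
  f <- lee_filter(ipt_ms, params$lee_window)
  ok <- f <= params$ipt_max
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- list()
  for (j in keep) {
    i0 <- starts[j]          # first IPT index of run
    i1 <- ends[j]            # last IPT index of run
    np <- i1 - i0 + 2L       # photons spanned by the run
    if (np < params$n_min) next
    t0 <- trace$t[i0]; t1 <- trace$t[i1 + 1L]
    dur_ms <- (t1 - t0) * 1e3
    if (dur_ms <= 0) next
    out[[length(out) + 1L]] <- data.frame(
      start = t0, duration = dur_ms, n_photons = np,
      normalized_intensity = np / dur_ms)
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "params") <- unclass(params)
  res
}

#' Count molecules per scan position
#'
#' Applies the burst search to every trace of a step scan and returns the
#' number of detected single-molecule transits per position (the digital
#' readout from which step-scan diffusion profiles are built).
#'
#' @param traces List of [photon_trace()] objects, one per position;
#'   duplicate position ids are rejected as ambiguous.
#' @param params A [burst_search_params()].
#' @return Data.frame with `position_id`, `coordinate`, `count` and `dwell`
#'   (trace duration, s).
#' @export
count_molecules <- function(traces, params = burst_search_params()) {
  ids <- vapply(traces, function(tr) tr$position_id, integer(1))
  if (anyDuplicated(ids)) {
    stop("duplicate position ids: concatenate traces per position first")
  }
  data.frame(
    position_id = ids,
    coordinate = vapply(traces, function(tr) tr$coordinate, numeric(1)),
    count = vapply(traces, function(tr) nrow(find_bursts(tr, params)),
                   numeric(1)),
    dwell = vapply(traces, function(tr) tr$duration, numeric(1)))
}

#' Concatenate photon traces recorded at the same position
#'
#' Appends `b` after `a`, shifting its timestamps by the duration of `a`.
#'
#' @param a,b [photon_trace()] objects with equal position ids.
#' @return A single `photon_trace`.
#' @export
concat_traces <- function(a, b) {
  if (a$position_id != b$position_id) {
    stop("traces were recorded at different positions")
  }
  photon_trace(c(a$t, b$t + a$duration), a$duration + b$duration,
               a$position_id, a$coordinate)
}
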