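## Resample one basis crossing profile onto within-crossing coordinates (um).
## Outside the simulated width the concentration is zero.
.resample_row <- function(y_um, prof_row, y_local) {
  approx(y_um, prof_row, xout = y_local, yleft = 0, yright = 0)$y
}

## Map concatenated chip coordinates to within-crossing transverse
## coordinates. Offsets: chip coordinate of the left channel edge per
## crossing; by default each scanned crossing is assumed centred on the
## channel (offset = mean(coord) - W/2).
.local_coords <- function(profile, width, crossing_offsets = NULL) {
  ks <- sort(unique(profile$crossing))
  y_local <- numeric(nrow(profile))
  offs <- numeric(length(ks))
  for (j in seq_along(ks)) {
    idx <- profile$crossing == ks[j]
    off <- if (is.null(crossing_offsets)) {
      mean(range(profile$coordinate[idx])) - width / 2
    } else crossing_offsets[j]
    offs[j] <- off
    y_local[idx] <- profile$coordinate[idx] - off
  }
  list(y_local = y_local, crossings = ks, offsets = offs)
}

## Weighted least squares of value ~ a * sim + b with a >= 0.
## Returns list(a, b, sse, fitted).
.ls_amp <- function(sim, value, w) {
  sw <- sum(w)
  sx <- sum(w * sim); sy <- sum(w * value)
  sxx <- sum(w * sim^2); sxy <- sum(w * sim * value)
  det <- sw * sxx - sx^2
  if (det <= 0) {
    a <- 0; b <- sy / sw
  } else {
    a <- (sw * sxy - sx * sy) / det
    b <- (sy - a * sx) / sw
    if (a < 0) { a <- 0; b <- sy / sw }
  }
  fitted <- a * sim + b
  list(a = a, b = b, sse = sum(w * (value - fitted)^2), fitted = fitted)
}

## sse over every basis grid node (matrix of resampled sims precomputed)
.grid_sse <- function(sims, value, w) {
  apply(sims, 1, function(s) .ls_amp(s, value, w)$sse)
}

## Interpolated basis profiles at radius r, resampled per point
.sim_at <- function(basis, r, y_local, crossing_of_point, crossings) {
  prof <- interpolate_profile(basis, r)
  s <- numeric(length(y_local))
  for (j in seq_along(crossings)) {
    idx <- crossing_of_point == crossings[j]
    s[idx] <- .resample_row(basis$y_um, prof[crossings[j], ], y_local[idx])
  }
  s
}

#' Global least-squares fit of a diffusion profile against a basis library
#'
#' Finds the hydrodynamic radius whose simulated diffusion profile, scaled by
#' a common nonnegative amplitude plus baseline, minimises the weighted sum
#' of squared residuals jointly over all scanned crossings. The radius is
#' refined beyond the grid by parabolic interpolation of the error surface
#' over the three best neighbouring nodes (ties broken towards the smaller
#' radius, deterministically). Step-mode profiles are weighted by Poisson
#' counting noise (`w = 1/max(value, 1)`); continuous-mode profiles
#' uniformly.
#'
#' @param profile A [diffusion_profile()].
#' @param basis A [simulate_basis()] library.
#' @param weights Optional numeric vector of per-point weights, overriding
#'   the mode-based default. Uniform rescaling leaves the fit unchanged.
#' @param weight_iterations For step-mode profiles with default weights, the
#'   Poisson weights are re-derived from the fitted model this many times
#'   (Pearson-style `w = 1/max(fitted, 1)`), which removes the small-count
#'   bias of weighting by the observed values. Ignored when `weights` is
#'   supplied.
#' @param crossing_offsets Optional chip coordinates (um) of the left channel
#'   edge for each crossing present in the profile; by default each crossing
#'   is assumed centred on the channel.
#' @param compute_errors Compute the global uncertainty and per-crossing
#'   local radius errors (default `TRUE`).
#' @return An object of class `smmds_fit` with elements `r_h` (nm), `d`
#'   (m^2/s), `amplitude`, `baseline`, `sse`, `r_h_error` (symmetric +/-
#'   range, nm), `local_errors` (per-crossing nm deviations), `at_boundary`,
#'   plus bookkeeping needed by its methods.
#' @seealso [fit_uncertainty()], [local_radius_error()]
#' @export
global_fit <- function(profile, basis, weights = NULL,
                       crossing_offsets = NULL, compute_errors = TRUE,
                       weight_iterations = 2) {
  stopifnot(inherits(profile, "diffusion_profile"),
            inherits(basis, "basis_library"))
  if (all(profile$value == 0)) stop("no signal: profile is identically zero")
  n_sig <- tapply(profile$value, profile$crossing, function(v) any(v > 0))
  if (sum(n_sig) < 2) stop("need signal in at least two crossings")

  mode <- attr(profile, "mode")
  w <- if (!is.null(weights)) weights
       else if (mode == "step") 1 / pmax(profile$value, 1)
       else rep(1, nrow(profile))
  if (length(w) != nrow(profile) || any(w <= 0)) {
    stop("weights must be positive, one per profile point")
  }

  width <- max(basis$y_um)
  lc <- .local_coords(profile, width, crossing_offsets)
  if (any(lc$crossings > length(basis$crossing_times_s))) {
    stop("profile references a crossing not present in the basis")
  }

  ## resample every grid node onto the profile coordinates
  n_nodes <- length(basis$rh_nm)
  sims <- matrix(0, n_nodes, nrow(profile))
  for (i in seq_len(n_nodes)) {
    for (j in seq_along(lc$crossings)) {
      k <- lc$crossings[j]
      idx <- profile$crossing == k
      sims[i, idx] <- .resample_row(basis$y_um, basis$profiles[i, k, ],
                                    lc$y_local[idx])
    }
  }
  fit_once <- function(w, warn_boundary = TRUE) {
    sse_grid <- .grid_sse(sims, profile$value, w)
    i_best <- which(sse_grid == min(sse_grid))[1]  # tie -> smallest radius
    at_boundary <- i_best == 1L || i_best == n_nodes
    sse_fun <- function(r) {
      .ls_amp(.sim_at(basis, r, lc$y_local, profile$crossing, lc$crossings),
              profile$value, w)$sse
    }
    if (!at_boundary) {
      ## continuous refinement between the neighbours of the best node, on
      ## the log-interpolated basis (the error surface is piecewise smooth
      ## with kinks at the grid nodes, so a plain three-point parabola is
      ## not accurate enough)
      opt <- optimize(function(lr) sse_fun(exp(lr)),
                      interval = log(basis$rh_nm[c(i_best - 1, i_best + 1)]),
                      tol = 1e-6)
      r_hat <- exp(opt$minimum)
    } else {
      r_hat <- basis$rh_nm[i_best]
      if (warn_boundary) {
        warning("fitted radius lies at the basis grid boundary")
      }
    }
    sim_hat <- .sim_at(basis, r_hat, lc$y_local, profile$crossing,
                       lc$crossings)
    ls <- .ls_amp(sim_hat, profile$value, w)
    if (ls$sse > sse_grid[i_best]) {      # guard: keep grid node if better
      r_hat <- basis$rh_nm[i_best]
      ls <- .ls_amp(sims[i_best, ], profile$value, w)
    }
    list(r_hat = r_hat, ls = ls, sse_grid = sse_grid, i_best = i_best,
         at_boundary = at_boundary, w = w)
  }

  res <- fit_once(w, warn_boundary = FALSE)
  if (is.null(weights) && mode == "step" && weight_iterations > 0) {
    for (it in seq_len(weight_iterations)) {
      res <- fit_once(1 / pmax(res$ls$fitted, 1),
                      warn_boundary = it == weight_iterations)
    }
  } else if (res$at_boundary) {
    warning("fitted radius lies at the basis grid boundary")
  }
  r_hat <- res$r_hat; ls <- res$ls
  sse_grid <- res$sse_grid; i_best <- res$i_best
  at_boundary <- res$at_boundary; w <- res$w

  fit <- structure(list(
    r_h = r_hat,
    d = diffusion_coefficient(r_hat * 1e-9,
                              do.call(solvent_conditions,
                                      basis$metadata$conditions)),
    amplitude = ls$a, baseline = ls$b, sse = ls$sse,
    r_h_error = NA_real_, local_errors = NULL,
    at_boundary = at_boundary,
    sse_grid = sse_grid, i_best = i_best,
    fitted_values = ls$fitted, weights = w,
    profile = profile, y_local = lc$y_local,
    crossings = lc$crossings, crossing_offsets = lc$offsets,
    mode = mode), class = "smmds_fit")

  if (compute_errors) {
    fit$r_h_error <- tryCatch(fit_uncertainty(fit, basis),
                              error = function(e) NA_real_)
    fit$local_errors <- local_radius_error(profile, basis, fit,
                                           weights = weights,
                                           crossing_offsets = crossing_offsets)
  }
  fit
}

#' Radius uncertainty from the curvature of the least-squares surface
#'
#' Second-order (Taylor) expansion of the weighted sum of squared residuals
#' about its minimum in \eqn{R_H}:
#' \eqn{\mathrm{var}(R_H) = 2\hat\sigma^2 / (d^2 SSE / dR_H^2)}, with
#' \eqn{\hat\sigma^2} estimated from the residuals. Reported as a symmetric
#' +/- range in nm.
#'
#' @param fit An [global_fit()] result.
#' @param basis The basis library used for the fit.
#' @return Half-width of the radius error range (nm).
#' @export
fit_uncertainty <- function(fit, basis) {
  stopifnot(inherits(fit, "smmds_fit"))
  if (fit$at_boundary) stop("fit at grid boundary: uncertainty undefined")
  ## finite-difference curvature of the continuous error surface at the
  ## refined minimum
  sse_at <- function(r) {
    .ls_amp(.sim_at(basis, r, fit$y_local, fit$profile$crossing,
                    fit$crossings),
            fit$profile$value, fit$weights)$sse
  }
  delta <- 0.02 * fit$r_h
  lo <- max(fit$r_h - delta, basis$rh_nm[1])
  hi <- min(fit$r_h + delta, basis$rh_nm[length(basis$rh_nm)])
  h1 <- fit$r_h - lo; h2 <- hi - fit$r_h
  s0 <- fit$sse; s_lo <- sse_at(lo); s_hi <- sse_at(hi)
  curv <- 2 * (h1 * s_hi + h2 * s_lo - (h1 + h2) * s0) /
    (h1 * h2 * (h1 + h2))
  if (!is.finite(curv) || curv <= 0) {
    stop("degenerate fit: non-positive curvature of the error surface")
  }
  n <- length(fit$fitted_values)
  p <- 3  # amplitude, baseline, radius
  sigma2 <- fit$sse / max(n - p, 1)
  sqrt(2 * sigma2 / curv)
}

#' Per-crossing local radius errors
#'
#' For each scanned crossing, the profile of that crossing alone is refitted
#' and the local error reported as the difference between the global radius
#' and the single-crossing radius. A crossing without signal yields `NA`.
#'
#' @param profile The fitted [diffusion_profile()].
#' @param basis The basis library.
#' @param fit The [global_fit()] result.
#' @param weights,crossing_offsets As in [global_fit()].
#' @return Named numeric vector, one entry per crossing (nm).
#' @export
local_radius_error <- function(profile, basis, fit, weights = NULL,
                               crossing_offsets = NULL) {
  ks <- sort(unique(profile$crossing))
  out <- setNames(rep(NA_real_, length(ks)), paste0("crossing", ks))
  for (j in seq_along(ks)) {
    idx <- profile$crossing == ks[j]
    if (!any(profile$value[idx] > 0)) next
    sub <- diffusion_profile(profile$coordinate[idx], profile$value[idx],
                             attr(profile, "mode"),
                             profile$crossing[idx])
    off <- if (is.null(crossing_offsets)) NULL else crossing_offsets[j]
    r_local <- tryCatch(
      .single_crossing_rh(sub, basis, weights = weights[idx],
                          crossing_offsets = off),
      error = function(e) NA_real_)
    out[j] <- fit$r_h - r_local
  }
  out
}

## radius from one crossing only (grid search + parabolic refinement);
## shares machinery with global_fit but skips the >= 2 crossings check
.single_crossing_rh <- function(profile, basis, weights = NULL,
                                crossing_offsets = NULL) {
  mode <- attr(profile, "mode")
  w <- if (!is.null(weights) && length(weights)) weights
       else if (mode == "step") 1 / pmax(profile$value, 1)
       else rep(1, nrow(profile))
  width <- max(basis$y_um)
  lc <- .local_coords(profile, width, crossing_offsets)
  k <- lc$crossings[1]
  sims <- t(vapply(seq_along(basis$rh_nm), function(i) {
    .resample_row(basis$y_um, basis$profiles[i, k, ], lc$y_local)
  }, numeric(nrow(profile))))
  sse_grid <- .grid_sse(sims, profile$value, w)
  i_best <- which(sse_grid == min(sse_grid))[1]
  if (i_best == 1L || i_best == length(basis$rh_nm)) {
    return(basis$rh_nm[i_best])
  }
  sse_fun <- function(r) {
    s <- .resample_row(basis$y_um, interpolate_profile(basis, r)[k, ],
                       lc$y_local)
    .ls_amp(s, profile$value, w)$sse
  }
  opt <- optimize(function(lr) sse_fun(exp(lr)),
                  interval = log(basis$rh_nm[c(i_best - 1, i_best + 1)]),
                  tol = 1e-6)
  exp(opt$minimum)
}

#' @export
print.smmds_fit <- function(x, ...) {
  err <- if (is.finite(x$r_h_error)) sprintf(" +/- %.3g", x$r_h_error) else ""
  cat(sprintf("smMDS global fit: R_H = %.4g%s nm (D = %.4g m^2/s)\n",
              x$r_h, err, x$d))
  cat(sprintf("  amplitude %.4g, baseline %.4g, SSE %.4g, %d points, %s mode\n",
              x$amplitude, x$baseline, x$sse,
              length(x$fitted_values), x$mode))
  if (x$at_boundary) cat("  warning: radius at basis grid boundary\n")
  invisible(x)
}

#' @export
summary.smmds_fit <- function(object, ...) {
  cat(sprintf("Hydrodynamic radius: %.4g nm", object$r_h))
  if (is.finite(object$r_h_error)) {
    cat(sprintf(" (+/- %.3g nm, curvature estimate)", object$r_h_error))
  }
  cat("\n")
  cat(sprintf("Diffusion coefficient: %.4g m^2/s\n", object$d))
  if (!is.null(object$local_errors)) {
    cat("Local radius errors (global - single-crossing, nm):\n")
    print(round(object$local_errors, 4))
  }
  invisible(object)
}

#' @export
coef.smmds_fit <- function(object, ...) {
  c(r_h = object$r_h, amplitude = object$amplitude,
    baseline = object$baseline)
}

#' @export
residuals.smmds_fit <- function(object, ...) {
  object$profile$value - object$fitted_values
}

#' @export
predict.smmds_fit <- function(object, ...) {
  object$fitted_values
}

#' @export
plot.smmds_fit <- function(x, ...) {
  plot(x$profile$coordinate, x$profile$value, type = "h", col = "grey40",
       xlab = "chip coordinate (um)",
       ylab = if (x$mode == "step") "molecules" else "photons/ms", ...)
  graphics::lines(x$profile$coordinate, x$fitted_values, col = "orange",
                  lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("R_H = %.3g nm", x$r_h))
  invisible(x)
}
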