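## ---- skew-normal helpers -------------------------------------------------
## density, sampler, and (mean, sd) <-> (location, scale) conversion for a
## given shape parameter alpha

#' Skew-normal density
#'
#' @param x Quantiles.
#' @param xi Location.
#' @param omega Scale (> 0).
#' @param alpha Shape (skewness; 0 recovers the normal density).
#' @return Density values.
#' @export
dskewnorm <- function(x, xi = 0, omega = 1, alpha = 0) {
  z <- (x - xi) / omega
  2 / omega * dnorm(z) * pnorm(alpha * z)
}

#' Skew-normal random deviates
#'
#' @param n Number of draws.
#' @inheritParams dskewnorm
#' @return Numeric vector of draws.
#' @export
rskewnorm <- function(n, xi = 0, omega = 1, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- abs(rnorm(n)); u1 <- rnorm(n)
  xi + omega * (delta * u0 + sqrt(1 - delta^2) * u1)
}

.sn_mean <- function(xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  xi + omega * delta * sqrt(2 / pi)
}

.sn_sd <- function(omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  omega * sqrt(1 - 2 * delta^2 / pi)
}

## solve (mean, sd, alpha) for (xi, omega)
.sn_from_moments <- function(mean, sd, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  omega <- sd / sqrt(1 - 2 * delta^2 / pi)
  list(xi = mean - omega * delta * sqrt(2 / pi), omega = omega)
}

## ---- centers and regions -------------------------------------------------

#' Oligomer region centers from the monomer brightness
#'
#' An n-mer carries n labeled monomer units, so its normalized burst
#' intensity centres at n times the monomer mean intensity.
#'
#' @param i_monomer Mean normalized intensity of the monomer (photons/ms).
#' @param n_max Largest oligomer order considered (>= 2).
#' @return Named vector of centers for n = 2..n_max (photons/ms).
#' @export
oligomer_centers <- function(i_monomer, n_max) {
  if (i_monomer <= 0) stop("`i_monomer` must be positive (photons/ms)")
  if (n_max < 2 || n_max != round(n_max)) stop("`n_max` must be an integer >= 2")
  n <- 2:n_max
  setNames(n * i_monomer, paste0(n, "mer"))
}

#' Species gating region in burst brightness
#'
#' @param label Region name.
#' @param center Region center (photons/ms).
#' @param half_width Half-width of the region (photons/ms, > 0); typically
#'   one standard deviation of the monomer brightness distribution.
#' @return An object of class `species_region`.
#' @export
species_region <- function(label, center, half_width) {
  if (half_width <= 0) stop("`half_width` must be positive")
  structure(list(label = label, center = center, half_width = half_width),
            class = "species_region")
}

#' Gating regions implied by a fitted brightness mixture
#'
#' One region per species, centred on the monomer mean and its integer
#' multiples, each one monomer standard deviation wide on either side.
#'
#' @param mixture A [fit_brightness_mixture()] result.
#' @return List of [species_region()] objects (monomer first).
#' @export
regions_from_mixture <- function(mixture) {
  centers <- c(mixture$i_monomer,
               if (mixture$n_species > 1)
                 oligomer_centers(mixture$i_monomer, mixture$n_species))
  labels <- c("monomer",
              if (mixture$n_species > 1)
                paste0(2:mixture$n_species, "mer"))
  mapply(function(l, c) species_region(l, c, mixture$sigma_monomer),
         labels, centers, SIMPLIFY = FALSE)
}

#' Select bursts whose brightness falls inside a species region
#'
#' @param bursts Burst table from [find_bursts()] (needs a
#'   `normalized_intensity` column).
#' @param region A [species_region()].
#' @return The subset of `bursts` with
#'   `|normalized_intensity - center| <= half_width`.
#' @export
gate_bursts <- function(bursts, region) {
  stopifnot(inherits(region, "species_region"))
  keep <- abs(bursts$normalized_intensity - region$center) <=
    region$half_width
  bursts[keep, , drop = FALSE]
}

## ---- mixture fitting -----------------------------------------------------

.softmax <- function(eta) {
  e <- exp(c(eta, 0) - max(c(eta, 0)))
  e / sum(e)
}

## pack/unpack: theta = (xi, log omega, alpha, eta[1..k-1]); wts are
## per-observation multiplicities (all 1 for plain data)
.mix_nll <- function(theta, x, k, wts = rep(1, length(x))) {
  w <- if (k == 1) 1 else .softmax(theta[4:(2 + k)])
  mixture_nll_cpp(x, theta[1], exp(theta[2]), theta[3], w, wts)
}

.mix_nll_grad <- function(theta, x, k, wts = rep(1, length(x))) {
  w <- if (k == 1) 1 else .softmax(theta[4:(2 + k)])
  g <- mixture_nll_grad_cpp(x, theta[1], exp(theta[2]), theta[3], w, wts)
  g[2:(2 + length(theta) - 1)]
}

.mix_init <- function(x, k, alpha0 = 3, scale0 = 1) {
  ## density peak locates the monomer; points below ~1.5x the peak set
  ## its spread; crude multinomial assignment seeds the weights
  dd <- stats::density(x, n = 512)
  mu0 <- dd$x[which.max(dd$y)] * scale0
  if (mu0 <= 0) mu0 <- median(x) * scale0
  s0 <- mad(x[x < 1.5 * mu0], center = mu0)
  if (!is.finite(s0) || s0 <= 0) s0 <- sd(x) / 2
  sn0 <- .sn_from_moments(mu0, s0, alpha0)
  w0 <- if (k == 1) 1 else {
    assign <- pmin(pmax(round(x / mu0), 1), k)
    tabulate(assign, k) / length(x)
  }
  w0 <- pmax(w0, 1e-3); w0 <- w0 / sum(w0)
  c(sn0$xi, log(sn0$omega), alpha0, if (k > 1) log(w0[-k] / w0[k]))
}

.fit_mixture_ml <- function(x, k, init = NULL, maxit = 2000,
                            reltol = 1e-12, wts = rep(1, length(x))) {
  if (is.null(init)) {
    ## multi-start: the likelihood has a spurious mode in which a wide,
    ## strongly skewed monomer component swallows the dimer; starting from
    ## several shapes and keeping the best likelihood avoids it
    starts <- list(.mix_init(x, k, 3, 1), .mix_init(x, k, 0.5, 1),
                   .mix_init(x, k, 5, 0.9))
    fits <- lapply(starts, function(s0) {
      tryCatch(.fit_mixture_ml(x, k, init = s0, maxit = maxit),
               error = function(e) NULL)
    })
    fits <- Filter(function(f) !is.null(f) && is.finite(f$nll), fits)
    if (!length(fits)) stop("mixture fit failed from all starting points")
    best <- which.min(vapply(fits, `[[`, numeric(1), "nll"))
    return(fits[[best]])
  }
  ## BFGS with the analytic gradient; Nelder-Mead as a safety net for the
  ## rare starting points where the line search stalls
  opt <- tryCatch(
    optim(init, .mix_nll, gr = .mix_nll_grad, x = x, k = k, wts = wts,
          method = "BFGS",
          control = list(maxit = maxit, reltol = reltol)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) {
    opt <- optim(init, .mix_nll, x = x, k = k, wts = wts,
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
  } else if (opt$convergence != 0) {
    opt2 <- optim(opt$par, .mix_nll, x = x, k = k, wts = wts,
                  method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-10))
    if (opt2$value <= opt$value) opt <- opt2
  }
  theta <- opt$par
  w <- if (k == 1) 1 else .softmax(theta[4:(2 + k)])
  list(theta = theta, w = w, nll = opt$value,
       convergence = opt$convergence)
}

#' Fit a brightness mixture of oligomeric states
#'
#' Maximum-likelihood fit of the normalized burst-intensity distribution with
#' a skew-normal monomer component (the skewness captures undersampling of
#' short transits) plus Gaussian oligomer components. Oligomer centers are
#' constrained to integer multiples of the fitted monomer mean intensity and
#' all oligomer standard deviations are tied to the monomer standard
#' deviation, so the model has 3 shape parameters plus the component weights
#' regardless of the number of species. Fitting uses unbinned intensities
#' (histogram binning is for display only).
#'
#' @param bursts Burst table (or numeric vector of normalized intensities,
#'   photons/ms).
#' @param n_species Number of species (monomer = 1, dimer = 2, ...).
#' @param min_bursts Minimum number of bursts required (default 200).
#' @param maxit Optimiser iteration cap.
#' @return An object of class `brightness_mixture`: `i_monomer`,
#'   `sigma_monomer` (mean and sd of the skew-normal, photons/ms), `xi`,
#'   `omega`, `alpha`, `n_species`, `oligomer_centers`, `abundances`
#'   (component weights, summing to 1), `logLik`, `n`, `convergence`.
#' @export
fit_brightness_mixture <- function(bursts, n_species,
                                   min_bursts = 200, maxit = 2000) {
  x <- if (is.numeric(bursts)) bursts else bursts$normalized_intensity
  if (length(x) < min_bursts) {
    stop(sprintf("need at least %d bursts, got %d", min_bursts, length(x)))
  }
  if (n_species < 1 || n_species != round(n_species)) {
    stop("`n_species` must be a positive integer")
  }
  k <- as.integer(n_species)
  fit <- .fit_mixture_ml(x, k, maxit = maxit)
  if (fit$convergence != 0) {
    stop("mixture fit did not converge (optim code ", fit$convergence, ")")
  }
  xi <- fit$theta[1]; omega <- exp(fit$theta[2]); alpha <- fit$theta[3]
  i1 <- .sn_mean(xi, omega, alpha)
  s1 <- .sn_sd(omega, alpha)
  structure(list(
    i_monomer = i1, sigma_monomer = s1,
    xi = xi, omega = omega, alpha = alpha,
    n_species = k,
    oligomer_centers = if (k > 1) oligomer_centers(i1, k) else numeric(0),
    abundances = setNames(fit$w, c("monomer",
                                   if (k > 1) paste0(2:k, "mer"))),
    logLik = -fit$nll, n = length(x),
    convergence = fit$convergence, theta = fit$theta),
    class = "brightness_mixture")
}

#' @export
print.brightness_mixture <- function(x, ...) {
  cat(sprintf(
    "Brightness mixture (%d species, %d bursts): I_monomer = %.4g photons/ms, sigma = %.4g photons/ms\n",
    x$n_species, x$n, x$i_monomer, x$sigma_monomer))
  cat("  abundances:",
      paste(sprintf("%s %.3f", names(x$abundances), x$abundances),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.brightness_mixture <- function(object, ...) {
  structure(object$logLik, df = 3 + object$n_species - 1,
            nobs = object$n, class = "logLik")
}

#' Mixture density implied by a fitted brightness mixture
#'
#' @param mixture A `brightness_mixture`.
#' @param x Intensities at which to evaluate (photons/ms).
#' @return Density values.
#' @export
mixture_density <- function(mixture, x) {
  d <- mixture$abundances[1] *
    dskewnorm(x, mixture$xi, mixture$omega, mixture$alpha)
  if (mixture$n_species > 1) {
    for (m in 2:mixture$n_species) {
      d <- d + mixture$abundances[m] *
        dnorm(x, m * mixture$i_monomer, mixture$sigma_monomer)
    }
  }
  d
}

#' Choose the number of oligomeric species by information criterion
#'
#' Fits the brightness mixture for each candidate species count and returns
#' the count minimising the Bayesian information criterion (the criterion is
#' reported alongside so alternatives can be inspected).
#'
#' @param bursts Burst table or numeric intensity vector.
#' @param k_range Candidate species counts.
#' @param ... Passed to [fit_brightness_mixture()].
#' @return A list of class `species_selection`: `k` (chosen count) and
#'   `table` (data.frame with `k`, `logLik`, `n_params`, `bic`).
#' @export
select_species_count <- function(bursts, k_range, ...) {
  if (!length(k_range)) stop("`k_range` must be nonempty")
  x <- if (is.numeric(bursts)) bursts else bursts$normalized_intensity
  rows <- lapply(sort(unique(as.integer(k_range))), function(k) {
    fit <- tryCatch(fit_brightness_mixture(x, k, ...),
                    error = function(e) NULL)
    if (is.null(fit)) return(data.frame(k = k, logLik = NA, n_params = NA,
                                        bic = Inf))
    p <- 3 + k - 1
    data.frame(k = k, logLik = fit$logLik, n_params = p,
               bic = -2 * fit$logLik + p * log(length(x)))
  })
  tab <- do.call(rbind, rows)
  structure(list(k = tab$k[which.min(tab$bic)], table = tab),
            class = "species_selection")
}

#' @export
print.species_selection <- function(x, ...) {
  cat("Species-count selection (BIC):\n")
  print(x$table, row.names = FALSE)
  cat("selected k =", x$k, "\n")
  invisible(x)
}

## component density matrix (n x k) at fixed shape parameters
.component_densities <- function(mixture, x) {
  k <- mixture$n_species
  dens <- matrix(0, length(x), k)
  dens[, 1] <- dskewnorm(x, mixture$xi, mixture$omega, mixture$alpha)
  if (k > 1) {
    for (m in 2:k) {
      dens[, m] <- dnorm(x, m * mixture$i_monomer, mixture$sigma_monomer)
    }
  }
  dens
}

## EM for mixture weights with fixed component densities and per-point
## multiplicities cnt (a multinomial bootstrap draw)
.em_weights <- function(dens, cnt, w0, tol = 1e-9, maxiter = 300) {
  n <- sum(cnt)
  w <- w0
  for (i in seq_len(maxiter)) {
    num <- sweep(dens, 2, w, `*`)
    resp <- num / pmax(rowSums(num), 1e-300)
    w_new <- colSums(resp * cnt) / n
    if (max(abs(w_new - w)) < tol) return(w_new)
    w <- w_new
  }
  w
}

#' Bootstrap confidence intervals for species abundances
#'
#' Percentile bootstrap over burst resampling. Each replicate resamples the
#' bursts with replacement and refits the full mixture (warm-started at the
#' full-data estimate), so the intervals reflect both counting noise and
#' the uncertainty of the monomer brightness calibration. A faster
#' `refit = "weights"` variant refits only the component weights by EM with
#' the shape parameters fixed; it understates the abundance uncertainty of
#' strongly overlapping components and is meant for quick exploration.
#' Fully reproducible under a fixed seed.
#'
#' @param mixture The full-data [fit_brightness_mixture()] result.
#' @param bursts The burst table (or intensity vector) that produced it.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param level Confidence level (default 0.99).
#' @param seed Integer seed.
#' @param refit `"full"` (default) or `"weights"`.
#' @param maxit Optimiser iteration cap per replicate for `refit = "full"`.
#' @return Matrix with one row per species and columns `lower`, `upper`.
#' @export
abundance_ci <- function(mixture, bursts, n_boot = 1000, level = 0.99,
                         seed = 1L, refit = c("full", "weights"),
                         maxit = 400) {
  refit <- match.arg(refit)
  x <- if (is.numeric(bursts)) bursts else bursts$normalized_intensity
  if (n_boot < 100) stop("`n_boot` must be >= 100")
  if (length(x) < 2 * mixture$n_species + 2) {
    stop("too few bursts to resample")
  }
  set.seed(seed)
  k <- mixture$n_species
  boots <- matrix(NA_real_, n_boot, k)
  if (refit == "weights") {
    dens <- .component_densities(mixture, x)
    n <- length(x)
    for (b in seq_len(n_boot)) {
      cnt <- tabulate(sample.int(n, replace = TRUE), n)
      boots[b, ] <- .em_weights(dens, cnt, mixture$abundances)
    }
  } else {
    n <- length(x)
    for (b in seq_len(n_boot)) {
      ## multinomial resample expressed as multiplicities over the ~63%
      ## distinct points; warm-started refits converge in a handful of
      ## BFGS steps, and a relative tolerance of 1e-8 on the
      ## log-likelihood is far below the bootstrap resolution
      cnt <- tabulate(sample.int(n, replace = TRUE), n)
      keep <- cnt > 0L
      fb <- .fit_mixture_ml(x[keep], k, init = mixture$theta,
                            maxit = maxit, reltol = 1e-8,
                            wts = cnt[keep])
      boots[b, ] <- fb$w
    }
  }
  a <- (1 - level) / 2
  ci <- t(apply(boots, 2, quantile, probs = c(a, 1 - a)))
  dimnames(ci) <- list(names(mixture$abundances), c("lower", "upper"))
  ci
}

#' Size versus burst-brightness threshold sweep
#'
#' Varies the minimum-photon threshold of the burst search while keeping the
#' inter-photon-time threshold fixed, rebuilding the step-scan diffusion
#' profile from the surviving bursts at each threshold and refitting the
#' hydrodynamic radius. Brighter (higher-threshold) bursts come from larger
#' assemblies, so a heterogeneous sample shows radii growing with the
#' threshold while a monodisperse one stays flat. The ensemble radius from
#' the smallest threshold's full burst set is returned alongside.
#'
#' @param traces List of [photon_trace()] objects (step scan).
#' @param n_min_values Ascending photon thresholds to sweep.
#' @param ipt_max Fixed inter-photon-time threshold (ms).
#' @param basis Basis library for fitting.
#' @param lee_window Lee-filter window.
#' @param crossing_boundaries Coordinate ranges of the crossings (see
#'   [profile_from_continuous()]).
#' @param min_bursts Entries with fewer surviving bursts are marked
#'   undersampled and not fitted.
#' @return A list of class `threshold_sweep`: `table` (data.frame `n_min`,
#'   `n_bursts`, `r_h`, `r_h_error`, `undersampled`) and `ensemble_r_h`.
#' @export
threshold_sweep <- function(traces, n_min_values, ipt_max, basis,
                            lee_window = 3, crossing_boundaries = NULL,
                            min_bursts = 100) {
  if (!length(n_min_values) || is.unsorted(n_min_values)) {
    stop("`n_min_values` must be nonempty and ascending")
  }
  ## one burst search at the loosest threshold; stricter thresholds filter
  base_params <- burst_search_params(ipt_max, min(n_min_values), lee_window)
  per_trace <- lapply(traces, find_bursts, params = base_params)
  coord <- vapply(traces, function(tr) tr$coordinate, numeric(1))
  dwell <- vapply(traces, function(tr) tr$duration, numeric(1))
  ids <- vapply(traces, function(tr) tr$position_id, integer(1))

  fit_for <- function(n_min) {
    cnt <- vapply(per_trace, function(b) sum(b$n_photons >= n_min),
                  numeric(1))
    n_tot <- sum(cnt)
    if (n_tot < min_bursts) {
      return(list(n = n_tot, r_h = NA_real_, err = NA_real_, under = TRUE))
    }
    prof <- profile_from_step(
      data.frame(position_id = ids, coordinate = coord, count = cnt,
                 dwell = dwell),
      crossing_boundaries = crossing_boundaries)
    ft <- tryCatch(global_fit(prof, basis, compute_errors = TRUE),
                   error = function(e) NULL)
    if (is.null(ft)) {
      return(list(n = n_tot, r_h = NA_real_, err = NA_real_, under = TRUE))
    }
    list(n = n_tot, r_h = ft$r_h, err = ft$r_h_error, under = FALSE)
  }

  rows <- lapply(n_min_values, fit_for)
  tab <- data.frame(
    n_min = n_min_values,
    n_bursts = vapply(rows, `[[`, numeric(1), "n"),
    r_h = vapply(rows, `[[`, numeric(1), "r_h"),
    r_h_error = vapply(rows, `[[`, numeric(1), "err"),
    undersampled = vapply(rows, `[[`, logical(1), "under"))
  structure(list(table = tab, ensemble_r_h = tab$r_h[1]),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("Burst photon-threshold sweep:\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("ensemble R_H (loosest threshold): %.4g nm\n", x$ensemble_r_h))
  invisible(x)
}
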