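#' Binding model for a multivalent antibody titrated against labeled antigen
#'
#' Describes the equilibrium of a labeled antigen binding one of
#' `stoichiometry` independent, identical sites on an unlabeled antibody
#' (default 2, the two Fab arms of an IgG). `k_d` is the per-site
#' dissociation constant.
#'
#' @param k_d Site dissociation constant (molar, > 0).
#' @param r_free Hydrodynamic radius of the free labeled antigen (nm).
#' @param r_bound Radius of the antigen--antibody complex (nm, > r_free).
#' @param antigen_total Total labeled-antigen concentration (molar).
#' @param stoichiometry Antigen binding sites per antibody (integer >= 1).
#' @return An object of class `isotherm_model`.
#' @export
isotherm_model <- function(k_d, r_free, r_bound, antigen_total,
                           stoichiometry = 2L) {
  if (k_d <= 0) stop("`k_d` must be positive (M)")
  if (r_bound <= r_free) stop("`r_bound` must exceed `r_free`")
  if (antigen_total <= 0) stop("`antigen_total` must be positive (M)")
  if (stoichiometry < 1 || stoichiometry != round(stoichiometry)) {
    stop("`stoichiometry` must be a positive integer")
  }
  structure(list(k_d = k_d, r_free = r_free, r_bound = r_bound,
                 antigen_total = antigen_total,
                 stoichiometry = as.integer(stoichiometry)),
            class = "isotherm_model")
}

## free-site concentration from exact mass balance for independent sites:
## s^2 + s (k_d + A_t - S_t) - k_d S_t = 0, S_t = stoichiometry * B_t
.free_sites <- function(model, antibody_total) {
  s_t <- model$stoichiometry * antibody_total
  b <- model$k_d + model$antigen_total - s_t
  ## numerically stable positive root
  disc <- sqrt(b^2 + 4 * model$k_d * s_t)
  s <- ifelse(b <= 0, (-b + disc) / 2,
              2 * model$k_d * s_t / (b + disc))
  s
}

#' Effective hydrodynamic radius along a titration
#'
#' Solves the exact mass balance (antigen depletion included) for the bound
#' fraction f of labeled antigen at each antibody concentration and returns
#' the mole-fraction-weighted effective radius
#' `(1 - f) r_free + f r_bound`. A partially occupied antibody carries the
#' antigen all the same, so any bound antigen is assigned `r_bound`.
#'
#' @param model An [isotherm_model()].
#' @param antibody_total Total antibody concentration(s), molar, >= 0.
#' @return Effective radii in nm (monotone nondecreasing in
#'   `antibody_total`, bounded by `r_free` and `r_bound`).
#' @export
effective_rh <- function(model, antibody_total) {
  stopifnot(inherits(model, "isotherm_model"))
  if (any(antibody_total < 0)) stop("`antibody_total` must be >= 0")
  s <- .free_sites(model, antibody_total)
  f <- s / (model$k_d + s)
  ## mass-balance self-check (closed-form root, conservation to round-off)
  a_free <- model$antigen_total * model$k_d / (model$k_d + s)
  stopifnot(all(abs(a_free + model$antigen_total * f -
                      model$antigen_total) <
                  1e-9 * model$antigen_total))
  (1 - f) * model$r_free + f * model$r_bound
}

#' Fit a size-based binding isotherm
#'
#' Weighted least-squares fit of effective hydrodynamic radius versus
#' titrant (antibody) concentration with the exact-mass-balance binding
#' model, over parameters `k_d`, `r_free` and `r_bound`. `k_d` is fitted on
#' the log scale; its uncertainty comes from the curvature of the fit
#' (delta method on log k_d).
#'
#' @param antibody_total Titrant concentrations (molar), >= 4 points
#'   spanning the transition.
#' @param r_h Measured effective radii (nm).
#' @param sd Optional per-point standard deviations (nm) for weighting.
#' @param antigen_total Fixed labeled-antigen concentration (molar).
#' @param stoichiometry Sites per antibody (fixed; default 2).
#' @return An object of class `isotherm_fit`: the fitted `model`, `k_d`,
#'   `k_d_error` (1-sigma, molar), `r_free`, `r_bound`, `fitted`,
#'   `residuals`.
#' @export
fit_isotherm <- function(antibody_total, r_h, sd = NULL, antigen_total,
                         stoichiometry = 2L) {
  if (length(antibody_total) < 4) stop("need at least 4 titration points")
  if (length(antibody_total) != length(r_h)) stop("length mismatch")
  span <- diff(range(r_h))
  noise <- if (!is.null(sd)) stats::median(sd) else 0
  if (span <= 0 || (noise > 0 && span < 4 * noise)) {
    stop("isotherm flat over the titration range: k_d unidentifiable")
  }
  w <- if (is.null(sd)) rep(1, length(r_h)) else 1 / sd^2
  ## midpoint-crossing start for k_d
  r_mid <- (min(r_h) + max(r_h)) / 2
  above <- which(r_h >= r_mid & antibody_total > 0)
  kd0 <- if (length(above)) antibody_total[min(above)] else
    stats::median(antibody_total[antibody_total > 0])
  dat <- data.frame(b = antibody_total, r = r_h, w = w)
  st <- as.integer(stoichiometry)
  pred <- function(log_kd, r_free, r_bound, b) {
    m <- list(k_d = exp(log_kd), r_free = r_free, r_bound = r_bound,
              antigen_total = antigen_total, stoichiometry = st)
    s <- .free_sites(m, b)
    f <- s / (m$k_d + s)
    (1 - f) * r_free + f * r_bound
  }
  fit <- minpack.lm::nlsLM(
    r ~ pred(log_kd, r_free, r_bound, b), data = dat, weights = w,
    start = list(log_kd = log(kd0), r_free = min(r_h), r_bound = max(r_h)),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- coef(fit)
  kd <- exp(cf[["log_kd"]])
  kd_se <- tryCatch(kd * sqrt(vcov(fit)["log_kd", "log_kd"]),
                    error = function(e) NA_real_)
  model <- isotherm_model(kd, cf[["r_free"]], cf[["r_bound"]],
                          antigen_total, st)
  structure(list(model = model, k_d = kd, k_d_error = kd_se,
                 r_free = cf[["r_free"]], r_bound = cf[["r_bound"]],
                 fitted = as.numeric(stats::fitted(fit)),
                 residuals = as.numeric(stats::resid(fit)),
                 data = dat, nls = fit),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  err <- if (is.finite(x$k_d_error))
    sprintf(" +/- %.3g pM", x$k_d_error * 1e12) else ""
  cat(sprintf("Binding isotherm fit: K_d = %.4g pM%s\n",
              x$k_d * 1e12, err))
  cat(sprintf("  R_H free = %.4g nm, bound = %.4g nm (%d sites/antibody, antigen %.3g pM)\n",
              x$r_free, x$r_bound, x$model$stoichiometry,
              x$model$antigen_total * 1e12))
  invisible(x)
}

#' @export
coef.isotherm_fit <- function(object, ...) {
  c(k_d = object$k_d, r_free = object$r_free, r_bound = object$r_bound)
}

#' @export
predict.isotherm_fit <- function(object, newdata = NULL, ...) {
  b <- if (is.null(newdata)) object$data$b else newdata
  effective_rh(object$model, b)
}

#' @export
plot.isotherm_fit <- function(x, ...) {
  b <- x$data$b
  plot(b, x$data$r, log = "x", xlab = "antibody (M)",
       ylab = "effective R_H (nm)", ...)
  bb <- exp(seq(log(min(b[b > 0])) - 1, log(max(b)) + 1, length.out = 200))
  graphics::lines(bb, effective_rh(x$model, bb), col = "orange", lwd = 2)
  invisible(x)
}
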