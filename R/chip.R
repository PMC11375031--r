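#' Microfluidic sizing-chip geometry
#'
#' Describes the observation channel of the sizing chip. The defaults mirror a
#' standard diffusional-sizing device: a 25 um x 225 um observation channel,
#' roughly 90 mm long, with sample and co-flowing buffer drawn through in a
#' ~1:8 volume ratio so the sample stream occupies 1/9 of the channel width
#' at the nozzle.
#'
#' @param channel_height Channel height in um.
#' @param observation_width Channel width in um (transverse scan direction).
#' @param channel_length Total observation-channel length in um.
#' @param sample_flow_fraction Fraction of the total flow carried by the
#'   sample stream; the inlet top-hat occupies this fraction of the width.
#' @param crossing_distances Optional numeric vector of downstream distances
#'   (um) of the scanned channel crossings; nondecreasing, first element 0,
#'   all within `channel_length`. When `NULL` (default), crossing positions
#'   are derived from residence times at simulation time (see
#'   [simulate_basis()]).
#' @return An object of class `chip_geometry`.
#' @export
chip_geometry <- function(channel_height = 25, observation_width = 225,
                          channel_length = 90000,
                          sample_flow_fraction = 1 / 9,
                          crossing_distances = NULL) {
  if (channel_height <= 0 || observation_width <= 0 || channel_length <= 0) {
    stop("channel dimensions must be positive")
  }
  if (sample_flow_fraction <= 0 || sample_flow_fraction >= 1) {
    stop("`sample_flow_fraction` must lie strictly between 0 and 1")
  }
  if (!is.null(crossing_distances)) {
    cd <- crossing_distances
    if (is.unsorted(cd) || cd[1] != 0 || any(cd < 0) ||
        any(cd > channel_length)) {
      stop("`crossing_distances` must be nondecreasing, start at 0 and not ",
           "exceed `channel_length`")
    }
  }
  structure(list(channel_height = channel_height,
                 observation_width = observation_width,
                 channel_length = channel_length,
                 sample_flow_fraction = sample_flow_fraction,
                 crossing_distances = crossing_distances),
            class = "chip_geometry")
}

#' Flow settings
#'
#' @param total_flow_rate Total volumetric flow rate in uL/h (sample plus
#'   buffer streams).
#' @return An object of class `flow_settings`.
#' @export
flow_settings <- function(total_flow_rate = 100) {
  if (total_flow_rate <= 0) stop("`total_flow_rate` must be positive (uL/h)")
  structure(list(total_flow_rate = total_flow_rate), class = "flow_settings")
}

## mean (plug-flow) velocity in um/s
.mean_velocity <- function(geom, flow) {
  q_um3_s <- flow$total_flow_rate * 1e9 / 3600
  q_um3_s / (geom$channel_height * geom$observation_width)
}

#' Residence time at a downstream distance
#'
#' Plug-flow estimate `t = distance / (Q / (height * width))` of the time a
#' molecule has spent travelling from the nozzle to a given channel position.
#'
#' @param geom A [chip_geometry()].
#' @param flow A [flow_settings()].
#' @param distance Downstream distance in um.
#' @return Residence time(s) in seconds.
#' @export
residence_time <- function(geom, flow, distance) {
  if (any(distance < 0) || any(distance > geom$channel_length)) {
    stop("`distance` must lie within [0, channel_length]")
  }
  distance / .mean_velocity(geom, flow)
}

#' Solver options for the advection--diffusion basis simulation
#'
#' The steady-state transport problem
#' \eqn{u(y,z)\,\partial c/\partial x = D(\partial^2 c/\partial y^2 +
#' \partial^2 c/\partial z^2)} is discretised on the channel cross-section
#' and marched implicitly downstream. `mode = "full"` uses the laminar
#' rectangular-duct (Poiseuille-series) velocity field and reads out the
#' mid-height slice; `mode = "depth_averaged"` collapses the depth dimension
#' and advects with the mean velocity (cheaper, slightly wider profiles).
#'
#' @param ny Number of transverse grid nodes (across the width).
#' @param nz Number of depth nodes (full mode; made odd so a node sits at
#'   mid-height).
#' @param mode `"full"` or `"depth_averaged"`.
#' @param n_terms Number of odd terms in the duct Poiseuille series.
#' @param waist Confocal-spot lateral 1/e^2 waist (um) used to blur the
#'   mid-height readout; blurring is skipped when the waist is below half a
#'   transverse grid cell.
#' @param readout For the full solver, `"mid_height"` (default, confocal
#'   slice at the channel mid-plane) or `"depth_averaged"` (plain average of
#'   the same 3-D solution over the depth, as a widefield detector would
#'   see).
#' @param n_steps_max,n_steps_min Bounds on the number of implicit marching
#'   steps per inter-crossing segment (chosen adaptively from the segment
#'   Fourier number).
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(ny = 151, nz = 31,
                           mode = c("full", "depth_averaged"),
                           n_terms = 11, waist = 0.3,
                           n_steps_max = 400, n_steps_min = 40,
                           readout = c("mid_height", "depth_averaged")) {
  mode <- match.arg(mode)
  readout <- match.arg(readout)
  if (ny < 11 || (mode == "full" && nz < 5)) {
    stop("solver grid too coarse: need ny >= 11 and nz >= 5")
  }
  if (n_steps_min < 4 || n_steps_max < n_steps_min) {
    stop("invalid marching-step bounds")
  }
  if (nz %% 2 == 0) nz <- nz + 1L
  structure(list(ny = as.integer(ny), nz = as.integer(nz), mode = mode,
                 n_terms = as.integer(n_terms), waist = waist,
                 n_steps_max = as.integer(n_steps_max),
                 n_steps_min = as.integer(n_steps_min), readout = readout),
            class = "solver_options")
}

## rectangular-duct Poiseuille velocity on the (y, z) grid, um/s,
## normalised so the cross-section integral equals Q
.duct_velocity <- function(y, z, W, H, n_terms, q_um3_s) {
  ## series in z (height) with decay across the (wide) y direction;
  ## cosh ratio computed in log space to avoid overflow
  u <- matrix(0, nrow = length(y), ncol = length(z))
  for (k in seq_len(n_terms)) {
    n <- 2L * k - 1L
    b <- n * pi * (W / 2) / H
    a <- n * pi * abs(y - W / 2) / H
    ratio <- exp(a - b + log1p(exp(-2 * a)) - log1p(exp(-2 * b)))
    u <- u + (1 / n^3) * outer(1 - ratio, sin(n * pi * z / H))
  }
  dy <- y[2] - y[1]; dz <- z[2] - z[1]
  wy <- rep(dy, length(y)); wy[c(1, length(y))] <- dy / 2
  wz <- rep(dz, length(z)); wz[c(1, length(z))] <- dz / 2
  integral <- as.numeric(t(wy) %*% u %*% wz)
  u * (q_um3_s / integral)
}

## cell-averaged centred top-hat inlet of width `frac * W` on grid y
.inlet_tophat <- function(y, W, frac) {
  dy <- y[2] - y[1]
  lo <- W / 2 - frac * W / 2
  hi <- W / 2 + frac * W / 2
  cl <- pmax(y - dy / 2, lo)
  cu <- pmin(y + dy / 2, hi)
  pmax(cu - cl, 0) / dy
}

## 1-D Neumann Laplacian (second difference), symmetric, zero column sums
.lap1d <- function(n, h) {
  d <- rep(-2, n); d[c(1, n)] <- -1
  Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                     diagonals = list(rep(1, n - 1), d, rep(1, n - 1))) / h^2
}

## substep layout for one segment: sharp inlets get geometrically graded
## blocks (small steps first), each block a constant step so one Cholesky
## factorisation serves the whole block
.segment_steps <- function(dt_seg, fo_seg, opts, graded) {
  n <- max(opts$n_steps_min,
           min(opts$n_steps_max, ceiling(4 * sqrt(max(fo_seg, 1)))))
  if (!graded) {
    return(list(h = dt_seg / n, n = rep(n, 1)))
  }
  nb <- 5L
  ratios <- 4^(0:(nb - 1))
  durations <- dt_seg * ratios / sum(ratios)
  per_block <- max(4L, ceiling(n / nb))
  list(h = durations / per_block, n = rep(per_block, nb))
}

#' Simulate a basis library of diffusion profiles
#'
#' Solves the steady advection--diffusion transport problem for each
#' hydrodynamic radius on a grid and records the mid-height transverse
#' concentration profile at every scanned channel crossing. The resulting
#' library is the calibration-free reference against which measured diffusion
#' profiles are fitted.
#'
#' Crossing positions are taken from `geom$crossing_distances` when set;
#' otherwise they are derived from `crossing_times` (residence times, s) at
#' the configured flow. The absolute positions of the scanned crossings are
#' chip-specific user configuration and are never inferred silently.
#'
#' @param geom A [chip_geometry()].
#' @param flow A [flow_settings()].
#' @param cond A [solvent_conditions()].
#' @param rh_grid Hydrodynamic-radius grid in nm, positive and sorted
#'   ascending. Default: 60 log-spaced nodes from 0.3 nm to 300 nm.
#' @param crossing_times Residence times (s) of the scanned crossings, used
#'   when the geometry carries no explicit crossing distances. First element
#'   must be 0 (the nozzle crossing reproduces the inlet).
#' @param solver A [solver_options()].
#' @return An object of class `basis_library`: list with elements `rh_nm`,
#'   `d` (m^2/s), `y_um`, `crossing_distances_um`, `crossing_times_s`,
#'   `profiles` (array `[n_rh, n_crossing, ny]`, inlet concentration = 1)
#'   and `metadata` (geometry, flow, conditions, solver settings, maximum
#'   relative mass-conservation error).
#' @export
simulate_basis <- function(geom = chip_geometry(), flow = flow_settings(),
                           cond = solvent_conditions(),
                           rh_grid = NULL,
                           crossing_times = c(0, 10, 26, 55),
                           solver = solver_options()) {
  cond <- .check_cond(cond)
  if (is.null(rh_grid)) {
    rh_grid <- exp(seq(log(0.3), log(300), length.out = 60))
  }
  if (any(rh_grid <= 0) || is.unsorted(rh_grid, strictly = TRUE)) {
    stop("`rh_grid` must be positive and strictly ascending (nm)")
  }
  v <- .mean_velocity(geom, flow)
  if (!is.null(geom$crossing_distances)) {
    xd <- geom$crossing_distances
    times <- xd / v
  } else {
    if (crossing_times[1] != 0 || is.unsorted(crossing_times)) {
      stop("`crossing_times` must be nondecreasing and start at 0")
    }
    ## crossings given as residence times are authoritative for transport;
    ## the distances reported alongside are nominal plug-flow equivalents
    ## (folded channels make the printed length an unreliable bound)
    times <- crossing_times
    xd <- times * v
  }
  n_cross <- length(times)
  if (n_cross < 2) stop("need at least two crossings")

  W <- geom$observation_width; H <- geom$channel_height
  ny <- solver$ny
  y <- seq(0, W, length.out = ny)
  dy <- y[2] - y[1]
  c0 <- .inlet_tophat(y, W, geom$sample_flow_fraction)
  d_grid <- diffusion_coefficient(rh_grid * 1e-9, cond)  # m^2/s
  d_um <- d_grid * 1e12                                   # um^2/s

  full <- solver$mode == "full"
  if (full) {
    nz <- solver$nz
    z <- seq(0, H, length.out = nz)
    q_um3_s <- flow$total_flow_rate * 1e9 / 3600
    u <- .duct_velocity(y, z, W, H, solver$n_terms, q_um3_s)
    uvec <- as.numeric(u)                       # y fastest, z slowest
    Wu <- Matrix::Diagonal(x = uvec)
    L <- Matrix::kronecker(Matrix::Diagonal(nz), .lap1d(ny, dy)) +
      Matrix::kronecker(.lap1d(nz, z[2] - z[1]), Matrix::Diagonal(ny))
    mid <- (nz + 1L) %/% 2L
    state0 <- rep(c0, nz)
    mass0 <- sum(uvec * state0)
  } else {
    L <- .lap1d(ny, dy)
    Wu <- Matrix::Diagonal(x = rep(v, ny))
    state0 <- c0
    mass0 <- v * sum(state0)
  }

  profiles <- array(NA_real_, dim = c(length(rh_grid), n_cross, ny))
  mass_err <- 0
  read_out <- function(state) {
    if (!full) return(state)
    if (solver$readout == "mid_height") {
      state[((mid - 1) * ny + 1):(mid * ny)]
    } else {
      rowMeans(matrix(state, ny, nz))
    }
  }

  for (i in seq_along(rh_grid)) {
    D <- d_um[i]
    state <- state0
    profiles[i, 1, ] <- read_out(state)
    for (k in 2:n_cross) {
      dt_seg <- times[k] - times[k - 1]
      if (dt_seg <= 0) { profiles[i, k, ] <- profiles[i, k - 1, ]; next }
      fo <- D * dt_seg / dy^2
      plan <- .segment_steps(dt_seg, fo, solver, graded = (k == 2))
      for (b in seq_along(plan$h)) {
        h <- plan$h[b]
        ## implicit downstream step dx = v * h (h is residence time):
        ## (Wu - dx D L) c_new = Wu c_old
        A <- Wu - (v * h * D) * L
        ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
        for (s in seq_len(plan$n[b])) {
          state <- as.numeric(Matrix::solve(ch, Wu %*% state))
        }
      }
      mass <- if (full) sum(uvec * state) else v * sum(state)
      mass_err <- max(mass_err, abs(mass / mass0 - 1))
      profiles[i, k, ] <- read_out(state)
    }
  }

  ## optional confocal-spot blur of the readout
  if (solver$waist >= dy / 2) {
    sigma <- solver$waist / 2
    half <- max(1L, ceiling(4 * sigma / dy))
    kern <- dnorm(seq(-half, half) * dy, sd = sigma)
    kern <- kern / sum(kern)
    for (i in seq_along(rh_grid)) for (k in seq_len(n_cross)) {
      p <- profiles[i, k, ]
      pe <- c(rep(p[1], half), p, rep(p[ny], half))
      profiles[i, k, ] <- as.numeric(stats::filter(pe, kern, sides = 2))[
        (half + 1):(half + ny)]
    }
  }

  structure(list(
    rh_nm = rh_grid, d = d_grid, y_um = y,
    crossing_distances_um = xd, crossing_times_s = times,
    profiles = profiles,
    metadata = list(geometry = unclass(geom), flow = unclass(flow),
                    conditions = unclass(cond), solver = unclass(solver),
                    mass_error = mass_err,
                    package_version = as.character(utils::packageVersion("smmds")))),
    class = "basis_library")
}

#' @export
print.basis_library <- function(x, ...) {
  cat(sprintf(
    "Basis library: %d radii (%.3g-%.3g nm), %d crossings (t = %s s), %d transverse nodes\n",
    length(x$rh_nm), min(x$rh_nm), max(x$rh_nm),
    length(x$crossing_times_s),
    paste(signif(x$crossing_times_s, 3), collapse = ", "),
    length(x$y_um)))
  cat(sprintf("  solver: %s mode, mass error %.2e\n",
              x$metadata$solver$mode, x$metadata$mass_error))
  invisible(x)
}

#' Interpolate basis profiles at an off-grid hydrodynamic radius
#'
#' Linear interpolation in log(R_H) between the two neighbouring grid rows;
#' exact at grid nodes.
#'
#' @param basis A [simulate_basis()] library.
#' @param r_h Hydrodynamic radius in nm, within the library grid.
#' @return Matrix `[n_crossing, ny]` of profile values.
#' @export
interpolate_profile <- function(basis, r_h) {
  g <- basis$rh_nm
  if (r_h < g[1] || r_h > g[length(g)]) {
    stop(sprintf("r_h = %.4g nm outside basis grid [%.4g, %.4g] nm",
                 r_h, g[1], g[length(g)]))
  }
  i <- findInterval(r_h, g, all.inside = TRUE)
  if (r_h == g[i]) return(basis$profiles[i, , ])
  if (r_h == g[i + 1]) return(basis$profiles[i + 1, , ])
  w <- (log(r_h) - log(g[i])) / (log(g[i + 1]) - log(g[i]))
  (1 - w) * basis$profiles[i, , ] + w * basis$profiles[i + 1, , ]
}

## profile second moment (variance) about its own mean, per crossing
.profile_variance <- function(values, y) {
  m0 <- sum(values)
  mu <- sum(values * y) / m0
  sum(values * (y - mu)^2) / m0
}

#' Write a basis library to a directory of CSV matrices plus JSON metadata
#'
#' One CSV per crossing (rows = radius grid, columns = transverse nodes) and
#' a `metadata.json` sidecar carrying geometry, flow, conditions, solver
#' settings and grids, so a fit is reproducible from the directory alone.
#'
#' @param basis A `basis_library`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_basis_library <- function(basis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_cross <- length(basis$crossing_times_s)
  for (k in seq_len(n_cross)) {
    write.csv(basis$profiles[, k, ],
              file.path(dir, sprintf("profiles_crossing%02d.csv", k)),
              row.names = FALSE)
  }
  meta <- c(basis$metadata,
            list(rh_nm = basis$rh_nm, d = basis$d, y_um = basis$y_um,
                 crossing_distances_um = basis$crossing_distances_um,
                 crossing_times_s = basis$crossing_times_s))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a basis library written by [write_basis_library()]
#'
#' @param dir Directory containing the CSV matrices and `metadata.json`.
#' @return A `basis_library`.
#' @export
read_basis_library <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  times <- meta$crossing_times_s
  rh <- meta$rh_nm
  ny <- length(meta$y_um)
  profiles <- array(NA_real_, dim = c(length(rh), length(times), ny))
  for (k in seq_along(times)) {
    m <- as.matrix(read.csv(
      file.path(dir, sprintf("profiles_crossing%02d.csv", k))))
    profiles[, k, ] <- m
  }
  structure(list(rh_nm = rh, d = meta$d, y_um = meta$y_um,
                 crossing_distances_um = meta$crossing_distances_um,
                 crossing_times_s = times, profiles = profiles,
                 metadata = meta[setdiff(names(meta),
                                         c("rh_nm", "d", "y_um",
                                           "crossing_distances_um",
                                           "crossing_times_s"))]),
            class = "basis_library")
}
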