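#' Write a photon trace as delimited text
#'
#' One timestamp (seconds) per line, preceded by `#`-prefixed header lines
#' recording the unit, duration, position id and chip coordinate.
#'
#' @param trace A [photon_trace()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_photon_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# smmds photon trace",
               "# unit: seconds",
               sprintf("# duration: %.17g", trace$duration),
               sprintf("# position_id: %d", trace$position_id),
               sprintf("# coordinate: %.17g", trace$coordinate)), con)
  writeLines(sprintf("%.17g", trace$t), con)
  invisible(path)
}

#' Read a photon trace written by [write_photon_trace()]
#'
#' Also accepts plain one-column files of integer 16-ps ticks when the
#' header declares `unit: ticks`.
#'
#' @param path Input file.
#' @return A [photon_trace()].
#' @export
read_photon_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get <- function(key, default = NA) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  unit <- get("unit", "seconds")
  ts <- as.numeric(body)
  duration <- as.numeric(get("duration"))
  if (is.na(duration)) {
    duration <- if (unit == "ticks") max(ts) * 16e-12 else max(ts)
  }
  num_or_na <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (length(v)) v else NA_real_
  }
  photon_trace(ts, duration,
               position_id = as.integer(num_or_na(get("position_id", 1L))),
               coordinate = num_or_na(get("coordinate", NA)),
               unit = unit)
}

#' Write a burst table
#' @param bursts Burst table from [find_bursts()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_bursts <- function(bursts, path) {
  write.csv(bursts, path, row.names = FALSE)
  invisible(path)
}

#' Read a burst table
#' @param path CSV written by [write_bursts()].
#' @return Data.frame of bursts.
#' @export
read_bursts <- function(path) read.csv(path)

#' Write a diffusion profile (CSV plus JSON sidecar)
#'
#' @param profile A `diffusion_profile`.
#' @param path Output CSV; a `<path>.json` sidecar records the mode.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  jsonlite::write_json(list(mode = attr(profile, "mode")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a diffusion profile written by [write_profile()]
#' @param path CSV path.
#' @return A `diffusion_profile`.
#' @export
read_profile <- function(path) {
  df <- read.csv(path)
  side <- paste0(path, ".json")
  mode <- if (file.exists(side)) {
    jsonlite::read_json(side)$mode
  } else "step"
  diffusion_profile(df$coordinate, df$value, mode, df$crossing)
}

#' Write a fit report as JSON
#'
#' @param fit An `smmds_fit`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(r_h_nm = fit$r_h, r_h_error_nm = fit$r_h_error,
              d_m2_s = fit$d,
              amplitude = fit$amplitude, baseline = fit$baseline,
              sse = fit$sse,
              local_errors_nm = as.list(fit$local_errors),
              at_boundary = fit$at_boundary, mode = fit$mode,
              crossing_offsets_um = fit$crossing_offsets,
              package_version = as.character(utils::packageVersion("smmds")))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
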