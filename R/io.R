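#' Write a spectroscopy session to a directory
#'
#' One CSV per recording (columns `time_s`, `radius_m`) plus a JSON
#' sidecar per recording carrying the transmit frequency, pressure, frame
#' rate, bubble id and radius unit. The baseline is written as
#' `baseline.csv`; ultrasound recordings as `recording_01.csv`, ... in
#' grid order.
#'
#' @param session A [spectroscopy_session()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "spectroscopy_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(curve, stem) {
    utils::write.csv(data.frame(time_s = curve$t, radius_m = curve$r),
                     file.path(dir, paste0(stem, ".csv")), row.names = FALSE)
    side <- list(fT = curve$fT, pnp = curve$pnp,
                 bubble_id = session$bubble_id %||% NA,
                 radius_unit = "m")
    jsonlite::write_json(side, file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, null = "null", na = "null",
                         digits = NA)
  }
  wr(session$baseline, "baseline")
  for (k in seq_along(session$recordings)) {
    wr(session$recordings[[k]], sprintf("recording_%02d", k))
  }
  invisible(dir)
}

.read_rt_csv <- function(csv, bubble_id_out = NULL) {
  side_path <- sub("\\.csv$", ".json", csv)
  if (!file.exists(side_path)) {
    stop("missing JSON sidecar for ", csv)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  tab <- utils::read.csv(csv)
  rcol <- intersect(c("radius_m", "radius_um"), names(tab))
  if (!"time_s" %in% names(tab) || length(rcol) != 1L) {
    stop("malformed session CSV ", csv,
         ": need columns time_s and radius_m (or radius_um)")
  }
  unit <- side$radius_unit %||% sub("radius_", "", rcol)
  scale <- switch(unit, m = 1, um = 1e-6,
                  stop("unknown radius unit '", unit, "' in ", side_path))
  rt_curve(tab$time_s, tab[[rcol]] * scale,
           fT = if (is.null(side$fT) || is.na(side$fT)) NA_real_ else side$fT,
           pnp = if (is.null(side$pnp) || is.na(side$pnp)) NA_real_ else side$pnp,
           bubble_id = side$bubble_id)
}

#' Read a spectroscopy session from a directory
#'
#' Counterpart of [write_session()]. Radii declared in micrometres in the
#' sidecar (`radius_unit: "um"`) are converted to metres. A non-baseline
#' recording without a transmit frequency is a parse error.
#'
#' @param dir Directory written by [write_session()] (or assembled by
#'   hand in the same layout).
#' @return A [spectroscopy_session()].
#' @export
read_session <- function(dir) {
  if (!dir.exists(dir)) stop("no such session directory: ", dir)
  bl <- file.path(dir, "baseline.csv")
  if (!file.exists(bl)) stop("session has no baseline.csv")
  baseline <- .read_rt_csv(bl)
  recs <- sort(list.files(dir, pattern = "^recording_\\d+\\.csv$",
                          full.names = TRUE))
  if (!length(recs)) stop("session has no recording_*.csv files")
  recordings <- lapply(recs, .read_rt_csv)
  for (k in seq_along(recordings)) {
    if (is.na(recordings[[k]]$fT)) {
      stop("recording ", basename(recs[k]), " has no transmit frequency (fT)")
    }
  }
  ord <- order(vapply(recordings, function(x) x$fT, numeric(1)))
  recordings <- recordings[ord]
  pnps <- vapply(recordings, function(x) x$pnp, numeric(1))
  spectroscopy_session(baseline, recordings,
                       pnp = if (all(is.na(pnps))) NA_real_ else
                         stats::median(pnps, na.rm = TRUE),
                       bubble_id = recordings[[1]]$bubble_id)
}

#' Write a two-channel stack as multi-page TIFF plus YAML metadata
#'
#' Pages are z-slices ordered within channel (all green slices, then all
#' red); the YAML sidecar records the voxel size (um), channel order and
#' stack dimensions. Intensities are rescaled to \[0, 1\] for the 32-bit
#' float TIFF; the scale is recorded in the metadata and undone on read.
#' Requires the `tiff` package.
#'
#' @param shell A [confocal_shell()].
#' @param path Output TIFF path; metadata goes to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(shell, path) {
  stopifnot(inherits(shell, "confocal_shell"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O")
  }
  dims <- dim(shell$green)
  scale <- max(abs(c(shell$green, shell$red)), 1e-12)
  pages <- c(lapply(seq_len(dims[3]), function(k) shell$green[, , k] / scale),
             lapply(seq_len(dims[3]), function(k) shell$red[, , k] / scale))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(voxel_um = as.list(shell$voxel * 1e6),
               channels = c("green", "red"),
               dims = as.list(dims),
               intensity_scale = scale)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a two-channel stack written by [write_stack()]
#'
#' Refuses to guess: missing metadata or a page count inconsistent with
#' two channels is an error.
#'
#' @param path TIFF path (metadata expected at `<path>.yaml`).
#' @return A [confocal_shell()] (geometry unset).
#' @export
read_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O")
  }
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path)) stop("missing stack metadata: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$voxel_um)) stop("stack metadata lacks voxel size")
  pages <- tiff::readTIFF(path, all = TRUE)
  dims <- as.integer(unlist(meta$dims))
  if (length(pages) != 2L * dims[3]) {
    stop("expected a two-channel stack with ", 2L * dims[3],
         " pages, found ", length(pages))
  }
  scale <- meta$intensity_scale %||% 1
  gr <- array(0, dims)
  rd <- array(0, dims)
  for (k in seq_len(dims[3])) {
    gr[, , k] <- pages[[k]] * scale
    rd[, , k] <- pages[[dims[3] + k]] * scale
  }
  ch <- unlist(meta$channels)
  if (!identical(ch, c("green", "red"))) {
    tmp <- gr
    gr <- rd
    rd <- tmp
  }
  confocal_shell(gr, rd, voxel = unlist(meta$voxel_um) * 1e-6)
}

#' Analysis configuration with the protocol defaults
#'
#' Bundles every tunable of the pipeline with the protocol values as
#' defaults: 300 kHz filter and analysis bandwidth, 6 dB harmonic
#' threshold, 2/3 inhomogeneity and 1/3 LC thresholds, 32 parts, 0.5 um
#' diameter bins with the N > 3 rule, and the physical constants.
#' `read_config()` overlays a YAML file on these defaults and validates.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    physics = unclass(physical_constants()),
    filter = list(bandwidth_hz = 300e3, order = 3),
    harmonic = list(bandwidth_hz = 300e3, threshold_db = 6,
                    min_recordings = 2, zero_pad = 4),
    fit = list(chi_bounds = c(0, 5), kappa_bounds = c(0, 1e-6), n_starts = 3),
    partition = list(n_bands = 4, n_sectors = 8, thickness_voxels = 3),
    buckle = list(min_diameter_um = 1, max_dist_um = 2, extensive_from = 5),
    population = list(bin_width_um = 0.5, min_n = 4),
    seed = NULL)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config block: ", nm)
    cfg[[nm]] <- utils::modifyList(cfg[[nm]] %||% list(), over[[nm]])
  }
  .validate_config(cfg)
  structure(cfg, class = "run_config")
}

.validate_config <- function(cfg) {
  stopifnot(cfg$filter$bandwidth_hz > 0,
            cfg$harmonic$threshold_db >= 0,
            cfg$harmonic$min_recordings >= 1,
            cfg$partition$n_bands >= 1, cfg$partition$n_sectors >= 1,
            cfg$population$bin_width_um > 0, cfg$population$min_n >= 1)
  do.call(physical_constants, cfg$physics)
  invisible(TRUE)
}

#' Read a YAML configuration file
#'
#' @param path YAML file whose top-level blocks match [run_config()].
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  do.call(run_config, yaml::read_yaml(path) %||% list())
}

#' Assemble cohort report tables
#'
#' Summarizes a cohort of per-bubble records into the standard tables:
#' shell parameters (median and IQR per type, in the display units
#' N/m and 1e-8 kg/s), oscillation-amplitude variability (max and median
#' IQR per type), second-harmonic/subharmonic response percentages,
#' deflation, and coating scores. Empty type groups are dropped with a
#' warning.
#'
#' @param bubbles Data frame with one row per bubble: `bubble_id`, `type`,
#'   and any of `chi`, `kappa_s`, `converged`, `deflation`,
#'   `subharmonic`, `second_harmonic` (logicals), `inhomogeneous_pct`,
#'   `lc_pct`, `buckle_count`.
#' @param records Optional long data frame for [iqr_grid()] (columns
#'   `bubble_id`, `type`, `diameter_um`, `fT`, `x0`).
#' @param bin_width,min_n Variability-grid settings, defaults 0.5 um and 4.
#'
#' @return List of data frames: `shell`, `variability` (when `records`
#'   given), `harmonics`, `deflation`, `coating`.
#' @export
report <- function(bubbles, records = NULL, bin_width = 0.5, min_n = 4L) {
  stopifnot(nrow(bubbles) >= 1L, "type" %in% names(bubbles))
  types <- split(bubbles, bubbles$type, drop = TRUE)
  fmt_med_iqr <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
  }
  shell <- NULL
  if (all(c("chi", "kappa_s") %in% names(bubbles))) {
    shell <- do.call(rbind, lapply(names(types), function(ty) {
      b <- types[[ty]]
      if ("converged" %in% names(b)) b <- b[b$converged, , drop = FALSE]
      if (!nrow(b)) {
        warning("type group '", ty, "' has no converged fits; omitted")
        return(NULL)
      }
      data.frame(type = ty, n = nrow(b),
                 elasticity_N_per_m = fmt_med_iqr(b$chi),
                 viscosity_1e8_kg_per_s = fmt_med_iqr(b$kappa_s * 1e8))
    }))
  }
  variability <- NULL
  if (!is.null(records)) {
    variability <- do.call(rbind, lapply(split(records, records$type),
                                         function(rr) {
      g <- iqr_grid(rr, bin_width, min_n)
      data.frame(type = rr$type[1],
                 max_iqr_pct = g$max_iqr_pct,
                 median_iqr_pct = g$median_iqr_pct)
    }))
  }
  harmonics <- NULL
  hcols <- intersect(c("subharmonic", "second_harmonic"), names(bubbles))
  if (length(hcols)) {
    harmonics <- do.call(rbind, lapply(names(types), function(ty) {
      b <- types[[ty]]
      out <- data.frame(type = ty, n = nrow(b))
      for (h in hcols) out[[paste0(h, "_pct")]] <- 100 * mean(b[[h]])
      out
    }))
  }
  defl <- NULL
  if ("deflation" %in% names(bubbles)) {
    defl <- do.call(rbind, lapply(names(types), function(ty) {
      data.frame(type = ty, n = nrow(types[[ty]]),
                 deflation_pct = fmt_med_iqr(100 * types[[ty]]$deflation))
    }))
  }
  coating <- NULL
  ccols <- intersect(c("inhomogeneous_pct", "lc_pct", "buckle_count"),
                     names(bubbles))
  if (length(ccols)) {
    coating <- do.call(rbind, lapply(names(types), function(ty) {
      out <- data.frame(type = ty, n = nrow(types[[ty]]))
      for (cc in ccols) out[[cc]] <- fmt_med_iqr(types[[ty]][[cc]])
      out
    }))
  }
  Filter(Negate(is.null),
         list(shell = shell, variability = variability,
              harmonics = harmonics, deflation = defl, coating = coating))
}
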