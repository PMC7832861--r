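#' Number-weighted size distribution
#'
#' Binned number-weighted diameter distribution (Coulter-counter style),
#' with the percentile diameters d10, d50 and d90 derived from the
#' cumulative number fraction by linear interpolation between bin centres.
#'
#' @param diameters Bin centres (um), strictly increasing.
#' @param counts Number-weighted counts (>= 0), same length.
#'
#' @return An object of class `size_distribution` with fields `diameters`,
#'   `counts`, `d10`, `d50`, `d90`.
#' @export
size_distribution <- function(diameters, counts) {
  if (length(diameters) != length(counts) || !length(diameters)) {
    stop("diameters and counts must be matching nonempty vectors")
  }
  if (any(diff(diameters) <= 0)) stop("diameters must be strictly increasing")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("size distribution has zero total count")
  p <- .size_percentiles(diameters, counts, c(0.10, 0.50, 0.90))
  structure(list(diameters = diameters, counts = counts,
                 d10 = p[1], d50 = p[2], d90 = p[3]),
            class = "size_distribution")
}

# percentiles of the cumulative number-weighted distribution, linear
# interpolation between bin centres; probes below/above the covered range
# clamp to the first/last occupied bin centre
.size_percentiles <- function(diameters, counts, probs) {
  keep <- counts > 0
  d <- diameters[keep]
  cum <- cumsum(counts[keep]) / sum(counts)
  if (length(d) == 1L) return(rep(d, length(probs)))
  stats::approx(cum, d, xout = probs, rule = 2, ties = "ordered")$y
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("Size distribution: %d bins, N = %g, d10/d50/d90 = %.2f/%.2f/%.2f um, span = %.2f\n",
              length(x$counts), sum(x$counts), x$d10, x$d50, x$d90, span(x)))
  invisible(x)
}

#' Span (polydispersity) of a size distribution
#'
#' `span = (d90 - d10) / d50`, the standard width measure of a
#' number-weighted size distribution. Scale-invariant; 0 for a
#' monodisperse sample.
#'
#' @param dist A [size_distribution()].
#' @return The span (dimensionless).
#' @export
span <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  (dist$d90 - dist$d10) / dist$d50
}

#' Number-weighted mean diameter
#'
#' @param dist A [size_distribution()].
#' @return Count-weighted mean of the bin centres (um).
#' @export
mean_diameter <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  stats::weighted.mean(dist$diameters, dist$counts)
}

#' Variability (IQR) grid of oscillation amplitudes
#'
#' Quantifies the population variability of the acoustic response as the
#' interquartile range of the relative oscillation amplitude x0 per
#' transmit frequency and per 0.5 um diameter bin, keeping only cells with
#' more than `min_n - 1` bubbles (the printed rule is N > 3, i.e. at least
#' 4). Bins are right-open and aligned to multiples of the bin width
#' (`[3.5, 4.0), [4.0, 4.5), ...`). IQRs use linearly interpolated order
#' statistics (R's default type 7 quantiles) and are reported in percent.
#'
#' @param records Data frame with columns `bubble_id`, `diameter_um`
#'   (initial diameter), `fT` (Hz) and `x0` (dimensionless), one row per
#'   bubble and transmit frequency.
#' @param bin_width Diameter bin width (um), default 0.5.
#' @param min_n Minimum bubbles per cell, default 4 (the `N > 3` rule).
#'
#' @return A list of class `iqr_grid`: `grid` (long data frame with
#'   `diameter_bin` (lower edge, um), `fT`, `n`, `iqr_pct` — `NA` for
#'   under-populated cells), `max_iqr_pct` and `median_iqr_pct` over the
#'   populated cells (both `NA`, with a warning, when no cell is
#'   populated).
#' @export
iqr_grid <- function(records, bin_width = 0.5, min_n = 4L) {
  need <- c("bubble_id", "diameter_um", "fT", "x0")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  bin_lo <- floor(records$diameter_um / bin_width) * bin_width
  cells <- split(records$x0,
                 paste(bin_lo, records$fT, sep = "|"), drop = TRUE)
  key <- do.call(rbind, strsplit(names(cells), "|", fixed = TRUE))
  n <- lengths(cells)
  iqr_pct <- ifelse(n >= min_n,
                    vapply(cells, function(v) 100 * iqr7(v), numeric(1)),
                    NA_real_)
  grid <- data.frame(diameter_bin = as.numeric(key[, 1]),
                     fT = as.numeric(key[, 2]),
                     n = as.integer(n),
                     iqr_pct = iqr_pct)
  grid <- grid[order(grid$diameter_bin, grid$fT), ]
  rownames(grid) <- NULL
  pop <- grid$iqr_pct[!is.na(grid$iqr_pct)]
  if (!length(pop)) {
    warning("no cell with N >= ", min_n, "; IQR grid is empty")
  }
  structure(list(grid = grid,
                 max_iqr_pct = if (length(pop)) max(pop) else NA_real_,
                 median_iqr_pct = if (length(pop)) stats::median(pop) else NA_real_),
            class = "iqr_grid")
}

#' @export
print.iqr_grid <- function(x, ...) {
  pop <- sum(!is.na(x$grid$iqr_pct))
  cat(sprintf("IQR grid: %d cells (%d populated), max = %.2f%%, median = %.2f%%\n",
              nrow(x$grid), pop, x$max_iqr_pct, x$median_iqr_pct))
  invisible(x)
}
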