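#' Two-channel 3D stack of a microbubble coating
#'
#' Container for a confocal acquisition of one bubble: a green (ligand)
#' and a red (lipid-phase dye) intensity array on a common voxel grid,
#' plus, once fitted, the sphere geometry of the coating.
#'
#' @param green,red 3D numeric arrays (x, y, z), same dimensions.
#' @param voxel Voxel size `c(dx, dy, dz)` in metres, all positive.
#' @param center Fitted sphere centre in voxel coordinates, or `NULL`.
#' @param radius Fitted sphere radius (m), or `NULL`; must exceed twice the
#'   largest voxel dimension.
#'
#' @return An object of class `confocal_shell`.
#' @export
confocal_shell <- function(green, red, voxel, center = NULL, radius = NULL) {
  stopifnot(is.array(green), is.array(red),
            length(dim(green)) == 3L, identical(dim(green), dim(red)))
  if (length(voxel) != 3L || any(!is.finite(voxel)) || any(voxel <= 0)) {
    stop("voxel must be three positive sizes (m)")
  }
  if (!is.null(radius) && radius <= 2 * max(voxel)) {
    stop("fitted radius must exceed 2 x the largest voxel size")
  }
  structure(list(green = green, red = red, voxel = as.numeric(voxel),
                 center = center, radius = radius),
            class = "confocal_shell")
}

#' @export
print.confocal_shell <- function(x, ...) {
  d <- dim(x$red)
  cat(sprintf("Confocal shell stack: %d x %d x %d voxels (%.2g x %.2g x %.2g um)",
              d[1], d[2], d[3],
              x$voxel[1] * 1e6, x$voxel[2] * 1e6, x$voxel[3] * 1e6))
  if (!is.null(x$radius)) {
    cat(sprintf(", fitted R = %.2f um", x$radius * 1e6))
  }
  cat("\n")
  invisible(x)
}

# physical voxel-centre coordinates along each axis
.axis_coords <- function(dims, voxel) {
  lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * voxel[a])
}

# radial distance of every voxel from a physical-space centre
.radial_distance <- function(dims, voxel, center_phys) {
  ax <- .axis_coords(dims, voxel)
  outer(outer((ax[[1]] - center_phys[1])^2,
              (ax[[2]] - center_phys[2])^2, "+"),
        (ax[[3]] - center_phys[3])^2, "+")^0.5
}

#' Fit a sphere to the coating signal
#'
#' Locates the coating as an intensity-weighted algebraic least-squares
#' sphere through the voxels of the chosen channel that exceed an Otsu
#' threshold (weights are the intensities above threshold). Works on
#' anisotropic voxels by fitting in physical coordinates.
#'
#' @param shell A [confocal_shell()] (geometry fields may be unset).
#' @param channel `"red"` (default; the lipid dye outlines the shell) or
#'   `"green"`.
#' @param threshold Intensity threshold; default Otsu on the channel.
#'
#' @return The input `confocal_shell` with `center` (voxel coordinates)
#'   and `radius` (m) filled in.
#' @export
fit_shell <- function(shell, channel = c("red", "green"), threshold = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(shell, "confocal_shell"))
  I <- shell[[channel]]
  if (diff(range(I)) == 0) stop("no shell signal: channel is constant")
  thr <- threshold %||% otsu_threshold(as.numeric(I))
  idx <- which(I > thr)
  if (length(idx) < 10L) stop("no shell signal above threshold")
  co <- arrayInd(idx, dim(I))
  p <- cbind((co[, 1] - 0.5) * shell$voxel[1],
             (co[, 2] - 0.5) * shell$voxel[2],
             (co[, 3] - 0.5) * shell$voxel[3])
  w <- as.numeric(I[idx]) - thr
  # algebraic sphere fit: |p|^2 = 2 c . p + (r^2 - |c|^2), linear in (c, b)
  sphere_fit <- function(p, w) {
    A <- cbind(2 * p, 1)
    beta <- unname(stats::lm.wfit(A, rowSums(p^2), w)$coefficients)
    ctr <- beta[1:3]
    r2 <- beta[4] + sum(ctr^2)
    if (!is.finite(r2) || r2 <= 0) stop("sphere fit failed")
    list(center = ctr, radius = sqrt(r2))
  }
  fit1 <- sphere_fit(p, w)
  # second pass restricted to a band around the first sphere, so bright
  # off-shell structures (buckles) cannot bias the geometry outward
  dist1 <- sqrt(colSums((t(p) - fit1$center)^2))
  keep <- abs(dist1 - fit1$radius) <= 3 * max(shell$voxel)
  fit2 <- if (sum(keep) >= 10L) sphere_fit(p[keep, , drop = FALSE], w[keep])
  else fit1
  ctr <- fit2$center
  radius <- fit2$radius
  ext <- dim(I) * shell$voxel
  if (radius > max(ext)) stop("fitted radius exceeds the stack bounds")
  shell$center <- ctr / shell$voxel + 0.5
  shell$radius <- radius
  shell
}

#' Equal-area angular partition of a spherical coating
#'
#' Subdivides the sphere into `n_bands x n_sectors` parts (default 4 x 8 =
#' 32): polar bands bounded at equal-area colatitudes (equal steps in
#' cos(theta)) crossed with equal azimuthal sectors. All parts have area
#' `4 pi R^2 / 32`, so area-based scores are quantized in uniform steps.
#'
#' @param n_bands Number of polar bands, default 4.
#' @param n_sectors Number of azimuthal sectors, default 8.
#'
#' @return An object of class `part_partition` with `cos_bounds`,
#'   `phi_bounds` and `n_parts`.
#' @export
part_partition <- function(n_bands = 4L, n_sectors = 8L) {
  stopifnot(n_bands >= 1L, n_sectors >= 1L)
  structure(list(n_bands = as.integer(n_bands),
                 n_sectors = as.integer(n_sectors),
                 n_parts = as.integer(n_bands * n_sectors),
                 cos_bounds = seq(1, -1, length.out = n_bands + 1L),
                 phi_bounds = seq(-pi, pi, length.out = n_sectors + 1L)),
            class = "part_partition")
}

#' Assign directions to parts of the partition
#'
#' @param partition A [part_partition()].
#' @param costheta Cosine of the colatitude (z-axis polar angle), in
#'   \[-1, 1\].
#' @param phi Azimuth (rad), in \[-pi, pi\].
#'
#' @return Integer part index in `1:n_parts` (parts numbered band-major:
#'   part = (band - 1) * n_sectors + sector).
#' @export
part_index <- function(partition, costheta, phi) {
  nb <- partition$n_bands
  ns <- partition$n_sectors
  band <- pmin(nb, 1L + floor((1 - costheta) / (2 / nb)))
  sector <- pmin(ns, 1L + floor((phi + pi) / (2 * pi / ns)))
  as.integer((band - 1L) * ns + sector)
}

#' Direction of each part centre
#'
#' Unit vectors at the (equal-area) centre of every part, ordered by part
#' index. Used by the synthetic generator as a quasi-uniform grid of
#' candidate domain sites.
#'
#' @param partition A [part_partition()].
#' @return An `n_parts x 3` matrix of unit vectors.
#' @export
part_centers <- function(partition) {
  nb <- partition$n_bands
  ns <- partition$n_sectors
  cosb <- (utils::head(partition$cos_bounds, -1) +
             utils::tail(partition$cos_bounds, -1)) / 2
  phib <- (utils::head(partition$phi_bounds, -1) +
             utils::tail(partition$phi_bounds, -1)) / 2
  out <- matrix(0, nb * ns, 3)
  for (b in seq_len(nb)) {
    st <- sqrt(1 - cosb[b]^2)
    for (s in seq_len(ns)) {
      out[(b - 1) * ns + s, ] <- c(st * cos(phib[s]), st * sin(phib[s]), cosb[b])
    }
  }
  out
}

#' Per-part mean intensities of the coating
#'
#' Collects the voxels within `thickness/2` of the fitted sphere radius,
#' assigns each to the part containing its direction, and reports the mean
#' green and red intensity per part. Parts with no voxels (e.g. poles
#' clipped by the imaged volume) are flagged excluded and removed from the
#' analyzed surface area.
#'
#' @param shell A fitted [confocal_shell()] (`center`, `radius` set).
#' @param partition A [part_partition()], default 4 x 8.
#' @param thickness Radial band thickness (m); default 3 voxels
#'   (`3 * max(voxel)`).
#'
#' @return A data frame of class `part_table` with one row per part:
#'   `part`, `band`, `sector`, `I_part` (green), `I_part_rhod` (red),
#'   `n_vox`, `area_um2`, `excluded`. Attributes: `radius`, `voxel`,
#'   `analyzed_area_um2`.
#' @export
part_intensities <- function(shell, partition = part_partition(),
                             thickness = NULL) {
  stopifnot(inherits(shell, "confocal_shell"))
  if (is.null(shell$center) || is.null(shell$radius)) {
    stop("shell geometry not fitted; run fit_shell() first")
  }
  thickness <- thickness %||% (3 * max(shell$voxel))
  if (thickness < min(shell$voxel)) stop("thickness must be >= 1 voxel")
  dims <- dim(shell$red)
  cp <- (shell$center - 0.5) * shell$voxel
  d <- .radial_distance(dims, shell$voxel, cp)
  idx <- which(abs(d - shell$radius) <= thickness / 2)
  if (!length(idx)) stop("no voxels in the shell band")
  co <- arrayInd(idx, dims)
  dx <- (co[, 1] - 0.5) * shell$voxel[1] - cp[1]
  dy <- (co[, 2] - 0.5) * shell$voxel[2] - cp[2]
  dz <- (co[, 3] - 0.5) * shell$voxel[3] - cp[3]
  dd <- d[idx]
  ct <- pmin(pmax(dz / dd, -1), 1)
  phi <- atan2(dy, dx)
  part <- part_index(partition, ct, phi)

  np <- partition$n_parts
  n_vox <- tabulate(part, nbins = np)
  sum_g <- rep(0, np); sum_r <- rep(0, np)
  gs <- as.numeric(shell$green[idx]); rs <- as.numeric(shell$red[idx])
  for (j in seq_len(np)) {
    sel <- part == j
    if (any(sel)) {
      sum_g[j] <- sum(gs[sel])
      sum_r[j] <- sum(rs[sel])
    }
  }
  excluded <- n_vox == 0L
  area_part <- 4 * pi * (shell$radius * 1e6)^2 / np
  tab <- data.frame(
    part = seq_len(np),
    band = rep(seq_len(partition$n_bands), each = partition$n_sectors),
    sector = rep(seq_len(partition$n_sectors), partition$n_bands),
    I_part = ifelse(excluded, NA_real_, sum_g / pmax(n_vox, 1L)),
    I_part_rhod = ifelse(excluded, NA_real_, sum_r / pmax(n_vox, 1L)),
    n_vox = n_vox,
    area_um2 = ifelse(excluded, 0, area_part),
    excluded = excluded)
  structure(tab,
            class = c("part_table", "data.frame"),
            radius = shell$radius, voxel = shell$voxel,
            analyzed_area_um2 = sum(tab$area_um2))
}

#' Construct a part table from given intensities
#'
#' Builds a [part_intensities()]-compatible table directly from per-part
#' mean intensities, e.g. to apply the classification rules to externally
#' computed or hand-constructed part data. All parts get the equal-area
#' share of the sphere surface.
#'
#' @param I_part Green-channel mean intensity per part.
#' @param I_part_rhod Red-channel mean intensity per part (defaults to
#'   `I_part`).
#' @param radius Sphere radius (m).
#' @param partition A [part_partition()] with `n_parts == length(I_part)`.
#' @param excluded Logical per part, default none.
#'
#' @return A `part_table`.
#' @export
part_table <- function(I_part, I_part_rhod = I_part, radius,
                       partition = part_partition(), excluded = NULL) {
  np <- partition$n_parts
  stopifnot(length(I_part) == np, length(I_part_rhod) == np)
  excluded <- excluded %||% rep(FALSE, np)
  area_part <- 4 * pi * (radius * 1e6)^2 / np
  tab <- data.frame(
    part = seq_len(np),
    band = rep(seq_len(partition$n_bands), each = partition$n_sectors),
    sector = rep(seq_len(partition$n_sectors), partition$n_bands),
    I_part = ifelse(excluded, NA_real_, I_part),
    I_part_rhod = ifelse(excluded, NA_real_, I_part_rhod),
    n_vox = ifelse(excluded, 0L, 1L),
    area_um2 = ifelse(excluded, 0, area_part),
    excluded = excluded)
  structure(tab, class = c("part_table", "data.frame"),
            radius = radius, voxel = NA_real_,
            analyzed_area_um2 = sum(tab$area_um2))
}

#' Axial-attenuation normalization factors for a cohort
#'
#' Confocal acquisitions attenuate with depth, leaving the equator of the
#' bubbles dimmer than the poles. The correction factor of part `j` is the
#' global median intensity (over all parts of all bubbles) divided by the
#' across-bubble median intensity of part `j`; multiplying part `j` by its
#' factor flattens the systematic angular profile while leaving an
#' unbiased cohort essentially untouched. Factors are computed per channel.
#'
#' Parts that a bubble's own classification rules already flag are
#' uninformative about the optical artifact and would corrupt the cohort
#' medians (a dye-excluding LC part says nothing about laser attenuation),
#' so per bubble the red values below one third of that bubble's median
#' and the green values deviating from the median by more than two thirds
#' of it are left out of the factor estimation. A part with no informative
#' value left borrows the median factor of its polar band (the artifact is
#' a polar profile); a part beyond all fallbacks gets a capped factor and
#' is flagged.
#'
#' @param cohort List of >= 3 [part_intensities()] tables on the same
#'   partition.
#' @param cap Upper bound for the factors, default 10.
#'
#' @return List of class `axial_factors`: `green` and `red` factor
#'   vectors (length `n_parts`), plus `flagged` (logical per part).
#' @export
axial_normalization <- function(cohort, cap = 10) {
  if (length(cohort) < 3L) {
    stop("axial normalization needs a cohort of >= 3 microbubbles")
  }
  np <- nrow(cohort[[1]])
  band <- cohort[[1]]$band
  one <- function(col, informative) {
    m <- vapply(cohort, function(pt) {
      v <- pt[[col]]
      v[!informative(v)] <- NA_real_
      v
    }, numeric(np))
    med_j <- apply(m, 1, stats::median, na.rm = TRUE)
    global <- stats::median(m, na.rm = TRUE)
    f <- global / med_j
    # polar-band fallback for parts with no informative cohort value
    miss <- !is.finite(f) | f <= 0
    if (any(miss) && !all(miss)) {
      band_f <- tapply(f[!miss], band[!miss], stats::median)
      f[miss] <- band_f[as.character(band[miss])]
    }
    bad <- !is.finite(f) | f <= 0
    f[bad] <- cap
    f[f > cap] <- cap
    list(f = f, bad = bad)
  }
  g <- one("I_part", function(v) {
    med <- stats::median(v, na.rm = TRUE)
    !is.na(v) & abs(v - med) <= (2 / 3) * med
  })
  r <- one("I_part_rhod", function(v) {
    med <- stats::median(v, na.rm = TRUE)
    !is.na(v) & v >= med / 3
  })
  structure(list(green = g$f, red = r$f, flagged = g$bad | r$bad),
            class = "axial_factors")
}

#' Apply axial normalization factors to a part table
#'
#' @param parts A [part_intensities()] table.
#' @param factors An [axial_normalization()] result.
#' @return The part table with `I_part` and `I_part_rhod` rescaled.
#' @export
normalize_parts <- function(parts, factors) {
  stopifnot(inherits(parts, "part_table"), inherits(factors, "axial_factors"))
  parts$I_part <- parts$I_part * factors$green[parts$part]
  parts$I_part_rhod <- parts$I_part_rhod * factors$red[parts$part]
  parts
}

#' Ligand-distribution inhomogeneity of a coating
#'
#' A part is inhomogeneous when its green (ligand) intensity deviates from
#' the bubble's median part intensity by more than two-thirds of that
#' median: `|I_part - I_median| > (2/3) I_median`. Returns the percentage
#' of inhomogeneous parts among the non-excluded parts.
#'
#' @param parts A [part_intensities()] table.
#' @param threshold Deviation threshold as a fraction of the median,
#'   default 2/3.
#' @return Percentage in \[0, 100\].
#' @export
ligand_inhomogeneity <- function(parts, threshold = 2 / 3) {
  stopifnot(inherits(parts, "part_table"))
  keep <- !parts$excluded
  if (!any(keep)) stop("all parts excluded")
  I <- parts$I_part[keep]
  med <- stats::median(I)
  100 * mean(abs(I - med) > threshold * med)
}

#' Liquid-condensed (LC) phase area of a coating
#'
#' Parts are classified as LC phase when their red (rhodamine-DHPE, i.e.
#' liquid-expanded dye) intensity is below one-third of the bubble's
#' median part intensity: `I_part_rhod < (1/3) I_median_rhod`. The LC area
#' is reported in um^2 and as a percentage of the analyzed surface area;
#' with equal-area parts the percentage is quantized in multiples of
#' `100 / n_parts` (3.125% for 32 parts).
#'
#' @param parts A [part_intensities()] table.
#' @param threshold LC threshold as a fraction of the median, default 1/3.
#' @return List: `lc_area_um2`, `lc_pct`, `lc_parts` (part indices).
#' @export
lc_phase_area <- function(parts, threshold = 1 / 3) {
  stopifnot(inherits(parts, "part_table"))
  keep <- !parts$excluded
  if (!any(keep)) stop("all parts excluded")
  med <- stats::median(parts$I_part_rhod[keep])
  lc <- keep & parts$I_part_rhod < threshold * med
  lc[is.na(lc)] <- FALSE
  area <- sum(parts$area_um2[lc])
  list(lc_area_um2 = area,
       lc_pct = 100 * area / sum(parts$area_um2[keep]),
       lc_parts = parts$part[lc])
}

#' Detect buckles attached to the coating
#'
#' Buckles (lipid bilayer protrusions) appear as bright connected blobs in
#' the red channel just outside the shell. Voxels brighter than the
#' threshold, lying outside the shell band but within `max_dist` of it,
#' are labelled into 6-connected components; components with an
#' equivalent spherical diameter of at least `min_diameter` (1 um) count
#' as buckles. The count maps to the usual categories: 0 none, 1 single,
#' 2-4 multiple, >= 5 extensive (boundaries configurable).
#'
#' @param shell A fitted [confocal_shell()].
#' @param thickness Shell band thickness (m), default 3 voxels.
#' @param max_dist Maximum distance beyond the band (m), default 2 um.
#' @param min_diameter Minimum equivalent diameter (m), default 1 um.
#' @param threshold Intensity threshold; default Otsu on the red channel.
#' @param extensive_from Count at which the category becomes
#'   `"extensive"`, default 5 (2 to `extensive_from - 1` is `"multiple"`).
#'
#' @return List: `count`, `category` (factor: none/single/multiple/
#'   extensive), `blobs` (data frame with `n_vox` and `diameter_um` of all
#'   candidate blobs, including sub-threshold ones).
#' @export
detect_buckles <- function(shell, thickness = NULL, max_dist = 2e-6,
                           min_diameter = 1e-6, threshold = NULL,
                           extensive_from = 5L) {
  stopifnot(inherits(shell, "confocal_shell"))
  if (is.null(shell$center) || is.null(shell$radius)) {
    stop("shell geometry not fitted; run fit_shell() first")
  }
  thickness <- thickness %||% (3 * max(shell$voxel))
  thr <- threshold %||% otsu_threshold(as.numeric(shell$red))
  dims <- dim(shell$red)
  cp <- (shell$center - 0.5) * shell$voxel
  d <- .radial_distance(dims, shell$voxel, cp)
  # one extra voxel of clearance so shell-edge voxels (sphere-fit jitter)
  # do not leak into the buckle region as spurious single-voxel blobs
  inner <- shell$radius + thickness / 2 + max(shell$voxel)
  mask <- shell$red > thr & d > inner & d <= inner + max_dist
  cats <- c("none", "single", "multiple", "extensive")
  if (!any(mask)) {
    return(list(count = 0L, category = factor("none", levels = cats),
                blobs = data.frame(n_vox = integer(0), diameter_um = numeric(0))))
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  vol <- sizes * prod(shell$voxel)
  diam <- (6 * vol / pi)^(1 / 3)
  count <- sum(diam >= min_diameter)
  category <- if (count == 0L) "none" else if (count == 1L) "single"
  else if (count < extensive_from) "multiple" else "extensive"
  list(count = count,
       category = factor(category, levels = cats),
       blobs = data.frame(n_vox = sizes, diameter_um = diam * 1e6))
}

#' Full coating score set of one fitted shell
#'
#' Convenience wrapper: part intensities (optionally axially normalized),
#' ligand inhomogeneity, LC phase area, and buckle detection.
#'
#' @param shell A fitted [confocal_shell()].
#' @param factors Optional [axial_normalization()] factors.
#' @param partition A [part_partition()].
#' @param thickness Shell band thickness (m), default 3 voxels.
#'
#' @return List of class `coating_scores`: `inhomogeneous_pct`,
#'   `lc_area_um2`, `lc_pct`, `buckle_count`, `buckle_category`, `parts`.
#' @export
coating_scores <- function(shell, factors = NULL,
                           partition = part_partition(), thickness = NULL) {
  pt <- part_intensities(shell, partition, thickness)
  if (!is.null(factors)) pt <- normalize_parts(pt, factors)
  lc <- lc_phase_area(pt)
  bk <- detect_buckles(shell, thickness)
  structure(list(inhomogeneous_pct = ligand_inhomogeneity(pt),
                 lc_area_um2 = lc$lc_area_um2,
                 lc_pct = lc$lc_pct,
                 buckle_count = bk$count,
                 buckle_category = bk$category,
                 parts = pt),
            class = "coating_scores")
}

#' @export
print.coating_scores <- function(x, ...) {
  cat(sprintf("Coating scores: %.1f%% inhomogeneous parts, LC %.2f um^2 (%.1f%%), %d buckle(s) [%s]\n",
              x$inhomogeneous_pct, x$lc_area_um2, x$lc_pct,
              x$buckle_count, as.character(x$buckle_category)))
  invisible(x)
}
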