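#' Synthetic two-channel confocal stack of a coated microbubble
#'
#' Voxelizes a spherical coating with known ground truth: a bright shell in
#' both channels, dye-excluding (dark) liquid-condensed domains in the red
#' channel, ligand-enriched hotspot patches in the green channel, attached
#' bright buckle blobs outside the shell, and a polar depth-attenuation
#' artifact.
#'
#' Domains and hotspots are spherical caps. Candidate cap centres are drawn
#' (seeded) from the 32 equal-area part-centre directions of the canonical
#' 4 x 8 partition — a quasi-uniform angular grid; sites are accepted
#' greedily under a non-overlap constraint, and when the requested packing
#' cannot be met without overlap the generator falls back to overlapping
#' placement and flags it (the realized dark fraction is then recomputed
#' from the voxelized shell and stored in the truth sidecar). By default
#' the requested LC coverage is realized as `round(32 * lc_fraction)` caps
#' of one part quantum (3.125% of the surface) each.
#'
#' @param diameter_um Bubble diameter (um).
#' @param lc_fraction Target dark-domain surface coverage in \[0, 1\].
#' @param n_domains Number of dark caps; default `round(32 * lc_fraction)`.
#' @param hotspots List with `n` (count, default 0), `contrast`
#'   (multiplier, default 3) and `quanta` (cap area in part quanta,
#'   default 1) for green-channel ligand patches.
#' @param buckles List of buckles, each a list with `diameter_um` and
#'   optionally `dir` (unit 3-vector); direction sampled when absent.
#' @param attenuation Either a number `a` in \[0, 1) giving the polar
#'   profile `1 - a * (1 - |cos(theta)|)` (equator dimmed by `a`), or a
#'   function of the colatitude `theta`. 0 disables the artifact.
#' @param voxel_um Isotropic voxel size (um), must be <= diameter/10.
#' @param shell_thickness_vox Drawn radial thickness of the coating in
#'   voxels, default 3 (sub-voxel monolayer plus PSF blur).
#' @param shell_value Shell intensity (arbitrary units), default 100.
#' @param noise_sigma Additive Gaussian noise s.d. in intensity units,
#'   default 0.
#' @param rotation Optional 3 x 3 rotation matrix applied to all domain,
#'   hotspot and buckle directions (used to test rotation robustness).
#' @param seed Integer seed fixing all randomness, or `NULL`.
#'
#' @return A [confocal_shell()] (geometry unset; use [fit_shell()]) with
#'   attribute `truth`: nominal and realized LC fraction, cap directions
#'   and angular radii, hotspot and buckle specifications, the true centre
#'   (voxel coordinates) and radius (m), attenuation, overlap flag, seed.
#' @export
synth_shell <- function(diameter_um, lc_fraction = 0, n_domains = NULL,
                        hotspots = list(n = 0), buckles = list(),
                        attenuation = 0, voxel_um = 0.1,
                        shell_thickness_vox = 3, shell_value = 100,
                        noise_sigma = 0,
                        rotation = NULL, seed = NULL) {
  if (lc_fraction < 0 || lc_fraction > 1) stop("lc_fraction must be in [0, 1]")
  if (voxel_um > diameter_um / 10) {
    stop("voxel_um must be <= diameter_um / 10")
  }
  R <- diameter_um / 2 * 1e-6
  vox <- voxel_um * 1e-6
  t_draw <- shell_thickness_vox * vox
  bmax <- if (length(buckles)) {
    max(vapply(buckles, function(b) b$diameter_um, numeric(1))) * 1e-6
  } else 0
  margin <- t_draw + bmax + 0.3e-6
  n_side <- ceiling(2 * (R + margin) / vox)
  dims <- rep(as.integer(n_side), 3L)
  cp <- rep(n_side * vox / 2, 3)

  with_local_seed(seed, {
    partition <- part_partition()
    sites <- part_centers(partition)

    q <- 1 / partition$n_parts
    if (is.null(n_domains)) n_domains <- round(lc_fraction / q)
    caps <- .place_caps(sites, n_domains,
                        rep(if (n_domains) lc_fraction / n_domains else 0,
                            n_domains))

    hs_n <- hotspots$n %||% 0
    hs_contrast <- hotspots$contrast %||% 3
    hs_quanta <- hotspots$quanta %||% 1
    hs <- .place_caps(sites, hs_n, rep(hs_quanta * q, hs_n))

    bk <- lapply(buckles, function(b) {
      dir <- b$dir %||% {
        v <- stats::rnorm(3)
        v / sqrt(sum(v^2))
      }
      list(diameter_um = b$diameter_um, dir = dir)
    })

    if (!is.null(rotation)) {
      if (nrow(caps$dirs)) caps$dirs <- caps$dirs %*% t(rotation)
      if (nrow(hs$dirs)) hs$dirs <- hs$dirs %*% t(rotation)
      bk <- lapply(bk, function(b) {
        b$dir <- as.numeric(rotation %*% b$dir)
        b
      })
    }

    d <- .radial_distance(dims, vox * c(1, 1, 1), cp)
    in_shell <- abs(d - R) <= t_draw / 2
    idx <- which(in_shell)
    co <- arrayInd(idx, dims)
    ux <- ((co[, 1] - 0.5) * vox - cp[1]) / d[idx]
    uy <- ((co[, 2] - 0.5) * vox - cp[2]) / d[idx]
    uz <- ((co[, 3] - 0.5) * vox - cp[3]) / d[idx]

    att_fun <- if (is.function(attenuation)) {
      attenuation
    } else {
      a <- attenuation
      function(theta) 1 - a * (1 - abs(cos(theta)))
    }
    att <- att_fun(acos(pmin(pmax(uz, -1), 1)))

    red_v <- rep(shell_value, length(idx))
    green_v <- rep(shell_value, length(idx))

    dark <- rep(FALSE, length(idx))
    if (nrow(caps$dirs)) {
      for (k in seq_len(nrow(caps$dirs))) {
        ca <- caps$dirs[k, ]
        ang <- ux * ca[1] + uy * ca[2] + uz * ca[3]
        dark <- dark | ang > cos(caps$alpha[k])
      }
    }
    red_v[dark] <- 0
    if (nrow(hs$dirs)) {
      hot <- rep(FALSE, length(idx))
      for (k in seq_len(nrow(hs$dirs))) {
        ca <- hs$dirs[k, ]
        ang <- ux * ca[1] + uy * ca[2] + uz * ca[3]
        hot <- hot | ang > cos(hs$alpha[k])
      }
      green_v[hot] <- green_v[hot] * hs_contrast
    }

    red <- array(0, dims)
    green <- array(0, dims)
    red[idx] <- red_v * att
    green[idx] <- green_v * att

    for (b in bk) {
      rb <- b$diameter_um / 2 * 1e-6
      bc <- cp + b$dir * (R + rb)
      db <- .radial_distance(dims, vox * c(1, 1, 1), bc)
      red[db <= rb] <- 1.5 * shell_value
    }

    if (noise_sigma > 0) {
      red <- red + stats::rnorm(length(red), 0, noise_sigma)
      green <- green + stats::rnorm(length(green), 0, noise_sigma)
    }

    out <- confocal_shell(green, red, voxel = vox * c(1, 1, 1))
    attr(out, "truth") <- list(
      lc_fraction = lc_fraction,
      realized_lc_fraction = if (length(idx)) sum(dark) / length(idx) else 0,
      n_domains = n_domains,
      cap_dirs = caps$dirs, cap_alpha = caps$alpha,
      overlap = caps$overlap,
      hotspots = list(n = hs_n, contrast = hs_contrast,
                      dirs = hs$dirs, alpha = hs$alpha),
      buckles = bk,
      attenuation = attenuation,
      center = cp / vox + 0.5, radius = R,
      shell_value = shell_value, noise_sigma = noise_sigma,
      seed = seed)
    out
  })
}

# Greedily place n caps with given area fractions on candidate unit-vector
# sites: shuffled sites are accepted while caps stay disjoint; if the
# packing cannot be completed, remaining caps are placed on the unused
# sites with the largest separation and the overlap flag is set.
.place_caps <- function(sites, n, area_fracs) {
  if (n == 0) {
    return(list(dirs = matrix(0, 0, 3), alpha = numeric(0), overlap = FALSE))
  }
  if (any(area_fracs > 1)) stop("infeasible domain packing: cap larger than sphere")
  alpha <- acos(pmin(pmax(1 - 2 * area_fracs, -1), 1))
  ord <- sample.int(nrow(sites))
  chosen <- integer(0)
  overlap <- FALSE
  for (i in ord) {
    if (length(chosen) >= n) break
    k <- length(chosen) + 1L
    ok <- TRUE
    for (jj in seq_along(chosen)) {
      sep <- acos(pmin(pmax(sum(sites[i, ] * sites[chosen[jj], ]), -1), 1))
      if (sep < alpha[k] + alpha[jj]) {
        ok <- FALSE
        break
      }
    }
    if (ok) chosen <- c(chosen, i)
  }
  if (length(chosen) < n) {
    overlap <- TRUE
    rest <- setdiff(ord, chosen)
    if (length(rest) < n - length(chosen)) {
      stop("infeasible domain packing: not enough candidate sites")
    }
    chosen <- c(chosen, rest[seq_len(n - length(chosen))])
  }
  list(dirs = sites[chosen, , drop = FALSE], alpha = alpha, overlap = overlap)
}
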