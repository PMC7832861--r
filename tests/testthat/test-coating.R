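test_that("the 4x8 partition tiles the sphere in equal-area parts", {
  pp <- part_partition()
  expect_equal(pp$n_parts, 32L)

  # every direction maps to exactly one part; areas are equal by construction
  set.seed(1)
  n <- 20000L
  ct <- runif(n, -1, 1)
  phi <- runif(n, -pi, pi)
  idx <- part_index(pp, ct, phi)
  expect_true(all(idx >= 1L & idx <= 32L))
  # uniform-on-sphere sampling in (cos theta, phi) lands uniformly in parts
  counts <- tabulate(idx, 32L)
  expect_lt(max(abs(counts - n / 32) / (n / 32)), 0.15)

  # rotating 45 degrees about the polar axis permutes azimuthal sectors
  idx_rot <- part_index(pp, ct, ifelse(phi + pi / 4 > pi,
                                       phi + pi / 4 - 2 * pi, phi + pi / 4))
  band <- (idx - 1L) %/% 8L
  sector <- (idx - 1L) %% 8L
  expect_true(all(idx_rot == band * 8L + (sector + 1L) %% 8L + 1L))

  ctr <- part_centers(pp)
  expect_equal(dim(ctr), c(32L, 3L))
  expect_equal(rowSums(ctr^2), rep(1, 32), tolerance = 1e-12)
  expect_true(all(part_index(pp, ctr[, 3], atan2(ctr[, 2], ctr[, 1])) == 1:32))
})

test_that("sphere fitting recovers synthetic shells to sub-voxel accuracy", {
  sh <- synth_shell(5.0, seed = 1)
  tru <- attr(sh, "truth")
  fs <- fit_shell(sh)
  expect_lt(max(abs(fs$center - tru$center)), 1)          # within 1 voxel
  expect_equal(fs$radius, tru$radius, tolerance = 0.02)   # within 2%

  expect_error(fit_shell(confocal_shell(array(1, c(12, 12, 12)),
                                        array(1, c(12, 12, 12)),
                                        rep(1e-7, 3))), "constant")
})

test_that("part intensities are exact on uniform shells", {
  # coating drawn thicker than the measurement band so every band voxel
  # carries the shell intensity
  sh <- synth_shell(5.0, seed = 2, shell_value = 80, shell_thickness_vox = 9)
  fs <- fit_shell(sh)
  pt <- part_intensities(fs)
  expect_equal(nrow(pt), 32L)
  expect_false(any(pt$excluded))
  expect_equal(pt$I_part, rep(80, 32), tolerance = 1e-6)
  expect_equal(pt$I_part_rhod, rep(80, 32), tolerance = 1e-6)
  # parts tile the fitted sphere exactly once
  expect_equal(sum(pt$area_um2), 4 * pi * (fs$radius * 1e6)^2,
               tolerance = 1e-9)
  expect_equal(sd(pt$area_um2), 0)

  # doubling the band thickness leaves the mean of a constant unchanged
  pt2 <- part_intensities(fs, thickness = 6 * max(fs$voxel))
  expect_equal(pt2$I_part_rhod, pt$I_part_rhod, tolerance = 1e-6)
})

test_that("the inhomogeneity rule |I - median| > 2/3 median is exact", {
  pt <- part_table(rep(10, 32), radius = 2.5e-6)
  expect_equal(ligand_inhomogeneity(pt), 0)

  # |2 - 10| = 8 > 20/3 -> one inhomogeneous part
  pt2 <- part_table(c(rep(10, 31), 2), radius = 2.5e-6)
  expect_equal(ligand_inhomogeneity(pt2), 100 / 32)

  # |4 - 10| = 6 < 20/3 -> none
  pt3 <- part_table(c(rep(10, 31), 4), radius = 2.5e-6)
  expect_equal(ligand_inhomogeneity(pt3), 0)
})

test_that("the LC rule I_rhod < 1/3 median is exact and areas are quantized", {
  d_um <- 5
  pt <- part_table(rep(10, 32), radius = d_um / 2 * 1e-6)
  expect_equal(lc_phase_area(pt)$lc_pct, 0)

  # one part at 3 with median 10: 3 < 10/3 -> one part quantum
  pt2 <- part_table(rep(10, 32), c(rep(10, 31), 3), radius = d_um / 2 * 1e-6)
  lc <- lc_phase_area(pt2)
  expect_equal(lc$lc_pct, 100 / 32)
  expect_equal(lc$lc_area_um2, pi * d_um^2 / 32, tolerance = 1e-9)

  # boundary: exactly one third is NOT below one third
  pt3 <- part_table(rep(9, 32), c(rep(9, 31), 3), radius = d_um / 2 * 1e-6)
  expect_equal(lc_phase_area(pt3)$lc_pct, 0)

  # excluded parts shrink the analyzed area; percentages stay in [0, 100]
  excl <- c(rep(FALSE, 28), rep(TRUE, 4))
  pt4 <- part_table(rep(10, 32), c(rep(10, 27), 1, rep(10, 4)),
                    radius = d_um / 2 * 1e-6, excluded = excl)
  expect_equal(lc_phase_area(pt4)$lc_pct, 100 / 28)
})

test_that("synthetic LC coverage is recovered within one part quantum", {
  for (case in list(c(6.0, 0.10), c(5.6, 0.22), c(6.4, 0.35), c(5.2, 0))) {
    sh <- synth_shell(case[1], lc_fraction = case[2], seed = round(31 + case[1]))
    lc <- lc_phase_area(part_intensities(fit_shell(sh)))
    # within one 3.125% part quantum of the generating coverage
    expect_lt(abs(lc$lc_pct - 100 * case[2]), 100 / 32 + 1e-9)
    # quantization: always a multiple of one part quantum
    expect_lt(abs(lc$lc_pct %% (100 / 32)), 1e-9)
  }
})

test_that("axial attenuation is corrected by cohort normalization", {
  cohort <- lapply(1:5, function(s) {
    part_intensities(fit_shell(synth_shell(6.0, attenuation = 0.5, seed = s)))
  })
  fac <- axial_normalization(cohort)
  pt <- normalize_parts(cohort[[1]], fac)
  # corrected parts uniform within 5%
  expect_lt(diff(range(pt$I_part)) / median(pt$I_part), 0.05)
  expect_lt(diff(range(pt$I_part_rhod)) / median(pt$I_part_rhod), 0.05)

  # an unbiased cohort is left essentially untouched
  flat <- lapply(6:9, function(s) {
    part_intensities(fit_shell(synth_shell(5.0, lc_fraction = 0.22, seed = s)))
  })
  fac0 <- axial_normalization(flat)
  for (ptf in flat) {
    before <- lc_phase_area(ptf)$lc_pct
    after <- lc_phase_area(normalize_parts(ptf, fac0))$lc_pct
    expect_equal(after, before, tolerance = 0.5)
    expect_equal(ligand_inhomogeneity(normalize_parts(ptf, fac0)),
                 ligand_inhomogeneity(ptf), tolerance = 0.5)
  }

  expect_error(axial_normalization(cohort[1]), ">= 3")
})

test_that("scores are invariant under sector-permuting rotations", {
  # 45-degree steps about the polar axis map parts onto parts, so the
  # quantized scores are exactly preserved
  base <- synth_shell(6.4, lc_fraction = 0.22, hotspots = list(n = 3),
                      seed = 77)
  lc0 <- lc_phase_area(part_intensities(fit_shell(base)))$lc_pct
  ih0 <- ligand_inhomogeneity(part_intensities(fit_shell(base)))
  for (k in c(1, 3, 5)) {
    rot <- rotation_matrix(c(0, 0, 1), k * pi / 4)
    shr <- synth_shell(6.4, lc_fraction = 0.22, hotspots = list(n = 3),
                       rotation = rot, seed = 77)
    ptr <- part_intensities(fit_shell(shr))
    expect_equal(lc_phase_area(ptr)$lc_pct, lc0, tolerance = 1e-9)
    expect_equal(ligand_inhomogeneity(ptr), ih0, tolerance = 1e-9)
  }
})

test_that("buckles are counted above the 1 um size threshold and categorized", {
  clean <- fit_shell(synth_shell(5.0, seed = 41))
  b0 <- detect_buckles(clean)
  expect_equal(b0$count, 0L)
  expect_equal(as.character(b0$category), "none")

  one <- fit_shell(synth_shell(5.0, buckles = list(list(diameter_um = 1.2)),
                               seed = 42))
  b1 <- detect_buckles(one)
  expect_equal(b1$count, 1L)
  expect_equal(as.character(b1$category), "single")

  small <- fit_shell(synth_shell(5.0, buckles = list(list(diameter_um = 0.8)),
                                 seed = 43))
  expect_equal(detect_buckles(small)$count, 0L)

  many <- fit_shell(synth_shell(6.0, seed = 44, buckles = lapply(
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1)),
    function(d) list(diameter_um = 1.3, dir = d))))
  bm <- detect_buckles(many)
  expect_equal(bm$count, 5L)
  expect_equal(as.character(bm$category), "extensive")

  three <- fit_shell(synth_shell(6.0, seed = 45, buckles = lapply(
    list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    function(d) list(diameter_um = 1.3, dir = d))))
  expect_equal(as.character(detect_buckles(three)$category), "multiple")
})

test_that("ligand hotspots register as inhomogeneous parts", {
  sh <- synth_shell(6.0, hotspots = list(n = 4, contrast = 3), seed = 55)
  ih <- ligand_inhomogeneity(part_intensities(fit_shell(sh)))
  expect_gte(ih, 100 * 3 / 32)   # at least 3 of the 4 patches flagged
  expect_lte(ih, 100 * 6 / 32)
})
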