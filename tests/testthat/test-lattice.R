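test_that("point-to-box distance follows the per-axis clamp", {
  h <- c(60, 10, 10)
  expect_equal(distance_point_to_box(c(0, 0, 0), half_dims = h), 0)
  expect_equal(distance_point_to_box(c(60, 10, 10), half_dims = h), 0)  # on the surface
  expect_equal(distance_point_to_box(c(70, 0, 0), half_dims = h), 10)
  expect_equal(distance_point_to_box(c(70, 20, 0), half_dims = h), sqrt(200))
  # vectorized form
  pts <- rbind(c(70, 0, 0), c(0, 0, 0), c(-70, -20, 15))
  expect_equal(distance_point_to_box(pts, half_dims = h),
               c(10, 0, sqrt(10^2 + 10^2 + 5^2)))

  # Monte-Carlo surface-sampling oracle: the sampled minimum approaches the
  # true distance from above
  set.seed(44)
  for (m in 1:4) {
    p <- runif(3, -150, 150)
    center <- c(0, 0, 0)
    d <- distance_point_to_box(p, center, h)
    mc <- oracle_box_distance_mc(p, center, h)
    if (d > 0) {
      expect_gte(mc, d - 1e-9)
      expect_lt(mc - d, 0.3)
    } else {
      expect_equal(mc, 0)
    }
  }
})

test_that("farthest-point distance is the corner maximum", {
  h <- c(60, 10, 10)
  # coincident boxes
  expect_equal(farthest_point_distance(c(0, 0, 0), h), 0)
  # face-sharing neighbour directly above: far face offset 20
  expect_equal(farthest_point_distance(c(0, 20, 0), h), 20)
  # face-sharing along x: far-face offset equals the cell length
  expect_equal(farthest_point_distance(c(120, 0, 0), h), 120)
  # grid-maximization oracle on random lattice offsets
  set.seed(12)
  for (m in 1:5) {
    nc <- c(120, 20, 20) * sample(-2:2, 3, replace = TRUE)
    expect_equal(farthest_point_distance(nc, h),
                 oracle_farthest_grid(nc, h, c(0, 0, 0), h), tolerance = 1e-9)
  }
})

test_that("voxel volume fractions hit their limits and self-converge", {
  h <- c(60, 10, 10)
  expect_equal(voxel_fraction_within(c(0, 20, 0), h, radius = 1e6), 1)
  expect_equal(voxel_fraction_within(c(0, 40, 0), h, radius = 0), 0)
  f1 <- voxel_fraction_within(c(0, 20, 0), h, radius = 20, resolution = 1)
  f05 <- voxel_fraction_within(c(0, 20, 0), h, radius = 20, resolution = 0.5)
  expect_lt(abs(f1 - f05), 0.02)
  expect_warning(voxel_fraction_within(c(0, 20, 0), h, radius = 20, resolution = 7),
                 "resolution")
  expect_error(voxel_fraction_within(c(0, 20, 0), h, radius = 20, resolution = 0),
               class = "aavrange_config_error")
})

test_that("coverage counting matches the exhaustive-offset brute force", {
  spec <- lattice_spec()
  for (pk in c("axis_aligned", "brick_staggered_x")) {
    sp <- lattice_spec(packing = pk)
    for (cr in list(c("whole_cell", "analytic"), c("whole_cell", "voxel"),
                    c("center_in", "analytic"), c("half_volume", "voxel"))) {
      res <- count_affected(sp, 84.5, coverage_criterion(cr[1], classify = cr[2]))
      oracle <- oracle_count_affected(c(120, 20, 20), 84.5, cr[1],
                                      classify = cr[2], packing = pk)
      expect_identical(res$n_affected, as.integer(oracle),
                       label = sprintf("N (%s, %s/%s)", pk, cr[1], cr[2]))
    }
  }
  # the center-in count under the default packing equals the known 158
  expect_identical(count_affected(spec, 84.5,
                                  coverage_criterion("center_in"))$n_affected, 158L)
})

test_that("zero radius leaves only the infected cell", {
  for (kind in c("whole_cell", "center_in", "half_volume")) {
    res <- count_affected(lattice_spec(), 0, coverage_criterion(kind))
    expect_identical(res$n_affected, 0L)
    expect_equal(res$min_infection_rate, 1)
  }
})

test_that("affected counts are monotone in radius and ordered across criteria", {
  spec <- lattice_spec()
  radii <- c(0, 10, 25, 45, 84.5, 120)
  for (kind in c("whole_cell", "center_in", "half_volume")) {
    n <- vapply(radii, function(r)
      count_affected(spec, r, coverage_criterion(kind))$n_affected, integer(1))
    expect_true(all(diff(n) >= 0), label = paste("monotone N,", kind))
  }
  for (r in c(45, 84.5)) {
    nw <- count_affected(spec, r, coverage_criterion("whole_cell"))$n_affected
    nh <- count_affected(spec, r, coverage_criterion("half_volume"))$n_affected
    nc <- count_affected(spec, r, coverage_criterion("center_in"))$n_affected
    expect_lte(nw, nh)
    expect_lte(nw, nc)
  }
})

test_that("counts are independent of the enumeration extent", {
  for (pk in c("axis_aligned", "brick_staggered_x")) {
    sp <- lattice_spec(packing = pk)
    for (kind in c("whole_cell", "center_in")) {
      a <- count_affected(sp, 84.5, coverage_criterion(kind))$n_affected
      b <- count_affected(sp, 84.5, coverage_criterion(kind),
                          extent_factor = 2)$n_affected
      expect_identical(a, b)
    }
  }
})

test_that("the affected set is mirror-symmetric about every axis", {
  res <- count_affected(lattice_spec(), 84.5, coverage_criterion("center_in"),
                        keep_offsets = TRUE)
  aff <- res$offsets[res$offsets$affected, c("i", "j", "k")]
  key <- function(d) sort(do.call(paste, c(d, sep = ",")))
  for (ax in c("i", "j", "k")) {
    mirrored <- aff
    mirrored[[ax]] <- -mirrored[[ax]]
    expect_identical(key(mirrored), key(aff))
  }
})

test_that("analytic whole-cell classification agrees with a fine voxel oracle", {
  # every offset within |i|,|j|,|k| <= 5: farthest-corner rule vs 0.25 um voxels
  res_a <- count_affected(lattice_spec(), 84.5, coverage_criterion("whole_cell"),
                          keep_offsets = TRUE)
  res_v <- count_affected(lattice_spec(), 84.5,
                          coverage_criterion("whole_cell", voxel_resolution = 0.25,
                                             classify = "voxel"),
                          keep_offsets = TRUE)
  a <- res_a$offsets; v <- res_v$offsets
  sel <- abs(a$i) <= 5 & abs(a$j) <= 5 & abs(a$k) <= 5
  m <- merge(a[sel, c("i", "j", "k", "affected")],
             v[, c("i", "j", "k", "affected")], by = c("i", "j", "k"))
  expect_identical(m$affected.x, m$affected.y)
})

test_that("rates are exact rational bookkeeping", {
  res <- count_affected(lattice_spec(), 84.5, coverage_criterion("center_in"))
  expect_identical(res$rate_num, 1L)
  expect_identical(res$rate_den, res$n_total)
  expect_identical(res$n_total, res$n_affected + 1L)
  # exact: 1 * (N + 1) / den == 1 in integers, not floating point
  expect_identical(res$rate_num * res$n_total, res$rate_den)
})

test_that("the convention sweep documents the paper-matching convention", {
  sw <- convention_sweep()
  pm <- attr(sw, "paper_matching")
  # voxel-classified axis-aligned whole-cell reproduces the reference count
  expect_identical(pm$packing, "axis_aligned")
  expect_identical(pm$whole_cell_classify, "voxel")
  expect_identical(pm$whole_cell$n_affected, 60L)
  expect_true(pm$whole_cell$matches_reference)
  # half-volume lands at 158 under every convention examined, not 156:
  # the residual discrepancy is reported, not forced
  expect_identical(pm$half_volume$n_affected, 158L)
  expect_false(pm$half_volume$matches_reference)
  expect_identical(nrow(sw), 8L)
})

test_that("dose fold-reduction is the plain rate ratio", {
  expect_equal(rate_to_dose_note(1 / 60, 0.334)$fold_reduction, 0.334 * 60)
  expect_equal(rate_to_dose_note(0.0064, 0.0064)$fold_reduction, 1)
  expect_error(rate_to_dose_note(0.4, 0.334), class = "aavrange_config_error")
})
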