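# Zone partitioning and the area / interface-length thickness measure.

test_that("rectangle arithmetic: default partition of a 38.4 x 3 mm band", {
  seg <- flat_seg(width = 38.4, thickness = 3)
  part <- partition_zones(seg)
  expect_equal(part$bounds, c(19.2 - 4.8, 19.2 + 4.8))
  mz <- measure_zones(seg, part)
  expect_equal(mz$area_mm2, c(43.2, 28.8, 43.2), tolerance = 1e-12)
  expect_equal(mz$interface_length_mm, c(14.4, 9.6, 14.4), tolerance = 1e-12)
  expect_equal(mz$thickness_mm, rep(3, 3), tolerance = 1e-12)
})

test_that("fraction convention with a quarter width equals the absolute 4.8 mm", {
  seg <- flat_seg(width = 38.4)
  pf <- partition_zones(seg, convention = "fraction_of_extent", fraction = 0.25)
  pa <- partition_zones(seg, convention = "absolute_mm", half_width = 4.8)
  expect_equal(pf$bounds, pa$bounds)
})

test_that("partition is translation-equivariant in the notch", {
  seg0 <- flat_seg(notch_x = 19.2)
  seg2 <- flat_seg(notch_x = 21.2)
  p0 <- partition_zones(seg0)
  p2 <- partition_zones(seg2)
  expect_equal(p2$bounds, p0$bounds + 2)
  expect_equal(diff(p2$bounds), diff(p0$bounds))
})

test_that("degenerate and truncated partitions are flagged", {
  seg <- flat_seg(width = 38.4)
  pf <- partition_zones(seg, convention = "fraction_of_extent", fraction = 1.0)
  mz <- measure_zones(seg, pf)
  expect_equal(mz$area_mm2[c(1, 3)], c(0, 0))
  expect_true(all(is.na(mz$thickness_mm[c(1, 3)])))
  expect_equal(mz$thickness_mm[2], 3, tolerance = 1e-12)

  expect_error(partition_zones(seg, half_width = 20), "exceeds")
  expect_warning(p <- partition_zones(flat_seg(notch_x = 3)), "truncated")
  expect_identical(p$status, "truncated")
  expect_equal(p$bounds[1], 0)
})

test_that("zone areas and interface lengths are conserved for wiggly bands", {
  set.seed(7)
  x <- seq(0, 30, length.out = 400)
  bone <- cbind(x, 10 + 0.4 * sin(x / 2.3))
  syn <- cbind(x, 7 + 0.5 * cos(x / 3.1))
  seg <- cartilage_segmentation(bone, syn, notch_point = c(13.7, 10))
  mz <- measure_zones(seg)  # conservation asserted internally at 1e-9
  poly <- cartizone:::cartilage_polygon(bone, syn)
  expect_equal(sum(mz$area_mm2),
               abs(cartizone:::polygon_area_signed(poly)), tolerance = 1e-12)
  expect_equal(sum(mz$interface_length_mm),
               cartizone:::polyline_length(bone), tolerance = 1e-12)
})

test_that("coordinate scaling scales lengths by c, areas by c^2, thickness by c", {
  base <- make_phantom(phantom_spec(profile = piecewise_profile,
                                    width = 38.4, n_points = 801L))
  mz1 <- measure_zones(base$segmentation)
  for (c_ in c(2, 0.5)) {
    seg_c <- cartilage_segmentation(
      base$segmentation$bone_polyline * c_,
      base$segmentation$synovial_polyline * c_,
      base$segmentation$notch_point * c_)
    mzc <- measure_zones(seg_c, partition_zones(seg_c, half_width = 4.8 * c_))
    expect_equal(mzc$interface_length_mm, mz1$interface_length_mm * c_,
                 tolerance = 1e-9)
    expect_equal(mzc$area_mm2, mz1$area_mm2 * c_^2, tolerance = 1e-9)
    expect_equal(mzc$thickness_mm, mz1$thickness_mm * c_, tolerance = 1e-9)
  }
})

test_that("site readings average per-image thickness arithmetically", {
  segs <- lapply(c(3.0, 3.1, 3.2), function(t) flat_seg(thickness = t))
  sr <- site_reading(segs, site = "right_lateral")
  expect_equal(sr$n_images, 3L)
  expect_equal(sr$mean$thickness_mm, rep(3.1, 3), tolerance = 1e-12)

  sr1 <- site_reading(list(segs[[1]], segs[[1]], segs[[1]]), site = "s")
  expect_equal(sr1$mean$thickness_mm, rep(3.0, 3), tolerance = 1e-12)
  expect_error(site_reading(list()), "at least one image")
})

test_that("notch suggestion finds the deepest central synovial point", {
  x <- seq(0, 38.4, length.out = 401)
  dip <- 7 + 1.2 * exp(-(x - 22)^2 / 4)  # synovial dips toward the bone at 22
  seg <- cartilage_segmentation(cbind(x, 10), cbind(x, dip), c(19.2, 10))
  sug <- suggest_notch(seg)
  expect_equal(sug[1], 22, tolerance = 0.1)
})
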