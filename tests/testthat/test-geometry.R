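test_that("gauge catalogue returns the printed catheter dimensions", {
  g18 <- gauge_spec("18G")
  expect_equal(g18$inner_diameter_mm, 0.84)
  expect_equal(g18$outer_diameter_mm, 1.27)
  g20 <- gauge_spec("20G")
  expect_equal(g20$inner_diameter_mm, 0.61)
  expect_equal(g20$outer_diameter_mm, 0.91)
  expect_equal(g18$length_mm, 35)
  expect_error(gauge_spec("22G"), "unsupported gauge")
})

test_that("clinical-relevance filter leaves the five pairs per gauge", {
  geo <- enumerate_configurations(rates = 2.1)
  expect_length(geo, 10)
  tab <- configurations_table(geo)
  for (g in c("18G", "20G")) {
    pairs <- tab[tab$gauge == g, c("tip_position", "angle_deg")]
    pairs <- pairs[order(pairs$tip_position, pairs$angle_deg), ]
    expect_equal(pairs$tip_position,
                 c("centre", "centre", "edge", "edge", "edge"))
    expect_equal(pairs$angle_deg, c(5, 10, 10, 15, 20))
  }
  # excluded pairs never appear
  expect_false(any(tab$tip_position == "centre" & tab$angle_deg %in% c(15, 20)))
  expect_false(any(tab$tip_position == "edge" & tab$angle_deg == 5))
})

test_that("full study enumeration counts 32 runs with controls", {
  runs <- enumerate_configurations(include_controls = TRUE)
  expect_length(runs, 32)
  tab <- configurations_table(runs)
  expect_equal(sum(tab$gauge == "none"), 1)          # patent control
  expect_equal(sum(tab$infusion_rate_mL_min == 0), 2) # + no-infusion case
})

test_that("enumeration is order-independent and empty requests are empty", {
  a <- configurations_table(enumerate_configurations(
    angles = c(20, 5, 15, 10), positions = c("edge", "centre"), rates = 50))
  b <- configurations_table(enumerate_configurations(rates = 50))
  key <- function(d) sort(do.call(paste, d))
  expect_equal(key(a), key(b))
  expect_length(enumerate_configurations(gauges = character(0)), 0)
})

test_that("configuration constructor enforces the study design", {
  expect_error(configuration("20G", 20, "centre", 2.1), "not a clinically")
  expect_error(configuration("18G", 5, "edge", 2.1), "not a clinically")
  expect_error(configuration(NULL, infusion_rate_mL_min = 50), "control")
  expect_silent(configuration("20G", 20, "edge", 0))
})

test_that("control domain is a plain rectangle with wall layers", {
  dom <- build_domain(configuration(NULL), test_vein(), 0.15)
  expect_false(any(dom$mask %in% c(2L, 3L)))
  expect_equal(sum(dom$mask == 0L), dom$nx * (dom$ny - 2L))
  fa <- fluid_area(dom)
  expect_equal(fa$raster_m2, fa$analytic_m2, tolerance = 1e-12)
})

test_that("catheter rasterization matches the blunt-tip trigonometry", {
  dom <- build_domain(configuration("20G", 20, "edge", 0), test_vein(),
                      0.1, tip_axial_mm = 14, standoff_mm = 0)
  # embedded length from trailing-surface wall clearance to the tip:
  # (D - OD) / sin(angle) for a wall-touching edge tip
  expect_equal(dom$embedded_len_mm, (2.4 - 0.91) / sin(20 * pi / 180),
               tolerance = 1e-10)
  dom2 <- build_domain(configuration("20G", 20, "edge", 0), test_vein(),
                       0.1, tip_axial_mm = 14)
  expect_equal(dom2$standoff_mm, 0.10)
  # masks partition and the catheter inlet aperture exists
  expect_true(all(dom2$mask %in% 0:3))
  expect_gt(sum(dom2$aperture), 0)
  expect_gt(sum(dom2$mask == 3L), 0)
  # blunt tip: no lumen cell lies beyond the tip face along the axis
  idx <- which(dom2$mask == 3L, arr.ind = TRUE)
  s <- (dom2$x[idx[, 1]] - dom2$tip[1]) * dom2$axis[1] +
    (dom2$y[idx[, 2]] - dom2$tip[2]) * dom2$axis[2]
  expect_true(all(s <= 1e-12))
})

test_that("rasterized fluid area converges to the analytic area", {
  errs <- sapply(c(0.15, 0.075, 0.0375), function(h) {
    dom <- build_domain(configuration("18G", 10, "edge", 0), test_vein(),
                        h, tip_axial_mm = 14)
    fa <- fluid_area(dom)
    abs(fa$raster_m2 - fa$analytic_m2) / fa$analytic_m2
  })
  expect_lte(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
  expect_lt(errs[3], 0.001)
})

test_that("infeasible geometries are rejected", {
  expect_error(build_domain(configuration("20G", 10, "edge", 0),
                            test_vein(), 0.2),
               "cell size")
  expect_error(build_domain(configuration("18G", 5, "centre", 0),
                            test_vein(), 0.15, tip_axial_mm = 5),
               "configuration error")
})
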