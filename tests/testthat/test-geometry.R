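# Idealized head geometry: cavity volume, opening areas, invariants.

test_that("closed ellipsoid cavity has the analytic volume", {
  g <- build_idealized_head(c(80, 66, 59))
  expect_equal(g$cavity_volume_ml, 4 / 3 * pi * 8.0 * 6.6 * 5.9,
               tolerance = 1e-12)
  expect_equal(g$cavity_volume_ml, 1305, tolerance = 1e-3)
  expect_length(g$openings, 0)
  g2 <- build_idealized_head(c(50, 50, 50))
  expect_equal(g2$cavity_volume_ml, 4 / 3 * pi * 125)
})

test_that("circular openings report the planar pi r^2 area and a larger curved area", {
  for (r in c(20, 30, 40, 50)) {
    g <- build_idealized_head(
      default_semi_axes,
      list(opening_spec("unilateral_circular", radius_mm = r)))
    op <- g$openings[[1]]
    expect_equal(op$area_planar_mm2, pi * r^2)
    # curved cap over the projected disc is necessarily at least as large,
    # and stays cap-like (below a hemisphere's 2x; r = 50 mm on an 80 mm
    # semi-axis is already a deep cap at ~1.6x)
    expect_gt(op$area_mm2, op$area_planar_mm2)
    expect_lt(op$area_mm2, 1.8 * op$area_planar_mm2)
  }
})

test_that("opening area grows strictly with radius", {
  areas <- vapply(c(20, 30, 40, 50), function(r)
    build_idealized_head(
      default_semi_axes,
      list(opening_spec("unilateral_circular", radius_mm = r))
    )$openings[[1]]$area_mm2, 0)
  expect_true(all(diff(areas) > 0))
})

test_that("bifrontal extents are resolved to a requested area within 1%", {
  for (target in c(7344, 17321)) {
    g <- build_idealized_head(
      default_semi_axes, list(opening_spec("bifrontal", area_mm2 = target)))
    expect_equal(g$openings[[1]]$area_mm2, target, tolerance = 0.01)
  }
  # the midline bar is excluded from the total area
  gb <- build_idealized_head(
    default_semi_axes,
    list(opening_spec("bifrontal_midline_bar", area_mm2 = 6589)))
  expect_equal(gb$openings[[1]]$area_mm2, 6589, tolerance = 0.01)
  gn <- build_idealized_head(
    default_semi_axes,
    list(opening_spec("bifrontal",
                      angular_extents = gb$openings[[1]]$angular_extents)))
  expect_gt(gn$openings[[1]]$area_mm2, gb$openings[[1]]$area_mm2)
})

test_that("mirrored unilateral openings have matching areas", {
  mk <- function(sgn) build_idealized_head(
    default_semi_axes,
    list(opening_spec("unilateral_circular", radius_mm = 35,
                      axis = c(sgn, 0, 0.4))))
  gl <- mk(-1); gr <- mk(1)
  expect_equal(gl$openings[[1]]$area_mm2, gr$openings[[1]]$area_mm2,
               tolerance = 1e-6)
})

test_that("invalid opening layouts are rejected with informative errors", {
  expect_error(build_idealized_head(
    default_semi_axes,
    list(opening_spec("unilateral_circular", radius_mm = 30, axis = c(1, 0, 0)),
         opening_spec("unilateral_circular", radius_mm = 30,
                      axis = c(1, 0.12, 0)))),
    "openings 1 and 2 overlap")
  # a crown opening centred on the mid-sagittal plane is not 'unilateral'
  expect_error(build_idealized_head(
    default_semi_axes,
    list(opening_spec("unilateral_circular", radius_mm = 30,
                      axis = c(0, 0, 1)))),
    "mid-sagittal")
  expect_error(opening_spec("unilateral_circular", radius_mm = -5), "radius")
  expect_error(opening_spec("bifrontal"), "angular_extents")
})
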