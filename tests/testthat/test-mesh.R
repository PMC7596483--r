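# Tetrahedral meshing: volume fidelity, refinement, boundary tagging.

test_that("mesh volume matches the analytic cavity volume within 2%", {
  g <- build_idealized_head(default_semi_axes)
  m <- mesh_head(g, 8)
  expect_equal(mesh_volume(m) / 1000, g$cavity_volume_ml, tolerance = 0.02)
  expect_true(check_mesh(m))
})

test_that("refining h strictly decreases the volume error", {
  g <- build_idealized_head(default_semi_axes)
  err <- vapply(c(16, 8), function(h)
    abs(mesh_volume(mesh_head(g, h)) / 1000 - g$cavity_volume_ml) /
      g$cavity_volume_ml, 0)
  expect_lt(err[2], err[1])
})

test_that("tagged opening facet areas track the curved patch area", {
  g <- build_idealized_head(
    default_semi_axes,
    list(opening_spec("unilateral_circular", radius_mm = 40)))
  m <- mesh_head(g, 8)
  tag <- m$tag_names[["opening_1"]]
  tagged <- sum(facet_areas(m$nodes, m$facets[m$facet_tags == tag, ,
                                              drop = FALSE]))
  expect_equal(tagged, g$openings[[1]]$area_mm2, tolerance = 0.03)
  # everything else is the fixed skull interface
  expect_setequal(unique(m$facet_tags),
                  c(m$tag_names[["fixed_interface"]], tag))
})

test_that("hemisphere region tags split the cells by the sagittal plane", {
  g <- build_idealized_head(default_semi_axes)
  m <- mesh_head(g, 12)
  cx <- (m$nodes[m$cells[, 1], 1] + m$nodes[m$cells[, 2], 1] +
         m$nodes[m$cells[, 3], 1] + m$nodes[m$cells[, 4], 1]) / 4
  left <- m$region_tags == m$tag_names[["left_hemisphere"]]
  expect_true(all(cx[left] < 0))
  expect_true(all(cx[!left] >= 0))
  # near-balanced split of volume
  v <- abs(dccsim:::tet_signed_volumes(m$nodes, m$cells))
  expect_equal(sum(v[left]) / sum(v), 0.5, tolerance = 0.02)
})

test_that("a bifrontal midline bar yields two opening patches separated by the bar", {
  g <- build_idealized_head(
    default_semi_axes,
    list(opening_spec("bifrontal_midline_bar", area_mm2 = 6589,
                      bar_width_mm = 25)))
  m <- mesh_head(g, 8)
  tl <- m$tag_names[["opening_1_left"]]; tr <- m$tag_names[["opening_1_right"]]
  expect_gt(sum(m$facet_tags == tl), 0)
  expect_gt(sum(m$facet_tags == tr), 0)
  fc <- (m$nodes[m$facets[, 1], 1] + m$nodes[m$facets[, 2], 1] +
         m$nodes[m$facets[, 3], 1]) / 3
  expect_true(all(fc[m$facet_tags == tl] < 0))
  expect_true(all(fc[m$facet_tags == tr] >= 0))
})

test_that("mirror-symmetric openings give matching meshes", {
  mk <- function(sgn) {
    g <- build_idealized_head(
      default_semi_axes,
      list(opening_spec("unilateral_circular", radius_mm = 35,
                        axis = c(sgn, 0, 0.4))))
    mesh_head(g, 10)
  }
  ml <- mk(-1); mr <- mk(1)
  expect_equal(mesh_volume(ml), mesh_volume(mr), tolerance = 1e-9)
  a <- function(m) sum(facet_areas(m$nodes,
                                   m$facets[m$facet_tags == 2, , drop = FALSE]))
  expect_equal(a(ml), a(mr), tolerance = 1e-6)
})

test_that("meshing guards its preconditions", {
  g <- build_idealized_head(
    default_semi_axes,
    list(opening_spec("unilateral_circular", radius_mm = 20)))
  expect_error(mesh_head(g, 25), "smaller than the smallest opening radius")
  expect_error(mesh_head(g, -1))
})
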