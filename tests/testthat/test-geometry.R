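test_that("mesh generation is deterministic and labels partition the boundary", {
  cfg <- anatomy_config(edge_length = 14)
  m1 <- build_biventricular_mesh(cfg, seed = 7)
  m2 <- build_biventricular_mesh(cfg, seed = 7)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$facet_label, m2$facet_label)

  expect_false(anyNA(m1$facet_label))
  expect_setequal(levels(m1$facet_label),
                  c("LV_ENDO", "RV_ENDO", "LV_SEPTUM", "RV_SEPTUM",
                    "EPI", "BASE"))
  # all six surface classes are populated on a biventricular mesh
  expect_true(all(table(m1$facet_label) > 0))
  # every element carries exactly one tag
  expect_false(anyNA(m1$element_tag))
  # transmural depth is a [0,1] field with both extremes attained
  expect_true(all(m1$node_depth >= 0 & m1$node_depth <= 1))
  expect_gt(max(m1$node_depth), 0.99)
  expect_lt(min(m1$node_depth), 0.01)

  # jitter perturbs only interior nodes and is seed-reproducible
  cj <- anatomy_config(edge_length = 14, jitter = 0.1)
  j1 <- build_biventricular_mesh(cj, seed = 3)
  j2 <- build_biventricular_mesh(cj, seed = 3)
  j3 <- build_biventricular_mesh(cj, seed = 4)
  expect_identical(j1$nodes, j2$nodes)
  expect_false(identical(j1$nodes, j3$nodes))
  expect_identical(j1$facets, m1$facets)  # surfaces untouched
})

test_that("configuration validation rejects degenerate anatomies", {
  expect_error(anatomy_config(lv_radii = c(-1, 20, 40)), "positive")
  expect_error(anatomy_config(fast_layer_thickness = 5, rv_wall_thickness = 3),
               "thinnest wall")
  expect_error(anatomy_config(base_truncation = 0.7), "base_truncation")
  expect_error(anatomy_config(base_truncation = 0, rv_offset = 10),
               "closed ellipsoid")
})

test_that("chamber volume matches the analytic ellipsoid and is rigid-motion invariant", {
  cfg <- anatomy_config(lv_radii = c(10, 10, 10), lv_wall_thickness = 4,
                        rv_offset = 0, base_truncation = 0,
                        edge_length = 1.5, fast_layer_thickness = 0)
  m <- build_biventricular_mesh(cfg)
  v <- chamber_volume(m, "LV", cap_base = FALSE) * 1000  # mm^3
  expect_equal(v, 4 / 3 * pi * 1000, tolerance = 0.02)

  # rigid motion: translation + rotation leave the volume unchanged
  mt <- m
  mt$nodes <- m$nodes %*% t(rotation_align(c(0, 0, 1), c(1, 2, 3)))
  mt$nodes <- sweep(mt$nodes, 2, c(100, -40, 7), "+")
  expect_equal(chamber_volume(mt, "LV", cap_base = FALSE) * 1000, v,
               tolerance = 1e-10)

  # an anisotropic closed ellipsoid hits the analytic 4/3 pi abc
  cfg2 <- anatomy_config(lv_radii = c(8, 10, 14), lv_wall_thickness = 4,
                         rv_offset = 0, base_truncation = 0,
                         edge_length = 1.5, fast_layer_thickness = 0)
  m2 <- build_biventricular_mesh(cfg2)
  expect_equal(chamber_volume(m2, "LV", cap_base = FALSE) * 1000,
               4 / 3 * pi * 8 * 10 * 14, tolerance = 0.02)
})

test_that("chamber volume converges under refinement (< 1% between levels)", {
  vols <- sapply(c(2, 1.4), function(h) {
    cfg <- anatomy_config(lv_radii = c(10, 10, 10), lv_wall_thickness = 4,
                          rv_offset = 0, base_truncation = 0,
                          edge_length = h, fast_layer_thickness = 0)
    chamber_volume(build_biventricular_mesh(cfg), "LV", cap_base = FALSE)
  })
  expect_lt(abs(diff(vols)) / vols[1], 0.01)
})

test_that("open-base cavities require capping and capped volumes are sane", {
  m <- heart_mesh()
  expect_error(chamber_volume(m, "LV", cap_base = FALSE), "open")
  v_lv <- chamber_volume(m, "LV")
  v_rv <- chamber_volume(m, "RV")
  expect_gt(v_lv, 60)   # dilated failing LV, ml
  expect_lt(v_lv, 300)
  expect_gt(v_rv, 10)
  expect_lt(v_rv, v_lv)
})

test_that("RV wall is 3 mm thick and the fast layer hugs the endocardium", {
  m <- heart_mesh()
  expect_equal(rv_wall_distance(m), 3, tolerance = 0.5 / 3)

  thick <- m$config$fast_layer_thickness
  cent <- (m$nodes[m$tets[, 1], ] + m$nodes[m$tets[, 2], ] +
             m$nodes[m$tets[, 3], ] + m$nodes[m$tets[, 4], ]) / 4
  lv_sel <- m$element_tag == "LV_FAST_LAYER"
  rv_sel <- m$element_tag == "RV_FAST_LAYER"
  expect_gt(sum(lv_sel), 0)
  expect_gt(sum(rv_sel), 0)
  d_lv <- surface_distance(cent[lv_sel, , drop = FALSE], m,
                           c("LV_ENDO", "LV_SEPTUM"))
  d_rv <- surface_distance(cent[rv_sel, , drop = FALSE], m,
                           c("RV_ENDO", "RV_SEPTUM"))
  expect_lte(max(d_lv), thick + 1e-9)
  expect_lte(max(d_rv), thick + 1e-9)

  # a vanishing layer clears the tags; a layer spanning the wall errors
  m0 <- tag_fast_layer(m, 0)
  expect_true(all(m0$element_tag == "MYO"))
  expect_error(tag_fast_layer(m, 3), "span")
})

test_that("VTK files round-trip nodes, cells and data arrays", {
  m <- build_biventricular_mesh(anatomy_config(edge_length = 16))
  path <- tempfile(fileext = ".vtk")
  write_vtk_mesh(m, path,
                 cell_data = list(depth = m$element_depth),
                 point_data = list(z = m$nodes[, 3]))
  v <- read_vtk_mesh(path)
  expect_equal(v$nodes, unname(m$nodes), tolerance = 1e-6)
  expect_equal(v$tets, unname(m$tets))
  expect_equal(v$cell_data$depth, m$element_depth, tolerance = 1e-6)
  expect_equal(v$point_data$z, m$nodes[, 3], tolerance = 1e-6)
  unlink(path)
})
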