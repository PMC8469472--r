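# synthetic: parametric crown generator and rigid motions

test_that("generated meshes are watertight with the declared topology", {
  g <- ado_fixture("bicuspid")
  expect_true(is_watertight(g$outer))
  expect_true(is_watertight(g$inner))
  expect_true(is_watertight(g$shell))
  expect_equal(nrow(g$shell$vertices),
               unname(g$truth$vertex_counts["shell"]))
  for (s in g[c("outer", "inner", "shell")])
    expect_silent(validate_surface(s, strict = TRUE))
})

test_that("ground truth matches mesh extrema within one resolution step", {
  g <- ado_fixture("bicuspid")
  spec <- bicuspid_spec()
  tr <- g$truth
  # tip heights were calibrated to the requested values
  expect_equal(unname(tr$cusp_tip_vestibular[3]),
               spec$cusp_height_vestibular, tolerance = 1e-6)
  expect_equal(unname(tr$cusp_tip_oral[3]), spec$cusp_height_oral,
               tolerance = 1e-6)
  # mesh extrema agree with the analytic model
  expect_lt(abs(max(g$outer$vertices[, 3]) - spec$cusp_height_vestibular),
            spec$resolution)
  expect_lt(abs(diff(range(g$outer$vertices[, 2])) -
                tr$max_vo_width[["enamel"]]), spec$resolution)
  expect_lt(abs(diff(range(g$inner$vertices[, 2])) -
                tr$inner_surface_max_width), spec$resolution)
  # calibrated occlusal relief
  expect_equal(unname((tr$cusp_tip_vestibular[3] + tr$cusp_tip_oral[3]) / 2 -
                      tr$fossa_point[3]), spec$fossa_depth,
               tolerance = 1e-6)
})

test_that("generation is deterministic, including seeded jitter", {
  s1 <- generate_bicuspid(bicuspid_spec(resolution = 0.45))
  s2 <- generate_bicuspid(bicuspid_spec(resolution = 0.45))
  expect_identical(s1$shell$vertices, s2$shell$vertices)
  expect_identical(s1$shell$faces, s2$shell$faces)
  j1 <- generate_bicuspid(bicuspid_spec(resolution = 0.45, jitter_sd = 0.01,
                                        seed = 9))
  j2 <- generate_bicuspid(bicuspid_spec(resolution = 0.45, jitter_sd = 0.01,
                                        seed = 9))
  expect_identical(j1$outer$vertices, j2$outer$vertices)
  expect_false(identical(j1$outer$vertices, s1$outer$vertices))
})

test_that("impossible specs are rejected", {
  expect_error(bicuspid_spec(enamel_thickness = 8), "half-width")
  expect_error(bicuspid_spec(resolution = 1), "resolution")
  expect_error(bicuspid_spec(fossa_depth = -1), "positive")
  # offset self-intersection guard
  expect_error(generate_bicuspid(bicuspid_spec(enamel_thickness = 3)),
               "self-intersect")
})

test_that("rigid motions are exact, invertible and reproducible", {
  s <- icosphere(2, 1)
  id <- apply_rigid_motion(s, rotation = diag(3), translation = c(0, 0, 0))
  expect_identical(id$surface$vertices, s$vertices)

  mv <- apply_rigid_motion(s, seed = 21)
  back <- apply_rigid_motion(mv$surface, rotation = t(mv$rotation),
                             translation = drop(-t(mv$rotation) %*%
                                                mv$translation))
  expect_lt(max(abs(back$surface$vertices - s$vertices)), 1e-9)

  mv2 <- apply_rigid_motion(s, seed = 21)
  expect_identical(mv$surface$vertices, mv2$surface$vertices)
  expect_equal(mv$rotation, mv2$rotation)

  # rotation matrix is orthonormal for axis-angle and quaternion input
  R1 <- rotation_matrix(c(0, 0, 1, pi / 3))
  expect_lt(max(abs(t(R1) %*% R1 - diag(3))), 1e-12)
  R2 <- rotation_matrix(c(cos(pi / 6), 0, 0, sin(pi / 6)), quaternion = TRUE)
  expect_lt(max(abs(R1 - R2)), 1e-12)
  expect_warning(rotation_matrix(c(0, 0, 2, pi / 3)), "normalised")
})
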