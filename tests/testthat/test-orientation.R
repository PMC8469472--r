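# orientation: occlusal border detection and tooth frame determination

test_that("the detected border traces the analytic crest ring", {
  g <- ado_fixture("bicuspid")
  refs <- rbind(g$truth$crest_ring,
                g$truth$cusp_tip_vestibular, g$truth$cusp_tip_oral)
  for (mesh in c("outer", "shell")) {
    s <- g[[mesh]]
    field <- estimate_curvature(s, 0.8)
    border <- detect_occlusal_border(s, field)
    expect_gte(nrow(border$points), 50L)
    expect_equal(anyDuplicated(border$vertex_indices), 0L)
    dd <- nn_dist(border$points, refs)
    # pointwise localisation is limited by the curvature smoothing radius
    # where the fossa-rim crest meets a cusp shoulder (see vignette)
    expect_lt(mean(dd), 0.3)
    expect_lt(max(dd), 1.25)
  }
})

test_that("a sphere has no occlusal surface", {
  s <- icosphere(3, 5)
  field <- estimate_curvature(s, 1.5)
  expect_error(detect_occlusal_border(s, field), "no occlusal surface")
})

test_that("border detection is stable under rigid motion", {
  g <- ado_fixture("bicuspid")
  s <- g$shell
  field <- estimate_curvature(s, 0.8)
  b0 <- detect_occlusal_border(s, field)
  mv <- apply_rigid_motion(s, seed = 3)
  f2 <- estimate_curvature(mv$surface, 0.8)
  b1 <- detect_occlusal_border(mv$surface, f2)
  moved <- b0$points %*% t(mv$rotation) +
    matrix(mv$translation, nrow(b0$points), 3, byrow = TRUE)
  # the loop is re-binned in the rotated frame, so compare as point sets
  expect_lt(max(nn_dist(moved, b1$points)), 0.6)
  expect_lt(max(nn_dist(b1$points, moved)), 0.6)
  # vertex identity is only loosely preserved (the loop is re-binned); the
  # geometric agreement above is the real invariance statement
  expect_gt(length(intersect(b0$vertex_indices, b1$vertex_indices)) /
            length(union(b0$vertex_indices, b1$vertex_indices)), 0.3)
})

test_that("a planar border with identical normals forces the frame", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  pts <- cbind(4 * cos(th), 2.5 * sin(th), 5)
  border <- structure(list(points = pts,
                           vertex_indices = seq_len(nrow(pts)),
                           normals = matrix(rep(c(0, 0, 1), nrow(pts)),
                                            ncol = 3, byrow = TRUE)),
                      class = "occlusal_border")
  # minimal host surface below the border so the vertical sign is defined
  host <- icosphere(2, 1)
  frame <- compute_frame(border, host)
  expect_equal(frame$vertical_axis, c(0, 0, 1))
  expect_equal(frame$origin, c(0, 0, 5), tolerance = 1e-9)
  expect_equal(abs(frame$mesiodistal_axis[1]), 1, tolerance = 1e-6)
})

test_that("frames are orthonormal, right-handed, and equivariant", {
  g <- ado_fixture("bicuspid")
  s <- g$shell
  field <- estimate_curvature(s, 0.8)
  o0 <- iterate_orientation(s, field)
  f0 <- o0$frame
  gram <- rbind(f0$mesiodistal_axis, f0$vestibulooral_axis,
                f0$vertical_axis)
  expect_lt(max(abs(gram %*% t(gram) - diag(3))), 1e-9)
  expect_gt(det(gram), 0)

  for (sd in 1:3) {
    mv <- apply_rigid_motion(s, seed = sd)
    f2 <- estimate_curvature(mv$surface, 0.8)
    o2 <- iterate_orientation(mv$surface, f2)
    # axes transform with the rotation (up to the detector's binning noise)
    expect_lt(angle_deg(o2$frame$vertical_axis,
                        drop(mv$rotation %*% f0$vertical_axis)), 1)
    expect_lt(angle_deg(o2$frame$mesiodistal_axis,
                        drop(mv$rotation %*% f0$mesiodistal_axis)), 1)
    expect_lt(max(abs(o2$frame$origin -
      (drop(mv$rotation %*% f0$origin) + mv$translation))), 0.25)
  }
})

test_that("orientation iteration converges quickly in canonical pose", {
  g <- ado_fixture("bicuspid")
  s <- g$shell
  field <- estimate_curvature(s, 0.8)
  o <- iterate_orientation(s, field)
  expect_true(o$frame$converged)
  expect_lte(o$frame$iterations_used, 2L)
  # degenerate tolerance: single pass equals plain compute_frame
  o1 <- iterate_orientation(s, field, tolerance = pi)
  expect_equal(o1$frame$iterations_used, 1L)
  b <- detect_occlusal_border(s, field)
  f1 <- compute_frame(b, s)
  expect_equal(o1$frame$vertical_axis, f1$vertical_axis)
})

test_that("a 30-degree tilt is recovered to within 2 degrees", {
  g <- ado_fixture("bicuspid")
  mv <- apply_rigid_motion(g$shell,
                           rotation = c(1, 0, 0, 30 * pi / 180),
                           translation = c(0, 0, 0))
  field <- estimate_curvature(mv$surface, 0.8)
  o <- iterate_orientation(mv$surface, field)
  truth_v <- drop(mv$rotation %*% g$truth$vertical_axis)
  expect_lt(angle_deg(o$frame$vertical_axis, truth_v), 2)
})
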