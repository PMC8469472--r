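# landmarks: parallel-tangent construction, curvature mode, cap splitting


test_that("the symmetric toy contour is landmarked exactly", {
  lm <- find_landmarks_euclidean(toy_contour())
  expect_equal(lm$points$vestibular_cusp_tip, c(4, 10))
  expect_equal(lm$points$oral_cusp_tip, c(-4, 10))
  expect_equal(lm$points$deepest_occlusal_point, c(0, 6))
  expect_equal(lm$depth, 4)
})

test_that("Euclidean landmarks agree with the exhaustive oracle", {
  cases <- list(toy_contour(), toy_contour_asym())
  # plus jittered variants of the asymmetric case
  set.seed(5)
  for (k in 1:4) {
    base <- toy_contour_asym()
    base[, 2] <- base[, 2] + stats::runif(nrow(base), -0.3, 0.3)
    cases[[length(cases) + 1L]] <- base
  }
  for (xy in cases) {
    lm <- find_landmarks_euclidean(xy)
    ob <- oracle_landmarks(xy)
    expect_false(is.null(ob))
    expect_setequal(lm$tip_indices, c(ob$l, ob$r))
    expect_equal(lm$deep_index, ob$deep)
    expect_equal(lm$depth, ob$depth, tolerance = 1e-12)
  }
})

test_that("Euclidean landmarks agree with the oracle on fixture sections", {
  res <- ado_fixture("shell_pipeline")
  checked <- 0L
  for (sc in res$contours[seq(5, 75, by = 10)]) {
    sl <- odontometry:::section_layers(sc)
    if (is.null(sl)) next
    xy <- sl$enamel
    lm <- tryCatch(find_landmarks_euclidean(xy, closed = FALSE),
                   error = function(e) NULL)
    if (is.null(lm)) next
    ob <- oracle_landmarks_open(xy)
    expect_setequal(lm$tip_indices, c(ob$l, ob$r))
    expect_equal(lm$deep_index, ob$deep)
    checked <- checked + 1L
  }
  expect_gte(checked, 4L)
})

test_that("landmarks are equivariant under in-plane rigid motion", {
  xy <- toy_contour_asym()
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  lm0 <- find_landmarks_euclidean(xy)
  # depth is invariant; landmark points transform with the motion
  moved <- sweep(xy %*% t(R), 2, c(3, -2), "+")
  # the rotated contour's "upper side" changes; rotate back for comparison
  lm1 <- find_landmarks_euclidean(sweep(moved, 2, c(3, -2)) %*% R)
  expect_equal(lm1$depth, lm0$depth, tolerance = 1e-9)
  expect_equal(lm1$points$deepest_occlusal_point,
               lm0$points$deepest_occlusal_point, tolerance = 1e-9)
  # point-order reversal leaves the construction unchanged
  lm2 <- find_landmarks_euclidean(xy[rev(seq_len(nrow(xy))), ])
  expect_equal(lm2$depth, lm0$depth)
  expect_setequal(
    list(lm2$points$vestibular_cusp_tip, lm2$points$oral_cusp_tip),
    list(lm0$points$vestibular_cusp_tip, lm0$points$oral_cusp_tip))
})

test_that("single-hump and degenerate contours fail cleanly", {
  th <- seq(0, 2 * pi, length.out = 100)[-100]
  circle <- cbind(cos(th), sin(th))
  expect_error(find_landmarks_euclidean(circle), "landmark failure")
  expect_error(find_landmarks_curvature(circle), "landmark failure")
  hump <- rbind(cbind(seq(-3, 3, by = 0.2),
                      4 * exp(-seq(-3, 3, by = 0.2)^2)),
                c(3, -1), c(-3, -1))
  expect_error(find_landmarks_euclidean(hump), "landmark failure")
})

test_that("curvature mode recovers analytic two-Gaussian peak positions", {
  xs <- seq(-6, 6, by = 0.05)
  f <- function(x) 8 + 2 * exp(-((x - 3) / 1.2)^2) +
    2.2 * exp(-((x + 3) / 1.2)^2) - 3 * exp(-(x / 1.5)^2)
  cont <- rbind(cbind(xs, f(xs)), cbind(rev(xs), -2))
  p1 <- stats::optimize(f, c(1, 5), maximum = TRUE)$maximum
  p2 <- stats::optimize(f, c(-5, -1), maximum = TRUE)$maximum
  lm <- find_landmarks_curvature(cont, window = 0.5)
  step <- 0.05
  expect_lt(abs(lm$points$vestibular_cusp_tip[1] - p1), step + 1e-9)
  expect_lt(abs(lm$points$oral_cusp_tip[1] - p2), step + 1e-9)
  # window stability on the smooth fixture
  lm2 <- find_landmarks_curvature(cont, window = 1.0)
  expect_lt(max(abs(unlist(lm$points[1:2]) - unlist(lm2$points[1:2]))), 0.2)
})

test_that("enamel-cap bands split at the cervical corners", {
  band <- toy_band()
  sp <- split_enamel_cap_contour(band)
  zc <- 6 * sqrt(1 - (5 / 5.2)^2) + 0.8 * cos(5)
  expect_equal(unname(sp$edge_points["vestibular", ]), c(5, zc),
               tolerance = 1e-9)
  expect_equal(unname(sp$edge_points["oral", ]), c(-5, zc),
               tolerance = 1e-9)
  # mirror symmetry of the symmetric band
  expect_lt(abs(sp$edge_points[1, 1] + sp$edge_points[2, 1]), 1e-6)
  expect_lt(abs(sp$edge_points[1, 2] - sp$edge_points[2, 2]), 1e-6)
  # partition conservation: shared endpoints counted twice
  expect_equal(nrow(sp$enamel) + nrow(sp$dentine), nrow(band) + 2L)
  # enamel sector holds the top
  expect_equal(max(sp$enamel[, 2]), max(band[, 2]))
})

test_that("fixture sections split within tolerance of generator margins", {
  g <- ado_fixture("bicuspid")
  res <- ado_fixture("shell_pipeline")
  frame <- res$frame
  a <- bicuspid_spec()$crown_md_halflength
  b <- bicuspid_spec()$crown_vo_halfwidth
  for (k in c(30, 40, 50)) {
    sc <- res$contours[[k]]
    sp <- split_enamel_cap_contour(sc)
    x0 <- sc$position  # projection onto +-x; enters only squared
    half_w <- b * sqrt(1 - (x0 / a)^2)
    expect_lt(abs(abs(diff(sp$edge_points[, 1])) / 2 - half_w), 0.1)
    # cervical edges sit in the z = 0 margin plane of the generator; map
    # back to world coordinates to avoid compounding frame-tilt error
    world_z <- vapply(1:2, function(side) {
      p <- frame$origin +
        sp$edge_points[side, 1] * frame$vestibulooral_axis +
        sp$edge_points[side, 2] * frame$vertical_axis
      # shift along md so the point lies in the cutting plane
      p <- p + (sc$position - sum(p * frame$mesiodistal_axis)) *
        frame$mesiodistal_axis
      p[3]
    }, 0)
    expect_lt(max(abs(world_z)), 0.1)
  }
})

test_that("validate_contour reports the documented failure reasons", {
  v <- validate_contour(toy_contour())
  expect_true(v$valid)
  open_poly <- toy_contour()
  v2 <- validate_contour(open_poly, closed = FALSE)
  expect_match(v2$reason, "open contour")
  hump <- rbind(cbind(seq(-3, 3, by = 0.2),
                      4 * exp(-seq(-3, 3, by = 0.2)^2)),
                c(3, -1), c(-3, -1))
  v3 <- validate_contour(hump)
  expect_false(v3$valid)
  expect_match(v3$reason, "no occlusal concavity")
  tiny <- cbind(c(0, 0.2, 0.2, 0, 0), c(0, 0, 0.2, 0.2, 0.1))
  v4 <- validate_contour(tiny)
  expect_false(v4$valid)
})


test_that("the parallel-tangent sandwich holds on all valid sections", {
  res <- ado_fixture("shell_pipeline")
  tab <- res$per_section
  lmt <- res$landmark_table
  for (k in unique(tab$section_index[tab$valid & tab$layer == "enamel"])) {
    sl <- odontometry:::section_layers(res$contours[[k]])
    lm <- tryCatch(find_landmarks_euclidean(sl$enamel, closed = FALSE),
                   error = function(e) NULL)
    if (is.null(lm)) next
    arc <- odontometry:::contour_arcs(min(lm$tip_indices),
                                      max(lm$tip_indices),
                                      nrow(sl$enamel), closed = FALSE)[[1]]
    i1 <- lm$tip_indices[1]; i2 <- lm$tip_indices[2]
    l <- if (sl$enamel[i1, 1] <= sl$enamel[i2, 1]) i1 else i2
    r <- if (l == i1) i2 else i1
    sd <- odontometry:::signed_line_distance(sl$enamel[arc, 1],
                                             sl$enamel[arc, 2],
                                             sl$enamel[l, ], sl$enamel[r, ])
    # all occlusal-arc points lie below the hull tangent, and the deepest
    # landmark attains the extreme distance (so every arc point lies
    # between the two parallel lines)
    expect_lte(max(sd), 1e-9)
    expect_equal(arc[which.min(sd)], lm$deep_index)
    # the sub-vertex refined tangent stays close to the vertex tangent
    vt <- lm$points$vestibular_cusp_tip
    ot <- lm$points$oral_cusp_tip
    dref <- odontometry:::signed_line_distance(
      c(sl$enamel[l, 1], sl$enamel[r, 1]),
      c(sl$enamel[l, 2], sl$enamel[r, 2]),
      if (vt[1] < ot[1]) vt else ot, if (vt[1] < ot[1]) ot else vt)
    expect_lt(max(abs(dref)), 0.02)
  }
})
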