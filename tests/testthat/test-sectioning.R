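# sectioning: ellipse approximation, plane stacks, plane-mesh contours

test_that("noiseless samples on an ellipse are fitted exactly", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  e <- fit_ellipse(cbind(5 * cos(th), 3 * sin(th)))
  expect_equal(e$semi_major, 5, tolerance = 1e-6)
  expect_equal(e$semi_minor, 3, tolerance = 1e-6)
  expect_equal(abs(e$major_axis_direction[1]), 1, tolerance = 1e-6)

  # equivariance: rotating the points rotates the axis
  R <- matrix(c(cos(pi / 6), sin(pi / 6), -sin(pi / 6), cos(pi / 6)), 2)
  e2 <- fit_ellipse(sweep(cbind(5 * cos(th), 3 * sin(th)) %*% t(R),
                          2, c(10, -4), "+"))
  expect_lt(acos(min(1, abs(sum(e2$major_axis_direction *
                                c(cos(pi / 6), sin(pi / 6)))))), 1e-4)
  expect_equal(e2$center, c(10, -4), tolerance = 1e-6)
})

test_that("circles fit with the documented direction tie-break", {
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  e <- fit_ellipse(cbind(2 * cos(th), 2 * sin(th)))
  expect_equal(e$semi_major, 2, tolerance = 1e-6)
  expect_equal(e$semi_minor, 2, tolerance = 1e-6)
  expect_equal(e$major_axis_direction, c(1, 0))
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_ellipse(cbind(1:4, 1:4)), "at least 5")
  expect_error(fit_ellipse(cbind(1:9, 2 * (1:9) + 1)), "collinear")
})

test_that("plane stacks are parallel, equally spaced, interior", {
  g <- ado_fixture("bicuspid")
  res <- ado_fixture("shell_pipeline")
  frame <- res$frame
  ss <- generate_planes(frame, frame$ellipse, g$shell, ns = 80)
  expect_equal(ss$ns, 80L)
  expect_equal(length(ss$plane_positions), 80L)
  gaps <- diff(ss$plane_positions)
  expect_true(all(abs(gaps - ss$spacing) < 1e-9))
  expect_equal(abs(sum(ss$plane_normal * frame$mesiodistal_axis)), 1,
               tolerance = 1e-12)
  # interior placement: extreme planes stay off the crown tips
  proj <- range(g$shell$vertices %*% frame$mesiodistal_axis)
  expect_gt(min(ss$plane_positions), proj[1])
  expect_lt(max(ss$plane_positions), proj[2])

  s1 <- generate_planes(frame, frame$ellipse, g$shell, ns = 1)
  expect_equal(s1$plane_positions, mean(proj), tolerance = 1e-9)
  expect_error(generate_planes(frame, frame$ellipse, g$shell, ns = 0), "ns")
})

test_that("a plane through a sphere centre yields a great circle", {
  s <- icosphere(4, 1)
  frame <- structure(list(origin = c(0, 0, 0), vertical_axis = c(0, 0, 1),
                          mesiodistal_axis = c(1, 0, 0),
                          vestibulooral_axis = c(0, 1, 0)),
                     class = "tooth_frame")
  ss <- structure(list(ns = 1L, plane_positions = 0,
                       plane_normal = c(1, 0, 0), spacing = 1),
                  class = "section_set")
  ct <- cut_surface(s, ss, frame)
  expect_length(ct, 1L)
  expect_length(ct[[1]]$polylines, 1L)
  p <- ct[[1]]$polylines[[1]]
  expect_true(p$closed)
  rr <- sqrt(rowSums(p$xy^2))
  expect_true(all(abs(rr - 1) < 2e-3))
  expect_lt(abs(abs(polygon_area(p$xy)) - pi) / pi, 0.005)

  # plane missing the mesh entirely
  ss2 <- ss; ss2$plane_positions <- 5
  expect_length(cut_surface(s, ss2, frame)[[1]]$polylines, 0L)
})

test_that("cutting watertight fixtures yields only closed polylines", {
  res <- ado_fixture("shell_pipeline")
  for (sc in res$contours) {
    for (p in sc$polylines) expect_true(p$closed)
  }
})

test_that("cutting outer+inner solids gives nested outer/inner polylines", {
  g <- ado_fixture("bicuspid")
  both <- tooth_surface(rbind(g$outer$vertices, g$inner$vertices),
                        rbind(g$outer$faces,
                              g$inner$faces + nrow(g$outer$vertices)),
                        validate = FALSE)
  res <- ado_fixture("shell_pipeline")
  ss <- structure(list(ns = 1L, plane_positions = 0,
                       plane_normal = res$frame$mesiodistal_axis,
                       spacing = 1),
                  class = "section_set")
  ct <- cut_surface(both, ss, res$frame)
  layers <- vapply(ct[[1]]$polylines, function(p) p$layer, "")
  expect_setequal(layers, c("outer", "inner"))
  # offset-shell oracle: minimal distance between nested contours is about
  # the enamel thickness. Both solids share the flat base plane, so the
  # comparison is restricted to the crown portion (1 mm above the base).
  outer_xy <- ct[[1]]$polylines[[which(layers == "outer")]]$xy
  inner_xy <- ct[[1]]$polylines[[which(layers == "inner")]]$xy
  v0 <- sum(res$frame$origin * res$frame$vertical_axis)
  keep <- inner_xy[, 2] > 1 - v0
  gap <- min(nn_dist(inner_xy[keep, , drop = FALSE], outer_xy))
  t <- bicuspid_spec()$enamel_thickness
  expect_lt(abs(gap - t) / t, 0.1)
})

test_that("sectioning is deterministic", {
  g <- ado_fixture("bicuspid")
  res <- ado_fixture("shell_pipeline")
  ss <- generate_planes(res$frame, res$frame$ellipse, g$shell, 20)
  c1 <- cut_surface(g$shell, ss, res$frame)
  c2 <- cut_surface(g$shell, ss, res$frame)
  expect_identical(c1, c2)
})

test_that("contours export to CSV and SVG", {
  res <- ado_fixture("shell_pipeline")
  csv <- tempfile(fileext = ".csv")
  write_contours_csv(res$contours[1:3], csv)
  df <- read.csv(csv)
  expect_true(all(c("section_index", "layer", "x", "y") %in% names(df)))
  svg <- tempfile(fileext = ".svg")
  write_section_svg(res$contours[[40]], svg)
  expect_true(any(grepl("<svg", readLines(svg))))
})
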