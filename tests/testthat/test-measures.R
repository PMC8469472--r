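# measures: per-section parameters, aggregation, layer comparison

test_that("the constructed toy contour measures exactly", {
  xy <- toy_contour()
  lm <- find_landmarks_euclidean(xy)
  p <- measure_section(xy, lm)
  expect_equal(p$tooth_vo_width, 14)
  expect_equal(p$occlusal_vo_width, 8)
  expect_equal(p$occlusal_depth, 4)
  expect_equal(p$cusp_tip_line_angle, 0)
  expect_equal(p$occlusal_depth_vertical, 4)
  expect_true(p$occlusal_vo_width <= p$tooth_vo_width)
})

test_that("tilted tip lines give the analytic angle and oracle depth", {
  # tips (-4, 10), (4, 8): slope -0.25
  xy <- rbind(c(-7, 0), c(-6, 8), c(-4, 10), c(-2, 7), c(0, 5), c(2, 7),
              c(4, 8), c(6, 6), c(7, 0), c(0, -4))
  lm <- find_landmarks_euclidean(xy)
  p <- measure_section(xy, lm)
  expect_equal(abs(p$cusp_tip_line_angle), atan(0.25) * 180 / pi,
               tolerance = 1e-9)
  # oracle: perpendicular distance of every arc vertex to the tip line
  tips <- rbind(lm$points$vestibular_cusp_tip, lm$points$oral_cusp_tip)
  arc <- xy[4:6, ]
  d <- abs(odontometry:::signed_line_distance(arc[, 1], arc[, 2],
                                              tips[2, ], tips[1, ]))
  expect_equal(p$occlusal_depth, max(d), tolerance = 1e-12)
  # the vertical-drop variant exceeds the perpendicular one for tilted lines
  expect_gt(p$occlusal_depth_vertical, p$occlusal_depth)
})

test_that("a circle measures width and area without landmarks", {
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  p <- measure_section(cbind(cos(th), sin(th)), landmarks = NULL)
  expect_equal(p$tooth_vo_width, 2, tolerance = 1e-4)
  expect_equal(p$enclosed_area, pi, tolerance = 1e-3)
  expect_true(is.na(p$occlusal_depth))
})

test_that("parameters are invariant under in-plane rigid motion", {
  xy <- toy_contour_asym()
  th <- -0.4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p0 <- measure_section(xy, find_landmarks_euclidean(xy))
  # rotate, landmark in the rotated frame upright again, measure
  lm0 <- find_landmarks_euclidean(xy)
  # depth and contour length are frame-free quantities
  moved <- sweep(xy %*% t(R), 2, c(12, 3), "+")
  expect_equal(odontometry:::polyline_length(moved, TRUE),
               p0$contour_length, tolerance = 1e-9)
  expect_equal(abs(polygon_area(moved)), p0$enclosed_area,
               tolerance = 1e-9)
})

test_that("aggregation computes maxima with indices and plain means", {
  mk <- function(w) structure(list(layer = "enamel", tooth_vo_width = w,
                                   contour_length = NA_real_,
                                   enclosed_area = NA_real_,
                                   occlusal_vo_width = NA_real_,
                                   occlusal_depth = NA_real_,
                                   occlusal_depth_vertical = NA_real_,
                                   cusp_tip_line_angle = NA_real_,
                                   cervical_shortest_vestibular = NA_real_,
                                   cervical_shortest_oral = NA_real_),
                              class = "section_parameters")
  params <- list(mk(10), mk(12), mk(11))
  rep <- aggregate_sections(params, valid = c(TRUE, TRUE, TRUE),
                            exclusion = "invalid-only")
  expect_equal(unname(rep$max["tooth_vo_width"]), 12)
  expect_equal(unname(rep$max_section["tooth_vo_width"]), 2L)
  expect_equal(unname(rep$mean["tooth_vo_width"]), 11)
  # marginal exclusion drops the outermost valid section at each end
  repm <- aggregate_sections(params, valid = c(TRUE, TRUE, TRUE),
                             exclusion = "marginal")
  expect_equal(repm$included, 2L)
  expect_error(aggregate_sections(params, valid = rep(FALSE, 3)),
               "empty report")
})

test_that("identical layers give 100% ratios everywhere", {
  lr <- layer_report_from_values(
    max_values = c(tooth_vo_width = 12, occlusal_vo_width = 8,
                   occlusal_depth = 3),
    mean_values = c(tooth_vo_width = 11, occlusal_vo_width = 7,
                    occlusal_depth = 2))
  rep <- tooth_report(lr, lr)
  pct <- rep$ratios$value[rep$ratios$quantity %in%
    c("tooth_vo_width_pct", "occlusal_vo_width_pct", "occlusal_depth_pct")]
  expect_true(all(pct == 100))
})

test_that("a zero enamel denominator yields a missing ratio", {
  en <- layer_report_from_values(max_values = c(occlusal_depth = 0))
  de <- layer_report_from_values(max_values = c(occlusal_depth = 1))
  rep <- tooth_report(en, de)
  r <- rep$ratios
  expect_true(is.na(r$value[r$quantity == "occlusal_depth_pct" &
                            r$variant == "maximal"]))
})

test_that("dentine stays inside enamel on every shared fixture section", {
  res <- ado_fixture("shell_pipeline")
  tab <- res$per_section
  wide <- merge(tab[tab$layer == "enamel", c("section_index",
                                             "tooth_vo_width")],
                tab[tab$layer == "dentine", c("section_index",
                                              "tooth_vo_width")],
                by = "section_index", suffixes = c("_en", "_de"))
  expect_true(all(wide$tooth_vo_width_de <= wide$tooth_vo_width_en + 1e-9))
})

test_that("report means are recomputable from the per-section table", {
  res <- ado_fixture("shell_pipeline")
  tab <- res$per_section
  en <- res$report$layers$enamel
  sub <- tab[tab$layer == "enamel" & tab$section_index %in% en$included, ]
  expect_equal(mean(sub$tooth_vo_width),
               unname(en$mean["tooth_vo_width"]), tolerance = 1e-12)
  expect_equal(max(sub$occlusal_depth, na.rm = TRUE),
               unname(en$max["occlusal_depth"]), tolerance = 1e-12)
})
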