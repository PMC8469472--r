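# Per-section odontometric parameters, stack aggregation and enamel-dentine
# comparison ratios.

#' Measure odontometric parameters on one section contour
#'
#' Horizontal = vestibulo-oral axis, vertical = the tooth frame's vertical
#' axis. The occlusal width is the horizontal-projection distance between
#' the two cusp tips; the occlusal depth is the perpendicular distance
#' between the cusp-tip tangent line and its parallel through the deepest
#' occlusal point (the vertical-drop variant is also reported).
#'
#' @param xy contour point matrix for the layer (closed polyline or sector).
#' @param landmarks a `contour_landmarks` for this contour, or NULL when
#'   landmark detection failed (size parameters are still measured).
#' @param layer `"enamel"` or `"dentine"`.
#' @param closed closed polyline? (areas are only computed when closed).
#' @param cervical_edges optional 2x2 matrix (vestibular, oral cervical edge
#'   points) enabling the cervical shortest distances.
#' @return object of class `section_parameters` (a named list; missing
#'   quantities are NA).
#' @export
measure_section <- function(xy, landmarks = NULL, layer = "enamel",
                            closed = TRUE, cervical_edges = NULL) {
  xy <- as.matrix(xy)
  p <- list(layer = layer)
  p$tooth_vo_width <- diff(range(xy[, 1]))
  p$contour_length <- polyline_length(xy, closed)
  p$enclosed_area <- if (closed) abs(polygon_area(xy)) else NA_real_
  p$occlusal_vo_width <- NA_real_
  p$occlusal_depth <- NA_real_
  p$occlusal_depth_vertical <- NA_real_
  p$cusp_tip_line_angle <- NA_real_
  p$cervical_shortest_vestibular <- NA_real_
  p$cervical_shortest_oral <- NA_real_
  if (!is.null(landmarks)) {
    lm <- landmarks$points
    vt <- lm$vestibular_cusp_tip; ot <- lm$oral_cusp_tip
    dp <- lm$deepest_occlusal_point
    p$occlusal_vo_width <- abs(vt[1] - ot[1])
    p$occlusal_depth <- abs(signed_line_distance(dp[1], dp[2], vt, ot))
    slope_ang <- atan2(vt[2] - ot[2], vt[1] - ot[1])
    if (slope_ang > pi / 2) slope_ang <- slope_ang - pi
    if (slope_ang < -pi / 2) slope_ang <- slope_ang + pi
    p$cusp_tip_line_angle <- slope_ang * 180 / pi
    # vertical-drop variant: drop from the tip line measured straight down
    if (abs(vt[1] - ot[1]) > 1e-12) {
      line_y <- ot[2] + (vt[2] - ot[2]) * (dp[1] - ot[1]) / (vt[1] - ot[1])
      p$occlusal_depth_vertical <- abs(line_y - dp[2])
    }
    if (!is.null(cervical_edges)) {
      mv <- lm$max_convexity_vestibular; mo <- lm$max_convexity_oral
      p$cervical_shortest_vestibular <-
        sqrt(sum((mv - cervical_edges[1, ])^2))
      p$cervical_shortest_oral <- sqrt(sum((mo - cervical_edges[2, ])^2))
    }
  }
  structure(p, class = "section_parameters")
}

PARAM_NAMES <- c("tooth_vo_width", "occlusal_vo_width", "occlusal_depth",
                 "occlusal_depth_vertical", "cusp_tip_line_angle",
                 "contour_length", "enclosed_area",
                 "cervical_shortest_vestibular", "cervical_shortest_oral")

#' Aggregate per-section parameters of one layer over the section stack
#'
#' Invalid sections are excluded; by default the outermost valid section at
#' each end of the stack is additionally treated as marginal and excluded
#' (the most mesially and distally located usable slices tend to carry
#' distorted morphology). Maxima keep their 1-based arg-max section index;
#' averages are the arithmetic mean over included sections, computed from
#' unrounded values.
#'
#' @param params list of `section_parameters` (or NULL where missing),
#'   indexed by section.
#' @param valid logical vector: which sections carry a valid contour.
#' @param exclusion `"marginal"` (default: invalid plus the outermost valid
#'   section at each end) or `"invalid-only"`.
#' @return object of class `layer_report`: `max` / `max_section` / `mean`
#'   per parameter, plus `included` and `excluded` section index vectors.
#' @export
aggregate_sections <- function(params, valid,
                               exclusion = c("marginal", "invalid-only")) {
  exclusion <- match.arg(exclusion)
  ns <- length(params)
  stopifnot(length(valid) == ns)
  inc <- which(valid)
  if (!length(inc)) stop("empty report: no valid sections in this layer")
  if (exclusion == "marginal" && length(inc) > 2L)
    inc <- inc[-c(1L, length(inc))]
  mx <- setNames(rep(NA_real_, length(PARAM_NAMES)), PARAM_NAMES)
  mxs <- setNames(rep(NA_integer_, length(PARAM_NAMES)), PARAM_NAMES)
  mn <- mx
  for (nm in PARAM_NAMES) {
    vals <- vapply(params[inc], function(p)
      if (is.null(p) || is.null(p[[nm]])) NA_real_ else as.numeric(p[[nm]]),
      0)
    ok <- is.finite(vals)
    if (any(ok)) {
      mx[nm] <- max(vals[ok])
      mxs[nm] <- inc[ok][which.max(vals[ok])]
      mn[nm] <- mean(vals[ok])
    }
  }
  structure(list(max = mx, max_section = mxs, mean = mn,
                 included = inc, excluded = setdiff(seq_len(ns), inc)),
            class = "layer_report")
}

#' Build a two-layer tooth report
#'
#' @param enamel,dentine `layer_report`s from [aggregate_sections()]; the
#'   dentine layer may be NULL for solid (single-layer) crowns.
#' @return object of class `tooth_report` with `layers` and (when both
#'   layers are present) `ratios` from [compare_layers()].
#' @export
tooth_report <- function(enamel, dentine = NULL) {
  rep <- structure(list(layers = list(enamel = enamel, dentine = dentine)),
                   class = "tooth_report")
  if (!is.null(dentine)) rep$ratios <- compare_layers(rep)
  rep
}

round2 <- function(x) round(x + 0, 2)

#' Dentine-to-enamel comparison ratios
#'
#' Emits the dentine-as-percent-of-enamel ratios for the maximal and average
#' vestibulo-oral widths (whole tooth and occlusal surface) and the vertical
#' occlusal depths, plus the per-layer vertical/horizontal (depth over
#' occlusal width) average ratios. Percentages are `100 * dentine / enamel`
#' rounded to 2 decimals; a zero enamel denominator yields NA.
#'
#' @param report a `tooth_report` with both layers present.
#' @return data frame with columns `quantity`, `variant`, `value`.
#' @export
compare_layers <- function(report) {
  stopifnot(inherits(report, "tooth_report"))
  en <- report$layers$enamel
  de <- report$layers$dentine
  if (is.null(en) || is.null(de))
    stop("both enamel and dentine layers are required")
  pct <- function(d, e) {
    if (!is.finite(e) || !is.finite(d) || e == 0) return(NA_real_)
    round2(100 * d / e)
  }
  rat <- function(a, b) {
    if (!is.finite(a) || !is.finite(b) || b == 0) return(NA_real_)
    round2(a / b)
  }
  data.frame(
    quantity = c("tooth_vo_width_pct", "occlusal_vo_width_pct",
                 "occlusal_depth_pct",
                 "tooth_vo_width_pct", "occlusal_vo_width_pct",
                 "occlusal_depth_pct",
                 "depth_width_ratio_enamel", "depth_width_ratio_dentine"),
    variant = c("maximal", "maximal", "maximal",
                "average", "average", "average",
                "average", "average"),
    value = c(
      pct(de$max[["tooth_vo_width"]], en$max[["tooth_vo_width"]]),
      pct(de$max[["occlusal_vo_width"]], en$max[["occlusal_vo_width"]]),
      pct(de$max[["occlusal_depth"]], en$max[["occlusal_depth"]]),
      pct(de$mean[["tooth_vo_width"]], en$mean[["tooth_vo_width"]]),
      pct(de$mean[["occlusal_vo_width"]], en$mean[["occlusal_vo_width"]]),
      pct(de$mean[["occlusal_depth"]], en$mean[["occlusal_depth"]]),
      rat(en$mean[["occlusal_depth"]], en$mean[["occlusal_vo_width"]]),
      rat(de$mean[["occlusal_depth"]], de$mean[["occlusal_vo_width"]])),
    stringsAsFactors = FALSE)
}

#' Construct a layer report directly from summary numbers
#'
#' Convenience constructor for comparing externally obtained maxima and
#' averages (e.g. a published measurement table) with [compare_layers()].
#'
#' @param max_values,mean_values named numeric vectors using the parameter
#'   names of `section_parameters` (e.g. `tooth_vo_width`).
#' @param max_sections optional named integer vector of arg-max sections.
#' @return a `layer_report`.
#' @export
layer_report_from_values <- function(max_values, mean_values = NULL,
                                     max_sections = NULL) {
  mx <- setNames(rep(NA_real_, length(PARAM_NAMES)), PARAM_NAMES)
  mxs <- setNames(rep(NA_integer_, length(PARAM_NAMES)), PARAM_NAMES)
  mn <- mx
  mx[names(max_values)] <- max_values
  if (!is.null(mean_values)) mn[names(mean_values)] <- mean_values
  if (!is.null(max_sections))
    mxs[names(max_sections)] <- as.integer(max_sections)
  structure(list(max = mx, max_section = mxs, mean = mn,
                 included = integer(), excluded = integer()),
            class = "layer_report")
}

#' @export
print.tooth_report <- function(x, ...) {
  cat("tooth_report\n")
  for (ln in names(x$layers)) {
    lr <- x$layers[[ln]]
    if (is.null(lr)) next
    cat(sprintf(" %s: %d sections included, %d excluded\n", ln,
                length(lr$included), length(lr$excluded)))
    for (nm in c("tooth_vo_width", "occlusal_vo_width", "occlusal_depth")) {
      cat(sprintf("   %-18s max %6.2f mm (section %s)  mean %6.2f mm\n", nm,
                  lr$max[[nm]],
                  ifelse(is.na(lr$max_section[[nm]]), "-",
                         lr$max_section[[nm]]),
                  lr$mean[[nm]]))
    }
  }
  if (!is.null(x$ratios)) {
    cat(" dentine/enamel ratios:\n")
    print(x$ratios, row.names = FALSE)
  }
  invisible(x)
}

#' Write the per-tooth report as JSON
#' @param report a `tooth_report`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list()
  for (ln in names(report$layers)) {
    lr <- report$layers[[ln]]
    if (is.null(lr)) next
    out[[ln]] <- list(max = as.list(lr$max),
                      max_section = as.list(lr$max_section),
                      mean = as.list(lr$mean),
                      included = lr$included, excluded = lr$excluded)
  }
  if (!is.null(report$ratios)) out$ratios <- report$ratios
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
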