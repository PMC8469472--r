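# End-to-end pipeline: orientation -> sectioning -> landmarks -> measures ->
# report, with a flat key-value configuration and inspectable artifacts.

#' Pipeline configuration
#'
#' All tunables of the automated measurement pipeline. Defaults follow the
#' package's documented conventions; the measurement pipeline itself is
#' deterministic.
#'
#' @param curvature_radius mm; NULL = 5x mean edge length.
#' @param border_percentile Gaussian-curvature mask percentile.
#' @param max_iterations,tolerance orientation iteration controls
#'   (tolerance in radians).
#' @param calibration_angle degrees, mesio-distal calibration threshold.
#' @param ns number of sections (default 80).
#' @param landmark_mode `"euclidean"` or `"curvature"`.
#' @param landmark_window mm, curvature-mode smoothing window.
#' @param min_depth mm, minimum occlusal pocket depth.
#' @param min_height,min_width mm, contour validity minima.
#' @param exclusion `"marginal"` or `"invalid-only"`.
#' @param tooth_number optional FDI tooth number (metadata; also fixes the
#'   mesial direction convention when given).
#' @param buccal_mark optional 3-vector marking the buccal (vestibular) side;
#'   used to orient the vestibulo-oral axis sign.
#' @param output_dir optional artifact directory.
#' @param overrides optional data frame of manual landmark corrections with
#'   columns `section`, `layer`, `landmark`, `x`, `y`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(curvature_radius = NULL,
                            border_percentile = 90,
                            max_iterations = 10L,
                            tolerance = 0.005,
                            calibration_angle = 25,
                            ns = 80L,
                            landmark_mode = c("euclidean", "curvature"),
                            landmark_window = 0.5,
                            min_depth = 0.2,
                            min_height = 0.5,
                            min_width = 1.0,
                            exclusion = c("marginal", "invalid-only"),
                            tooth_number = NA_integer_,
                            buccal_mark = NULL,
                            output_dir = NULL,
                            overrides = NULL) {
  landmark_mode <- match.arg(landmark_mode)
  exclusion <- match.arg(exclusion)
  cfg <- list(curvature_radius = curvature_radius,
              border_percentile = border_percentile,
              max_iterations = as.integer(max_iterations),
              tolerance = tolerance,
              calibration_angle = calibration_angle,
              ns = as.integer(ns),
              landmark_mode = landmark_mode,
              landmark_window = landmark_window,
              min_depth = min_depth, min_height = min_height,
              min_width = min_width,
              exclusion = exclusion,
              tooth_number = tooth_number,
              buccal_mark = buccal_mark,
              output_dir = output_dir,
              overrides = overrides)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (cfg$ns < 1L) stop("config error: ns must be at least 1")
  if (!is.null(cfg$curvature_radius) && cfg$curvature_radius <= 0)
    stop("config error: curvature_radius must be positive")
  if (cfg$border_percentile <= 0 || cfg$border_percentile > 100)
    stop("config error: border_percentile must be in (0, 100]")
  if (cfg$tolerance <= 0) stop("config error: tolerance must be positive")
  if (cfg$max_iterations < 1L)
    stop("config error: max_iterations must be at least 1")
  if (cfg$landmark_window <= 0)
    stop("config error: landmark_window must be positive")
  if (!is.null(cfg$buccal_mark) && length(cfg$buccal_mark) != 3L)
    stop("config error: buccal_mark must be a 3-vector")
  invisible(cfg)
}

#' Write a pipeline configuration as a flat key-value file
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  enc <- function(v) {
    if (is.null(v)) return("NULL")
    if (is.data.frame(v)) return(jsonlite::toJSON(v, digits = NA))
    paste(vapply(v, function(x)
      if (is.character(x)) x else format(x, digits = 17), ""),
      collapse = ",")
  }
  keys <- names(config)
  writeLines(paste0(keys, " = ", vapply(config[keys], enc, "")), path)
  invisible(path)
}

#' Read a pipeline configuration from a flat key-value file
#' @param path file written by [write_pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr(" = ", lines), invert = TRUE)
  cfg <- list()
  numeric_keys <- c("curvature_radius", "border_percentile", "max_iterations",
                    "tolerance", "calibration_angle", "ns", "landmark_window",
                    "min_depth", "min_height", "min_width", "tooth_number",
                    "buccal_mark")
  for (p in kv) {
    key <- trimws(p[1]); val <- p[2]
    if (val == "NULL") { cfg[key] <- list(NULL); next }
    if (key == "overrides") {
      cfg[[key]] <- as.data.frame(jsonlite::fromJSON(val))
      next
    }
    if (key %in% numeric_keys) {
      cfg[[key]] <- as.numeric(strsplit(val, ",")[[1]])
    } else {
      cfg[[key]] <- val
    }
  }
  do.call(pipeline_config, cfg)
}

#' Run the full odontometric pipeline
#'
#' Executes orientation (occlusal border + tooth frame), transverse
#' sectioning, landmark detection per section and layer, measurement and
#' aggregation. Identical inputs and configuration give identical outputs.
#' When `config$output_dir` is set, every stage's intermediate artifact is
#' written there (contours and landmarks CSV, frame and report JSON, applied
#' configuration, per-section SVG overlays, and a log of settings and
#' exclusions).
#'
#' @param input a [tooth_surface()] or a mesh file path.
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `report` (a `tooth_report`),
#'   `frame`, `border`, `sections`, `contours`, `per_section` (data frame),
#'   `landmark_table`.
#' @export
run_pipeline <- function(input, config = pipeline_config()) {
  validate_config(config)
  surface <- if (inherits(input, "tooth_surface")) input
             else load_surface(input)
  log_lines <- c("stage settings:",
                 paste0("  ns = ", config$ns),
                 paste0("  landmark_mode = ", config$landmark_mode),
                 paste0("  border_percentile = ", config$border_percentile))

  field <- estimate_curvature(surface, config$curvature_radius)
  orient <- iterate_orientation(surface, field,
                                percentile = config$border_percentile,
                                max_iterations = config$max_iterations,
                                tolerance = config$tolerance,
                                calibration_angle = config$calibration_angle)
  frame <- orient$frame
  border <- orient$border
  frame <- apply_buccal_mark(frame, config$buccal_mark)
  sections <- generate_planes(frame, frame$ellipse, surface, config$ns)
  contours <- cut_surface(surface, sections, frame)

  per_sec <- analyse_sections(contours, config)
  en_rep <- aggregate_sections(per_sec$params$enamel, per_sec$valid$enamel,
                               config$exclusion)
  de_rep <- NULL
  if (any(per_sec$valid$dentine))
    de_rep <- aggregate_sections(per_sec$params$dentine,
                                 per_sec$valid$dentine, config$exclusion)
  report <- tooth_report(en_rep, de_rep)

  log_lines <- c(log_lines,
                 sprintf("enamel: %d valid sections", sum(per_sec$valid$enamel)),
                 sprintf("dentine: %d valid sections", sum(per_sec$valid$dentine)),
                 sprintf("frame converged: %s (%d iterations)",
                         frame$converged, frame$iterations_used))

  res <- structure(list(report = report, frame = frame, border = border,
                        sections = sections, contours = contours,
                        per_section = per_sec$table,
                        landmark_table = per_sec$landmark_table,
                        log = log_lines),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_artifacts(res, config)
  res
}

apply_buccal_mark <- function(frame, mark) {
  if (is.null(mark)) return(frame)
  if (sum(frame$vestibulooral_axis * (mark - frame$origin)) < 0) {
    # flip vo and md together to keep the frame right-handed
    frame$vestibulooral_axis <- -frame$vestibulooral_axis
    frame$mesiodistal_axis <- -frame$mesiodistal_axis
  }
  frame
}

# classify the polylines of one section into per-layer contours
section_layers <- function(sc) {
  closed <- Filter(function(p) p$closed, sc$polylines)
  if (!length(closed)) return(NULL)
  inner <- Filter(function(p) identical(p$layer, "inner"), closed)
  outer <- Filter(function(p) identical(p$layer, "outer"), closed)
  if (length(inner) >= 1L && length(outer) >= 1L) {
    # nested contours (separate outer/inner surfaces cut together)
    pick <- function(ps) ps[[which.max(vapply(ps, function(p)
      abs(polygon_area(p$xy)), 0))]]
    return(list(mode = "nested",
                enamel = pick(outer)$xy, dentine = pick(inner)$xy,
                enamel_closed = TRUE, dentine_closed = TRUE,
                cervical = NULL))
  }
  band <- closed[[which.max(vapply(closed, function(p)
    abs(polygon_area(p$xy)), 0))]]
  split <- tryCatch(split_enamel_cap_contour(band$xy), error = function(e) NULL)
  if (!is.null(split)) {
    return(list(mode = "cap", enamel = split$enamel, dentine = split$dentine,
                enamel_closed = FALSE, dentine_closed = FALSE,
                cervical = split$edge_points))
  }
  list(mode = "solid", enamel = band$xy, dentine = NULL,
       enamel_closed = TRUE, dentine_closed = FALSE, cervical = NULL)
}

analyse_sections <- function(contours, config) {
  ns <- length(contours)
  layers <- c("enamel", "dentine")
  params <- list(enamel = vector("list", ns), dentine = vector("list", ns))
  valid <- list(enamel = rep(FALSE, ns), dentine = rep(FALSE, ns))
  rows <- list(); lmrows <- list()
  for (k in seq_len(ns)) {
    sl <- section_layers(contours[[k]])
    if (is.null(sl)) next
    for (layer in layers) {
      xy <- sl[[layer]]
      if (is.null(xy) || nrow(xy) < 5L) next
      closed <- sl[[paste0(layer, "_closed")]]
      lmk <- tryCatch(
        switch(config$landmark_mode,
               euclidean = find_landmarks_euclidean(
                 xy, closed, min_depth = config$min_depth),
               curvature = find_landmarks_curvature(
                 xy, window = config$landmark_window, closed = closed)),
        error = function(e) NULL)
      overridden <- character()
      if (!is.null(config$overrides) && !is.null(lmk)) {
        ov <- config$overrides
        sel <- ov$section == k & ov$layer == layer
        for (r in which(sel)) {
          lmk$points[[ov$landmark[r]]] <- c(ov$x[r], ov$y[r])
          overridden <- c(overridden, ov$landmark[r])
        }
      }
      cerv <- sl$cervical
      if (!is.null(cerv) && !is.null(lmk)) {
        lmk$points$cervical_enamel_edge_vestibular <- cerv[1, ]
        lmk$points$cervical_enamel_edge_oral <- cerv[2, ]
      }
      vres <- validate_contour(xy, closed = closed || sl$mode == "cap",
                               landmarks = if (is.null(lmk))
                                 simpleError("landmark failure") else lmk,
                               min_height = config$min_height,
                               min_width = config$min_width)
      p <- measure_section(xy, lmk, layer = layer, closed = closed,
                           cervical_edges = cerv)
      params[[layer]][[k]] <- p
      valid[[layer]][k] <- vres$valid && !is.null(lmk)
      rows[[length(rows) + 1L]] <- data.frame(
        section_index = k, layer = layer, valid = valid[[layer]][k],
        reason = vres$reason,
        tooth_vo_width = p$tooth_vo_width,
        occlusal_vo_width = p$occlusal_vo_width,
        occlusal_depth = p$occlusal_depth,
        occlusal_depth_vertical = p$occlusal_depth_vertical,
        cusp_tip_line_angle = p$cusp_tip_line_angle,
        contour_length = p$contour_length,
        enclosed_area = p$enclosed_area,
        cervical_shortest_vestibular = p$cervical_shortest_vestibular,
        cervical_shortest_oral = p$cervical_shortest_oral)
      if (!is.null(lmk)) {
        for (nm in names(lmk$points)) {
          pt <- lmk$points[[nm]]
          lmrows[[length(lmrows) + 1L]] <- data.frame(
            section_index = k, layer = layer, landmark = nm,
            x = pt[1], y = pt[2], mode = lmk$mode,
            overridden = nm %in% overridden)
        }
      }
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else NULL
  lmt <- if (length(lmrows)) do.call(rbind, lmrows) else NULL
  list(params = params, valid = valid, table = table, landmark_table = lmt)
}

write_artifacts <- function(res, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$output_dir
  write_contours_csv(res$contours, file.path(od, "contours.csv"))
  if (!is.null(res$landmark_table))
    write_landmarks_csv(res$landmark_table, file.path(od, "landmarks.csv"))
  if (!is.null(res$per_section))
    write.csv(res$per_section, file.path(od, "sections.csv"),
              row.names = FALSE)
  write_report_json(res$report, file.path(od, "report.json"))
  write_frame_json(res$frame, file.path(od, "frame.json"))
  write_pipeline_config(config, file.path(od, "config.txt"))
  writeLines(res$log, file.path(od, "pipeline.log"))
  svgdir <- file.path(od, "svg")
  dir.create(svgdir, showWarnings = FALSE)
  for (sc in res$contours) {
    if (!length(sc$polylines)) next
    write_section_svg(sc, file.path(svgdir,
                                    sprintf("section_%03d.svg",
                                            sc$section_index)))
  }
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$frame)
  print(x$report)
  invisible(x)
}
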