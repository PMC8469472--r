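# Occlusal border detection and tooth coordinate system determination.
#
# The anatomical occlusal surface is the central depression of the crown; its
# border is traced as a closed loop through the vertices of maximal Gaussian
# curvature that encircles a region lying below the border plane. The frame
# is then: origin = border centroid, vertical axis = mean border normal,
# mesio-distal axis = major axis of the ellipse fitted to the projected
# border (calibrated against the crown's maximal planar extent), and the
# vestibulo-oral axis completes a right-handed triad. Border selection and
# frame computation are alternated until the vertical axis settles.

#' Detect the occlusal border loop
#'
#' Depression-first search: concave basins (connected components of
#' negative mean curvature, excluding any spanning more than 35% of the
#' surface) are candidate occlusal depressions. For each basin the border
#' is traced per azimuth as the crest vertex (maximal ridge curvature
#' kappa1, preferring vertices of the high-K percentile mask) just outside
#' the basin edge, with a second pass re-picking each azimuth near the
#' circular running median of the ring radii. A candidate qualifies when
#' the enclosed same-facing surface region lies below the loop plane; among
#' qualifying basins the one enclosing the largest projected area wins, and
#' near-ties raise an ambiguity error.
#'
#' @param surface a [tooth_surface()].
#' @param field matching `curvature_field`.
#' @param percentile mask percentile (default 90).
#' @param restrict optional integer vector of vertex indices to which the
#'   search is restricted (used by [iterate_orientation()]).
#' @param n_bins angular bins used to order the loop.
#' @return object of class `occlusal_border`: `points` (ordered closed loop,
#'   first vertex not repeated), `vertex_indices`, `normals`.
#' @export
detect_occlusal_border <- function(surface, field, percentile = 90,
                                   restrict = NULL, n_bins = 72L) {
  stopifnot(inherits(field, "curvature_field"))
  adj <- vertex_adjacency(surface)
  # depression-first search: the occlusal surface is a concave basin; its
  # border is the ring of maximal Gaussian curvature just outside the basin
  # edge. Basins are connected components of concave (negative mean
  # curvature) vertices.
  concave <- which((field$kappa1 + field$kappa2) / 2 < 0)
  if (!is.null(restrict)) concave <- intersect(concave, restrict)
  basins <- components_of(concave, adj)
  # the occlusal surface is a bounded, centrally located depression; a
  # basin spanning a large share of the model (e.g. the whole pulpal vault
  # of an enamel cap) is not a candidate
  basins <- basins[lengths(basins) >= 20L &
                   lengths(basins) <= 0.35 * nrow(surface$vertices)]
  if (!length(basins))
    stop("no occlusal surface detected: no concave depression on the crown")
  mask <- curvature_percentile_mask(field, percentile)
  if (!is.null(restrict)) mask <- intersect(mask, restrict)
  cands <- list()
  for (basin in basins) {
    cand <- try_border_candidate(surface, field, basin, mask, n_bins)
    if (!is.null(cand)) cands[[length(cands) + 1L]] <- cand
  }
  if (!length(cands))
    stop("no occlusal surface detected: no high-curvature loop encircles a depression")
  scores <- vapply(cands, function(c) c$score, 0)
  best <- which.max(scores)
  if (length(cands) > 1L) {
    rest <- scores[-best]
    if (any(rest > 0.95 * scores[best]))
      stop(sprintf(
        "ambiguous occlusal border: %d candidate loops with scores %s",
        length(cands), paste(sprintf("%.2f", sort(scores, decreasing = TRUE)),
                             collapse = ", ")))
  }
  cands[[best]]$border
}

components_of <- function(ids, adj) {
  inset <- new.env(hash = TRUE)
  for (i in ids) assign(as.character(i), TRUE, envir = inset)
  seen <- new.env(hash = TRUE)
  comps <- list()
  for (i in ids) {
    if (!is.null(seen[[as.character(i)]])) next
    queue <- i
    comp <- integer(0)
    seen[[as.character(i)]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, cur)
      for (nb in adj[[cur]]) {
        cnb <- as.character(nb)
        if (is.null(inset[[cnb]]) || !is.null(seen[[cnb]])) next
        seen[[cnb]] <- TRUE
        queue <- c(queue, nb)
      }
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

# interpret one concave basin as the occlusal depression and trace the
# max-K convex ring just outside its edge; returns list(border, score) or
# NULL when the basin has no such encircling ridge
try_border_candidate <- function(surface, field, basin, mask, n_bins) {
  pts <- surface$vertices[basin, , drop = FALSE]
  ctr <- colMeans(pts)
  n0 <- colMeans(field$normal[basin, , drop = FALSE])
  if (sqrt(sum(n0^2)) < 1e-9) return(NULL)
  n0 <- n0 / sqrt(sum(n0^2))
  e1 <- if (abs(n0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * n0) * n0; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(n0, e1)
  relv <- sweep(surface$vertices, 2, ctr)
  uu <- drop(relv %*% e1); ww <- drop(relv %*% e2)
  hh <- drop(relv %*% n0)
  ang <- atan2(ww, uu)
  rad <- sqrt(uu^2 + ww^2)
  bin_of <- pmin(n_bins, 1L + floor((ang + pi) / (2 * pi) * n_bins))
  # radial extent of the basin per azimuth (the basin edge)
  edge <- rep(NA_real_, n_bins)
  bb <- bin_of[basin]
  for (b in unique(bb)) edge[b] <- max(rad[basin][bb == b])
  filled <- which(is.finite(edge))
  if (length(filled) < 0.6 * n_bins) return(NULL)  # basin not central/annular
  # fill azimuth gaps by nearest filled bin (circular)
  if (length(filled) < n_bins) {
    for (b in which(!is.finite(edge))) {
      dd <- pmin(abs(filled - b), n_bins - abs(filled - b))
      edge[b] <- edge[filled[which.min(dd)]]
    }
  }
  window <- max(1.2, 2.5 * field$neighborhood_radius)
  # candidate ring vertices: convex, same-facing, just outside the basin
  # edge; prefer the high-K percentile mask, fall back to all convex
  convex <- field$kappa1 > 0 & drop(field$normal %*% n0) > 0
  in_mask <- logical(length(convex)); in_mask[mask] <- TRUE
  pick_bin <- function(b, lo, hi) {
    in_window <- which(convex & bin_of == b & rad >= lo & rad <= hi)
    if (!length(in_window)) return(0L)
    pool <- in_window[in_mask[in_window]]
    if (!length(pool)) pool <- in_window
    # localise the crest by ridge strength kappa1: at azimuths where the
    # border crosses a saddle col, Gaussian curvature vanishes but the
    # transverse ridge curvature still peaks on the crest
    pool[which.max(field$kappa1[pool])]
  }
  loop_ids <- vapply(seq_len(n_bins), function(b)
    pick_bin(b, 0.75 * edge[b], edge[b] + window), 0L)
  if (sum(loop_ids > 0L) < 0.85 * n_bins) return(NULL)
  # refinement: the crest radius varies smoothly around the ring; re-pick
  # each bin near the circular running median of the first-pass radii,
  # which rejects undershoot to the basin wall and overrun to cusp flanks
  rb <- rep(NA_real_, n_bins)
  rb[loop_ids > 0L] <- rad[loop_ids[loop_ids > 0L]]
  rmed <- circular_running_median(rb, k = 7L)
  tol <- max(0.8, field$neighborhood_radius)
  loop_ids <- vapply(seq_len(n_bins), function(b)
    pick_bin(b, max(0.75 * edge[b], rmed[b] - tol), rmed[b] + tol), 0L)
  loop_ids <- loop_ids[loop_ids > 0L]
  if (length(loop_ids) < 0.85 * n_bins) return(NULL)
  loop_ids <- loop_ids[order(ang[loop_ids])]
  loop_ids <- loop_ids[!duplicated(loop_ids)]
  loop_pts <- surface$vertices[loop_ids, , drop = FALSE]
  # depression test: enclosed same-facing region lies below the loop plane
  poly <- cbind(uu[loop_ids], ww[loop_ids])
  inside <- point_in_polygon(uu, ww, poly)
  inside[loop_ids] <- FALSE
  inside <- inside & drop(field$normal %*% n0) > 0
  if (sum(inside) < 3L) return(NULL)
  depth <- mean(hh[inside]) - mean(hh[loop_ids])
  if (depth >= 0) return(NULL)
  score <- abs(polygon_area(poly))
  # support tube: all vertices within 0.5 mm of the traced loop. The loop
  # itself is vertex-quantised; the tube is a nearly selection-invariant
  # set that stabilises the frame's normal average and ellipse fit.
  d2 <- outer(rowSums(surface$vertices^2), rep(1, length(loop_ids))) -
    2 * surface$vertices %*% t(loop_pts) +
    outer(rep(1, nrow(surface$vertices)), rowSums(loop_pts^2))
  support <- which(sqrt(pmax(0, apply(d2, 1, min))) <= 0.5)
  border <- structure(list(points = loop_pts, vertex_indices = loop_ids,
                           normals = field$normal[loop_ids, , drop = FALSE],
                           support_indices = support,
                           support_points = surface$vertices[support, ,
                                                             drop = FALSE],
                           support_normals = field$normal[support, ,
                                                          drop = FALSE]),
                      class = "occlusal_border")
  list(border = border, score = score)
}

#' Compute the tooth coordinate frame from an occlusal border
#'
#' Origin is the border centroid; the vertical axis is the mean border
#' normal; the mesio-distal axis is the major axis of the ellipse fitted to
#' the border projected into the plane perpendicular to the vertical axis,
#' calibrated against the crown's maximal planar extent: when the two
#' directions disagree by more than `calibration_angle` degrees the
#' maximal-extent direction is used and the frame flagged. The
#' vestibulo-oral axis completes the right-handed triad.
#'
#' @param border an `occlusal_border`.
#' @param surface the surface it came from.
#' @param calibration_angle degrees; default 25.
#' @return object of class `tooth_frame`: `origin`, `vertical_axis`,
#'   `mesiodistal_axis`, `vestibulooral_axis`, `ellipse`, `calibrated`,
#'   plus `iterations_used`/`converged` filled by [iterate_orientation()].
#' @export
compute_frame <- function(border, surface, calibration_angle = 25) {
  pts <- border$points
  if (nrow(pts) < 3L) stop("degenerate border: fewer than 3 points")
  origin <- colMeans(pts)
  # the vertical axis comes from the loop normals themselves (the crest-top
  # normals are unbiased); the denser support tube only stabilises the
  # ellipse fit below against vertex-selection jitter
  fit_pts <- if (!is.null(border$support_points) &&
                 nrow(border$support_points) >= nrow(pts))
    border$support_points else pts
  nT <- colMeans(border$normals)
  len <- sqrt(sum(nT^2))
  if (len < 1e-9) stop("degenerate border: normals cancel")
  nT <- nT / len
  # orient the vertical axis away from the crown body
  body_dir <- origin - colMeans(surface$vertices)
  if (sum(nT * body_dir) < 0) nT <- -nT
  e1 <- if (abs(nT[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * nT) * nT; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(nT, e1)
  rel <- sweep(fit_pts, 2, origin)
  pr2 <- cbind(rel %*% e1, rel %*% e2)
  sv <- svd(scale(pr2, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate border: projected points are collinear")
  ell <- fit_ellipse(pr2)
  md2 <- ell$major_axis_direction
  md <- md2[1] * e1 + md2[2] * e2
  # calibration against maximal crown dimensions
  relv <- sweep(surface$vertices, 2, origin)
  uu <- relv %*% e1; ww <- relv %*% e2
  th <- seq(0, pi, length.out = 181)[-181]
  ext <- vapply(th, function(t) {
    p <- uu * cos(t) + ww * sin(t)
    diff(range(p))
  }, 0)
  tmax <- th[which.max(ext)]
  mext <- cos(tmax) * e1 + sin(tmax) * e2
  ang <- acos(min(1, abs(sum(md * mext))))
  calibrated <- FALSE
  if (ang > calibration_angle * pi / 180) {
    md <- mext
    calibrated <- TRUE
  }
  md <- md - sum(md * nT) * nT
  md <- md / sqrt(sum(md^2))
  # deterministic sign: positive mesio-distal direction toward the larger
  # crown half (measured by extent beyond the origin)
  pmd <- relv %*% md
  if (max(pmd) < -min(pmd)) md <- -md
  vo <- cross3(nT, md)
  structure(list(origin = origin, vertical_axis = nT, mesiodistal_axis = md,
                 vestibulooral_axis = vo, ellipse = ell,
                 calibrated = calibrated, iterations_used = 1L,
                 converged = NA),
            class = "tooth_frame")
}

# circular running median with NA passthrough (NAs filled from neighbours)
circular_running_median <- function(x, k = 7L) {
  n <- length(x)
  half <- k %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    ix <- ((i - half - 1L):(i + half - 1L)) %% n + 1L
    out[i] <- stats::median(x[ix], na.rm = TRUE)
  }
  out
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.tooth_frame <- function(x, ...) {
  cat("tooth_frame\n")
  cat("  origin        :", sprintf("%.3f", x$origin), "\n")
  cat("  vertical      :", sprintf("%.4f", x$vertical_axis), "\n")
  cat("  mesio-distal  :", sprintf("%.4f", x$mesiodistal_axis), "\n")
  cat("  vestibulo-oral:", sprintf("%.4f", x$vestibulooral_axis), "\n")
  cat("  calibrated:", x$calibrated, " converged:", x$converged,
      " iterations:", x$iterations_used, "\n")
  invisible(x)
}

#' Iterate border detection and frame computation to convergence
#'
#' After the first pass, the border search is restricted to the crown region
#' facing the current occlusal direction (vertices whose normals have a
#' positive component along the vertical axis), and the frame is recomputed;
#' iteration stops when the vertical axis changes by less than `tolerance`
#' radians or `max_iterations` is reached.
#'
#' @param surface a [tooth_surface()].
#' @param field matching `curvature_field`.
#' @param percentile mask percentile.
#' @param max_iterations default 10.
#' @param tolerance radians, default 0.005.
#' @param calibration_angle degrees, passed to [compute_frame()].
#' @return list with `border` and `frame` (frame carries `iterations_used`
#'   and `converged`).
#' @export
iterate_orientation <- function(surface, field, percentile = 90,
                                max_iterations = 10L, tolerance = 0.005,
                                calibration_angle = 25) {
  border <- detect_occlusal_border(surface, field, percentile)
  frame <- compute_frame(border, surface, calibration_angle)
  iterations <- 1L
  converged <- FALSE
  best <- list(border = border, frame = frame, delta = Inf)
  if (tolerance >= pi) {
    frame$iterations_used <- 1L
    frame$converged <- TRUE
    return(list(border = border, frame = frame))
  }
  while (iterations < max_iterations) {
    visible <- which(drop(field$normal %*% frame$vertical_axis) > 0)
    border2 <- tryCatch(
      detect_occlusal_border(surface, field, percentile, restrict = visible),
      error = function(e) NULL)
    if (is.null(border2)) break
    frame2 <- compute_frame(border2, surface, calibration_angle)
    delta <- acos(min(1, abs(sum(frame2$vertical_axis * frame$vertical_axis))))
    iterations <- iterations + 1L
    if (delta < best$delta)
      best <- list(border = border2, frame = frame2, delta = delta)
    border <- border2
    frame <- frame2
    if (delta < tolerance) { converged <- TRUE; break }
  }
  if (!converged && iterations >= max_iterations) {
    warning("orientation did not converge; returning most stable frame")
    border <- best$border
    frame <- best$frame
  }
  frame$iterations_used <- iterations
  frame$converged <- converged
  list(border = border, frame = frame)
}

#' Export a tooth frame as a JSON 4x4 rigid transform sidecar
#'
#' The transform maps tooth-frame coordinates (mesio-distal, vestibulo-oral,
#' vertical) to the mesh's world coordinates.
#'
#' @param frame a `tooth_frame`.
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_frame_json <- function(frame, path) {
  M <- rbind(cbind(frame$mesiodistal_axis, frame$vestibulooral_axis,
                   frame$vertical_axis, frame$origin), c(0, 0, 0, 1))
  jsonlite::write_json(
    list(transform = unname(as.data.frame(M)),
         calibrated = frame$calibrated, converged = frame$converged,
         iterations_used = frame$iterations_used),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
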