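# Landmark detection on 2D transverse contours.
#
# The morphological model: a transverse contour of a posterior tooth shows
# two principal elevations (vestibular and oral cusps) separated by the
# occlusal valley. Exactly two parallel lines can be drawn: one tangent to
# both cusp tips, the other through the deepest point of the occlusal
# contour. Landmarks are found either by Euclidean construction (upper
# convex hull bridge) or by contour curvature analysis.

#' Landmarks of one transverse contour (Euclidean mode)
#'
#' Computes the upper convex hull of the contour; the hull edge bridging the
#' deepest pocket (maximal perpendicular depth of its subtended contour arc)
#' yields the two cusp tips, and the deepest occlusal point is the arc point
#' of maximal perpendicular distance below that tangent line.
#'
#' @param xy two-column matrix: contour points (horizontal = vestibulo-oral,
#'   vertical = occlusal direction), ordered along the contour.
#' @param closed is the polyline closed?
#' @param min_depth mm; pockets shallower than this are not accepted as an
#'   occlusal valley (default 0.2 mm, separating anatomy from mesh noise).
#' @return object of class `contour_landmarks` with `points` (named list of
#'   2D landmarks), `mode`, `tip_line` (point + unit direction), `depth`.
#' @export
find_landmarks_euclidean <- function(xy, closed = TRUE, min_depth = 0.2) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 5L) stop("landmark failure: contour too short")
  bridge <- best_hull_bridge(xy, closed, min_depth)
  if (is.null(bridge))
    stop("landmark failure: no occlusal concavity on the upper side")
  tips <- xy[c(bridge$i1, bridge$i2), , drop = FALSE]
  deepest <- xy[bridge$deep_idx, ]
  # sub-vertex refinement: on a smoothly sampled summit the true tangency
  # point lies between vertices; a local parabola in the tip-line frame
  # recovers it. Sharp corners (true polygonal tips) are left untouched.
  for (it in 1:5) {
    dirv <- tips[2, ] - tips[1, ]
    dirv <- dirv / sqrt(sum(dirv^2))
    tips <- rbind(refine_tip(xy, bridge$i1, dirv, closed),
                  refine_tip(xy, bridge$i2, dirv, closed))
  }
  vest <- which.max(tips[, 1])
  oral <- 3L - vest
  dirv <- tips[2, ] - tips[1, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  pts <- list(
    vestibular_cusp_tip = tips[vest, ],
    oral_cusp_tip = tips[oral, ],
    deepest_occlusal_point = deepest,
    max_convexity_vestibular = xy[which.max(xy[, 1]), ],
    max_convexity_oral = xy[which.min(xy[, 1]), ])
  depth <- abs(signed_line_distance(deepest[1], deepest[2],
                                    tips[1, ], tips[2, ]))
  structure(list(points = pts, mode = "euclidean",
                 tip_line = list(point = tips[1, ], direction = dirv),
                 depth = depth,
                 tip_indices = c(bridge$i1, bridge$i2),
                 deep_index = bridge$deep_idx),
            class = "contour_landmarks")
}

# parabolic sub-vertex tip refinement in the frame aligned with the tip
# line; corners (turning angle above `corner_deg`) are kept as vertices
refine_tip <- function(xy, idx, dirv, closed, span = 5L, corner_deg = 20) {
  n <- nrow(xy)
  ix <- if (closed) ((idx - span - 1L):(idx + span - 1L)) %% n + 1L
        else (idx - span):(idx + span)
  ix <- ix[ix >= 1L & ix <= n]
  if (length(ix) < 5L) return(xy[idx, ])
  p <- match(idx, ix)
  if (is.na(p) || p <= 1L || p >= length(ix)) return(xy[idx, ])
  e1 <- xy[ix[p], ] - xy[ix[p - 1L], ]
  e2 <- xy[ix[p + 1L], ] - xy[ix[p], ]
  turn <- acos(min(1, max(-1, sum(e1 * e2) /
    sqrt(sum(e1^2) * sum(e2^2)))))
  if (!is.finite(turn) || turn > corner_deg * pi / 180) return(xy[idx, ])
  rel <- sweep(xy[ix, , drop = FALSE], 2, xy[idx, ])
  u <- rel[, 1] * dirv[1] + rel[, 2] * dirv[2]
  v <- -rel[, 1] * dirv[2] + rel[, 2] * dirv[1]
  if (anyDuplicated(u)) return(xy[idx, ])
  fit <- tryCatch(stats::lm.fit(cbind(1, u, u^2), v)$coefficients,
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit[3]) || abs(fit[3]) < 1e-9)
    return(xy[idx, ])
  ustar <- -fit[2] / (2 * fit[3])
  if (ustar < min(u) || ustar > max(u)) return(xy[idx, ])
  vstar <- fit[1] + fit[2] * ustar + fit[3] * ustar^2
  xy[idx, ] + c(ustar * dirv[1] - vstar * dirv[2],
                ustar * dirv[2] + vstar * dirv[1])
}

# exhaustive-over-hull-edges pocket search. Returns the hull edge subtending
# the deepest pocket on the upper side, or NULL when no pocket exceeds
# min_depth.
best_hull_bridge <- function(xy, closed = TRUE, min_depth = 0.2) {
  n <- nrow(xy)
  hull <- unique(grDevices::chull(xy[, 1], xy[, 2]))  # clockwise order
  nh <- length(hull)
  if (nh < 3L) return(NULL)
  best <- NULL
  hull_set <- logical(n)
  hull_set[hull] <- TRUE
  for (k in seq_len(nh)) {
    i1 <- hull[k]
    i2 <- hull[(k %% nh) + 1L]
    # contour arc from i1 to i2 not containing other hull vertices
    arcs <- contour_arcs(i1, i2, n, closed)
    arc <- NULL
    for (a in arcs) {
      interior <- setdiff(a, c(i1, i2))
      if (!length(interior)) { if (is.null(arc)) arc <- a; next }
      if (!any(hull_set[interior])) { arc <- a; break }
    }
    if (is.null(arc)) next
    interior <- setdiff(arc, c(i1, i2))
    if (!length(interior)) next
    # order tips left-to-right; a pocket opening upward has its arc below
    # the edge, i.e. negative signed distance w.r.t. the left->right line
    l <- if (xy[i1, 1] <= xy[i2, 1]) i1 else i2
    r <- if (l == i1) i2 else i1
    sd <- signed_line_distance(xy[interior, 1], xy[interior, 2],
                               xy[l, ], xy[r, ])
    j <- which.min(sd)
    depth <- -sd[j]
    if (depth < min_depth) next
    # the pocket must sit on the upper side of the contour: its bridge must
    # lie above the contour's vertical midline
    ymid <- (min(xy[, 2]) + max(xy[, 2])) / 2
    if ((xy[l, 2] + xy[r, 2]) / 2 < ymid) next
    # both tips must stand above the valley floor: a pocket under a flank
    # tail (single-hump contour) is not an occlusal valley
    if (min(xy[l, 2], xy[r, 2]) <= xy[interior[j], 2]) next
    if (is.null(best) || depth > best$depth)
      best <- list(i1 = l, i2 = r, depth = depth, deep_idx = interior[j])
  }
  best
}

# the two index paths from i1 to i2 along a contour
contour_arcs <- function(i1, i2, n, closed) {
  if (i1 == i2) return(list())
  fwd <- if (i1 < i2) i1:i2 else c(i1:n, 1:i2)
  bwd <- if (i1 < i2) c(i1:1, n:i2) else i1:i2
  if (!closed) {
    lo <- min(i1, i2); hi <- max(i1, i2)
    return(list(lo:hi))
  }
  list(fwd, bwd)
}

#' Landmarks of one transverse contour (curvature mode)
#'
#' The contour is resampled at arc-length step `window / 10` and its signed
#' curvature smoothed over the window; cusp tips are the two most prominent
#' convex curvature maxima on the upper side, and the deepest occlusal point
#' is the extremal concave-curvature point on the occlusal arc between them.
#'
#' @param xy contour point matrix (ordered).
#' @param window smoothing window, mm of arc length (default 0.5).
#' @param closed is the polyline closed?
#' @return a `contour_landmarks` (mode `"curvature"`).
#' @export
find_landmarks_curvature <- function(xy, window = 0.5, closed = TRUE) {
  xy <- as.matrix(xy)
  step <- window / 10
  rs <- resample_polyline(xy, step, closed)
  m <- nrow(rs)
  if (m < 12L) stop("landmark failure: contour too short")
  kap <- discrete_curvature(rs, closed)
  w <- max(3L, round(window / step))
  kap_s <- moving_average(kap, w, closed)
  upper <- rs[, 2] > (min(rs[, 2]) + max(rs[, 2])) / 2
  # cusp summits: the two most prominent elevation peaks on the upper side
  # (prominence on the height profile is robust to intermediate ridgelets);
  # each tip is then localised at the summit's convex-curvature maximum
  peaks <- which(local_maxima(rs[, 2], closed) & upper)
  if (length(peaks) < 2L)
    stop("landmark failure: fewer than two convex curvature peaks")
  prom <- peak_prominence(rs[, 2], peaks, closed)
  ord <- peaks[order(-prom)]
  t1 <- ord[1]
  sep_ok <- abs(rs[ord, 1] - rs[t1, 1]) > max(window, 1e-6)
  if (!any(sep_ok[-1]))
    stop("landmark failure: fewer than two distinct cusp peaks")
  t2 <- ord[-1][which(sep_ok[-1])[1]]
  # refine each tip to the curvature maximum within its summit region
  refine <- function(tp) {
    span <- max(3L, round(window / step))
    ix <- if (closed) ((tp - span - 1L):(tp + span - 1L)) %% m + 1L
          else max(1L, tp - span):min(m, tp + span)
    ix[which.max(kap_s[ix])]
  }
  t1 <- refine(t1); t2 <- refine(t2)
  tips <- rs[c(t1, t2), , drop = FALSE]
  # occlusal arc: the index path between tips avoiding the lowest point
  low <- which.min(rs[, 2])
  arcs <- contour_arcs(min(t1, t2), max(t1, t2), m, closed)
  arc <- arcs[[1]]
  if (closed && low %in% arcs[[1]]) arc <- arcs[[2]]
  interior <- setdiff(arc, c(t1, t2))
  if (!length(interior))
    stop("landmark failure: empty occlusal arc")
  deep <- interior[which.min(kap_s[interior])]
  vest <- which.max(tips[, 1]); oral <- 3L - vest
  dirv <- tips[2, ] - tips[1, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  depth <- abs(signed_line_distance(rs[deep, 1], rs[deep, 2],
                                    tips[1, ], tips[2, ]))
  structure(list(points = list(
    vestibular_cusp_tip = tips[vest, ],
    oral_cusp_tip = tips[oral, ],
    deepest_occlusal_point = rs[deep, ],
    max_convexity_vestibular = rs[which.max(rs[, 1]), ],
    max_convexity_oral = rs[which.min(rs[, 1]), ]),
    mode = "curvature",
    tip_line = list(point = tips[1, ], direction = dirv),
    depth = depth, resampled = rs),
    class = "contour_landmarks")
}

# signed discrete curvature via the turning of adjacent unit tangents
discrete_curvature <- function(xy, closed = TRUE) {
  n <- nrow(xy)
  prev <- if (closed) c(n, 1:(n - 1)) else c(1, 1:(n - 1))
  nxt <- if (closed) c(2:n, 1) else c(2:n, n)
  e1 <- xy - xy[prev, , drop = FALSE]
  e2 <- xy[nxt, , drop = FALSE] - xy
  l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
  crossz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  dotv <- rowSums(e1 * e2)
  ang <- atan2(crossz, dotv)
  kap <- 2 * ang / pmax(l1 + l2, 1e-300)
  # convex (outward-bulging) positive regardless of traversal direction
  area <- polygon_area(xy)
  if (closed && area < 0) kap <- -kap
  if (!closed && sum(kap) < 0) kap <- -kap
  if (!closed) kap[c(1, n)] <- 0
  kap
}

moving_average <- function(x, w, closed = TRUE) {
  n <- length(x)
  half <- w %/% 2
  if (closed) {
    xx <- c(tail(x, half), x, head(x, half))
    as.numeric(stats::filter(xx, rep(1 / (2 * half + 1), 2 * half + 1),
                             sides = 2))[(half + 1):(half + n)]
  } else {
    out <- x
    for (i in seq_len(n)) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      out[i] <- mean(x[lo:hi])
    }
    out
  }
}

# topographic prominence of peaks in a (possibly circular) height series:
# peak height minus the higher of the two saddles toward the nearest higher
# peaks; the global maximum gets height - min
peak_prominence <- function(y, peaks, closed = TRUE) {
  n <- length(y)
  vapply(peaks, function(p) {
    side_saddle <- function(dir) {
      lo <- y[p]
      i <- p
      for (k in seq_len(n)) {
        i <- if (closed) ((i - 1L + dir) %% n) + 1L else i + dir
        if (!closed && (i < 1L || i > n)) return(lo)
        lo <- min(lo, y[i])
        if (y[i] > y[p]) return(lo)
        if (closed && i == p) return(lo)
      }
      lo
    }
    y[p] - max(side_saddle(1L), side_saddle(-1L))
  }, 0)
}

local_maxima <- function(x, closed = TRUE) {
  n <- length(x)
  prev <- if (closed) c(n, 1:(n - 1)) else c(1, 1:(n - 1))
  nxt <- if (closed) c(2:n, 1) else c(2:n, n)
  strict <- x > x[prev] & x > x[nxt]
  strict
}

#' Split an enamel-cap band contour at the cervical enamel edges
#'
#' An enamel-cap cross-section is a closed band: the outer (enamel) arc and
#' the inner (dentine-facing) arc meet at the cervical margin on the
#' vestibular and oral sides. The two separation points are the sharp
#' cervical turning points of the band — detected among the lower-half
#' vertices as the most acute exterior turns, taking the outermost
#' (extreme-abscissa) corner of each cervical notch. The band is split there
#' into the upper/outer (enamel) and lower/inner (dentine) open arcs; the
#' two edge points are shared by both.
#'
#' @param section a `section_contour` whose first closed polyline is the
#'   full enamel-cap band (or a two-column matrix of the band itself).
#' @param min_turn degrees; minimum exterior turning angle accepted as a
#'   cervical corner (default 45).
#' @return list with `enamel` (xy matrix), `dentine` (xy matrix),
#'   `edge_points` (2x2 matrix: vestibular, oral), `edge_indices`.
#' @export
split_enamel_cap_contour <- function(section, min_turn = 45) {
  xy <- if (is.matrix(section)) section
        else {
          cl <- Filter(function(p) p$closed, section$polylines)
          if (length(cl) != 1L)
            stop("split failure: expected exactly one closed band polyline")
          cl[[1]]$xy
        }
  n <- nrow(xy)
  if (n < 8L) stop("split failure: band too short")
  kap <- discrete_curvature(xy, closed = TRUE)
  prev <- c(n, 1:(n - 1)); nxt <- c(2:n, 1)
  e1 <- xy - xy[prev, , drop = FALSE]
  e2 <- xy[nxt, , drop = FALSE] - xy
  turn <- acos(pmin(1, pmax(-1, rowSums(e1 * e2) /
    pmax(sqrt(rowSums(e1^2) * rowSums(e2^2)), 1e-300))))
  lower <- xy[, 2] < min(xy[, 2]) + 0.35 * (max(xy[, 2]) - min(xy[, 2]))
  cand <- which(lower & turn > min_turn * pi / 180)
  if (!length(cand)) stop("split failure: no acute cervical corners found")
  xmid <- mean(range(xy[, 1]))
  right <- cand[xy[cand, 1] > xmid]
  left <- cand[xy[cand, 1] <= xmid]
  if (!length(right) || !length(left))
    stop("split failure: cervical corners not found on both sides")
  i_right <- right[which.max(xy[right, 1])]
  i_left <- left[which.min(xy[left, 1])]
  arcs <- contour_arcs(min(i_right, i_left), max(i_right, i_left), n,
                       closed = TRUE)
  top <- which.max(xy[, 2])
  enamel_arc <- if (top %in% arcs[[1]]) arcs[[1]] else arcs[[2]]
  dentine_arc <- if (top %in% arcs[[1]]) arcs[[2]] else arcs[[1]]
  edge_pts <- rbind(vestibular = xy[i_right, ], oral = xy[i_left, ])
  list(enamel = xy[enamel_arc, , drop = FALSE],
       dentine = xy[dentine_arc, , drop = FALSE],
       edge_points = edge_pts,
       edge_indices = c(vestibular = i_right, oral = i_left))
}

#' Validate a section contour for measurement
#'
#' A section is invalid when the polyline is open, the two-cusp occlusal
#' structure is absent (landmark detection failed), or the contour is
#' smaller than the configured minima — the marginal-slice situations the
#' selection criteria exclude.
#'
#' @param xy contour matrix (one layer's polyline or sector).
#' @param closed closed polyline?
#' @param landmarks a `contour_landmarks`, or the error from attempting to
#'   compute one, or NULL to attempt Euclidean landmarks here.
#' @param min_height,min_width mm minima (defaults 0.5 and 1.0).
#' @return list with `valid` flag and `reason` string ("" when valid).
#' @export
validate_contour <- function(xy, closed = TRUE, landmarks = NULL,
                             min_height = 0.5, min_width = 1.0) {
  if (is.null(xy) || nrow(xy) < 5L)
    return(list(valid = FALSE, reason = "empty or tiny contour"))
  if (!closed)
    return(list(valid = FALSE, reason = "open contour"))
  height <- diff(range(xy[, 2]))
  width <- diff(range(xy[, 1]))
  if (height < min_height || width < min_width)
    return(list(valid = FALSE, reason = sprintf(
      "contour below minimum size (%.2f x %.2f mm)", width, height)))
  if (is.null(landmarks))
    landmarks <- tryCatch(find_landmarks_euclidean(xy, closed),
                          error = function(e) e)
  if (inherits(landmarks, "error") || inherits(landmarks, "condition"))
    return(list(valid = FALSE, reason = "no occlusal concavity"))
  list(valid = TRUE, reason = "")
}

#' Write landmarks of a section stack to CSV
#' @param landmark_table data frame as produced by [run_pipeline()]
#'   intermediates (columns section_index, layer, landmark, x, y, mode,
#'   overridden).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_landmarks_csv <- function(landmark_table, path) {
  write.csv(landmark_table, path, row.names = FALSE)
  invisible(path)
}
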