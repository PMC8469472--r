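# Odontotomy: ellipse approximation of the occlusal border, generation of
# equally spaced transverse cutting planes, and plane-mesh intersection into
# 2D section contours expressed in the common tooth frame.

#' Direct least-squares ellipse fit
#'
#' Fits the algebraic conic ax^2 + bxy + cy^2 + dx + ey + f = 0 with the
#' ellipse-specific constraint 4ac - b^2 = 1 (Fitzgibbon/Halir-Flusser), so
#' the result is always an ellipse.
#'
#' @param points two-column matrix of 2D points (at least 5, not collinear).
#' @return object of class `fitted_ellipse`: `center`, `semi_major`,
#'   `semi_minor`, `major_axis_direction` (unit 2-vector; for a circle the
#'   tie is broken to (1, 0)).
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 5L) stop("ellipse fit needs at least 5 points")
  x <- points[, 1]; y <- points[, 2]
  mx <- mean(x); my <- mean(y)
  x <- x - mx; y <- y - my
  sv <- svd(cbind(x, y))$d
  if (sv[2] < 1e-10 * max(sv[1], 1))
    stop("ellipse fit failed: points are collinear")
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("ellipse fit failed: no elliptical solution")
  a1 <- evec[, ok[1]]
  coef <- c(a1, Tm %*% a1)  # a b c d e f in centred coordinates
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  s <- sqrt((A - C)^2 + B^2)
  a_len <- sqrt(num / (den * (s - (A + C))))
  b_len <- sqrt(num / (den * (-s - (A + C))))
  semi_major <- max(a_len, b_len)
  semi_minor <- min(a_len, b_len)
  if (s < 1e-12 * abs(A + C) ||
      (semi_major - semi_minor) < 1e-9 * semi_major) {
    dir <- c(1, 0)  # circle: documented tie-break
  } else {
    theta <- 0.5 * atan2(B, A - C)
    dir <- c(cos(theta), sin(theta))
    perp <- c(-dir[2], dir[1])
    # disambiguate the axis-angle convention against the data spread
    if (stats::var(x * perp[1] + y * perp[2]) >
        stats::var(x * dir[1] + y * dir[2])) dir <- perp
  }
  if (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0)) dir <- -dir
  structure(list(center = c(cx + mx, cy + my), semi_major = semi_major,
                 semi_minor = semi_minor, major_axis_direction = dir),
            class = "fitted_ellipse")
}

#' Generate equally spaced transverse cutting planes
#'
#' Planes are perpendicular to the mesio-distal axis and span the crown's
#' full projected extent with interior placement: plane k sits at
#' `span_min + k * span / (ns + 1)`, so both extreme planes always intersect
#' the crown rather than grazing its tips.
#'
#' @param frame a `tooth_frame` (see [compute_frame()]).
#' @param ellipse the fitted occlusal-border ellipse (kept for provenance).
#' @param surface the surface to be sectioned.
#' @param ns number of sections (default 80).
#' @return object of class `section_set`: `ns`, `plane_positions` (offsets
#'   along the mesio-distal axis), `plane_normal`, `spacing`.
#' @export
generate_planes <- function(frame, ellipse, surface, ns = 80L) {
  stopifnot(inherits(frame, "tooth_frame"))
  ns <- as.integer(ns)
  if (ns < 1L) stop("ns must be at least 1")
  proj <- surface$vertices %*% frame$mesiodistal_axis
  span <- range(proj)
  width <- span[2] - span[1]
  spacing <- width / (ns + 1)
  positions <- span[1] + seq_len(ns) * spacing
  structure(list(ns = ns, plane_positions = positions,
                 plane_normal = frame$mesiodistal_axis, spacing = spacing),
            class = "section_set")
}

#' Cut a surface with a stack of transverse planes
#'
#' Each plane-mesh intersection is chained triangle by triangle into closed
#' polylines (open chains can only arise from non-watertight regions; they
#' are kept but flagged). Polylines are expressed in 2D section coordinates:
#' horizontal = vestibulo-oral axis, vertical = vertical axis, so all
#' sections share axes. For enamel-cap style sections, a polyline nested
#' inside another is tagged `inner` (dentine-facing), containment depth 0 is
#' `outer`.
#'
#' @param surface a [tooth_surface()].
#' @param sections a `section_set` from [generate_planes()].
#' @param frame the `tooth_frame` defining the 2D coordinates.
#' @return list of `section_contour` objects (one per plane, mesial to
#'   distal), each with `section_index`, `position`, and `polylines` — a list
#'   of `list(xy, closed, layer)`.
#' @export
cut_surface <- function(surface, sections, frame) {
  v <- surface$vertices
  f <- surface$faces
  n <- frame$mesiodistal_axis
  origin <- frame$origin
  proj <- drop(v %*% n)
  horiz <- drop((v %*% frame$vestibulooral_axis))
  vert <- drop((v %*% frame$vertical_axis))
  h0 <- sum(origin * frame$vestibulooral_axis)
  v0 <- sum(origin * frame$vertical_axis)
  nv <- nrow(v)
  out <- vector("list", sections$ns)
  for (k in seq_len(sections$ns)) {
    c0 <- sections$plane_positions[k]
    d <- proj - c0
    d[d == 0] <- 1e-12  # deterministic perturbation for on-plane vertices
    s1 <- d[f[, 1]] > 0; s2 <- d[f[, 2]] > 0; s3 <- d[f[, 3]] > 0
    crossing <- which((s1 != s2) | (s2 != s3))
    polys <- list()
    if (length(crossing)) {
      fc <- f[crossing, , drop = FALSE]
      # the two crossed edges per face, as undirected vertex-pair keys
      ekeys <- matrix(NA_real_, length(crossing), 2)
      epts_h <- matrix(NA_real_, length(crossing), 2)
      epts_v <- matrix(NA_real_, length(crossing), 2)
      cross_edge <- function(i, j) {
        di <- d[i]; dj <- d[j]
        tt <- di / (di - dj)
        list(key = (nv + 1) * pmin(i, j) + pmax(i, j),
             h = horiz[i] + tt * (horiz[j] - horiz[i]),
             v = vert[i] + tt * (vert[j] - vert[i]))
      }
      slot <- rep(1L, length(crossing))
      for (pair in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
        i <- fc[, pair[1]]; j <- fc[, pair[2]]
        cr <- (d[i] > 0) != (d[j] > 0)
        if (!any(cr)) next
        ce <- cross_edge(i[cr], j[cr])
        rows <- which(cr)
        for (t in seq_along(rows)) {
          r <- rows[t]
          ekeys[r, slot[r]] <- ce$key[t]
          epts_h[r, slot[r]] <- ce$h[t]
          epts_v[r, slot[r]] <- ce$v[t]
          slot[r] <- slot[r] + 1L
        }
      }
      polys <- chain_segments(ekeys, epts_h, epts_v, h0, v0)
    }
    polys <- tag_nesting(polys)
    out[[k]] <- structure(list(section_index = k, position = c0,
                               polylines = polys),
                          class = "section_contour")
  }
  out
}

# chain per-face intersection segments into polylines by walking shared
# edge keys (each key is shared by at most two crossing faces)
chain_segments <- function(ekeys, epts_h, epts_v, h0, v0) {
  nf <- nrow(ekeys)
  allkeys <- unique(as.vector(ekeys))
  k1 <- match(ekeys[, 1], allkeys)
  k2 <- match(ekeys[, 2], allkeys)
  nk <- length(allkeys)
  # coordinates per key (identical from either face sharing it)
  kh <- numeric(nk); kv <- numeric(nk)
  kh[k1] <- epts_h[, 1]; kv[k1] <- epts_v[, 1]
  kh[k2] <- epts_h[, 2]; kv[k2] <- epts_v[, 2]
  # faces incident to each key (at most 2)
  fa <- integer(nk); fb <- integer(nk)
  for (r in seq_len(nf)) {
    for (kk in c(k1[r], k2[r])) {
      if (fa[kk] == 0L) fa[kk] <- r else fb[kk] <- r
    }
  }
  used <- rep(FALSE, nf)
  polys <- list()
  other_key <- function(r, kk) if (k1[r] == kk) k2[r] else k1[r]
  for (start in seq_len(nf)) {
    if (used[start]) next
    # walk forward from this face
    chain <- integer(0)
    cur_face <- start
    cur_key <- k1[start]
    # rewind to an endpoint if the chain is open
    repeat {
      prev <- if (fa[cur_key] == cur_face) fb[cur_key] else fa[cur_key]
      if (prev == 0L || used[prev] || prev == start) break
      cur_face <- prev
      cur_key <- other_key(prev, cur_key)
      if (cur_face == start) break
    }
    first_face <- cur_face
    first_key <- other_key(cur_face, cur_key)
    keyseq <- c(first_key)
    repeat {
      used[cur_face] <- TRUE
      keyseq <- c(keyseq, cur_key)
      nxt <- if (fa[cur_key] == cur_face) fb[cur_key] else fa[cur_key]
      if (nxt == 0L || used[nxt]) break
      cur_face <- nxt
      cur_key <- other_key(nxt, cur_key)
    }
    closed <- length(keyseq) > 2L && keyseq[1] == keyseq[length(keyseq)]
    if (closed) keyseq <- keyseq[-length(keyseq)]
    xy <- cbind(kh[keyseq] - h0, kv[keyseq] - v0)
    if (nrow(xy) < 2L) next
    polys[[length(polys) + 1L]] <- list(xy = xy, closed = closed,
                                        layer = "unknown")
  }
  polys
}

# even-odd containment depth tagging: depth 0 = outer, odd depth = inner
tag_nesting <- function(polys) {
  if (!length(polys)) return(polys)
  closed <- vapply(polys, function(p) p$closed, TRUE)
  for (i in seq_along(polys)) {
    if (!closed[i]) { polys[[i]]$layer <- "unknown"; next }
    depth <- 0L
    p0 <- polys[[i]]$xy[1, ]
    for (j in seq_along(polys)) {
      if (i == j || !closed[j]) next
      if (point_in_polygon(p0[1], p0[2], polys[[j]]$xy)) depth <- depth + 1L
    }
    polys[[i]]$layer <- if (depth %% 2L == 0L) "outer" else "inner"
  }
  polys
}

#' Export section contours as CSV
#' @param contours list of `section_contour` from [cut_surface()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- list()
  for (sc in contours) {
    for (pi in seq_along(sc$polylines)) {
      p <- sc$polylines[[pi]]
      rows[[length(rows) + 1L]] <- data.frame(
        section_index = sc$section_index, polyline_id = pi, layer = p$layer,
        closed = p$closed, x = p$xy[, 1], y = p$xy[, 2])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(section_index = integer(), polyline_id = integer(),
                        layer = character(), closed = logical(),
                        x = numeric(), y = numeric())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render one section as a simple SVG (visual QC)
#' @param contour a `section_contour`.
#' @param path output SVG path.
#' @param landmarks optional `contour_landmarks` to overlay as dots.
#' @return `path` invisibly.
#' @export
write_section_svg <- function(contour, path, landmarks = NULL) {
  polys <- contour$polylines
  allxy <- do.call(rbind, lapply(polys, function(p) p$xy))
  if (is.null(allxy)) allxy <- matrix(0, 1, 2)
  pad <- 1
  xr <- range(allxy[, 1]) + c(-pad, pad)
  yr <- range(allxy[, 2]) + c(-pad, pad)
  sc <- 40
  w <- diff(xr) * sc; h <- diff(yr) * sc
  tx <- function(x) (x - xr[1]) * sc
  ty <- function(y) (yr[2] - y) * sc
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">',
    w, h))
  cols <- c(outer = "#1b6ca8", inner = "#c0392b", unknown = "#777777")
  for (p in polys) {
    pts <- paste(sprintf("%.2f,%.2f", tx(p$xy[, 1]), ty(p$xy[, 2])),
                 collapse = " ")
    lines <- c(lines, sprintf(
      '<%s points="%s" fill="none" stroke="%s" stroke-width="1.5"/>',
      if (p$closed) "polygon" else "polyline", pts, cols[[p$layer]]))
  }
  if (!is.null(landmarks)) {
    for (nm in names(landmarks$points)) {
      pt <- landmarks$points[[nm]]
      if (is.null(pt) || anyNA(pt)) next
      lines <- c(lines, sprintf(
        '<circle cx="%.2f" cy="%.2f" r="3" fill="#e67e22"><title>%s</title></circle>',
        tx(pt[1]), ty(pt[2]), nm))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
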