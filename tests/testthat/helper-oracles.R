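# independent exhaustive oracle: scan ALL vertex pairs as tip candidates
# (both must be on the convex hull), bridge the deepest pocket, scan ALL
# arc vertices for the deepest point
oracle_landmarks <- function(xy, min_depth = 0.2) {
  n <- nrow(xy)
  hull <- unique(grDevices::chull(xy))
  best <- NULL
  for (i in hull) for (j in hull) {
    if (i == j) next
    l <- if (xy[i, 1] <= xy[j, 1]) i else j
    r <- if (l == i) j else i
    # candidate tangent must have every point at or below it
    sd <- odontometry:::signed_line_distance(xy[, 1], xy[, 2], xy[l, ],
                                             xy[r, ])
    if (any(sd > 1e-9)) next
    for (arc in odontometry:::contour_arcs(l, r, n, TRUE)) {
      interior <- setdiff(arc, c(l, r))
      if (!length(interior) || any(interior %in% hull)) next
      depths <- -sd[interior]
      k <- which.max(depths)
      if (depths[k] < min_depth) next
      ymid <- (min(xy[, 2]) + max(xy[, 2])) / 2
      if ((xy[l, 2] + xy[r, 2]) / 2 < ymid) next
      if (is.null(best) || depths[k] > best$depth)
        best <- list(l = l, r = r, depth = depths[k],
                     deep = interior[k])
    }
  }
  best
}

# oracle for open polylines (single arc between endpoint indices)
oracle_landmarks_open <- function(xy, min_depth = 0.2) {
  n <- nrow(xy)
  hull <- unique(grDevices::chull(xy))
  best <- NULL
  for (i in hull) for (j in hull) {
    if (i == j) next
    l <- if (xy[i, 1] <= xy[j, 1]) i else j
    r <- if (l == i) j else i
    sd <- odontometry:::signed_line_distance(xy[, 1], xy[, 2], xy[l, ],
                                             xy[r, ])
    if (any(sd > 1e-9)) next
    interior <- setdiff(min(l, r):max(l, r), c(l, r))
    if (!length(interior) || any(interior %in% hull)) next
    depths <- -sd[interior]
    k <- which.max(depths)
    if (depths[k] < min_depth) next
    ymid <- (min(xy[, 2]) + max(xy[, 2])) / 2
    if ((xy[l, 2] + xy[r, 2]) / 2 < ymid) next
    if (is.null(best) || depths[k] > best$depth)
      best <- list(l = l, r = r, depth = depths[k], deep = interior[k])
  }
  best
}
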