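# Small 2D helpers shared by sectioning, landmarks and measures.

#' Signed area of a closed polygon (shoelace)
#' @param xy two-column matrix of vertices (closing edge implied).
#' @return signed area; positive for counter-clockwise orientation.
#' @export
polygon_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Even-odd point-in-polygon test
#' @param px,py point coordinates (vectorised).
#' @param poly two-column polygon matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    jj <- j[k]
    cross <- ((y[k] > py) != (y[jj] > py)) &
      (px < (x[jj] - x[k]) * (py - y[k]) / (y[jj] - y[k]) + x[k])
    inside <- xor(inside, cross)
  }
  inside
}

polyline_length <- function(xy, closed = FALSE) {
  if (closed) xy <- rbind(xy, xy[1, ])
  sum(sqrt(rowSums(diff(xy)^2)))
}

# perpendicular distance of points from the line through a, b (2D);
# positive on the left of a->b
signed_line_distance <- function(px, py, a, b) {
  d <- b - a
  len <- sqrt(sum(d^2))
  ((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])) / len
}

# arc-length resampling of a polyline (closed or open) at a given step
resample_polyline <- function(xy, step, closed = FALSE) {
  if (closed) xy <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  n <- max(8L, ceiling(total / step))
  targets <- seq(0, total, length.out = n + 1L)
  if (closed) targets <- targets[-length(targets)]
  ix <- findInterval(targets, s, rightmost.closed = TRUE)
  ix <- pmin(ix, nrow(xy) - 1L)
  frac <- (targets - s[ix]) / pmax(seg[ix], 1e-300)
  xy[ix, , drop = FALSE] +
    (xy[ix + 1L, , drop = FALSE] - xy[ix, , drop = FALSE]) * frac
}
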