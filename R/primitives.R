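# Small analytic test meshes: icosphere, planar grid, saddle patch.

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; the standard analytic
#' fixture for curvature validation (K = 1/r^2 everywhere).
#'
#' @param subdivisions number of 4-to-1 subdivision passes (0 = icosahedron).
#' @param radius sphere radius in mm.
#' @param center sphere centre.
#' @return a [tooth_surface()].
#' @export
icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    # midpoint cache keyed on the undirected vertex pair
    key <- function(a, b) (nv + 1) * pmin(a, b) + pmax(a, b)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    k <- key(e[, 1], e[, 2])
    uk <- !duplicated(k)
    mids <- (v[e[uk, 1], , drop = FALSE] + v[e[uk, 2], , drop = FALSE]) / 2
    mid_id <- nv + seq_len(sum(uk))
    lookup <- mid_id[match(k, k[uk])]
    m12 <- lookup[seq_len(nrow(f))]
    m23 <- lookup[nrow(f) + seq_len(nrow(f))]
    m31 <- lookup[2 * nrow(f) + seq_len(nrow(f))]
    v <- rbind(v, mids)
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  orient_faces(tooth_surface(v, f, validate = FALSE))
}

#' Planar grid patch
#' @param n grid points per side.
#' @param width side length in mm (centred on the origin, z = 0).
#' @return a [tooth_surface()].
#' @export
planar_grid <- function(n = 15, width = 5) {
  g <- seq(-width / 2, width / 2, length.out = n)
  v <- as.matrix(expand.grid(x = g, y = g))
  v <- cbind(v, 0)
  idx <- matrix(seq_len(n * n), n, n)
  f <- NULL
  a <- as.vector(idx[-n, -n]); b <- as.vector(idx[-1, -n])
  c_ <- as.vector(idx[-1, -1]); d <- as.vector(idx[-n, -1])
  f <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  tooth_surface(v, f, validate = FALSE)
}

#' Saddle patch z = x^2 - y^2
#' @param n grid points per side.
#' @param width side length in mm.
#' @return a [tooth_surface()].
#' @export
saddle_patch <- function(n = 15, width = 2) {
  s <- planar_grid(n, width)
  v <- s$vertices
  v[, 3] <- v[, 1]^2 - v[, 2]^2
  tooth_surface(v, s$faces, validate = FALSE)
}
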