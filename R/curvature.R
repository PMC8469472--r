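# Per-vertex principal curvature estimation and the high-curvature mask used
# for occlusal border detection.

#' Estimate per-vertex principal and Gaussian curvature
#'
#' Fits a local quadric patch over all vertices within a Euclidean ball of
#' the given radius around each vertex (expressed in the tangent frame of the
#' angle-weighted vertex normal) and reads the principal curvatures kappa1 >=
#' kappa2 off the patch's shape operator. Convex-outward regions (cusp tips)
#' have positive curvature; Gaussian curvature is K = kappa1 * kappa2.
#'
#' The radius is the method's main tunable: it must exceed the mean edge
#' length (default 5x) so that second-order fits are overdetermined and
#' stable against mesh noise.
#'
#' @param surface a [tooth_surface()].
#' @param radius neighbourhood radius in mm; default 5x mean edge length.
#' @return an object of class `curvature_field` with per-vertex `kappa1`,
#'   `kappa2` (1/mm), `gaussian` (1/mm^2), unit `normal`s, `n_neighbors` and
#'   the `neighborhood_radius` used.
#' @export
estimate_curvature <- function(surface, radius = NULL) {
  validate_surface(surface)
  mel <- mean_edge_length(surface)
  if (is.null(radius)) radius <- 5 * mel
  if (radius <= 0) stop("radius must be positive")
  if (radius <= mel)
    stop(sprintf("radius (%.4g mm) must exceed the mean edge length (%.4g mm)",
                 radius, mel))
  nrm <- if (!is.null(surface$normals)) surface$normals
         else vertex_normals(surface)
  res <- .curvature_quadric(surface$vertices, nrm, radius)
  if (any(res$n_neighbors < 6L)) {
    bad <- which(res$n_neighbors < 6L)[1]
    stop(sprintf(
      "under-sampled neighbourhood at vertex %d (%d neighbours in %.4g mm); raise the radius or refine the mesh",
      bad, res$n_neighbors[bad], radius))
  }
  structure(list(kappa1 = res$kappa1, kappa2 = res$kappa2,
                 gaussian = res$kappa1 * res$kappa2, normal = res$normal,
                 n_neighbors = res$n_neighbors,
                 neighborhood_radius = radius),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf(
    "curvature_field: %d vertices, radius %.3g mm, K in [%.3g, %.3g] 1/mm^2\n",
    length(x$kappa1), x$neighborhood_radius, min(x$gaussian), max(x$gaussian)))
  invisible(x)
}

#' High-Gaussian-curvature vertex mask
#'
#' Returns the vertices whose Gaussian curvature lies in the top
#' `100 - percentile` percent of K, restricted to ridge-like convex vertices
#' (kappa1 > 0). Ties are broken by vertex index so the selection is
#' deterministic; `percentile = 100` returns the argmax vertex (or tied set).
#'
#' @param field a `curvature_field`.
#' @param percentile value in (0, 100].
#' @return integer vector of vertex indices (may be empty).
#' @export
curvature_percentile_mask <- function(field, percentile) {
  stopifnot(inherits(field, "curvature_field"))
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0,100]")
  conv <- which(field$kappa1 > 0 & is.finite(field$gaussian))
  if (!length(conv)) return(integer())
  K <- field$gaussian[conv]
  if (percentile == 100) return(conv[K == max(K)])
  m <- max(1L, round(length(conv) * (100 - percentile) / 100))
  conv[order(-K, conv)][seq_len(m)]
}

#' Export per-vertex curvature as CSV
#' @param field a `curvature_field`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curvature_csv <- function(field, path) {
  df <- data.frame(index = seq_along(field$kappa1), kappa1 = field$kappa1,
                   kappa2 = field$kappa2, gaussian = field$gaussian)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
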