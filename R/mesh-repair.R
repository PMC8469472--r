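# Repair utilities: patch small perforations, smooth, decimate.
# Hole filling is perimeter-capped so large anatomical openings (the cervical
# boundary of an enamel cap) are never closed automatically.

#' Repair a triangulated tooth surface
#'
#' @param surface a [tooth_surface()].
#' @param fill_holes triangulate boundary loops whose perimeter is below
#'   `hole_perimeter_max` (fan around the loop centroid).
#' @param smooth_iterations Taubin smoothing passes (shrink-compensated
#'   Laplacian; 0 = no smoothing). Boundary vertices are kept fixed.
#' @param target_face_count optional decimation target (quadric edge
#'   collapse, midpoint placement).
#' @param hole_perimeter_max mm; holes with longer perimeter are left open
#'   (default 2 mm — the cervical opening is far larger and must survive).
#' @param hausdorff_tol mm; edge collapses whose quadric error exceeds this
#'   are refused (default 0.01 mm), bounding geometric drift.
#' @return repaired `tooth_surface` satisfying the structural invariants
#'   (edge-manifold, no degenerate faces).
#' @export
repair_surface <- function(surface, fill_holes = TRUE, smooth_iterations = 0L,
                           target_face_count = NULL,
                           hole_perimeter_max = 2, hausdorff_tol = 0.01) {
  s <- merge_duplicate_vertices(surface)
  s <- drop_degenerate_faces(s)
  cnt <- edge_face_count(s)
  if (any(cnt > 2L)) {
    ek <- edge_keys(s$faces, nrow(s$vertices))
    bad <- unique(ek$key)[table(ek$key) > 2L]
    sel <- match(bad, ek$key)
    stop(sprintf(
      "non-manifold surface cannot be repaired; offending edges: %s",
      paste(sprintf("(%d,%d)", ek$lo[sel], ek$hi[sel]), collapse = " ")))
  }
  if (isTRUE(fill_holes)) s <- fill_small_holes(s, hole_perimeter_max)
  if (smooth_iterations > 0L) s <- smooth_surface(s, smooth_iterations)
  if (!is.null(target_face_count) && target_face_count < nrow(s$faces))
    s <- decimate_surface(s, target_face_count, hausdorff_tol)
  s <- orient_faces(s)
  validate_surface(s, strict = TRUE)
  s
}

# directed boundary edges (a -> b as they appear in their single face)
directed_boundary_edges <- function(surface) {
  f <- surface$faces; nv <- nrow(surface$vertices)
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  key <- (as.double(nv) + 1) * from + to
  rkey <- (as.double(nv) + 1) * to + from
  b <- !(rkey %in% key)
  cbind(from[b], to[b])
}

fill_small_holes <- function(surface, perimeter_max) {
  repeat {
    de <- directed_boundary_edges(surface)
    if (nrow(de) == 0L) return(surface)
    nxt <- de[match(seq_len(nrow(surface$vertices)), de[, 1]), 2]
    # walk loops following the directed boundary
    seen <- rep(FALSE, nrow(surface$vertices))
    filled_any <- FALSE
    v <- surface$vertices
    newv <- list(); newf <- list()
    for (r in seq_len(nrow(de))) {
      a <- de[r, 1]
      if (seen[a]) next
      loop <- a
      cur <- a
      ok <- TRUE
      repeat {
        seen[cur] <- TRUE
        cur <- nxt[cur]
        if (is.na(cur)) { ok <- FALSE; break }
        if (cur == a) break
        if (seen[cur]) { ok <- FALSE; break }
        loop <- c(loop, cur)
      }
      if (!ok || length(loop) < 3L) next
      per <- sum(sqrt(rowSums((v[loop, , drop = FALSE] -
                               v[c(loop[-1], loop[1]), , drop = FALSE])^2)))
      if (per > perimeter_max) next
      ctr <- colMeans(v[loop, , drop = FALSE])
      ci <- nrow(v) + length(newv) + 1L
      newv[[length(newv) + 1L]] <- ctr
      # boundary edge a->b belongs to the hole loop in walk order; the patch
      # triangle must traverse it b->a to oppose the existing face
      tris <- cbind(c(loop[-1], loop[1]), loop, ci)
      newf[[length(newf) + 1L]] <- tris
      filled_any <- TRUE
    }
    if (!filled_any) return(surface)
    v2 <- rbind(v, do.call(rbind, newv))
    f2 <- rbind(surface$faces, do.call(rbind, newf))
    surface <- tooth_surface(v2, f2, validate = FALSE)
  }
}

#' Taubin-smooth a surface (shrink-compensated Laplacian)
#'
#' @param surface a [tooth_surface()].
#' @param iterations number of lambda/mu pass pairs.
#' @param lambda,mu Taubin factors; defaults 0.5 / -0.53.
#' @return smoothed surface (same topology).
#' @export
smooth_surface <- function(surface, iterations, lambda = 0.5, mu = -0.53) {
  adj <- vertex_adjacency(surface)
  nv <- nrow(surface$vertices)
  bnd <- unique(as.vector(boundary_edges(surface)))
  free <- setdiff(seq_len(nv), bnd)
  v <- surface$vertices
  # flatten adjacency for vectorised umbrella operator
  deg <- lengths(adj)
  src <- rep(seq_len(nv), deg)
  dst <- unlist(adj, use.names = FALSE)
  umbrella <- function(v) {
    s <- rowsum(v[dst, , drop = FALSE], src)
    s / deg - v
  }
  for (it in seq_len(iterations)) {
    d <- umbrella(v); v[free, ] <- v[free, ] + lambda * d[free, ]
    d <- umbrella(v); v[free, ] <- v[free, ] + mu * d[free, ]
  }
  tooth_surface(v, surface$faces, validate = FALSE)
}

# quadric edge-collapse decimation with midpoint placement
decimate_surface <- function(surface, target_face_count, hausdorff_tol = 0.01) {
  v <- surface$vertices
  f <- surface$faces
  # per-vertex quadrics: sum over incident faces of outer(plane, plane)
  fn <- face_normals(surface)
  d <- -rowSums(fn * v[f[, 1], , drop = FALSE])
  planes <- cbind(fn, d)
  Q <- array(0, c(4, 4, nrow(v)))
  for (k in 1:3) {
    for (i in 1:4) for (j in 1:4) {
      acc <- rowsum(planes[, i] * planes[, j], f[, k])
      ids <- as.integer(rownames(acc))
      Q[i, j, ids] <- Q[i, j, ids] + acc[, 1]
    }
  }
  bnd <- unique(as.vector(boundary_edges(surface)))
  is_bnd <- rep(FALSE, nrow(v)); is_bnd[bnd] <- TRUE
  alive_v <- rep(TRUE, nrow(v))
  repeat {
    if (nrow(f) <= target_face_count) break
    nv <- nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
    keep <- !duplicated((nv + 1) * as.double(lo) + hi)
    lo <- lo[keep]; hi <- hi[keep]
    # refuse boundary edges: collapsing them distorts open margins
    okb <- !(is_bnd[lo] | is_bnd[hi])
    lo <- lo[okb]; hi <- hi[okb]
    if (!length(lo)) break
    mid <- (v[lo, , drop = FALSE] + v[hi, , drop = FALSE]) / 2
    midh <- cbind(mid, 1)
    cost <- numeric(length(lo))
    for (i in seq_along(lo)) {
      Qe <- Q[, , lo[i]] + Q[, , hi[i]]
      cost[i] <- drop(midh[i, ] %*% Qe %*% midh[i, ])
    }
    ord <- order(cost)
    adj <- vertex_adjacency(tooth_surface(v, f, validate = FALSE))
    touched <- rep(FALSE, nv)
    collapsed <- 0L
    need <- ceiling((nrow(f) - target_face_count) / 2)
    map <- seq_len(nv)
    for (i in ord) {
      a <- lo[i]; b <- hi[i]
      if (touched[a] || touched[b]) next
      if (cost[i] > hausdorff_tol^2) break
      # link condition (simplified): shared one-ring must be exactly 2 verts
      if (length(intersect(adj[[a]], adj[[b]])) != 2L) next
      v[a, ] <- mid[i, ]
      Q[, , a] <- Q[, , a] + Q[, , b]
      map[b] <- a
      alive_v[b] <- FALSE
      touched[c(a, b, adj[[a]], adj[[b]])] <- TRUE
      collapsed <- collapsed + 1L
      if (collapsed >= need) break
    }
    if (collapsed == 0L) {
      warning("decimation stopped before target: tolerance exhausted")
      break
    }
    f <- matrix(map[f], ncol = 3)
    f <- f[f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3], ,
           drop = FALSE]
  }
  s <- drop_unreferenced(tooth_surface(v, f, validate = FALSE))
  drop_degenerate_faces(s)
}
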