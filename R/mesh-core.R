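#' @useDynLib odontometry, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd quantile setNames
#' @importFrom utils head tail modifyList write.csv read.csv
NULL

DEGENERATE_AREA_TOL <- 1e-12   # mm^2, faces thinner than this are dropped
VERTEX_MERGE_TOL <- 1e-9       # mm, duplicate-vertex merge distance

#' Triangulated tooth surface
#'
#' Canonical in-memory representation of a tooth crown (or enamel-cap)
#' reconstruction: a triangulated irregular network in millimetres.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param normals optional numeric matrix of per-vertex unit normals.
#' @param validate check invariants (in-range indices, non-degenerate faces).
#'
#' @return An object of class `tooth_surface` with elements `vertices`,
#'   `faces` and optionally `normals`.
#' @export
tooth_surface <- function(vertices, faces, normals = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  s <- structure(list(vertices = vertices, faces = faces, normals = normals),
                 class = "tooth_surface")
  if (validate) validate_surface(s)
  s
}

#' Validate a tooth surface against its structural invariants
#'
#' @param surface a `tooth_surface`.
#' @param strict also require edge-manifoldness (every edge borders at most
#'   two faces); used after repair.
#' @return the surface, invisibly; errors describe the first violation.
#' @export
validate_surface <- function(surface, strict = FALSE) {
  v <- surface$vertices
  f <- surface$faces
  if (nrow(v) < 4L) stop("surface has fewer than 4 vertices")
  if (nrow(f) < 4L) stop("surface has fewer than 4 faces")
  if (any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (any(f < 1L) || any(f > nrow(v))) stop("face index out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("face references a repeated vertex")
  a <- face_areas(surface)
  if (any(a < DEGENERATE_AREA_TOL))
    stop(sprintf("%d degenerate face(s) with area below %g mm^2",
                 sum(a < DEGENERATE_AREA_TOL), DEGENERATE_AREA_TOL))
  if (strict) {
    cnt <- edge_face_count(surface)
    if (any(cnt > 2L))
      stop(sprintf("surface is not edge-manifold: %d edge(s) border >2 faces",
                   sum(cnt > 2L)))
  }
  invisible(surface)
}

#' @export
print.tooth_surface <- function(x, ...) {
  nb <- tryCatch(sum(edge_face_count(x) == 1L), error = function(e) NA_integer_)
  cat(sprintf("tooth_surface: %d vertices, %d faces, %s boundary edges\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.na(nb)) "?" else nb))
  invisible(x)
}

# --- basic mesh queries -----------------------------------------------------

face_cross <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Per-face areas in mm^2
#' @param surface a `tooth_surface`
#' @return numeric vector of length `nrow(surface$faces)`
#' @export
face_areas <- function(surface) {
  cr <- face_cross(surface)
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(surface) {
  cr <- face_cross(surface)
  n <- sqrt(rowSums(cr^2))
  n[n == 0] <- 1
  cr / n
}

#' Angle-weighted per-vertex outward normals
#' @param surface a `tooth_surface`
#' @return unit-normal matrix, one row per vertex
#' @export
vertex_normals <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  fn <- face_normals(surface)
  ang <- matrix(0, nrow(f), 3)
  for (k in 1:3) {
    i0 <- f[, k]; i1 <- f[, (k %% 3) + 1L]; i2 <- f[, ((k + 1) %% 3) + 1L]
    a <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
    b <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
    ca <- rowSums(a * b) / pmax(sqrt(rowSums(a^2) * rowSums(b^2)), 1e-300)
    ang[, k] <- acos(pmin(1, pmax(-1, ca)))
  }
  nrm <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    w <- ang[, k]
    for (d in 1:3)
      nrm[, d] <- nrm[, d] + unname(tapply2(fn[, d] * w, f[, k], nrow(v)))
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

# rowsum-backed accumulation over vertex ids, padded to n entries
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# canonical undirected edge keys: n*min+max with n = vertex count + 1
edge_keys <- function(faces, nv) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  list(key = (as.double(nv) + 1) * lo + hi, lo = lo, hi = hi)
}

edge_face_count <- function(surface) {
  ek <- edge_keys(surface$faces, nrow(surface$vertices))
  tab <- table(ek$key)
  as.integer(tab)
}

#' Boundary edges (edges bordering exactly one face)
#' @param surface a `tooth_surface`
#' @return two-column integer matrix of vertex index pairs (possibly 0 rows)
#' @export
boundary_edges <- function(surface) {
  ek <- edge_keys(surface$faces, nrow(surface$vertices))
  tab <- table(ek$key)
  bkey <- as.double(names(tab)[tab == 1L])
  sel <- match(bkey, ek$key)
  cbind(ek$lo[sel], ek$hi[sel])
}

#' Ordered boundary loops of an open surface
#' @param surface a `tooth_surface`
#' @return list of integer vectors, each an ordered closed loop of vertex
#'   indices (first vertex not repeated at the end); empty list if watertight
#' @export
boundary_loops <- function(surface) {
  be <- boundary_edges(surface)
  if (nrow(be) == 0L) return(list())
  # adjacency among boundary vertices
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  loops <- list()
  for (r in seq_len(nrow(be))) {
    a <- be[r, 1]; b <- be[r, 2]
    if (!is.null(used[[ekey(a, b)]])) next
    loop <- c(a, b)
    used[[ekey(a, b)]] <- TRUE
    repeat {
      cur <- loop[length(loop)]
      nxts <- adj[[as.character(cur)]]
      nxt <- NA_integer_
      for (cand in nxts) {
        if (is.null(used[[ekey(cur, cand)]])) { nxt <- cand; break }
      }
      if (is.na(nxt)) break
      used[[ekey(cur, nxt)]] <- TRUE
      if (nxt == loop[1]) break
      loop <- c(loop, nxt)
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Is the surface watertight (no boundary edges)?
#' @param surface a `tooth_surface`
#' @return logical
#' @export
is_watertight <- function(surface) {
  nrow(boundary_edges(surface)) == 0L
}

# one-ring vertex adjacency as a list of integer vectors
vertex_adjacency <- function(surface) {
  f <- surface$faces; nv <- nrow(surface$vertices)
  from <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  to   <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  adj <- vector("list", nv)
  sp <- split(to, from)
  adj[as.integer(names(sp))] <- lapply(sp, function(x) unique.default(x))
  adj
}

mean_edge_length <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  keep <- !duplicated((as.double(nrow(v)) + 1) * lo + hi)
  d <- v[lo[keep], , drop = FALSE] - v[hi[keep], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

# --- cleanup helpers --------------------------------------------------------

# merge vertices closer than tol (grid snap), drop degenerate/duplicate faces
merge_duplicate_vertices <- function(surface, tol = VERTEX_MERGE_TOL) {
  v <- surface$vertices; f <- surface$faces
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  v2 <- v[first, , drop = FALSE]
  f2 <- matrix(map[f], ncol = 3)
  f2 <- f2[f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3], ,
           drop = FALSE]
  # drop duplicate faces irrespective of rotation
  fk <- apply(f2, 1, function(r) paste(sort(r), collapse = "_"))
  f2 <- f2[!duplicated(fk), , drop = FALSE]
  drop_unreferenced(tooth_surface(v2, f2, validate = FALSE))
}

drop_unreferenced <- function(surface) {
  used <- sort(unique(as.vector(surface$faces)))
  map <- integer(nrow(surface$vertices))
  map[used] <- seq_along(used)
  tooth_surface(surface$vertices[used, , drop = FALSE],
                matrix(map[surface$faces], ncol = 3), validate = FALSE)
}

drop_degenerate_faces <- function(surface, tol = DEGENERATE_AREA_TOL) {
  a <- face_areas(surface)
  tooth_surface(surface$vertices, surface$faces[a >= tol, , drop = FALSE],
                validate = FALSE)
}

# make winding consistent across each connected face component; orient
# closed components outward (positive signed volume)
orient_faces <- function(surface) {
  f <- surface$faces
  nf <- nrow(f)
  if (nf == 0L) return(surface)
  nv <- nrow(surface$vertices)
  ek <- edge_keys(f, nv)
  fid <- rep(seq_len(nf), 3L)
  ord <- order(ek$key)
  key_s <- ek$key[ord]; fid_s <- fid[ord]
  # pairs of faces sharing an edge
  same <- which(key_s[-1] == key_s[-length(key_s)])
  pa <- fid_s[same]; pb <- fid_s[same + 1L]
  adjf <- split(c(pb, pa), c(pa, pb))
  # directed edge sets per face for orientation agreement checks
  flip <- rep(NA, nf)
  dir_edges <- function(tri, flipped) {
    t <- if (flipped) tri[c(1, 3, 2)] else tri
    rbind(t[c(1, 2)], t[c(2, 3)], t[c(3, 1)])
  }
  queue <- integer(nf)
  for (seed in seq_len(nf)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    queue[1] <- seed; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      cur <- queue[qh]; qh <- qh + 1L
      de_cur <- dir_edges(f[cur, ], flip[cur])
      for (nb in adjf[[as.character(cur)]]) {
        if (!is.na(flip[nb])) next
        # shared edge must appear in opposite directions when windings agree
        de_nb <- dir_edges(f[nb, ], FALSE)
        agree <- FALSE
        for (i in 1:3) for (j in 1:3) {
          if (de_cur[i, 1] == de_nb[j, 2] && de_cur[i, 2] == de_nb[j, 1])
            agree <- TRUE
          }
        flip[nb] <- !agree
        qt <- qt + 1L; queue[qt] <- nb
      }
    }
  }
  f2 <- f
  f2[flip, ] <- f[flip, c(1, 3, 2), drop = FALSE]
  s2 <- tooth_surface(surface$vertices, f2, validate = FALSE)
  if (is_watertight(s2) && signed_volume(s2) < 0)
    s2$faces <- s2$faces[, c(1, 3, 2), drop = FALSE]
  s2
}

signed_volume <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}
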