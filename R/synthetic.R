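# Parametric two-cusp crown generator with analytic ground truth.
#
# The crown top is a smooth height field over an elliptical base:
#   z(x,y) = H * (1 - rho^6)^(1/2)                      (bulging dome)
#          + sum_i h_i * exp(-d_i^2 / w^2) * E(rho)     (two cusp bumps)
#          - D * exp(-q^4) * E(rho)                     (central fossa)
# where rho^2 = (x/a)^2 + (y/b)^2, q is an anisotropic fossa coordinate
# elongated mesio-distally, and E(rho) = 1 - rho^8 tapers the perturbations
# so the cervical margin stays exactly in the z = 0 plane. The dome meets
# the margin with a vertical tangent, so the maximal vestibulo-oral width
# (2b) sits at the cervical margin, as on real molar crowns.
#
# The inner ("dentine") surface is the outer one offset inward along the
# analytic surface normal by the enamel thickness; outer and inner margins
# are stitched into a watertight enamel-cap shell.

#' Specification for a synthetic two-cusp tooth crown
#'
#' Defaults mimic the scale of an upper second molar crown: vestibulo-oral
#' width 14 mm, occlusal relief exactly 3 mm (calibrated), enamel thickness
#' 0.75 mm (kept below the outer surface's minimal curvature radius so the
#' inward offset cannot self-intersect). Lengths in mm.
#'
#' @param cusp_height_vestibular,cusp_height_oral target z of the two cusp
#'   tips above the cervical plane.
#' @param cusp_separation distance between the two cusp bump centres (the
#'   contour cusp tips land slightly closer together because the dome flank
#'   pulls the height maxima inward).
#' @param crown_vo_halfwidth,crown_md_halflength semi-axes of the cervical
#'   ellipse (vestibulo-oral = y, mesio-distal = x).
#' @param fossa_depth target vertical relief: mean cusp tip height minus the
#'   deepest fossa point.
#' @param crest_ring_radius vestibulo-oral radius of the fossa rim (the
#'   high-Gaussian-curvature crest encircling the occlusal surface).
#' @param enamel_thickness uniform inward offset of the inner surface.
#' @param resolution target mesh edge length.
#' @param jitter_sd standard deviation of seeded vertex jitter along the
#'   normal (default 0 = exact surface).
#' @param seed RNG seed used only when `jitter_sd > 0`.
#' @return an object of class `bicuspid_spec`.
#' @export
bicuspid_spec <- function(cusp_height_vestibular = 6.7,
                          cusp_height_oral = 6.5,
                          cusp_separation = 11.2,
                          crown_vo_halfwidth = 7.0,
                          crown_md_halflength = 7.5,
                          fossa_depth = 3.0,
                          crest_ring_radius = 2.5,
                          enamel_thickness = 0.75,
                          resolution = 0.25,
                          jitter_sd = 0,
                          seed = 1L) {
  spec <- list(cusp_height_vestibular = cusp_height_vestibular,
               cusp_height_oral = cusp_height_oral,
               cusp_separation = cusp_separation,
               crown_vo_halfwidth = crown_vo_halfwidth,
               crown_md_halflength = crown_md_halflength,
               fossa_depth = fossa_depth,
               crest_ring_radius = crest_ring_radius,
               enamel_thickness = enamel_thickness,
               resolution = resolution,
               jitter_sd = jitter_sd,
               seed = as.integer(seed),
               # internal shape constants
               fossa_elongation = 2.2,
               cusp_bump_width = 2.6,
               ridge_height = 0.3,
               ridge_width = 0.45,
               dome_height = 0.88 * (cusp_height_vestibular +
                                     cusp_height_oral) / 2)
  lens <- c(cusp_height_vestibular, cusp_height_oral, cusp_separation,
            crown_vo_halfwidth, crown_md_halflength, fossa_depth,
            crest_ring_radius, enamel_thickness, resolution)
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (enamel_thickness >= crown_vo_halfwidth)
    stop("enamel thickness must be smaller than the crown half-width")
  if (resolution >= crest_ring_radius / 5)
    stop("resolution must be below crest_ring_radius / 5")
  structure(spec, class = "bicuspid_spec")
}

# height-field closure for a spec with calibrated amplitudes h_v, h_o, D
crown_height_fun <- function(spec, h_v, h_o, D) {
  a <- spec$crown_md_halflength; b <- spec$crown_vo_halfwidth
  H <- spec$dome_height
  yc <- spec$cusp_separation / 2
  w2 <- spec$cusp_bump_width^2
  fx <- spec$crest_ring_radius * spec$fossa_elongation
  fy <- spec$crest_ring_radius
  function(x, y) {
    r2 <- (x / a)^2 + (y / b)^2
    r2c <- pmin(r2, 1)
    dome <- H * sqrt(pmax(0, 1 - r2c^3))
    env <- 1 - r2c^4
    # blunt (super-Gaussian) cusps: low curvature at the apex keeps the
    # inward enamel offset valid at realistic thicknesses
    bv <- h_v * exp(-((x^2 + (y - yc)^2) / w2)^2)
    bo <- h_o * exp(-((x^2 + (y + yc)^2) / w2)^2)
    q <- sqrt((x / fx)^2 + (y / fy)^2)
    # marginal ridge: a convex crest encircling the fossa at q = 1, i.e. at
    # vestibulo-oral radius r0 — this is the high-K crest ring the occlusal
    # border detector is expected to trace
    ridge <- spec$ridge_height * exp(-((q - 1) / spec$ridge_width)^2)
    dome + (bv + bo - D * exp(-q^4) + ridge) * env
  }
}

# maximize f over 2D with optim from a given start, optionally box-bounded
max2d <- function(f, start, lower = NULL, upper = NULL) {
  if (is.null(lower)) {
    o <- stats::optim(start, function(p) -f(p[1], p[2]),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  } else {
    o <- stats::optim(start, function(p) -f(p[1], p[2]), method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 10, maxit = 500))
  }
  list(xy = o$par, value = -o$value)
}

# calibrate bump/fossa amplitudes so analytic tip heights and relief match
calibrate_amplitudes <- function(spec) {
  yc <- spec$cusp_separation / 2
  h_v <- spec$cusp_height_vestibular; h_o <- spec$cusp_height_oral
  D <- spec$fossa_depth
  tipv <- c(0, yc); tipo <- c(0, -yc); ctr <- c(0, 0)
  fx <- spec$crest_ring_radius * spec$fossa_elongation
  fy <- spec$crest_ring_radius
  for (it in 1:40) {
    z <- crown_height_fun(spec, h_v, h_o, D)
    # searches are box-bounded to the relevant feature so the optimiser
    # cannot wander to the cervical margin (where z -> 0 globally)
    mv <- max2d(z, tipv, lower = c(-2, yc - 2.5), upper = c(2, yc + 2.5))
    mo <- max2d(z, tipo, lower = c(-2, -yc - 2.5), upper = c(2, -yc + 2.5))
    mf <- max2d(function(x, y) -z(x, y), ctr,
                lower = c(-fx, -fy), upper = c(fx, fy))
    zf <- -mf$value
    tipv <- mv$xy; tipo <- mo$xy; ctr <- mf$xy
    err_v <- spec$cusp_height_vestibular - mv$value
    err_o <- spec$cusp_height_oral - mo$value
    err_d <- spec$fossa_depth - ((mv$value + mo$value) / 2 - zf)
    h_v <- h_v + err_v; h_o <- h_o + err_o; D <- D + err_d
    if (max(abs(c(err_v, err_o, err_d))) < 1e-10) break
  }
  list(h_v = h_v, h_o = h_o, D = D,
       tip_v = c(tipv, mv$value), tip_o = c(tipo, mo$value),
       fossa = c(ctr, zf))
}

# analytic outward normal of the height field surface (numeric gradient);
# exactly at the margin the tangent is vertical and the normal horizontal
height_field_normal <- function(z, x, y, a, b, eps = 1e-6) {
  r2 <- (x / a)^2 + (y / b)^2
  n <- matrix(0, length(x), 3)
  margin <- r2 > 1 - 1e-9
  if (any(!margin)) {
    xi <- x[!margin]; yi <- y[!margin]
    zx <- (z(xi + eps, yi) - z(xi - eps, yi)) / (2 * eps)
    zy <- (z(xi, yi + eps) - z(xi, yi - eps)) / (2 * eps)
    W <- sqrt(1 + zx^2 + zy^2)
    n[!margin, ] <- cbind(-zx / W, -zy / W, 1 / W)
  }
  if (any(margin)) {
    gx <- x[margin] / a^2; gy <- y[margin] / b^2
    g <- sqrt(gx^2 + gy^2)
    n[margin, ] <- cbind(gx / g, gy / g, 0)
  }
  n
}

# ring radii (as tau in [0, pi/2]) spaced by arc length of the steepest
# azimuthal profile so triangles stay near-isotropic down the flank
ring_taus <- function(spec, z, step) {
  a <- spec$crown_md_halflength; b <- spec$crown_vo_halfwidth
  tg <- seq(0, pi / 2, length.out = 2000)
  rho <- sin(tg)
  # worst-case arc speed over four azimuths
  sp <- rep(0, length(tg))
  for (phi in c(0, pi / 4, pi / 2, 3 * pi / 4)) {
    x <- a * rho * cos(phi); y <- b * rho * sin(phi)
    zz <- z(x, y)
    seg <- sqrt(diff(x)^2 + diff(y)^2 + diff(zz)^2)
    sp <- pmax(sp, c(seg, seg[length(seg)]))
  }
  s <- cumsum(sp)
  total <- s[length(s)]
  nring <- max(8L, ceiling(total / step))
  targets <- seq(0, total, length.out = nring + 1L)
  tau <- stats::approx(s, tg, xout = targets, rule = 2)$y
  tau[-1]  # drop the pole (added separately)
}

# stitch two rings of vertex indices (ordered by angle in [0, 2pi)) into a
# triangulated annulus; rings may have different counts
stitch_rings <- function(inner_ids, inner_ang, outer_ids, outer_ang) {
  n1 <- length(inner_ids); n2 <- length(outer_ids)
  tris <- matrix(0L, 0, 3)
  res <- vector("list", n1 + n2)
  k <- 0L
  i <- 1L; j <- 1L
  # advance around both rings once, always connecting to the closer angle
  ang1 <- c(inner_ang, inner_ang[1] + 2 * pi)
  ang2 <- c(outer_ang, outer_ang[1] + 2 * pi)
  while (i <= n1 || j <= n2) {
    adv1 <- if (i <= n1 && j <= n2) ang1[i + 1] <= ang2[j + 1] else i <= n1
    if (adv1) {
      k <- k + 1L
      res[[k]] <- c(inner_ids[i], outer_ids[((j - 1L) %% n2) + 1L],
                    inner_ids[(i %% n1) + 1L])
      i <- i + 1L
    } else {
      k <- k + 1L
      res[[k]] <- c(outer_ids[j], outer_ids[(j %% n2) + 1L],
                    inner_ids[((i - 1L) %% n1) + 1L])
      j <- j + 1L
    }
  }
  do.call(rbind, res[seq_len(k)])
}

# triangulated flat disk bounded by an existing ring of vertices: interior
# rings are scaled copies of the boundary, stitched ring to ring, with a fan
# at the centre. ring_ids index `verts0` rows; returns extra vertices (to be
# appended after verts0) and faces in the combined indexing.
mesh_flat_cap <- function(verts0, ring_ids, step) {
  ring <- verts0[ring_ids, , drop = FALSE]
  ctr <- colMeans(ring)
  ang <- atan2(ring[, 2] - ctr[2], ring[, 1] - ctr[1]) %% (2 * pi)
  ord <- order(ang)  # stitching requires monotone angles
  ring_ids <- ring_ids[ord]
  ring <- ring[ord, , drop = FALSE]
  ang <- ang[ord]
  rad <- mean(sqrt(rowSums(sweep(ring[, 1:2, drop = FALSE], 2,
                                 ctr[1:2])^2)))
  nring <- max(1L, round(rad / step))
  nv0 <- nrow(verts0)
  newv <- list(); faces <- list()
  prev_ids <- ring_ids; prev_ang <- ang
  nn <- length(ring_ids)
  for (k in seq_len(nring - 1L)) {
    s <- (nring - k) / nring
    nk <- max(8L, ceiling(nn * s))
    sel <- round(seq(1L, nn, length.out = nk + 1L))[-(nk + 1L)]
    pts <- sweep(sweep(ring[sel, , drop = FALSE], 2, ctr), 1, s, "*")
    pts <- sweep(pts, 2, ctr, "+")
    ids <- nv0 + (if (length(newv)) sum(vapply(newv, nrow, 0L)) else 0L) +
      seq_len(nk)
    newv[[k]] <- pts
    faces[[length(faces) + 1L]] <- stitch_rings(ids, ang[sel],
                                                prev_ids, prev_ang)
    prev_ids <- ids; prev_ang <- ang[sel]
  }
  ci <- nv0 + (if (length(newv)) sum(vapply(newv, nrow, 0L)) else 0L) + 1L
  newv[[length(newv) + 1L]] <- matrix(ctr, 1, 3)
  np <- length(prev_ids)
  faces[[length(faces) + 1L]] <- cbind(ci, prev_ids,
                                       prev_ids[c(2:np, 1)])
  list(vertices = do.call(rbind, newv), faces = do.call(rbind, faces))
}

# triangulated height-field disk: returns vertices, faces, margin ring ids
mesh_crown_top <- function(spec, z, step) {
  a <- spec$crown_md_halflength; b <- spec$crown_vo_halfwidth
  taus <- ring_taus(spec, z, step)
  verts <- list(c(0, 0, z(0, 0)))
  ring_ids <- list()
  ring_angs <- list()
  nv <- 1L
  scale_mean <- sqrt((a^2 + b^2) / 2)
  for (k in seq_along(taus)) {
    rho <- sin(taus[k])
    nphi <- max(8L, ceiling(2 * pi * rho * scale_mean / step))
    phi <- 2 * pi * (seq_len(nphi) - 1L) / nphi
    x <- a * rho * cos(phi); y <- b * rho * sin(phi)
    verts[[k + 1L]] <- cbind(x, y, z(x, y))
    ring_ids[[k]] <- nv + seq_len(nphi)
    ring_angs[[k]] <- phi
    nv <- nv + nphi
  }
  v <- do.call(rbind, lapply(verts, function(m) matrix(m, ncol = 3)))
  # pole fan
  r1 <- ring_ids[[1]]; n1 <- length(r1)
  faces <- cbind(1L, r1, r1[c(2:n1, 1)])
  for (k in seq_len(length(taus) - 1L)) {
    faces <- rbind(faces, stitch_rings(ring_ids[[k]], ring_angs[[k]],
                                       ring_ids[[k + 1L]],
                                       ring_angs[[k + 1L]]))
  }
  list(vertices = v, faces = faces,
       margin_ids = ring_ids[[length(ring_ids)]],
       margin_ang = ring_angs[[length(ring_angs)]])
}

#' Generate a synthetic two-cusp tooth crown with ground truth
#'
#' Produces three watertight meshes: the solid outer ("enamel") crown, the
#' solid inner ("dentine") crown, and the enamel-cap shell (outer surface
#' joined to the inward-offset inner surface along the cervical margin), plus
#' analytic ground-truth landmarks computed from the continuous model by
#' numerical optimisation (independent of the meshes).
#'
#' @param spec a [bicuspid_spec()].
#' @return list with elements `outer`, `inner`, `shell` (tooth_surface) and
#'   `truth` (class `bicuspid_truth`).
#' @export
generate_bicuspid <- function(spec) {
  stopifnot(inherits(spec, "bicuspid_spec"))
  a <- spec$crown_md_halflength; b <- spec$crown_vo_halfwidth
  t <- spec$enamel_thickness
  cal <- calibrate_amplitudes(spec)
  z <- crown_height_fun(spec, cal$h_v, cal$h_o, cal$D)

  # self-intersection guard for the inward offset: the offset distance must
  # stay below the smallest concave radius of curvature of the top surface
  kmax <- max_abs_curvature(z, a, b)
  if (t * kmax >= 1)
    stop(sprintf(
      "enamel thickness %.3g mm exceeds the minimal curvature radius %.3g mm: offset would self-intersect",
      t, 1 / kmax))

  # orient a face set by a reference normal field evaluated at face centroids
  orient_by_normal <- function(verts, faces, ref_normal_at) {
    ctr <- (verts[faces[, 1], , drop = FALSE] + verts[faces[, 2], , drop = FALSE] +
            verts[faces[, 3], , drop = FALSE]) / 3
    e1 <- verts[faces[, 2], , drop = FALSE] - verts[faces[, 1], , drop = FALSE]
    e2 <- verts[faces[, 3], , drop = FALSE] - verts[faces[, 1], , drop = FALSE]
    fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    flip <- rowSums(fn * ref_normal_at(ctr)) < 0
    faces[flip, ] <- faces[flip, c(1, 3, 2), drop = FALSE]
    faces
  }
  top_normal <- function(ctr) height_field_normal(z, ctr[, 1], ctr[, 2], a, b)

  top <- mesh_crown_top(spec, z, spec$resolution)
  v_out <- top$vertices
  if (spec$jitter_sd > 0) {
    set.seed(spec$seed)
    nrm0 <- height_field_normal(z, v_out[, 1], v_out[, 2], a, b)
    interior <- seq_len(nrow(v_out))
    interior <- setdiff(interior, top$margin_ids)
    d <- stats::rnorm(length(interior), 0, spec$jitter_sd)
    v_out[interior, ] <- v_out[interior, ] + d * nrm0[interior, ]
  }
  nrm <- height_field_normal(z, top$vertices[, 1], top$vertices[, 2], a, b)
  v_in <- top$vertices - t * nrm

  nv <- nrow(v_out)
  margin <- top$margin_ids

  # top faces: outward (up) via the analytic normal; cap faces: downward
  top_faces <- orient_by_normal(v_out, top$faces, top_normal)
  down <- function(ctr) matrix(rep(c(0, 0, -1), each = nrow(ctr)), ncol = 3)
  up_field <- top_normal

  # solid outer crown: top + flat graded-disk cervical cap
  m <- margin; nm <- length(m)
  ocap <- mesh_flat_cap(v_out, m, spec$resolution)
  outer_v <- rbind(v_out, ocap$vertices)
  ocap_f <- orient_by_normal(outer_v, ocap$faces, down)
  outer <- tooth_surface(outer_v, rbind(top_faces, ocap_f), validate = TRUE)

  # solid inner crown (same parameter-domain topology, offset vertices)
  icap <- mesh_flat_cap(v_in, m, spec$resolution)
  inner_v <- rbind(v_in, icap$vertices)
  inner_top <- orient_by_normal(inner_v, top$faces, up_field)
  icap_f <- orient_by_normal(inner_v, icap$faces, down)
  inner <- tooth_surface(inner_v, rbind(inner_top, icap_f), validate = TRUE)

  # enamel-cap shell: outer top + reversed inner top + cervical margin band
  # (a flat annulus at z = 0 exposing the enamel rim, facing down)
  shell_v <- rbind(v_out, v_in)
  inner_faces <- inner_top[, c(1, 3, 2), drop = FALSE] + nv
  band <- rbind(cbind(m[c(2:nm, 1)], m, m + nv),
                cbind(m[c(2:nm, 1)], m + nv, m[c(2:nm, 1)] + nv))
  band <- orient_by_normal(shell_v, band, down)
  shell <- tooth_surface(shell_v, rbind(top_faces, inner_faces, band),
                         validate = TRUE)

  truth <- make_ground_truth(spec, z, cal, nrm, top, t)
  truth$vertex_counts <- c(outer = nrow(outer$vertices),
                           inner = nrow(inner$vertices),
                           shell = nrow(shell$vertices))
  list(outer = outer, inner = inner, shell = shell, truth = truth)
}

# densely sample |kappa| of the height field (principal curvature bound used
# by the offset guard), avoiding the singular margin annulus
max_abs_curvature <- function(z, a, b, n = 60) {
  g <- expand.grid(x = seq(-a * 0.92, a * 0.92, length.out = n),
                   y = seq(-b * 0.92, b * 0.92, length.out = n))
  keep <- (g$x / a)^2 + (g$y / b)^2 < 0.85
  x <- g$x[keep]; y <- g$y[keep]
  eps <- 1e-4
  zxx <- (z(x + eps, y) - 2 * z(x, y) + z(x - eps, y)) / eps^2
  zyy <- (z(x, y + eps) - 2 * z(x, y) + z(x, y - eps)) / eps^2
  zxy <- (z(x + eps, y + eps) - z(x + eps, y - eps) -
          z(x - eps, y + eps) + z(x - eps, y - eps)) / (4 * eps^2)
  zx <- (z(x + eps, y) - z(x - eps, y)) / (2 * eps)
  zy <- (z(x, y + eps) - z(x, y - eps)) / (2 * eps)
  W <- sqrt(1 + zx^2 + zy^2)
  # bound via mean and Gaussian curvature of the Monge patch
  Km <- ((1 + zy^2) * zxx - 2 * zx * zy * zxy + (1 + zx^2) * zyy) / (2 * W^3)
  Kg <- (zxx * zyy - zxy^2) / W^4
  disc <- pmax(0, Km^2 - Kg)
  max(abs(Km) + sqrt(disc))
}

# Gaussian and mean curvature of the continuous height field at (x, y);
# sign convention: convex (dome-like, bulging toward +z normal) positive
height_field_curvatures <- function(z, x, y, eps = 1e-4) {
  zxx <- (z(x + eps, y) - 2 * z(x, y) + z(x - eps, y)) / eps^2
  zyy <- (z(x, y + eps) - 2 * z(x, y) + z(x, y - eps)) / eps^2
  zxy <- (z(x + eps, y + eps) - z(x + eps, y - eps) -
          z(x - eps, y + eps) + z(x - eps, y - eps)) / (4 * eps^2)
  zx <- (z(x + eps, y) - z(x - eps, y)) / (2 * eps)
  zy <- (z(x, y + eps) - z(x, y - eps)) / (2 * eps)
  W <- sqrt(1 + zx^2 + zy^2)
  K <- (zxx * zyy - zxy^2) / W^4
  H <- -((1 + zy^2) * zxx - 2 * zx * zy * zxy + (1 + zx^2) * zyy) / (2 * W^3)
  list(K = K, H = H)
}

height_field_gaussian <- function(z, x, y, eps = 1e-4) {
  height_field_curvatures(z, x, y, eps)$K
}

make_ground_truth <- function(spec, z, cal, nrm, top, t) {
  a <- spec$crown_md_halflength; b <- spec$crown_vo_halfwidth

  # inner-surface height as a function of (x, y) via the offset map is not a
  # graph in general; for landmarks we optimise over the parameter domain
  offset_pt <- function(x, y) {
    p <- cbind(x, y, z(x, y))
    p - t * height_field_normal(z, x, y, a, b)
  }
  inner_z <- function(x, y) offset_pt(x, y)[, 3]

  fy <- spec$crest_ring_radius
  fx <- fy * spec$fossa_elongation
  tv <- cal$tip_v[1:2]; to <- cal$tip_o[1:2]
  tip_in_v <- max2d(function(x, y) inner_z(x, y), tv,
                    lower = tv - 2, upper = tv + 2)
  tip_in_o <- max2d(function(x, y) inner_z(x, y), to,
                    lower = to - 2, upper = to + 2)
  fossa_in <- max2d(function(x, y) -inner_z(x, y), cal$fossa[1:2],
                    lower = c(-fx, -fy), upper = c(fx, fy))
  p_iv <- offset_pt(tip_in_v$xy[1], tip_in_v$xy[2])
  p_io <- offset_pt(tip_in_o$xy[1], tip_in_o$xy[2])
  p_if <- offset_pt(fossa_in$xy[1], fossa_in$xy[2])

  # cervical margin curves (outer: the base ellipse at z = 0)
  phi <- seq(0, 2 * pi, length.out = 721)[-721]
  cerv_out <- cbind(a * cos(phi), b * sin(phi), 0)
  gx <- cos(phi) / a; gy <- sin(phi) / b
  gn <- sqrt(gx^2 + gy^2)
  cerv_in <- cerv_out - t * cbind(gx / gn, gy / gn, 0)
  w_in <- 2 * max(cerv_in[, 2])

  # crest ring: per-azimuth maximal Gaussian curvature of the continuous
  # surface within the fossa rim zone
  fy <- spec$crest_ring_radius
  fx <- fy * spec$fossa_elongation
  nphi <- 360
  ring <- matrix(0, nphi, 3)
  for (i in seq_len(nphi)) {
    ph <- 2 * pi * (i - 1) / nphi
    rr <- fy * fx / sqrt((fx * sin(ph))^2 + (fy * cos(ph))^2)  # fossa ellipse
    qs <- seq(0.6, 1.6, length.out = 200) * rr
    cv <- height_field_curvatures(z, qs * cos(ph), qs * sin(ph))
    # crest = maximal ridge curvature kappa1 among convex (H > 0) points;
    # kappa1 localises the crest even where it crosses a saddle col and K
    # changes sign (the concave bowl wall has K > 0 but H < 0)
    k1 <- cv$H + sqrt(pmax(0, cv$H^2 - cv$K))
    conv <- which(cv$H > 0)
    qb <- if (length(conv)) qs[conv[which.max(k1[conv])]] else rr
    ring[i, ] <- c(qb * cos(ph), qb * sin(ph), z(qb * cos(ph), qb * sin(ph)))
  }

  structure(list(
    spec = spec,
    amplitudes = cal[c("h_v", "h_o", "D")],
    cusp_tip_vestibular = c(cal$tip_v[1:2], cal$tip_v[3]),
    cusp_tip_oral = c(cal$tip_o[1:2], cal$tip_o[3]),
    fossa_point = cal$fossa,
    cusp_tip_vestibular_inner = as.numeric(p_iv),
    cusp_tip_oral_inner = as.numeric(p_io),
    fossa_point_inner = as.numeric(p_if),
    # the dentine sector of a cap contour shares the cervical edge points
    # with enamel, so its maximal horizontal extent equals the enamel one;
    # the inner surface alone is narrower by twice the enamel thickness
    max_vo_width = c(enamel = 2 * b, dentine = 2 * b),
    inner_surface_max_width = w_in,
    max_vo_width_md_position = c(enamel = 0, dentine = 0),
    occlusal_depth = c(
      enamel = (cal$tip_v[3] + cal$tip_o[3]) / 2 - cal$fossa[3],
      dentine = (p_iv[3] + p_io[3]) / 2 - p_if[3]),
    cervical_outer = cerv_out,
    cervical_inner = cerv_in,
    crest_ring = ring,
    origin = c(0, 0, mean(ring[, 3])),
    vertical_axis = c(0, 0, 1),
    mesiodistal_axis = c(1, 0, 0),
    vestibulooral_axis = c(0, 1, 0)
  ), class = "bicuspid_truth")
}

#' Apply a rigid motion to a surface
#'
#' @param surface a [tooth_surface()].
#' @param rotation 3x3 rotation matrix, or axis-angle (length-4
#'   `c(axis, angle)`), or unit quaternion (length-4 `c(w, x, y, z)` with
#'   `quaternion = TRUE`), or `NULL` to draw a random rotation from `seed`.
#' @param translation length-3 vector, or `NULL` for a seeded random one.
#' @param seed RNG seed for random motions.
#' @param quaternion interpret a length-4 `rotation` as a quaternion.
#' @return list with `surface` (moved), `rotation` (matrix), `translation`.
#' @export
apply_rigid_motion <- function(surface, rotation = NULL, translation = NULL,
                               seed = NULL, quaternion = FALSE) {
  if (is.null(rotation) || is.null(translation)) {
    if (is.null(seed)) stop("provide rotation/translation or a seed")
    set.seed(seed)
    if (is.null(rotation)) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      rotation <- c(ax, stats::runif(1, 0, 2 * pi))
    }
    if (is.null(translation)) translation <- stats::runif(3, -10, 10)
  }
  R <- rotation_matrix(rotation, quaternion)
  v <- surface$vertices %*% t(R) +
    matrix(translation, nrow(surface$vertices), 3, byrow = TRUE)
  s <- tooth_surface(v, surface$faces,
                     normals = if (!is.null(surface$normals))
                       surface$normals %*% t(R),
                     validate = FALSE)
  list(surface = s, rotation = R, translation = as.numeric(translation))
}

#' Build a rotation matrix from axis-angle, quaternion or matrix input
#' @param rotation see [apply_rigid_motion()].
#' @param quaternion interpret length-4 input as a quaternion.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(rotation, quaternion = FALSE) {
  if (is.matrix(rotation)) {
    if (!all(dim(rotation) == c(3, 3))) stop("rotation matrix must be 3x3")
    return(rotation)
  }
  if (length(rotation) != 4L) stop("rotation must be 3x3, axis-angle or quaternion")
  if (quaternion) {
    q <- rotation / sqrt(sum(rotation^2))
    if (abs(sum(rotation^2) - 1) > 1e-9)
      warning("non-unit quaternion normalised")
    w <- q[1]; x <- q[2]; y <- q[3]; zz <- q[4]
    return(matrix(c(
      1 - 2 * (y^2 + zz^2), 2 * (x * y - w * zz), 2 * (x * zz + w * y),
      2 * (x * y + w * zz), 1 - 2 * (x^2 + zz^2), 2 * (y * zz - w * x),
      2 * (x * zz - w * y), 2 * (y * zz + w * x), 1 - 2 * (x^2 + y^2)),
      3, 3, byrow = TRUE))
  }
  ax <- rotation[1:3]
  nrmax <- sqrt(sum(ax^2))
  if (abs(nrmax - 1) > 1e-9) warning("non-unit rotation axis normalised")
  ax <- ax / nrmax
  th <- rotation[4]
  Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * (Kx %*% Kx)
}
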