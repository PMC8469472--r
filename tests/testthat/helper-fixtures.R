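# Shared fixtures, generated once per session and cached across test files.

if (!exists(".ado_cache", envir = globalenv())) {
  assign(".ado_cache", new.env(parent = emptyenv()), envir = globalenv())
}

ado_fixture <- function(name) {
  cache <- get(".ado_cache", envir = globalenv())
  if (!is.null(cache[[name]])) return(cache[[name]])
  val <- switch(name,
    bicuspid = generate_bicuspid(bicuspid_spec()),
    shell_pipeline = run_pipeline(ado_fixture("bicuspid")$shell,
                                  shell_config()),
    sphere1 = icosphere(4, 1),
    sphere2 = icosphere(4, 2),
    stop("unknown fixture: ", name))
  cache[[name]] <- val
  val
}

# analysis settings used throughout: curvature radius of about one third of
# the fixture's crest-ring radius resolves the fossa rim
shell_config <- function(...) {
  pipeline_config(curvature_radius = 0.8, ...)
}

# toy two-cusp contour: tips (-4, 10), (4, 10), valley (0, 6), convex body
toy_contour <- function() {
  rbind(c(-7, 0), c(-6, 8), c(-4, 10), c(-2, 8), c(0, 6), c(2, 8),
        c(4, 10), c(6, 8), c(7, 0), c(0, -4))
}

# asymmetric variant: tips (-4, 10), (4, 8), valley near (0, 5)
toy_contour_asym <- function() {
  rbind(c(-7, 0), c(-6, 8), c(-4, 10), c(-2, 7.5), c(0, 5), c(2, 7),
        c(4, 8), c(6, 6.5), c(7, 0), c(0, -4))
}

# hand-built symmetric enamel-cap band with sharp cervical corners at
# (+-5, 0): outer arc over the top, inner arc underneath, closed band
toy_band <- function() {
  xs <- seq(-5, 5, by = 0.25)
  outer_arc <- cbind(xs, 6 * sqrt(pmax(0, 1 - (xs / 5.2)^2)) +
                       0.8 * cos(xs))
  inner <- rev(xs[abs(xs) <= 4.4])
  inner_arc <- cbind(inner, 6 * sqrt(pmax(0, 1 - (inner / 5.2)^2)) +
                       0.8 * cos(inner) - 1)
  rbind(outer_arc, inner_arc)
}

nn_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) - 2 * a %*% t(b) +
    outer(rep(1, nrow(a)), rowSums(b^2))
  sqrt(pmax(0, apply(d2, 1, min)))
}

angle_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
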