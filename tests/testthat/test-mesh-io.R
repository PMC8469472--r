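# mesh_io: readers/writers, validation, repair

test_that("a tetrahedron round-trips through STL and PLY identically", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  tet <- tooth_surface(v, f)
  stl <- tempfile(fileext = ".stl")
  ply <- tempfile(fileext = ".ply")
  write_surface(tet, stl)
  write_surface(tet, ply)
  s1 <- load_surface(stl)
  s2 <- load_surface(ply)
  expect_equal(nrow(s1$vertices), 4L)
  expect_equal(nrow(s1$faces), 4L)
  # identical vertex sets after canonical sorting
  canon <- function(s) {
    o <- order(s$vertices[, 1], s$vertices[, 2], s$vertices[, 3])
    s$vertices[o, ]
  }
  expect_equal(canon(s1), canon(s2), tolerance = 1e-12)
  expect_equal(nrow(s1$faces), nrow(s2$faces))
})

test_that("write/load round trip is identity within 1e-6 mm in all formats", {
  s <- icosphere(2, 7)   # mm-scale like a crown
  for (fmt in c("ply", "stl", "obj")) {
    for (bin in if (fmt == "obj") FALSE else c(FALSE, TRUE)) {
      path <- tempfile(fileext = paste0(".", fmt))
      write_surface(s, path, binary = bin)
      s2 <- load_surface(path)
      expect_equal(nrow(s2$faces), nrow(s$faces), info = fmt)
      expect_lt(max(nn_dist(s$vertices, s2$vertices)), 1e-6)
      expect_lt(max(nn_dist(s2$vertices, s$vertices)), 1e-6)
    }
  }
})

test_that("synthetic fixture files reload with the declared vertex count", {
  g <- ado_fixture("bicuspid")
  path <- tempfile(fileext = ".ply")
  write_surface(g$shell, path, binary = TRUE)
  s2 <- load_surface(path)
  expect_equal(nrow(s2$vertices), unname(g$truth$vertex_counts["shell"]))
})

test_that("invalid inputs are rejected with clear errors", {
  expect_error(load_surface(tempfile()), "does not exist")
  bad <- tempfile(fileext = ".ply")
  writeLines("not a mesh", bad)
  expect_error(load_surface(bad), "PLY")
  expect_error(tooth_surface(matrix(0, 4, 3), rbind(c(1, 2, 9), c(1, 2, 3),
                                                    c(1, 3, 4), c(2, 3, 4))),
               "out of range")
  unknown <- tempfile(fileext = ".xyz")
  writeLines("1 2 3", unknown)
  expect_error(load_surface(unknown), "format")
})

test_that("STL write of a non-manifold surface warns but writes", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5), c(3, 4, 5))
  s <- tooth_surface(v, f)
  path <- tempfile(fileext = ".stl")
  expect_warning(write_surface(s, path), "non-watertight")
  expect_true(file.exists(path))
})

test_that("repair leaves a closed icosphere untouched and patches holes", {
  s <- icosphere(2, 1)
  r <- repair_surface(s, fill_holes = TRUE)
  expect_equal(nrow(r$faces), nrow(s$faces))
  expect_equal(nrow(r$vertices), nrow(s$vertices))

  holed <- s
  holed$faces <- holed$faces[-1, , drop = FALSE]
  expect_equal(nrow(boundary_edges(holed)), 3L)
  patched <- repair_surface(holed, fill_holes = TRUE)
  expect_equal(nrow(boundary_edges(patched)), 0L)
  expect_true(is_watertight(patched))
})

test_that("large boundary loops (cervical openings) are never filled", {
  # sphere with a big polar opening (like a cervical margin) and one
  # missing face elsewhere: only the single-face hole may be patched
  s <- icosphere(3, 5)
  vz <- matrix(s$vertices[s$faces, 3], ncol = 3)
  keep <- apply(vz, 1, min) < 4          # remove the polar cap
  open_s <- odontometry:::drop_unreferenced(
    tooth_surface(s$vertices, s$faces[keep, , drop = FALSE],
                  validate = FALSE))
  low <- which(matrix(open_s$vertices[open_s$faces, 3],
                      ncol = 3)[, 1] < -4)[1]
  open_s$faces <- open_s$faces[-low, , drop = FALSE]
  loops0 <- boundary_loops(open_s)
  expect_equal(length(loops0), 2L)
  r <- repair_surface(open_s, fill_holes = TRUE)
  loops1 <- boundary_loops(r)
  expect_equal(length(loops1), 1L)       # the small hole is patched
  expect_gt(length(loops1[[1]]), 10L)    # the big opening survives
})

test_that("Taubin smoothing shrinks noise on a jittered sphere", {
  set.seed(7)
  s <- icosphere(3, 1)
  nrm <- vertex_normals(s)
  s$vertices <- s$vertices + stats::rnorm(nrow(s$vertices), 0, 0.01) * nrm
  dev0 <- mean(abs(sqrt(rowSums(s$vertices^2)) - 1))
  sm <- smooth_surface(s, 10)
  dev1 <- mean(abs(sqrt(rowSums(sm$vertices^2)) - 1))
  expect_lt(dev1, dev0)
})

test_that("decimation reduces faces, preserves closedness, bounds drift", {
  s <- icosphere(3, 1)
  d <- suppressWarnings(
    repair_surface(s, target_face_count = 600, hausdorff_tol = 0.05))
  expect_lt(nrow(d$faces), nrow(s$faces) / 2)
  expect_true(is_watertight(d))
  # all decimated vertices stay near the unit sphere
  expect_lt(max(abs(sqrt(rowSums(d$vertices^2)) - 1)), 0.05)
})

test_that("unrepairable non-manifold input errors with offending edges", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1),
             c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5), c(1, 2, 6))
  expect_error(repair_surface(tooth_surface(v, f)), "\\(1,2\\)")
})

test_that("repair is idempotent", {
  s <- icosphere(2, 1)
  s$faces <- s$faces[-5, , drop = FALSE]
  r1 <- repair_surface(s, fill_holes = TRUE)
  r2 <- repair_surface(r1, fill_holes = TRUE)
  expect_equal(r2$faces, r1$faces)
  expect_equal(r2$vertices, r1$vertices)
})
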