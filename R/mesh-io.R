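# Readers/writers for the three interchange formats used downstream of uCT
# segmentation. Binary PLY is little-endian only; OBJ handles v/f records.

format_from_path <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("ply", "stl", "obj")) return(ext)
  stop("cannot auto-detect mesh format from extension: ", path)
}

#' Load a triangulated tooth surface from PLY, STL or OBJ
#'
#' Coordinates are taken to be millimetres (no unit metadata exists in these
#' formats). After parsing, duplicate vertices within 1e-9 mm are merged,
#' degenerate faces dropped and the face winding made consistent (outward for
#' watertight meshes).
#'
#' @param path file path.
#' @param format `"ply"`, `"stl"`, `"obj"` or `"auto"` (from extension).
#' @return a [tooth_surface()].
#' @export
load_surface <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  format <- tolower(format)
  if (format == "auto") format <- format_from_path(path)
  raw <- switch(format,
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path),
    stop("unsupported format: ", format))
  if (nrow(raw$vertices) == 0L || nrow(raw$faces) == 0L)
    stop("empty mesh: ", path)
  s <- tooth_surface(raw$vertices, raw$faces, validate = FALSE)
  s <- merge_duplicate_vertices(s)
  s <- drop_degenerate_faces(s)
  s <- orient_faces(s)
  validate_surface(s)
  s
}

#' Write a triangulated surface to PLY, STL or OBJ
#'
#' @param surface a [tooth_surface()].
#' @param path output file path.
#' @param format `"ply"`, `"stl"`, `"obj"` or `"auto"` (from extension).
#' @param binary write the binary variant (PLY/STL only).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, format = "auto", binary = FALSE) {
  validate_surface(surface)
  format <- tolower(format)
  if (format == "auto") format <- format_from_path(path)
  if (format == "stl" && !is_watertight(surface))
    warning("writing non-watertight surface to STL")
  switch(format,
    ply = write_ply(surface, path, binary),
    stl = if (binary) write_stl_binary(surface, path)
          else write_stl_ascii(surface, path),
    obj = write_obj(surface, path),
    stop("unsupported format: ", format))
  invisible(path)
}

# --- PLY --------------------------------------------------------------------

ply_type_info <- function(t) {
  switch(t,
    char = , int8 = list(what = "integer", size = 1, signed = TRUE),
    uchar = , uint8 = list(what = "integer", size = 1, signed = FALSE),
    short = , int16 = list(what = "integer", size = 2, signed = TRUE),
    ushort = , uint16 = list(what = "integer", size = 2, signed = FALSE),
    int = , int32 = list(what = "integer", size = 4, signed = TRUE),
    uint = , uint32 = list(what = "integer", size = 4, signed = TRUE),
    float = , float32 = list(what = "double", size = 4, signed = TRUE),
    double = , float64 = list(what = "double", size = 8, signed = TRUE),
    stop("unsupported PLY type: ", t))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unreadable PLY file (no end_header): ", path)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 1000L) stop("unreadable PLY header: ", path)
  }
  if (trimws(header[1]) != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  if (!length(fmt_line)) stop("PLY file without format line: ", path)
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3],
                                    item_type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY file lacks vertex/face elements: ", path)

  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    pos <- 1L
    out <- list()
    for (el in elements) {
      n <- el$count
      rows <- txt[pos:(pos + n - 1L)]
      pos <- pos + n
      out[[el$name]] <- rows
    }
    vprops <- names(elements$vertex$props)
    vmat <- do.call(rbind, lapply(out$vertex, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    xyz <- vmat[, match(c("x", "y", "z"), vprops), drop = FALSE]
    faces <- do.call(rbind, lapply(out$face, function(r) {
      v <- as.numeric(strsplit(trimws(r), "\\s+")[[1]])
      cnt <- v[1]
      if (cnt != 3) stop("non-triangular PLY face (", cnt, " vertices)")
      v[2:4] + 1
    }))
    return(list(vertices = xyz, faces = faces))
  }
  if (fmt != "binary_little_endian")
    stop("unsupported PLY format: ", fmt)
  endian <- "little"
  read_scalar <- function(type, n = 1L) {
    ti <- ply_type_info(type)
    readBin(con, what = ti$what, n = n, size = ti$size,
            signed = ti$signed, endian = endian)
  }
  verts <- NULL; faces <- NULL
  for (el in elements) {
    props <- el$props
    if (!any(vapply(props, `[[`, TRUE, "list"))) {
      # fixed-width element: read row-wise (types may differ per property)
      types <- vapply(props, `[[`, "", "type")
      mat <- matrix(0, el$count, length(props))
      for (i in seq_len(el$count))
        for (j in seq_along(types)) mat[i, j] <- read_scalar(types[j])
      if (el$name == "vertex")
        verts <- mat[, match(c("x", "y", "z"), names(props)), drop = FALSE]
    } else {
      rows <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        vals <- NULL
        for (p in props) {
          if (p$list) {
            cnt <- read_scalar(p$count_type)
            items <- read_scalar(p$item_type, cnt)
            vals <- c(vals, items)
          } else {
            vals <- c(vals, read_scalar(p$type))
          }
        }
        rows[[i]] <- vals
      }
      if (el$name == "face") {
        if (any(lengths(rows) != 3L)) stop("non-triangular PLY face")
        faces <- do.call(rbind, rows) + 1
      }
    }
  }
  list(vertices = verts, faces = faces)
}

write_ply <- function(surface, path, binary = FALSE) {
  v <- surface$vertices; f <- surface$faces
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(v)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(paste(format(v[, 1], digits = 17), format(v[, 2], digits = 17),
                     format(v[, 3], digits = 17)), con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

# --- STL --------------------------------------------------------------------

stl_is_ascii <- function(path) {
  # binary STL: 80-byte header, uint32 triangle count, 50 bytes/triangle
  sz <- file.size(path)
  if (sz >= 84) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    ntri <- readBin(con, "integer", size = 4, endian = "little")
    if (length(ntri) && !is.na(ntri) && sz == 84 + 50 * as.double(ntri))
      return(FALSE)
  }
  head <- readBin(path, "raw", n = 6L)
  identical(tolower(rawToChar(head[1:5])), "solid")
}

read_stl <- function(path) {
  if (stl_is_ascii(path)) {
    lines <- readLines(path, warn = FALSE)
    vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(t)
      as.numeric(t[2:4])))
    if (is.null(coords) || nrow(coords) %% 3L != 0L)
      stop("malformed ASCII STL: ", path)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    ntri <- readBin(con, "integer", size = 4, endian = "little")
    if (!length(ntri) || ntri <= 0) stop("malformed binary STL: ", path)
    rec <- readBin(con, "raw", n = ntri * 50L)
    if (length(rec) < ntri * 50L) stop("truncated binary STL: ", path)
    m <- matrix(rec, nrow = 50L)
    fl <- readBin(as.vector(m[1:48, ]), "double", n = ntri * 12L, size = 4,
                  endian = "little")
    fl <- matrix(fl, ncol = 12L, byrow = TRUE)
    coords <- matrix(0, 3 * ntri, 3)
    coords[seq(1, 3 * ntri, 3), ] <- fl[, 4:6, drop = FALSE]
    coords[seq(2, 3 * ntri, 3), ] <- fl[, 7:9, drop = FALSE]
    coords[seq(3, 3 * ntri, 3), ] <- fl[, 10:12, drop = FALSE]
  }
  ntri <- nrow(coords) / 3L
  faces <- matrix(seq_len(3L * ntri), ncol = 3, byrow = TRUE)
  list(vertices = coords, faces = faces)
}

write_stl_ascii <- function(surface, path) {
  v <- surface$vertices; f <- surface$faces
  fn <- face_normals(surface)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid surface", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       fn[i, 1], fn[i, 2], fn[i, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      p <- v[f[i, k], ]
      writeLines(sprintf("      vertex %.17g %.17g %.17g", p[1], p[2], p[3]),
                 con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid surface", con)
  invisible(path)
}

write_stl_binary <- function(surface, path) {
  v <- surface$vertices; f <- surface$faces
  fn <- face_normals(surface)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(as.vector(t(rbind(fn[i, ], v[f[i, 1], ], v[f[i, 2], ],
                               v[f[i, 3], ]))),
             con, size = 4, endian = "little")
    writeBin(raw(2L), con)
  }
  invisible(path)
}

# --- OBJ --------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(t)
    as.numeric(t[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(t) {
    ix <- as.integer(sub("/.*", "", t[-1]))
    if (length(ix) != 3L) stop("non-triangular OBJ face")
    ix
  }))
  list(vertices = verts, faces = faces)
}

write_obj <- function(surface, path) {
  v <- surface$vertices; f <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", format(v[, 1], digits = 17),
                   format(v[, 2], digits = 17), format(v[, 3], digits = 17)),
             con)
  writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}
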