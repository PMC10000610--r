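# Triangle-mesh container and OBJ/PLY/STL readers and writers.
# Coordinates are in arbitrary "distance units"; no rescaling is applied.

#' Construct a triangle mesh
#'
#' A minimal triangulated-surface container: an `n x 3` matrix of vertex
#' coordinates and an `m x 3` matrix of 1-based vertex indices per
#' triangular face.
#'
#' @param vertices numeric matrix with columns x, y, z.
#' @param faces integer matrix of 1-based vertex indices, one row per
#'   triangle.
#' @param validate check invariants (indices in range, no degenerate face,
#'   positive vertical extent). Default `TRUE`.
#' @return an object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns (x, y, z)")
  if (ncol(faces) != 3L) stop("faces must have 3 columns (triangles only)")
  colnames(vertices) <- c("x", "y", "z")
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate triangle-mesh invariants
#'
#' Checks that every face index addresses an existing vertex, that no face
#' is degenerate (zero area / collinear vertices), and that the mesh has
#' positive vertical extent.
#'
#' @param mesh a `triangle_mesh`.
#' @return `mesh`, invisibly; stops with an error on violation.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  if (nv == 0L || nrow(f) == 0L) stop("empty mesh")
  if (anyNA(v) || anyNA(f)) stop("mesh contains NA values")
  if (min(f) < 1L || max(f) > nv) stop("face index out of range")
  a <- v[f[, 1L], , drop = FALSE]
  ab <- v[f[, 2L], , drop = FALSE] - a
  ac <- v[f[, 3L], , drop = FALSE] - a
  # twice the face area, via the cross-product norm
  cx <- ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L]
  cy <- ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L]
  cz <- ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L]
  area2 <- sqrt(cx^2 + cy^2 + cz^2)
  scale2 <- pmax(rowSums(ab^2), rowSums(ac^2), .Machine$double.eps)
  if (any(area2 <= 1e-12 * scale2)) stop("degenerate (collinear) face")
  if (diff(range(v[, 3L])) <= 0) stop("mesh has no vertical extent")
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  zr <- range(x$vertices[, 3L])
  cat(sprintf("triangle_mesh: %d vertices, %d faces, z in [%.4g, %.4g]\n",
              nrow(x$vertices), nrow(x$faces), zr[1L], zr[2L]))
  invisible(x)
}

mesh_format_from_path <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (!ext %in% c("obj", "ply", "stl"))
    stop("cannot auto-detect mesh format from extension '", ext,
         "'; pass format = \"obj\", \"ply\" or \"stl\"")
  ext
}

#' Load a triangulated surface mesh
#'
#' Reads OBJ (ASCII), PLY (ASCII or binary little-endian) or STL (ASCII or
#' binary).  STL stores vertices per facet; coincident vertices (within
#' 1e-8 distance units) are merged on load so plane slicing sees a
#' connected surface, and faces collapsed by the merge are dropped.
#'
#' @param path file path.
#' @param format `"obj"`, `"ply"`, `"stl"`, or `"auto"` (default; from the
#'   file extension).
#' @return a [triangle_mesh()].
#' @export
load_mesh <- function(path, format = c("auto", "obj", "ply", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- mesh_format_from_path(path)
  switch(format,
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl(path))
}

#' Save a triangulated surface mesh
#'
#' Writes OBJ, ASCII PLY or ASCII STL.  Coordinates are written with 17
#' significant digits, so a round-trip through [load_mesh()] preserves them
#' to double precision.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format `"obj"`, `"ply"`, `"stl"`, or `"auto"` (from the
#'   extension).
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, format = c("auto", "obj", "ply", "stl")) {
  format <- match.arg(format)
  validate_mesh(mesh)
  if (format == "auto") format <- mesh_format_from_path(path)
  switch(format,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path),
         stl = write_stl(mesh, path))
  invisible(path)
}

num <- function(x) as.numeric(x)

# ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L || length(flines) == 0L) stop("empty mesh in ", path)
  vtok <- strsplit(sub("^v\\s+", "", vlines), "\\s+")
  verts <- t(vapply(vtok, function(t) num(t[1:3]), numeric(3L)))
  # face entries may be v, v/vt, v//vn or v/vt/vn; keep the vertex index
  ftok <- strsplit(sub("^f\\s+", "", flines), "\\s+")
  faces_list <- lapply(ftok, function(t) {
    idx <- as.integer(vapply(strsplit(t, "/"), `[`, "", 1L))
    idx[idx < 0L] <- nrow(verts) + 1L + idx[idx < 0L]
    if (length(idx) < 3L) stop("face with fewer than 3 vertices")
    # fan-triangulate polygons
    if (length(idx) == 3L) matrix(idx, 1L)
    else cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  })
  faces <- do.call(rbind, faces_list)
  if (anyNA(faces)) stop("unparseable face record in ", path)
  if (max(faces) > nrow(verts) || min(faces) < 1L)
    stop("face index out of range in ", path)
  triangle_mesh(verts, faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1L], mesh$vertices[, 2L],
                     mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]),
             con)
}

# ---- PLY ------------------------------------------------------------------

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1L, size = sz, endian = "little")
  else {
    signed <- !startsWith(type, "u")
    readBin(con, "integer", 1L, size = sz, signed = signed || sz == 4L,
            endian = "little")
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PLY header in ", path)
    header <- c(header, trimws(line))
    if (trimws(line) == "end_header") break
  }
  if (header[1L] != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop("unsupported PLY format (big-endian): ", path)

  # parse element/property declarations, in declared order
  elements <- list()
  cur <- NULL
  for (h in header) {
    tok <- strsplit(h, "\\s+")[[1L]]
    if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]),
                  props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      if (tok[2L] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5L], list = TRUE, count_type = tok[3L],
               item_type = tok[4L])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3L], list = FALSE, type = tok[2L])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY without vertex/face elements: ", path)

  verts <- NULL
  faces <- NULL
  if (!binary) {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    pos <- 0L
    for (el in elements) {
      rows <- rest[pos + seq_len(el$count)]
      pos <- pos + el$count
      tok <- strsplit(trimws(rows), "\\s+")
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        ix <- match(c("x", "y", "z"), pn)
        if (anyNA(ix)) stop("PLY vertex element lacks x/y/z: ", path)
        verts <- t(vapply(tok, function(t) num(t[ix]), numeric(3L)))
      } else if (el$name == "face") {
        faces <- do.call(rbind, lapply(tok, function(t) {
          n <- as.integer(t[1L])
          idx <- as.integer(t[2L:(1L + n)]) + 1L
          if (n == 3L) matrix(idx, 1L)
          else cbind(idx[1L], idx[2:(n - 1L)], idx[3:n])
        }))
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        types <- vapply(el$props, function(p)
          if (p$list) stop("list property on PLY vertex element") else p$type,
          "")
        pn <- vapply(el$props, `[[`, "", "name")
        same <- length(unique(types)) == 1L
        if (same && types[1L] %in% c("float", "float32", "double", "float64")) {
          sz <- ply_type_size[[types[1L]]]
          dat <- readBin(con, "double", el$count * length(types), size = sz,
                         endian = "little")
          m <- matrix(dat, ncol = length(types), byrow = TRUE)
        } else {
          m <- matrix(0, el$count, length(types))
          for (i in seq_len(el$count))
            for (j in seq_along(el$props))
              m[i, j] <- ply_read_scalar(con, types[j])
        }
        ix <- match(c("x", "y", "z"), pn)
        if (anyNA(ix)) stop("PLY vertex element lacks x/y/z: ", path)
        verts <- m[, ix, drop = FALSE]
      } else if (el$name == "face") {
        p <- el$props[[1L]]
        if (!p$list) stop("PLY face element without index list")
        faces_list <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          n <- ply_read_scalar(con, p$count_type)
          idx <- integer(n)
          for (j in seq_len(n)) idx[j] <- ply_read_scalar(con, p$item_type)
          idx <- idx + 1L
          faces_list[[i]] <- if (n == 3L) matrix(idx, 1L)
            else cbind(idx[1L], idx[2:(n - 1L)], idx[3:n])
        }
        faces <- do.call(rbind, faces_list)
      } else {
        # skip unknown scalar-only element
        for (i in seq_len(el$count))
          for (p in el$props) {
            if (p$list) stop("cannot skip list property in PLY element ",
                             el$name)
            ply_read_scalar(con, p$type)
          }
      }
    }
  }
  if (is.null(verts) || is.null(faces) || nrow(faces) == 0L)
    stop("empty mesh in ", path)
  triangle_mesh(verts, faces)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$vertices[, 1L], mesh$vertices[, 2L],
                     mesh$vertices[, 3L]), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                     mesh$faces[, 3L] - 1L), con)
}

# ---- STL ------------------------------------------------------------------

#' Merge coincident vertices
#'
#' Collapses vertices closer than `tol` onto a single vertex (grid
#' quantisation at pitch `tol`) and drops faces that the merge degenerates.
#' Used on STL load, where every facet carries its own vertex copies.
#'
#' @param vertices,faces as in [triangle_mesh()].
#' @param tol merge distance, default 1e-8 distance units.
#' @return a [triangle_mesh()].
#' @keywords internal
merge_vertices <- function(vertices, faces, tol = 1e-8) {
  key <- paste(round(vertices[, 1L] / tol), round(vertices[, 2L] / tol),
               round(vertices[, 3L] / tol))
  first <- !duplicated(key)
  newid <- match(key, key[first])
  verts <- vertices[first, , drop = FALSE]
  f <- matrix(newid[faces], ncol = 3L)
  keep <- f[, 1L] != f[, 2L] & f[, 2L] != f[, 3L] & f[, 1L] != f[, 3L]
  if (!any(keep)) stop("all faces degenerate after vertex merge")
  triangle_mesh(verts, f[keep, , drop = FALSE])
}

read_stl <- function(path) {
  # ASCII STL starts with "solid" and contains "facet"; binary is
  # 80-byte header + uint32 count + 50 bytes per facet.
  head_raw <- readBin(path, "raw", n = 512L)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0L)])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  if (is_ascii) {
    lines <- trimws(readLines(path, warn = FALSE))
    vlines <- lines[startsWith(lines, "vertex")]
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
      stop("malformed ASCII STL: ", path)
    tok <- strsplit(sub("^vertex\\s+", "", vlines), "\\s+")
    verts <- t(vapply(tok, function(t) num(t[1:3]), numeric(3L)))
  } else {
    sz <- file.info(path)$size
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    nfac <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (nfac <= 0L || sz < 84 + 50 * nfac) stop("malformed binary STL: ", path)
    raw <- readBin(con, "raw", 50L * nfac)
    # each 50-byte facet: 12 float32 (normal + 3 vertices) + uint16 pad
    off <- rep((seq_len(nfac) - 1L) * 50L, each = 48L) + seq_len(48L)
    floats <- readBin(raw[off], "double", 12L * nfac, size = 4L,
                      endian = "little")
    m <- matrix(floats, ncol = 12L, byrow = TRUE)
    verts <- matrix(t(m[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  merge_vertices(verts, faces)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  ab <- v[f[, 2L], , drop = FALSE] - a
  ac <- v[f[, 3L], , drop = FALSE] - a
  nx <- ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L]
  ny <- ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L]
  nz <- ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), .Machine$double.eps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  vtx <- function(i) sprintf("    vertex %.17g %.17g %.17g",
                             v[f[, i], 1L], v[f[, i], 2L], v[f[, i], 3L])
  body <- paste(sprintf("  facet normal %.9g %.9g %.9g",
                        nx / nn, ny / nn, nz / nn),
                "    outer loop", vtx(1L), vtx(2L), vtx(3L),
                "    endloop", "  endfacet", sep = "\n")
  writeLines(body, con)
  writeLines("endsolid mesh", con)
}
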