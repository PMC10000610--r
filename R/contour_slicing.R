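# Horizontal plane slicing of a cone mesh into ordered, closed boundary
# contours.  Each crossing face contributes one segment; segments are
# chained into loops via shared mesh edges (exact integer matching on
# canonical edge ids, so chaining never depends on floating-point endpoint
# tolerance); the largest-area closed loop per altitude is kept and
# oriented counterclockwise.

#' Construct a contour slice
#'
#' @param points numeric matrix of (x, y) polyline vertices; the loop is
#'   closed implicitly (last point connects to first).
#' @param z slicing altitude, distance units.
#' @param layer_index 0-based layer number from the bottom, or `NA`.
#' @param validate check invariants (>= 3 points, consecutive points
#'   distinct, counterclockwise orientation).
#' @return an object of class `contour_slice`.
#' @export
contour_slice <- function(points, z, layer_index = NA_integer_,
                          validate = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("contour points must have 2 columns (x, y)")
  colnames(points) <- c("x", "y")
  cs <- structure(list(points = points, z = as.numeric(z),
                       layer_index = as.integer(layer_index)),
                  class = "contour_slice")
  if (validate) {
    if (nrow(points) < 3L) stop("contour needs >= 3 points")
    nxt <- rbind(points[-1L, , drop = FALSE], points[1L, , drop = FALSE])
    if (any(sqrt(rowSums((nxt - points)^2)) <= 1e-9))
      stop("consecutive contour points coincide")
    if (polygon_area(points) <= 0)
      stop("contour must be counterclockwise (positive signed area)")
  }
  cs
}

#' @export
print.contour_slice <- function(x, ...) {
  cat(sprintf("contour_slice: layer %s, z = %.4g, %d points, area %.4g\n",
              ifelse(is.na(x$layer_index), "?", x$layer_index), x$z,
              nrow(x$points), polygon_area(x$points)))
  invisible(x)
}

#' Signed area of a closed polygon
#'
#' Shoelace formula; positive for counterclockwise vertex order.
#'
#' @param points matrix of (x, y) vertices (closing edge implicit).
#' @return signed area.
#' @export
polygon_area <- function(points) {
  x <- points[, 1L]
  y <- points[, 2L]
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Equally spaced slicing altitudes
#'
#' Interior altitudes `z_i = z_min + i (z_max - z_min) / (n_layers + 1)`,
#' i = 1..n_layers: equally spaced from the bottom of the cone to the top
#' while avoiding the degenerate base and apex planes.
#'
#' @param mesh a [triangle_mesh()].
#' @param n_layers number of layers (>= 1), default 40.
#' @return increasing vector of `n_layers` altitudes strictly inside the
#'   mesh z range.
#' @export
slice_heights <- function(mesh, n_layers = 40L) {
  if (n_layers < 1L) stop("n_layers must be >= 1")
  zr <- range(mesh$vertices[, 3L])
  if (diff(zr) <= 0) stop("flat mesh: z_max equals z_min")
  zr[1L] + seq_len(n_layers) * diff(zr) / (n_layers + 1)
}

#' Extract the boundary contour at one altitude
#'
#' Intersects every face crossing the horizontal plane at `z`, chains the
#' resulting segments into closed loops, and returns the loop of largest
#' absolute signed area, oriented counterclockwise.  A vertex lying exactly
#' on the plane would create degenerate point intersections, so the plane
#' is nudged up by `1e-9 * (z_max - z_min)` until no vertex is exactly on
#' it; the displacement is far below any geometric tolerance.
#'
#' @param mesh a [triangle_mesh()].
#' @param z altitude, strictly inside the mesh z range.
#' @param layer_index optional 0-based layer number stored on the result.
#' @return a [contour_slice()].
#' @export
extract_contour <- function(mesh, z, layer_index = NA_integer_) {
  v <- mesh$vertices
  f <- mesh$faces
  zr <- range(v[, 3L])
  if (!(z > zr[1L] && z < zr[2L]))
    stop(sprintf("altitude z = %g outside mesh z range (%g, %g)",
                 z, zr[1L], zr[2L]))
  eps <- 1e-9 * diff(zr)
  guard <- 0L
  while (any(v[, 3L] == z)) {
    z <- z + eps
    guard <- guard + 1L
    if (guard > 64L || z >= zr[2L])
      stop("could not find a vertex-free slicing plane near z")
  }

  # canonical edges (smaller index first) of all faces
  ea <- cbind(f[, 1L], f[, 2L], f[, 3L])
  eb <- cbind(f[, 2L], f[, 3L], f[, 1L])
  a <- pmin(ea, eb)
  b <- pmax(ea, eb)
  nv <- nrow(v)
  key <- as.numeric(a) + as.numeric(b) * (nv + 1)   # unique per edge
  za <- v[a, 3L]
  zb <- v[b, 3L]
  crossing <- (za - z) * (zb - z) < 0               # no vertex on plane
  ncross <- matrix(crossing, ncol = 3L)
  nper <- rowSums(ncross)
  segfaces <- which(nper == 2L)
  if (length(segfaces) < 3L)
    stop(sprintf("no closed contour at z = %g", z))

  ckey <- key[crossing]
  ukey <- unique(ckey)
  eid <- match(key, ukey)                           # NA for non-crossing
  # intersection point of each unique crossing edge
  pick <- match(ukey, key)
  t <- (z - za[pick]) / (zb[pick] - za[pick])
  px <- v[a[pick], 1L] + t * (v[b[pick], 1L] - v[a[pick], 1L])
  py <- v[a[pick], 2L] + t * (v[b[pick], 2L] - v[a[pick], 2L])

  # one segment per crossing face: its two crossing-edge ids
  em <- matrix(eid, ncol = 3L)[segfaces, , drop = FALSE]
  segs <- t(apply(em, 1L, function(r) r[!is.na(r)]))
  if (ncol(segs) != 2L) stop("internal error: face without 2 crossing edges")

  loops <- chain_loops(segs)
  if (length(loops) == 0L)
    stop(sprintf("no closed contour at z = %g (open or broken surface)", z))
  polys <- lapply(loops, function(ids) cbind(px[ids], py[ids]))
  areas <- vapply(polys, polygon_area, 0)
  best <- polys[[which.max(abs(areas))]]
  if (polygon_area(best) < 0) best <- best[rev(seq_len(nrow(best))), ,
                                           drop = FALSE]
  # drop (rare) near-coincident consecutive points
  nxt <- rbind(best[-1L, , drop = FALSE], best[1L, , drop = FALSE])
  keep <- sqrt(rowSums((nxt - best)^2)) > 1e-9
  best <- best[keep, , drop = FALSE]
  if (nrow(best) < 3L)
    stop(sprintf("degenerate contour at z = %g", z))
  contour_slice(best, z, layer_index)
}

# Chain segments (rows of 2 point ids) into closed loops.  A point id on a
# closed section belongs to exactly 2 segments; ids seen once lie on open
# chains, which are dropped.
chain_loops <- function(segs) {
  ns <- nrow(segs)
  pt <- c(segs[, 1L], segs[, 2L])
  sg <- rep(seq_len(ns), 2L)
  deg <- tabulate(pt)
  inc <- split(sg, pt)                  # point id -> incident segments
  used <- logical(ns)
  loops <- list()
  for (s0 in seq_len(ns)) {
    if (used[s0]) next
    start_pt <- segs[s0, 1L]
    if (deg[start_pt] != 2L || deg[segs[s0, 2L]] != 2L) next
    loop <- integer(0L)
    cur_seg <- s0
    cur_pt <- start_pt
    closed <- FALSE
    repeat {
      used[cur_seg] <- TRUE
      loop <- c(loop, cur_pt)
      nxt_pt <- if (segs[cur_seg, 1L] == cur_pt) segs[cur_seg, 2L]
                else segs[cur_seg, 1L]
      if (nxt_pt == start_pt) {
        closed <- TRUE
        break
      }
      if (deg[nxt_pt] != 2L) break      # runs into a boundary: open chain
      cand <- inc[[as.character(nxt_pt)]]
      nxt_seg <- cand[cand != cur_seg & !used[cand]]
      if (length(nxt_seg) == 0L) break
      cur_seg <- nxt_seg[1L]
      cur_pt <- nxt_pt
    }
    if (closed && length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Slice a mesh into equally spaced contours
#'
#' Extracts one contour per altitude from [slice_heights()], bottom to
#' top.  Layers where extraction fails (e.g. a broken surface at that
#' altitude) are returned as `NULL` rather than fabricated; an error is
#' raised only if every layer fails.
#'
#' @param mesh a [triangle_mesh()].
#' @param n_layers number of layers, default 40.
#' @return list of length `n_layers`: [contour_slice()] or `NULL` per
#'   layer, with attribute `"heights"`.
#' @export
slice_mesh <- function(mesh, n_layers = 40L) {
  validate_mesh(mesh)
  zs <- slice_heights(mesh, n_layers)
  out <- vector("list", length(zs))
  for (i in seq_along(zs)) {
    out[[i]] <- tryCatch(extract_contour(mesh, zs[i], layer_index = i - 1L),
                         error = function(e) NULL)
  }
  if (all(vapply(out, is.null, TRUE)))
    stop("contour extraction failed at every altitude")
  attr(out, "heights") <- zs
  out
}
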