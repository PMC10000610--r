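# Seeded parametric generator of conical powder heaps with Gaussian-bump
# lumpiness, emulating graded milk-powder cones.  The physical samples get
# their roughness from moisture-induced clumping; here the same observable
# (radial deviation from contour circularity) is produced by a controllable
# radial displacement field, which gives every downstream stage a ground
# truth.

#' Specify one Gaussian surface bump
#'
#' A lump on the cone flank, modelled as a separable Gaussian radial
#' displacement centred at angle `theta_center` and altitude `z_center`:
#' `a * exp(-dtheta^2 / (2 sigma_theta^2) - (z - z_center)^2 / (2 sigma_z^2))`
#' with `dtheta` the wrapped angular distance.
#'
#' @param amplitude radial bump height, distance units (>= 0).
#' @param theta_center angular position, radians.
#' @param z_center altitude of the bump centre, distance units.
#' @param sigma_theta angular half-width, radians (> 0).
#' @param sigma_z vertical half-width, distance units (> 0).
#' @return a one-row data frame (row-bindable into a bump table).
#' @export
bump_spec <- function(amplitude, theta_center, z_center, sigma_theta,
                      sigma_z) {
  if (amplitude < 0) stop("bump amplitude must be >= 0")
  if (sigma_theta <= 0 || sigma_z <= 0) stop("bump widths must be > 0")
  data.frame(amplitude = amplitude, theta_center = theta_center,
             z_center = z_center, sigma_theta = sigma_theta,
             sigma_z = sigma_z)
}

cone_grid <- function(R0, H, n_theta, n_z) {
  if (R0 <= 0 || H <= 0) stop("R0 and H must be positive")
  if (n_theta < 8L) stop("n_theta must be >= 8")
  if (n_z < 4L) stop("n_z must be >= 4")
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  z <- H * (seq_len(n_z) - 1L) / n_z      # rings at i*H/n_z, i = 0..n_z-1
  list(theta = rep(theta, times = n_z),
       z = rep(z, each = n_theta),
       n_theta = as.integer(n_theta), n_z = as.integer(n_z))
}

cone_faces <- function(n_theta, n_z) {
  # quads between consecutive rings, split into two triangles, plus an apex
  # fan from the top ring; vertex layout: ring-major, apex last
  idx <- function(ring, j) (ring - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  j <- seq_len(n_theta)
  quads <- lapply(seq_len(n_z - 1L), function(ring) {
    a <- idx(ring, j); b <- idx(ring, j + 1L)
    c2 <- idx(ring + 1L, j + 1L); d <- idx(ring + 1L, j)
    rbind(cbind(a, b, c2), cbind(a, c2, d))
  })
  apex <- n_theta * n_z + 1L
  fan <- cbind(idx(n_z, j), idx(n_z, j + 1L), apex)
  faces <- do.call(rbind, c(quads, list(fan)))
  dimnames(faces) <- NULL
  faces
}

#' Generate an ideal (perfectly smooth) cone mesh
#'
#' Open lateral surface of a right circular cone: `n_z` rings of `n_theta`
#' vertices at altitudes `i * H / n_z` (i = 0..n_z-1), every ring-`i`
#' vertex exactly at radius `R0 * (1 - z_i / H)`, plus a single apex vertex
#' at (0, 0, H).  No base cap is generated; slicing only needs the flank.
#'
#' @param R0 base radius, distance units (> 0).
#' @param H height, distance units (> 0).
#' @param n_theta vertices per ring (>= 8).
#' @param n_z number of rings (>= 4).
#' @return a [triangle_mesh()] with `n_theta * n_z + 1` vertices.
#' @export
make_perfect_cone <- function(R0, H, n_theta = 192L, n_z = 96L) {
  make_lumpy_cone(synthetic_cone_spec(R0, H, n_theta, n_z, bumps = NULL))
}

#' Specify a synthetic lumpy cone
#'
#' @param R0,H,n_theta,n_z cone geometry, as in [make_perfect_cone()].
#' @param bumps a bump table ([bump_spec()] rows), or `NULL` for none.
#' @param seed optional integer recorded with the spec.
#' @return an object of class `synthetic_cone_spec`.
#' @export
synthetic_cone_spec <- function(R0, H, n_theta = 192L, n_z = 96L,
                                bumps = NULL, seed = NULL) {
  if (R0 <= 0 || H <= 0) stop("R0 and H must be positive")
  if (n_theta < 8L) stop("n_theta must be >= 8")
  if (n_z < 4L) stop("n_z must be >= 4")
  if (!is.null(bumps) && nrow(bumps) > 0L) {
    if (any(bumps$amplitude < 0)) stop("bump amplitude must be >= 0")
    if (any(bumps$sigma_theta <= 0) || any(bumps$sigma_z <= 0))
      stop("bump widths must be > 0")
    if (any(bumps$z_center < 0 | bumps$z_center > H))
      stop("bump z_center outside [0, H]")
  }
  structure(list(R0 = R0, H = H, n_theta = as.integer(n_theta),
                 n_z = as.integer(n_z), bumps = bumps, seed = seed),
            class = "synthetic_cone_spec")
}

#' Evaluate the radial displacement field of a bump table
#'
#' @param bumps bump table or `NULL`.
#' @param theta,z vectors of equal length (angle in radians, altitude).
#' @return vector of radial displacements (sum over bumps).
#' @export
bump_field <- function(bumps, theta, z) {
  disp <- numeric(length(theta))
  if (is.null(bumps) || nrow(bumps) == 0L) return(disp)
  for (i in seq_len(nrow(bumps))) {
    b <- bumps[i, ]
    dth <- (theta - b$theta_center + pi) %% (2 * pi) - pi
    disp <- disp + b$amplitude *
      exp(-dth^2 / (2 * b$sigma_theta^2) -
            (z - b$z_center)^2 / (2 * b$sigma_z^2))
  }
  disp
}

#' Generate a lumpy cone mesh
#'
#' The radius of the lateral surface is
#' `r(theta, z) = R0 (1 - z/H) + sum of Gaussian bumps`; an empty bump
#' table reproduces [make_perfect_cone()] exactly.
#'
#' @param spec a [synthetic_cone_spec()].
#' @return a [triangle_mesh()].
#' @export
make_lumpy_cone <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cone_spec"))
  g <- cone_grid(spec$R0, spec$H, spec$n_theta, spec$n_z)
  r <- spec$R0 * (1 - g$z / spec$H) + bump_field(spec$bumps, g$theta, g$z)
  verts <- rbind(cbind(r * cos(g$theta), r * sin(g$theta), g$z),
                 c(0, 0, spec$H))
  triangle_mesh(verts, cone_faces(g$n_theta, g$n_z))
}

# Roughness-class presets.  Bump count and amplitude grow with class; the
# angular width is set so a lump's effective arc extent (+/- 3 sigma) at
# its own altitude is ~10 distance units, matching the lump size the
# spectra should recover.  Altitudes are bottom-biased (Beta(1, 3) fraction
# of H): lumps roll down the heap.
class_presets <- list(
  list(count = c(0L, 2L), amp = c(0.02, 0.07)),   # class 0: original
  list(count = 6L,        amp = c(0.30, 0.70)),   # class 1: smooth
  list(count = 12L,       amp = c(0.70, 1.30)),   # class 2: medium
  list(count = 20L,       amp = c(1.30, 2.30))    # class 3: rough
)

#' Draw a graded synthetic powder-cone sample
#'
#' Seeded generator of one cone in roughness class 0 (original, nearly
#' smooth) to 3 (rough).  Bump count and amplitude grow with class
#' (preset means: 0-2 bumps <= 0.07; ~6 bumps ~0.5; ~12 bumps ~1.0;
#' ~20 bumps ~1.8 distance units); bump altitudes are Beta(1, 3)-biased
#' toward the base; the angular width targets a ~10-unit lump arc length.
#' Whole-milk samples get a slightly larger amplitude multiplier than trim
#' (fat promotes clumping); base radius and height are jittered by ~2% per
#' sample.  Fully reproducible for fixed `(class_id, powder_type, seed)`.
#'
#' @param class_id roughness class, 0..3.
#' @param powder_type `"trim"` or `"whole"`.
#' @param seed integer; drives all draws for this sample.
#' @param R0,H nominal base radius and height, distance units.
#' @param n_theta,n_z mesh resolution.
#' @param lump_arc target lump arc length, distance units (default 10).
#' @return a [triangle_mesh()] with attribute `"spec"` (the
#'   [synthetic_cone_spec()] used, including the drawn bump table).
#' @export
make_class_sample <- function(class_id, powder_type = c("trim", "whole"),
                              seed = 1L, R0 = 60, H = 42,
                              n_theta = 192L, n_z = 96L, lump_arc = 10) {
  powder_type <- match.arg(powder_type)
  if (!class_id %in% 0:3) stop("class_id must be 0, 1, 2 or 3")
  dseed <- (as.integer(seed) %% 10000019L) * 97L + as.integer(class_id) * 13L +
    (powder_type == "whole") * 7L
  preset <- class_presets[[class_id + 1L]]
  spec <- with_seed(dseed, {
    R0s <- R0 * (1 + 0.02 * stats::runif(1, -1, 1))
    Hs <- H * (1 + 0.02 * stats::runif(1, -1, 1))
    amp_mult <- if (powder_type == "whole") 1.05 else 1.0
    n <- if (length(preset$count) == 2L)
      sample(preset$count[1L]:preset$count[2L], 1L)
    else max(1L, stats::rpois(1L, preset$count))
    bumps <- NULL
    if (n > 0L) {
      zc <- Hs * stats::rbeta(n, 1, 3)
      rc <- pmax(R0s * (1 - zc / Hs), 2)
      bumps <- data.frame(
        amplitude = amp_mult * stats::runif(n, preset$amp[1L], preset$amp[2L]),
        theta_center = stats::runif(n, 0, 2 * pi),
        z_center = zc,
        sigma_theta = pmin(lump_arc / (6 * rc), pi / 4),
        sigma_z = stats::runif(n, 0.8, 1.2) * lump_arc / 6)
    }
    synthetic_cone_spec(R0s, Hs, n_theta, n_z, bumps, seed = dseed)
  })
  mesh <- make_lumpy_cone(spec)
  attr(mesh, "spec") <- spec
  mesh
}

#' Generate the full synthetic study set
#'
#' One cone per (class, powder type, replicate): 4 classes x 2 powder
#' types x `n_replicates`, the layout of a graded-sample study set.
#'
#' @param seed integer master seed; per-sample seeds are derived from it.
#' @param n_replicates replicates per class/type pair (default 3, giving
#'   24 cones).
#' @param ... passed to [make_class_sample()] (resolution, geometry).
#' @return a list with elements `meshes` (list of [triangle_mesh()]),
#'   `labels` (integer class per mesh) and `ids` (sample names).
#' @export
make_study_set <- function(seed = 1L, n_replicates = 3L, ...) {
  grid <- expand.grid(rep = seq_len(n_replicates),
                      type = c("trim", "whole"), class = 0:3,
                      stringsAsFactors = FALSE)
  meshes <- vector("list", nrow(grid))
  ids <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    srep <- (as.integer(seed) %% 1000003L) * 1009L + i
    meshes[[i]] <- make_class_sample(grid$class[i], grid$type[i],
                                     seed = srep, ...)
    ids[i] <- sprintf("class%d_%s_rep%d", grid$class[i], grid$type[i],
                      grid$rep[i])
  }
  list(meshes = meshes, labels = grid$class, ids = ids)
}
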