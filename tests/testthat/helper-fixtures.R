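# Fixtures are built in code: no mesh files ship with the tests.

# Axis-aligned unit cube [0,1]^3, 12 triangles with outward-facing normals.
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # faces by vertex index into the expand.grid order (x fastest)
  quads <- rbind(
    c(1, 3, 4, 2),   # z = 0 (bottom, viewed from below)
    c(5, 6, 8, 7),   # z = 1
    c(1, 2, 6, 5),   # y = 0
    c(3, 7, 8, 4),   # y = 1
    c(1, 5, 7, 3),   # x = 0
    c(2, 4, 8, 6))   # x = 1
  faces <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  triangle_mesh(v, faces)
}

# Closed contour sampled from an analytic polar curve r(theta).
analytic_contour <- function(rfun, n = 720, z = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  r <- rfun(th)
  contour_slice(cbind(r * cos(th), r * sin(th)), z = z)
}

# Independent O(M^2) DFT oracle: unnormalised forward transform,
# one-sided magnitudes at harmonics 1..M/2.
direct_dft_mag <- function(e) {
  M <- length(e)
  k <- seq_len(M %/% 2)
  j <- seq_len(M) - 1
  vapply(k, function(kk) {
    Mod(sum(e * exp(-2i * pi * kk * j / M)))
  }, 0)
}

# Brute-force trapezoid over an explicit (lambda, magnitude) table.
brute_trapz <- function(lam, mag) {
  o <- order(lam)
  lam <- lam[o]
  mag <- mag[o]
  s <- 0
  for (i in seq_len(length(lam) - 1)) {
    s <- s + (lam[i + 1] - lam[i]) * (mag[i] + mag[i + 1]) / 2
  }
  s
}

# Small cone defaults used across tests to keep runtimes down.
small_cone <- function(...) make_perfect_cone(10, 20, n_theta = 64, n_z = 32)
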