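test_that("circle fit is exact on noiseless circular data", {
  f1 <- fit_circle(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
  expect_equal(c(f1$cx, f1$cy), c(0, 0), tolerance = 1e-12)
  expect_equal(f1$R, 1, tolerance = 1e-12)

  th <- 2 * pi * (0:99) / 100
  pts <- cbind(3 + 7 * cos(th), -2 + 7 * sin(th))
  f2 <- fit_circle(pts)
  expect_equal(c(f2$cx, f2$cy, f2$R), c(3, -2, 7), tolerance = 1e-9)
  expect_lt(f2$rms_residual, 1e-9)

  sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  f3 <- fit_circle(sq)
  expect_equal(c(f3$cx, f3$cy), c(0, 0), tolerance = 1e-12)
  expect_equal(f3$R, sqrt(2), tolerance = 1e-12)

  expect_error(fit_circle(rbind(c(0, 0), c(1, 1))), ">= 3")
  expect_error(fit_circle(cbind(0:5, 0:5)), "collinear")
})

test_that("unwrap reproduces analytic deviations and validates its grid", {
  # exact circle: deviations vanish
  circ <- analytic_contour(function(th) rep(5, length(th)), n = 360)
  prof0 <- unwrap(circ, fit_circle(circ))
  expect_lt(max(abs(prof0$e)), 1e-9)
  expect_lt(abs(mean(prof0$e)), 1e-9)

  # r(theta) = 10 + 0.5 cos(4 theta): deviation is -0.5 cos(4 theta)
  cont <- analytic_contour(function(th) 10 + 0.5 * cos(4 * th), n = 720)
  fit <- fit_circle(cont)
  prof <- unwrap(cont, fit, M = 512)
  expect_lt(max(abs(prof$e + 0.5 * cos(4 * prof$theta))), 1e-3)
  expect_lt(abs(mean(prof$e)), 1e-9)
  expect_equal(prof$P, 2 * pi * fit$R)
  expect_equal(prof$s, prof$theta * fit$R)

  expect_error(unwrap(cont, fit, M = 100), "power of two")
  expect_error(unwrap(cont, fit, M = 8), "power of two")
})

test_that("unwrap averages duplicate angles", {
  # three distinct angles plus a duplicated angle with a different radius
  th <- c(0, 0, pi / 2, pi, 3 * pi / 2)
  r <- c(4, 6, 5, 5, 5)
  cs <- contour_slice(cbind(r * cos(th), r * sin(th)), z = 1,
                      validate = FALSE)
  fit <- structure(list(cx = 0, cy = 0, R = 5, rms_residual = 0),
                   class = "circle_fit")
  prof <- unwrap(cs, fit, M = 16)
  expect_equal(prof$r[1], 5)     # mean of 4 and 6 at theta = 0
})

test_that("spectrum matches the closed-form DFT of a pure cosine", {
  M <- 512L
  theta <- 2 * pi * (seq_len(M) - 1L) / M
  prof <- structure(list(theta = theta, r = 10 - cos(8 * theta),
                         e = cos(8 * theta), R = 10, P = 2 * pi * 10,
                         s = theta * 10, z = 1, layer_index = 0L),
                    class = "deviation_profile")
  sp <- spectrum(prof)
  expect_equal(sp$mag[8], M / 2, tolerance = 1e-9)
  expect_lt(max(sp$mag[-8]), 1e-9)
  expect_equal(sp$lam, sp$P / sp$k)
  expect_equal(sp$beta, 1 / sp$lam)
  expect_true(all(diff(sp$lam) < 0))

  # linearity: doubling e doubles every magnitude
  prof2 <- prof
  prof2$e <- 2 * prof2$e
  expect_equal(spectrum(prof2)$mag, 2 * sp$mag, tolerance = 1e-12)

  # null signal
  prof0 <- prof
  prof0$e <- numeric(M)
  expect_true(all(spectrum(prof0)$mag == 0))
})

test_that("FFT spectrum equals the direct O(M^2) DFT", {
  set.seed(31)
  for (M in c(64L, 512L)) {
    theta <- 2 * pi * (seq_len(M) - 1L) / M
    e <- stats::rnorm(M)
    e <- e - mean(e)
    prof <- structure(list(theta = theta, r = 10 - e, e = e, R = 10,
                           P = 2 * pi * 10, s = theta * 10, z = 1,
                           layer_index = 0L),
                      class = "deviation_profile")
    expect_lt(max(abs(spectrum(prof)$mag - direct_dft_mag(e))), 1e-8)
  }
})

test_that("one-sided magnitudes satisfy Parseval's identity", {
  set.seed(17)
  M <- 256L
  theta <- 2 * pi * (seq_len(M) - 1L) / M
  e <- stats::rnorm(M)
  e <- e - mean(e)
  prof <- structure(list(theta = theta, r = 10 - e, e = e, R = 10,
                         P = 2 * pi * 10, s = theta * 10, z = 1,
                         layer_index = 0L),
                    class = "deviation_profile")
  sp <- spectrum(prof)
  # unnormalised one-sided convention: interior bins appear twice in the
  # two-sided sum, Nyquist once, DC is zero after centring
  lhs <- 2 * sum(sp$mag[seq_len(M / 2 - 1)]^2) + sp$mag[M / 2]^2
  expect_equal(lhs, M * sum(e^2), tolerance = 1e-8)
  # which ties layer_std to the spectrum
  expect_equal(layer_std(prof), sqrt(sum(e^2) / M), tolerance = 1e-12)
})

test_that("Q is a band-restricted trapezoid with the expected properties", {
  M <- 512L
  theta <- 2 * pi * (seq_len(M) - 1L) / M
  prof <- structure(list(theta = theta, r = 10 - cos(8 * theta),
                         e = cos(8 * theta), R = 10, P = 2 * pi * 10,
                         s = theta * 10, z = 1, layer_index = 0L),
                    class = "deviation_profile")
  sp <- spectrum(prof)

  # brute-force oracle over the same restricted lambda table
  sel <- sp$lam >= 2 * sp$P / M & sp$lam <= sp$P / 2
  expect_equal(compute_Q(sp), brute_trapz(sp$lam[sel], sp$mag[sel]),
               tolerance = 1e-12)

  # linearity of the integral
  prof2 <- prof
  prof2$e <- 2 * prof2$e
  expect_equal(compute_Q(spectrum(prof2)), 2 * compute_Q(sp),
               tolerance = 1e-12)

  # zero spectrum -> Q = 0
  prof0 <- prof
  prof0$e <- numeric(M)
  expect_equal(compute_Q(spectrum(prof0)), 0)

  # band handling
  expect_error(compute_Q(sp, lam_min = 5, lam_max = 4), "lam_min")
  expect_error(compute_Q(sp, lam_min = 1000, lam_max = 2000), "empty")
  # band excluding the k = 8 line removes essentially all energy
  expect_lt(compute_Q(sp, lam_min = 1, lam_max = 5), 1e-9)
})

test_that("layer_std matches closed forms and ignores DC offsets", {
  M <- 256L
  theta <- 2 * pi * (seq_len(M) - 1L) / M
  mkprof <- function(e) structure(
    list(theta = theta, r = 10 - e, e = e - mean(e), R = 10,
         P = 2 * pi * 10, s = theta * 10, z = 1, layer_index = 0L),
    class = "deviation_profile")
  expect_equal(layer_std(mkprof(numeric(M))), 0)
  expect_equal(layer_std(mkprof(cos(theta))), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(layer_std(mkprof(cos(theta) + 7)), 1 / sqrt(2),
               tolerance = 1e-12)
})

test_that("Q increases strictly with bump amplitude", {
  amps <- c(0.25, 0.5, 1, 1.5, 2)
  for (s in 1:5) {
    set.seed(s)
    th0 <- runif(1, 0, 2 * pi)
    qs <- vapply(amps, function(a) {
      cont <- analytic_contour(function(th) {
        d <- (th - th0 + pi) %% (2 * pi) - pi
        30 + a * exp(-d^2 / (2 * 0.06^2))
      }, n = 720)
      compute_Q(spectrum(unwrap(cont, fit_circle(cont))))
    }, 0)
    expect_true(all(diff(qs) > 0), info = paste("seed", s))
  }
})

test_that("dominant wavelength recovers the generating lump arc length", {
  set.seed(42)
  ratios <- replicate(20, {
    R <- runif(1, 20, 40)
    nb <- sample(3:12, 1)
    th0 <- runif(nb, 0, 2 * pi)
    amp <- runif(nb, 0.5, 2)
    arc <- 10
    st <- arc / (6 * R)                    # +/- 3 sigma spans the arc
    cont <- analytic_contour(function(th) {
      r <- rep(R, length(th))
      for (i in seq_len(nb)) {
        d <- (th - th0[i] + pi) %% (2 * pi) - pi
        r <- r + amp[i] * exp(-d^2 / (2 * st^2))
      }
      r
    }, n = 720)
    sp <- spectrum(unwrap(cont, fit_circle(cont)))
    dominant_wavelength(sp) / arc
  })
  expect_true(all(ratios > 0.5 & ratios < 2))
})

test_that("perfect-cone layers sit below the analytic tessellation floor", {
  n_theta <- 96L
  m <- make_perfect_cone(60, 42, n_theta, 48)
  slices <- slice_mesh(m, 10)
  for (cs in slices) {
    fit <- fit_circle(cs)
    q <- compute_Q(spectrum(unwrap(cs, fit)))
    expect_lt(q, tessellation_noise_floor(fit$R, n_theta))
  }
})
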