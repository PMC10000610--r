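# The per-layer roughness mathematics: least-squares circle fit, deviation
# unwrapping e(theta) = R - r(theta), uniform-grid resampling, FFT over
# spatial wavelength, the Q energy statistic, and per-layer standard
# deviation.

#' Least-squares circle fit
#'
#' Kasa algebraic fit: linear least squares on the circle equation
#' `x^2 + y^2 = 2 cx x + 2 cy y + c`, solved in closed form.  Exact on
#' noiseless circular data; deterministic.
#'
#' @param points numeric matrix of (x, y) coordinates (>= 3 non-collinear
#'   points) or a [contour_slice()].
#' @return an object of class `circle_fit` with `cx`, `cy`, `R` and
#'   `rms_residual` (root-mean-square radial residual).
#' @export
fit_circle <- function(points) {
  if (inherits(points, "contour_slice")) points <- points$points
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("circle fit needs >= 3 points")
  x <- points[, 1L]
  y <- points[, 2L]
  A <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  dec <- qr(A)
  if (dec$rank < 3L) stop("collinear points: circle fit is singular")
  sol <- qr.coef(dec, rhs)
  cx <- sol[1L]
  cy <- sol[2L]
  R2 <- sol[3L] + cx^2 + cy^2
  if (R2 <= 0) stop("circle fit produced non-positive radius")
  R <- sqrt(R2)
  rad <- sqrt((x - cx)^2 + (y - cy)^2)
  structure(list(cx = unname(cx), cy = unname(cy), R = unname(R),
                 rms_residual = sqrt(mean((rad - R)^2))),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("circle_fit: center (%.6g, %.6g), R = %.6g, rms residual %.3g\n",
              x$cx, x$cy, x$R, x$rms_residual))
  invisible(x)
}

#' Unwrap a contour into a radial deviation profile
#'
#' Expresses the contour as radius vs angle around the fitted circle
#' centre (counterclockwise from +x), resamples the radius onto `M`
#' uniform angles by periodic linear interpolation, and forms the
#' mean-centred deviation `e = (R - r) - mean(R - r)`.  Duplicate angles
#' (non-star-shaped lumps make r(theta) multi-valued) are averaged after
#' sorting.
#'
#' @param contour a [contour_slice()].
#' @param fit the [fit_circle()] result for this contour.
#' @param M uniform grid size; a power of two >= 16 (default 512).
#' @return an object of class `deviation_profile` with `theta` (M uniform
#'   angles in `[0, 2*pi)`), `r` (resampled radii), `e` (centred
#'   deviations), `R`, `P = 2*pi*R` (perimeter of the fitted circle), `s =
#'   theta * R` (linear arc positions), `z` and `layer_index`.
#' @export
unwrap <- function(contour, fit, M = 512L) {
  stopifnot(inherits(contour, "contour_slice"), inherits(fit, "circle_fit"))
  if (!is_power_of_two(M) || M < 16L)
    stop("M must be a power of two >= 16")
  M <- as.integer(M)
  if (nrow(contour$points) < 3L) stop("contour needs >= 3 points")
  dx <- contour$points[, 1L] - fit$cx
  dy <- contour$points[, 2L] - fit$cy
  th <- atan2(dy, dx) %% (2 * pi)
  r <- sqrt(dx^2 + dy^2)
  o <- order(th)
  th <- th[o]
  r <- r[o]
  grp <- cumsum(c(TRUE, diff(th) > 1e-12))
  if (max(grp) < length(th)) {
    r <- as.numeric(tapply(r, grp, mean))
    th <- as.numeric(tapply(th, grp, function(v) v[1L]))
  }
  if (length(th) < 3L) stop("fewer than 3 distinct angles on contour")
  # periodic wraparound for the interpolation
  thx <- c(th[length(th)] - 2 * pi, th, th[1L] + 2 * pi)
  rx <- c(r[length(r)], r, r[1L])
  grid <- 2 * pi * (seq_len(M) - 1L) / M
  rg <- stats::approx(thx, rx, xout = grid, method = "linear")$y
  e <- fit$R - rg
  e <- e - mean(e)
  structure(list(theta = grid, r = rg, e = e, R = fit$R, P = 2 * pi * fit$R,
                 s = grid * fit$R, z = contour$z,
                 layer_index = contour$layer_index),
            class = "deviation_profile")
}

#' @export
print.deviation_profile <- function(x, ...) {
  cat(sprintf(
    "deviation_profile: layer %s, M = %d, R = %.5g, sd(e) = %.4g\n",
    ifelse(is.na(x$layer_index), "?", x$layer_index), length(x$e), x$R,
    layer_std(x)))
  invisible(x)
}

#' One-sided roughness spectrum of a deviation profile
#'
#' Unnormalised forward FFT of `e`; one-sided magnitudes at harmonics
#' k = 1..M/2.  DC is excluded (it is ~0 after mean-centring) and neither
#' the DC nor the Nyquist magnitude receives a one-sided doubling
#' adjustment.  Each harmonic maps to spatial wavelength
#' `lambda_k = P / k` (distance units along the fitted-circle perimeter P)
#' and spatial frequency `beta_k = k / P = 1 / lambda_k`.
#'
#' @param profile a [unwrap()] result.
#' @return an object of class `roughness_spectrum` with `k`, `beta`,
#'   `lam`, `mag`, `P`, `M`, `z`, `layer_index`.
#' @export
spectrum <- function(profile) {
  stopifnot(inherits(profile, "deviation_profile"))
  M <- length(profile$e)
  X <- stats::fft(profile$e)
  k <- seq_len(M %/% 2L)
  structure(list(k = k, beta = k / profile$P, lam = profile$P / k,
                 mag = Mod(X)[k + 1L], P = profile$P, M = M,
                 z = profile$z, layer_index = profile$layer_index),
            class = "roughness_spectrum")
}

#' @export
print.roughness_spectrum <- function(x, ...) {
  cat(sprintf(
    "roughness_spectrum: layer %s, M = %d, P = %.5g, Q(default band) = %.5g\n",
    ifelse(is.na(x$layer_index), "?", x$layer_index), x$M, x$P, compute_Q(x)))
  invisible(x)
}

#' Roughness energy Q of a spectrum
#'
#' `Q = integral of |FFT(e)| over wavelength`, evaluated by trapezoidal
#' integration of the one-sided magnitudes over the (non-uniform)
#' wavelength grid, restricted to `[lam_min, lam_max]`.  The default band
#' `[2P/M, P/2]` abridges the wavelength axis: it drops the k = 1
#' fundamental (ellipse-like centring drift, not lumpiness) and keeps all
#' shorter wavelengths down to twice the grid pitch.
#'
#' @param spec a [spectrum()] result.
#' @param lam_min,lam_max wavelength band, distance units; defaults
#'   `2 * P / M` and `P / 2`.
#' @return the scalar Q (>= 0).
#' @export
compute_Q <- function(spec, lam_min = NULL, lam_max = NULL) {
  stopifnot(inherits(spec, "roughness_spectrum"))
  if (is.null(lam_min)) lam_min <- 2 * spec$P / spec$M
  if (is.null(lam_max)) lam_max <- spec$P / 2
  if (lam_min >= lam_max) stop("lam_min must be < lam_max")
  sel <- spec$lam >= lam_min & spec$lam <= lam_max
  if (!any(sel)) stop("empty wavelength band: no harmonics inside")
  lam <- rev(spec$lam[sel])            # ascending wavelength
  mag <- rev(spec$mag[sel])
  if (length(lam) == 1L) return(0)
  sum(diff(lam) * (mag[-1L] + mag[-length(mag)]) / 2)
}

#' Per-layer standard deviation of the deviation profile
#'
#' Population standard deviation of the centred deviations `e` on the
#' uniform grid, `sqrt(mean(e^2))`.
#'
#' @param profile a [unwrap()] result.
#' @return scalar standard deviation.
#' @export
layer_std <- function(profile) {
  stopifnot(inherits(profile, "deviation_profile"))
  sqrt(mean(profile$e^2))
}

#' Dominant wavelength of a roughness spectrum
#'
#' Summarises where in the wavelength axis the spectral energy sits.  The
#' default `"centroid"` method returns `P / kbar` with `kbar` the
#' magnitude-weighted mean harmonic index over the band: for lump-like
#' (Gaussian) deviations, whose magnitude envelope decays monotonically
#' with harmonic index, this recovers the lump arc length to within a
#' factor ~1.3, whereas the literal in-band argmax (`method = "argmax"`,
#' also provided) sits at the long-wavelength band edge for any smooth
#' monotone envelope and is only informative for narrowband deviations.
#'
#' @param spec a [spectrum()] result.
#' @param lam_min,lam_max band, defaults as in [compute_Q()].
#' @param method `"centroid"` (default) or `"argmax"`.
#' @return dominant wavelength, distance units.
#' @export
dominant_wavelength <- function(spec, lam_min = NULL, lam_max = NULL,
                                method = c("centroid", "argmax")) {
  stopifnot(inherits(spec, "roughness_spectrum"))
  method <- match.arg(method)
  if (is.null(lam_min)) lam_min <- 2 * spec$P / spec$M
  if (is.null(lam_max)) lam_max <- spec$P / 2
  sel <- spec$lam >= lam_min & spec$lam <= lam_max
  if (!any(sel)) stop("empty wavelength band: no harmonics inside")
  k <- spec$k[sel]
  mag <- spec$mag[sel]
  if (sum(mag) <= 0) return(NA_real_)
  if (method == "argmax") spec$P / k[which.max(mag)]
  else spec$P / (sum(k * mag) / sum(mag))
}

#' Upper bound on the tessellation noise floor of an ideal cone
#'
#' A perfect cone meshed with `n_theta` vertices per ring yields polygonal
#' contours whose radial deviation from the fitted circle is bounded by
#' the chord sagitta `R (1 - cos(pi / n_theta))`.  Bounding every FFT
#' magnitude by `M * max|e|` and the band integral by the band width gives
#' a conservative analytic ceiling on the per-layer Q that pure
#' tessellation can produce.
#'
#' @param R contour radius at the layer, distance units.
#' @param n_theta mesh vertices per ring.
#' @param M resampling grid size.
#' @param lam_min,lam_max integration band; defaults as in [compute_Q()]
#'   with `P = 2*pi*R`.
#' @return upper bound on Q, same units as [compute_Q()].
#' @export
tessellation_noise_floor <- function(R, n_theta, M = 512L,
                                     lam_min = NULL, lam_max = NULL) {
  P <- 2 * pi * R
  if (is.null(lam_min)) lam_min <- 2 * P / M
  if (is.null(lam_max)) lam_max <- P / 2
  sagitta <- R * (1 - cos(pi / n_theta))
  M * sagitta * (lam_max - lam_min)
}

#' Plot a deviation profile
#'
#' Deviation `e` against linear arc position `s = theta * R`.
#'
#' @param x a `deviation_profile`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.deviation_profile <- function(x, ...) {
  graphics::plot(x$s, x$e, type = "l", xlab = "arc position s (distance units)",
                 ylab = "deviation e (distance units)", ...)
  invisible(x)
}

#' Plot a roughness spectrum
#'
#' FFT magnitude against wavelength, log-log axes.
#'
#' @param x a `roughness_spectrum`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.roughness_spectrum <- function(x, ...) {
  keep <- x$mag > 0
  graphics::plot(x$lam[keep], x$mag[keep], type = "l", log = "xy",
                 xlab = "wavelength (distance units)",
                 ylab = "|FFT(e)|", ...)
  invisible(x)
}
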