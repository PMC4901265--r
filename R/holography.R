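# Angular-spectrum holography engine: free-space propagation, autofocus,
# transport-of-intensity initialization, multi-height iterative phase
# recovery, and tilted-plane (rotational field transform) correction.
#
# Units: lateral distances and z in micrometres, wavelengths in nanometres.

#' Construct a complex optical wavefront
#'
#' @param values 2D complex (or real) matrix of field amplitudes.
#' @param pitch_um Sampling pitch in micrometres (> 0).
#' @param wavelength_nm Illumination wavelength in nanometres (> 0).
#' @param n_medium Refractive index of the propagation medium.
#' @return Object of class `complex_field`.
#' @export
complex_field <- function(values, pitch_um, wavelength_nm, n_medium = 1) {
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("field values must be finite")
  if (pitch_um <= 0) stop("pitch_um must be positive")
  if (wavelength_nm <= 0) stop("wavelength_nm must be positive")
  structure(list(values = values + 0i, pitch_um = pitch_um,
                 wavelength_nm = wavelength_nm, n_medium = n_medium),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field %dx%d, pitch %.3g um, lambda %.4g nm, n=%.3g>\n",
              nrow(x$values), ncol(x$values), x$pitch_um, x$wavelength_nm,
              x$n_medium))
  invisible(x)
}

#' Construct an in-line hologram measurement
#'
#' @param intensity 2D non-negative real matrix.
#' @param z2_um Sample-to-sensor distance in micrometres.
#' @inheritParams complex_field
#' @return Object of class `hologram`.
#' @export
hologram <- function(intensity, z2_um, wavelength_nm, pitch_um) {
  if (any(intensity < 0)) stop("hologram intensity must be non-negative")
  structure(list(intensity = intensity, z2_um = z2_um,
                 wavelength_nm = wavelength_nm, pitch_um = pitch_um),
            class = "hologram")
}

#' Build a z-sorted stack of holograms
#'
#' @param holograms List of [hologram()] objects with strictly increasing
#'   `z2_um`.
#' @return Object of class `hologram_stack`.
#' @export
hologram_stack <- function(holograms) {
  z <- vapply(holograms, function(h) h$z2_um, numeric(1))
  if (any(diff(z) <= 0))
    stop("holograms must be sorted by strictly increasing z2_um")
  if (any(vapply(holograms, function(h) any(!is.finite(h$intensity)), logical(1))))
    stop("hologram intensities contain non-finite values")
  structure(list(holograms = holograms, z2_um = z), class = "hologram_stack")
}

# fft frequencies in cycles/um for even or odd n
.fftfreq <- function(n, pitch) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * pitch)
}

# pad to next even size with edge replication; returns padded matrix + dims
.pad_even <- function(m) {
  nr <- nrow(m) + nrow(m) %% 2
  nc <- ncol(m) + ncol(m) %% 2
  m[pmin(seq_len(nr), nrow(m)), pmin(seq_len(nc), ncol(m)), drop = FALSE]
}

.fft2 <- function(m) stats::fft(m)
.ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

#' Angular-spectrum free-space propagation
#'
#' Fourier transforms the field, multiplies its angular spectrum by the
#' transfer function exp(i 2 pi dz sqrt((n/lambda)^2 - fx^2 - fy^2)) on the
#' propagating band, zeroes the evanescent components, and inverse
#' transforms. Energy on the propagating band is conserved.
#'
#' @param f A [complex_field()].
#' @param dz_um Signed propagation distance in micrometres.
#' @return A propagated `complex_field`.
#' @export
angular_spectrum_propagate <- function(f, dz_um) {
  if (!is.finite(dz_um)) stop("dz_um must be finite")
  v <- f$values
  odim <- dim(v)
  v <- .pad_even(v)
  lam <- f$wavelength_nm / 1000
  nu <- f$n_medium / lam                       # cycles/um
  fx <- .fftfreq(nrow(v), f$pitch_um)
  fy <- .fftfreq(ncol(v), f$pitch_um)
  arg <- nu^2 - outer(fx^2, fy^2, `+`)
  H <- matrix(0 + 0i, nrow(v), ncol(v))
  prop <- arg > 0
  H[prop] <- exp(2i * pi * dz_um * sqrt(arg[prop]))
  out <- .ifft2(.fft2(v) * H)
  out <- out[seq_len(odim[1]), seq_len(odim[2]), drop = FALSE]
  complex_field(out, f$pitch_um, f$wavelength_nm, f$n_medium)
}

# Tamura coefficient of the gradient magnitude of an amplitude image:
# sharp, in-focus reconstructions maximize it.
.tamura_sharpness <- function(amp) {
  gx <- amp[-1, , drop = FALSE] - amp[-nrow(amp), , drop = FALSE]
  gy <- amp[, -1, drop = FALSE] - amp[, -ncol(amp), drop = FALSE]
  g <- sqrt(gx[, -ncol(gx), drop = FALSE]^2 + gy[-nrow(gy), , drop = FALSE]^2)
  m <- mean(g)
  if (m <= 0) return(0)
  sqrt(stats::sd(g) / m)
}

#' Autofocus: estimate the sample-to-sensor distance of a hologram
#'
#' Back-propagates sqrt(intensity) over a coarse grid of candidate distances,
#' evaluates a sharpness criterion on the amplitude, then refines around the
#' coarse argmax with golden-section/parabolic search.
#'
#' @param h A [hologram()] (its `z2_um` is ignored; that is what is being
#'   estimated).
#' @param z_range Numeric `c(zmin, zmax)` search interval in micrometres.
#' @param steps Number of coarse-grid evaluations (default 21).
#' @param criterion Sharpness function of an amplitude matrix (default the
#'   Tamura coefficient of the gradient magnitude).
#' @param region Optional `list(rows =, cols =)` restricting the criterion to
#'   a sub-region (used for per-region focus in tilt estimation).
#' @return Estimated focus distance in micrometres.
#' @export
autofocus <- function(h, z_range, steps = 21, criterion = .tamura_sharpness,
                      region = NULL) {
  if (z_range[1] >= z_range[2]) stop("z_range must satisfy zmin < zmax")
  if (stats::sd(h$intensity) == 0)
    stop("hologram is constant; no focus can be found")
  f0 <- complex_field(sqrt(h$intensity), h$pitch_um, h$wavelength_nm)
  score <- function(z) {
    a <- Mod(angular_spectrum_propagate(f0, -z)$values)
    if (!is.null(region)) a <- a[region$rows, region$cols, drop = FALSE]
    criterion(a)
  }
  zg <- seq(z_range[1], z_range[2], length.out = steps)
  sg <- vapply(zg, score, numeric(1))
  i <- which.max(sg)
  lo <- zg[max(i - 1, 1)]
  hi <- zg[min(i + 1, steps)]
  stats::optimize(score, c(lo, hi), maximum = TRUE,
                  tol = 0.2)$maximum
}

#' Initial phase estimate from the transport of intensity equation
#'
#' Uses two holograms of the stack (by default the first and last): the
#' axial intensity derivative is approximated by their finite difference and
#' inverted through a regularized Fourier-domain Poisson solve, assuming a
#' slowly varying intensity. The returned phase map is zero-mean.
#'
#' @param h1,h2 [hologram()]s sharing shape, wavelength and pitch, with
#'   `z2_um(h2) > z2_um(h1)`.
#' @param eps Regularization of the Poisson inversion as a fraction of the
#'   maximum squared transverse frequency (default 1e-3).
#' @return Real zero-mean phase matrix in radians.
#' @export
tie_initial_phase <- function(h1, h2, eps = 1e-3) {
  if (!identical(dim(h1$intensity), dim(h2$intensity)))
    stop("holograms must share dimensions")
  if (h1$wavelength_nm != h2$wavelength_nm || h1$pitch_um != h2$pitch_um)
    stop("holograms must share wavelength and pitch")
  dz <- h2$z2_um - h1$z2_um
  if (dz == 0) stop("holograms are at the same height (dz = 0)")
  lam <- h1$wavelength_nm / 1000
  k <- 2 * pi / lam
  ibar <- mean((h1$intensity + h2$intensity) / 2)
  didz <- (h2$intensity - h1$intensity) / dz
  fx <- .fftfreq(nrow(didz), h1$pitch_um)
  fy <- .fftfreq(ncol(didz), h1$pitch_um)
  k2 <- 4 * pi^2 * outer(fx^2, fy^2, `+`)
  k2reg <- pmax(k2, eps * max(k2))
  # solve  laplacian(phi) = -k * dI/dz / Ibar
  rhs <- -k * didz / ibar
  phi <- Re(.ifft2(.fft2(rhs) / (-k2reg)))
  phi - mean(phi)
}

#' Multi-height iterative phase recovery
#'
#' Starting from sqrt(first intensity) with an initial phase guess, the
#' field is propagated through the z-sorted measurement planes in forward
#' and backward sweeps; at each plane the amplitude is replaced by the
#' average of the current guess and the square root of the measurement,
#' keeping the phase. After convergence (RMS amplitude change below `tol`,
#' capped at `max_sweeps` sweeps) the field at a chosen plane is
#' back-propagated to the object plane.
#'
#' @param s A [hologram_stack()] with at least one plane.
#' @param init_phase Initial phase matrix (default all zeros; use
#'   [tie_initial_phase()] on the first/last planes for a better start).
#' @param max_sweeps Sweep cap (default 20).
#' @param tol Early-stop threshold on the RMS change of the plane-1
#'   amplitude between sweeps (default 1e-4).
#' @param tilt Optional [fit_tilt_plane()] result: each amplitude update is
#'   then performed on the sensor-parallel rotated field and rotated back.
#' @param final_plane Index of the plane whose converged field is
#'   back-propagated to the object plane (default 1, the closest).
#' @return A `complex_field` at the object plane, with attributes
#'   `rms_history` (per-sweep RMS amplitude change) and `sweeps`.
#' @export
multiheight_phase_recovery <- function(s, init_phase = NULL, max_sweeps = 20,
                                       tol = 1e-4, tilt = NULL,
                                       final_plane = 1) {
  if (!inherits(s, "hologram_stack")) stop("s must be a hologram_stack")
  hs <- s$holograms
  K <- length(hs)
  h1 <- hs[[1]]
  if (is.null(init_phase)) init_phase <- matrix(0, nrow(h1$intensity), ncol(h1$intensity))
  amp <- vector("list", K)
  for (k in seq_len(K)) amp[[k]] <- sqrt(hs[[k]]$intensity)
  tilted <- !is.null(tilt) &&
    (abs(tilt$theta_x_deg) > 0 || abs(tilt$theta_y_deg) > 0)
  to_obj <- function(f) if (tilted) rotate_field(f, .neg_tilt(tilt)) else f
  to_sen <- function(f) if (tilted) rotate_field(f, tilt) else f
  update <- function(f, k) {
    # amplitude constraint applied in the sensor-parallel frame; only the
    # correction is rotated back, so the interpolation error of the
    # rotational transform scales with the (shrinking) update, not with the
    # field itself
    v <- to_sen(f)
    v2 <- v
    v2$values <- (Mod(v$values) + amp[[k]]) / 2 * exp(1i * Arg(v$values))
    if (!tilted) return(v2)
    dv <- v2
    dv$values <- v2$values - v$values
    f$values <- f$values + to_obj(dv)$values
    f
  }
  # the zero/TIE-phase starting guess is used as-is in the object frame:
  # rotating a field whose phase is not yet physical only injects noise
  f <- complex_field(amp[[1]] * exp(1i * init_phase),
                     h1$pitch_um, h1$wavelength_nm)
  prev_a1 <- Mod(f$values)
  rms_hist <- numeric(0)
  misfit_hist <- numeric(0)
  sweeps <- 0
  if (K >= 2) {
    for (sw in seq_len(max_sweeps)) {
      for (k in 2:K)
        f <- update(angular_spectrum_propagate(f, s$z2_um[k] - s$z2_um[k - 1]), k)
      for (k in (K - 1):1)
        f <- update(angular_spectrum_propagate(f, s$z2_um[k] - s$z2_um[k + 1]), k)
      a1 <- Mod(f$values)
      rms_hist <- c(rms_hist, sqrt(mean((a1 - prev_a1)^2)))
      misfit_hist <- c(misfit_hist, sum((a1 - amp[[1]])^2))
      prev_a1 <- a1
      sweeps <- sw
      if (rms_hist[sw] < tol) break
    }
  }
  if (final_plane != 1)
    for (k in 2:final_plane)
      f <- update(angular_spectrum_propagate(f, s$z2_um[k] - s$z2_um[k - 1]), k)
  obj <- angular_spectrum_propagate(f, -s$z2_um[final_plane])
  attr(obj, "rms_history") <- rms_hist
  attr(obj, "misfit_history") <- misfit_hist
  attr(obj, "sweeps") <- sweeps
  obj
}

#' Fit a tilt plane to per-region focus distances
#'
#' Least-squares plane z = a x + b y + c through autofocused control points;
#' the slopes give the tilt angles of the object plane relative to the
#' sensor.
#'
#' @param points Data frame or matrix with columns `x_um`, `y_um`, `z_um`
#'   (at least 3 non-collinear points).
#' @return Object of class `tilt_plane` with `theta_x_deg`, `theta_y_deg`,
#'   `z0_um`, `residuals_um` and `fitted_um`.
#' @export
fit_tilt_plane <- function(points) {
  p <- as.data.frame(points)
  names(p)[1:3] <- c("x_um", "y_um", "z_um")
  if (nrow(p) < 3) stop("need at least 3 points")
  X <- cbind(1, p$x_um, p$y_um)
  if (qr(X)$rank < 3) stop("control points are collinear; plane fit is rank-deficient")
  cf <- qr.solve(X, p$z_um)
  fitted <- drop(X %*% cf)
  tp <- structure(list(theta_x_deg = atan(cf[2]) * 180 / pi,
                       theta_y_deg = atan(cf[3]) * 180 / pi,
                       z0_um = cf[1],
                       residuals_um = p$z_um - fitted,
                       fitted_um = fitted),
                  class = "tilt_plane")
  if (max(abs(c(tp$theta_x_deg, tp$theta_y_deg))) >= 45)
    stop("fitted tilt exceeds 45 degrees; not a plausible object tilt")
  tp
}

#' Construct a tilt plane from angles
#'
#' @param theta_x_deg,theta_y_deg Tilt angles (degrees) of the object plane
#'   along x and y.
#' @return Object of class `tilt_plane`.
#' @export
tilt_plane <- function(theta_x_deg = 0, theta_y_deg = 0) {
  if (max(abs(c(theta_x_deg, theta_y_deg))) >= 45)
    stop("|tilt| must be below 45 degrees")
  structure(list(theta_x_deg = theta_x_deg, theta_y_deg = theta_y_deg,
                 z0_um = 0, residuals_um = numeric(0), fitted_um = numeric(0)),
            class = "tilt_plane")
}

.neg_tilt <- function(t) tilt_plane(-t$theta_x_deg, -t$theta_y_deg)

# Rotate the angular spectrum about one axis: remap the transverse frequency
# along `axis` (1 = fx, 2 = fy) onto the rotated plane's grid with cubic
# spline interpolation and Jacobian weighting. Two numerical safeguards make
# this usable on hologram-like fields: (1) the content is circularly shifted
# so its energy centroid sits at the coordinate origin, removing the
# near-Nyquist linear phase that would defeat the interpolation (the
# rotation axis then passes through the content); (2) a dominant uniform
# background (the unscattered reference wave) is split off and rotated
# analytically -- a rotated plane wave is an off-grid spectral delta that no
# interpolation can represent -- while only the scattered part goes through
# the spectral remap.
.rotate_axis <- function(f, theta_rad, axis, pad = 2) {
  if (theta_rad == 0) return(f)
  v <- .pad_even(f$values)
  odim <- dim(f$values)
  n0 <- dim(v)
  c0 <- mean(v)
  split_bg <- Mod(c0) > sqrt(mean(Mod(v - c0)^2))
  if (split_bg) v <- v - c0
  shift2 <- function(m, s) {
    m[((seq_len(nrow(m)) - 1 + s[1]) %% nrow(m)) + 1,
      ((seq_len(ncol(m)) - 1 + s[2]) %% ncol(m)) + 1, drop = FALSE]
  }
  # energy centroid on the circle (first Fourier moment), 0-based index
  circ_centroid <- function(w) {
    n <- length(w)
    m1 <- sum(w * exp(-2i * pi * (seq_len(n) - 1) / n))
    if (Mod(m1) < 1e-12 * sum(w)) 0L else (round(-Arg(m1) / (2 * pi) * n) %% n)
  }
  # 1) make the content a contiguous block centered mid-grid, 2) zero-pad,
  # 3) shift the content centroid to the origin sample: the spectrum then
  # carries no near-Nyquist linear phase and is oversampled enough for the
  # interpolation below; the rotation axis passes through the content.
  w <- Mod(v)^2
  s1 <- c(circ_centroid(rowSums(w)) - floor(n0[1] / 2),
          circ_centroid(colSums(w)) - floor(n0[2] / 2)) %% n0
  v <- shift2(v, s1)
  if (pad > 1) {
    vp <- matrix(0 + 0i, n0[1] * pad, n0[2] * pad)
    vp[seq_len(n0[1]), seq_len(n0[2])] <- v
    v <- vp
  }
  s2 <- floor(n0 / 2)
  v <- shift2(v, s2)
  lam <- f$wavelength_nm / 1000
  nu <- f$n_medium / lam
  fx <- .fftfreq(nrow(v), f$pitch_um)
  fy <- .fftfreq(ncol(v), f$pitch_um)
  FT <- .fft2(v)
  if (axis == 2) { FT <- t(FT); tmp <- fx; fx <- fy; fy <- tmp }
  n1 <- length(fx)
  ord <- order(fx)                # natural (shifted) frequency order
  fxs <- fx[ord]
  ct <- cos(theta_rad); st <- sin(theta_rad)
  out <- matrix(0 + 0i, n1, length(fy))
  for (j in seq_along(fy)) {
    r2 <- nu^2 - fxs^2 - fy[j]^2
    inband_out <- r2 > 0
    if (!any(inband_out)) next
    fz <- sqrt(pmax(r2, 0))
    src <- fxs * ct + fz * st     # source frequency on the unrotated plane
    jac <- abs(ct - fxs / pmax(fz, 1e-12) * st)
    ok <- inband_out & (src^2 + fy[j]^2 < nu^2) &
      src >= fxs[1] & src <= fxs[n1]
    if (!any(ok)) next
    col <- FT[ord, j]
    sre <- stats::splinefun(fxs, Re(col), method = "natural")
    sim <- stats::splinefun(fxs, Im(col), method = "natural")
    val <- complex(real = sre(src[ok]), imaginary = sim(src[ok])) * jac[ok]
    colout <- rep(0 + 0i, n1)
    colout[ok] <- val
    out[ord, j] <- colout
  }
  if (axis == 2) out <- t(out)
  res <- .ifft2(out)
  if (split_bg) {
    # analytic rotation of the uniform background: a plane wave along z seen
    # on the rotated plane is a tilted plane wave with transverse frequency
    # -sin(theta) * n/lambda and Jacobian weight 1/cos(theta). It is added
    # in the centered frame on signed coordinates, so the off-grid carrier
    # is smooth across the content and its wrap jump falls in the zero pad;
    # it then rides through the same unshift/crop path as the scattered
    # part, keeping their relative alignment exact.
    f0 <- -sin(theta_rad) * nu
    np <- dim(res)[axis]
    x0 <- seq_len(np) - 1
    xs <- ifelse(x0 < np / 2, x0, x0 - np) * f$pitch_um
    carrier <- c0 / cos(theta_rad) * exp(2i * pi * f0 * xs)
    res <- if (axis == 1) res + matrix(carrier, dim(res)[1], dim(res)[2])
           else res + matrix(carrier, dim(res)[1], dim(res)[2], byrow = TRUE)
  }
  res <- shift2(res, dim(res) - s2)                      # origin -> mid-block
  res <- res[seq_len(n0[1]), seq_len(n0[2]), drop = FALSE]
  res <- shift2(res, n0 - s1)                            # undo pre-centering
  complex_field(res[seq_len(odim[1]), seq_len(odim[2]), drop = FALSE],
                f$pitch_um, f$wavelength_nm, f$n_medium)
}

#' Rotational transformation of a field onto a tilted plane
#'
#' Remaps the angular spectrum onto the frequency grid of a plane rotated by
#' the tilt angles (cubic-spline interpolation, Jacobian weighting).
#' `rotate_field(rotate_field(f, t), -t)` is the identity up to
#' interpolation error on band-limited fields.
#'
#' @param f A [complex_field()].
#' @param t A [tilt_plane()] (or the result of [fit_tilt_plane()]).
#' @return The field on the rotated plane.
#' @export
rotate_field <- function(f, t) {
  lam <- f$wavelength_nm / 1000
  # sampling limit: rotation shifts the band edge by sin(theta)*n/lambda
  fmax <- 1 / (2 * f$pitch_um)
  for (th in c(t$theta_x_deg, t$theta_y_deg))
    if (abs(sin(th * pi / 180)) * f$n_medium / lam > fmax)
      stop("tilt angle too large for the field's sampling")
  f <- .rotate_axis(f, t$theta_x_deg * pi / 180, 1)
  .rotate_axis(f, t$theta_y_deg * pi / 180, 2)
}

#' Multi-height phase recovery with digital tilt correction
#'
#' Convenience wrapper around [multiheight_phase_recovery()] with a tilt
#' plane: each amplitude update is performed on the sensor-parallel rotated
#' field, then rotated back. With zero tilt this is exactly
#' [multiheight_phase_recovery()].
#'
#' @inheritParams multiheight_phase_recovery
#' @param t A `tilt_plane`.
#' @param ... Passed to [multiheight_phase_recovery()].
#' @return A `complex_field` at the object plane.
#' @export
multiheight_with_tilt <- function(s, t, ...) {
  multiheight_phase_recovery(s, tilt = t, ...)
}
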