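# Synthetic-data generators that make every pipeline stage testable
# offline: tissue-mimicking phantoms, forward-simulated hologram stacks,
# transmission color-checker spectra, distorted camera renderings, and
# degraded lens-based views. All generators are deterministic under a fixed
# seed; the seed is recorded in the output.

# smooth random field in [0,1]: seeded white noise blurred to a correlation
# length of `scale` pixels
.smooth_field <- function(size, scale) {
  f <- matrix(stats::rnorm(size^2), size, size)
  f <- EBImage::gblur(f, sigma = scale)
  (f - min(f)) / (max(f) - min(f))
}

#' Generate a nuclei-and-stroma tissue-mimicking phantom
#'
#' Reproducible field of elliptical "nuclei" (purplish blue, sharp
#' boundaries, Poisson-distributed count) over low-frequency "stroma"
#' texture (pink), emulating an H&E-stained section. Returns the complex
#' object (amplitude/phase) driving the hologram simulator together with
#' the per-pixel ground-truth color image.
#'
#' @param seed Integer seed.
#' @param size Image side in pixels (>= 256).
#' @param pitch_um Pixel pitch in micrometres (default 0.5).
#' @param nuclei_density Expected nuclei per 10^4 pixels (default 6).
#' @return Object of class `phantom`: `amplitude` in \[0, 1\], `phase`
#'   (radians), `pitch_um`, `truth_rgb` (size x size x 3), `nuclei_mask`,
#'   `n_nuclei`, `label`, `seed`.
#' @export
make_tissue_phantom <- function(seed, size = 256, pitch_um = 0.5,
                                nuclei_density = 6) {
  if (size < 256) stop("size must be >= 256")
  stroma_rgb <- c(0.91, 0.62, 0.75)     # eosin pink
  nuclei_rgb <- c(0.42, 0.32, 0.72)     # hematoxylin purplish blue
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    tex <- .smooth_field(size, size / 24)              # stroma density
    openness <- .smooth_field(size, size / 10)         # sparse open areas
    truth <- array(0, c(size, size, 3))
    stroma_w <- 0.35 + 0.65 * tex
    stroma_w <- stroma_w * (openness > 0.15)
    for (ch in 1:3)
      truth[, , ch] <- 1 - stroma_w * (1 - stroma_rgb[ch])
    n_nuclei <- stats::rpois(1, nuclei_density * size^2 / 1e4)
    mask <- matrix(FALSE, size, size)
    xg <- matrix(rep(seq_len(size), each = size), size)
    yg <- matrix(rep(seq_len(size), size), size)
    for (i in seq_len(n_nuclei)) {
      cx <- stats::runif(1, 8, size - 8); cy <- stats::runif(1, 8, size - 8)
      a <- stats::runif(1, 3, 7); b <- stats::runif(1, 3, 7)
      th <- stats::runif(1, 0, pi)
      dx <- xg - cx; dy <- yg - cy
      u <- dx * cos(th) + dy * sin(th); v <- -dx * sin(th) + dy * cos(th)
      mask <- mask | ((u / a)^2 + (v / b)^2 <= 1)
    }
    shade <- 0.85 + 0.3 * tex             # slight per-pixel nucleus variation
    for (ch in 1:3) {
      pl <- truth[, , ch]
      pl[mask] <- (nuclei_rgb[ch] * shade)[mask]
      truth[, , ch] <- pmin(pmax(pl, 0), 1)
    }
  })
  lum <- 0.2126 * truth[, , 1] + 0.7152 * truth[, , 2] + 0.0722 * truth[, , 3]
  amplitude <- 0.15 + 0.85 * lum          # absorbing object, transparent bg
  phase <- 1.2 * (1 - lum)                # optical thickness tracks absorption
  structure(list(amplitude = amplitude, phase = phase, pitch_um = pitch_um,
                 truth_rgb = truth, nuclei_mask = mask, n_nuclei = n_nuclei,
                 label = "nuclei-stroma tissue mimic", seed = seed),
            class = "phantom")
}

#' Forward-simulate a multi-height hologram stack from a phantom
#'
#' Propagates the complex object field to each sample-to-sensor distance
#' with the angular-spectrum operator and records the intensity, with
#' optional shot-like noise (Gaussian, sd proportional to sqrt(intensity))
#' and an optional object-plane tilt.
#'
#' @param ph A [make_tissue_phantom()] result (or any list with
#'   `amplitude`, `phase`, `pitch_um`).
#' @param z2_um Ascending vector of sample-to-sensor distances.
#' @param wavelength_nm Illumination wavelength (default 532).
#' @param noise_sigma Shot-noise scale (default 0, noiseless).
#' @param tilt Optional [tilt_plane()] of the object relative to the sensor.
#' @param seed Seed for the noise (default 1).
#' @return A [hologram_stack()].
#' @export
simulate_hologram_stack <- function(ph, z2_um, wavelength_nm = 532,
                                    noise_sigma = 0, tilt = NULL, seed = 1) {
  if (any(diff(z2_um) <= 0)) stop("z2_um must be ascending")
  obj <- complex_field(ph$amplitude * exp(1i * ph$phase), ph$pitch_um,
                       wavelength_nm)
  tilted <- !is.null(tilt) &&
    (abs(tilt$theta_x_deg) > 0 || abs(tilt$theta_y_deg) > 0)
  set.seed(seed)
  hs <- lapply(z2_um, function(z) {
    u <- angular_spectrum_propagate(obj, z)
    if (tilted) u <- rotate_field(u, tilt)
    I <- Mod(u$values)^2
    if (noise_sigma > 0)
      I <- pmax(I + noise_sigma * sqrt(I) *
                  matrix(stats::rnorm(length(I)), nrow(I)), 0)
    hologram(I, z, wavelength_nm, ph$pitch_um)
  })
  hologram_stack(hs)
}

#' Generate synthetic transmission color-checker spectra
#'
#' 46 smooth transmission curves (sums of 2-4 Gaussian bands, clipped to
#' \[0, 1\]) on the 400-700 nm grid, split 22 + 24 across two checkers,
#' spanning the chromaticity gamut. These are synthetic stand-ins for
#' theatrical color filters, not digitized filter data.
#'
#' @param seed Integer seed.
#' @return List of class `checker_set`: `spectra` (list of 46
#'   [spectral_curve()]s), `layout` (data frame with `patch_id`, `checker`),
#'   `seed`.
#' @export
make_checker_spectra <- function(seed) {
  wl <- dcfm_wavelengths()
  set.seed(seed)
  spectra <- vector("list", 46)
  for (i in 1:46) {
    nb <- sample(2:4, 1)
    v <- rep(0.02, length(wl))
    for (b in seq_len(nb)) {
      center <- stats::runif(1, 400, 700)
      width <- stats::runif(1, 25, 90)
      height <- stats::runif(1, 0.25, 1)
      v <- v + height * exp(-(wl - center)^2 / (2 * width^2))
    }
    spectra[[i]] <- spectral_curve(pmin(pmax(v, 0), 1))
  }
  layout <- data.frame(patch_id = sprintf("p%02d", 1:46),
                       checker = rep(c(1L, 2L), c(22L, 24L)))
  structure(list(spectra = spectra, layout = layout, seed = seed),
            class = "checker_set")
}

#' Ground-truth colors of a checker set
#'
#' Integrates each transmission spectrum against the standard observer
#' under D65.
#'
#' @param checker A [make_checker_spectra()] result.
#' @return List with matrices `lab` (46 x 3) and `rgb` (46 x 3, linear,
#'   unclipped).
#' @export
checker_ground_truth <- function(checker) {
  xyz <- t(vapply(checker$spectra, spectrum_to_xyz, numeric(3)))
  list(lab = xyz_to_lab(xyz), rgb = xyz_to_linear_rgb(xyz), xyz = xyz)
}

#' Define a camera spectral/colorimetric model
#'
#' @param responsivities 3 x 31 matrix of per-channel spectral
#'   responsivities on the package wavelength grid; default a colorimetric
#'   (Luther-condition) camera derived from the color matching functions.
#' @param desaturation Chroma retention factor in (0, 1\]: observed Lab
#'   chroma = factor x true rendered chroma (default 1).
#' @param noise_sigma Additive Gaussian noise sd on linear RGB (default 0).
#' @param spectral_shift_nm Per-channel shifts of the responsivity curves,
#'   emulating filter-dye errors (default c(0, 0, 0)).
#' @param gains Per-channel analog gains (default c(1, 1, 1)).
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(responsivities = NULL, desaturation = 1,
                         noise_sigma = 0, spectral_shift_nm = c(0, 0, 0),
                         gains = c(1, 1, 1)) {
  cmf <- cmf_cie1931_d65()
  if (is.null(responsivities))
    responsivities <- .m_xyz2rgb %*% rbind(cmf$xbar, cmf$ybar, cmf$zbar)
  if (any(spectral_shift_nm != 0)) {
    wl <- cmf$wavelengths_nm
    for (ch in 1:3)
      responsivities[ch, ] <- stats::approx(wl + spectral_shift_nm[ch],
                                            responsivities[ch, ], xout = wl,
                                            rule = 2)$y
  }
  stopifnot(desaturation > 0, all(gains > 0))
  structure(list(responsivities = responsivities, desaturation = desaturation,
                 noise_sigma = noise_sigma, gains = gains),
            class = "camera_model")
}

#' Render checker patches through a camera model
#'
#' Per patch, raw channel c integrates t * S * resp_c (S = D65); gains are
#' applied, the white-balanced color is desaturated toward gray in Lab by
#' the configured factor, and seeded Gaussian noise is added. The returned
#' colors emulate a camera's raw linear output; the flat-transmitter
#' rendering is attached as `white_rgb` for the calibration's white-balance
#' step.
#'
#' @param checker A [make_checker_spectra()] result (or a list of
#'   `spectral_curve`s).
#' @param cam A [camera_model()].
#' @param seed Noise seed (default 1).
#' @return m x 3 matrix of observed linear RGB, with attribute `white_rgb`.
#' @export
render_camera <- function(checker, cam, seed = 1) {
  spectra <- if (inherits(checker, "checker_set")) checker$spectra else checker
  cmf <- cmf_cie1931_d65()
  k <- 1 / sum(cmf$illuminant * cmf$ybar)
  raw_one <- function(t) k * drop(cam$responsivities %*% (t$values * cmf$illuminant))
  raw <- t(vapply(spectra, raw_one, numeric(3)))
  white <- k * drop(cam$responsivities %*% (rep(1, 31) * cmf$illuminant))
  wb <- sweep(raw, 2, white, `/`)
  if (cam$desaturation != 1) {
    lab <- xyz_to_lab(linear_rgb_to_xyz(wb))
    lab[, 2:3] <- cam$desaturation * lab[, 2:3]
    wb <- xyz_to_linear_rgb(lab_to_xyz(lab))
  }
  obs <- sweep(wb, 2, cam$gains * white, `*`)
  if (cam$noise_sigma > 0) {
    set.seed(seed)
    obs <- obs + matrix(stats::rnorm(length(obs), 0, cam$noise_sigma),
                        nrow(obs)) * mean(abs(obs))
  }
  attr(obs, "white_rgb") <- cam$gains * white
  colnames(obs) <- c("R", "G", "B")
  obs
}

#' Degrade a ground-truth color image into a simulated lens-based view
#'
#' Gaussian blur -> downsample -> re-upsample (emulating the resolution
#' gap), followed by a known projective misalignment and per-channel
#' sub-pixel offsets (emulating channel dislocation of a cheap lens), plus
#' optional additive noise.
#'
#' @param truth_rgb H x W x 3 linear RGB array.
#' @param blur_sigma Blur in pixels (> 0).
#' @param downsample Integer downsampling factor (default 4).
#' @param H Optional 3x3 projective misalignment (maps output coordinates to
#'   source coordinates; default identity).
#' @param channel_offsets_px 3 x 2 matrix of per-channel (dx, dy) shifts
#'   (default zeros).
#' @param noise_sigma Additive Gaussian noise sd (default 0).
#' @param seed Noise seed (default 1).
#' @return Degraded H x W x 3 array.
#' @export
degrade_to_lensbased <- function(truth_rgb, blur_sigma, downsample = 4,
                                 H = NULL, channel_offsets_px = NULL,
                                 noise_sigma = 0, seed = 1) {
  if (blur_sigma <= 0) stop("blur_sigma must be > 0")
  d <- dim(truth_rgb)[1:2]
  out <- truth_rgb
  for (ch in 1:3) {
    pl <- EBImage::gblur(truth_rgb[, , ch], sigma = blur_sigma)
    if (downsample > 1) {
      lo <- EBImage::resize(pl, w = round(d[1] / downsample),
                            h = round(d[2] / downsample))
      pl <- EBImage::resize(lo, w = d[1], h = d[2])
    }
    Hc <- if (is.null(H)) diag(3) else H
    if (!is.null(channel_offsets_px)) {
      Ht <- diag(3)
      Ht[1, 3] <- channel_offsets_px[ch, 1]
      Ht[2, 3] <- channel_offsets_px[ch, 2]
      Hc <- Hc %*% Ht
    }
    if (!identical(Hc, diag(3))) pl <- warp_projective(pl, Hc, fill = mean(pl))
    out[, , ch] <- pl
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    out <- out + array(stats::rnorm(length(out), 0, noise_sigma), dim(out))
  }
  out
}
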