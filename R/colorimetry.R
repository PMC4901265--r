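# Color-space machinery: spectra -> XYZ via the standard observer, the
# XYZ <-> linear sRGB <-> CIELAB conversions, and the CIE-94 color distance
# used for all quantification in this package.

#' Construct a spectral transmission curve
#'
#' @param values Transmission per wavelength, dimensionless, in \[0, 1\].
#' @param wavelengths_nm Strictly increasing wavelength grid (default the
#'   package grid, 400-700 nm by 10).
#' @return An object of class `spectral_curve`.
#' @export
spectral_curve <- function(values, wavelengths_nm = dcfm_wavelengths()) {
  if (length(values) != length(wavelengths_nm))
    stop("values and wavelengths_nm lengths differ")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("transmission values must lie in [0, 1]")
  structure(list(wavelengths_nm = wavelengths_nm,
                 values = pmin(pmax(values, 0), 1)),
            class = "spectral_curve")
}

#' Integrate a transmission spectrum to XYZ tristimulus values
#'
#' Computes X = sum(t * S * xbar) / sum(S * ybar) (and likewise Y, Z), where
#' S is the illuminant. Normalization is chosen so a perfect transmitter
#' (t = 1 everywhere) returns the illuminant white with Y = 1.
#'
#' @param t A `spectral_curve`.
#' @param cmf A `cmf_set` (default CIE 1931 2-degree + D65).
#' @return Named numeric vector `c(X =, Y =, Z =)`.
#' @export
spectrum_to_xyz <- function(t, cmf = cmf_cie1931_d65()) {
  if (!identical(as.numeric(t$wavelengths_nm), as.numeric(cmf$wavelengths_nm)))
    stop("wavelength grid of spectrum does not match that of the CMF set; ",
         "resample explicitly before integrating")
  k <- 1 / sum(cmf$illuminant * cmf$ybar)
  tv <- t$values
  c(X = k * sum(tv * cmf$illuminant * cmf$xbar),
    Y = k * sum(tv * cmf$illuminant * cmf$ybar),
    Z = k * sum(tv * cmf$illuminant * cmf$zbar))
}

#' D65 white point of the shipped illuminant table
#'
#' XYZ of a perfect transmitter under the shipped D65 table; Y = 1 exactly.
#'
#' @return Named numeric vector `c(X =, Y =, Z =)`.
#' @export
d65_white <- function() {
  spectrum_to_xyz(spectral_curve(rep(1, 31)))
}

# sRGB primaries / D65, IEC 61966-2-1 matrices.
.m_rgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
.m_xyz2rgb <- solve(.m_rgb2xyz)

#' Convert XYZ to linear sRGB
#'
#' Fixed sRGB/D65 3x3 matrix; out-of-gamut components pass through unclipped
#' (an attribute flags them), so the round trip with [linear_rgb_to_xyz()] is
#' an exact identity.
#'
#' @param xyz Numeric length-3 vector, or 3-column matrix of colors (rows).
#' @return Numeric of the same shape with components R, G, B.
#' @export
xyz_to_linear_rgb <- function(xyz) {
  v <- if (is.matrix(xyz)) t(.m_xyz2rgb %*% t(xyz)) else drop(.m_xyz2rgb %*% xyz)
  if (is.matrix(v)) colnames(v) <- c("R", "G", "B") else names(v) <- c("R", "G", "B")
  attr(v, "out_of_gamut") <- any(v < -1e-9 | v > 1 + 1e-9)
  v
}

#' Convert linear sRGB to XYZ
#'
#' @param rgb Numeric length-3 vector, or 3-column matrix of colors (rows).
#' @return Numeric of the same shape with components X, Y, Z.
#' @export
linear_rgb_to_xyz <- function(rgb) {
  v <- if (is.matrix(rgb)) t(.m_rgb2xyz %*% t(rgb)) else drop(.m_rgb2xyz %*% rgb)
  if (is.matrix(v)) colnames(v) <- c("X", "Y", "Z") else names(v) <- c("X", "Y", "Z")
  v
}

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' Convert XYZ to CIELAB
#'
#' Standard CIELAB forward transform, including the linear segment below the
#' (6/29)^3 cutoff.
#'
#' @param xyz Numeric length-3 vector or 3-column matrix.
#' @param white Reference white XYZ (default the shipped D65 white).
#' @return `c(L =, a =, b =)` (or 3-column matrix).
#' @export
xyz_to_lab <- function(xyz, white = d65_white()) {
  if (any(white <= 0)) stop("reference white must have strictly positive components")
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, 1)
  fx <- .lab_f(m[, 1] / white[[1]])
  fy <- .lab_f(m[, 2] / white[[2]])
  fz <- .lab_f(m[, 3] / white[[3]])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (is.matrix(xyz)) out else { v <- drop(out); names(v) <- c("L", "a", "b"); v }
}

#' Convert CIELAB to XYZ
#'
#' @inheritParams xyz_to_lab
#' @param lab Numeric length-3 `(L, a, b)` vector or 3-column matrix.
#' @return `c(X =, Y =, Z =)` (or 3-column matrix).
#' @export
lab_to_xyz <- function(lab, white = d65_white()) {
  if (any(white <= 0)) stop("reference white must have strictly positive components")
  m <- if (is.matrix(lab)) lab else matrix(lab, 1)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  out <- cbind(X = white[[1]] * .lab_finv(fx),
               Y = white[[2]] * .lab_finv(fy),
               Z = white[[3]] * .lab_finv(fz))
  if (is.matrix(lab)) out else { v <- drop(out); names(v) <- c("X", "Y", "Z"); v }
}

#' CIE 1931 chromaticity coordinates
#'
#' @param xyz Numeric length-3 XYZ with positive sum.
#' @return `c(x =, y =)`.
#' @export
chromaticity <- function(xyz) {
  s <- sum(xyz)
  if (!is.finite(s) || s <= 0) stop("chromaticity undefined for zero-sum color")
  c(x = xyz[[1]] / s, y = xyz[[2]] / s)
}

#' CIE-94 color difference
#'
#' Graphic-arts parameter set (kL = kC = kH = 1, K1 = 0.045, K2 = 0.015).
#' The first argument is the reference color: its chroma enters the weighting
#' functions, so the distance is not symmetric in its arguments (inherent to
#' CIE-94).
#'
#' @param ref Reference Lab color: length-3 vector or 3-column matrix.
#' @param sample Sample Lab color, same shape.
#' @return Non-negative color difference(s).
#' @export
cie94_distance <- function(ref, sample) {
  p <- if (is.matrix(ref)) ref else matrix(ref, 1)
  q <- if (is.matrix(sample)) sample else matrix(sample, 1)
  dL <- p[, 1] - q[, 1]
  c1 <- sqrt(p[, 2]^2 + p[, 3]^2)
  c2 <- sqrt(q[, 2]^2 + q[, 3]^2)
  dC <- c1 - c2
  da <- p[, 2] - q[, 2]
  db <- p[, 3] - q[, 3]
  dH2 <- pmax(da^2 + db^2 - dC^2, 0)
  sC <- 1 + 0.045 * c1
  sH <- 1 + 0.015 * c1
  de <- sqrt(dL^2 + (dC / sC)^2 + dH2 / sH^2)
  if (is.matrix(ref) || is.matrix(sample)) de else de[[1]]
}

#' Mean CIE-94 distance between two sets of Lab colors
#'
#' @param ref Matrix of reference Lab colors (rows).
#' @param sample Matrix of sample Lab colors (rows).
#' @return Mean of the per-row distances.
#' @export
mean_cie94 <- function(ref, sample) mean(cie94_distance(ref, sample))
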