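# Four-step color calibration in CIELAB, fitted once per imaging system on
# a color checker and then applied to any capture from that system:
#   (1) white-balance normalization by an empty-field reference,
#   (2) polynomial lightness correction,
#   (3) a single least-squares chroma (desaturation) scale,
#   (4) a 2nd-order polynomial color transformation matrix U.

# ordering of the 2nd-order feature vector; versioned with fitted models
.term_order <- "1,L,a,b,L2,a2,b2,La,Lb,ab"

.poly_features <- function(lab) {
  L <- lab[, 1]; a <- lab[, 2]; b <- lab[, 3]
  cbind(1, L, a, b, L^2, a^2, b^2, L * a, L * b, a * b)
}

#' Convert an RGB image array to a Lab pixel matrix and back
#'
#' @param img H x W x 3 array of linear RGB.
#' @param white Reference white XYZ.
#' @return `rgb_array_to_lab`: n x 3 Lab matrix (row-major pixels);
#'   `lab_to_rgb_array`: H x W x 3 array.
#' @export
rgb_array_to_lab <- function(img, white = d65_white()) {
  d <- dim(img)
  m <- matrix(img, d[1] * d[2], 3)
  xyz_to_lab(linear_rgb_to_xyz(m), white)
}

#' @rdname rgb_array_to_lab
#' @param lab n x 3 Lab matrix.
#' @param dims `c(H, W)` of the target image.
#' @export
lab_to_rgb_array <- function(lab, dims, white = d65_white()) {
  rgb <- xyz_to_linear_rgb(lab_to_xyz(lab, white))
  array(rgb, c(dims, 3))
}

#' White-balance an image by an empty-field reference
#'
#' Per-pixel, per-channel division by the empty capture, with a floor on the
#' denominator of 1e-4 times the empty image's median.
#'
#' @param img,empty H x W x 3 arrays of the same shape.
#' @return Normalized array; the empty image divided by itself is all ones.
#' @export
normalize_white_balance <- function(img, empty) {
  if (!identical(dim(img), dim(empty))) stop("image and empty reference shapes differ")
  floor_val <- 1e-4 * stats::median(empty)
  img / pmax(empty, floor_val)
}

#' Fit the lightness correction polynomial
#'
#' Least-squares polynomial mapping observed L to ground-truth L.
#'
#' @param obs_L,truth_L Numeric vectors of equal length.
#' @param degree Polynomial degree (default 1, appropriate for a linear
#'   camera response).
#' @return Coefficients in increasing-power order `(intercept, x, x^2, ...)`.
#' @export
fit_lightness <- function(obs_L, truth_L, degree = 1) {
  if (length(obs_L) < degree + 1) stop("need at least degree+1 points")
  if (stats::sd(obs_L) == 0) stop("observed lightness is constant; fit is rank-deficient")
  X <- outer(obs_L, 0:degree, `^`)
  drop(qr.solve(X, truth_L))
}

.polyval_inc <- function(coef, x) {
  y <- 0
  for (i in rev(seq_along(coef))) y <- y * x + coef[i]
  y
}

#' Fit the global chroma (desaturation) scale
#'
#' s = sum(c_obs * c_truth) / sum(c_obs^2), the least-squares scalar mapping
#' observed chroma to ground-truth chroma; applying the model multiplies
#' both a and b by s (hue angles are preserved).
#'
#' @param obs,truth m x 3 Lab matrices.
#' @return Scalar s > 0.
#' @export
fit_chroma_scale <- function(obs, truth) {
  co <- sqrt(obs[, 2]^2 + obs[, 3]^2)
  ct <- sqrt(truth[, 2]^2 + truth[, 3]^2)
  if (all(co == 0)) stop("all observed patches are gray; chroma scale undefined")
  sum(co * ct) / sum(co^2)
}

#' Fit the 2nd-order color transformation matrix U
#'
#' Solves Q = U P in the least-squares sense, where column j of P is the
#' 10-term quadratic feature vector (1, L, a, b, L^2, a^2, b^2, La, Lb, ab)
#' of observed patch j and column j of Q is its ground-truth (L, a, b).
#'
#' @param obs,truth m x 3 Lab matrices with m >= 10.
#' @param ridge Ridge fallback strength used when the feature Gram matrix is
#'   ill-conditioned (default 1e-8, relative).
#' @return 3 x 10 matrix U with attributes `residuals` (per-patch Euclidean
#'   Lab residual) and `term_order`.
#' @export
fit_color_transform <- function(obs, truth, ridge = 1e-8) {
  m <- nrow(obs)
  if (m < 10) stop("need at least 10 patches to fit the 10-term transform")
  P <- t(.poly_features(obs))              # 10 x m
  Q <- t(truth)                            # 3 x m
  G <- P %*% t(P)
  cn <- kappa(G, exact = TRUE)
  if (!is.finite(cn) || cn > 1e12) {
    warning("feature matrix ill-conditioned (kappa = ", format(cn, digits = 3),
            "); using ridge-regularized solution")
    G <- G + ridge * mean(diag(G)) * diag(10)
  }
  U <- Q %*% t(P) %*% solve(G)
  res <- sqrt(colSums((Q - U %*% P)^2))
  attr(U, "residuals") <- res
  attr(U, "term_order") <- .term_order
  U
}

#' Fit the full four-step calibration model on a patch set
#'
#' @param obs_rgb m x 3 matrix of observed linear RGB patch colors (raw
#'   camera output, before white balance).
#' @param truth_lab m x 3 matrix of ground-truth Lab colors.
#' @param white_rgb Observed RGB of the empty field (flat transmitter) used
#'   for white balance; default `NULL` skips the white-balance step (inputs
#'   already normalized).
#' @param lightness_degree Degree of the lightness fit (default 1).
#' @return Object of class `calibration_model` containing the white
#'   reference, lightness coefficients, chroma scale `s`, transform `U`,
#'   and per-step training diagnostics (`mean_de94` after each step).
#' @export
fit_calibration <- function(obs_rgb, truth_lab, white_rgb = NULL,
                            lightness_degree = 1) {
  if (nrow(obs_rgb) != nrow(truth_lab)) stop("observed and truth patch counts differ")
  if (nrow(obs_rgb) < 10) stop("need at least 10 patches")
  # step 1: white balance
  wb <- if (is.null(white_rgb)) obs_rgb else sweep(obs_rgb, 2, white_rgb, `/`)
  lab1 <- xyz_to_lab(linear_rgb_to_xyz(wb))
  de <- c(step1 = mean_cie94(truth_lab, lab1))
  # step 2: lightness
  lcoef <- fit_lightness(lab1[, 1], truth_lab[, 1], lightness_degree)
  lab2 <- lab1; lab2[, 1] <- .polyval_inc(lcoef, lab1[, 1])
  de <- c(de, step2 = mean_cie94(truth_lab, lab2))
  # step 3: chroma scale
  s <- fit_chroma_scale(lab2, truth_lab)
  lab3 <- lab2; lab3[, 2:3] <- s * lab2[, 2:3]
  de <- c(de, step3 = mean_cie94(truth_lab, lab3))
  # step 4: 2nd-order transform
  U <- fit_color_transform(lab3, truth_lab)
  lab4 <- t(U %*% t(.poly_features(lab3)))
  de <- c(de, step4 = mean_cie94(truth_lab, lab4))
  structure(list(white_rgb = white_rgb, lightness_coef = lcoef,
                 chroma_scale = s, U = U, term_order = .term_order,
                 lightness_degree = lightness_degree,
                 training_mean_de94 = de),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>\n")
  cat("  lightness coef:", format(x$lightness_coef, digits = 4), "\n")
  cat("  chroma scale s:", format(x$chroma_scale, digits = 4), "\n")
  cat("  training mean dE94 by step:",
      paste(names(x$training_mean_de94),
            format(x$training_mean_de94, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

# apply steps 2-4 to a Lab pixel matrix
.apply_lab_steps <- function(model, lab) {
  lab[, 1] <- .polyval_inc(model$lightness_coef, lab[, 1])
  lab[, 2:3] <- model$chroma_scale * lab[, 2:3]
  t(model$U %*% t(.poly_features(lab)))
}

#' Apply a fitted calibration model
#'
#' Pipeline: white balance (if an empty-field reference was supplied) ->
#' RGB to Lab -> lightness polynomial -> chroma scale -> 2nd-order
#' transform -> Lab to RGB. A pixelwise operation after white balance, so
#' it commutes with cropping.
#'
#' @param img H x W x 3 linear RGB array, or an m x 3 matrix of patch
#'   colors.
#' @param model A fitted `calibration_model`.
#' @param empty Optional empty-field image overriding the model's scalar
#'   white reference (per-pixel white balance).
#' @return Calibrated image/colors of the same shape.
#' @export
apply_calibration <- function(img, model, empty = NULL) {
  if (!inherits(model, "calibration_model")) stop("model is not a fitted calibration_model")
  if (is.matrix(img)) {
    wb <- if (is.null(model$white_rgb)) img else sweep(img, 2, model$white_rgb, `/`)
    lab <- .apply_lab_steps(model, xyz_to_lab(linear_rgb_to_xyz(wb)))
    return(xyz_to_linear_rgb(lab_to_xyz(lab)))
  }
  d <- dim(img)
  wb <- img
  if (!is.null(empty)) wb <- normalize_white_balance(img, empty)
  else if (!is.null(model$white_rgb))
    for (ch in 1:3) wb[, , ch] <- img[, , ch] / model$white_rgb[ch]
  lab <- .apply_lab_steps(model, rgb_array_to_lab(wb))
  lab_to_rgb_array(lab, d[1:2])
}

#' Mean color of an image region in Lab
#'
#' Averages R, G, B over the region first (linear-light mean), then converts
#' the mean color to Lab.
#'
#' @param img H x W x 3 linear RGB array.
#' @param region Logical H x W mask, or `list(rows =, cols =)` index
#'   ranges.
#' @return `c(L =, a =, b =)`.
#' @export
patch_mean_color <- function(img, region) {
  if (is.list(region)) {
    sub <- img[region$rows, region$cols, , drop = FALSE]
    rgb <- apply(sub, 3, mean)
  } else {
    if (!any(region)) stop("empty region")
    rgb <- vapply(1:3, function(ch) mean(img[, , ch][region]), numeric(1))
  }
  if (length(rgb) == 0 || any(!is.finite(rgb))) stop("empty region")
  xyz_to_lab(linear_rgb_to_xyz(rgb))
}
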