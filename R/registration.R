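# Projective (homography) registration built from grid control points:
# normalized cross-correlation (FFT-based, subpixel) around each control
# point yields correspondences, a DLT fit with RANSAC rejects outliers, and
# inverse-mapped bilinear warping applies the transform.
#
# Point coordinates are (x, y) = (column, row), 1-indexed.

# Deterministic linear-congruential generator so RANSAC never touches R's
# global RNG stream.
.lcg_new <- function(seed) {
  state <- as.double(seed %% 2147483647)
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 48271) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

# Direct linear transform homography: to ~ H %*% from (homogeneous), with
# Hartley normalization for conditioning.
.dlt_homography <- function(from, to) {
  norm_pts <- function(p) {
    mu <- colMeans(p)
    d <- mean(sqrt(rowSums(sweep(p, 2, mu)^2)))
    s <- if (d > 0) sqrt(2) / d else 1
    T <- matrix(c(s, 0, -s * mu[1], 0, s, -s * mu[2], 0, 0, 1), 3, 3, byrow = TRUE)
    list(T = T, p = cbind(s * (p[, 1] - mu[1]), s * (p[, 2] - mu[2])))
  }
  nf <- norm_pts(from); nt <- norm_pts(to)
  f <- nf$p; t2 <- nt$p
  n <- nrow(f)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- f[i, 1]; y <- f[i, 2]; u <- t2[i, 1]; v <- t2[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  if (nrow(A) < 9) A <- rbind(A, matrix(0, 9 - nrow(A), 9))
  h <- svd(A, nu = 0)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nt$T) %*% H %*% nf$T
  H / H[3, 3]
}

.apply_homography <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}

#' Estimate a projective transform from point correspondences with RANSAC
#'
#' @param from,to n x 2 matrices of (x, y) correspondences; the returned H
#'   maps `from` onto `to`.
#' @param thresh_px RANSAC inlier threshold in pixels (default 1).
#' @param iters Number of minimal samples (default 400).
#' @return List with the 3x3 matrix `H`, logical `inliers`, and the RMS
#'   reprojection error over the inliers.
#' @export
estimate_homography <- function(from, to, thresh_px = 1, iters = 400) {
  n <- nrow(from)
  if (n < 4) stop("need at least 4 correspondences")
  rng <- .lcg_new(n * 7919 + 17)
  best <- NULL; best_n <- -1
  for (it in seq_len(iters)) {
    idx <- unique(ceiling(rng(8) * n))[1:4]
    if (any(is.na(idx))) next
    H <- tryCatch(.dlt_homography(from[idx, , drop = FALSE], to[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(H) || any(!is.finite(H))) next
    err <- sqrt(rowSums((.apply_homography(H, from) - to)^2))
    inl <- is.finite(err) & err < thresh_px
    if (sum(inl) > best_n) { best_n <- sum(inl); best <- inl }
  }
  if (is.null(best) || best_n < 4) stop("RANSAC failed: no consensus set")
  H <- .dlt_homography(from[best, , drop = FALSE], to[best, , drop = FALSE])
  err <- sqrt(rowSums((.apply_homography(H, from) - to)^2))
  inl <- is.finite(err) & err < thresh_px
  if (sum(inl) >= 4)
    H <- .dlt_homography(from[inl, , drop = FALSE], to[inl, , drop = FALSE])
  list(H = H, inliers = inl,
       rms_px = sqrt(mean(rowSums((.apply_homography(H, from[inl, , drop = FALSE]) -
                                     to[inl, , drop = FALSE])^2))))
}

#' Warp an image with a projective transform (inverse mapping, bilinear)
#'
#' @param img 2D matrix.
#' @param H Homography mapping output (x, y) coordinates to source
#'   coordinates.
#' @param dims Output dimensions `c(nrow, ncol)` (default those of `img`).
#' @param fill Value for samples falling outside the source (default 0).
#' @return Warped matrix.
#' @export
warp_projective <- function(img, H, dims = dim(img), fill = 0) {
  nr <- dims[1]; nc <- dims[2]
  xy <- cbind(rep(seq_len(nc), each = nr), rep(seq_len(nr), nc))
  src <- .apply_homography(H, xy)
  sx <- src[, 1]; sy <- src[, 2]
  x0 <- floor(sx); y0 <- floor(sy)
  wx <- sx - x0; wy <- sy - y0
  ok <- x0 >= 1 & x0 + 1 <= ncol(img) & y0 >= 1 & y0 + 1 <= nrow(img)
  val <- rep(fill, nr * nc)
  if (any(ok)) {
    i00 <- (x0[ok] - 1) * nrow(img) + y0[ok]
    v00 <- img[i00]; v10 <- img[i00 + nrow(img)]
    v01 <- img[i00 + 1]; v11 <- img[i00 + nrow(img) + 1]
    val[ok] <- (1 - wx[ok]) * (1 - wy[ok]) * v00 + wx[ok] * (1 - wy[ok]) * v10 +
      (1 - wx[ok]) * wy[ok] * v01 + wx[ok] * wy[ok] * v11
  }
  matrix(val, nr, nc)
}

# Subpixel displacement of a reference patch inside a moving-image search
# window, by phase correlation (spectrally whitened cross-power spectrum,
# Hann-windowed zero-mean signals) with parabolic peak interpolation. The
# whitened correlation peaks sharply at the true shift regardless of the
# window's extra content; `corr` is the peak height (1 = perfect match).
.patch_shift <- function(ref, mov, eps = 1e-12, alpha = 0.75) {
  nr <- max(nrow(ref), nrow(mov)); nc <- max(ncol(ref), ncol(mov))
  nr <- nr + nr %% 2; nc <- nc + nc %% 2
  embed <- function(m) {
    out <- matrix(0, nr, nc)
    w <- outer(0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = nrow(m))),
               0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = ncol(m))))
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- (m - mean(m)) * w
    out
  }
  a <- embed(ref); b <- embed(mov)
  # partial whitening (exponent < 1) keeps the peak sharp without blowing up
  # noise-dominated frequencies when one image is strongly blurred
  X <- Conj(stats::fft(a)) * stats::fft(b)
  cc <- Re(stats::fft(X / pmax(Mod(X), eps)^alpha, inverse = TRUE)) / (nr * nc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sub <- function(i, n, get) {
    ym <- get(((i - 2) %% n) + 1); y0 <- get(i); yp <- get((i %% n) + 1)
    den <- ym - 2 * y0 + yp
    if (den == 0) 0 else 0.5 * (ym - yp) / den
  }
  dr <- sub(pk[1], nr, function(i) cc[i, pk[2]])
  dc <- sub(pk[2], nc, function(i) cc[pk[1], i])
  sh <- c(pk[1] - 1 + dr, pk[2] - 1 + dc)
  sh <- ifelse(sh > c(nr, nc) / 2, sh - c(nr, nc), sh)
  list(dy = sh[1], dx = sh[2], corr = max(cc))
}

#' Find control-point correspondences between two images
#'
#' Lays a regular grid of control points over the reference, extracts a
#' patch around each, and finds the matching subpixel location in the moving
#' image by normalized cross-correlation within a search window.
#'
#' @param ref,mov 2D matrices with overlapping content.
#' @param grid Points per side of the control grid (default 5).
#' @param patch Patch half-size in pixels (default 24).
#' @param search Search margin around the patch in pixels (default 20).
#' @param min_corr Minimum phase-correlation peak height to accept a match
#'   (default 0.08).
#' @return List of matrices `from` (in `ref`), `to` (in `mov`), and `corr`.
#' @export
find_correspondences <- function(ref, mov, grid = 6, patch = 24, search = 20,
                                 min_corr = 0.08) {
  margin <- patch + search + 2
  if (nrow(ref) < 2 * margin + 8 || ncol(ref) < 2 * margin + 8)
    stop("images too small for the requested patch/search sizes")
  ys <- round(seq(margin, nrow(ref) - margin, length.out = grid))
  xs <- round(seq(margin, ncol(ref) - margin, length.out = grid))
  from <- to <- NULL; corr <- numeric(0)
  for (y in ys) for (x in xs) {
    pr <- ref[(y - patch):(y + patch), (x - patch):(x + patch)]
    y0 <- max(1, y - patch - search); y1 <- min(nrow(mov), y + patch + search)
    x0 <- max(1, x - patch - search); x1 <- min(ncol(mov), x + patch + search)
    pm <- mov[y0:y1, x0:x1]
    if (stats::sd(pr) == 0 || stats::sd(pm) == 0) next
    s <- .patch_shift(pr, pm)
    if (s$corr < min_corr) next
    # position of the ref patch origin inside the mov window
    my <- y0 + s$dy + (y - (y - patch))   # = y0 + dy + patch
    mx <- x0 + s$dx + (x - (x - patch))
    from <- rbind(from, c(x, y))
    to <- rbind(to, c(mx, my))
    corr <- c(corr, s$corr)
  }
  if (is.null(from)) stop("no control-point matches found")
  list(from = from, to = to, corr = corr)
}

#' Register a moving image onto a reference with a projective transform
#'
#' @inheritParams find_correspondences
#' @param thresh_px RANSAC inlier threshold (default 1 px).
#' @param min_matches Minimum robust matches required (default 8).
#' @param passes Number of estimate-warp-refine passes (default 2; the
#'   second pass removes the bias local matching incurs under rotation or
#'   perspective within a patch).
#' @param ... Passed to [find_correspondences()].
#' @return List with `H` (maps reference coordinates to moving-image
#'   coordinates), `warped` (moving image resampled onto the reference
#'   grid), `n_matches`, `rms_px`.
#' @export
register_projective <- function(ref, mov, thresh_px = 1, min_matches = 8,
                                passes = 2, ...) {
  H <- diag(3)
  cur <- mov
  n_in <- 0; rms <- NA_real_
  for (p in seq_len(passes)) {
    cp <- find_correspondences(ref, cur, ...)
    fit <- estimate_homography(cp$from, cp$to, thresh_px = thresh_px)
    n_in <- sum(fit$inliers)
    if (p == 1 && n_in < min_matches)
      stop("registration failed: only ", n_in, " robust matches (need ",
           min_matches, ")")
    if (p > 1 && n_in < 4) break     # refinement failed; keep previous pass
    H <- H %*% fit$H                 # cur(x) = mov(H_prev x) => compose
    rms <- fit$rms_px
    if (p < passes) cur <- warp_projective(mov, H, dims = dim(ref),
                                           fill = mean(mov))
  }
  list(H = H, warped = warp_projective(mov, H, dims = dim(ref)),
       n_matches = n_in, rms_px = rms)
}
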