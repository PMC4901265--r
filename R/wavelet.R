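# Multilevel 2D discrete wavelet transform with the biorthogonal 3.7 filter
# bank. The transform is the workhorse of both the denoising and the image
# fusion steps; it is implemented here as a periodized convolution filter
# bank applied after an outer symmetric pad to a multiple of 2^N, giving
# perfect reconstruction to machine precision.

# B-spline biorthogonal 3.7 analysis/synthesis filters (standard constants).
.bior37 <- list(
  dec_lo = c( 0.0030210861012608843, -0.009063258303782653, -0.01683176542131064,
              0.074663985074019,      0.03133297870736289,  -0.301159125922835,
             -0.02649924094534547,    0.9516421218971786,    0.9516421218971786,
             -0.02649924094534547,   -0.301159125922835,     0.03133297870736289,
              0.074663985074019,     -0.01683176542131064,  -0.009063258303782653,
              0.0030210861012608843),
  dec_hi = c(0, 0, 0, 0, 0, 0, -0.1767766952966369, 0.5303300858899106,
             -0.5303300858899106, 0.1767766952966369, 0, 0, 0, 0, 0, 0),
  rec_lo = c(0, 0, 0, 0, 0, 0, 0.1767766952966369, 0.5303300858899106,
             0.5303300858899106, 0.1767766952966369, 0, 0, 0, 0, 0, 0),
  rec_hi = c( 0.0030210861012608843,  0.009063258303782653, -0.01683176542131064,
             -0.074663985074019,      0.03133297870736289,   0.301159125922835,
             -0.02649924094534547,   -0.9516421218971786,    0.9516421218971786,
              0.02649924094534547,   -0.301159125922835,    -0.03133297870736289,
              0.074663985074019,      0.01683176542131064,  -0.009063258303782653,
             -0.0030210861012608843))

.wavelet_filters <- function(name = "bior3.7") {
  if (!identical(name, "bior3.7")) stop("unsupported wavelet basis: ", name)
  .bior37
}

# Circular convolution of each column of a matrix with filter h (FFT-based).
.circ_cols <- function(m, h) {
  n <- nrow(m)
  # fold the filter modulo n so periodization stays exact when the band is
  # shorter than the filter support
  hp <- numeric(n)
  for (i in seq_along(h)) {
    j <- (i - 1) %% n + 1
    hp[j] <- hp[j] + h[i]
  }
  Re(stats::mvfft(stats::mvfft(m) * as.vector(stats::fft(hp)), inverse = TRUE)) / n
}

.circ_shift_rows <- function(m, s) {
  n <- nrow(m)
  m[((seq_len(n) - 1 + s) %% n) + 1, , drop = FALSE]
}

# One analysis level along columns: returns list(a, d), each nrow/2 x ncol.
.dwt_cols <- function(m, f) {
  n <- nrow(m)
  if (n %% 2 != 0) stop("odd extent in DWT; pad first")
  keep <- seq(1, n, by = 2)
  list(a = .circ_cols(m, f$dec_lo)[keep, , drop = FALSE],
       d = .circ_cols(m, f$dec_hi)[keep, , drop = FALSE])
}

# Inverse of .dwt_cols; the filter-bank delay of 2L-1 taps shows up as a
# circular shift of len(filter)-1 samples after synthesis.
.idwt_cols <- function(a, d, f) {
  n <- 2 * nrow(a)
  ua <- matrix(0, n, ncol(a)); ua[seq(1, n, 2), ] <- a
  ud <- matrix(0, n, ncol(d)); ud[seq(1, n, 2), ] <- d
  y <- .circ_cols(ua, f$rec_lo) + .circ_cols(ud, f$rec_hi)
  .circ_shift_rows(y, length(f$rec_lo) - 1)
}

#' Single-level 2D DWT
#'
#' @param x Numeric matrix with even dimensions.
#' @param wavelet Basis name; only `"bior3.7"` is shipped.
#' @return List with approximation `a` and detail bands `h`, `v`, `d`
#'   (horizontal, vertical, diagonal), each of half the linear size.
#' @export
dwt2 <- function(x, wavelet = "bior3.7") {
  f <- .wavelet_filters(wavelet)
  cc <- .dwt_cols(x, f)                       # along rows of the image (dim 1)
  ra <- .dwt_cols(t(cc$a), f)                 # along columns
  rd <- .dwt_cols(t(cc$d), f)
  list(a = t(ra$a), h = t(ra$d), v = t(rd$a), d = t(rd$d))
}

#' Single-level inverse 2D DWT
#'
#' @param bands List as returned by [dwt2()].
#' @inheritParams dwt2
#' @return Reconstructed matrix.
#' @export
idwt2 <- function(bands, wavelet = "bior3.7") {
  f <- .wavelet_filters(wavelet)
  ca <- t(.idwt_cols(t(bands$a), t(bands$h), f))
  cd <- t(.idwt_cols(t(bands$v), t(bands$d), f))
  .idwt_cols(ca, cd, f)
}

# Symmetric (reflection, half-sample) pad of a matrix to target dims.
.pad_symmetric <- function(x, nr, nc) {
  idx <- function(n, target) {
    i <- seq_len(target)
    # fold indices 1..target into 1..n by half-sample reflection
    p <- (i - 1) %% (2 * n)
    ifelse(p < n, p + 1, 2 * n - p)
  }
  x[idx(nrow(x), nr), idx(ncol(x), nc), drop = FALSE]
}

#' Multilevel 2D wavelet decomposition
#'
#' Pads the input symmetrically to a multiple of 2^levels, then applies
#' [dwt2()] recursively to the approximation band.
#'
#' @param x Numeric matrix.
#' @param levels Decomposition depth N (>= 1).
#' @inheritParams dwt2
#' @return Object of class `wavedec2`: approximation at level N, per-level
#'   detail bands, and the original dimensions for exact cropping on
#'   reconstruction.
#' @export
wavedec2 <- function(x, levels, wavelet = "bior3.7") {
  stopifnot(levels >= 1)
  mult <- 2^levels
  if (min(dim(x)) < mult)
    stop("decomposition depth ", levels, " too deep for a ",
         nrow(x), "x", ncol(x), " image")
  nr <- mult * ceiling(nrow(x) / mult)
  nc <- mult * ceiling(ncol(x) / mult)
  orig <- dim(x)
  x <- .pad_symmetric(x, nr, nc)
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    b <- dwt2(x, wavelet)
    details[[l]] <- b[c("h", "v", "d")]
    x <- b$a
  }
  structure(list(approx = x, details = details, levels = levels,
                 wavelet = wavelet, orig_dim = orig),
            class = "wavedec2")
}

#' Multilevel 2D wavelet reconstruction
#'
#' @param w A `wavedec2` object.
#' @return Matrix of the original (pre-pad) dimensions.
#' @export
waverec2 <- function(w) {
  x <- w$approx
  for (l in rev(seq_len(w$levels)))
    x <- idwt2(c(list(a = x), w$details[[l]]), w$wavelet)
  x[seq_len(w$orig_dim[1]), seq_len(w$orig_dim[2]), drop = FALSE]
}

#' Wavelet hard-threshold denoising
#'
#' Multilevel DWT, hard threshold of all detail coefficients at the universal
#' threshold T = sigma * sqrt(2 log M), with the noise level sigma estimated
#' from the median absolute deviation of the finest diagonal band
#' (sigma = MAD / 0.6745). The approximation band is left untouched.
#'
#' @param plane 2D numeric matrix.
#' @param wavelet Basis name (default `"bior3.7"`, shared with the fusion
#'   step).
#' @param levels Decomposition depth (default 3).
#' @param threshold Optional fixed threshold overriding the estimate.
#' @return Denoised matrix of the same dimensions.
#' @export
wavelet_denoise <- function(plane, wavelet = "bior3.7", levels = 3,
                            threshold = NULL) {
  if (any(!is.finite(plane))) stop("plane contains non-finite values")
  w <- wavedec2(plane, levels, wavelet)
  if (is.null(threshold)) {
    dband <- w$details[[1]]$d
    sigma <- stats::median(abs(dband - stats::median(dband))) / 0.6745
    threshold <- sigma * sqrt(2 * log(length(plane)))
  }
  for (l in seq_len(w$levels))
    w$details[[l]] <- lapply(w$details[[l]],
                             function(b) ifelse(abs(b) > threshold, b, 0))
  waverec2(w)
}
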