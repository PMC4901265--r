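# Shared fixtures, built in code at test time.

psnr <- function(a, b) 10 * log10(1 / mean((a - b)^2))

grad_mag <- function(m) {
  gx <- m[-1, -1] - m[-nrow(m), -1]
  gy <- m[-1, -1] - m[-1, -ncol(m)]
  sqrt(gx^2 + gy^2)
}

luminance <- function(img) {
  0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
}

# complex field whose angular spectrum is a smooth, compact bump: genuinely
# band-limited and spectrally resolved, the regime where the rotational
# field transform is accurate
smooth_spectrum_field <- function(n = 128, pitch = 1, wavelength_nm = 532,
                                  width_bins = 8) {
  fx <- dcfm:::.fftfreq(n, pitch)
  s <- width_bins / (n * pitch)
  G <- outer(fx, fx, function(u, v) exp(-(u^2 + v^2) / (2 * s^2)))
  complex_field(dcfm:::.ifft2(G), pitch, wavelength_nm)
}

# color image in the regime digital color fusion targets: chroma varying
# slowly, brightness carrying the fine structure
detail_color_image <- function(n = 256, seed = 21, hue_amp = 0.15) {
  set.seed(seed)
  xs <- seq(0, 1, length.out = n)
  hue <- array(0, c(n, n, 3))
  hue[, , 1] <- outer(xs, xs, function(x, y) 0.62 + hue_amp * sin(2 * pi * x) * cos(pi * y))
  hue[, , 2] <- outer(xs, xs, function(x, y) 0.55 + 0.85 * hue_amp * cos(2 * pi * y))
  hue[, , 3] <- outer(xs, xs, function(x, y) 0.60 + 0.85 * hue_amp * sin(pi * (x + y)))
  fine <- EBImage::gblur(matrix(stats::rnorm(n^2), n), 1.0)
  fine <- (fine - min(fine)) / (max(fine) - min(fine))
  bright <- 0.35 + 0.65 * fine
  hue * array(rep(bright, 3), c(n, n, 3))
}

# small complex object for fast holography tests (simulate_hologram_stack
# only needs amplitude/phase/pitch_um)
small_phantom <- function(n = 128, seed = 5, pitch_um = 0.5) {
  set.seed(seed)
  base <- EBImage::gblur(matrix(stats::rnorm(n^2), n), 2)
  base <- (base - min(base)) / (max(base) - min(base))
  list(amplitude = 0.4 + 0.6 * base, phase = 0.8 * (1 - base),
       pitch_um = pitch_um)
}

# crop of the tissue phantom: sharp nuclear boundaries give autofocus and
# tilt metrics something to bite on
sharp_phantom <- function(n = 128, seed = 5, pitch_um = 0.5) {
  ph <- make_tissue_phantom(seed, 256, pitch_um)
  i <- 64 + seq_len(n)
  list(amplitude = ph$amplitude[i, i], phase = ph$phase[i, i],
       pitch_um = pitch_um)
}

expect_rel_l2 <- function(a, b, tol) {
  rel <- sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
  expect_lt(rel, tol)
}
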