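# Angular-spectrum engine: propagation, autofocus, TIE initialization,
# multi-height recovery, tilt-plane fitting.

test_that("propagation is unitary, composable, and matches the free-space phase", {
  f <- smooth_spectrum_field(128)
  expect_lt(max(Mod(angular_spectrum_propagate(f, 0)$values - f$values)), 1e-12)
  fb <- angular_spectrum_propagate(angular_spectrum_propagate(f, 300), -300)
  expect_lt(max(Mod(fb$values - f$values)), 1e-8)
  e0 <- sum(Mod(f$values)^2)
  ep <- sum(Mod(angular_spectrum_propagate(f, 250)$values)^2)
  expect_lt(abs(ep - e0) / e0, 1e-8)
  f12 <- angular_spectrum_propagate(angular_spectrum_propagate(f, 100), 150)
  fc <- angular_spectrum_propagate(f, 250)
  expect_lt(max(Mod(f12$values - fc$values)), 1e-8)
  # closed-form free-space solution for a uniform plane wave
  pw <- complex_field(matrix(1 + 0i, 64, 64), 1, 532)
  pp <- angular_spectrum_propagate(pw, 123.4)
  expect_lt(max(Mod(pp$values - exp(2i * pi * 123.4 / 0.532))), 1e-10)
  expect_error(angular_spectrum_propagate(pw, NA), "finite")
})

test_that("autofocus finds the simulated focus distance", {
  ph <- sharp_phantom(128)
  st <- simulate_hologram_stack(ph, z2_um = 500, wavelength_nm = 532)
  h <- st$holograms[[1]]
  z <- autofocus(h, c(300, 700))
  expect_lt(abs(z - 500), 5)
  # criterion is unimodal near the focus on the refined scan
  f0 <- complex_field(sqrt(h$intensity), h$pitch_um, h$wavelength_nm)
  zs <- seq(460, 540, by = 10)
  sc <- vapply(zs, function(z2) dcfm:::.tamura_sharpness(
    Mod(angular_spectrum_propagate(f0, -z2)$values)), numeric(1))
  expect_equal(which.max(sc), which.min(abs(zs - 500)), tolerance = 1)
  expect_error(autofocus(hologram(matrix(1, 32, 32), 100, 532, 0.5), c(50, 200)),
               "constant")
})

test_that("per-region autofocus resolves two objects at different depths", {
  n <- 192
  xs <- seq_len(n)
  mk <- function(ctr) {
    d <- outer(xs, xs, function(x, y) (x - ctr[1])^2 + (y - ctr[2])^2 <= 6^2)
    a <- matrix(1, n, n); a[d] <- 0.15; a
  }
  o1 <- complex_field(mk(c(48, 96)), 0.5, 532)
  o2 <- complex_field(mk(c(144, 96)), 0.5, 532)
  I <- Mod(angular_spectrum_propagate(o1, 400)$values +
             angular_spectrum_propagate(o2, 520)$values - 1)^2
  h <- hologram(I, 0, 532, 0.5)
  z1 <- autofocus(h, c(300, 620), region = list(rows = 1:96, cols = 1:n))
  z2 <- autofocus(h, c(300, 620), region = list(rows = 97:n, cols = 1:n))
  expect_lt(abs(z1 - 400), 15)
  expect_lt(abs(z2 - 520), 15)
  expect_gt(abs(z1 - z2), 60)
})

test_that("TIE initialization recovers a weak phase and respects scaling", {
  n <- 256
  x <- seq(-1, 1, length.out = n)
  quad <- 0.3 * outer(x^2, x^2, `+`)
  obj <- complex_field(exp(1i * quad), 0.5, 532)
  u <- angular_spectrum_propagate(obj, 200)
  I1 <- Mod(u$values)^2
  I2 <- Mod(angular_spectrum_propagate(u, 15)$values)^2
  h1 <- hologram(I1, 200, 532, 0.5); h2 <- hologram(I2, 215, 532, 0.5)
  truth <- Arg(u$values); truth <- truth - mean(truth)
  phi <- tie_initial_phase(h1, h2, eps = 1e-5)
  expect_gt(cor(as.vector(phi), as.vector(truth)), 0.9)
  expect_lt(abs(mean(phi)), 1e-10)
  # equal intensities give a zero phase map
  expect_lt(max(abs(tie_initial_phase(h1, hologram(I1, 215, 532, 0.5)))), 1e-12)
  # invariance to a common intensity scale
  phi2 <- tie_initial_phase(hologram(3 * I1, 200, 532, 0.5),
                            hologram(3 * I2, 215, 532, 0.5), eps = 1e-5)
  expect_lt(max(abs(phi2 - phi)), 1e-8)
  expect_error(tie_initial_phase(h1, hologram(I2, 200, 532, 0.5)), "dz")
})

test_that("multi-height recovery converges on a noiseless simulated stack", {
  ph <- small_phantom(128, seed = 5)
  st <- simulate_hologram_stack(ph, 300 + 15 * (0:7))
  phi0 <- tie_initial_phase(st$holograms[[1]], st$holograms[[8]])
  rec <- multiheight_phase_recovery(st, init_phase = phi0)
  expect_gt(cor(as.vector(Mod(rec$values)), as.vector(ph$amplitude)), 0.9)
  expect_lte(attr(rec, "sweeps"), 20)
  rms <- attr(rec, "rms_history")
  expect_lt(rms[length(rms)], 1e-4)
  # update magnitude non-increasing over the tail of the iteration
  tail_rms <- rms[max(1, length(rms) - 4):length(rms)]
  expect_true(all(diff(tail_rms) <= 1e-12))
  # data misfit at the first plane never increases between sweeps
  mf <- attr(rec, "misfit_history")
  expect_true(all(diff(mf) <= 1e-6 * mf[1]))
})

test_that("single-hologram stack reduces to plain back-propagation", {
  ph <- small_phantom(64, seed = 6)
  st <- simulate_hologram_stack(ph, 250)
  rec <- multiheight_phase_recovery(st)
  h <- st$holograms[[1]]
  direct <- angular_spectrum_propagate(
    complex_field(sqrt(h$intensity), h$pitch_um, h$wavelength_nm), -250)
  expect_identical(rec$values, direct$values)
})

test_that("pure-amplitude objects reconstruct with near-flat phase", {
  ph <- small_phantom(128, seed = 8)
  ph$phase <- ph$phase * 0
  st <- simulate_hologram_stack(ph, 300 + 15 * (0:7))
  rec <- multiheight_phase_recovery(st)
  a <- Arg(rec$values * exp(-1i * mean(Arg(rec$values))))
  expect_lt(sd(a), 0.2)
})

test_that("stack construction validates ordering and finiteness", {
  h1 <- hologram(matrix(1, 8, 8), 100, 532, 0.5)
  h2 <- hologram(matrix(1, 8, 8), 90, 532, 0.5)
  expect_error(hologram_stack(list(h1, h2)), "increasing")
  hbad <- hologram(matrix(1, 8, 8), 200, 532, 0.5)
  hbad$intensity[1] <- NaN
  expect_error(hologram_stack(list(h1, hbad)), "finite")
  expect_error(hologram(matrix(-1, 4, 4), 10, 532, 0.5), "non-negative")
})

test_that("tilt-plane fitting recovers slopes and rejects degenerate input", {
  # coplanar points: exact fit, zero residual
  set.seed(10)
  x <- runif(12, 0, 1000); y <- runif(12, 0, 1000)
  z <- 100 + 0.01 * x
  tp <- fit_tilt_plane(data.frame(x_um = x, y_um = y, z_um = z))
  expect_equal(tp$theta_x_deg, atan(0.01) * 180 / pi, tolerance = 1e-10)
  expect_equal(tp$theta_y_deg, 0, tolerance = 1e-10)
  expect_lt(max(abs(tp$residuals_um)), 1e-9)
  # symmetric noise perturbs angles within a least-squares bound
  eps <- 2
  znoisy <- z + rep(c(eps, -eps), 6)
  tp2 <- fit_tilt_plane(data.frame(x_um = x, y_um = y, z_um = znoisy))
  expect_lt(abs(tp2$theta_x_deg - tp$theta_x_deg),
            atan(4 * eps / diff(range(x))) * 180 / pi)
  # collinear points are rank-deficient
  expect_error(fit_tilt_plane(data.frame(x_um = 1:5, y_um = 2 * (1:5),
                                         z_um = rnorm(5))), "collinear")
  expect_error(fit_tilt_plane(data.frame(x_um = 1:2, y_um = 1:2, z_um = 1:2)),
               "3 points")
})
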