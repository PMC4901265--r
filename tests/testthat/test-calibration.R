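# Four-step CIELAB color calibration.

test_that("white balance divides out the empty-field response", {
  set.seed(1)
  empty <- array(runif(3 * 32 * 32, 0.5, 1), c(32, 32, 3))
  expect_equal(normalize_white_balance(empty, empty),
               array(1, c(32, 32, 3)), tolerance = 1e-12)
  expect_equal(normalize_white_balance(0.5 * empty, empty),
               array(0.5, c(32, 32, 3)), tolerance = 1e-12)
  # channel gains on a flat scene are removed even for a structured empty
  gains <- c(2, 1, 1)
  chk <- outer(rep(c(0.6, 1), length.out = 32), rep(c(1, 0.8), length.out = 32))
  emp2 <- array(0, c(32, 32, 3))
  for (ch in 1:3) emp2[, , ch] <- gains[ch] * chk
  scene <- 0.7 * emp2
  out <- normalize_white_balance(scene, emp2)
  expect_lt(max(abs(out - 0.7)), 1e-12)
  expect_error(normalize_white_balance(empty, empty[1:16, , , drop = FALSE]),
               "shape")
})

test_that("lightness fit matches closed-form least squares", {
  obs <- c(10, 30, 50, 70, 90)
  expect_equal(fit_lightness(obs, obs), c(0, 1), tolerance = 1e-10)
  expect_equal(fit_lightness(obs, 0.8 * obs + 5), c(5, 0.8), tolerance = 1e-10)
  set.seed(2)
  noise <- rnorm(5, 0, 0.5)
  cf <- fit_lightness(obs, 0.8 * obs + 5 + noise)
  # perturbation bounded by the exact LS solution on the noise alone
  X <- cbind(1, obs)
  delta <- solve(t(X) %*% X, t(X) %*% noise)
  expect_equal(cf, c(5, 0.8) + unname(drop(delta)), tolerance = 1e-10)
  expect_error(fit_lightness(rep(50, 5), obs), "constant")
})

test_that("chroma scale is the closed-form scalar least squares", {
  set.seed(3)
  truth <- cbind(runif(8, 20, 80), runif(8, -40, 40), runif(8, -40, 40))
  expect_equal(fit_chroma_scale(truth, truth), 1, tolerance = 1e-12)
  half <- truth; half[, 2:3] <- 0.5 * truth[, 2:3]
  expect_equal(fit_chroma_scale(half, truth), 2, tolerance = 1e-12)
  # mixed desaturation factors: explicit scalar LS oracle
  fac <- rep(c(0.4, 0.5, 0.6), length.out = 8)
  mixed <- truth; mixed[, 2:3] <- fac * truth[, 2:3]
  co <- sqrt(mixed[, 2]^2 + mixed[, 3]^2)
  ct <- sqrt(truth[, 2]^2 + truth[, 3]^2)
  expect_equal(fit_chroma_scale(mixed, truth), sum(co * ct) / sum(co^2),
               tolerance = 1e-12)
  gray <- truth; gray[, 2:3] <- 0
  expect_error(fit_chroma_scale(gray, truth), "gray")
})

test_that("color transform recovers known mappings", {
  set.seed(4)
  obs <- cbind(runif(46, 10, 95), runif(46, -50, 50), runif(46, -50, 50))
  # identity data reproduce the identity mapping on the patches
  U <- fit_color_transform(obs, obs)
  back <- t(U %*% t(dcfm:::.poly_features(obs)))
  expect_lt(max(abs(back - obs)), 1e-8)
  # exact recovery of a random 3x10 generator
  U0 <- matrix(rnorm(30, 0, 0.3), 3, 10)
  truth <- t(U0 %*% t(dcfm:::.poly_features(obs)))
  Uhat <- fit_color_transform(obs, truth)
  expect_lt(max(abs(Uhat - U0)) / max(abs(U0)), 1e-6)
  # square system (m = 10, generic): zero residual
  U10 <- fit_color_transform(obs[1:10, ], truth[1:10, ] + rnorm(30))
  expect_lt(max(attr(U10, "residuals")), 1e-6)
  expect_error(fit_color_transform(obs[1:9, ], obs[1:9, ]), "10")
})

test_that("fitting on perfect data yields an identity calibration", {
  ck <- make_checker_spectra(5)
  truth <- checker_ground_truth(ck)
  obs_rgb <- truth$rgb
  model <- fit_calibration(obs_rgb, truth$lab)
  out <- apply_calibration(obs_rgb, model)
  expect_lt(max(abs(out - obs_rgb)), 1e-6)
  # and on an image: identity model leaves pixels unchanged
  img <- array(runif(3 * 48 * 48, 0.1, 0.9), c(48, 48, 3))
  out_img <- apply_calibration(img, model)
  expect_lt(max(abs(out_img - img)), 1e-4)
})

test_that("model-family distortions are inverted almost exactly", {
  ck <- make_checker_spectra(6)
  truth <- checker_ground_truth(ck)
  cam <- camera_model(desaturation = 0.5)      # pure in-family distortion
  obs <- render_camera(ck, cam)
  model <- fit_calibration(obs, truth$lab, white_rgb = attr(obs, "white_rgb"))
  cal <- apply_calibration(obs, model)
  lab_cal <- xyz_to_lab(linear_rgb_to_xyz(cal))
  expect_lt(mean_cie94(truth$lab, lab_cal), 0.1)
})

test_that("each calibration step improves the simulated distorted camera", {
  ck <- make_checker_spectra(42)
  truth <- checker_ground_truth(ck)
  cam <- camera_model(desaturation = 0.5, noise_sigma = 0.005,
                      spectral_shift_nm = c(12, -10, 8), gains = c(1.3, 1, 0.8))
  obs <- render_camera(ck, cam, seed = 42)
  model <- fit_calibration(obs, truth$lab, white_rgb = attr(obs, "white_rgb"))
  de <- model$training_mean_de94
  expect_true(all(diff(de) <= 1e-9))
  expect_lt(de[["step4"]], 2.5)
})

test_that("calibration commutes with cropping", {
  ck <- make_checker_spectra(7)
  truth <- checker_ground_truth(ck)
  cam <- camera_model(desaturation = 0.6, gains = c(1.2, 1, 0.9))
  obs <- render_camera(ck, cam)
  model <- fit_calibration(obs, truth$lab, white_rgb = attr(obs, "white_rgb"))
  set.seed(8)
  img <- array(runif(3 * 64 * 64, 0.1, 0.9), c(64, 64, 3))
  whole <- apply_calibration(img, model)
  crop <- apply_calibration(img[17:48, 9:40, , drop = FALSE], model)
  expect_equal(whole[17:48, 9:40, ], crop[, , ], tolerance = 1e-12)
})

test_that("patch mean color averages RGB linearly before conversion", {
  img <- array(0.25, c(20, 20, 3))
  u <- patch_mean_color(img, list(rows = 1:20, cols = 1:20))
  expect_equal(unname(u), unname(xyz_to_lab(linear_rgb_to_xyz(rep(0.25, 3)))))
  # half black / half white: RGB mean 0.5, then Lab of mid-gray
  img2 <- array(0, c(20, 20, 3)); img2[1:10, , ] <- 1
  v <- patch_mean_color(img2, list(rows = 1:20, cols = 1:20))
  expect_equal(unname(v), unname(xyz_to_lab(linear_rgb_to_xyz(rep(0.5, 3)))))
  # gradient mean equals the analytic integral mean
  grad <- array(rep(seq(0, 1, length.out = 20), 20 * 3), c(20, 20, 3))
  w <- patch_mean_color(grad, list(rows = 1:20, cols = 1:20))
  expect_equal(unname(w), unname(xyz_to_lab(linear_rgb_to_xyz(rep(0.5, 3)))))
  expect_error(patch_mean_color(img, matrix(FALSE, 20, 20)), "empty")
})
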