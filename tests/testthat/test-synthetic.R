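# Synthetic-data generators: determinism, contracts, physical consistency.

test_that("tissue phantom is deterministic and two-toned", {
  a <- make_tissue_phantom(3, size = 256)
  b <- make_tissue_phantom(3, size = 256)
  expect_identical(a$truth_rgb, b$truth_rgb)
  expect_identical(a$amplitude, b$amplitude)
  expect_true(all(a$amplitude >= 0 & a$amplitude <= 1))
  # nuclei and stroma modes are far apart in color
  nuc <- vapply(1:3, function(ch) mean(a$truth_rgb[, , ch][a$nuclei_mask]),
                numeric(1))
  str_px <- !a$nuclei_mask
  str <- vapply(1:3, function(ch) mean(a$truth_rgb[, , ch][str_px]), numeric(1))
  d <- cie94_distance(xyz_to_lab(linear_rgb_to_xyz(nuc)),
                      xyz_to_lab(linear_rgb_to_xyz(str)))
  expect_gt(d, 15)
  expect_gt(nuc[3], nuc[1])    # nuclei are blue-dominant
  expect_gt(str[1], str[3])    # stroma is red-dominant
  expect_error(make_tissue_phantom(1, size = 128), "256")
})

test_that("nucleus count follows the requested Poisson intensity", {
  lambda <- 6 * 256^2 / 1e4
  counts <- vapply(1:8, function(s) make_tissue_phantom(s, 256)$n_nuclei,
                   numeric(1))
  expect_lt(abs(mean(counts) - lambda) / lambda, 0.15)
})

test_that("hologram simulation is physically consistent", {
  # empty object: uniform unit intensity at every height
  empty <- list(amplitude = matrix(1, 64, 64), phase = matrix(0, 64, 64),
                pitch_um = 0.5)
  st <- simulate_hologram_stack(empty, c(200, 300))
  for (h in st$holograms) expect_lt(max(abs(h$intensity - 1)), 1e-10)
  expect_error(simulate_hologram_stack(empty, c(300, 200)), "ascending")
  # determinism of the noise path
  ph <- small_phantom(64)
  s1 <- simulate_hologram_stack(ph, c(250, 300), noise_sigma = 0.01, seed = 4)
  s2 <- simulate_hologram_stack(ph, c(250, 300), noise_sigma = 0.01, seed = 4)
  expect_identical(s1$holograms[[1]]$intensity, s2$holograms[[1]]$intensity)
})

test_that("doubling the wavelength doubles the Fresnel fringe spacing", {
  n <- 256
  xs <- seq_len(n)
  disk <- outer(xs, xs, function(x, y) (x - n / 2)^2 + (y - n / 2)^2 <= 2.5^2)
  a <- matrix(1, n, n); a[disk] <- 0.1          # small absorber
  ph <- list(amplitude = a, phase = matrix(0, n, n), pitch_um = 0.5)
  # Fresnel zeros satisfy r_k^2 = k * lambda * z + const, so the median
  # successive difference of r^2 at the fringe crossings estimates lambda*z
  fringe_scale <- function(wl) {
    st <- simulate_hologram_stack(ph, 400, wavelength_nm = wl)
    prof <- st$holograms[[1]]$intensity[n / 2, (n / 2):n]
    r <- (seq_along(prof) - 1) * 0.5
    d <- prof - 1
    zc <- r[which(diff(sign(d)) != 0)]
    zc <- zc[zc > 10 & zc < 48]
    zc <- zc[c(TRUE, diff(zc) > 2)]
    median(diff(zc^2))
  }
  s450 <- fringe_scale(450)
  s900 <- fringe_scale(900)
  expect_lt(abs(s450 - 0.45 * 400) / (0.45 * 400), 0.1)  # lambda*z closed form
  expect_lt(abs(s900 - 0.90 * 400) / (0.90 * 400), 0.1)
  expect_lt(abs(s900 / s450 - 2), 0.2)
})

test_that("checker fixture: 46 patches, 22 + 24, spanning the gamut", {
  ck <- make_checker_spectra(42)
  expect_length(ck$spectra, 46)
  expect_equal(as.vector(table(ck$layout$checker)), c(22, 24))
  for (s in ck$spectra) expect_true(all(s$values >= 0 & s$values <= 1))
  expect_identical(make_checker_spectra(42)$spectra, ck$spectra)
  # chromaticity convex hull covers a reasonable gamut area
  truth <- checker_ground_truth(ck)
  xy <- t(apply(truth$xyz, 1, chromaticity))
  hull <- chull(xy)
  area <- abs(sum(xy[hull, 1] * xy[c(hull[-1], hull[1]), 2] -
                    xy[c(hull[-1], hull[1]), 1] * xy[hull, 2])) / 2
  expect_gt(area, 0.05)
})

test_that("camera rendering distorts as configured", {
  ck <- make_checker_spectra(9)
  truth <- checker_ground_truth(ck)
  # colorimetric camera, no distortion: observed colors match ground truth
  ideal <- render_camera(ck, camera_model())
  wb <- sweep(ideal, 2, attr(ideal, "white_rgb"), `/`)
  lab <- xyz_to_lab(linear_rgb_to_xyz(wb))
  expect_lt(mean_cie94(truth$lab, lab), 0.5)
  # desaturation halves every chroma relative to the ideal rendering
  des <- render_camera(ck, camera_model(desaturation = 0.5))
  labd <- xyz_to_lab(linear_rgb_to_xyz(sweep(des, 2, attr(des, "white_rgb"), `/`)))
  chroma <- function(m) sqrt(m[, 2]^2 + m[, 3]^2)
  expect_equal(chroma(labd), 0.5 * chroma(lab), tolerance = 1e-6)
})

test_that("calibration shrinks the distorted camera's error several-fold", {
  ck <- make_checker_spectra(42)
  truth <- checker_ground_truth(ck)
  cam <- camera_model(desaturation = 0.5, noise_sigma = 0.005,
                      spectral_shift_nm = c(12, -10, 8), gains = c(1.3, 1, 0.8))
  obs <- render_camera(ck, cam, seed = 42)
  model <- fit_calibration(obs, truth$lab, white_rgb = attr(obs, "white_rgb"))
  before <- model$training_mean_de94[["step1"]]
  after <- model$training_mean_de94[["step4"]]
  expect_gt(before / after, 3)
})

test_that("lens-based degradation is controllable and recoverable", {
  ph <- make_tissue_phantom(11, size = 256)
  # near-zero blur, no misalignment: near identity
  id <- degrade_to_lensbased(ph$truth_rgb, blur_sigma = 0.01, downsample = 1)
  expect_lt(max(abs(id - ph$truth_rgb)), 1e-3)
  expect_error(degrade_to_lensbased(ph$truth_rgb, blur_sigma = 0), "> 0")
  # known channel offsets recovered by channel alignment
  offs <- rbind(c(3.5, -2.0), c(0, 0), c(-2.5, 1.5))
  shifted <- degrade_to_lensbased(ph$truth_rgb, blur_sigma = 0.7,
                                  downsample = 1, channel_offsets_px = offs)
  al <- align_channels(shifted)
  tr <- attr(al, "transforms")   # H maps G coords to the shifted channel's
  expect_lt(abs(tr$R[1, 3] + 3.5), 0.2)
  expect_lt(abs(tr$R[2, 3] - 2.0), 0.2)
  expect_lt(abs(tr$B[1, 3] - 2.5), 0.2)
  # determinism
  d1 <- degrade_to_lensbased(ph$truth_rgb, 2, 4, noise_sigma = 0.01, seed = 3)
  d2 <- degrade_to_lensbased(ph$truth_rgb, 2, 4, noise_sigma = 0.01, seed = 3)
  expect_identical(d1, d2)
})
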