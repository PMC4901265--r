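# File interchange: hologram stacks as 16-bit grayscale TIFFs with a JSON
# manifest, reconstructions as 32-bit float TIFF pairs with a scale
# sidecar, and calibration models as JSON.

#' Write / read a hologram stack as TIFFs plus a JSON manifest
#'
#' The manifest records wavelength, pitch and, per plane, the file name,
#' z2 and the intensity scale used for 16-bit quantization.
#'
#' @param s A [hologram_stack()].
#' @param dir Output directory (created if needed).
#' @return `write_hologram_stack`: the manifest path, invisibly;
#'   `read_hologram_stack`: a `hologram_stack`.
#' @export
write_hologram_stack <- function(s, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  planes <- lapply(seq_along(s$holograms), function(i) {
    h <- s$holograms[[i]]
    fn <- sprintf("plane_%02d.tif", i)
    scale <- max(h$intensity, 1e-12)
    tiff::writeTIFF(h$intensity / scale, file.path(dir, fn),
                    bits.per.sample = 16)
    list(file = fn, z2_um = h$z2_um, intensity_scale = scale)
  })
  h1 <- s$holograms[[1]]
  manifest <- list(wavelength_nm = h1$wavelength_nm, pitch_um = h1$pitch_um,
                   planes = planes)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hologram_stack
#' @export
read_hologram_stack <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"))
  hs <- lapply(m$planes, function(p) {
    img <- tiff::readTIFF(file.path(dir, p$file))
    hologram(img * p$intensity_scale, p$z2_um, m$wavelength_nm, m$pitch_um)
  })
  hologram_stack(hs)
}

#' Write / read a complex reconstruction as a float TIFF pair
#'
#' Amplitude and phase are written as 32-bit float TIFFs normalized to
#' \[0, 1\]; the normalization constants live in a JSON sidecar so the
#' round trip is lossless up to float precision.
#'
#' @param f A [complex_field()].
#' @param prefix Output path prefix (`<prefix>_amplitude.tif`,
#'   `<prefix>_phase.tif`, `<prefix>_meta.json`).
#' @return `write_reconstruction`: `prefix`, invisibly;
#'   `read_reconstruction`: a `complex_field`.
#' @export
write_reconstruction <- function(f, prefix) {
  amp <- Mod(f$values)
  phs <- Arg(f$values)
  amp_max <- max(amp, 1e-12)
  tiff::writeTIFF(amp / amp_max, paste0(prefix, "_amplitude.tif"),
                  bits.per.sample = 32)
  tiff::writeTIFF((phs + pi) / (2 * pi), paste0(prefix, "_phase.tif"),
                  bits.per.sample = 32)
  jsonlite::write_json(list(amplitude_scale = amp_max,
                            pitch_um = f$pitch_um,
                            wavelength_nm = f$wavelength_nm,
                            n_medium = f$n_medium),
                       paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_reconstruction
#' @export
read_reconstruction <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"))
  amp <- tiff::readTIFF(paste0(prefix, "_amplitude.tif")) * meta$amplitude_scale
  phs <- tiff::readTIFF(paste0(prefix, "_phase.tif")) * 2 * pi - pi
  complex_field(amp * exp(1i * phs), meta$pitch_um, meta$wavelength_nm,
                meta$n_medium)
}

#' Save / load a calibration model as JSON
#'
#' Stores the white reference, lightness coefficients, chroma scale, the
#' transform U (row-major) and the versioned feature term order.
#'
#' @param model A fitted `calibration_model`.
#' @param path JSON file path.
#' @return `save_calibration_model`: `path`, invisibly;
#'   `load_calibration_model`: a `calibration_model`.
#' @export
save_calibration_model <- function(model, path) {
  obj <- list(white_rgb = model$white_rgb,
              lightness_coef = model$lightness_coef,
              lightness_degree = model$lightness_degree,
              chroma_scale = model$chroma_scale,
              U_row_major = as.vector(t(model$U)),
              term_order = model$term_order,
              training_mean_de94 = as.list(model$training_mean_de94),
              created = format(Sys.time(), tz = "UTC"),
              package_version = as.character(utils::packageVersion("dcfm")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration_model
#' @export
load_calibration_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$term_order, .term_order))
    stop("calibration model uses an unsupported feature term order: ",
         o$term_order)
  structure(list(white_rgb = o$white_rgb,
                 lightness_coef = o$lightness_coef,
                 lightness_degree = o$lightness_degree,
                 chroma_scale = o$chroma_scale,
                 U = matrix(o$U_row_major, 3, 10, byrow = TRUE),
                 term_order = o$term_order,
                 training_mean_de94 = unlist(o$training_mean_de94)),
            class = "calibration_model")
}

#' Read / write a linear RGB image as TIFF
#'
#' Thin wrappers around the tiff package keeping images as plain arrays in
#' \[0, 1\].
#'
#' @param path TIFF file path.
#' @param img H x W x 3 array (values clipped to \[0, 1\] on write).
#' @param bits Bits per sample on write (default 16).
#' @return `read_rgb_tiff`: H x W x 3 array; `write_rgb_tiff`: `path`,
#'   invisibly.
#' @export
read_rgb_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_rgb_tiff
#' @export
write_rgb_tiff <- function(img, path, bits = 16) {
  tiff::writeTIFF(pmin(pmax(img, 0), 1), path, bits.per.sample = bits)
  invisible(path)
}
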