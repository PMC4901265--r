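# Conditioning of demosaiced mobile-camera captures: inter-channel
# projective alignment and wavelet hard-threshold denoising (the denoiser
# itself lives in wavelet.R).

#' Align the R and B channels of a demosaiced capture onto the G channel
#'
#' Cheap lens modules displace the color channels relative to each other;
#' this estimates a projective transform per channel from control-point
#' matches (with RANSAC outlier rejection) and warps R and B onto G. G, the
#' most densely sampled channel of a Bayer mosaic, is left unchanged.
#'
#' @param img H x W x 3 array of linear RGB planes (values >= 0).
#' @param min_matches Minimum robust matches per channel (default 8).
#' @param pass_through If `TRUE`, a channel whose alignment fails is left
#'   untouched (with a warning) instead of erroring.
#' @param ... Passed to [register_projective()].
#' @return Array of the same shape with aligned channels; attribute
#'   `transforms` holds the per-channel homographies.
#' @export
align_channels <- function(img, min_matches = 8, pass_through = FALSE, ...) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  g <- img[, , 2]
  out <- img
  tr <- list(R = diag(3), G = diag(3), B = diag(3))
  for (ch in c(1, 3)) {
    name <- c("R", "", "B")[ch]
    res <- tryCatch(register_projective(g, img[, , ch],
                                        min_matches = min_matches, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (pass_through) {
        warning("channel ", name, " alignment failed (", conditionMessage(res),
                "); passing through unaligned")
        next
      }
      stop("channel ", name, " alignment failed: ", conditionMessage(res))
    }
    # skip the resampling when the transform is indistinguishable from the
    # identity: repeated alignment is then exactly idempotent
    corners <- cbind(c(1, ncol(g), 1, ncol(g)), c(1, 1, nrow(g), nrow(g)))
    disp <- max(sqrt(rowSums((.apply_homography(res$H, corners) - corners)^2)))
    if (disp >= 0.1) {
      out[, , ch] <- res$warped
      tr[[name]] <- res$H
    }
  }
  attr(out, "transforms") <- tr
  out
}

#' Denoise each channel of an RGB image by wavelet hard thresholding
#'
#' @param img H x W x 3 array (or 2D matrix, treated as one channel).
#' @inheritParams wavelet_denoise
#' @return Denoised image of the same shape.
#' @export
denoise_rgb <- function(img, wavelet = "bior3.7", levels = 3, threshold = NULL) {
  if (is.matrix(img)) return(wavelet_denoise(img, wavelet, levels, threshold))
  for (ch in seq_len(dim(img)[3]))
    img[, , ch] <- wavelet_denoise(img[, , ch], wavelet, levels, threshold)
  img
}
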