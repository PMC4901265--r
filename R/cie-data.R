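# CIE standard-observer and illuminant tables, shipped as constants so that
# ground-truth colors are bit-reproducible across machines.

#' Wavelength grid used throughout the package
#'
#' The hyperspectral acquisition grid: 400 to 700 nm in 10 nm steps
#' (31 samples). All shipped spectral tables live on this grid.
#'
#' @return Numeric vector of wavelengths in nanometres.
#' @export
dcfm_wavelengths <- function() seq(400, 700, by = 10)

# CIE 1931 2-degree standard observer, 10 nm tabulation, 400-700 nm.
.cie1931_xbar <- c(
  0.014310, 0.043510, 0.134380, 0.283900, 0.348280, 0.336200, 0.290800,
  0.195360, 0.095640, 0.032010, 0.004900, 0.009300, 0.063270, 0.165500,
  0.290400, 0.433450, 0.594500, 0.762100, 0.916300, 1.026300, 1.062200,
  1.002600, 0.854450, 0.642400, 0.447900, 0.283500, 0.164900, 0.087400,
  0.046770, 0.022700, 0.011359)

.cie1931_ybar <- c(
  0.000396, 0.001210, 0.004000, 0.011600, 0.023000, 0.038000, 0.060000,
  0.090980, 0.139020, 0.208020, 0.323000, 0.503000, 0.710000, 0.862000,
  0.954000, 0.994950, 0.995000, 0.952000, 0.870000, 0.757000, 0.631000,
  0.503000, 0.381000, 0.265000, 0.175000, 0.107000, 0.061000, 0.032000,
  0.017000, 0.008210, 0.004102)

.cie1931_zbar <- c(
  0.067850, 0.207400, 0.645600, 1.385600, 1.747060, 1.772110, 1.669200,
  1.287640, 0.812950, 0.465180, 0.272000, 0.158200, 0.078250, 0.042160,
  0.020300, 0.008750, 0.003900, 0.002100, 0.001650, 0.001100, 0.000800,
  0.000340, 0.000190, 0.000050, 0.000020, 0.000000, 0.000000, 0.000000,
  0.000000, 0.000000, 0.000000)

# CIE standard illuminant D65, relative spectral power, same grid.
.d65_spd <- c(
   82.7549,  91.4860,  93.4318,  86.6823, 104.8650, 117.0080, 117.8120,
  114.8610, 115.9230, 108.8110, 109.3540, 107.8020, 104.7900, 107.6890,
  104.4050, 104.0460, 100.0000,  96.3342,  95.7880,  88.6856,  90.0062,
   89.5991,  87.6987,  83.2886,  83.6992,  80.0268,  80.2146,  82.2778,
   78.2842,  69.7213,  71.6091)

#' CIE 1931 2-degree color matching functions with D65 illuminant
#'
#' Returns the standard-observer responsivities resampled to the package's
#' 10 nm grid together with the D65 relative spectral power distribution.
#'
#' @return An object of class `cmf_set`: a list with `wavelengths_nm`,
#'   `xbar`, `ybar`, `zbar` and `illuminant`.
#' @export
cmf_cie1931_d65 <- function() {
  structure(
    list(wavelengths_nm = dcfm_wavelengths(),
         xbar = .cie1931_xbar, ybar = .cie1931_ybar, zbar = .cie1931_zbar,
         illuminant = .d65_spd),
    class = "cmf_set")
}
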