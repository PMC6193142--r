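# Per-particle corrections applied before alignment:
#   phase flip -> edge-mean normalization -> top-hat band-pass.
# The order is fixed; preprocess_stack() records it in an attribute.

#' Contrast transfer function parameters
#'
#' Defocus follows the printed convention of negative-stain work: negative
#' values denote underfocus (e.g. -0.75 um).
#'
#' @param defocus_um defocus in micrometres (negative = underfocus).
#' @param voltage_kv acceleration voltage in kV.
#' @param cs_mm spherical aberration in mm.
#' @param amplitude_contrast amplitude contrast fraction in `[0, 1]`.
#' @param pixel_size pixel size in Angstrom.
#' @return An object of class `ctf_params`.
#' @export
ctf_params <- function(defocus_um = -0.75, voltage_kv = 120, cs_mm = 2.0,
                       amplitude_contrast = 0.10, pixel_size = 4) {
  stopifnot_scalar(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop("pixel size must be positive")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("amplitude contrast must be in [0, 1]")
  structure(list(defocus_um = defocus_um, voltage_kv = voltage_kv,
                 cs_mm = cs_mm, amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size),
            class = "ctf_params")
}

# relativistic electron wavelength in Angstrom
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2639 / sqrt(v * (1 + 0.97845e-6 * v))
}

#' Evaluate the CTF at spatial frequencies
#'
#' `CTF(k) = -(sqrt(1 - A^2) sin(gamma) + A cos(gamma))` with the phase
#' `gamma(k) = -pi lambda z k^2 + (pi/2) Cs lambda^3 k^4`, `z` the
#' underfocus in Angstrom (positive for printed negative defocus).
#'
#' @param ctf a [ctf_params()] object.
#' @param freq spatial frequencies in 1/Angstrom.
#' @return CTF values (positive contrast at low frequency for underfocus).
#' @export
ctf_eval <- function(ctf, freq) {
  lambda <- electron_wavelength(ctf$voltage_kv)
  z <- -ctf$defocus_um * 1e4          # underfocus, Angstrom
  cs <- ctf$cs_mm * 1e7
  a <- ctf$amplitude_contrast
  gamma <- -pi * lambda * z * freq^2 + (pi / 2) * cs * lambda^3 * freq^4
  -(sqrt(1 - a^2) * sin(gamma) + a * cos(gamma))
}

#' First zero crossing of the CTF
#'
#' Located by bracketing the first sign change of [ctf_eval()] on a fine
#' frequency grid and polishing with [stats::uniroot()].
#'
#' @param ctf a [ctf_params()] object.
#' @param max_freq upper search bound in 1/Angstrom (default Nyquist).
#' @return Frequency of the first zero in 1/Angstrom, or `NA` if none below
#'   `max_freq`.
#' @export
ctf_first_zero <- function(ctf, max_freq = 1 / (2 * ctf$pixel_size)) {
  k <- seq(1e-5, max_freq, length.out = 4096)
  v <- ctf_eval(ctf, k)
  s <- which(v[-1] * v[-length(v)] <= 0)
  if (length(s) == 0) return(NA_real_)
  uniroot(function(q) ctf_eval(ctf, q), c(k[s[1]], k[s[1] + 1]),
          tol = 1e-10)$root
}

#' Phase-flip CTF correction
#'
#' Multiplies each Fourier coefficient by the sign of the CTF at its radial
#' frequency; the DC term is untouched.  Applying the correction twice
#' returns the original image (involution).
#'
#' @param image square numeric matrix.
#' @param ctf a [ctf_params()] object (its `pixel_size` is used).
#' @return The corrected image.
#' @export
phase_flip <- function(image, ctf) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("'image' must be a square matrix")
  if (ctf$pixel_size <= 0) stop("zero pixel size")
  n <- nrow(image)
  fx <- fft_freq(n, ctf$pixel_size)
  k <- sqrt(outer(fx^2, fx^2, `+`))
  sgn <- sign(ctf_eval(ctf, k))
  sgn[1, 1] <- 1          # DC untouched
  sgn[sgn == 0] <- 1
  ft <- fft(image) * sgn
  out <- Re(fft(ft, inverse = TRUE)) / length(image)
  dimnames(out) <- NULL
  out
}

#' Edge-mean normalization
#'
#' Subtracts the mean of the 1-px border ring, then divides by the global
#' standard deviation of the residual; a constant image maps to all zeros
#' and is flagged in the `"flagged"` attribute.
#'
#' @param image numeric matrix, at least 3x3.
#' @return Normalized image; border-ring mean 0 and global SD 1.
#' @export
edge_mean_normalize <- function(image) {
  if (!is.matrix(image) || any(dim(image) < 3L))
    stop("'image' must be a matrix of at least 3x3")
  n <- nrow(image); m <- ncol(image)
  border <- c(image[1, ], image[n, ], image[2:(n - 1), 1], image[2:(n - 1), m])
  res <- image - mean(border)
  s <- sqrt(mean(res^2) - mean(res)^2)
  if (s == 0) {
    out <- array(0, dim(image))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  out <- res / s
  attr(out, "flagged") <- FALSE
  out
}

#' Top-hat band-pass filter
#'
#' Zeroes Fourier amplitudes outside `[1/highpass, 1/lowpass]` cycles per
#' Angstrom with hard edges (ringing is accepted; this is the filter the
#' single-particle pipeline uses, 600 A / 20 A by default).
#'
#' @param image numeric matrix.
#' @param pixel_size pixel size in Angstrom.
#' @param highpass high-pass cut-on wavelength in Angstrom.
#' @param lowpass low-pass cut-off wavelength in Angstrom.
#' @return Filtered image; Parseval energy never increases.
#' @export
bandpass_tophat <- function(image, pixel_size, highpass = 600, lowpass = 20) {
  if (!(highpass > lowpass)) stop("need highpass > lowpass (both in Angstrom)")
  nyq <- 1 / (2 * pixel_size)
  if (1 / lowpass > nyq)
    stop(sprintf("lowpass %g A is beyond Nyquist (%g A at %g A/px)",
                 lowpass, 1 / nyq, pixel_size))
  n <- nrow(image); m <- ncol(image)
  k <- sqrt(outer(fft_freq(n, pixel_size)^2, fft_freq(m, pixel_size)^2, `+`))
  keep <- k >= 1 / highpass & k <= 1 / lowpass
  ft <- fft(image) * keep
  out <- Re(fft(ft, inverse = TRUE)) / length(image)
  dimnames(out) <- NULL
  out
}

#' Preprocess a particle stack
#'
#' Applies, in this fixed order: phase-flip CTF correction (if `ctf` is
#' given), edge-mean normalization, top-hat band-pass.  The order is
#' recorded in the `"preprocess_log"` attribute of the result.
#'
#' @param stack a [particle_stack()].
#' @param ctf optional [ctf_params()]; its pixel size is overridden by the
#'   stack's.
#' @param highpass,lowpass band-pass wavelengths in Angstrom.
#' @return A preprocessed [particle_stack()].
#' @export
preprocess_stack <- function(stack, ctf = NULL, highpass = 600, lowpass = 20) {
  px <- voxel_size(stack)
  steps <- character(0)
  if (!is.null(ctf)) {
    ctf$pixel_size <- px
    steps <- "phase_flip"
  }
  steps <- c(steps, "edge_mean_normalize", "bandpass_tophat")
  out <- as_plain_array(stack)
  for (i in seq_len(dim(out)[3])) {
    img <- out[, , i]
    if (!is.null(ctf)) img <- phase_flip(img, ctf)
    img <- edge_mean_normalize(img)
    img <- bandpass_tophat(img, px, highpass, lowpass)
    out[, , i] <- img
  }
  res <- particle_stack(out, px)
  attr(res, "preprocess_log") <- steps
  res
}
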