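#' Specify a Gabor-in-noise stimulus
#'
#' Bundles every physical parameter of the oriented-grating-in-noise
#' stimulus: a Gabor patch (peak contrast `peak_contrast_cp`, orientation
#' `orientation_theta`, spatial frequency `spatial_freq_f`, Gaussian
#' envelope `envelope_sigma`, phase `phase_psi` in cycles) is mixed
#' additively with spectrally bandpass-filtered noise of contrast
#' `noise_contrast_cn` on a square pixel grid, and faded to the background
#' luminance by a circular Butterworth-style aperture.
#'
#' The defaults describe a 300 x 300 pixel patch spanning 5.3 x 5.3 degrees
#' of visual angle: a 1.25 cycles/degree Gabor with envelope SD 0.6 degrees
#' and phase 0.25 cycles, 15% noise contrast, background luminance
#' 51.9 cd/m2, and a radius-2.5 degree aperture whose half-amplitude point
#' sits at 1/(2 x 0.275) = 1.82 degrees.
#'
#' @param peak_contrast_cp Gabor peak contrast, percent in \[0, 100\].
#' @param noise_contrast_cn Noise peak contrast, percent.
#' @param orientation_theta Carrier orientation, degrees. The discrimination
#'   task uses +/-20 degrees around a reference axis at 0 (vertical) or 90
#'   (horizontal), i.e. -20, 20, 70 or 110.
#' @param phase_psi Carrier phase in cycles; the carrier phase in radians is
#'   `2 * pi * phase_psi`.
#' @param spatial_freq_f Carrier spatial frequency, cycles/degree.
#' @param envelope_sigma Gaussian envelope SD, degrees.
#' @param background_L0 Background luminance, cd/m2.
#' @param grid_px Image side length, pixels (square grid).
#' @param grid_deg Image side length, degrees of visual angle.
#' @param aperture_radius Hard crop radius of the aperture, degrees.
#' @param aperture_cutoff Aperture cut-off frequency, cycles/degree; the
#'   radial fade window is `1 / (1 + (2 * cutoff * r)^(2 * order))`.
#' @param aperture_order Aperture window order (integer).
#' @param trim_level Gabor values with absolute value below this are set
#'   to zero (patch trimming).
#' @param noise_order Butterworth order of the two low-pass filters whose
#'   difference defines the noise power spectrum.
#' @param noise_norm How the noise field is standardised after the inverse
#'   Fourier transform: `"peak"` scales to unit maximum absolute value (so
#'   `noise_contrast_cn` is a peak contrast, like the Gabor's), `"sd"`
#'   scales to unit standard deviation.
#'
#' @return An object of class `cl_stimulus_spec` (a named list).
#' @examples
#' spec <- stimulus_spec(peak_contrast_cp = 8, orientation_theta = 20)
#' img <- make_stimulus(spec, seed = 1)
#' @export
stimulus_spec <- function(peak_contrast_cp = 100,
                          noise_contrast_cn = 15,
                          orientation_theta = 20,
                          phase_psi = 0.25,
                          spatial_freq_f = 1.25,
                          envelope_sigma = 0.6,
                          background_L0 = 51.9,
                          grid_px = 300L,
                          grid_deg = 5.3,
                          aperture_radius = 2.5,
                          aperture_cutoff = 0.275,
                          aperture_order = 7L,
                          trim_level = 0.005,
                          noise_order = 3L,
                          noise_norm = c("peak", "sd")) {
  assert_scalar_num(peak_contrast_cp, "peak_contrast_cp", 0, 100)
  assert_scalar_num(noise_contrast_cn, "noise_contrast_cn", 0, 100)
  assert_scalar_num(orientation_theta, "orientation_theta")
  assert_scalar_num(phase_psi, "phase_psi")
  assert_scalar_num(spatial_freq_f, "spatial_freq_f", 0, strict_lower = TRUE)
  assert_scalar_num(envelope_sigma, "envelope_sigma", 0, strict_lower = TRUE)
  assert_scalar_num(background_L0, "background_L0", 0)
  assert_scalar_num(grid_px, "grid_px", 2)
  assert_scalar_num(grid_deg, "grid_deg", 0, strict_lower = TRUE)
  assert_scalar_num(aperture_radius, "aperture_radius", 0, strict_lower = TRUE)
  assert_scalar_num(aperture_cutoff, "aperture_cutoff", 0, strict_lower = TRUE)
  assert_scalar_num(aperture_order, "aperture_order", 1)
  assert_scalar_num(trim_level, "trim_level", 0)
  assert_scalar_num(noise_order, "noise_order", 1)
  spec <- list(
    peak_contrast_cp = peak_contrast_cp,
    noise_contrast_cn = noise_contrast_cn,
    orientation_theta = orientation_theta,
    phase_psi = phase_psi,
    spatial_freq_f = spatial_freq_f,
    envelope_sigma = envelope_sigma,
    background_L0 = background_L0,
    grid_px = as.integer(grid_px),
    grid_deg = grid_deg,
    aperture_radius = aperture_radius,
    aperture_cutoff = aperture_cutoff,
    aperture_order = as.integer(aperture_order),
    trim_level = trim_level,
    noise_order = as.integer(noise_order),
    noise_norm = match.arg(noise_norm)
  )
  structure(spec, class = "cl_stimulus_spec")
}

#' @export
print.cl_stimulus_spec <- function(x, ...) {
  cat("<stimulus spec> ", x$grid_px, "x", x$grid_px, " px (",
      x$grid_deg, " deg), theta = ", x$orientation_theta,
      " deg, cp = ", x$peak_contrast_cp, "%, cn = ",
      x$noise_contrast_cn, "%\n", sep = "")
  invisible(x)
}

degrees_per_pixel <- function(spec) spec$grid_deg / spec$grid_px

# Pixel-centre coordinates in degrees, image centre at (0, 0).
# x runs rightward along columns, y downward along rows; for an even grid
# the centres sit at half-integer pixel offsets around the origin.
grid_coords <- function(spec) {
  n <- spec$grid_px
  dpp <- degrees_per_pixel(spec)
  ((seq_len(n)) - (n + 1) / 2) * dpp
}

#' Generate the Gabor term of a stimulus
#'
#' Evaluates a unit-amplitude Gabor patch
#' `G(x, y) = exp(-(x^2 + y^2) / (2 sigma^2)) *
#'   sin(2 pi f (x cos(theta) + y sin(theta)) + phi)`
#' with `phi = 2 pi * phase_psi`, on the spec's pixel grid, and trims
#' values smaller in magnitude than `trim_level` to zero.
#'
#' @param spec A [stimulus_spec()].
#' @return A `grid_px` x `grid_px` numeric matrix (unitless, in \[-1, 1\]).
#' @examples
#' G <- make_gabor(stimulus_spec())
#' range(G)
#' @export
make_gabor <- function(spec) {
  stopifnot(inherits(spec, "cl_stimulus_spec"))
  co <- grid_coords(spec)
  x <- matrix(co, spec$grid_px, spec$grid_px, byrow = TRUE)  # columns
  y <- matrix(co, spec$grid_px, spec$grid_px)                # rows
  gabor_field(x, y, spec)
}

# Gabor evaluated on arbitrary coordinates (degrees).
gabor_field <- function(x, y, spec) {
  th <- spec$orientation_theta * pi / 180
  phi <- 2 * pi * spec$phase_psi
  env <- exp(-(x^2 + y^2) / (2 * spec$envelope_sigma^2))
  g <- env * sin(2 * pi * spec$spatial_freq_f *
                   (x * cos(th) + y * sin(th)) + phi)
  g[abs(g) < spec$trim_level] <- 0
  g
}

# FFT frequency coordinates (cycles/degree) for an n-point axis.
fft_freqs <- function(n, dpp) {
  k <- seq_len(n) - 1L
  ifelse(k <= n / 2, k, k - n) / (n * dpp)
}

#' Generate a bandpass-filtered noise field
#'
#' Constructs phase-randomised spectrally filtered noise: a bandpass
#' spectrum is built as the difference of two radial Butterworth low-pass
#' filters (order `noise_order`) with cut-off frequencies one octave below
#' and one octave above the Gabor's spatial frequency (`f/2` and `2f`);
#' it is combined with an i.i.d. uniform \[0, 2 pi) phase spectrum and the
#' field is the real part of the inverse Fourier transform, with the DC
#' coefficient zeroed.  The result is standardised according to
#' `spec$noise_norm` (unit peak by default, so that the noise contrast is
#' a peak contrast).
#'
#' @inheritParams make_gabor
#' @param seed Integer seed; the field is bit-reproducible per seed.
#' @return A zero-mean `grid_px` x `grid_px` numeric matrix with attributes
#'   `seed` and `cutoffs` (cycles/degree).
#' @examples
#' N <- make_noise_field(stimulus_spec(), seed = 7)
#' abs(mean(N)) < 1e-12
#' @export
make_noise_field <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cl_stimulus_spec"))
  n <- spec$grid_px
  dpp <- degrees_per_pixel(spec)
  f <- spec$spatial_freq_f
  cutoffs <- c(low = f / 2, high = 2 * f)
  fr <- sqrt(outer(fft_freqs(n, dpp)^2, fft_freqs(n, dpp)^2, `+`))
  bw <- function(fc) 1 / (1 + (fr / fc)^(2 * spec$noise_order))
  pow <- bw(cutoffs[["high"]]) - bw(cutoffs[["low"]])
  pow[pow < 0] <- 0
  pow[1, 1] <- 0  # DC
  phase <- with_seed(seed, matrix(runif(n * n, 0, 2 * pi), n, n))
  field <- Re(fft(pow * exp(1i * phase), inverse = TRUE)) / (n * n)
  field <- field - mean(field)
  s <- switch(spec$noise_norm,
              peak = max(abs(field)),
              sd = sd(as.vector(field)))
  if (s == 0) abort("Degenerate noise field (zero everywhere).")
  field <- field / s
  structure(field, seed = seed, cutoffs = cutoffs)
}

#' Combine Gabor and noise terms into a luminance image
#'
#' Forms the additive mixture
#' `L(x, y) = (1 + cp/100 * G(x, y) + cn/100 * N(x, y)) * L0`
#' and applies the circular aperture ([apply_circular_aperture()]).
#' Negative luminances (possible for extreme contrast combinations) are
#' clipped to zero with a warning.
#'
#' @param gabor Matrix from [make_gabor()] (or zeros for noise-only).
#' @param noise Matrix from [make_noise_field()] (or zeros for a noiseless
#'   Gabor).
#' @param spec A [stimulus_spec()].
#' @param aperture Apply the circular aperture (default `TRUE`).
#' @return A `cl_luminance_image`: a numeric matrix of luminances (cd/m2)
#'   with attributes `degrees_per_pixel` and `background`.
#' @export
compose_stimulus <- function(gabor, noise, spec, aperture = TRUE) {
  stopifnot(inherits(spec, "cl_stimulus_spec"))
  if (!all(dim(gabor) == c(spec$grid_px, spec$grid_px)) ||
      !all(dim(noise) == c(spec$grid_px, spec$grid_px))) {
    abort("`gabor` and `noise` must both live on the spec's grid.")
  }
  lum <- (1 + spec$peak_contrast_cp / 100 * gabor +
            spec$noise_contrast_cn / 100 * noise) * spec$background_L0
  if (any(lum < 0)) {
    warn("Luminance below zero after mixing; clipping to 0 cd/m2.")
    lum[lum < 0] <- 0
  }
  img <- luminance_image(lum, spec)
  if (aperture) img <- apply_circular_aperture(img, spec)
  img
}

luminance_image <- function(values, spec) {
  structure(values,
            degrees_per_pixel = degrees_per_pixel(spec),
            background = spec$background_L0,
            class = c("cl_luminance_image", "matrix", "array"))
}

#' @export
print.cl_luminance_image <- function(x, ...) {
  cat("<luminance image> ", nrow(x), "x", ncol(x), " px, ",
      signif(attr(x, "degrees_per_pixel") * nrow(x), 3),
      " deg, range [", signif(min(x), 4), ", ", signif(max(x), 4),
      "] cd/m2\n", sep = "")
  invisible(x)
}

#' Fade a luminance image to background with a circular aperture
#'
#' Multiplies the deviation from background luminance by the radial window
#' `W(r) = 1 / (1 + (2 * cutoff * r)^(2 * order))` — the squared-magnitude
#' response of a Butterworth low-pass filter read as a spatial fade, unity
#' at the centre with half-amplitude at `r = 1/(2 * cutoff)` — and hard-sets
#' every pixel beyond `aperture_radius` to the background luminance.
#'
#' @param img A `cl_luminance_image` on the spec's grid.
#' @param spec A [stimulus_spec()].
#' @return The faded `cl_luminance_image`.
#' @export
apply_circular_aperture <- function(img, spec) {
  stopifnot(inherits(spec, "cl_stimulus_spec"))
  if (!all(dim(img) == c(spec$grid_px, spec$grid_px))) {
    abort("`img` must live on the spec's grid.")
  }
  co <- grid_coords(spec)
  r <- sqrt(outer(co^2, co^2, `+`))
  w <- aperture_window(r, spec$aperture_cutoff, spec$aperture_order)
  L0 <- spec$background_L0
  out <- L0 + (unclass(img) - L0) * w
  out[r > spec$aperture_radius] <- L0
  luminance_image(out, spec)
}

aperture_window <- function(r, cutoff, order) {
  1 / (1 + (2 * cutoff * r)^(2 * order))
}

#' Synthesise a complete stimulus
#'
#' Convenience wrapper: Gabor term + noise field + additive mixture +
#' circular aperture.
#'
#' @inheritParams make_noise_field
#' @return A `cl_luminance_image`.
#' @export
make_stimulus <- function(spec, seed = NULL) {
  compose_stimulus(make_gabor(spec), make_noise_field(spec, seed), spec)
}
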