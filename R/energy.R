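#' Build a quadrature orientation-energy filter bank
#'
#' The representational front end: for each orientation x spatial-frequency
#' pair it holds a quadrature pair of band-limited, zero-mean Gabor kernels
#' (cosine and sine phase, a quarter-cycle apart).  Squaring and summing the
#' two filter responses yields a phase-invariant local energy map; pooling
#' the map over space gives one location-tolerant, unnormalised energy
#' scalar per (orientation, frequency) channel — a model of pooled V1
#' complex-cell output.
#'
#' The kernel envelope SD is set from the frequency bandwidth:
#' `sigma = sqrt(log(2)/2) / (pi * f) * (2^b + 1) / (2^b - 1)` for a
#' half-amplitude bandwidth of `b` octaves.
#'
#' @param orientations Orientations (degrees) the bank is tuned to.
#'   Defaults to the task's +/-20 degree offsets around the vertical and
#'   horizontal reference axes: -20, 20, 70, 110.
#' @param freqs Spatial frequencies, cycles/degree.
#' @param bandwidth_octaves Half-amplitude frequency bandwidth, octaves.
#' @param kernel_extent Kernel side length, degrees; must hold at least one
#'   carrier cycle.
#' @param degrees_per_pixel Sampling resolution of the images the bank will
#'   be applied to.
#' @param pooling Spatial pooling operator for the energy map, `"sum"` or
#'   `"max"`.
#' @return A `cl_filter_bank`.
#' @examples
#' bank <- build_filter_bank()
#' @export
build_filter_bank <- function(orientations = c(-20, 20, 70, 110),
                              freqs = 1.25,
                              bandwidth_octaves = 1,
                              kernel_extent = 2.4,
                              degrees_per_pixel = 5.3 / 300,
                              pooling = c("sum", "max")) {
  pooling <- match.arg(pooling)
  if (kernel_extent < 1 / min(freqs)) {
    abort("`kernel_extent` too small to hold one carrier cycle.")
  }
  npx <- floor(kernel_extent / degrees_per_pixel)
  if (npx %% 2 == 0) npx <- npx + 1L  # odd size, centred kernel
  co <- (seq_len(npx) - (npx + 1) / 2) * degrees_per_pixel
  x <- matrix(co, npx, npx, byrow = TRUE)
  y <- matrix(co, npx, npx)
  b <- 2^bandwidth_octaves
  kernels <- list()
  for (f in freqs) {
    sigma <- sqrt(log(2) / 2) / (pi * f) * (b + 1) / (b - 1)
    env <- exp(-(x^2 + y^2) / (2 * sigma^2))
    for (th in orientations) {
      thr <- th * pi / 180
      arg <- 2 * pi * f * (x * cos(thr) + y * sin(thr))
      even <- env * cos(arg)
      odd <- env * sin(arg)
      even <- even - mean(even)  # zero DC response
      odd <- odd - mean(odd)
      kernels[[key_of(th, f)]] <- list(even = even, odd = odd,
                                       orientation = th, freq = f)
    }
  }
  structure(list(orientations = orientations, freqs = freqs,
                 bandwidth_octaves = bandwidth_octaves,
                 degrees_per_pixel = degrees_per_pixel,
                 kernel_px = npx, pooling = pooling, kernels = kernels),
            class = "cl_filter_bank")
}

key_of <- function(th, f) sprintf("th%+.4f_f%.4f", th, f)

#' @export
print.cl_filter_bank <- function(x, ...) {
  cat("<filter bank> ", length(x$kernels), " quadrature pairs (",
      length(x$orientations), " orientations x ", length(x$freqs),
      " frequencies), ", x$kernel_px, " px kernels, pooling = ",
      x$pooling, "\n", sep = "")
  invisible(x)
}

# 2-D "same"-size linear convolution via zero-padded FFTs.
conv2_same <- function(img, kern) {
  ni <- dim(img); nk <- dim(kern)
  n <- ni + nk - 1L
  pi_ <- matrix(0, n[1], n[2]); pi_[seq_len(ni[1]), seq_len(ni[2])] <- img
  pk <- matrix(0, n[1], n[2]); pk[seq_len(nk[1]), seq_len(nk[2])] <- kern
  full <- Re(fft(fft(pi_) * fft(pk), inverse = TRUE)) / prod(n)
  off <- (nk - 1L) %/% 2L
  full[off[1] + seq_len(ni[1]), off[2] + seq_len(ni[2])]
}

#' Pooled orientation energy of a stimulus image
#'
#' Contrast-normalises the image (`(L - L0) / L0`), convolves it with the
#' quadrature pair tuned to (`orientation`, `freq`), squares and sums the
#' two response maps into a local energy map, and pools over space with the
#' bank's pooling operator.  The result is a single unnormalised energy
#' scalar, invariant to the carrier phase and tolerant to stimulus
#' location.
#'
#' @param img A `cl_luminance_image` (or a plain matrix already in contrast
#'   units, in which case `background` must be `NULL`-safe).
#' @param bank A [build_filter_bank()].
#' @param orientation,freq Channel to read out; must be present in the
#'   bank.
#' @return A non-negative scalar.
#' @export
orientation_energy <- function(img, bank, orientation, freq = bank$freqs[1]) {
  stopifnot(inherits(bank, "cl_filter_bank"))
  k <- bank$kernels[[key_of(orientation, freq)]]
  if (is.null(k)) {
    abort(sprintf("Channel (%s deg, %s cpd) not present in the bank.",
                  orientation, freq))
  }
  cimg <- contrast_image(img)
  emap <- conv2_same(cimg, k$even)^2 + conv2_same(cimg, k$odd)^2
  switch(bank$pooling, sum = sum(emap), max = max(emap))
}

contrast_image <- function(img) {
  if (inherits(img, "cl_luminance_image")) {
    L0 <- attr(img, "background")
    (unclass(img) - L0) / L0
  } else {
    unclass(img)
  }
}

#' All channel energies of one image, as a tibble
#'
#' @inheritParams orientation_energy
#' @return A tibble with columns `orientation`, `freq`, `energy`.
#' @export
stimulus_energies <- function(img, bank) {
  stopifnot(inherits(bank, "cl_filter_bank"))
  purrr::map_df(bank$kernels, function(k) {
    tibble(orientation = k$orientation, freq = k$freq,
           energy = orientation_energy(img, bank, k$orientation, k$freq))
  })
}

#' Normalise trial-wise orientation energies
#'
#' Adds normalised energy columns `E_ccw` and `E_cw` to a trial table with
#' raw energies `E_ccw_raw` / `E_cw_raw`.  In `"session_max"` mode (the
#' fitting convention) all raw energies are divided by the session-wide
#' maximum, so the largest normalised energy is exactly 1; `"fixed"` mode
#' divides by a supplied calibration constant `k`, which keeps the mapping
#' causal for online (generative) use.
#'
#' @param trials A data frame with columns `E_ccw_raw` and `E_cw_raw`.
#' @param mode `"session_max"` or `"fixed"`.
#' @param k Positive calibration constant for `"fixed"` mode.
#' @return `trials` as a tibble with `E_ccw`, `E_cw` added (replaced if
#'   already present).
#' @export
normalize_energies <- function(trials, mode = c("session_max", "fixed"),
                               k = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(trials),
            all(c("E_ccw_raw", "E_cw_raw") %in% names(trials)))
  if (nrow(trials) == 0) abort("Empty trial stream.")
  if (any(trials$E_ccw_raw < 0) || any(trials$E_cw_raw < 0)) {
    abort("Raw energies must be non-negative.")
  }
  divisor <- switch(mode,
    session_max = {
      m <- max(trials$E_ccw_raw, trials$E_cw_raw)
      if (m == 0) abort("All-zero energy stream cannot be max-normalised.")
      m
    },
    fixed = {
      assert_scalar_num(k, "k", 0, strict_lower = TRUE)
      k
    }
  )
  trials %>%
    as_tibble() %>%
    mutate(E_ccw = .data$E_ccw_raw / divisor,
           E_cw = .data$E_cw_raw / divisor)
}
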