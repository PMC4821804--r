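test_that("Gabor term matches its closed form on the grid", {
  # odd grid puts a pixel exactly at the origin, where envelope = 1 and
  # the carrier is sin(phi) = sin(pi/2) = 1 under the phase convention
  spec <- stimulus_spec(grid_px = 301)
  G <- make_gabor(spec)
  expect_equal(G[151, 151], 1.0)

  # theta = 0: the carrier argument is independent of y, so any two rows
  # agree up to the isotropic envelope ratio
  s0 <- stimulus_spec(orientation_theta = 0, trim_level = 0, grid_px = 64)
  G0 <- make_gabor(s0)
  co <- conflearn:::grid_coords(s0)
  env <- exp(-co^2 / (2 * s0$envelope_sigma^2))
  carrier_row <- G0[20, ] / env[20] / env
  for (r in c(1, 33, 50)) {
    expect_equal(G0[r, ] / env[r] / env, carrier_row, tolerance = 1e-10)
  }

  # trimming: the envelope-only cut-off radius is sigma * sqrt(2 ln 200)
  r_star <- 0.6 * sqrt(2 * log(200))
  expect_equal(r_star, 1.953148, tolerance = 1e-6)
  big <- stimulus_spec(grid_deg = 8, grid_px = 452)  # grid wider than 2 r*
  Gb <- make_gabor(big)
  cb <- conflearn:::grid_coords(big)
  rr <- sqrt(outer(cb^2, cb^2, `+`))
  expect_true(all(Gb[rr > r_star + 0.02] == 0))
  expect_false(any(Gb != 0 & abs(Gb) < 0.005))  # nothing below trim survives
})

test_that("Gabor spec validation rejects degenerate parameters", {
  expect_error(stimulus_spec(envelope_sigma = 0), "envelope_sigma")
  expect_error(stimulus_spec(spatial_freq_f = -1), "spatial_freq_f")
  expect_error(stimulus_spec(peak_contrast_cp = 120), "peak_contrast_cp")
})

test_that("noise field is bandpass, zero-mean and seed-reproducible", {
  spec <- stimulus_spec()
  N <- make_noise_field(spec, seed = 11)
  expect_equal(unname(attr(N, "cutoffs")), c(0.625, 2.5))  # one octave
  expect_lt(abs(mean(N)), 1e-12)
  expect_equal(max(abs(N)), 1)  # unit-peak standardisation
  expect_identical(N, make_noise_field(spec, seed = 11))
  expect_false(identical(unclass(N), unclass(make_noise_field(spec, 12))))

  # spectral energy concentrates inside [f/2, 2f]
  n <- spec$grid_px
  dpp <- conflearn:::degrees_per_pixel(spec)
  fr <- sqrt(outer(conflearn:::fft_freqs(n, dpp)^2,
                   conflearn:::fft_freqs(n, dpp)^2, `+`))
  pw <- Mod(stats::fft(unclass(N)))^2
  tight <- fr >= 0.625 * 0.9 & fr <= 2.5 * 1.1
  loose <- fr >= 0.625 * 0.5 & fr <= 2.5 * 1.5
  expect_gt(sum(pw[tight]) / sum(pw), 0.9)
  expect_gt(sum(pw[loose]) / sum(pw), 0.99)
})

test_that("stimulus composition follows the additive mixture", {
  spec <- stimulus_spec(peak_contrast_cp = 8)
  n <- spec$grid_px
  # hand-evaluated pixel: G = 1, N = 0 at 8% contrast on L0 = 51.9
  G1 <- matrix(1, n, n)
  img <- compose_stimulus(G1, matrix(0, n, n), spec, aperture = FALSE)
  expect_equal(img[1, 1], 56.052)

  # collapse to background at zero contrast
  s0 <- stimulus_spec(peak_contrast_cp = 0, noise_contrast_cn = 0)
  flat <- compose_stimulus(matrix(0, n, n), matrix(0, n, n), s0)
  expect_true(all(flat == 51.9))

  # linearity in G and N (fixed L0, no aperture)
  withr::with_seed(5, {
    Ga <- matrix(rnorm(n * n), n); Gb <- matrix(rnorm(n * n), n)
    Na <- matrix(rnorm(n * n), n)
  })
  la <- compose_stimulus(Ga, Na, spec, aperture = FALSE)
  lb <- compose_stimulus(Gb, Na, spec, aperture = FALSE)
  lab <- compose_stimulus(Ga + Gb, Na, spec, aperture = FALSE)
  l0 <- compose_stimulus(matrix(0, n, n), Na, spec, aperture = FALSE)
  expect_equal(unclass(lab), unclass(la) + unclass(lb) - unclass(l0),
               tolerance = 1e-12)

  # negative luminance clips with a warning
  hot <- stimulus_spec(peak_contrast_cp = 100, noise_contrast_cn = 15)
  expect_warning(
    res <- compose_stimulus(matrix(-1, n, n), matrix(-1, n, n), hot,
                            aperture = FALSE),
    "clipping")
  expect_true(all(res >= 0))
})

test_that("circular aperture fades to and crops at background", {
  spec <- stimulus_spec(peak_contrast_cp = 100, noise_contrast_cn = 0)
  # window: unity at centre, half-amplitude at r = 1/(2 * 0.275)
  expect_equal(conflearn:::aperture_window(0, 0.275, 7), 1)
  expect_equal(conflearn:::aperture_window(1 / (2 * 0.275), 0.275, 7), 0.5)

  img <- make_stimulus(spec, seed = 2)
  co <- conflearn:::grid_coords(spec)
  rr <- sqrt(outer(co^2, co^2, `+`))
  expect_true(all(img[rr > 2.5] == spec$background_L0))
  # centre pixel effectively unattenuated relative to the raw mixture
  raw <- compose_stimulus(make_gabor(spec),
                          make_noise_field(spec, seed = 2), spec,
                          aperture = FALSE)
  centre <- which(rr == min(rr), arr.ind = TRUE)[1, ]
  expect_equal(img[centre[1], centre[2]], raw[centre[1], centre[2]],
               tolerance = 1e-6)
})

test_that("stimuli are bit-reproducible and survive 16-bit PNG round trips", {
  spec <- stimulus_spec(peak_contrast_cp = 8, grid_px = 96, grid_deg = 1.7)
  a <- make_stimulus(spec, seed = 9)
  b <- make_stimulus(spec, seed = 9)
  expect_identical(a, b)

  path <- withr::local_tempfile(fileext = ".png")
  write_stimulus_png(a, path, spec = spec)
  back <- read_stimulus_png(path)
  lum_max <- 2 * spec$background_L0
  expect_lt(max(abs(back - a)), lum_max / 65535)  # 16-bit quantisation
  expect_equal(attr(back, "degrees_per_pixel"),
               attr(a, "degrees_per_pixel"))
})
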