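# Epoching, referencing, filtering, standardization, segmentation, grids.

make_rec <- function(data, fs = 250) {
  eeg_recording(data, fs = fs,
                channel_names = paste0("ch", seq_len(nrow(data))))
}

test_that("epoching extracts (end - start) * fs samples and scales volts", {
  rec <- make_rec(matrix(rnorm(2 * 400 * 250), 2), fs = 250)
  ep <- epoch_resting(rec)
  expect_equal(ncol(ep$data), (320 - 20) * 250)
  ep_uv <- epoch_resting(rec, units = "uV")
  ep_v <- epoch_resting(rec, units = "V")
  expect_equal(ep_v$data, ep_uv$data * 1e6)
  short <- make_rec(matrix(rnorm(2 * 300 * 250), 2), fs = 250)
  expect_error(epoch_resting(short), "300.0 s")
})

test_that("subset-average referencing zeroes the reference mean at every sample", {
  co <- tiny_cohort(n_sf = 2, n_nsf = 2, seed = 3)
  rec <- epoch_resting(co$recordings[[1]])
  rr <- rereference(rec)
  ref_mean <- colMeans(rr$data[reference_channels_1020(), ])
  expect_lt(max(abs(ref_mean)), 1e-10)
  expect_equal(nrow(rr$data), 21)
  # constant identical channels -> all zero
  const <- eeg_recording(matrix(5, 21, 100), fs = 100,
                         channel_names = montage_1020())
  expect_true(all(rereference(const)$data == 0))
  # 2-channel toy, reference = both channels
  toy <- eeg_recording(matrix(c(1, 3, 3, 1), 2, byrow = FALSE), fs = 10,
                       channel_names = c("a", "b"))
  out <- rereference(toy, reference_channels = c("a", "b"))
  expect_equal(unname(out$data), matrix(c(-1, 1, 1, -1), 2))
  expect_error(rereference(toy, reference_channels = "Cz"), "Cz")
})

test_that("bandpass passes in-band tones and rejects out-of-band tones", {
  fs <- 250
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  tone <- function(f) matrix(sin(2 * pi * f * t), 1)
  rms <- function(m) sqrt(mean(m^2))
  r10 <- bandpass(make_rec(tone(10), fs), c(39, 41))
  expect_lt(rms(r10$data), 0.05 * rms(tone(10)))
  r40 <- bandpass(make_rec(tone(40), fs), c(39, 41))
  expect_gt(rms(r40$data), 0.8 * rms(tone(40)))
  # re-filtering within the passband changes little
  once <- bandpass(make_rec(tone(40), fs), c(35, 45))
  twice <- bandpass(once, c(35, 45))
  mid <- 1000:4000   # away from edge transients
  expect_lt(max(abs(once$data[mid] - twice$data[mid])), 0.05)
  expect_error(bandpass(make_rec(tone(10), fs), c(120, 130)), "Nyquist")
})

test_that("the lowest 0.1-2 Hz band is usable (stable design) at 250 Hz", {
  fs <- 250
  set.seed(4)
  rec <- make_rec(matrix(rnorm(2 * 30 * fs), 2), fs)
  out <- bandpass(rec, c(0.1, 2))
  expect_true(all(is.finite(out$data)))
  expect_lt(sd(out$data[1, ]), 1)          # narrowband noise, no blow-up
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  r1 <- bandpass(make_rec(matrix(sin(2 * pi * t), 1), fs), c(0.1, 2))
  expect_gt(sqrt(mean(r1$data^2)), 0.8 * sqrt(0.5))  # 1 Hz passes
})

test_that("white-noise stopband attenuation is at least 20 dB an octave out", {
  fs <- 250
  set.seed(9)
  rec <- make_rec(matrix(rnorm(fs * 60), 1), fs)
  out <- bandpass(rec, c(10, 20))
  p_in <- power_spectrum(out$data[1, ])
  f <- seq(0, length(p_in) - 1) * fs / length(p_in)
  pass <- mean(p_in[f >= 12 & f <= 18])
  stop_hi <- mean(p_in[f >= 40 & f <= 45])   # one octave above high edge
  stop_lo <- mean(p_in[f >= 4 & f <= 5])     # one octave below low edge
  expect_gt(10 * log10(pass / stop_hi), 20)
  expect_gt(10 * log10(pass / stop_lo), 20)
})

test_that("standardization gives per-channel mean 0 sd 1 and is idempotent", {
  rec <- make_rec(matrix(c(1, 2, 3, 10, 20, 30), 2, byrow = TRUE), fs = 1)
  st <- standardize(rec)
  expect_equal(rowMeans(st$data), c(ch1 = 0, ch2 = 0))
  expect_equal(apply(st$data, 1, sd), c(ch1 = 1, ch2 = 1))
  expect_equal(standardize(st)$data, st$data, tolerance = 1e-12)
  const <- make_rec(matrix(c(1, 2, 3, 7, 7, 7), 2, byrow = TRUE), fs = 1)
  expect_error(standardize(const), "ch2")
})

test_that("segment cutting takes the leading round(fs * length) samples", {
  rec <- make_rec(matrix(seq_len(2 * 300 * 250), 2, byrow = TRUE), fs = 250)
  seg <- cut_segment(rec, 210)
  expect_equal(ncol(seg$data), 52500)
  expect_equal(unname(seg$data[1, 1:3]), c(1, 2, 3))
  expect_equal(ncol(cut_segment(rec, 1)$data), 250)
  expect_error(cut_segment(rec, 301), "exceeds")
})

test_that("spectral grid is the 50 two-Hz bands from 0.1-2 to 49-51", {
  g <- make_spectral_grid()
  expect_equal(nrow(g), 50)
  expect_equal(c(g$low_hz[1], g$high_hz[1]), c(0.1, 2))
  expect_equal(c(g$low_hz[50], g$high_hz[50]), c(49, 51))
  expect_equal(g$low_hz[2:50], 1:49)
  expect_true(all(g$high_hz[2:50] - g$low_hz[2:50] == 2))
})

test_that("temporal grid is 1..30 s then 60..300 s by 30", {
  w <- make_temporal_grid()
  expect_length(w, 39)
  expect_equal(w[1], 1)
  expect_equal(w[39], 300)
  expect_true(all(c(210, 300) %in% w))
  expect_false(45 %in% w)
  expect_true(all(diff(w) > 0))
})

test_that("the composed chain equals the stages applied in the fixed order", {
  co <- tiny_cohort(n_sf = 2, n_nsf = 2, seed = 6)
  raw <- co$recordings[[1]]
  seg <- preprocess_segment(raw, band = c(8, 12), length_s = 20)
  manual <- raw |> epoch_resting() |> rereference() |>
    bandpass(c(8, 12)) |> standardize() |> cut_segment(20)
  expect_equal(seg$data, manual$data)
  # moments hold pre-cut: the full filtered epoch is exactly standardized
  full <- raw |> epoch_resting() |> rereference() |>
    bandpass(c(8, 12)) |> standardize()
  expect_lt(max(abs(rowMeans(full$data))), 1e-6)
  expect_lt(max(abs(apply(full$data, 1, sd) - 1)), 1e-6)
})
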