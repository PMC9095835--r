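mk_epochs <- function(x, fs = 500) {
  # channels x samples -> one-epoch epoched_recording
  structure(list(epochs = array(x, c(1, nrow(x), ncol(x))), fs = fs,
                 kept_epoch_ids = 0L),
            class = "epoched_recording")
}

flat_spectrum <- function(value = 1, fmax = 120) {
  f <- seq(0, fmax, by = 0.5)
  tcdeeg:::new_spectrum(f, matrix(value, 1, length(f)), per_epoch = FALSE,
                        level = "channel", fs = 500)
}

test_that("a pure on-grid sinusoid concentrates in its 1-bin neighborhood", {
  fs <- 500
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- rbind(sin(2 * pi * 10 * t))
  spec <- epoch_fft_power(mk_epochs(x, fs))
  p <- spec$power[1, 1, ]
  near <- abs(spec$freqs - 10) <= 0.5 + 1e-9
  expect_gt(sum(p[near]) / sum(p), 0.99)
  expect_equal(spec$freqs[which.max(p)], 10)

  zero <- epoch_fft_power(mk_epochs(matrix(0, 1, 1000), fs))
  expect_true(all(zero$power == 0))

  expect_error(epoch_fft_power(mk_epochs(matrix(0, 1, 900), fs)), "2 s")
})

test_that("averaged white-noise periodograms are flat across 2-90 Hz", {
  fs <- 500
  set.seed(33)
  acc <- 0
  for (chunk in 1:10) { # 10^4 epochs in memory-bounded chunks
    x <- matrix(stats::rnorm(1000 * 1000), 1000)
    acc <- acc + rowSums(tcdeeg:::hann_periodogram(x, fs)$power)
  }
  freqs <- (0:500) * 0.5
  m <- acc / 1e4
  inband <- m[freqs >= 2 & freqs <= 90]
  expect_lt(max(inband) / min(inband), 1.2)
})

test_that("Welch PSD integrates to the variance and scales quadratically", {
  fs <- 500
  set.seed(7)
  x <- matrix(stats::rnorm(fs * 60, sd = 3), 1)
  psd <- welch_psd(x, fs = fs)
  expect_equal(sum(psd$power) * 0.5, 9, tolerance = 0.05 * 9)
  psd2 <- welch_psd(2 * x, fs = fs)
  expect_equal(psd2$power, 4 * psd$power, tolerance = 1e-12)

  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  s <- rbind(sin(2 * pi * 10 * t))
  w <- welch_psd(s, fs = fs)
  e <- epoch_fft_power(mk_epochs(s[, 1:1000, drop = FALSE], fs))
  expect_equal(w$freqs[which.max(w$power[1, ])],
               e$freqs[which.max(e$power[1, 1, ])])

  expect_error(welch_psd(matrix(0, 1, 600), fs = fs), "too short")
})

test_that("band power follows the half-open edge convention and the notch gap", {
  spec <- flat_spectrum(0)
  spec$power[1, spec$freqs == 10] <- 5
  bp <- band_power(spec)
  expect_equal(as.vector(bp$absolute),
               c(0, 0, 0, 5, 0, 0, 0), ignore_attr = TRUE) # alpha2 only

  gap <- flat_spectrum(0)
  gap$power[1, gap$freqs == 60] <- 7
  expect_true(all(band_power(gap)$absolute == 0))

  flat <- band_power(flat_spectrum(1))
  expect_equal(as.vector(flat$absolute), c(3, 8, 4, 5, 34, 50, 50),
               ignore_attr = TRUE)

  narrow <- flat_spectrum(1, fmax = 50)
  expect_error(band_power(narrow), "gamma")
})

test_that("relative power averages per-epoch shares and sums to one", {
  # two epochs, one location, constructed per-epoch band powers
  abs_p <- array(0, c(2, 1, 7))
  abs_p[1, 1, ] <- c(1, 1, 1, 1, 1, 0, 0) # theta share 0.2
  abs_p[2, 1, ] <- c(1, 4, 2, 1, 1, 1, 0) # theta share 0.4
  bp <- structure(list(absolute = abs_p, bands = band_names(),
                       per_epoch = TRUE, level = "channel"),
                  class = "band_power")
  rp <- relative_power(bp)
  expect_equal(as.numeric(rp$relative[1, "theta"]), 0.3)
  expect_equal(rowSums(rp$relative), 1, ignore_attr = TRUE, tolerance = 1e-10)

  one <- structure(list(absolute = array(c(0, 0, 0, 0, 0, 2, 0), c(1, 1, 7)),
                        bands = band_names(), per_epoch = TRUE,
                        level = "channel"), class = "band_power")
  r1 <- relative_power(one)
  expect_equal(as.vector(r1$relative), c(0, 0, 0, 0, 0, 1, 0))

  flat <- relative_power(band_power(flat_spectrum(1)))
  expect_equal(as.numeric(flat$relative[1, "gamma1"]), 50 / 154)

  zero <- structure(list(absolute = array(0, c(1, 1, 7)), bands = band_names(),
                         per_epoch = TRUE, level = "channel"),
                    class = "band_power")
  expect_error(relative_power(zero), "zero total")
})

test_that("band + relative pipeline equals a brute-force one-shot computation", {
  fs <- 500
  set.seed(12)
  x <- matrix(stats::rnorm(3 * 1000, sd = 4), 3)
  spec <- epoch_fft_power(mk_epochs(x, fs))
  rp <- relative_power(band_power(spec))
  bands <- frequency_bands()
  brute <- t(apply(spec$power[1, , ], 1, function(p) {
    per_band <- vapply(seq_len(7), function(b) {
      sum(p[spec$freqs >= bands$low[b] & spec$freqs < bands$high[b]])
    }, numeric(1))
    per_band / sum(per_band)
  }))
  expect_equal(unname(rp$relative), brute, tolerance = 1e-12)
})

test_that("cortical smoothing preserves constants, mass and the identity limit", {
  mesh <- fix("tiny_mesh")
  const <- rep(3.7, mesh$n_vertices)
  expect_equal(smooth_on_cortex(const, mesh, 3), const, tolerance = 1e-12)

  impulse <- rep(0, mesh$n_vertices)
  impulse[7] <- 10
  sm <- smooth_on_cortex(impulse, mesh, 25)
  expect_equal(sum(sm), 10, tolerance = 1e-9)
  expect_true(sm[7] < 10) # actually spread with a wide kernel

  expect_identical(smooth_on_cortex(impulse, mesh, 0), impulse)

  set.seed(6)
  v <- stats::rnorm(mesh$n_vertices)
  expect_equal(mean(smooth_on_cortex(v, mesh, 15)), mean(v), tolerance = 1e-9)
})

test_that("PAF finds the largest interior log-power local maximum in 6-14 Hz", {
  f <- seq(0, 120, by = 0.5)
  bump <- function(center, height, width = 1) height * exp(-(f - center)^2 / (2 * width^2))
  background <- 1 / pmax(f, 0.5)

  single <- tcdeeg:::new_spectrum(f, rbind(background + bump(9.5, 2)), FALSE,
                                  "channel", 500)
  expect_equal(compute_paf(single)$paf_hz, 9.5)

  mono <- tcdeeg:::new_spectrum(f, rbind(background), FALSE, "channel", 500)
  res <- compute_paf(mono)
  expect_true(res$missing)
  expect_true(is.na(res$paf_hz))

  two <- tcdeeg:::new_spectrum(f, rbind(background + bump(7, 3) + bump(10, 1.5)),
                               FALSE, "channel", 500)
  expect_equal(compute_paf(two)$paf_hz, 7.0)
})
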