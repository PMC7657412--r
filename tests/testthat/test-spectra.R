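test_that("amplitude spectrum localizes pure tones at the expected bins", {
  fps <- 20; n <- 3200
  t <- (0:(n - 1)) / fps
  # respiratory rate 14 cycles/min
  sp <- amplitude_spectrum(sin(2 * pi * (14 / 60) * t), fps)
  pk <- peak_frequency(sp, 0.03, 0.3)
  expect_lt(abs(pk - 14 / 60), fps / n + 1e-12)       # within one bin
  # cardiac 79 beats/min
  sp2 <- amplitude_spectrum(0.3 * sin(2 * pi * (79 / 60) * t), fps)
  expect_lt(abs(peak_frequency(sp2, 1.0, 1.7) - 79 / 60), fps / n + 1e-12)
  # grid properties
  expect_equal(diff(sp$freqs_hz)[1], fps / n)
  expect_equal(max(sp$freqs_hz), fps / 2)
})

test_that("constant series have zero amplitude beyond the zero bin", {
  sp <- amplitude_spectrum(rep(2.5, 128), 20)
  expect_true(all(abs(sp$amplitude[-1, 1, 1]) < 1e-12))
})

test_that("unit-amplitude on-grid sinusoid gives unit peak amplitude", {
  fps <- 20; n <- 1200
  t <- (0:(n - 1)) / fps
  sp <- amplitude_spectrum(sin(2 * pi * (14 / 60) * t), fps)
  k <- which.min(abs(sp$freqs_hz - 14 / 60))
  expect_equal(sp$amplitude[k, 1, 1], 1, tolerance = 1e-9)
  expect_true(all(sp$amplitude[-c(1, k), 1, 1] < 1e-9))
})

test_that("transform normalization conserves energy (Parseval)", {
  set.seed(9)
  n <- 256; fps <- 20
  x <- rnorm(n)
  xc <- x - mean(x)
  sp <- amplitude_spectrum(x, fps)
  amp <- sp$amplitude[, 1, 1]
  nf <- length(amp)
  # reconstruct two-sided |X|^2 from one-sided amplitudes
  mod2 <- (amp * n / 2)^2 * 2                  # interior bins and conjugates
  mod2[1] <- (amp[1] * n)^2
  mod2[nf] <- (amp[nf] * n)^2                  # Nyquist (even n)
  expect_equal(sum(mod2), n * sum(xc^2), tolerance = 1e-9)
})

test_that("SNV normalization standardizes the retained range per pixel", {
  set.seed(21)
  x <- array(rnorm(600 * 3 * 2), c(600, 3, 2))
  x[, 1, 1] <- x[, 1, 1] + 2 * sin(2 * pi * 0.2 * (1:600) / 20)
  raw <- amplitude_spectrum(x, 20)
  snv <- snv_normalize(raw)
  sel <- which(raw$freqs_hz >= attr(snv, "snv_f_min"))
  for (i in 1:3) for (j in 1:2) {
    z <- snv$amplitude[sel, i, j]
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
  }
})

test_that("SNV is affine-invariant and preserves peak locations", {
  set.seed(22)
  x <- rnorm(400) + sin(2 * pi * 0.25 * (1:400) / 10)
  raw <- amplitude_spectrum(x, 10)
  snv1 <- snv_normalize(raw)
  scaled <- raw
  scaled$amplitude <- 3.7 * raw$amplitude + 0.4   # per-pixel affine rescale
  snv2 <- snv_normalize(scaled)
  expect_equal(snv1$amplitude[-1, , ], snv2$amplitude[-1, , ],
               tolerance = 1e-9)
  expect_identical(which.max(raw$amplitude[-1, 1, 1]),
                   which.max(snv1$amplitude[-1, 1, 1]))
})

test_that("zero-spread pixels are excluded with a message", {
  x <- array(rnorm(200), c(100, 1, 2))
  x[, 1, 2] <- 5                        # constant -> zero spectral spread
  expect_message(snv <- snv_normalize(amplitude_spectrum(x, 20)),
                 "1 pixel")
  expect_true(all(is.na(snv$amplitude[-1, 1, 2])))
  expect_true(all(is.finite(snv$amplitude[-1, 1, 1])))
})

test_that("band metric averages the SNV amplitudes in the closed band", {
  set.seed(30)
  x <- array(rnorm(1200 * 2 * 2), c(1200, 2, 2))
  snv <- snv_normalize(amplitude_spectrum(x, 20))
  m <- band_metric(snv, 0.03, 0.3)
  sel <- which(snv$freqs_hz >= 0.03 & snv$freqs_hz <= 0.3)
  expect_equal(m[1, 1], mean(snv$amplitude[sel, 1, 1]))
  # band collapsed to a single bin returns that bin
  f1 <- snv$freqs_hz[30]
  m1 <- band_metric(snv, f1, f1)
  expect_equal(m1[2, 2], snv$amplitude[30, 2, 2])
  # too-short series for the band is a configuration error naming the need
  short <- snv_normalize(amplitude_spectrum(array(rnorm(32), c(32, 1, 1)), 20))
  expect_error(band_metric(short, 0.03, 0.3), "frames")
})

test_that("peak frequency breaks ties toward the lower frequency", {
  sp <- amplitude_spectrum(rnorm(128), 16)
  sp$amplitude[, 1, 1] <- 0
  sp$amplitude[c(10, 20), 1, 1] <- 1      # exact tie
  expect_equal(peak_frequency(sp, 0, 8), sp$freqs_hz[10])
  # injected delta at a known bin
  sp$amplitude[15, 1, 1] <- 2
  expect_equal(peak_frequency(sp, 0, 8), sp$freqs_hz[15])
})

test_that("half-rectified respiration shows its second harmonic", {
  fps <- 20; n <- 3200
  sig <- hemodynamic_signal(list(a_resp = 1), n, fps, seed = 1,
                            resp_waveform = "half_rectified")
  sp <- amplitude_spectrum(sig$delta_hbo, fps)
  pk2 <- peak_frequency(sp, 0.35, 0.55)
  expect_lt(abs(pk2 - 2 * 14 / 60), fps / n + 1e-12)
})

test_that("Kruskal-Wallis region comparison matches a hand-ranked fixture", {
  # 9 pixels: two identical constant regions and one shifted region;
  # tie-corrected H computed by hand from the rank sums is exactly 8
  metric <- matrix(c(1, 1, 1, 1, 1, 1, 2, 2, 2), 3, 3)
  regions <- list(a = matrix(c(TRUE, TRUE, TRUE, rep(FALSE, 6)), 3, 3),
                  b = matrix(c(rep(FALSE, 3), TRUE, TRUE, TRUE, rep(FALSE, 3)), 3, 3),
                  c = matrix(c(rep(FALSE, 6), TRUE, TRUE, TRUE), 3, 3))
  rc <- region_compare(metric, regions)
  expect_equal(rc$statistic, 8, tolerance = 1e-12)
  expect_equal(rc$df, 2)
  expect_identical(rc$summary$region, c("a", "b", "c"))
  expect_equal(rc$summary$median, c(1, 1, 2))
  expect_error(region_compare(metric, list(a = regions$a,
                                           b = matrix(FALSE, 3, 3))),
               "empty")
})

test_that("region comparison controls type-I error under the null", {
  set.seed(77)
  reject <- replicate(300, {
    vals <- matrix(rnorm(60), 20, 3)
    m <- matrix(vals, 20, 3)
    regions <- list(r1 = col(m) == 1, r2 = col(m) == 2, r3 = col(m) == 3)
    region_compare(m, regions)$p.value < 0.05
  })
  expect_gt(mean(reject), 0.01)
  expect_lt(mean(reject), 0.11)
})
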