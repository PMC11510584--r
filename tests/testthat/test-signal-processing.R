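test_that("bandpass passes the band centre at unit gain with zero phase", {
  fs <- 10e6
  t <- seq_len(20000) / fs
  x <- sin(2 * pi * 390e3 * t)
  y <- bandpass_ultraharmonic(x, fs)
  mid <- 5000:15000
  expect_gt(max(abs(y[mid])), 0.95)
  expect_lt(max(abs(y[mid])), 1.001)  # allow for passband ripple
  # zero phase: cross-correlation peak at zero lag
  cc <- stats::ccf(y[mid], x[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("bandpass attenuates the 258 kHz drive as the response oracle predicts", {
  fs <- 10e6
  # oracle: squared magnitude of the designed filter at 258 kHz
  bf <- signal::butter(4, c(380e3, 400e3) / (fs / 2), type = "pass")
  h <- signal::freqz(bf, region = NULL, n = 4096, Fs = fs)
  gain258 <- abs(h$h[which.min(abs(h$f - 258e3))])^2  # forward-backward
  expect_lt(20 * log10(gain258), -40)
  t <- seq_len(20000) / fs
  y <- bandpass_ultraharmonic(sin(2 * pi * 258e3 * t), fs)
  att_db <- 20 * log10(max(abs(y[5000:15000])))
  expect_lt(att_db, -40)
})

test_that("bandpass maps zeros to zeros and rejects bands at Nyquist", {
  expect_equal(bandpass_ultraharmonic(numeric(1000)), numeric(1000))
  expect_error(bandpass_ultraharmonic(numeric(1000), fs = 700e3), "Nyquist")
})

test_that("zero-phase filtering preserves the centre of mass of a symmetric pulse", {
  fs <- 10e6
  n <- 30000
  t <- (seq_len(n) - n / 2) / fs
  pulse <- exp(-t^2 / (2 * (2e-4)^2)) * cos(2 * pi * 390e3 * t)
  y <- bandpass_ultraharmonic(pulse, fs)
  com <- function(v) sum(seq_along(v) * v^2) / sum(v^2)
  expect_lt(abs(com(y) - com(pulse)), 2)
})

test_that("ICD band integral notches the subharmonic and is linear", {
  fs <- 10e6
  n <- 50000
  t <- seq_len(n) / fs
  sub <- sin(2 * pi * 129e3 * t)     # inside the notch
  inband <- sin(2 * pi * 121e3 * t)  # inside the integration band
  i_sub <- icd_band_integral(sub, fs)
  i_in <- icd_band_integral(inband, fs)
  expect_gt(i_in / max(i_sub, 1e-12), 10)
  # the notched tone leaks less than 1% of the in-band tone
  expect_lt(i_sub, 0.01 * i_in)
  # linearity in amplitude for a fixed noise realization
  set.seed(1)
  w <- rnorm(n)
  expect_equal(icd_band_integral(2 * w, fs), 2 * icd_band_integral(w, fs),
               tolerance = 1e-10)
})

test_that("ICD ratio series is the channel mean, identity on equal inputs, scale invariant", {
  set.seed(2)
  ci <- matrix(abs(rnorm(40, 10)), 10, 4)
  expect_equal(as.numeric(icd_ratio_series(ci, ci)), rep(1, 10))
  bi <- matrix(abs(rnorm(40, 10)), 10, 4)
  r1 <- icd_ratio_series(ci, bi)
  r2 <- icd_ratio_series(3.7 * ci, 3.7 * bi)
  expect_equal(as.numeric(r1), as.numeric(r2))
  expect_equal(as.numeric(r1), rowMeans(ci / bi))
  expect_error(icd_ratio_series(ci, bi[1:5, ]), "mismatch")
  # zero baseline is guarded and flagged
  bi0 <- bi; bi0[3, 2] <- 0
  rg <- icd_ratio_series(ci, bi0)
  expect_true(attr(rg, "guarded")[3])
  expect_true(all(is.finite(rg)))
})

test_that("ICD flag uses mean + 5 SD of the first 10 steps, strictly greater", {
  expect_identical(icd_flag(rep(1, 30)), NA_integer_)  # zero-SD ties never flag
  set.seed(3)
  r <- rnorm(20, 1, 0.02)
  thr <- mean(r[1:10]) + 5 * sd(r[1:10])
  r[14] <- thr + 0.01
  expect_identical(icd_flag(r), 14L)
  r[12] <- thr + 0.05
  expect_identical(icd_flag(r), 12L)
  expect_warning(f <- icd_flag(rnorm(5, 1, 0.01)), "fewer steps")
  expect_identical(f, NA_integer_)
})

test_that("ICD flag localizes the inertial-cavitation crossing on simulated ramps", {
  sc <- test_constants(2.5e-3)
  geom <- test_geom(1)  # 4 PCI receivers; only the ICD chain is exercised
  hits <- 0
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    sub <- sample_virtual_subject(1, seed = 100 + s,
                                  positions = matrix(0, 1, 3),
                                  emission = emission_model(sigmoid_slope = Inf),
                                  constants = sc,
                                  pic_competitive_frac = 1)
    pic <- sub$targets$pic
    steps <- 1:32
    pnp <- 0.15e6 + (steps - 1) * 15e3
    true_cross <- which(pnp >= pic)[1]
    base <- t(vapply(steps, function(k) {
      cap <- simulate_burst(geom, sub, 1, pnp[k], 1e-3, mb_present = FALSE,
                            seed = 9000 + 40 * s + k, constants = sc,
                            phase_tag = "baseline")
      sonocal:::icd_integrals(cap)
    }, numeric(4)))
    calib <- t(vapply(steps, function(k) {
      cap <- simulate_burst(geom, sub, 1, pnp[k], 1e-3, mb_present = TRUE,
                            seed = 5000 + 40 * s + k, constants = sc)
      sonocal:::icd_integrals(cap)
    }, numeric(4)))
    fl <- icd_flag(icd_ratio_series(calib, base))
    if (!is.na(fl) && abs(fl - true_cross) <= 2) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})
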