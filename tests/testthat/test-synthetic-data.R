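test_that("threshold pressures follow the truncated normal with the encoded mean", {
  sub <- sample_virtual_subject(10000, seed = 1)
  expect_lt(abs(mean(sub$targets$pthr) - 0.53e6), 0.01e6)
  expect_lt(abs(sd(sub$targets$pthr) - 0.09e6), 0.005e6)
  expect_true(all(sub$targets$pthr >= 0.15e6 + 15e3))
})

test_that("degenerate and invalid threshold spreads behave as specified", {
  sub <- sample_virtual_subject(8, seed = 2, pthr_sd = 0)
  expect_true(all(sub$targets$pthr == 0.53e6))
  expect_error(sample_virtual_subject(8, seed = 2, pthr_sd = -1), "negative")
})

test_that("intra-grid threshold range matches the Monte-Carlo range oracle", {
  # oracle: plain normal draws under the same per-seed discipline
  # (E[range of 16 iid N(0,1)] ~ 3.53, so ~0.318 MPa at SD 0.09 MPa)
  seeds <- 1:300
  oracle <- vapply(seeds, function(s) {
    set.seed(s)
    diff(range(rnorm(16, 0.53e6, 0.09e6)))
  }, numeric(1))
  rg <- vapply(seeds, function(s) {
    diff(range(sample_virtual_subject(16, seed = s)$targets$pthr))
  }, numeric(1))
  expect_equal(mean(rg), mean(oracle), tolerance = 1e-6)
  expect_lt(abs(mean(rg) / 1e6 - 3.529 * 0.09), 0.02)
  # the hierarchical within/between split narrows the intra-grid range to the
  # in vivo level (~0.23 MPa) while keeping the marginal SD
  rgh <- vapply(seeds, function(s) {
    diff(range(sample_virtual_subject(16, seed = s,
                                      pthr_between_sd = 0.062e6)$targets$pthr))
  }, numeric(1))
  expect_lt(abs(mean(rgh) / 1e6 - 3.529 * sqrt(0.09^2 - 0.062^2)), 0.02)
})

test_that("grid layout uses the planned spacing and seeds reproduce exactly", {
  s1 <- sample_virtual_subject(16, seed = 3)
  s2 <- sample_virtual_subject(16, seed = 3)
  expect_identical(s1$targets, s2$targets)
  xs <- sort(unique(s1$targets$x))
  expect_equal(diff(xs), rep(3.5e-3, 3))
})

test_that("burst captures have the contracted shape and reproduce per seed", {
  sc <- test_constants(2e-3)
  geom <- test_geom(2)
  sub <- point_subject(c(0, 0, 0), emission = emission_model(), constants = sc)
  cap <- simulate_burst(geom, sub, 1, 0.5e6, 1e-3, seed = 4, constants = sc)
  expect_equal(nrow(cap$pci_rf), round(sc$capture_length * sc$sampling_rate))
  expect_equal(ncol(cap$pci_rf), 8)
  expect_equal(ncol(cap$icd_rf), 4)
  cap2 <- simulate_burst(geom, sub, 1, 0.5e6, 1e-3, seed = 4, constants = sc)
  expect_identical(cap$pci_rf, cap2$pci_rf)
  expect_error(simulate_burst(geom, sub, 99, 0.5e6, 1e-3, constants = sc),
               "unknown target")
  expect_warning(simulate_burst(geom, sub, 1, 0.5e6, 2e-3, seed = 1,
                                constants = sc), "protocol")
})

test_that("baseline captures carry no ultraharmonic tone above the noise", {
  sc <- test_constants(3e-3)
  geom <- test_geom(2)
  sub <- point_subject(c(0, 0, 0), emission = emission_model(clutter_n = 0),
                       constants = sc)
  cap <- simulate_burst(geom, sub, 1, 0.7e6, 1e-3, mb_present = FALSE,
                        seed = 6, constants = sc, phase_tag = "baseline")
  expect_false(cap$activated)
  sp <- spectral_summary(cap$pci_rf[, 1], sc$sampling_rate)
  at_uh <- sp$magnitude[which.min(abs(sp$freqs - 387e3))]
  off <- sp$magnitude[sp$freqs > 0.5e6 & sp$freqs < 4e6]
  expect_lt(at_uh, quantile(off, 0.999))
})

test_that("tone amplitudes follow the 1/r spreading law", {
  sc <- test_constants(2.5e-3)
  geom <- test_geom(2)
  src <- c(5e-3, -3e-3, 2e-3)
  sub <- point_subject(src, constants = sc)
  cap <- simulate_burst(geom, sub, 1, sub$targets$pthr + 1e3, 1e-3,
                        seed = 7, constants = sc)
  expect_true(cap$activated)
  r <- sqrt(rowSums(sweep(geom$pci_receiver_positions, 2, src)^2))
  amp <- apply(abs(cap$pci_rf), 2, max)
  expect_equal(amp * r, rep(mean(amp * r), length(r)), tolerance = 1e-6)
})

test_that("inter-channel tone lags equal the geometric delay differences", {
  sc <- test_constants(2.5e-3, sampling_rate = 40e6)
  geom <- test_geom(2)
  src <- c(2e-3, 1e-3, -3e-3)
  sub <- point_subject(src, constants = sc)
  cap <- simulate_burst(geom, sub, 1, sub$targets$pthr + 1e3, 1e-3,
                        seed = 8, constants = sc)
  tau <- propagation_delay(src, geom$pci_receiver_positions, 1482)
  fs <- sc$sampling_rate
  # envelope cross-correlation between channel pairs
  for (pair in list(c(1, 5), c(2, 8))) {
    a <- abs(cap$pci_rf[, pair[1]])
    b <- abs(cap$pci_rf[, pair[2]])
    lags <- -2000:2000
    cc <- vapply(lags, function(l) {
      ia <- max(1, 1 + l):min(length(a), length(a) + l)
      sum(a[ia] * b[ia - l])
    }, numeric(1))
    lag_meas <- lags[which.max(cc)] / fs
    lag_true <- tau[pair[1]] - tau[pair[2]]
    expect_lt(abs(lag_meas - lag_true), 1.5 / fs + 1e-9)
  }
})

test_that("expected beamformed ultraharmonic power is monotone in pressure", {
  sc <- test_constants(2.5e-3)
  geom <- test_geom(4)
  sub <- point_subject(c(0, 0, 0), emission = emission_model(clutter_n = 0),
                       constants = sc, seed = 12)
  grid <- beamform_grid(c(0, 0, 0), extent = c(3e-3, 3e-3, 5e-3))
  pthr <- sub$targets$pthr
  mean_power <- vapply(c(pthr - 30e3, pthr, pthr + 30e3), function(pnp) {
    mean(vapply(1:6, function(s) {
      cap <- simulate_burst(geom, sub, 1, pnp, 1e-3, seed = 50 * s,
                            constants = sc)
      beamform_volume(cap, geom, grid, bandpass = TRUE)$spta
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_power) >= 0))
})

test_that("outcome tables encode the dose-response and protein couplings", {
  sub <- sample_virtual_subject(16, seed = 9)
  plan <- sonication_plan(sub, burst_length = 5e-3, target_level = 75,
                          n_tx_bursts = 240)
  tab <- generate_outcome_table(sub, plan, seed = 10)
  expect_equal(nrow(tab), 16)
  expect_true(all(tab$gd_true >= 1))
  expect_true(all(tab$rbc_area_mm2 >= 0))
  # noiseless protein link is an exact line
  sub0 <- sub
  sub0$protein_link$albumin$noise_sd <- 0
  tab0 <- generate_outcome_table(sub0, plan, seed = 10)
  fit <- linregress_r2(tab0$gd_true, tab0$albumin)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$slope, sub$protein_link$albumin$slope, tolerance = 1e-9)
})

test_that("RBC extravasation is greater for 1 ms than 10 ms bursts", {
  wins <- vapply(1:40, function(s) {
    sub <- sample_virtual_subject(33, seed = 200 + s)
    p1 <- sonication_plan(sub, burst_length = 1e-3, target_level = 75,
                          n_tx_bursts = 120)
    p10 <- sonication_plan(sub, burst_length = 10e-3, target_level = 75,
                           n_tx_bursts = 120)
    m1 <- mean(generate_outcome_table(sub, p1, seed = s)$rbc_area_mm2)
    m10 <- mean(generate_outcome_table(sub, p10, seed = s + 1)$rbc_area_mm2)
    m1 > m10
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("default albumin coupling reproduces the reported explained variance", {
  combos <- list(c(5, 50), c(10, 50), c(1, 75), c(5, 75), c(10, 75))
  r2s <- vapply(1:60, function(i) {
    tab <- do.call(rbind, lapply(seq_along(combos), function(a) {
      s <- sample_virtual_subject(13, seed = i * 31 + a)
      pl <- sonication_plan(s, burst_length = combos[[a]][1] * 1e-3,
                            target_level = combos[[a]][2],
                            n_tx_bursts = sample(c(0, 60, 120, 240), 1))
      generate_outcome_table(s, pl, seed = i * 97 + a)
    }))
    linregress_r2(tab$gd_true, tab$albumin)$r2
  }, numeric(1))
  expect_lt(abs(median(r2s) - 0.63), 0.1)
})

test_that("synthetic T1w volumes are exact in the noiseless limit", {
  tg <- matrix(c(0, 0, 0, 3.5e-3, 0, 0), 2, 3, byrow = TRUE)
  v0 <- simulate_t1w_volume(tg, c(1, 1), noise_sd = 0)
  expect_true(all(v0$data == 100))
  v <- simulate_t1w_volume(tg, c(1.3, 1.5), noise_sd = 0)
  q <- relative_gd_enhancement(v, tg, seed = 2)
  expect_equal(q$rel_gd, c(1.3, 1.5), tolerance = 0.025)
  expect_error(simulate_t1w_volume(matrix(c(1, 0, 0), 1), 1.3, noise_sd = 0),
               "field of view")
  expect_error(simulate_t1w_volume(tg, c(0.9, 1.2)), ">= 1")
})

test_that("ROI quantification is unbiased under symmetric voxel noise", {
  tg <- matrix(c(0, 0, 0), 1)
  vals <- vapply(1:60, function(s) {
    v <- simulate_t1w_volume(tg, 1.0, noise_sd = 0.02, seed = s, n_slices = 9)
    relative_gd_enhancement(v, tg, seed = s)$rel_gd
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1.0), 0.01)
})
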