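test_that("a single blob above both gates yields one peak at its apex", {
  img <- blob_image(apexes = data.frame(mod = 25, samp = 50, height = 1e5))
  pk <- detect_peaks(img, min_counts = 1e5, min_snr = 0)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$apex_mod - 25), 1)
  expect_lte(abs(pk$apex_samp - 50), 1)
  # below the count gate -> nothing
  expect_equal(nrow(detect_peaks(img, min_counts = 1e10)), 0)
})

test_that("raising the count gate never increases the peak count", {
  set.seed(10)
  img <- blob_image(apexes = data.frame(mod = c(10, 25, 40, 52),
                                        samp = c(20, 60, 35, 70),
                                        height = c(2e4, 8e4, 3e5, 1e6)))
  gates <- c(0, 1e5, 5e5, 2e6, 1e7, 1e9)
  n <- vapply(gates, function(g) nrow(detect_peaks(img, min_counts = g)),
              numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("detection is invariant to a constant offset plus background subtraction", {
  img <- blob_image(apexes = data.frame(mod = 30, samp = 40, height = 2e5))
  p1 <- detect_peaks(subtract_background(img, 12), min_counts = 1e5)
  shifted <- img; shifted$image <- shifted$image + 7000
  p2 <- detect_peaks(subtract_background(shifted, 12), min_counts = 1e5)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p1$apex_mod, p2$apex_mod)
  expect_lt(abs(p1$volume - p2$volume) / p1$volume, 0.01)
})

test_that("well-separated injected compounds are all recovered near truth", {
  cfg <- tiny_synth()
  lib <- tiny_library()
  run <- simulate_run(list(run_id = "t", group = "MHO"), lib,
                      abundances = rep(1, 3), config = cfg, seed = 5)
  ch <- fold_run(run, "70eV")
  sub <- subtract_background(tic(ch), 15)
  noise <- estimate_noise(sub)
  pk <- detect_peaks(sub, min_counts = 1e5, min_snr = 5, noise = noise)
  expect_gte(nrow(pk), 3)
  for (i in seq_len(nrow(run$truth))) {
    d1 <- abs(pk$rt1 - run$truth$rt1[i]) * 60 / cfg$modulation_period
    d2 <- abs(pk$rt2 - run$truth$rt2[i])
    expect_true(any(d1 <= 1 & d2 <= 0.1))
  }
})

test_that("volume integration is an exact footprint sum with additivity", {
  img <- tic_image(matrix(1, 20, 16), 1, 16)
  expect_equal(integrate_volume(img, 1:7), 7)
  expect_error(integrate_volume(img, integer()), "empty")
  set.seed(11)
  img$image <- matrix(runif(320), 20, 16)
  a <- sample(320, 30); b <- setdiff(sample(320, 50), a)
  expect_equal(integrate_volume(img, c(a, b)),
               integrate_volume(img, a) + integrate_volume(img, b))
})

test_that("a full-support Gaussian footprint integrates to the analytic mass", {
  img <- blob_image(n1 = 100, n2 = 80, s1 = 2, s2 = 3,
                    apexes = data.frame(mod = 50, samp = 40, height = 1e4))
  analytic <- 1e4 * 2 * pi * 2 * 3
  expect_lt(abs(sum(img$image) - analytic) / analytic, 0.02)
  pk <- detect_peaks(img, min_counts = 0)
  expect_lt(abs(pk$volume[1] - analytic) / analytic, 0.02)
})

test_that("apex spectra reproduce the injected library spectra", {
  cfg <- tiny_synth(noise_sd_70 = 0, noise_sd_12 = 0, shot_noise = FALSE,
                    baseline_level_70 = 0, baseline_level_12 = 0,
                    rt_jitter_1d = 0, rt_jitter_2d = 0)
  lib <- tiny_library()
  run <- simulate_run(list(run_id = "t", group = "MHO"), lib,
                      abundances = rep(1, 3), config = cfg, seed = 5)
  ch <- fold_run(run, "70eV")
  pk <- detect_peaks(tic(ch), min_counts = 1e5)
  pk <- add_peak_spectra(pk, ch)
  expect_equal(nrow(pk), 3)
  for (i in seq_len(3)) {
    truth_i <- which.min(abs(run$truth$rt1 - pk$rt1[i]))
    want <- lib[[truth_i]]$spectrum_70
    got <- pk$spectrum[[i]]
    expect_identical(got$mz, want$mz)
    expect_equal(got$intensity, want$intensity, tolerance = 2e-3)
    # co-recorded 12 eV channel carries the complementary signature
    s12 <- peak_spectrum(fold_run(run, "12eV"), pk[i, ])
    expect_gte(direct_match_factor(s12, lib[[truth_i]]$spectrum_12), 900)
  }
  expect_error(peak_spectrum(ch, list(apex_mod = 0, apex_samp = 1)),
               "outside")
  zero <- ch; zero$cube[] <- 0
  expect_error(peak_spectrum(zero, pk[1, ]), "all-zero")
})
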