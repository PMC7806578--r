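test_that("the study design enumerates every subject/replicate combination", {
  d <- make_study_design(4, 3, 5, 2, 2)
  expect_equal(nrow(d), 48)
  expect_equal(sum(d$group == "QC"), 16)
  d_qc <- make_study_design(4, 0, 0, 2, 2)
  expect_equal(nrow(d_qc), 16)
  expect_equal(nrow(make_study_design(1, 0, 0, 1, 1)), 1)
  expect_true(all(d$group %in% c("QC", "MHO", "MUO")))
  expect_false(anyDuplicated(d$run_id) > 0)
  expect_error(make_study_design(1, 1, 1, 0, 1), ">= 1")
  expect_error(make_study_design(-1, 1, 1, 1, 1), ">= 0")
})

test_that("the library honours its invariants and the fixed reference subset", {
  expect_length(build_spectral_library(0), 0)
  expect_error(build_spectral_library(-1), ">= 0")
  lib <- build_spectral_library(30, seed = 9)
  expect_identical(lib, build_spectral_library(30, seed = 9))
  expect_length(lib, 30)
  for (e in lib) {
    expect_equal(max(e$spectrum_70$intensity), 999)
    expect_equal(max(e$spectrum_12$intensity), 999)
    expect_true(e$response_12 > 0 && e$response_12 < e$response_70)
    expect_true(e$two_d_time >= 0 && e$two_d_time < 5)
  }
  # dual-energy signature of the N-acetyl-D-glucosamine entry: silyl
  # fragments 73/129/147 at 70 eV, high-mass 202/319/333 enhanced at 12 eV
  nag <- lib[["N-Acetyl-D-glucosamine, 4TMS methyloxime (anti)"]]
  expect_true(all(c(73, 129, 147) %in% nag$spectrum_70$mz))
  expect_true(all(c(202, 319, 333) %in% nag$spectrum_12$mz))
  lo <- function(s) sum(s$intensity[s$mz < 200]) / sum(s$intensity)
  expect_gt(lo(nag$spectrum_70), lo(nag$spectrum_12))
  ref <- reference_compounds()
  expect_equal(ref$ri[ref$name == "Urea, 2TMS"], 1192)
})

test_that("simulate_run validates inputs and is deterministic without noise", {
  cfg <- tiny_synth(noise_sd_70 = 0, noise_sd_12 = 0, shot_noise = FALSE,
                    rt_jitter_1d = 0, rt_jitter_2d = 0)
  lib <- tiny_library()
  expect_error(simulate_run(list(run_id = "x", group = "QC"), lib,
                            abundances = 1:2, config = cfg),
               "does not match")
  r1 <- simulate_run(list(run_id = "x", group = "QC"), lib, rep(1, 3),
                     cfg, seed = 1)
  r2 <- simulate_run(list(run_id = "x", group = "QC"), lib, rep(1, 3),
                     cfg, seed = 99)  # no stochastic terms left
  expect_identical(r1$stream_70, r2$stream_70)
  expect_identical(r1$stream_12, r2$stream_12)
  # empty library -> baseline-only run
  empty <- structure(list(), class = "spectral_library",
                     class_effects = numeric())
  r0 <- simulate_run(list(run_id = "x", group = "QC"), empty, numeric(),
                     tiny_synth(), seed = 1)
  expect_equal(nrow(r0$truth), 0)
  expect_lt(sum(r0$stream_70),
            1.5 * 40 * 100 * tiny_synth()$baseline_level_70)
})

test_that("identical config and seed give identical runs with noise on", {
  cfg <- tiny_synth()
  lib <- tiny_library()
  a <- simulate_run(list(run_id = "x", group = "MUO"), lib, rep(1, 3),
                    cfg, seed = 42)
  b <- simulate_run(list(run_id = "x", group = "MUO"), lib, rep(1, 3),
                    cfg, seed = 42)
  expect_identical(a$stream_70, b$stream_70)
  expect_identical(a$truth, b$truth)
})

test_that("class effects scale MUO volumes by the configured ratio", {
  # glucuronolactone: printed +325.2 % difference -> MUO:MHO ratio 4.252
  lib <- build_spectral_library(16, seed = 2)
  cfg <- synth_config(mz_range = c(45, 244))
  gl <- "D-(+)-Glucuronic acid gamma-lactone, 3TMS methyloxime"
  muo <- simulate_run(list(run_id = "m", group = "MUO"), lib,
                      rep(1, 16), cfg, seed = 3)
  mho <- simulate_run(list(run_id = "h", group = "MHO"), lib,
                      rep(1, 16), cfg, seed = 3)
  ratio <- muo$truth$volume_70[muo$truth$name == gl] /
    mho$truth$volume_70[mho$truth$name == gl]
  expect_equal(ratio, 4.252)
})

test_that("injected volume is conserved and channels are asymmetric", {
  cfg <- tiny_synth()
  lib <- tiny_library()
  run <- simulate_run(list(run_id = "x", group = "QC"), lib, rep(1, 3),
                      cfg, seed = 6)
  # baseline adds, never subtracts (up to count rounding)
  expect_gte(sum(run$stream_70) + 1, sum(run$truth$volume_70))
  expect_lt(sum(run$stream_12), sum(run$stream_70))
})

test_that("empirical retention jitter matches the configured RSDs", {
  cfg <- tiny_synth(noise_sd_70 = 0, noise_sd_12 = 0, shot_noise = FALSE,
                    baseline_level_70 = 0, baseline_level_12 = 0)
  lib <- tiny_library()[1]
  rt1 <- rt2 <- numeric(60)
  for (i in 1:60) {
    run <- simulate_run(list(run_id = "x", group = "QC"), lib, 1, cfg,
                        seed = 1000 + i)
    rt1[i] <- run$truth$rt1
    rt2[i] <- run$truth$rt2
  }
  expect_lt(abs(rsd(rt1) - cfg$rt_jitter_1d) / cfg$rt_jitter_1d, 0.3)
  expect_lt(abs(rsd(rt2) - cfg$rt_jitter_2d) / cfg$rt_jitter_2d, 0.3)
})

test_that("the alkane run emits one monotone blob per alkane", {
  cfg <- synth_config(mz_range = c(45, 244))
  run <- simulate_alkane_run(cfg, seed = 2)
  expect_equal(nrow(run$truth), 24)  # C7..C30
  expect_true(all(diff(run$truth$rt1) > 0))
  sub <- subtract_background(
    tic(fold_run(run, "70eV")), 15)
  noise <- estimate_noise(sub)
  pk <- detect_peaks(sub, min_counts = 1e5, min_snr = 5, noise = noise)
  expect_equal(nrow(pk), 24)
  # detected apexes, ordered by rt1, increase monotonically
  expect_true(all(diff(sort(pk$rt1)) > 0))
  # ladder that does not fit the run is rejected
  expect_error(simulate_alkane_run(tiny_synth()), "does not fit")
})
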