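test_that("retention indices interpolate linearly on the alkane ladder", {
  calib <- ri_calibration(7:30, 0.8 + 0.45 * (0:23))
  t10 <- calib$rt1[calib$carbons == 10]
  t11 <- calib$rt1[calib$carbons == 11]
  expect_equal(retention_index(t10, calib), 1000)
  expect_equal(retention_index((t10 + t11) / 2, calib), 1050)
  # every alkane's own retention time maps to 100 x carbon number
  expect_equal(retention_index(calib$rt1, calib), 100 * (7:30))
  # strictly increasing between calibration points
  rts <- seq(t10, t11, length.out = 20)
  expect_true(all(diff(retention_index(rts, calib)) > 0))
  expect_warning(retention_index(0.1, calib), "outside")
  expect_error(ri_calibration(7, 1), ">= 2")
  expect_error(ri_calibration(c(7, 8), c(2, 1)), "increase strictly")
})

test_that("retention indices also work on a nonuniform ladder", {
  calib <- ri_calibration(c(8, 9, 11), c(1, 1.5, 3.1))
  expect_equal(retention_index(1.25, calib), 850)
  expect_equal(retention_index(3.1, calib), 1100)
})

test_that("identification enforces all three gates with inclusive boundaries", {
  lib <- build_spectral_library(16, seed = 3)
  nag <- "N-Acetyl-D-glucosamine, 4TMS methyloxime (anti)"
  s <- lib[[nag]]$spectrum_70
  ri <- lib[[nag]]$ri

  hit <- identify_compound(s, ri, lib)
  expect_identical(hit$compound[1], nag)
  expect_true(hit$accepted[1])
  expect_identical(hit$dmf[1], 999L)

  # RI tolerance: |delta| = 10 accepted, 11 rejected
  expect_true(identify_compound(s, ri + 10, lib)$accepted[1])
  expect_false(any(identify_compound(s, ri + 11, lib)$accepted))

  # match-factor boundaries are inclusive
  noisy <- normalize_spectrum(
    spectrum(s$mz, s$intensity * seq(0.8, 1.2, length.out = nrow(s))))
  d <- direct_match_factor(noisy, s)
  r <- reverse_match_factor(noisy, s)
  expect_lt(d, 999L)
  at_gate <- identify_compound(noisy, ri, lib, min_dmf = d, min_rmf = r)
  expect_true(at_gate$accepted[at_gate$compound == nag])
  above <- identify_compound(noisy, ri, lib, min_dmf = d + 1L, min_rmf = r)
  expect_false(any(above$accepted))
  expect_error(identify_compound(s, ri, list()), "empty")
})

test_that("tightening any identification gate never accepts a rejected candidate", {
  set.seed(50)
  lib <- build_spectral_library(10, seed = 5)
  q <- rand_spec()
  loose <- identify_compound(q, 1500, lib, min_dmf = 0, min_rmf = 0,
                             ri_tol = 1e6)
  for (i in 1:10) {
    gates <- list(min_dmf = sample(0:999, 1), min_rmf = sample(0:999, 1),
                  ri_tol = runif(1, 0, 500))
    tight <- do.call(identify_compound, c(list(q, 1500, lib), gates))
    tight <- tight[match(loose$compound, tight$compound), ]
    expect_true(all(!tight$accepted | loose$accepted))
  }
})

test_that("class composites accumulate per mode", {
  img <- blob_image(apexes = data.frame(mod = 25, samp = 40, height = 2e5))
  expect_equal(class_composite(list(img), list(identity_transform()),
                               "sum")$image, img$image)
  expect_equal(class_composite(rep(list(img), 5),
                               rep(list(identity_transform()), 5),
                               "mean")$image, img$image)
  expect_error(class_composite(list(), list()), "empty")
})

test_that("fuzzy ratio is zero for proportional images and flags local change", {
  img <- blob_image(apexes = data.frame(mod = c(20, 40), samp = c(30, 60),
                                        height = c(1e5, 8e4)))
  self <- fuzzy_ratio(img, img, floor = 1e-6)
  expect_true(any(!is.na(self$log2_ratio)))
  expect_equal(max(abs(self$log2_ratio), na.rm = TRUE), 0)

  doubled <- img; doubled$image <- 2 * img$image
  glob <- fuzzy_ratio(doubled, img, floor = 1e-6)
  expect_equal(max(abs(glob$log2_ratio), na.rm = TRUE), 0)

  # doubling one blob in a many-blob pattern (total shift then small):
  # positive at that blob, near zero at the untouched ones
  many <- data.frame(mod = c(10, 20, 30, 40, 50, 15, 45),
                     samp = c(15, 30, 45, 60, 75, 65, 20),
                     height = c(8e4, 1e5, 9e4, 8e4, 1.2e5, 7e4, 1.1e5))
  base <- blob_image(apexes = many)
  up_ap <- many; up_ap$height[2] <- 2 * up_ap$height[2]
  up <- blob_image(apexes = up_ap)
  fr <- fuzzy_ratio(up, base, floor = 1e-4)
  expect_gt(fr$log2_ratio[20, 30], 0.5)
  expect_lt(abs(fr$log2_ratio[40, 60]), 0.25)
  expect_lt(abs(fr$log2_ratio[50, 75]), 0.25)

  # antisymmetry under swapping analyzed and reference
  swapped <- fuzzy_ratio(base, up, floor = 1e-4)
  expect_equal(swapped$log2_ratio, -fr$log2_ratio)

  # one-pixel misalignment is absorbed at the blob cores by the 3x3 window
  shift_ap <- many; shift_ap$mod <- many$mod + 1; shift_ap$samp <- many$samp + 1
  near <- fuzzy_ratio(blob_image(apexes = shift_ap), base, floor = 1e-4)
  for (k in seq_len(nrow(many))) {
    expect_lt(abs(near$log2_ratio[many$mod[k], many$samp[k]]), 0.35)
  }

  other <- blob_image(n1 = 30, n2 = 80,
                      apexes = data.frame(mod = 10, samp = 10, height = 1))
  expect_error(fuzzy_ratio(img, other), "grids differ")
})

test_that("fuzzy-ratio direction matches injected class effects end to end", {
  cfg <- tiny_synth()
  lib <- tiny_library()
  effects <- c(alpha = 3, beta = 1, gamma = 0.3)
  attr(lib, "class_effects") <- effects
  imgs <- list(MHO = list(), MUO = list())
  for (grp in names(imgs)) {
    for (i in 1:3) {
      run <- simulate_run(list(run_id = paste0(grp, i), group = grp),
                          lib, rep(1, 3), cfg,
                          seed = 100 * i + (grp == "MUO"))
      imgs[[grp]][[i]] <- subtract_background(tic(fold_run(run, "70eV")),
                                              12)
    }
  }
  id3 <- rep(list(identity_transform()), 3)
  comp_mho <- class_composite(imgs$MHO, id3, "sum")
  comp_muo <- class_composite(imgs$MUO, id3, "sum")
  fr <- fuzzy_ratio(comp_muo, comp_mho)
  px <- function(nm) {
    i <- which(names(lib) == nm)
    run <- simulate_run(list(run_id = "x", group = "QC"), lib, rep(1, 3),
                        tiny_synth(rt_jitter_1d = 0, rt_jitter_2d = 0),
                        seed = 1)
    c(round(run$truth$mod[i]), round(run$truth$samp[i]))
  }
  a <- px("alpha"); g <- px("gamma")
  expect_gt(fr$log2_ratio[a[1], a[2]], 0.5)   # up in MUO
  expect_lt(fr$log2_ratio[g[1], g[2]], -0.5)  # down in MUO
})
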