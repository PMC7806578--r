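make_template <- function(peaks) {
  template_from_peaks(peaks, grid = list(modulation_period = 5,
                                         acquisition_rate = 20,
                                         n1 = 60, n2 = 100))
}

test_that("template matching is exact on identical peaks and gated by RT and spectra", {
  set.seed(30)
  specs <- replicate(5, rand_spec(), simplify = FALSE)
  pk <- fake_peaks(rt1 = c(1, 2, 3, 4, 5), rt2 = c(1, 2, 3, 1.5, 2.5),
                   spectra = specs)
  tmpl <- make_template(pk)
  m <- match_template(tmpl, pk)
  expect_equal(nrow(m), 5)
  expect_equal(m$dmf, rep(999L, 5))

  # retention shift within the window still matches; beyond it does not
  shifted <- pk; shifted$rt1 <- pk$rt1 + 0.08
  expect_equal(nrow(match_template(tmpl, shifted, window_1d = 0.125)), 5)
  far <- pk; far$rt1 <- pk$rt1 + 0.5
  expect_equal(nrow(match_template(tmpl, far, window_1d = 0.125)), 0)

  # spectrally scrambled peak at the right RT fails the similarity gate
  scrambled <- pk
  scrambled$spectrum <- replicate(5, rand_spec(), simplify = FALSE)
  m2 <- match_template(tmpl, scrambled)
  expect_true(all(m2$dmf >= 750))
  expect_lt(nrow(m2), 5)
  expect_error(match_template(tmpl, pk, min_dmf = 1500), "\\[0, 999\\]")
})

test_that("the reliable rule keeps entries matched in more than half the runs", {
  expect_equal(reliable_threshold(48), 25)
  expect_equal(reliable_threshold(2), 2)
  expect_equal(reliable_threshold(3), 2)
  counts <- c(a = 25, b = 24, c = 48)
  expect_identical(select_reliable(counts, 48), c("a", "c"))
  expect_identical(select_reliable(c(x = 1, y = 2), 2), "y")
  expect_error(select_reliable(counts, 0), ">= 1")
})

test_that("affine transforms are recovered exactly and under noise", {
  set.seed(31)
  pairs <- data.frame(tmpl_rt1 = runif(12, 0, 10),
                      tmpl_rt2 = runif(12, 0, 5))
  pairs$run_rt1 <- 1.02 * pairs$tmpl_rt1 + 0.3
  pairs$run_rt2 <- 0.97 * pairs$tmpl_rt2 - 0.1
  tf <- fit_transform(pairs)
  expect_equal(tf$a1, 1.02, tolerance = 1e-9)
  expect_equal(tf$b1, 0.3, tolerance = 1e-9)
  expect_equal(tf$a2, 0.97, tolerance = 1e-9)
  expect_lt(tf$rms1, 1e-9)

  ident <- pairs
  ident$run_rt1 <- ident$tmpl_rt1; ident$run_rt2 <- ident$tmpl_rt2
  ti <- fit_transform(ident)
  expect_equal(c(ti$a1, ti$b1, ti$a2, ti$b2), c(1, 0, 1, 0),
               tolerance = 1e-9)

  noisy <- pairs
  noisy$run_rt1 <- noisy$run_rt1 + rnorm(12, 0, 0.02)
  noisy$run_rt2 <- noisy$run_rt2 + rnorm(12, 0, 0.02)
  tn <- fit_transform(noisy)
  expect_lt(tn$rms1, 2 * 0.02)
  expect_lt(tn$rms2, 2 * 0.02)

  expect_error(fit_transform(pairs[1:2, ]), ">= 3")
  degen <- pairs; degen$tmpl_rt1 <- 1
  expect_error(fit_transform(degen), "degenerate")

  inv <- invert_transform(tf)
  back <- predict_transform(inv, tf$a1 * 2 + tf$b1, tf$a2 * 1 + tf$b2)
  expect_equal(back$rt1, 2, tolerance = 1e-12)
  expect_equal(back$rt2, 1, tolerance = 1e-12)
})

test_that("composites accumulate aligned images", {
  img <- blob_image(apexes = data.frame(mod = c(20, 40),
                                        samp = c(30, 60),
                                        height = c(1e5, 5e4)))
  one <- build_composite(list(img), list(identity_transform()))
  expect_equal(one$image, img$image)
  three <- build_composite(rep(list(img), 3),
                           rep(list(identity_transform()), 3))
  expect_equal(three$image, 3 * img$image)
  m <- build_composite(rep(list(img), 3),
                       rep(list(identity_transform()), 3), mode = "mean")
  expect_equal(m$image, img$image)
})

test_that("composite resampling undoes known retention shifts", {
  img <- blob_image(apexes = data.frame(mod = 30, samp = 50, height = 1e5))
  # a run shifted by +2 modulations and +0.1 s
  shifted <- blob_image(apexes = data.frame(mod = 32, samp = 50 + 0.1 * 16,
                                            height = 1e5))
  tf <- structure(list(a1 = 1, b1 = 2 * 5 / 60, a2 = 1, b2 = 0.1,
                       rms1 = 0, rms2 = 0, n = 4L), class = "rt_transform")
  comp <- build_composite(list(shifted), list(tf))
  apex <- which(comp$image == max(comp$image), arr.ind = TRUE)
  expect_lte(abs(apex[1, 1] - 30), 1)
  expect_lte(abs(apex[1, 2] - 50), 1)
})

test_that("region delineation follows the detection gates and yields disjoint polygons", {
  img <- blob_image(apexes = data.frame(mod = c(15, 35, 50),
                                        samp = c(25, 55, 75),
                                        height = c(2e5, 3e5, 1e3)))
  regions <- delineate_regions(img, min_counts = 1e5)
  expect_equal(nrow(regions), 2)  # the weak blob stays below the gate
  expect_true(all(regions$kind == "peak_region"))
  polys <- regions$polygon
  expect_length(intersect(polys[[1]], polys[[2]]), 0)
  expect_equal(nrow(delineate_regions(img, min_counts = 1e12)), 0)
})

test_that("quantification reproduces per-run region volumes", {
  img <- blob_image(apexes = data.frame(mod = c(20, 40),
                                        samp = c(30, 60),
                                        height = c(1e5, 5e4)))
  n <- 4
  comp <- build_composite(rep(list(img), n),
                          rep(list(identity_transform()), n))
  regions <- delineate_regions(comp, min_counts = 1e5)
  tmpl <- make_template(fake_peaks(numeric(), numeric(), list()))
  tmpl <- add_regions(tmpl, regions)
  fm <- quantify_features(rep(list(img), n),
                          tmpl, rep(list(identity_transform()), n))
  expect_identical(dim(fm$volumes), c(4L, 2L))
  for (g in 1:2) {
    expect_equal(fm$volumes[, g],
                 rep(integrate_volume(comp, regions$polygon[[g]]) / n, 4),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  pr <- percent_response(fm)
  expect_equal(unname(rowSums(pr$volumes)), rep(100, 4), tolerance = 1e-6)
})

test_that("template growth recovers entries the seeding run missed", {
  set.seed(33)
  spec_a <- rand_spec(); spec_b <- rand_spec()
  run1 <- fake_peaks(2, 1.5, list(spec_a))
  run23 <- fake_peaks(c(2, 4), c(1.5, 2.5), list(spec_a, spec_b))
  tmpl <- make_template(run1)
  al <- align_runs(tmpl, list(run1, run23, run23))
  expect_equal(length(al$match_counts), 2)
  rel <- select_reliable(al$match_counts, 3)
  expect_length(rel, 2)  # compound B, absent from the seed, is recovered
  al0 <- align_runs(tmpl, list(run1, run23, run23), augment = FALSE)
  expect_equal(length(al0$match_counts), 1)
})
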