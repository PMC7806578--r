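## Synthetic dual-energy GCxGC-TOF MS runs with known ground truth.
##
## The generator emulates the acquisition design of a tandem-ionization
## (12 eV + 70 eV) saliva-metabolome study: 4 QC + 3 MHO + 5 MUO subjects
## x 2 process x 2 analytical replicates (48 runs per data stream), a 5 s
## modulation period sampled at 50 Hz per channel, retention-time jitter of
## 0.20% RSD in 1D and 1.90% in 2D, an order-of-magnitude lower 12 eV
## response, column-bleed baseline with smooth 1D drift plus noise, and
## class-dependent abundance effects patterned on the study's discriminant
## metabolite table.

#' Synthetic acquisition and study configuration
#'
#' Defaults are the study conditions the generator emulates; see the
#' methods vignette for the rationale behind each value.
#'
#' @param modulation_period modulation period (s).
#' @param acquisition_rate acquisition frequency (Hz per channel);
#'   `modulation_period * acquisition_rate` must be a positive integer.
#' @param n_modulations run length in modulations.
#' @param mz_range integer nominal-mass window `(min, max)` Da. Library
#'   fragments outside the window are mass-filtered at simulation time and
#'   the spectrum renormalized, so a compound's deposited TIC volume is
#'   independent of the window.
#' @param alkane_carbons carbon numbers of the retention-index alkane
#'   ladder.
#' @param alkane_t0,alkane_step first-dimension elution model of the
#'   ladder: C_n elutes at `alkane_t0 + alkane_step * (n - min(carbons))`
#'   minutes (temperature-programmed linearity).
#' @param rt_jitter_1d,rt_jitter_2d run-to-run retention-time jitter,
#'   percent RSD (multiplicative Gaussian).
#' @param baseline_level_70,baseline_level_12 per-channel background TIC
#'   level (counts per pixel).
#' @param noise_sd_70,noise_sd_12 per-channel background noise, as the
#'   standard deviation of a TIC pixel (counts); distributed over the bleed
#'   m/z bins proportionally to the square root of their baseline share.
#' @param shot_noise apply Poisson noise to the deposited signal.
#' @param drift_fraction peak-to-peak amplitude of the monotone 1D baseline
#'   ramp (column bleed), as a fraction of the baseline level.
#' @param sigma_1d,sigma_2d 2D Gaussian peak widths: sigma in modulations
#'   (1D) and seconds (2D).
#' @param bleed_mz,bleed_weights nominal masses carrying the column-bleed
#'   baseline and their relative shares.
#' @param class_effects named per-compound MUO:MHO abundance ratios
#'   (`NULL` = take the library's own defaults).
#' @param subject_cv,process_cv,analytical_cv lognormal coefficients of
#'   variation of per-subject, per-process-replicate and per-analytical-run
#'   metabolite abundances.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(modulation_period = 5,
                         acquisition_rate = 50,
                         n_modulations = 144,
                         mz_range = c(45, 500),
                         alkane_carbons = 7:30,
                         alkane_t0 = 0.8,
                         alkane_step = 0.45,
                         rt_jitter_1d = 0.20,
                         rt_jitter_2d = 1.90,
                         baseline_level_70 = 23000,
                         baseline_level_12 = 1840,
                         noise_sd_70 = 5000,
                         noise_sd_12 = 50,
                         shot_noise = TRUE,
                         drift_fraction = 0.4,
                         sigma_1d = 1,
                         sigma_2d = 0.05,
                         bleed_mz = c(73, 147, 207, 281, 355),
                         bleed_weights = c(0.35, 0.25, 0.20, 0.12, 0.08),
                         class_effects = NULL,
                         subject_cv = 0.15,
                         process_cv = 0.08,
                         analytical_cv = 0.08) {
  pts <- modulation_period * acquisition_rate
  if (abs(pts - round(pts)) > 1e-9 || round(pts) <= 0) {
    stop("modulation_period x acquisition_rate must be a positive integer")
  }
  if (rt_jitter_1d < 0 || rt_jitter_2d < 0) stop("jitter RSDs must be >= 0")
  if (length(bleed_mz) != length(bleed_weights)) {
    stop("bleed_mz and bleed_weights lengths differ")
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Map a linear retention index to first-dimension retention time
#'
#' Linear interpolation on the configured alkane ladder (the elution model
#' is linear in carbon number, so the map is globally linear); values
#' outside the ladder extrapolate linearly.
#'
#' @param ri linear retention index (100 x carbon number at the ladder).
#' @param config a [synth_config()].
#' @return first-dimension time, minutes.
#' @export
ri_to_rt1 <- function(ri, config) {
  n0 <- min(config$alkane_carbons)
  config$alkane_t0 + config$alkane_step * (ri / 100 - n0)
}

#' Nominal alkane first-dimension elution times
#' @param config a [synth_config()].
#' @return data.frame with `carbon` and `rt1` (min).
#' @export
alkane_times <- function(config) {
  n0 <- min(config$alkane_carbons)
  data.frame(carbon = config$alkane_carbons,
             rt1 = config$alkane_t0 +
               config$alkane_step * (config$alkane_carbons - n0))
}

## Reference (named) library entries -------------------------------------
## A fixed subset of the synthetic library mirrors the study's discriminant
## metabolites: their printed retention indices, second-dimension times and
## MUO:MHO percent differences are kept; the dual-energy fragment spectra
## are synthetic but follow the TMS-derivative fragmentation logic (70 eV
## dominated by low-m/z silyl fragments such as 73/129/147, 12 eV
## re-weighted toward high-m/z structure-diagnostic fragments, e.g.
## 202/319/333 for N-acetyl-D-glucosamine).

#' @noRd
sp <- function(...) {
  v <- c(...)
  spectrum(as.integer(names(v)), unname(v))
}

#' @noRd
reference_entry_list <- function() {
  e <- function(name, ri, rt2, pct_diff, s70, s12) {
    list(name = name, ri = ri, two_d_time = rt2, pct_diff = pct_diff,
         spectrum_70 = normalize_spectrum(s70),
         spectrum_12 = normalize_spectrum(s12))
  }
  list(
    e("3-Methyl-2-oxobutanoic acid, TMS", 1052, 1.76, 52.7,
      sp("73" = 999, "89" = 300, "100" = 250, "131" = 400, "158" = 150,
         "173" = 80),
      sp("131" = 500, "158" = 999, "173" = 700, "188" = 300)),
    e("Urea, 2TMS", 1192, 2.98, 99.0,
      sp("73" = 700, "99" = 150, "147" = 999, "171" = 300, "189" = 450,
         "204" = 100),
      sp("147" = 300, "171" = 600, "189" = 999, "204" = 650)),
    e("Serine, 3TMS", 1367, 1.68, -59.4,
      sp("73" = 800, "100" = 200, "116" = 350, "147" = 500, "204" = 999,
         "218" = 400, "278" = 60),
      sp("204" = 999, "218" = 700, "278" = 400, "306" = 150)),
    e("Pyroglutamic acid, 2TMS", 1510, 2.42, -17.8,
      sp("73" = 600, "84" = 250, "147" = 400, "156" = 999, "230" = 300,
         "258" = 100),
      sp("156" = 700, "230" = 999, "258" = 500, "273" = 200)),
    e("2-Deoxy-D-ribose, 3TMS methyloxime", 1589, 1.62, 87.8,
      sp("73" = 999, "103" = 300, "117" = 350, "129" = 400, "147" = 450,
         "217" = 250, "307" = 90),
      sp("217" = 800, "231" = 400, "307" = 999, "335" = 300)),
    e("5-Aminovaleric acid, 3TMS", 1624, 1.84, 75.3,
      sp("73" = 850, "86" = 300, "147" = 500, "156" = 400, "174" = 999,
         "248" = 200, "318" = 70),
      sp("156" = 150, "174" = 999, "248" = 700, "318" = 450, "333" = 200)),
    e("Citric acid, 4TMS", 1836, 1.84, 10.8,
      sp("73" = 999, "147" = 650, "183" = 300, "211" = 250, "273" = 500,
         "347" = 200, "363" = 100),
      sp("211" = 200, "273" = 999, "347" = 700, "363" = 400, "375" = 250)),
    e("Tyrosine, 2TMS", 1889, 2.16, -12.6,
      sp("73" = 500, "100" = 200, "147" = 300, "179" = 999, "208" = 350,
         "218" = 250, "280" = 120),
      sp("179" = 700, "208" = 999, "280" = 500, "310" = 200)),
    e("D-Sorbitol, 6TMS", 1920, 1.18, -71.9,
      sp("73" = 999, "103" = 450, "147" = 550, "205" = 500, "217" = 400,
         "319" = 250, "345" = 90),
      sp("205" = 700, "217" = 500, "319" = 999, "345" = 400, "421" = 150)),
    e("D-(+)-Glucuronic acid gamma-lactone, 3TMS methyloxime", 1923, 1.70,
      325.2,
      sp("73" = 999, "129" = 350, "147" = 500, "160" = 300, "217" = 400,
         "231" = 200, "333" = 120),
      sp("160" = 400, "217" = 800, "333" = 999, "375" = 350)),
    e("N-Acetyl-D-glucosamine, 4TMS methyloxime (anti)", 2052, 2.24, 53.9,
      sp("73" = 999, "129" = 400, "147" = 450, "202" = 250, "217" = 180,
         "319" = 90, "333" = 70),
      sp("202" = 700, "217" = 300, "319" = 999, "333" = 850)),
    e("N-Acetyl-D-glucosamine, 4TMS trimethylsilyloxime (isomer II)", 2149,
      2.86, 48.8,
      sp("73" = 999, "129" = 380, "147" = 460, "202" = 240, "217" = 200,
         "319" = 100, "333" = 80),
      sp("202" = 650, "217" = 350, "319" = 950, "333" = 999)),
    e("N-Acetylneuraminic acid methyl ester, 5TMS", 2270, 2.38, 77.2,
      sp("73" = 999, "100" = 250, "147" = 500, "173" = 300, "205" = 350,
         "317" = 150, "375" = 100),
      sp("173" = 200, "205" = 500, "317" = 999, "375" = 600, "400" = 250)),
    e("D-Lactose, 8TMS (isomer 1)", 2526, 1.80, -87.5,
      sp("73" = 999, "103" = 350, "147" = 420, "191" = 300, "204" = 550,
         "217" = 450, "361" = 300),
      sp("204" = 600, "217" = 400, "361" = 999, "451" = 300)),
    e("D-Lactose, 8TMS (isomer 2)", 2604, 2.22, -87.5,
      sp("73" = 999, "103" = 330, "147" = 430, "191" = 320, "204" = 520,
         "217" = 430, "361" = 320),
      sp("204" = 570, "217" = 380, "361" = 999, "451" = 320)),
    e("Sucrose, 8TMS", 2678, 1.70, 40.9,
      sp("73" = 999, "103" = 300, "147" = 400, "217" = 500, "271" = 250,
         "361" = 450, "437" = 120),
      sp("217" = 400, "231" = 150, "271" = 300, "361" = 999, "437" = 500,
         "451" = 250))
  )
}

#' The fixed reference compounds of the synthetic library
#'
#' @return data.frame with `name`, `ri`, `two_d_time` (s) and `pct_diff`
#'   (percent MUO-vs-MHO abundance difference, `(MUO - MHO)/MHO x 100`).
#' @export
reference_compounds <- function() {
  ref <- reference_entry_list()
  data.frame(name = vapply(ref, `[[`, character(1), "name"),
             ri = vapply(ref, `[[`, numeric(1), "ri"),
             two_d_time = vapply(ref, `[[`, numeric(1), "two_d_time"),
             pct_diff = vapply(ref, `[[`, numeric(1), "pct_diff"))
}

#' Build a synthetic dual-energy spectral library
#'
#' Returns `n_compounds` entries, each with a retention index, a
#' second-dimension elution time, dual-energy fragment spectra (70 eV
#' dominated by low-m/z TMS-type fragments; 12 eV re-weighted toward
#' high-m/z fragments) and per-channel response factors with
#' `0 < response_12 < response_70` (about one order of magnitude apart).
#' A fixed named subset mirrors the study's discriminant metabolites with
#' their printed retention indices (see [reference_compounds()]); the
#' remainder are randomly generated. Retention positions are spaced so
#' that compounds close in retention index differ in second-dimension
#' time.
#'
#' @param n_compounds number of entries (>= 0).
#' @param seed RNG seed; identical `(n_compounds, seed, ...)` give
#'   byte-identical libraries.
#' @param include_reference include the fixed named subset first.
#' @param ri_range retention-index range for random entries.
#' @param two_d_range second-dimension elution window (s) for random
#'   entries.
#' @param weak_12_fraction fraction of entries whose 12 eV response is
#'   suppressed far below any practical detection gate (emulating analytes
#'   visible only at 70 eV).
#' @param modulation_period used only to validate `two_d_time` bounds.
#' @return object of class `spectral_library`: named list of entries with
#'   fields `name`, `ri`, `two_d_time`, `spectrum_70`, `spectrum_12`,
#'   `response_70`, `response_12`, `pct_diff`; default MUO:MHO ratios in
#'   `attr(, "class_effects")`.
#' @export
build_spectral_library <- function(n_compounds, seed = 1,
                                   include_reference = TRUE,
                                   ri_range = c(850, 2650),
                                   two_d_range = c(1.0, 3.2),
                                   weak_12_fraction = 0,
                                   modulation_period = 5) {
  if (n_compounds < 0) stop("n_compounds must be >= 0")
  set.seed(seed)
  entries <- list()
  if (include_reference && n_compounds > 0) {
    entries <- utils::head(reference_entry_list(), n_compounds)
  }
  taken_ri <- vapply(entries, `[[`, numeric(1), "ri")
  taken_2d <- vapply(entries, `[[`, numeric(1), "two_d_time")
  n_random <- n_compounds - length(entries)
  for (k in seq_len(n_random)) {
    ri <- NA
    for (try in 1:300) {
      cand <- runif(1, ri_range[1], ri_range[2])
      if (!length(taken_ri) || min(abs(taken_ri - cand)) >= 40) {
        ri <- cand
        break
      }
    }
    near2d <- numeric()
    if (is.na(ri)) {  # crowded: fall back to 2D separation
      ri <- runif(1, ri_range[1], ri_range[2])
      near2d <- taken_2d[abs(taken_ri - ri) < 40]
    }
    rt2 <- runif(1, two_d_range[1], two_d_range[2])
    for (try in 1:300) {
      if (!length(near2d) || min(abs(near2d - rt2)) >= 0.4) break
      rt2 <- runif(1, two_d_range[1], two_d_range[2])
    }
    ## 70 eV: silyl backbone + random mid/high fragments
    mids <- sort(sample(setdiff(85:240, 147L), sample(3:5, 1)))
    highs <- sort(sample(250:480, sample(1:3, 1)))
    m70 <- c(73, 147, mids, highs)
    i70 <- c(999 * runif(1, 0.7, 1), runif(1, 200, 700),
             runif(length(mids), 100, 600), runif(length(highs), 50, 300))
    ## 12 eV: highest-m/z fragments dominate, plus the strongest mid
    top <- utils::head(order(-m70), 3)
    m12 <- c(m70[top], mids[which.max(i70[2 + seq_along(mids)])])
    i12 <- c(runif(3, 400, 999), runif(1, 250, 600))
    o <- !duplicated(m12)
    entries[[length(entries) + 1L]] <-
      list(name = sprintf("compound_%03d", k), ri = ri, two_d_time = rt2,
           pct_diff = NA_real_,
           spectrum_70 = normalize_spectrum(spectrum(m70, i70)),
           spectrum_12 = normalize_spectrum(spectrum(m12[o], i12[o])))
    taken_ri <- c(taken_ri, ri)
    taken_2d <- c(taken_2d, rt2)
  }
  ## per-channel response factors
  for (k in seq_along(entries)) {
    r70 <- min(max(rlnorm(1, log(4e6), 0.8), 1.5e6), 5e7)
    ratio <- min(max(rlnorm(1, log(10), 0.25), 5), 30)
    entries[[k]]$response_70 <- r70
    entries[[k]]$response_12 <- r70 / ratio
  }
  if (weak_12_fraction > 0 && length(entries)) {
    n_weak <- round(weak_12_fraction * length(entries))
    weak <- sample(seq_along(entries), n_weak)
    for (k in weak) {
      entries[[k]]$response_12 <- entries[[k]]$response_70 / 2000
    }
  }
  for (k in seq_along(entries)) {
    if (entries[[k]]$two_d_time < 0 ||
        entries[[k]]$two_d_time >= modulation_period) {
      stop("two_d_time outside [0, modulation_period) for ",
           entries[[k]]$name)
    }
  }
  names(entries) <- vapply(entries, `[[`, character(1), "name")
  pct <- vapply(entries, `[[`, numeric(1), "pct_diff")
  effects <- ifelse(is.na(pct), 1, 1 + pct / 100)
  names(effects) <- names(entries)
  structure(entries, class = "spectral_library", class_effects = effects)
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("<spectral_library>", length(x), "compounds\n")
  if (length(x)) {
    ri <- vapply(x, `[[`, numeric(1), "ri")
    cat("  RI", round(min(ri)), "-", round(max(ri)), ";",
        sum(!is.na(vapply(x, `[[`, numeric(1), "pct_diff"))),
        "named reference entries\n")
  }
  invisible(x)
}

#' Enumerate the runs of a study design
#'
#' Every (subject, process replicate, analytical replicate) combination
#' becomes one run with a stable identifier. The default arguments
#' reproduce the emulated study: (4 QC + 3 MHO + 5 MUO) x 2 x 2 = 48 runs.
#'
#' @param n_qc,n_mho,n_muo subjects per group (>= 0).
#' @param process_reps,analytical_reps replicate counts (>= 1).
#' @return data.frame of class `study_design` with columns `run_id`,
#'   `subject_id`, `group`, `process_rep`, `analytical_rep`.
#' @export
make_study_design <- function(n_qc = 4, n_mho = 3, n_muo = 5,
                              process_reps = 2, analytical_reps = 2) {
  if (n_qc < 0 || n_mho < 0 || n_muo < 0) stop("subject counts must be >= 0")
  if (process_reps < 1 || analytical_reps < 1) {
    stop("replicate counts must be >= 1")
  }
  subjects <- data.frame(
    subject_id = c(sprintf("QC%d", seq_len(n_qc)),
                   sprintf("MHO%d", seq_len(n_mho)),
                   sprintf("MUO%d", seq_len(n_muo))),
    group = rep(c("QC", "MHO", "MUO"), c(n_qc, n_mho, n_muo))
  )
  out <- expand.grid(analytical_rep = seq_len(analytical_reps),
                     process_rep = seq_len(process_reps),
                     subject_id = subjects$subject_id,
                     stringsAsFactors = FALSE)
  out <- out[, c("subject_id", "process_rep", "analytical_rep")]
  out$group <- subjects$group[match(out$subject_id, subjects$subject_id)]
  out$run_id <- sprintf("%s_P%d_A%d", out$subject_id, out$process_rep,
                        out$analytical_rep)
  out <- out[, c("run_id", "subject_id", "group", "process_rep",
                 "analytical_rep")]
  rownames(out) <- NULL
  class(out) <- c("study_design", "data.frame")
  out
}

#' Draw per-run compound abundances for a study design
#'
#' Lognormal hierarchy: a per-subject level (CV `subject_cv`), a
#' per-process-replicate level (CV `process_cv`) and per-run analytical
#' noise (CV `analytical_cv`), all multiplicative around 1. Class effects
#' are NOT applied here; [simulate_run()] scales MUO runs by the library's
#' (or config's) MUO:MHO ratios.
#'
#' @param design a [make_study_design()] data.frame.
#' @param library a [build_spectral_library()].
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @return numeric matrix `[run, compound]` with dimnames.
#' @export
draw_abundances <- function(design, library, config, seed = 1) {
  set.seed(seed)
  nc <- length(library)
  subjects <- unique(design$subject_id)
  subj_eff <- matrix(exp(rnorm(length(subjects) * nc, 0, config$subject_cv)),
                     nrow = length(subjects),
                     dimnames = list(subjects, names(library)))
  procs <- unique(design[, c("subject_id", "process_rep")])
  proc_key <- paste(procs$subject_id, procs$process_rep)
  proc_eff <- matrix(exp(rnorm(nrow(procs) * nc, 0, config$process_cv)),
                     nrow = nrow(procs), dimnames = list(proc_key, NULL))
  anal_eff <- matrix(exp(rnorm(nrow(design) * nc, 0, config$analytical_cv)),
                     nrow = nrow(design))
  ab <- subj_eff[design$subject_id, , drop = FALSE] *
    proc_eff[paste(design$subject_id, design$process_rep), , drop = FALSE] *
    anal_eff
  dimnames(ab) <- list(design$run_id, names(library))
  ab
}

## Cube synthesis --------------------------------------------------------

## Sparse blob deposit: returns linear cube indices and the counts to add
## (one in-place array assignment per channel avoids repeated array copies).
#' @noRd
deposit_blob <- function(dims, c1, c2, vol, bins, bin_weights, config) {
  s1 <- config$sigma_1d
  s2 <- config$sigma_2d * config$acquisition_rate
  i <- max(1L, floor(c1 - 4 * s1)):min(dims[1], ceiling(c1 + 4 * s1))
  j <- max(1L, floor(c2 - 4 * s2)):min(dims[2], ceiling(c2 + 4 * s2))
  if (!length(i) || !length(j) || max(i) < 1 || max(j) < 1) return(NULL)
  w1 <- exp(-0.5 * ((i - c1) / s1)^2); w1 <- w1 / sum(w1)
  w2 <- exp(-0.5 * ((j - c2) / s2)^2); w2 <- w2 / sum(w2)
  blob <- as.numeric(vol * outer(w2, w1))
  ## linear indices in stream layout: scan = (mod - 1) * P + samp
  pix <- as.numeric(outer(j, (i - 1) * dims[2], "+"))
  scans <- as.numeric(dims[1]) * dims[2]
  list(idx = as.numeric(outer(pix, (bins - 1) * scans, "+")),
       val = as.numeric(outer(blob, bin_weights)))
}

## Restrict a spectrum to the m/z window and return bin indices + weights
## that sum to 1 (the mass filter does not change deposited volume).
#' @noRd
spectrum_bins <- function(s, mz_axis) {
  keep <- s$mz >= mz_axis[1] & s$mz <= mz_axis[length(mz_axis)]
  if (!any(keep)) return(NULL)
  list(bins = match(s$mz[keep], mz_axis),
       weights = s$intensity[keep] / sum(s$intensity[keep]))
}

## Builds one channel directly in raw-stream layout ([scan, mz] matrix,
## scans in modulation-major order) to avoid shuffling the full cube.
#' @noRd
build_channel_stream <- function(positions, volumes, spectra, config,
                                 baseline_level, noise_sd) {
  n1 <- config$n_modulations
  P <- as.integer(round(config$modulation_period * config$acquisition_rate))
  mz_axis <- config$mz_range[1]:config$mz_range[2]
  nm <- length(mz_axis)
  stream <- matrix(0, nrow = n1 * P, ncol = nm)
  ## column-bleed baseline with monotone 1D drift, plus Gaussian noise on
  ## the bleed bins (total TIC pixel noise = noise_sd)
  ramp <- if (n1 > 1) {
    1 + config$drift_fraction * ((seq_len(n1) - 1) / (n1 - 1) - 0.5)
  } else rep(1, n1)
  in_rng <- config$bleed_mz >= mz_axis[1] & config$bleed_mz <= mz_axis[nm]
  bmz <- config$bleed_mz[in_rng]
  bw <- config$bleed_weights[in_rng]
  if (length(bw)) bw <- bw / sum(bw)
  for (b in seq_along(bmz)) {
    bin <- match(bmz[b], mz_axis)
    col <- rep(baseline_level * bw[b] * ramp, each = P)
    if (noise_sd > 0) {
      col <- col + rnorm(n1 * P, 0, noise_sd * sqrt(bw[b]))
    }
    stream[, bin] <- round(pmax(col, 0))
  }
  ## deposit signal, then Poisson shot noise on signal voxels
  if (length(volumes)) {
    parts <- vector("list", length(volumes))
    for (k in seq_along(volumes)) {
      sb <- spectra[[k]]
      if (is.null(sb)) next
      parts[[k]] <- deposit_blob(c(n1, P, nm), positions$mod[k],
                                 positions$samp[k], volumes[k], sb$bins,
                                 sb$weights, config)
    }
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts)) {
      idx <- unlist(lapply(parts, `[[`, "idx"), use.names = FALSE)
      val <- unlist(lapply(parts, `[[`, "val"), use.names = FALSE)
      ## sum contributions of overlapping blobs per voxel
      agg <- rowsum(val, idx)
      idx_u <- as.numeric(rownames(agg))
      lam <- agg[, 1]
      add <- if (config$shot_noise) rpois(length(lam), lam) else round(lam)
      stream[idx_u] <- stream[idx_u] + add
    }
  }
  stream
}

#' Simulate one dual-energy GCxGC run
#'
#' Each compound of the library appears as a 2D Gaussian blob at its
#' RI-determined first-dimension position and its `two_d_time`
#' second-dimension position, jittered by the configured retention-time
#' RSDs (jitter is shared between the two channels, as both observe the
#' same physical elution). Per-channel apex spectra equal the library
#' spectra (mass-filtered to the m/z window) up to noise; blob TIC volume
#' is `abundance x response_<channel>`. Runs of MUO subjects additionally
#' scale abundances by the per-compound class-effect ratios.
#'
#' @param design_entry one row of [make_study_design()] (or a list with
#'   `run_id` and `group`).
#' @param library a [build_spectral_library()].
#' @param abundances per-compound scalars, same length/order as `library`
#'   (e.g. a row of [draw_abundances()]).
#' @param config a [synth_config()].
#' @param seed RNG seed; identical inputs give identical output.
#' @return list of class `synthetic_run`: raw channel streams `stream_70`
#'   and `stream_12` (`[scan, mz]` matrices), `mz_axis`, `meta`, and the
#'   ground-truth table `truth` (name, true apex retention coordinates,
#'   true per-channel volumes).
#' @export
simulate_run <- function(design_entry, library, abundances, config,
                         seed = 1) {
  if (length(abundances) != length(library)) {
    stop("abundances length (", length(abundances),
         ") does not match the library (", length(library), ")")
  }
  set.seed(seed)
  mz_axis <- config$mz_range[1]:config$mz_range[2]
  group <- design_entry$group
  effects <- config$class_effects %||% attr(library, "class_effects")
  ab <- as.numeric(abundances)
  if (identical(group, "MUO") && length(library)) {
    ratio <- effects[names(library)]
    ratio[is.na(ratio)] <- 1
    ab <- ab * ratio
  }
  n <- length(library)
  ri <- vapply(library, `[[`, numeric(1), "ri")
  rt2_nom <- vapply(library, `[[`, numeric(1), "two_d_time")
  rt1_nom <- ri_to_rt1(ri, config)
  j1 <- if (n) rnorm(n, 0, config$rt_jitter_1d / 100) else numeric()
  j2 <- if (n) rnorm(n, 0, config$rt_jitter_2d / 100) else numeric()
  rt1 <- rt1_nom * (1 + j1)
  rt2 <- rt2_nom * (1 + j2)
  positions <- list(mod = rt1_to_mod(rt1, config$modulation_period),
                    samp = rt2_to_samp(rt2, config$acquisition_rate))
  vol70 <- ab * vapply(library, `[[`, numeric(1), "response_70")
  vol12 <- ab * vapply(library, `[[`, numeric(1), "response_12")
  bins70 <- lapply(library, function(e) spectrum_bins(e$spectrum_70, mz_axis))
  bins12 <- lapply(library, function(e) spectrum_bins(e$spectrum_12, mz_axis))
  stream70 <- build_channel_stream(positions, vol70, bins70, config,
                                   config$baseline_level_70,
                                   config$noise_sd_70)
  stream12 <- build_channel_stream(positions, vol12, bins12, config,
                                   config$baseline_level_12,
                                   config$noise_sd_12)
  truth <- data.frame(name = if (n) names(library) else character(),
                      rt1 = rt1, rt2 = rt2,
                      mod = positions$mod, samp = positions$samp,
                      volume_70 = vol70, volume_12 = vol12,
                      abundance = ab, row.names = NULL)
  structure(
    list(stream_70 = stream70, stream_12 = stream12,
         mz_axis = mz_axis,
         meta = list(run_id = design_entry$run_id %||% "run",
                     group = group %||% NA_character_,
                     modulation_period = config$modulation_period,
                     acquisition_rate = config$acquisition_rate),
         truth = truth),
    class = "synthetic_run")
}

#' Fold one channel of a synthetic run
#'
#' @param run a [simulate_run()] result.
#' @param channel `"70eV"` or `"12eV"`.
#' @return a [chromatogram2d()].
#' @export
fold_run <- function(run, channel = c("70eV", "12eV")) {
  channel <- match.arg(channel)
  stream <- if (channel == "70eV") run$stream_70 else run$stream_12
  fold(stream, run$meta$modulation_period, run$meta$acquisition_rate,
       mz_axis = run$mz_axis, channel = channel, run_id = run$meta$run_id)
}

#' Simulate an n-alkane calibration run
#'
#' One blob per alkane of the configured ladder (default C7-C30), at
#' monotonically increasing first-dimension times; used for linear
#' retention-index calibration.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @return list of class `synthetic_run` (as [simulate_run()]); the
#'   ground-truth table maps `carbon` number to true apex `rt1`.
#' @export
simulate_alkane_run <- function(config, seed = 1) {
  at <- alkane_times(config)
  run_min <- config$n_modulations * config$modulation_period / 60
  if (max(at$rt1) >= run_min - 0.1) {
    stop("alkane ladder (up to ", max(at$rt1), " min) does not fit in a ",
         round(run_min, 2), " min run; extend n_modulations")
  }
  nalk <- nrow(at)
  lib <- vector("list", nalk)
  for (k in seq_len(nalk)) {
    cn <- at$carbon[k]
    mplus <- 14L * cn + 2L
    s70 <- spectrum(c(57, 71, 85, 99, 113),
                    c(999, 700, 450, 250, 150))
    m12 <- c(85, 99, 113); i12 <- c(400, 999, 600)
    if (mplus <= config$mz_range[2]) {
      m12 <- c(m12, mplus); i12 <- c(i12, 800)
    }
    lib[[k]] <- list(name = sprintf("n-C%d", cn),
                     ri = 100 * cn,
                     two_d_time = 1.0 + 0.015 * (cn - min(at$carbon)),
                     pct_diff = NA_real_,
                     spectrum_70 = normalize_spectrum(s70),
                     spectrum_12 = normalize_spectrum(spectrum(m12, i12)),
                     response_70 = 5e6, response_12 = 5e5)
  }
  names(lib) <- vapply(lib, `[[`, character(1), "name")
  lib <- structure(lib, class = "spectral_library",
                   class_effects = setNames(rep(1, nalk), names(lib)))
  run <- simulate_run(list(run_id = "alkanes", group = "QC"), lib,
                      abundances = rep(1, nalk), config = config,
                      seed = seed)
  run$truth$carbon <- at$carbon
  run
}
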