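## Desk-scale validation experiments. These run the full pipeline on
## synthetic studies that reproduce the emulated design (48 runs,
## instrument-level retention jitter) and measure how well the known
## ground truth is recovered. Shared by the test suite and
## scripts/acceptance.R.

#' Map template-space features to library compounds
#'
#' Greedy nearest-neighbour assignment of features (regions or reliable
#' peaks) to the compounds' nominal retention positions, within a
#' retention window; one compound per feature and vice versa.
#'
#' @param features data.frame with `id`, `rt1`, `rt2` (template space).
#' @param library a [build_spectral_library()].
#' @param config a [synth_config()] (for the RI -> time map).
#' @param window_1d,window_2d assignment windows (min, s).
#' @return data.frame `compound`, `feature_id` (NA where unmatched).
#' @export
map_features_to_compounds <- function(features, library, config,
                                      window_1d = 0.125, window_2d = 0.2) {
  rt1_nom <- ri_to_rt1(vapply(library, `[[`, numeric(1), "ri"), config)
  rt2_nom <- vapply(library, `[[`, numeric(1), "two_d_time")
  out <- data.frame(compound = names(library),
                    feature_id = NA_character_)
  if (!nrow(features)) return(out)
  cand <- expand.grid(ci = seq_along(library), fi = seq_len(nrow(features)))
  d1 <- abs(rt1_nom[cand$ci] - features$rt1[cand$fi])
  d2 <- abs(rt2_nom[cand$ci] - features$rt2[cand$fi])
  ok <- d1 <= window_1d & d2 <= window_2d
  cand <- cand[ok, , drop = FALSE]
  dist <- sqrt(d1[ok]^2 + d2[ok]^2)
  cand <- cand[order(dist), , drop = FALSE]
  used_c <- logical(length(library)); used_f <- logical(nrow(features))
  for (i in seq_len(nrow(cand))) {
    ci <- cand$ci[i]; fi <- cand$fi[i]
    if (!used_c[ci] && !used_f[fi]) {
      out$feature_id[ci] <- features$id[fi]
      used_c[ci] <- TRUE; used_f[fi] <- TRUE
    }
  }
  out
}

#' Class effects for the recovery experiment
#'
#' The `n_effect` compounds with the largest printed percent differences
#' keep their MUO:MHO ratios; every other compound is null (ratio 1).
#'
#' @param library a [build_spectral_library()].
#' @param n_effect number of effect compounds.
#' @return named ratio vector.
#' @export
effect_subset <- function(library, n_effect = 8) {
  effects <- attr(library, "class_effects")
  pct <- abs(100 * (effects - 1))
  keep <- names(sort(pct, decreasing = TRUE))[seq_len(min(n_effect,
                                                          sum(pct > 0)))]
  out <- setNames(rep(1, length(effects)), names(effects))
  out[keep] <- effects[keep]
  out
}

#' Parameter-recovery experiment on the fused stream
#'
#' Simulates replicates of the emulated 48-run study (4 QC + 3 MHO +
#' 5 MUO x 2 x 2) with `n_compounds` compounds of which `n_effect` carry
#' MUO-vs-MHO abundance effects of at least 50 percent, runs the full
#' fused-stream pipeline, maps peak regions back to the injected
#' compounds, and scores: the fraction of effect compounds that are both
#' Kruskal-Wallis-selected (alpha 0.05) and have VIP >= 1; the fraction of
#' null compounds passing both gates; and the fraction of injected
#' compounds selected as reliable peaks at the 750/750 match gates.
#'
#' @param seed base RNG seed.
#' @param n_replicates independent replicate studies.
#' @param n_compounds,n_effect library size and number of effect compounds.
#' @param synth a [synth_config()]; the default uses a 144-modulation,
#'   45-244 Da window (see the methods vignette on problem sizes).
#' @return data.frame with one row per replicate (`effect_rate`,
#'   `null_rate`, `reliable_fraction`) plus the means as attributes.
#' @export
run_recovery_experiment <- function(seed = 1, n_replicates = 5,
                                    n_compounds = 30, n_effect = 8,
                                    synth = synth_config(
                                      mz_range = c(45, 244))) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    lib0 <- build_spectral_library(n_compounds,
                                   seed = child_seed(seed, 1),
                                   modulation_period =
                                     synth$modulation_period)
    cfg <- pipeline_config(seed = child_seed(seed, 1000 * r),
                           channels = "fused",
                           n_compounds = n_compounds,
                           class_effects = effect_subset(lib0, n_effect),
                           synth = synth)
    res <- run_pipeline(cfg)
    ch <- res$channels[["fused"]]
    effects <- cfg$class_effects
    effect_names <- names(effects)[abs(effects - 1) >= 0.5]
    null_names <- setdiff(names(res$library), effect_names)

    ## region-level gates
    regions <- ch$fingerprint$template$entries
    regions <- regions[regions$kind == "peak_region", c("id", "rt1", "rt2")]
    names(regions)[1] <- "id"
    mp <- map_features_to_compounds(regions, res$library, synth)
    kw <- ch$stats$kw; vip <- ch$stats$vip$vip
    passes <- function(nm) {
      fid <- mp$feature_id[mp$compound == nm]
      if (is.na(fid)) return(FALSE)
      sel <- kw$selected[kw$feature == fid]
      isTRUE(sel) && isTRUE(vip[fid] >= 1)
    }
    effect_hits <- vapply(effect_names, passes, logical(1))
    null_hits <- vapply(null_names, passes, logical(1))

    ## reliable-peak coverage
    rel <- ch$fingerprint$template$entries
    rel <- rel[rel$kind == "reliable_peak", c("id", "rt1", "rt2")]
    mp_rel <- map_features_to_compounds(rel, res$library, synth)
    rows[[r]] <- data.frame(
      replicate = r,
      effect_rate = mean(effect_hits),
      null_rate = mean(null_hits),
      reliable_fraction = mean(!is.na(mp_rel$feature_id)),
      n_regions = nrow(regions),
      n_reliable = nrow(rel))
  }
  out <- do.call(rbind, rows)
  attr(out, "means") <- colMeans(out[, c("effect_rate", "null_rate",
                                         "reliable_fraction")])
  out
}

#' Null calibration of the Kruskal-Wallis selection
#'
#' Simulates `n_features` null features (zero injected class effects)
#' over exchangeable runs drawn from the generator's abundance model --
#' one run per subject, 12 vs 20 runs, lognormal variability combining
#' the subject, process and analytical levels -- and reports the fraction
#' selected at `alpha`. Under a calibrated test this fraction lies within
#' the binomial sampling band around `alpha`.
#'
#' @param seed RNG seed.
#' @param n_features number of simulated null features.
#' @param n_group1,n_group2 runs per group.
#' @param synth a [synth_config()] (for the variability levels).
#' @param alpha selection level.
#' @return list with `rate`, `n_features`, `alpha`, and the 95 percent
#'   binomial interval `band`.
#' @export
run_null_calibration <- function(seed = 1, n_features = 1000,
                                 n_group1 = 12, n_group2 = 20,
                                 synth = synth_config(), alpha = 0.05) {
  set.seed(seed)
  n <- n_group1 + n_group2
  cv <- sqrt(synth$subject_cv^2 + synth$process_cv^2 +
             synth$analytical_cv^2)
  volumes <- matrix(exp(rnorm(n * n_features, 0, cv)), nrow = n)
  colnames(volumes) <- sprintf("f%04d", seq_len(n_features))
  groups <- rep(c("MHO", "MUO"), c(n_group1, n_group2))
  kw <- kw_dunn_bonferroni(volumes, groups, alpha = alpha)
  rate <- mean(kw$selected)
  band <- alpha + c(-1, 1) * 1.96 * sqrt(alpha * (1 - alpha) / n_features)
  list(rate = rate, n_features = n_features, alpha = alpha, band = band)
}

#' Channel-fusion benefit experiment
#'
#' Simulates one 48-run study in which a fraction of the compounds falls
#' below the 12 eV detection gate (suppressed 12 eV response factors) and
#' compares the reliable-peak counts of the three data streams. With
#' sub-threshold 12 eV responses the expected ordering is
#' fused >= 70 eV >= 12 eV.
#'
#' @param seed RNG seed.
#' @param weak_12_fraction fraction of compounds invisible at 12 eV.
#' @param n_compounds library size.
#' @param synth a [synth_config()].
#' @return list with per-channel `reliable` counts and mean detected-peak
#'   counts `detected`.
#' @export
run_fusion_benefit <- function(seed = 1, weak_12_fraction = 0.3,
                               n_compounds = 30,
                               synth = synth_config(mz_range = c(45, 244))) {
  cfg <- pipeline_config(seed = seed, channels = c("70eV", "12eV", "fused"),
                         n_compounds = n_compounds,
                         weak_12_fraction = weak_12_fraction,
                         synth = synth)
  res <- run_pipeline(cfg)
  list(
    reliable = vapply(res$channels, function(ch) {
      length(ch$fingerprint$reliable_ids)
    }, numeric(1)),
    detected = vapply(res$channels, function(ch) mean(ch$n_peaks),
                      numeric(1)))
}
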