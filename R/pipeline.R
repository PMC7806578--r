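## End-to-end pipeline: simulate -> fold/fuse -> background subtraction ->
## peak detection -> template alignment -> peak regions -> feature matrix
## -> statistics, independently for the 70 eV, 12 eV and fused streams.

#' Pipeline configuration
#'
#' All stage parameters with their defaults: S/N gate 100 expressed as the
#' per-channel absolute TIC count thresholds (500,000 / 5,000 / 100,000
#' counts for 70 eV / 12 eV / fused), template-match gates DMF/RMF 750,
#' identification gates DMF 900 / RMF 950 / RI +-10, selection alpha 0.05,
#' VIP gate 1. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults (see the returned list for the
#'   full set of keys). `synth` takes a [synth_config()]; `design_args`
#'   the arguments of [make_study_design()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    channels = c("70eV", "12eV", "fused"),
    n_compounds = 30,
    include_reference = TRUE,
    weak_12_fraction = 0,
    library_args = list(),
    class_effects = NULL,
    design_args = list(n_qc = 4, n_mho = 3, n_muo = 5, process_reps = 2,
                       analytical_reps = 2),
    synth = synth_config(),
    ball_radius = 15,
    min_counts = c("70eV" = 5e5, "12eV" = 5e3, "fused" = 1e5),
    min_snr = 5,
    match_dmf = 750, match_rmf = 750,
    window_1d = 0.125, window_2d = 0.15,
    n_refine = 1,
    id_dmf = 900, id_rmf = 950, ri_tol = 10,
    alpha = 0.05, vip_threshold = 1, n_pls_components = 2,
    contrast_unit = "subject",   # average technical replicates ("run" opt.)
    contrast_scale = "volume"    # raw aligned volumes ("percent" opt.)
  )
  args <- list(...)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) {
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, args)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Process one channel of one simulated run
#'
#' Folds (and for the fused stream, sums) the raw streams, computes the
#' TIC image, subtracts the rolling-ball background, estimates the noise,
#' detects peaks at the channel's gates and attaches apex spectra from the
#' raw cube.
#'
#' @param run a [simulate_run()] result.
#' @param channel `"70eV"`, `"12eV"` or `"fused"`.
#' @param config a [pipeline_config()].
#' @return list with `image` (background-subtracted [tic_image()]),
#'   `noise`, `peaks`.
#' @details The implementation computes the TIC image and the apex
#'   spectra directly from the raw stream (modulation-major scan order),
#'   which is arithmetically identical to folding the full cube first
#'   (`tic(fold(stream)) == stream` path; asserted by the test suite) but
#'   avoids materializing three cubes per run.
#' @export
process_run_channel <- function(run, channel, config) {
  stream <- switch(channel,
    "70eV" = run$stream_70,
    "12eV" = run$stream_12,
    "fused" = run$stream_70 + run$stream_12,
    stop("unknown channel: ", channel))
  P <- as.integer(round(run$meta$modulation_period *
                          run$meta$acquisition_rate))
  n1 <- nrow(stream) %/% P
  img <- tic_image(matrix(rowSums(stream), nrow = n1, ncol = P,
                          byrow = TRUE),
                   run$meta$modulation_period, run$meta$acquisition_rate,
                   channel = channel, run_id = run$meta$run_id)
  sub <- subtract_background(img, config$ball_radius)
  noise <- estimate_noise(sub)
  peaks <- detect_peaks(sub, min_counts = config$min_counts[[channel]],
                        min_snr = config$min_snr, noise = noise)
  peaks$spectrum <- lapply(seq_len(nrow(peaks)), function(i) {
    v <- stream[(peaks$apex_mod[i] - 1L) * P + peaks$apex_samp[i], ]
    keep <- v > 0
    if (!any(keep)) return(NULL)
    normalize_spectrum(spectrum(run$mz_axis[keep], v[keep]))
  })
  attr(sub, "background") <- NULL
  attr(sub, "residual") <- NULL
  list(image = sub, noise = noise, peaks = peaks)
}

#' Template alignment, peak regions and quantification for one channel
#'
#' Seeds the template from the run with the highest total TIC, matches all
#' runs (one transform-refinement pass), keeps reliable entries
#' ([select_reliable()]), builds the sum composite, delineates peak
#' regions at the composite-scaled gate and quantifies them across runs.
#'
#' @param images background-subtracted [tic_image()]s, one per run.
#' @param peaks_by_run matching `peak_list`s with spectra.
#' @param config a [pipeline_config()].
#' @param channel channel name (for the count gate).
#' @param run_meta data.frame of run metadata (e.g. the study design).
#' @return list with `template`, `transforms`, `match_counts`,
#'   `reliable_ids`, `composite`, `features` (a `feature_matrix`).
#' @export
fingerprint_channel <- function(images, peaks_by_run, config, channel,
                                run_meta = NULL) {
  n_runs <- length(images)
  totals <- vapply(images, function(x) sum(x$image), numeric(1))
  seed_run <- which.max(totals)
  grid <- list(modulation_period = images[[seed_run]]$modulation_period,
               acquisition_rate = images[[seed_run]]$acquisition_rate,
               n1 = nrow(images[[seed_run]]$image),
               n2 = ncol(images[[seed_run]]$image))
  template <- template_from_peaks(peaks_by_run[[seed_run]], grid)
  al <- align_runs(template, peaks_by_run,
                   window_1d = config$window_1d, window_2d = config$window_2d,
                   min_dmf = config$match_dmf, min_rmf = config$match_rmf,
                   n_refine = config$n_refine)
  template <- al$template
  reliable_ids <- select_reliable(al$match_counts, n_runs)
  keep <- template$entries$id %in% reliable_ids
  template$entries <- template$entries[keep, , drop = FALSE]
  composite <- build_composite(images, al$transforms, mode = "sum")
  noise_c <- estimate_noise(composite$image)
  regions <- delineate_regions(composite,
                               min_counts = config$min_counts[[channel]] *
                                 n_runs,
                               min_snr = config$min_snr, noise = noise_c)
  template <- add_regions(template, regions)
  features <- quantify_features(images, template, al$transforms,
                                run_meta = run_meta)
  list(template = template, transforms = al$transforms,
       match_counts = al$match_counts, reliable_ids = reliable_ids,
       composite = composite, features = features)
}

#' Class-discriminant statistics for one channel
#'
#' Percent-response normalization and PCA over all runs (QCs included),
#' and the MUO-vs-MHO contrast (QC runs excluded): Kruskal-Wallis
#' selection at `alpha` and PLS-DA VIP scores. By default the contrast is
#' computed on subject-aggregated raw volumes: process/analytical
#' replicates of one subject are technical replicates, so they are
#' averaged before group testing (`contrast_unit = "run"` uses runs
#' directly), and raw aligned volumes avoid the compositional closure
#' that percent responses suffer on small feature panels
#' (`contrast_scale = "percent"` restores percent responses).
#'
#' @param features a `feature_matrix` whose `runs` carry `group` and
#'   `subject_id` columns.
#' @param config a [pipeline_config()].
#' @return list with `percent`, `pca`, `kw`, `vip`, `contrast_units`.
#' @export
channel_statistics <- function(features, config) {
  pr <- percent_response(features)
  pca <- if (ncol(pr$volumes) >= 2) pca_features(pr) else NULL
  contrast <- features$runs$group %in% c("MHO", "MUO")
  kw <- NULL; vip <- NULL; units <- NULL
  if (sum(contrast) >= 4 && ncol(features$volumes) >= 1 &&
      length(unique(features$runs$group[contrast])) == 2) {
    m <- if (identical(config$contrast_scale, "percent")) {
      pr$volumes[contrast, , drop = FALSE]
    } else {
      features$volumes[contrast, , drop = FALSE]
    }
    g <- features$runs$group[contrast]
    if (identical(config$contrast_unit, "subject") &&
        !is.null(features$runs$subject_id)) {
      subj <- features$runs$subject_id[contrast]
      m <- rowsum(m, subj) / as.vector(table(subj)[sort(unique(subj))])
      g <- features$runs$group[contrast][match(rownames(m), subj)]
      units <- rownames(m)
    } else {
      units <- features$runs$run_id[contrast]
    }
    kw <- kw_dunn_bonferroni(m, g, alpha = config$alpha)
    vip <- tryCatch(
      plsda_vip(m, g, n_components = config$n_pls_components),
      error = function(e) NULL)
  }
  list(percent = pr, pca = pca, kw = kw, vip = vip,
       contrast_units = units)
}

#' Run the full untargeted fingerprinting pipeline on synthetic data
#'
#' Simulates the configured study (one dual-energy run per design row) and
#' processes the requested data streams independently (70 eV, 12 eV,
#' fused), each through background subtraction, peak detection, template
#' alignment with reliable-peak selection, composite peak-region
#' delineation, quantification, and statistics. Deterministic given
#' `(config, seed)`.
#'
#' @param config a [pipeline_config()].
#' @return manifest list: `config`, `library`, `design`, `truth` (per-run
#'   ground-truth tables) and per-channel results (`fingerprint`,
#'   `stats`, `n_peaks`, `noise_levels`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  synth <- config$synth
  if (!is.null(config$class_effects)) {
    synth$class_effects <- config$class_effects
  }
  library <- do.call(build_spectral_library, c(
    list(config$n_compounds, seed = child_seed(seed, 1),
         include_reference = config$include_reference,
         weak_12_fraction = config$weak_12_fraction,
         modulation_period = synth$modulation_period),
    config$library_args))
  design <- do.call(make_study_design, config$design_args)
  ab <- draw_abundances(design, library, synth,
                        seed = child_seed(seed, 2))
  n_runs <- nrow(design)
  channels <- config$channels
  images <- setNames(lapply(channels, function(ch) vector("list", n_runs)),
                     channels)
  peaks <- images
  noise_levels <- setNames(lapply(channels, function(ch) numeric(n_runs)),
                           channels)
  truth <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    run <- simulate_run(design[i, ], library, ab[i, ], synth,
                        seed = child_seed(seed, 100 + i))
    truth[[i]] <- run$truth
    for (ch in channels) {
      pc <- process_run_channel(run, ch, config)
      images[[ch]][[i]] <- pc$image
      peaks[[ch]][[i]] <- pc$peaks
      noise_levels[[ch]][i] <- pc$noise$level
    }
  }
  names(truth) <- design$run_id
  out <- list(config = config, library = library, design = design,
              truth = truth, channels = list())
  for (ch in channels) {
    fp <- fingerprint_channel(images[[ch]], peaks[[ch]], config, ch,
                              run_meta = design)
    st <- channel_statistics(fp$features, config)
    out$channels[[ch]] <- list(
      fingerprint = fp, stats = st,
      n_peaks = vapply(peaks[[ch]], nrow, integer(1)),
      noise_levels = noise_levels[[ch]])
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", nrow(x$design), "runs,", length(x$library),
      "compounds\n")
  for (ch in names(x$channels)) {
    cc <- x$channels[[ch]]
    cat(sprintf(
      "  %-5s: %3d reliable peaks, %3d peak regions, %s selected at alpha\n",
      ch, length(cc$fingerprint$reliable_ids),
      sum(cc$fingerprint$template$entries$kind == "peak_region"),
      if (is.null(cc$stats$kw)) "NA" else sum(cc$stats$kw$selected)))
  }
  invisible(x)
}
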