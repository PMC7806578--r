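## Untargeted fingerprinting: template matching across chromatograms,
## reliable-peak selection, retention-transform fitting, composite images,
## peak-region delineation and cross-sample quantification.

#' Seed a template from the peaks of one run
#'
#' @param peaks a `peak_list` with spectra attached
#'   ([add_peak_spectra()]).
#' @param grid list with `modulation_period`, `acquisition_rate`, `n1`,
#'   `n2` (template pixel grid); taken from the seeding image.
#' @return object of class `gc_template`: data.frame `entries` with
#'   columns `id`, `rt1`, `rt2`, `kind` and list columns `spectrum`,
#'   `polygon`, plus the grid.
#' @export
template_from_peaks <- function(peaks, grid) {
  entries <- data.frame(id = sprintf("RP%03d", peaks$peak_id),
                        rt1 = peaks$rt1, rt2 = peaks$rt2,
                        kind = rep("reliable_peak", nrow(peaks)),
                        stringsAsFactors = FALSE)
  entries$spectrum <- peaks$spectrum
  entries$polygon <- rep(list(NULL), nrow(entries))
  structure(list(entries = entries, grid = grid), class = "gc_template")
}

#' @export
print.gc_template <- function(x, ...) {
  cat("<gc_template>", nrow(x$entries), "entries (",
      sum(x$entries$kind == "reliable_peak"), "reliable peaks,",
      sum(x$entries$kind == "peak_region"), "peak regions )\n")
  invisible(x)
}

#' Match template entries to the peaks of one run
#'
#' Candidates are restricted to a retention window around the (optionally
#' transform-corrected) expected position; a candidate is eligible iff both
#' the direct and the reverse match factor between template and peak
#' spectrum reach their thresholds. Eligible pairs are assigned one-to-one
#' greedily in descending DMF order, ties broken by the nearest Euclidean
#' retention distance.
#'
#' @param template a `gc_template`.
#' @param peaks a `peak_list` with spectra.
#' @param window_1d,window_2d half-widths of the retention window (min, s).
#'   The defaults cover about three sigma of typical run-to-run jitter
#'   (0.20% 1D / 1.90% 2D RSD).
#' @param min_dmf,min_rmf spectral-similarity gates in `[0, 999]`.
#' @param transform optional [fit_transform()] result mapping template
#'   retention times into this run's retention times.
#' @return data.frame with one row per matched entry: `entry_id`,
#'   `peak_id`, `dmf`, `rmf`, template and run retention times.
#' @export
match_template <- function(template, peaks, window_1d = 0.125,
                           window_2d = 0.15, min_dmf = 750, min_rmf = 750,
                           transform = NULL) {
  if (window_1d <= 0 || window_2d <= 0) stop("windows must be > 0")
  if (min_dmf < 0 || min_dmf > 999 || min_rmf < 0 || min_rmf > 999) {
    stop("match-factor thresholds must lie in [0, 999]")
  }
  ent <- template$entries[template$entries$kind == "reliable_peak", ,
                          drop = FALSE]
  empty <- data.frame(entry_id = character(), peak_id = integer(),
                      dmf = integer(), rmf = integer(),
                      tmpl_rt1 = numeric(), tmpl_rt2 = numeric(),
                      run_rt1 = numeric(), run_rt2 = numeric())
  if (!nrow(ent) || !nrow(peaks)) return(empty)
  exp1 <- ent$rt1; exp2 <- ent$rt2
  if (!is.null(transform)) {
    pred <- predict_transform(transform, ent$rt1, ent$rt2)
    exp1 <- pred$rt1; exp2 <- pred$rt2
  }
  cand <- list()
  for (e in seq_len(nrow(ent))) {
    sel <- which(abs(peaks$rt1 - exp1[e]) <= window_1d &
                 abs(peaks$rt2 - exp2[e]) <= window_2d)
    for (p in sel) {
      dmf <- direct_match_factor(peaks$spectrum[[p]], ent$spectrum[[e]])
      if (dmf < min_dmf) next
      rmf <- reverse_match_factor(peaks$spectrum[[p]], ent$spectrum[[e]])
      if (rmf < min_rmf) next
      cand[[length(cand) + 1L]] <- data.frame(
        e = e, p = p, dmf = dmf, rmf = rmf,
        dist = sqrt((peaks$rt1[p] - exp1[e])^2 +
                    (peaks$rt2[p] - exp2[e])^2))
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$dmf, cand$dist), , drop = FALSE]
  used_e <- logical(nrow(ent)); used_p <- logical(nrow(peaks))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    e <- cand$e[i]; p <- cand$p[i]
    if (!used_e[e] && !used_p[p]) {
      keep[i] <- TRUE; used_e[e] <- TRUE; used_p[p] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(entry_id = ent$id[cand$e], peak_id = peaks$peak_id[cand$p],
             dmf = cand$dmf, rmf = cand$rmf,
             tmpl_rt1 = ent$rt1[cand$e], tmpl_rt2 = ent$rt2[cand$e],
             run_rt1 = peaks$rt1[cand$p], run_rt2 = peaks$rt2[cand$p],
             row.names = NULL)
}

#' Reliable-entry selection rule
#'
#' Keeps entries positively matched across more than half of the
#' chromatograms of the set: `count >= floor(n_runs / 2) + 1` (25 of 48).
#'
#' @param match_counts named per-entry match counts.
#' @param n_runs number of chromatograms in the set (>= 1).
#' @return names of the qualifying entries.
#' @export
select_reliable <- function(match_counts, n_runs) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  names(match_counts)[match_counts >= reliable_threshold(n_runs)]
}

#' @rdname select_reliable
#' @export
reliable_threshold <- function(n_runs) {
  floor(n_runs / 2) + 1
}

#' Fit the per-dimension affine retention transform
#'
#' Least-squares affine fit, independently per dimension, of run retention
#' times against template retention times.
#'
#' @param pairs data.frame with `tmpl_rt1`, `tmpl_rt2`, `run_rt1`,
#'   `run_rt2` (as returned by [match_template()]); needs >= 3 pairs with
#'   retention spread in both dimensions.
#' @return object of class `rt_transform`: `a1, b1, a2, b2` with
#'   `run_rt = a * tmpl_rt + b`, plus RMS residuals `rms1`, `rms2`.
#' @export
fit_transform <- function(pairs) {
  if (nrow(pairs) < 3) {
    stop("need >= 3 matched pairs to fit a transform, got ", nrow(pairs))
  }
  if (var(pairs$tmpl_rt1) <= 0 || var(pairs$tmpl_rt2) <= 0) {
    stop("degenerate geometry: matched pairs do not span both dimensions")
  }
  f1 <- lm(run_rt1 ~ tmpl_rt1, data = pairs)
  f2 <- lm(run_rt2 ~ tmpl_rt2, data = pairs)
  structure(list(a1 = unname(coef(f1)[2]), b1 = unname(coef(f1)[1]),
                 a2 = unname(coef(f2)[2]), b2 = unname(coef(f2)[1]),
                 rms1 = sqrt(mean(f1$residuals^2)),
                 rms2 = sqrt(mean(f2$residuals^2)),
                 n = nrow(pairs)),
            class = "rt_transform")
}

#' @export
print.rt_transform <- function(x, ...) {
  cat(sprintf("<rt_transform> rt1' = %.5f rt1 %+.4f (rms %.4g);", x$a1,
              x$b1, x$rms1),
      sprintf("rt2' = %.5f rt2 %+.4f (rms %.4g); n = %d\n", x$a2, x$b2,
              x$rms2, x$n))
  invisible(x)
}

#' Identity retention transform
#' @return an `rt_transform` mapping every retention time to itself.
#' @export
identity_transform <- function() {
  structure(list(a1 = 1, b1 = 0, a2 = 1, b2 = 0, rms1 = 0, rms2 = 0,
                 n = 0L), class = "rt_transform")
}

#' Apply / invert a retention transform
#'
#' @param transform an `rt_transform`.
#' @param rt1,rt2 template-space retention times.
#' @return list with transformed `rt1`, `rt2`.
#' @export
predict_transform <- function(transform, rt1, rt2) {
  list(rt1 = transform$a1 * rt1 + transform$b1,
       rt2 = transform$a2 * rt2 + transform$b2)
}

#' @rdname predict_transform
#' @export
invert_transform <- function(transform) {
  if (transform$a1 == 0 || transform$a2 == 0) {
    stop("transform is not invertible (zero scale)")
  }
  structure(list(a1 = 1 / transform$a1, b1 = -transform$b1 / transform$a1,
                 a2 = 1 / transform$a2, b2 = -transform$b2 / transform$a2,
                 rms1 = transform$rms1, rms2 = transform$rms2,
                 n = transform$n), class = "rt_transform")
}

## Bilinear sampling of image M at fractional (mod, samp) coordinates.
## Coordinates outside the grid sample as 0.
#' @noRd
bilinear_sample <- function(M, mod, samp) {
  n1 <- nrow(M); n2 <- ncol(M)
  i0 <- floor(mod); j0 <- floor(samp)
  di <- mod - i0; dj <- samp - j0
  val <- function(i, j) {
    ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2
    out <- numeric(length(i))
    out[ok] <- M[cbind(i[ok], j[ok])]
    out
  }
  val(i0, j0) * (1 - di) * (1 - dj) +
    val(i0 + 1, j0) * di * (1 - dj) +
    val(i0, j0 + 1) * (1 - di) * dj +
    val(i0 + 1, j0 + 1) * di * dj
}

#' Build a composite chromatogram from aligned runs
#'
#' Each run's TIC image is resampled into template space (bilinear
#' interpolation at the forward-transformed pixel coordinates) and the
#' resampled images are accumulated pixel-wise.
#'
#' @param images list of [tic_image()]s (all on the same grid).
#' @param transforms list of `rt_transform`s, one per run (template ->
#'   run).
#' @param mode `"sum"` (composite chromatogram) or `"mean"` (class
#'   composites).
#' @return a [tic_image()] in template space.
#' @export
build_composite <- function(images, transforms, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (!length(images)) stop("no images to composite")
  dims <- lapply(images, function(x) dim(x$image))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1) {
    stop("images do not share a common grid")
  }
  ref <- images[[1]]
  n1 <- nrow(ref$image); n2 <- ncol(ref$image)
  grid_mod <- matrix(seq_len(n1), n1, n2)
  grid_samp <- matrix(rep(seq_len(n2), each = n1), n1, n2)
  rt1 <- mod_to_rt1(grid_mod, ref$modulation_period)
  rt2 <- samp_to_rt2(grid_samp, ref$acquisition_rate)
  acc <- matrix(0, n1, n2)
  for (r in seq_along(images)) {
    tf <- transforms[[r]]
    pred <- predict_transform(tf, rt1, rt2)
    m <- rt1_to_mod(pred$rt1, ref$modulation_period)
    s <- rt2_to_samp(pred$rt2, ref$acquisition_rate)
    acc <- acc + bilinear_sample(images[[r]]$image, m, s)
  }
  if (mode == "mean") acc <- acc / length(images)
  tic_image(acc, ref$modulation_period, ref$acquisition_rate,
            channel = ref$channel, run_id = paste0("composite_", mode))
}

#' Delineate untargeted peak regions on a composite chromatogram
#'
#' Runs [detect_peaks()] on the composite; every surviving peak's watershed
#' footprint becomes a peak-region polygon. Regions are disjoint by
#' construction (watershed partition).
#'
#' @param composite a composite [tic_image()].
#' @param min_counts absolute response gate on the composite (for a sum
#'   composite of N runs, N x the per-run gate).
#' @param min_snr,noise,h,floor passed to [detect_peaks()].
#' @return data.frame of template entries (`kind = "peak_region"`) with
#'   list column `polygon` (linear pixel indices in template space).
#' @export
delineate_regions <- function(composite, min_counts = 0, min_snr = 0,
                              noise = NULL, h = NULL, floor = NULL) {
  pk <- detect_peaks(composite, min_counts = min_counts, min_snr = min_snr,
                     noise = noise, h = h, floor = floor)
  entries <- data.frame(id = sprintf("PR%03d", pk$peak_id),
                        rt1 = pk$rt1, rt2 = pk$rt2,
                        kind = rep("peak_region", nrow(pk)),
                        stringsAsFactors = FALSE)
  entries$spectrum <- rep(list(NULL), nrow(entries))
  entries$polygon <- pk$footprint
  entries
}

#' Add peak-region entries to a template
#'
#' @param template a `gc_template`.
#' @param regions the result of [delineate_regions()].
#' @return the extended `gc_template`.
#' @export
add_regions <- function(template, regions) {
  template$entries <- rbind(template$entries, regions)
  template
}

#' Quantify aligned peak regions across runs
#'
#' For every run, each region polygon is mapped into run space through the
#' run's retention transform and integrated on the run's
#' background-subtracted TIC image (bilinear sampling at the transformed
#' pixel centres; the affine scale is ~1 so the sum approximates the
#' volume integral). Regions mapped outside the image contribute 0 with a
#' warning.
#'
#' @param images list of background-subtracted [tic_image()]s, one per run.
#' @param template a `gc_template` containing peak-region entries.
#' @param transforms list of `rt_transform`s (template -> run), one per
#'   run.
#' @param run_meta optional data.frame with one row per run (`run_id`,
#'   `group`, ...).
#' @return object of class `feature_matrix`: list with `volumes`
#'   (`[run, region]` matrix), `runs` (metadata data.frame) and `features`
#'   (region id + template retention times).
#' @export
quantify_features <- function(images, template, transforms,
                              run_meta = NULL) {
  ent <- template$entries[template$entries$kind == "peak_region", ,
                          drop = FALSE]
  ref <- images[[1]]
  n1 <- nrow(ref$image)
  vols <- matrix(0, nrow = length(images), ncol = nrow(ent),
                 dimnames = list(vapply(images, `[[`, character(1),
                                        "run_id"),
                                 ent$id))
  for (g in seq_len(nrow(ent))) {
    px <- ent$polygon[[g]]
    pm <- ((px - 1) %% n1) + 1
    ps <- ((px - 1) %/% n1) + 1
    rt1 <- mod_to_rt1(pm, ref$modulation_period)
    rt2 <- samp_to_rt2(ps, ref$acquisition_rate)
    for (r in seq_along(images)) {
      pred <- predict_transform(transforms[[r]], rt1, rt2)
      m <- rt1_to_mod(pred$rt1, ref$modulation_period)
      s <- rt2_to_samp(pred$rt2, ref$acquisition_rate)
      inside <- m >= 1 & m <= nrow(images[[r]]$image) &
        s >= 1 & s <= ncol(images[[r]]$image)
      if (!all(inside)) {
        warning("region ", ent$id[g], " maps partly outside run ",
                images[[r]]$run_id, call. = FALSE)
      }
      vols[r, g] <- max(sum(bilinear_sample(images[[r]]$image, m, s)), 0)
    }
  }
  if (is.null(run_meta)) {
    run_meta <- data.frame(run_id = rownames(vols))
  }
  structure(list(volumes = vols, runs = run_meta,
                 features = ent[, c("id", "rt1", "rt2")]),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$volumes), "runs x", ncol(x$volumes),
      "features",
      if (isTRUE(attr(x, "percent"))) "(% response)\n" else "(TIC volumes)\n")
  invisible(x)
}

#' Align a set of runs against a seed template
#'
#' One matching pass at the identity transform, a per-run affine fit on
#' the matched pairs, and `n_refine` re-matching passes using the fitted
#' transforms (iterative template refinement). With `augment = TRUE`
#' (default) the template is then grown: peaks left unmatched in a run
#' are mapped back into template space through the inverse transform and
#' added as new entries unless an entry with a similar spectrum already
#' sits within the retention window (this recovers compounds that the
#' seeding run missed, e.g. because they co-eluted or fell below its
#' gates there). A final matching pass over the grown template produces
#' the per-entry match counts.
#'
#' @param template seed `gc_template` (see [template_from_peaks()]).
#' @param peaks_by_run list of `peak_list`s with spectra.
#' @param window_1d,window_2d,min_dmf,min_rmf see [match_template()].
#' @param n_refine number of re-match passes after transform fitting.
#' @param augment grow the template with unmatched peaks.
#' @return list with `template` (possibly grown), `matches` (per run),
#'   `transforms` (per run) and `match_counts` (named per-entry counts
#'   across runs).
#' @export
align_runs <- function(template, peaks_by_run, window_1d = 0.125,
                       window_2d = 0.15, min_dmf = 750, min_rmf = 750,
                       n_refine = 1, augment = TRUE) {
  n_runs <- length(peaks_by_run)
  matches <- vector("list", n_runs)
  transforms <- rep(list(identity_transform()), n_runs)
  match_pass <- function(r, tmpl) {
    match_template(tmpl, peaks_by_run[[r]], window_1d, window_2d,
                   min_dmf, min_rmf,
                   transform = transforms[[r]])
  }
  for (r in seq_len(n_runs)) {
    m <- match_template(template, peaks_by_run[[r]], window_1d, window_2d,
                        min_dmf, min_rmf)
    for (it in seq_len(n_refine)) {
      tf <- tryCatch(fit_transform(m), error = function(e) NULL)
      if (is.null(tf)) break
      transforms[[r]] <- tf
      m <- match_pass(r, template)
    }
    matches[[r]] <- m
  }
  if (augment) {
    next_id <- nrow(template$entries) + 1L
    for (r in seq_len(n_runs)) {
      pk <- peaks_by_run[[r]]
      un <- setdiff(pk$peak_id, matches[[r]]$peak_id)
      if (!length(un)) next
      inv <- invert_transform(transforms[[r]])
      ent <- template$entries
      for (pid in un) {
        i <- which(pk$peak_id == pid)
        spec <- pk$spectrum[[i]]
        if (is.null(spec)) next
        back <- predict_transform(inv, pk$rt1[i], pk$rt2[i])
        near <- which(abs(ent$rt1 - back$rt1) <= window_1d &
                      abs(ent$rt2 - back$rt2) <= window_2d)
        dup <- FALSE
        for (e in near) {
          if (!is.null(ent$spectrum[[e]]) &&
              direct_match_factor(spec, ent$spectrum[[e]]) >= min_dmf) {
            dup <- TRUE
            break
          }
        }
        if (dup) next
        new <- data.frame(id = sprintf("RP%03d", next_id),
                          rt1 = back$rt1, rt2 = back$rt2,
                          kind = "reliable_peak", stringsAsFactors = FALSE)
        new$spectrum <- list(spec)
        new$polygon <- list(NULL)
        template$entries <- rbind(template$entries, new)
        ent <- template$entries
        next_id <- next_id + 1L
      }
    }
    for (r in seq_len(n_runs)) {
      matches[[r]] <- match_pass(r, template)
    }
  }
  ids <- template$entries$id[template$entries$kind == "reliable_peak"]
  counts <- setNames(integer(length(ids)), ids)
  for (m in matches) {
    counts[m$entry_id] <- counts[m$entry_id] + 1L
  }
  list(template = template, matches = matches, transforms = transforms,
       match_counts = counts)
}

#' Serialize a template to JSON
#'
#' @param template a `gc_template`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path) {
  ent <- template$entries
  payload <- list(
    grid = template$grid,
    entries = lapply(seq_len(nrow(ent)), function(i) {
      list(id = ent$id[i], rt1 = ent$rt1[i], rt2 = ent$rt2[i],
           kind = ent$kind[i],
           spectrum = if (!is.null(ent$spectrum[[i]])) {
             list(mz = ent$spectrum[[i]]$mz,
                  intensity = ent$spectrum[[i]]$intensity)
           },
           polygon = ent$polygon[[i]])
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
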