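## Background handling and tandem-channel fusion.
##
## Greyscale morphology is implemented here as separable running min/max
## filters with a flat square structuring element and replicate padding
## (EBImage's erode/dilate are binary-only).

#' @noRd
filter_rows <- function(m, r, fun) {
  n <- nrow(m)
  out <- m
  for (d in seq_len(r)) {
    up <- m[c(rep(1L, d), seq_len(n - d)), , drop = FALSE]
    dn <- m[c(seq_len(n - d) + d, rep(n, d)), , drop = FALSE]
    out <- fun(out, up, dn)
  }
  out
}

#' @noRd
filter_cols <- function(m, r, fun) {
  t(filter_rows(t(m), r, fun))
}

#' Greyscale erosion/dilation with a flat square element of half-width r
#' @noRd
erode_gray <- function(m, r) filter_cols(filter_rows(m, r, pmin), r, pmin)

#' @noRd
dilate_gray <- function(m, r) filter_cols(filter_rows(m, r, pmax), r, pmax)

#' Rolling-ball background subtraction of a TIC image
#'
#' Estimates the structured background (column bleed, baseline drift) as
#' the greyscale morphological opening of the TIC image -- a rolling ball
#' with a flat top: erosion followed by dilation with a flat square
#' structuring element of half-width `ball_radius` -- and subtracts it.
#' The opening is everywhere less than or equal to the input, so the
#' residual is non-negative before the pedestal correction; remaining
#' negative values are clipped to 0. Features narrower than the element
#' (2D peaks) are preserved; smooth ramps and flat offsets are removed.
#'
#' @param image a [tic_image()].
#' @param ball_radius structuring-element half-width in pixels (>= 1).
#'   The default, 15, is five times the expected second-dimension peak
#'   width (sigma ~ 0.05 s at 50 Hz ~ 3 px).
#' @return A [tic_image()] with the background removed. The estimated
#'   background is attached as `attr(, "background")` and the unclipped
#'   residual as `attr(, "residual")` (used for noise estimation, where the
#'   symmetric negative lobe of the noise matters).
#' @note On a monotone baseline the outermost `ball_radius` pixels of the
#'   image retain a boundary bias (an opening cannot reconstruct a ramp
#'   beyond the data edge); keep analytes away from the very start and end
#'   of the run.
#' @export
subtract_background <- function(image, ball_radius = 15) {
  stopifnot(inherits(image, "tic_image"))
  if (ball_radius < 1) stop("ball_radius must be >= 1")
  img <- image$image
  if (2 * ball_radius + 1 > max(dim(img))) {
    stop("ball_radius ", ball_radius, " exceeds the image extent ",
         paste(dim(img), collapse = "x"))
  }
  r <- as.integer(ball_radius)
  bg <- dilate_gray(erode_gray(img, r), r)
  residual <- img - bg
  ## pedestal correction: the erosion step of the opening rides ~2 noise
  ## standard deviations below the baseline on noisy images; re-centre the
  ## background pixels of the residual at zero
  med <- stats::median(residual)
  bg <- bg + med
  residual <- residual - med
  out <- image
  out$image <- pmax(residual, 0)
  attr(out, "background") <- bg
  attr(out, "residual") <- residual
  out
}

#' Robust background-noise estimate of a TIC image
#'
#' Median-absolute-deviation scale (x 1.4826) of the background pixels.
#' Intended for use on the unclipped residual of [subtract_background()]
#' (attached there as `attr(, "residual")`), where background pixels are
#' symmetric about zero, or on any signal-free image.
#'
#' @param image a [tic_image()] or a numeric matrix.
#' @param exclusion_mask optional logical matrix, `TRUE` for pixels to
#'   exclude (signal areas).
#' @return list with `level` (counts, >= 0) and `method`, class
#'   `noise_estimate`.
#' @export
estimate_noise <- function(image, exclusion_mask = NULL) {
  img <- if (inherits(image, "tic_image")) {
    r <- attr(image, "residual")
    if (is.null(r)) image$image else r
  } else {
    image
  }
  px <- if (is.null(exclusion_mask)) as.numeric(img) else img[!exclusion_mask]
  if (length(px) == 0) stop("all pixels are masked; cannot estimate noise")
  if (length(px) < 100) {
    stop("need >= 100 background pixels to estimate noise, got ", length(px))
  }
  structure(list(level = stats::mad(px), method = "mad"),
            class = "noise_estimate")
}

#' Convert a signal-to-noise gate to an absolute TIC count threshold
#'
#' `counts = snr * noise$level`. With the channel noise levels of a
#' dual-energy acquisition this reproduces the usual per-channel absolute
#' response thresholds (e.g. S/N 100 with 5,000-count noise on the 70 eV
#' channel gives 500,000 counts).
#'
#' @param snr signal-to-noise ratio (> 0).
#' @param noise a `noise_estimate` (or a bare number of counts).
#' @return counts.
#' @export
snr_threshold_to_counts <- function(snr, noise) {
  if (snr <= 0) stop("snr must be > 0")
  level <- if (is.list(noise)) noise$level else noise
  snr * level
}

#' Fuse the two tandem-ionization data streams of one run
#'
#' Voxel-wise sum of the 70 eV and 12 eV cubes of the same run: no
#' rescaling, so `total(fused) = total(70 eV) + total(12 eV)` exactly.
#'
#' @param chan70,chan12 [chromatogram2d()] objects on identical grids
#'   (same m/z axis, modulation period, acquisition rate, run id).
#' @return A [chromatogram2d()] with `channel = "fused"`.
#' @export
fuse_channels <- function(chan70, chan12) {
  stopifnot(inherits(chan70, "chromatogram2d"),
            inherits(chan12, "chromatogram2d"))
  if (!identical(dim(chan70$cube), dim(chan12$cube))) {
    stop("cube dimensions differ: ", paste(dim(chan70$cube), collapse = "x"),
         " vs ", paste(dim(chan12$cube), collapse = "x"))
  }
  if (!identical(chan70$mz_axis, chan12$mz_axis)) {
    stop("m/z axes differ between channels")
  }
  if (chan70$modulation_period != chan12$modulation_period) {
    stop("modulation periods differ between channels")
  }
  if (chan70$acquisition_rate != chan12$acquisition_rate) {
    stop("acquisition rates differ between channels")
  }
  if (!identical(chan70$run_id, chan12$run_id)) {
    stop("run ids differ: ", chan70$run_id, " vs ", chan12$run_id)
  }
  chromatogram2d(chan70$cube + chan12$cube, chan70$mz_axis,
                 chan70$modulation_period, chan70$acquisition_rate,
                 channel = "fused", run_id = chan70$run_id)
}
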