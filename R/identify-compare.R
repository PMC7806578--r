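## Retention-index computation, library identification with spectral and
## RI gates, class composites and fuzzy-ratio comparative rendering.

#' Retention-index calibration from an n-alkane ladder
#'
#' @param carbons alkane carbon numbers (unique; >= 2).
#' @param rt1 first-dimension retention times (min), strictly increasing
#'   with carbon number.
#' @return object of class `ri_calibration`.
#' @export
ri_calibration <- function(carbons, rt1) {
  if (length(carbons) != length(rt1)) stop("carbons/rt1 length mismatch")
  if (length(carbons) < 2) stop("RI calibration needs >= 2 alkanes")
  o <- order(carbons)
  carbons <- carbons[o]; rt1 <- rt1[o]
  if (anyDuplicated(carbons)) stop("duplicate carbon numbers")
  if (any(diff(rt1) <= 0)) {
    stop("alkane retention times must increase strictly with carbon number")
  }
  structure(list(carbons = carbons, rt1 = rt1), class = "ri_calibration")
}

#' Linear (temperature-programmed) retention index
#'
#' Van den Dool-Kratz linear interpolation between bracketing alkanes:
#' `I = 100 n + 100 (rt - t_n) / (t_(n+1) - t_n)`. Only the
#' first-dimension retention time enters. Values outside the ladder are
#' linearly extrapolated and flagged with a warning.
#'
#' @param rt1 first-dimension retention time(s), minutes.
#' @param calib an [ri_calibration()].
#' @return retention index (same length as `rt1`), strictly increasing in
#'   `rt1`.
#' @export
retention_index <- function(rt1, calib) {
  stopifnot(inherits(calib, "ri_calibration"))
  outside <- rt1 < min(calib$rt1) | rt1 > max(calib$rt1)
  if (any(outside)) {
    warning(sum(outside), " retention time(s) outside the alkane ladder; ",
            "linearly extrapolated", call. = FALSE)
  }
  ## linear interpolation on (rt, 100*carbon); linear extrapolation from
  ## the terminal segments
  x <- calib$rt1; y <- 100 * calib$carbons
  inner <- approx(x, y, xout = pmin(pmax(rt1, min(x)), max(x)))$y
  lo <- rt1 < min(x); hi <- rt1 > max(x)
  s1 <- (y[2] - y[1]) / (x[2] - x[1])
  n <- length(x)
  s2 <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  inner[lo] <- y[1] + s1 * (rt1[lo] - x[1])
  inner[hi] <- y[n] + s2 * (rt1[hi] - x[n])
  inner
}

#' Identify a peak against a spectral library
#'
#' Candidates are ranked by direct match factor; a candidate is accepted
#' iff `dmf >= min_dmf`, `rmf >= min_rmf` (boundary inclusive) and
#' `|ri_exp - ri_lib| <= ri_tol`. Matching uses the 70 eV library spectra
#' by default (identification channel).
#'
#' @param peak_spec the peak's apex [spectrum()].
#' @param ri_exp experimental retention index of the peak.
#' @param library a [build_spectral_library()] (any `spectral_library`).
#' @param min_dmf,min_rmf,ri_tol acceptance gates.
#' @param channel which library spectra to match: `"70eV"` or `"12eV"`.
#' @return data.frame with `compound`, `dmf`, `rmf`, `ri_lib`,
#'   `delta_ri`, `accepted`, sorted by `dmf` descending.
#' @export
identify_compound <- function(peak_spec, ri_exp, library, min_dmf = 900,
                              min_rmf = 950, ri_tol = 10,
                              channel = c("70eV", "12eV")) {
  if (!length(library)) stop("spectral library is empty")
  channel <- match.arg(channel)
  field <- if (channel == "70eV") "spectrum_70" else "spectrum_12"
  dmf <- integer(length(library)); rmf <- integer(length(library))
  for (k in seq_along(library)) {
    ref <- library[[k]][[field]]
    dmf[k] <- direct_match_factor(peak_spec, ref)
    rmf[k] <- reverse_match_factor(peak_spec, ref)
  }
  ri_lib <- vapply(library, `[[`, numeric(1), "ri")
  out <- data.frame(compound = names(library), dmf = dmf, rmf = rmf,
                    ri_lib = ri_lib, delta_ri = ri_exp - ri_lib,
                    row.names = NULL)
  out$accepted <- out$dmf >= min_dmf & out$rmf >= min_rmf &
    abs(out$delta_ri) <= ri_tol
  out[order(-out$dmf), , drop = FALSE]
}

#' Composite image of a sample class
#'
#' Aligned accumulation (sum or mean) of the runs of one class; see
#' [build_composite()].
#'
#' @param images list of [tic_image()]s of the class (>= 1).
#' @param transforms matching list of `rt_transform`s.
#' @param mode `"sum"` or `"mean"`.
#' @return a [tic_image()].
#' @export
class_composite <- function(images, transforms, mode = c("sum", "mean")) {
  if (!length(images)) stop("class is empty")
  build_composite(images, transforms, mode = match.arg(mode))
}

#' Fuzzy ratio of two composite images
#'
#' Both images are first normalized by their own total response, so a
#' global intensity scale between classes cancels. To absorb residual
#' misalignment, each normalized image is replaced by its windowed maximum
#' (greyscale dilation with a square window of half-width
#' `tolerance_window` pixels) before the per-pixel ratio is taken. Pixels
#' where either windowed image falls below `floor` are masked (`NA`).
#' The output is the signed log2 ratio: positive where the analyzed class
#' responds more, negative where the reference class responds more;
#' swapping the two images negates the result exactly.
#'
#' @param analyzed,reference [tic_image()]s on the same grid.
#' @param tolerance_window window half-width in pixels (default 1, i.e.
#'   3x3).
#' @param floor intensity floor in normalized units; default 3x the
#'   reference image's noise estimate divided by its total.
#' @return object of class `ratio_image`: list with `log2_ratio` matrix
#'   (`NA` where masked) and the axes of the inputs.
#' @export
fuzzy_ratio <- function(analyzed, reference, tolerance_window = 1,
                        floor = NULL) {
  stopifnot(inherits(analyzed, "tic_image"), inherits(reference, "tic_image"))
  if (!identical(dim(analyzed$image), dim(reference$image))) {
    stop("image grids differ: ",
         paste(dim(analyzed$image), collapse = "x"), " vs ",
         paste(dim(reference$image), collapse = "x"))
  }
  ta <- sum(analyzed$image); tr <- sum(reference$image)
  if (ta <= 0 || tr <= 0) stop("image totals must be > 0")
  A <- analyzed$image / ta
  R <- reference$image / tr
  if (tolerance_window > 0) {
    A <- dilate_gray(A, as.integer(tolerance_window))
    R <- dilate_gray(R, as.integer(tolerance_window))
  }
  if (is.null(floor)) {
    floor <- 3 * stats::mad(reference$image) / tr
  }
  ratio <- log2(A / R)
  ratio[A < floor | R < floor] <- NA_real_
  structure(list(log2_ratio = ratio, rt1_min = analyzed$rt1_min,
                 rt2_s = analyzed$rt2_s, floor = floor,
                 tolerance_window = tolerance_window),
            class = "ratio_image")
}

#' @export
print.ratio_image <- function(x, ...) {
  r <- x$log2_ratio
  cat("<ratio_image>", nrow(r), "x", ncol(r), "pixels;",
      sum(!is.na(r)), "unmasked;",
      "log2 range", paste(round(range(r, na.rm = TRUE), 2), collapse = " .. "),
      "\n")
  invisible(x)
}

#' Render a ratio image to PNG
#'
#' Red/green diverging map: green where the analyzed class responds more,
#' red where the reference class responds more, mid-grey where masked.
#'
#' @param ratio a `ratio_image`.
#' @param path output PNG path.
#' @param max_abs saturation point for |log2 ratio|.
#' @return `path`, invisibly.
#' @export
render_ratio_png <- function(ratio, path, max_abs = 3) {
  r <- ratio$log2_ratio
  v <- pmax(pmin(r / max_abs, 1), -1)
  g <- pmax(v, 0); rd <- pmax(-v, 0)
  rgb <- array(0.25, dim = c(dim(r), 3))
  rgb[, , 1][!is.na(v)] <- rd[!is.na(v)]
  rgb[, , 2][!is.na(v)] <- g[!is.na(v)]
  rgb[, , 3][!is.na(v)] <- 0
  ## orient: 1D along x, 2D along y, origin bottom-left
  img <- EBImage::Image(rgb, colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}
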