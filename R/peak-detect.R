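## 2D peak detection on TIC images: watershed segmentation seeded at local
## maxima, apex spectra, footprints, volumes and S/N.

#' Detect 2D peaks on a background-subtracted TIC image
#'
#' Segments the image by a local-maxima-seeded watershed (EBImage), with an
#' h-maxima-style `tolerance` that merges shoulder maxima closer in height
#' than `h` to their dominant neighbour. Each catchment contributes at most
#' one peak: the apex is its highest pixel (ties broken toward lower
#' first-dimension, then lower second-dimension index), and the footprint is
#' the connected set of pixels above `floor` around the apex within the
#' catchment. Peaks are retained iff `volume >= min_counts` and
#' `apex / noise >= min_snr`, and returned sorted by volume, descending.
#'
#' @param image a background-subtracted [tic_image()].
#' @param min_counts minimum footprint TIC volume (absolute response gate;
#'   see [snr_threshold_to_counts()] for the S/N-derived value).
#' @param min_snr minimum apex-to-noise ratio.
#' @param noise a `noise_estimate` from [estimate_noise()]; a level of 0
#'   disables the S/N gate and the footprint floor.
#' @param h watershed merge tolerance; default `3 * noise$level`.
#' @param floor footprint inclusion floor; default `2 * noise$level`.
#' @return data.frame of class `peak_list` with columns `peak_id`, `rt1`
#'   (min), `rt2` (s), `apex_mod`, `apex_samp`, `apex_tic`, `volume`,
#'   `snr`, and list columns `footprint` (linear pixel indices into the
#'   image) and `spectrum` (filled by [add_peak_spectra()]).
#' @export
detect_peaks <- function(image, min_counts = 0, min_snr = 0, noise = NULL,
                         h = NULL, floor = NULL) {
  stopifnot(inherits(image, "tic_image"))
  img <- image$image
  level <- if (is.null(noise)) 0 else noise$level
  if (is.null(h)) h <- 3 * level
  if (is.null(floor)) floor <- 2 * level
  n1 <- nrow(img); n2 <- ncol(img)

  pos <- pmax(img, 0)
  if (max(pos) <= 0) return(empty_peak_list(image))
  ws <- EBImage::imageData(
    EBImage::watershed(EBImage::Image(pos), tolerance = max(h, 1e-12),
                       ext = 1))
  ## connected components above the floor, for local footprints
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(pos > floor)))

  nlab <- max(ws)
  if (nlab == 0) return(empty_peak_list(image))
  rows <- vector("list", nlab)
  idx_all <- which(ws > 0)
  by_lab <- split(idx_all, ws[idx_all])
  for (k in seq_along(by_lab)) {
    px <- by_lab[[k]]
    vals <- img[px]
    vmax <- max(vals)
    cand <- px[vals == vmax]
    if (length(cand) > 1L) {
      cm <- ((cand - 1L) %% n1) + 1L       # modulation index
      cs <- ((cand - 1L) %/% n1) + 1L      # sample index
      o <- order(cm, cs)
      cand <- cand[o]
    }
    apex <- cand[1L]
    fp <- px[comp[px] == comp[apex] & pos[px] > floor]
    if (!length(fp)) fp <- apex
    vol <- sum(img[fp])
    snr <- if (level > 0) img[apex] / level else Inf
    if (vol < min_counts || snr < min_snr) next
    rows[[k]] <- list(apex = apex, vol = vol, snr = snr, fp = fp)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_peak_list(image))

  apex <- vapply(rows, `[[`, numeric(1), "apex")
  am <- ((apex - 1) %% n1) + 1
  as_ <- ((apex - 1) %/% n1) + 1
  out <- data.frame(
    peak_id = NA_integer_,
    rt1 = mod_to_rt1(am, image$modulation_period),
    rt2 = samp_to_rt2(as_, image$acquisition_rate),
    apex_mod = as.integer(am), apex_samp = as.integer(as_),
    apex_tic = img[apex],
    volume = vapply(rows, `[[`, numeric(1), "vol"),
    snr = vapply(rows, `[[`, numeric(1), "snr")
  )
  out$footprint <- lapply(rows, `[[`, "fp")
  out$spectrum <- rep(list(NULL), nrow(out))
  o <- order(-out$volume, out$apex_mod, out$apex_samp)
  out <- out[o, , drop = FALSE]
  out$peak_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  attr(out, "run_id") <- image$run_id
  attr(out, "channel") <- image$channel
  attr(out, "image_dim") <- dim(img)
  out
}

#' @noRd
empty_peak_list <- function(image) {
  out <- data.frame(peak_id = integer(), rt1 = numeric(), rt2 = numeric(),
                    apex_mod = integer(), apex_samp = integer(),
                    apex_tic = numeric(), volume = numeric(),
                    snr = numeric())
  out$footprint <- list()
  out$spectrum <- list()
  class(out) <- c("peak_list", "data.frame")
  attr(out, "run_id") <- image$run_id
  attr(out, "channel") <- image$channel
  attr(out, "image_dim") <- dim(image$image)
  out
}

#' Apex ("peak") spectrum of a detected 2D peak
#'
#' The MS signature of a peak is the m/z vector at its single largest data
#' point (the apex pixel) of the raw cube, normalized to base peak 999.
#' No deconvolution of co-eluting signals is attempted.
#'
#' @param cube a [chromatogram2d()] (raw, pre background subtraction).
#' @param peak one row of a `peak_list` (or a list with `apex_mod`,
#'   `apex_samp`).
#' @return a normalized [spectrum()]; zero-intensity bins are dropped.
#' @export
peak_spectrum <- function(cube, peak) {
  stopifnot(inherits(cube, "chromatogram2d"))
  i <- peak$apex_mod; j <- peak$apex_samp
  d <- dim(cube$cube)
  if (i < 1 || i > d[1] || j < 1 || j > d[2]) {
    stop("apex pixel (", i, ",", j, ") lies outside the cube bounds")
  }
  v <- cube$cube[i, j, ]
  keep <- v > 0
  if (!any(keep)) stop("apex pixel has an all-zero spectrum")
  normalize_spectrum(spectrum(cube$mz_axis[keep], v[keep]))
}

#' Attach apex spectra to every peak of a peak list
#'
#' @param peaks a `peak_list`.
#' @param cube the matching raw [chromatogram2d()].
#' @return `peaks` with the `spectrum` list column filled.
#' @export
add_peak_spectra <- function(peaks, cube) {
  peaks$spectrum <- lapply(seq_len(nrow(peaks)), function(i) {
    peak_spectrum(cube, peaks[i, ])
  })
  peaks
}

#' Integrate the TIC volume over a footprint
#'
#' Exact sum of the TIC image over the footprint pixels.
#'
#' @param image a [tic_image()].
#' @param footprint linear pixel indices into the image.
#' @return counts.
#' @export
integrate_volume <- function(image, footprint) {
  stopifnot(inherits(image, "tic_image"))
  if (length(footprint) == 0) stop("footprint is empty")
  sum(image$image[footprint])
}

#' Serialize a peak list to CSV (spectra as an MSP sidecar)
#'
#' @param peaks a `peak_list`.
#' @param path CSV path; a `.msp` sidecar with the apex spectra is written
#'   alongside when spectra are present.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(run_id = attr(peaks, "run_id") %||% NA,
                   channel = attr(peaks, "channel") %||% NA,
                   peak_id = peaks$peak_id,
                   rt1_min = peaks$rt1, rt2_s = peaks$rt2,
                   volume = peaks$volume, snr = peaks$snr)
  utils::write.csv(df, path, row.names = FALSE)
  specs <- peaks$spectrum
  if (length(specs) && !is.null(specs[[1]])) {
    names(specs) <- sprintf("peak_%03d", peaks$peak_id)
    write_msp(specs, sub("\\.csv$", ".msp", path))
  }
  invisible(path)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
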