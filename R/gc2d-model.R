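## Core GCxGC data model: folding of the detector stream into the 2D plane,
## TIC images, and the plain-text run container.

VALID_CHANNELS <- c("70eV", "12eV", "fused")

#' Construct a 2D chromatogram
#'
#' A `chromatogram2d` holds the per-run, per-channel data cube indexed
#' `[modulation, intra-modulation sample, m/z bin]` together with its
#' acquisition metadata. The first-dimension time of modulation `k`
#' (1-based) is `(k-1) * modulation_period` seconds from the start of the
#' run (reported in minutes); the second-dimension time of sample `j` is
#' `(j-1) / acquisition_rate` seconds. No injection-delay offset is applied.
#'
#' @param cube numeric 3D array `[modulation, sample, mz]`, counts.
#' @param mz_axis integer vector of nominal masses (Da), one per m/z bin.
#' @param modulation_period modulation period in seconds.
#' @param acquisition_rate acquisition frequency in Hz per channel.
#' @param channel one of `"70eV"`, `"12eV"`, `"fused"`.
#' @param run_id run identifier.
#' @return An object of class `chromatogram2d`.
#' @export
chromatogram2d <- function(cube, mz_axis, modulation_period, acquisition_rate,
                           channel, run_id = "run") {
  if (length(dim(cube)) != 3L) {
    stop("`cube` must be a 3D array [modulation, sample, mz]")
  }
  if (dim(cube)[3] != length(mz_axis)) {
    stop("third cube dimension (", dim(cube)[3], ") does not match mz_axis (",
         length(mz_axis), ")")
  }
  pts <- modulation_period * acquisition_rate
  if (abs(pts - round(pts)) > 1e-9 || round(pts) <= 0) {
    stop("modulation_period x acquisition_rate must be a positive integer")
  }
  if (dim(cube)[2] != round(pts)) {
    stop("cube has ", dim(cube)[2], " intra-modulation samples but ",
         "modulation_period x acquisition_rate = ", round(pts))
  }
  if (!channel %in% VALID_CHANNELS) {
    stop("unknown channel tag '", channel, "'; expected one of ",
         paste(VALID_CHANNELS, collapse = ", "))
  }
  structure(
    list(cube = cube, mz_axis = as.integer(mz_axis),
         modulation_period = modulation_period,
         acquisition_rate = acquisition_rate,
         channel = channel, run_id = run_id),
    class = "chromatogram2d"
  )
}

#' @export
print.chromatogram2d <- function(x, ...) {
  d <- dim(x$cube)
  cat("<chromatogram2d> run", x$run_id, "channel", x$channel, "\n")
  cat("  ", d[1], "modulations x", d[2], "samples x", d[3], "m/z bins\n")
  cat("  modulation period", x$modulation_period, "s, acquisition",
      x$acquisition_rate, "Hz, m/z", min(x$mz_axis), "-", max(x$mz_axis), "\n")
  invisible(x)
}

#' Fold a raw detector stream into a 2D chromatogram
#'
#' Reshapes a scan-by-scan detector stream (rows = detector events at the
#' acquisition rate, columns = m/z bins) into the modulation-aligned cube:
#' modulation column `k` holds scans `[(k-1)*P + 1, k*P]` where
#' `P = modulation_period * acquisition_rate`. No data are dropped; folding
#' preserves total counts exactly.
#'
#' @param stream numeric matrix `[scan, mz]`.
#' @param modulation_period seconds.
#' @param acquisition_rate Hz.
#' @param mz_axis nominal mass per column of `stream`.
#' @param channel,run_id metadata passed to [chromatogram2d()].
#' @return A [chromatogram2d()].
#' @export
fold <- function(stream, modulation_period, acquisition_rate,
                 mz_axis = seq_len(ncol(stream)), channel = "70eV",
                 run_id = "run") {
  stream <- as.matrix(stream)
  pts <- modulation_period * acquisition_rate
  if (abs(pts - round(pts)) > 1e-9 || round(pts) <= 0) {
    stop("modulation_period x acquisition_rate must be a positive integer")
  }
  pts <- as.integer(round(pts))
  n <- nrow(stream)
  if (n %% pts != 0L) {
    stop("stream length ", n, " is not divisible by ", pts,
         " points per modulation (remainder ", n %% pts, ")")
  }
  n1 <- n %/% pts
  cube <- aperm(array(stream, dim = c(pts, n1, ncol(stream))), c(2L, 1L, 3L))
  chromatogram2d(cube, mz_axis, modulation_period, acquisition_rate,
                 channel, run_id)
}

#' Flatten a 2D chromatogram back to its raw detector stream
#'
#' Inverse of [fold()]: `flatten(fold(x)) == x`.
#'
#' @param chrom a [chromatogram2d()].
#' @return numeric matrix `[scan, mz]`.
#' @export
flatten <- function(chrom) {
  d <- dim(chrom$cube)
  m <- array(aperm(chrom$cube, c(2L, 1L, 3L)), dim = c(d[1] * d[2], d[3]))
  m
}

#' Total ion current image of a 2D chromatogram
#'
#' Pixel-wise sum over the m/z axis. The sum over the TIC image equals the
#' sum over the cube exactly.
#'
#' @param chrom a [chromatogram2d()].
#' @return An object of class `tic_image`: list with `image`
#'   (`[modulation, sample]` matrix), axis vectors `rt1_min` and `rt2_s`,
#'   and acquisition metadata.
#' @export
tic <- function(chrom) {
  d <- dim(chrom$cube)
  flat <- chrom$cube
  dim(flat) <- c(d[1] * d[2], d[3])
  img <- matrix(rowSums(flat), nrow = d[1], ncol = d[2])
  tic_image(img, chrom$modulation_period, chrom$acquisition_rate,
            channel = chrom$channel, run_id = chrom$run_id)
}

#' Construct a TIC image
#'
#' @param image numeric matrix `[modulation, sample]`.
#' @param modulation_period seconds.
#' @param acquisition_rate Hz.
#' @param channel,run_id metadata.
#' @return `tic_image` object.
#' @export
tic_image <- function(image, modulation_period, acquisition_rate,
                      channel = "70eV", run_id = "run") {
  structure(
    list(image = image,
         rt1_min = mod_to_rt1(seq_len(nrow(image)), modulation_period),
         rt2_s = samp_to_rt2(seq_len(ncol(image)), acquisition_rate),
         modulation_period = modulation_period,
         acquisition_rate = acquisition_rate,
         channel = channel, run_id = run_id),
    class = "tic_image"
  )
}

#' @export
print.tic_image <- function(x, ...) {
  cat("<tic_image> run", x$run_id, "channel", x$channel, ":",
      nrow(x$image), "modulations x", ncol(x$image), "samples, total",
      format(sum(x$image), digits = 6), "counts\n")
  invisible(x)
}

## Run container ---------------------------------------------------------
## One text file per run and channel: a single JSON header line (prefixed
## "#tandemgc-run ") followed by the scan x m/z count matrix as TSV.
## Counts are detector counts (integers), so the round trip is exact.

RUN_META_FIELDS <- c("run_id", "channel", "modulation_period",
                     "acquisition_rate", "mz_axis")

#' Write a 2D chromatogram to the package run container
#'
#' The container is plain text: a JSON metadata header line followed by the
#' unfolded scan-by-scan count matrix (tab separated, one column per m/z
#' bin). `read_run(write_run(x))` is the identity on cube, axes and
#' metadata.
#'
#' @param chrom a [chromatogram2d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram2d"))
  meta <- list(run_id = chrom$run_id, channel = chrom$channel,
               modulation_period = chrom$modulation_period,
               acquisition_rate = chrom$acquisition_rate,
               mz_axis = chrom$mz_axis)
  header <- paste0("#tandemgc-run ",
                   jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  writeLines(header, path)
  data.table::fwrite(data.table::as.data.table(flatten(chrom)), path,
                     sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read a 2D chromatogram from the package run container
#'
#' @param path file written by [write_run()].
#' @return A [chromatogram2d()].
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("no such run file: ", path)
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#tandemgc-run ")) {
    stop("not a tandemgc run container: ", path)
  }
  meta <- jsonlite::fromJSON(sub("^#tandemgc-run ", "", header))
  missing <- setdiff(RUN_META_FIELDS, names(meta))
  if (length(missing)) {
    stop("run container is missing metadata fields: ",
         paste(missing, collapse = ", "))
  }
  stream <- as.matrix(data.table::fread(path, sep = "\t", skip = 1L,
                                        header = FALSE))
  dimnames(stream) <- NULL
  fold(stream, meta$modulation_period, meta$acquisition_rate,
       mz_axis = meta$mz_axis, channel = meta$channel, run_id = meta$run_id)
}
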