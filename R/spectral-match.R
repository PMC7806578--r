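## NIST-style spectral similarity on the 0-999 scale.
##
## Scores are weighted cosines with the Stein-Scott identity-search
## weighting w = intensity^0.6 * mz^3. The NIST composite score (dot
## product plus ratio-of-adjacent-peaks term) is intentionally not
## implemented; the pure weighted cosine is what all gate thresholds in
## this package operate on.

#' Construct a mass spectrum
#'
#' @param mz integer nominal masses (Da), strictly increasing.
#' @param intensity non-negative intensities.
#' @return data.frame of class `spectrum` with columns `mz`, `intensity`.
#' @export
spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity)) stop("mz/intensity length mismatch")
  o <- order(mz)
  mz <- as.integer(mz[o]); intensity <- as.numeric(intensity[o])
  if (anyDuplicated(mz)) stop("m/z values must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(data.frame(mz = mz, intensity = intensity),
            class = c("spectrum", "data.frame"))
}

#' Normalize a spectrum to base peak 999
#'
#' Scales intensities so the base peak is 999; relative intensities are
#' preserved (no rounding). Idempotent.
#'
#' @param s a [spectrum()].
#' @return normalized [spectrum()].
#' @export
normalize_spectrum <- function(s) {
  if (is.null(s) || nrow(s) == 0) stop("cannot normalize an empty spectrum")
  m <- max(s$intensity)
  if (m <= 0) stop("cannot normalize an all-zero spectrum")
  s$intensity <- s$intensity * (999 / m)
  s
}

## Stein-Scott identity weights on a pair of aligned intensity vectors.
#' @noRd
ss_weights <- function(intensity, mz, int_exp = 0.6, mz_exp = 3) {
  intensity^int_exp * as.numeric(mz)^mz_exp
}

#' @noRd
weighted_cosine_999 <- function(mz_a, int_a, mz_b, int_b,
                                int_exp = 0.6, mz_exp = 3) {
  mz_u <- union(mz_a, mz_b)
  ia <- int_a[match(mz_u, mz_a)]; ia[is.na(ia)] <- 0
  ib <- int_b[match(mz_u, mz_b)]; ib[is.na(ib)] <- 0
  wa <- ss_weights(ia, mz_u, int_exp, mz_exp)
  wb <- ss_weights(ib, mz_u, int_exp, mz_exp)
  sa <- sum(wa); sb <- sum(wb)
  if (sa == 0 || sb == 0) return(0L)
  as.integer(round(999 * sum(sqrt(wa * wb))^2 / (sa * sb)))
}

#' Direct match factor (DMF)
#'
#' Weighted-cosine spectral similarity over the union of the two m/z sets,
#' with weights `intensity^0.6 * mz^3`, reported as an integer on the NIST
#' 0-999 scale. Symmetric; `direct_match_factor(s, s) == 999`.
#'
#' @param a,b [spectrum()] objects (normalization does not affect the
#'   score; it is scale-invariant).
#' @param int_exp,mz_exp weighting exponents (identity-search defaults).
#' @return integer score in `[0, 999]`.
#' @export
direct_match_factor <- function(a, b, int_exp = 0.6, mz_exp = 3) {
  if (is.null(a) || nrow(a) == 0 || is.null(b) || nrow(b) == 0) {
    stop("match factors are undefined for empty spectra")
  }
  weighted_cosine_999(a$mz, a$intensity, b$mz, b$intensity, int_exp, mz_exp)
}

#' Reverse match factor (RMF)
#'
#' The direct match factor computed only over m/z values present in the
#' reference spectrum: peaks found only in the query (e.g. co-eluting
#' impurities) are ignored. Intentionally asymmetric;
#' `reverse_match_factor(s, s) == 999`.
#'
#' @param query query (analyzed) [spectrum()].
#' @param reference reference (library/template) [spectrum()].
#' @param int_exp,mz_exp weighting exponents.
#' @return integer score in `[0, 999]`.
#' @export
reverse_match_factor <- function(query, reference, int_exp = 0.6, mz_exp = 3) {
  if (is.null(reference) || nrow(reference) == 0) {
    stop("reverse match factor needs a non-empty reference spectrum")
  }
  if (is.null(query) || nrow(query) == 0) {
    stop("reverse match factor needs a non-empty query spectrum")
  }
  keep <- query$mz %in% reference$mz
  weighted_cosine_999(query$mz[keep], query$intensity[keep],
                      reference$mz, reference$intensity, int_exp, mz_exp)
}

#' Match a query spectrum against a reference spectrum
#'
#' @param query,reference [spectrum()] objects.
#' @return list with integer `dmf` and `rmf`.
#' @export
match_spectra <- function(query, reference) {
  list(dmf = direct_match_factor(query, reference),
       rmf = reverse_match_factor(query, reference))
}

## MSP text format -------------------------------------------------------

#' Write spectra in NIST MSP text format
#'
#' @param spectra named list of [spectrum()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(spectra)) {
    s <- spectra[[nm]]
    writeLines(c(paste0("Name: ", nm),
                 paste0("Num Peaks: ", nrow(s)),
                 paste(s$mz, round(s$intensity, 3), sep = " ",
                       collapse = "; ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read spectra from NIST MSP text format
#'
#' @param path MSP file.
#' @return named list of [spectrum()] objects.
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  out <- list()
  name <- NULL
  buf <- character()
  flush_entry <- function() {
    if (is.null(name)) return()
    pairs <- unlist(strsplit(paste(buf, collapse = "; "), ";"))
    pairs <- trimws(pairs[nzchar(trimws(pairs))])
    mzint <- do.call(rbind, strsplit(pairs, "\\s+"))
    out[[name]] <<- spectrum(as.integer(mzint[, 1]), as.numeric(mzint[, 2]))
  }
  for (ln in lines) {
    if (grepl("^Name:", ln)) {
      flush_entry()
      name <- trimws(sub("^Name:", "", ln))
      buf <- character()
    } else if (grepl("^Num Peaks:", ln) || !nzchar(trimws(ln))) {
      ## header/separator, skip
    } else {
      buf <- c(buf, ln)
    }
  }
  flush_entry()
  out
}
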