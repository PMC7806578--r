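# Shared fixtures: everything is generated in code at test time.

# Small acquisition geometry for unit tests (40 modulations x 100 samples,
# 76 m/z bins); noise levels scaled with the m/z window.
tiny_synth <- function(...) {
  args <- modifyList(
    list(n_modulations = 40, acquisition_rate = 20, mz_range = c(45, 120),
         baseline_level_70 = 2000, baseline_level_12 = 160,
         noise_sd_70 = 200, noise_sd_12 = 5),
    list(...))
  do.call(synth_config, args)
}

# A hand-built library whose fragments all lie inside the tiny m/z window.
tiny_library <- function() {
  e <- function(name, ri, rt2, m70, i70, m12, i12, r70 = 4e6, r12 = 4e5) {
    list(name = name, ri = ri, two_d_time = rt2, pct_diff = NA_real_,
         spectrum_70 = normalize_spectrum(spectrum(m70, i70)),
         spectrum_12 = normalize_spectrum(spectrum(m12, i12)),
         response_70 = r70, response_12 = r12)
  }
  lib <- list(
    e("alpha", 950, 1.2, c(73, 81, 95, 110), c(999, 400, 250, 120),
      c(95, 110, 118), c(300, 999, 600)),
    e("beta", 1080, 2.9, c(73, 88, 101), c(999, 700, 300),
      c(88, 101, 115), c(400, 999, 500)),
    e("gamma", 1190, 1.9, c(73, 91, 104, 117), c(800, 999, 350, 200),
      c(104, 117), c(500, 999))
  )
  names(lib) <- vapply(lib, `[[`, character(1), "name")
  structure(lib, class = "spectral_library",
            class_effects = setNames(rep(1, 3), names(lib)))
}

# Deterministic Gaussian-blob TIC image (no noise).
blob_image <- function(n1 = 60, n2 = 80, apexes, s1 = 2, s2 = 3,
                       baseline = 0, period = 5, rate = 16) {
  stopifnot(round(period * rate) == n2)
  img <- matrix(baseline, n1, n2)
  for (k in seq_len(nrow(apexes))) {
    g1 <- exp(-0.5 * ((seq_len(n1) - apexes$mod[k]) / s1)^2)
    g2 <- exp(-0.5 * ((seq_len(n2) - apexes$samp[k]) / s2)^2)
    img <- img + apexes$height[k] * outer(g1, g2)
  }
  tic_image(img, period, rate)
}

# Random nominal-mass spectrum for match-factor property tests.
rand_spec <- function(k = sample(3:10, 1), mz_max = 500) {
  mz <- sort(sample(45:mz_max, k))
  normalize_spectrum(spectrum(mz, runif(k, 1, 999)))
}

# Independent brute-force weighted-cosine oracle (loop over the m/z
# union; no shared code with the implementation).
naive_mf <- function(a, b, int_exp = 0.6, mz_exp = 3) {
  allmz <- sort(union(a$mz, b$mz))
  s <- sa <- sb <- 0
  for (m in allmz) {
    ia <- if (m %in% a$mz) a$intensity[a$mz == m] else 0
    ib <- if (m %in% b$mz) b$intensity[b$mz == m] else 0
    wa <- ia^int_exp * m^mz_exp
    wb <- ib^int_exp * m^mz_exp
    s <- s + sqrt(wa * wb); sa <- sa + wa; sb <- sb + wb
  }
  if (sa == 0 || sb == 0) return(0L)
  as.integer(round(999 * s^2 / (sa * sb)))
}

naive_rmf <- function(query, reference) {
  keep <- query$mz %in% reference$mz
  if (!any(keep)) return(0L)
  q <- spectrum(query$mz[keep], query$intensity[keep])
  naive_mf(q, reference)
}

# Closed-form tie-corrected Kruskal-Wallis p for two groups.
kw_closed_form_p <- function(x, g) {
  r <- rank(x); N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / as.vector(table(g))) - 3 * (N + 1)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  stats::pchisq(H / C, df = length(unique(g)) - 1, lower.tail = FALSE)
}

# Minimal peak_list builder for alignment tests.
fake_peaks <- function(rt1, rt2, spectra, volume = 1e6,
                       period = 5, rate = 20) {
  n <- length(rt1)
  out <- data.frame(peak_id = seq_len(n), rt1 = rt1, rt2 = rt2,
                    apex_mod = as.integer(round(rt1 * 60 / period + 1)),
                    apex_samp = as.integer(round(rt2 * rate + 1)),
                    apex_tic = rep(volume, n), volume = rep(volume, n),
                    snr = rep(1000, n))
  out$footprint <- as.list(seq_len(n))
  out$spectrum <- spectra
  class(out) <- c("peak_list", "data.frame")
  out
}
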