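# Welch power spectral density: demeaned, Hann-windowed segments, 50%
# overlap, zero-padded so the frequency resolution is at most 0.5 Hz.
# `x` may be a matrix (time x channels); segments are batched through mvfft.
welch_psd <- function(x, fs, seg_sec = 1, overlap = 0.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  seg <- min(n, round(seg_sec * fs))
  step <- max(1, round(seg * (1 - overlap)))
  starts <- seq(1, n - seg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hann
  nfft <- 2^ceiling(log2(seg * 2))
  nf <- nfft %/% 2 + 1
  # stack all (segment, channel) slices into one big fft batch
  slices <- matrix(0, nfft, length(starts) * ncol(x))
  j <- 0
  for (s in starts) {
    xi <- x[s:(s + seg - 1), , drop = FALSE]
    xi <- sweep(xi, 2, colMeans(xi)) * w
    slices[seq_len(seg), j + seq_len(ncol(x))] <- xi
    j <- j + ncol(x)
  }
  X <- Mod(stats::mvfft(slices)[seq_len(nf), , drop = FALSE])^2
  acc <- matrix(0, nf, ncol(x))
  for (k in seq_along(starts)) {
    acc <- acc + X[, (k - 1) * ncol(x) + seq_len(ncol(x)), drop = FALSE]
  }
  psd <- acc / (length(starts) * sum(w^2) * fs)
  list(freq = (seq_len(nf) - 1) * fs / nfft, psd = psd)
}

#' Relative spectral power in a band
#'
#' Fraction of Welch-periodogram power inside `band` relative to the power
#' in `total_band`. Scale-invariant and bounded in \[0, 1\].
#'
#' @param x signal (numeric vector), at least 2 s of samples.
#' @param fs sample rate (Hz).
#' @param band target band (Hz), default the lower alpha band 8-10 Hz.
#' @param total_band reference band (Hz), default 0.5-30 Hz.
#' @return Fraction in \[0, 1\], or `NA` for an all-zero/constant signal.
#' @examples
#' t <- seq(0, 4, by = 1/250)
#' relative_band_power(sin(2 * pi * 9 * t), fs = 250)
#' @export
relative_band_power <- function(x, fs, band = c(8, 10),
                                total_band = c(0.5, 30)) {
  if (band[1] < total_band[1] || band[2] > total_band[2]) {
    abort("`band` must lie inside `total_band`.")
  }
  if (length(x) < 2 * fs) abort("need at least 2 s of signal.")
  if (sd(x) == 0) return(NA_real_)
  ps <- welch_psd(x, fs)
  in_band <- ps$freq >= band[1] & ps$freq <= band[2]
  in_total <- ps$freq >= total_band[1] & ps$freq <= total_band[2]
  tot <- sum(ps$psd[in_total])
  if (tot <= 0) return(NA_real_)
  sum(ps$psd[in_band]) / tot
}

#' Dominant spectral peak frequency
#'
#' Frequency of the maximum Welch spectral density within `search_band`.
#'
#' @param x signal (numeric vector).
#' @param fs sample rate (Hz).
#' @param search_band band searched for the peak (Hz).
#' @return Peak frequency (Hz), or `NA` for a flat/degenerate spectrum.
#' @export
peak_frequency <- function(x, fs, search_band = c(1, 30)) {
  if (length(x) < 2 * fs) abort("need at least 2 s of signal.")
  if (sd(x) == 0) return(NA_real_)
  ps <- welch_psd(x, fs)
  sel <- ps$freq >= search_band[1] & ps$freq <= search_band[2]
  p <- ps$psd[sel]; f <- ps$freq[sel]
  if (max(p) <= 0 || diff(range(p)) == 0) return(NA_real_)
  f[which.max(p)]
}

#' Spectral outcome measures for a cycle
#'
#' Per-node relative lower-alpha power and peak frequency of the
#' EEG-like excitatory membrane potentials.
#'
#' @param output a `cycle_output`.
#' @param band lower alpha band (Hz).
#' @param total_band total band for relative power (Hz).
#' @param search_band peak-frequency search band (Hz).
#' @return Tibble with `node`, `label`, `rel_lower_alpha`, `peak_freq`.
#' @export
spectral_metrics <- function(output, band = c(8, 10),
                             total_band = c(0.5, 30),
                             search_band = c(1, 30)) {
  n <- ncol(output$signals)
  ps <- welch_psd(output$signals, output$fs)
  in_band <- ps$freq >= band[1] & ps$freq <= band[2]
  in_total <- ps$freq >= total_band[1] & ps$freq <= total_band[2]
  in_search <- ps$freq >= search_band[1] & ps$freq <= search_band[2]
  tot <- colSums(ps$psd[in_total, , drop = FALSE])
  rel <- ifelse(tot > 0,
                colSums(ps$psd[in_band, , drop = FALSE]) / tot, NA_real_)
  pk <- apply(ps$psd[in_search, , drop = FALSE], 2, function(p) {
    if (max(p) <= 0 || diff(range(p)) == 0) NA_real_
    else ps$freq[in_search][which.max(p)]
  })
  flat <- apply(output$signals, 2, sd) == 0
  rel[flat] <- NA_real_; pk[flat] <- NA_real_
  tibble::tibble(
    node = seq_len(n),
    label = colnames(output$signals),
    rel_lower_alpha = unname(rel),
    peak_freq = unname(pk))
}
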