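# zero-phase band-pass (4th-order Butterworth, forward-backward)
band_pass <- function(x, fs, band) {
  ny <- fs / 2
  if (band[2] >= ny) abort("upper band edge must be below the Nyquist rate.")
  bf <- signal::butter(4, band / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# analytic signal via frequency-domain Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a signal
#'
#' Band-limits the signal (default 4-13 Hz, covering the model's
#' alpha-dominated activity), takes the analytic-signal phase, and trims a
#' fraction of samples at each edge where the filter and Hilbert transform
#' are unreliable.
#'
#' @param x signal (numeric vector), at least 2 s of samples.
#' @param fs sample rate (Hz).
#' @param band analysis band (Hz); `NULL` skips filtering.
#' @param trim fraction of samples dropped at each edge.
#' @return Phase series (radians, wrapped), shorter than `x` by `2 * trim`.
#' @export
instantaneous_phase <- function(x, fs, band = c(4, 13), trim = 0.1) {
  if (any(!is.finite(x))) abort("signal must be finite.")
  if (length(x) < 2 * fs) abort("need at least 2 s of signal.")
  if (sd(x) == 0) abort("phase is undefined for a constant signal.")
  if (!is.null(band)) x <- band_pass(x - mean(x), fs, band)
  ph <- Arg(analytic_signal(x - mean(x)))
  n <- length(ph)
  drop <- floor(trim * n)
  ph[(drop + 1):(n - drop)]
}

#' Phase Lag Index of two phase series
#'
#' \eqn{PLI = | \langle sign(\sin \Delta\phi(t)) \rangle |}: the asymmetry
#' of the phase-difference distribution around zero. 1 means perfect
#' nonzero-lag phase locking; 0 means no coupling or coupling with a phase
#' difference centred around 0 mod \eqn{\pi} (as produced by volume
#' conduction). Samples with \eqn{\sin \Delta\phi} exactly 0 contribute 0
#' to the mean but count in the denominator.
#'
#' @param x,y phase series (radians), equal length.
#' @return PLI in \[0, 1\]; symmetric in its arguments.
#' @export
pli <- function(x, y) {
  if (length(x) != length(y)) abort("phase series must have equal length.")
  if (length(x) == 0) abort("empty phase series.")
  abs(mean(sign(sin(x - y))))
}

#' Phase Lag Index matrix of a multichannel recording
#'
#' PLI for all node pairs, plus the global mean over distinct pairs.
#'
#' @param signals time x nodes numeric matrix (or a `cycle_output`).
#' @param fs sample rate (Hz); taken from a `cycle_output` automatically.
#' @param band phase-estimation band (Hz).
#' @param trim edge-trim fraction passed to [instantaneous_phase()].
#' @return A `pli_matrix`: list with the symmetric `values` matrix
#'   (zero diagonal) and `global_mean`.
#' @export
pli_matrix <- function(signals, fs = NULL, band = c(4, 13), trim = 0.1) {
  if (inherits(signals, "cycle_output")) {
    fs <- signals$fs
    signals <- signals$signals
  }
  if (is.null(fs)) abort("`fs` is required for a bare signal matrix.")
  n <- ncol(signals)
  if (n < 2) abort("need at least 2 channels.")
  ph1 <- instantaneous_phase(signals[, 1], fs, band, trim)
  phases <- matrix(0, length(ph1), n)
  phases[, 1] <- ph1
  for (i in seq_len(n)[-1]) {
    phases[, i] <- instantaneous_phase(signals[, i], fs, band, trim)
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    dphi <- phases[, (i + 1):n, drop = FALSE] - phases[, i]
    M[i, (i + 1):n] <- abs(colMeans(sign(sin(dphi))))
  }
  M <- M + t(M)
  dimnames(M) <- list(colnames(signals), colnames(signals))
  structure(list(values = M,
                 global_mean = mean(M[upper.tri(M)])),
            class = "pli_matrix")
}

#' @export
print.pli_matrix <- function(x, ...) {
  cat(sprintf("<pli_matrix> %d nodes, global mean PLI = %.3f\n",
              nrow(x$values), x$global_mean))
  invisible(x)
}

#' Tidy a PLI matrix into a pair table
#'
#' @param x a `pli_matrix`.
#' @param ... unused.
#' @return Tibble with `node_i`, `node_j`, `pli` (upper triangle).
#' @export
tidy.pli_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(node_i = idx[, 1], node_j = idx[, 2],
                 pli = x$values[idx])
}
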