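# Welch spectra, relative power, band summaries, and the cross-spectral
# matrix feeding coherence, partial coherence and network efficiency.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / n))

as_epoch_set <- function(x) {
  if (inherits(x, "epoch_set")) return(x)
  if (inherits(x, "multichannel_recording"))
    return(epoch_set(list(x$data), x$fs, x$channels, nrow(x$data) / x$fs))
  stop("expected an epoch_set or multichannel_recording")
}

# Short-time Fourier blocks across all epochs: Hann-windowed segments of
# nperseg samples with fractional overlap, one-sided frequency grid.
# Returns the complex block spectra per channel plus the PSD scale factor.
welch_blocks <- function(epochs, nperseg, overlap_frac) {
  epochs <- as_epoch_set(epochs)
  fs <- epochs$fs
  len <- nrow(epochs$epochs[[1L]])
  if (len < nperseg)
    stop(sprintf("epoch length (%d) shorter than nperseg (%d)", len, nperseg))
  step <- max(1L, as.integer(round(nperseg * (1 - overlap_frac))))
  starts <- seq(1L, len - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  nch <- length(epochs$channels)
  nfreq <- nperseg %/% 2L + 1L
  blocks <- lapply(seq_len(nch), function(j) {
    segs <- do.call(cbind, lapply(epochs$epochs, function(e)
      vapply(starts, function(s) e[s:(s + nperseg - 1L), j] * w,
             numeric(nperseg))))
    stats::mvfft(segs)[seq_len(nfreq), , drop = FALSE]
  })
  list(blocks = blocks, freqs = (0:(nfreq - 1L)) * fs / nperseg,
       n_blocks = ncol(blocks[[1L]]), scale = 1 / (fs * sum(w^2)),
       fs = fs, nperseg = nperseg, channels = epochs$channels)
}

# one-sided correction: double every bin except DC and Nyquist
onesided_factor <- function(nfreq, nperseg) {
  fac <- rep(2, nfreq)
  fac[1L] <- 1
  if (nperseg %% 2L == 0L) fac[nfreq] <- 1
  fac
}

#' Welch power spectral density
#'
#' Averaged modified periodograms (Hann window) over all blocks of all
#' epochs.  With `fs = 512` and the default 512-sample blocks the
#' frequency resolution is exactly 1.0 Hz.
#'
#' @param epochs an [epoch_set()] (or a [multichannel_recording()],
#'   treated as a single epoch).
#' @param nperseg block size in samples.
#' @param overlap_frac fractional overlap between consecutive blocks
#'   (default 0.5).
#' @return An object of class `power_spectrum`: `freqs` (Hz), `power`
#'   (density matrix, frequency x channel, units^2/Hz), `nperseg`,
#'   `n_blocks`, `fs`, `channels`.
#' @export
welch_psd <- function(epochs, nperseg = 512, overlap_frac = 0.5) {
  wb <- welch_blocks(epochs, nperseg, overlap_frac)
  fac <- onesided_factor(length(wb$freqs), wb$nperseg)
  power <- vapply(wb$blocks, function(B)
    rowMeans(Mod(B)^2) * wb$scale * fac, numeric(length(wb$freqs)))
  colnames(power) <- wb$channels
  structure(list(freqs = wb$freqs, power = power, nperseg = wb$nperseg,
                 n_blocks = wb$n_blocks, fs = wb$fs, channels = wb$channels),
            class = "power_spectrum")
}

band_bins <- function(freqs, band, closed = FALSE) {
  if (closed) which(freqs >= band[1L] & freqs <= band[2L])
  else which(freqs >= band[1L] & freqs < band[2L])
}

#' Relative power spectrum
#'
#' Expresses power in each bin as a fraction of the total power over the
#' normalization band (1-256 Hz by default), per channel.  Band edges are
#' half-open `[lo, hi)` throughout the package so adjacent bands tile
#' without double counting.
#'
#' @param ps a [welch_psd()] result.
#' @param norm_band two-element numeric, normalization band in Hz.
#' @return An object of class `relative_power_spectrum` with `freqs`,
#'   `relpower` (fractions), `norm_band`, `channels`.
#' @export
relative_power <- function(ps, norm_band = c(1, 256)) {
  stopifnot(inherits(ps, "power_spectrum"))
  bins <- band_bins(ps$freqs, norm_band)
  if (length(bins) == 0L) stop("normalization band outside the frequency grid")
  tot <- colSums(ps$power[bins, , drop = FALSE])
  if (any(tot <= 0)) stop("zero total power in the normalization band")
  relp <- sweep(ps$power, 2L, tot, "/")
  structure(list(freqs = ps$freqs, relpower = relp, norm_band = norm_band,
                 channels = ps$channels),
            class = "relative_power_spectrum")
}

#' Band-summed relative power
#'
#' Sum of relative power over bins with `band[1] <= f < band[2]`.
#'
#' @param rel a [relative_power()] result.
#' @param band two-element numeric (Hz).
#' @return Named numeric vector, one fraction per channel.
#' @export
band_power <- function(rel, band) {
  stopifnot(inherits(rel, "relative_power_spectrum"))
  bins <- band_bins(rel$freqs, band)
  if (length(bins) == 0L) stop("empty frequency band")
  colSums(rel$relpower[bins, , drop = FALSE])
}

#' Center of mass of the theta band
#'
#' Power-weighted mean frequency over the (closed) theta band, the
#' statistic used to quantify leftward/rightward shifts of the theta peak.
#'
#' @param ps a [welch_psd()] result.
#' @param band two-element numeric (Hz), default 4-12 (rodent hippocampal
#'   theta).
#' @return Named numeric vector of center-of-mass frequencies (Hz) per
#'   channel.
#' @export
theta_center_of_mass <- function(ps, band = c(4, 12)) {
  stopifnot(inherits(ps, "power_spectrum"))
  bins <- band_bins(ps$freqs, band, closed = TRUE)
  if (length(bins) == 0L) stop("empty frequency band")
  P <- ps$power[bins, , drop = FALSE]
  tot <- colSums(P)
  if (any(tot <= 0)) stop("zero power in the theta band")
  colSums(P * ps$freqs[bins]) / tot
}

#' Cross-spectral matrix
#'
#' Welch estimate of the full matrix of auto- and cross-spectra between
#' all channel pairs; the parent object of coherence, partial coherence
#' and the coherence network.
#'
#' @inheritParams welch_psd
#' @return An object of class `spectral_matrix`: `freqs`, `S` (complex
#'   array, channel x channel x frequency, Hermitian at every frequency
#'   with real non-negative diagonal), `n_blocks`, `channels`, `fs`.
#' @export
cross_spectral_matrix <- function(epochs, nperseg = 512, overlap_frac = 0.5) {
  wb <- welch_blocks(epochs, nperseg, overlap_frac)
  nch <- length(wb$channels)
  if (nch < 2L) stop("cross-spectral matrix requires at least 2 channels")
  if (wb$n_blocks < 2L)
    stop("at least 2 Welch blocks are required: coherence estimated from a single block is identically 1; use longer recordings or more epochs")
  nfreq <- length(wb$freqs)
  fac <- onesided_factor(nfreq, wb$nperseg)
  S <- array(0i, dim = c(nch, nch, nfreq))
  for (i in seq_len(nch)) {
    for (j in i:nch) {
      sij <- rowMeans(wb$blocks[[i]] * Conj(wb$blocks[[j]])) * wb$scale * fac
      S[i, j, ] <- sij
      if (j > i) S[j, i, ] <- Conj(sij)
    }
  }
  dimnames(S) <- list(wb$channels, wb$channels, NULL)
  structure(list(freqs = wb$freqs, S = S, n_blocks = wb$n_blocks,
                 channels = wb$channels, fs = wb$fs),
            class = "spectral_matrix")
}
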