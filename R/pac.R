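# Phase-amplitude coupling: modulation index, comodulograms,
# phase-binned amplitude curves, and the PAC phase shift.
#
# The modulation index used here is the normalized mean-vector length
#   MI = | < A_H(t) * exp(i * phi_L(t)) > | / < A_H(t) >,
# i.e. the modulus of the time-averaged complex signal z(t), divided by
# the mean envelope so that MI is dimensionless in [0, 1] and invariant
# under rescaling of the amplitude channel.  For an envelope
# A = 1 + m*cos(phi) the population value is exactly m/2.

get_channel <- function(rec, label) {
  stopifnot(inherits(rec, "multichannel_recording"))
  j <- match(label, rec$channels)
  if (is.na(j)) stop(sprintf("channel '%s' not present", label))
  rec$data[, j]
}

# default half-width of the amplitude band around f_H: wide enough to
# pass the modulation sidebands at f_H +/- f_L
amp_halfwidth_default <- function(f_phase) max(5, f_phase + 2)

# Cache of two-pass FIR frequency responses restricted to the band's
# spectral support (filter design and padded FFT are identical across
# animals and replicates for a fixed grid, so they are computed once).
.fir_cache <- new.env(parent = emptyenv())

fir_band_response <- function(f_lo, f_hi, fs, N) {
  key <- sprintf("%.6g|%.6g|%.6g|%d", f_lo, f_hi, fs, N)
  ent <- .fir_cache[[key]]
  if (!is.null(ent)) return(ent)
  b <- fir_bandpass_taps(f_lo, f_hi, fs)
  L <- length(b)
  trans <- min(2, f_hi - f_lo)
  k0 <- as.integer(max(2, floor((f_lo - 2 * trans) * N / fs) + 1))
  k1 <- as.integer(min(N %/% 2, ceiling((f_hi + 2 * trans) * N / fs) + 1))
  bf <- fft(c(b, rep(0, N - L)))[k0:k1]
  # two passes squared, delay compensation folded in as a phase ramp
  ent <- list(w = bf^2 * exp(2i * pi * ((k0:k1) - 1) * (L - 1) / N),
              k0 = k0, k1 = k1, L = L)
  if (length(ls(.fir_cache)) > 600L)
    rm(list = ls(.fir_cache), envir = .fir_cache)
  .fir_cache[[key]] <- ent
  ent
}

# Decimated analytic band signal: inverse FFT over the band's support
# only, aliased onto a grid of M = N/d points, giving z at sample times
# 1, 1+d, 1+2d, ... at a fraction of the full-length transform cost.
band_analytic_dec <- function(xf, N, fs, ent, M, nd) {
  Y <- 2 * xf[ent$k0:ent$k1] * ent$w
  Yf <- complex(length.out = M)
  idx <- ((ent$k0:ent$k1) - 1L) %% M + 1L
  Yf[idx] <- Yf[idx] + Y
  z <- fft(Yf, inverse = TRUE) / N
  z[seq_len(nd)]
}

#' Modulation index of phase-amplitude coupling
#'
#' Normalized mean-vector-length MI between a phase series (slow
#' oscillation) and an amplitude-envelope series (fast oscillation).
#' Edge-transient guard samples of both series are trimmed before
#' averaging.
#'
#' @param phase_series an [analytic()] series supplying `phase`.
#' @param amp_series an [analytic()] series supplying `amplitude`; must
#'   have the same length and sampling rate.
#' @return MI scalar in `[0, 1]`.
#' @export
modulation_index <- function(phase_series, amp_series) {
  stopifnot(inherits(phase_series, "analytic_series"),
            inherits(amp_series, "analytic_series"))
  n <- length(phase_series$phase)
  if (length(amp_series$amplitude) != n)
    stop("phase and amplitude series have different lengths")
  g <- max(phase_series$guard_n, amp_series$guard_n)
  if (2L * g >= n) stop("series too short after transient trimming")
  idx <- (g + 1L):(n - g)
  A <- amp_series$amplitude[idx]
  mA <- mean(A)
  if (mA <= 0) stop("zero amplitude envelope")
  Mod(mean(A * exp(1i * phase_series$phase[idx]))) / mA
}

# MI from precomputed phase/envelope vectors over a set of sample
# windows.  "pooled": one mean vector over all window samples (lowest
# noise floor; the default).  "per_epoch": MI per window, averaged --
# mirrors per-epoch analysis but carries each window's |.| noise floor
# into the average, which matters for short windows.
mi_windowed <- function(phi, A, windows, mode = "pooled") {
  if (mode == "pooled") {
    idx <- unlist(lapply(windows, function(w) w[1L]:w[2L]))
    return(Mod(mean(A[idx] * exp(1i * phi[idx]))) / mean(A[idx]))
  }
  vals <- vapply(windows, function(w) {
    idx <- w[1L]:w[2L]
    a <- A[idx]
    Mod(mean(a * exp(1i * phi[idx]))) / mean(a)
  }, numeric(1L))
  mean(vals)
}

#' Comodulogram of phase-amplitude coupling
#'
#' MI over a grid of phase frequencies (default 2-12 Hz, step 2) and
#' amplitude frequencies (default 10-200 Hz, step 5).  The phase and
#' amplitude sources may be the same channel (intrasite PAC) or different
#' channels (intersite PAC).  Filtering is performed on the continuous
#' signal; MI is then computed per analysis window (per epoch when
#' `windows` is supplied) and averaged.
#'
#' @param rec a [multichannel_recording()], typically notch-filtered.
#' @param phase_channel,amp_channel channel labels.
#' @param phase_grid,amp_grid frequency grids in Hz, strictly inside
#'   `(0, fs/2)` after band widening.
#' @param phase_halfwidth half-width of the phase band (Hz).
#' @param amp_halfwidth_rule function of the phase frequency giving the
#'   amplitude-band half-width (default `max(5, f_L + 2)`, passing the
#'   modulation sidebands at `f_H +/- f_L`).
#' @param windows optional list of `c(start, end)` sample ranges (e.g.
#'   retained artifact-free epochs) entering the MI; defaults to the
#'   whole guard-trimmed recording.
#' @param epoch_mode `"pooled"` computes one mean vector over all
#'   window samples; `"per_epoch"` computes MI per window and averages.
#' @return An object of class `comodulogram`: `phase_freqs`, `amp_freqs`,
#'   `mi` (matrix, phase x amplitude), `phase_channel`, `amp_channel`.
#' @export
comodulogram <- function(rec, phase_channel, amp_channel = phase_channel,
                         phase_grid = seq(2, 12, by = 2),
                         amp_grid = seq(10, 200, by = 5),
                         phase_halfwidth = 1,
                         amp_halfwidth_rule = amp_halfwidth_default,
                         windows = NULL,
                         epoch_mode = c("pooled", "per_epoch")) {
  epoch_mode <- match.arg(epoch_mode)
  fs <- rec$fs
  hw_max <- max(vapply(phase_grid, amp_halfwidth_rule, numeric(1L)))
  if (max(amp_grid) + hw_max >= fs / 2 || min(phase_grid) - phase_halfwidth <= 0)
    stop("frequency grid (after band widening) outside (0, Nyquist)")
  xp <- get_channel(rec, phase_channel)
  xa <- get_channel(rec, amp_channel)
  n <- length(xp)
  Lmax <- ceiling(3.3 * fs / min(2, 2 * phase_halfwidth)) + 2L
  N <- next_pow2(n + 2L * Lmax)
  xf_p <- fft(c(xp, rep(0, N - n)))
  xf_a <- if (identical(phase_channel, amp_channel)) xf_p
          else fft(c(xa, rep(0, N - n)))
  # frequency responses for every band in the grid (cached across calls)
  ents_p <- lapply(phase_grid, function(fl)
    fir_band_response(fl - phase_halfwidth, fl + phase_halfwidth, fs, N))
  # amplitude-band low edge clamped to 1 Hz: at the bottom of the grid
  # (f_H near 10 Hz) the sideband-wide band would otherwise cross 0
  ents_a <- lapply(seq_along(phase_grid), function(i) {
    hw <- amp_halfwidth_rule(phase_grid[i])
    lapply(amp_grid, function(fh)
      fir_band_response(max(fh - hw, 1), fh + hw, fs, N))
  })
  # common decimation so phase and amplitude series share sample times
  max_sup <- max(vapply(c(ents_p, unlist(ents_a, recursive = FALSE)),
                        function(e) e$k1 - e$k0 + 1L, integer(1L)))
  M <- min(N, next_pow2(2L * max_sup))
  d <- N %/% M
  nd <- (n - 1L) %/% d + 1L
  mi <- matrix(NA_real_, length(phase_grid), length(amp_grid),
               dimnames = list(phase_grid, amp_grid))
  for (i in seq_along(phase_grid)) {
    zp <- band_analytic_dec(xf_p, N, fs, ents_p[[i]], M, nd)
    phi <- Arg(zp)
    for (j in seq_along(amp_grid)) {
      ent_a <- ents_a[[i]][[j]]
      za <- band_analytic_dec(xf_a, N, fs, ent_a, M, nd)
      g <- 2L * max(ents_p[[i]]$L, ent_a$L)    # transient guard, full-rate samples
      if (2L * g >= n) stop("recording too short for the PAC filter lengths")
      win <- if (is.null(windows)) list(c(g + 1L, n - g))
             else lapply(windows, function(w)
               c(max(w[1L], g + 1L), min(w[2L], n - g)))
      win <- Filter(function(w) w[2L] - w[1L] > fs, win)
      if (length(win) == 0L) stop("no analysis window survives transient trimming")
      win_d <- lapply(win, function(w)
        c((w[1L] - 1L) %/% d + 1L, (w[2L] - 1L) %/% d + 1L))
      mi[i, j] <- mi_windowed(phi, Mod(za), win_d, epoch_mode)
    }
  }
  structure(list(phase_freqs = phase_grid, amp_freqs = amp_grid, mi = mi,
                 phase_channel = phase_channel, amp_channel = amp_channel),
            class = "comodulogram")
}

#' Mean PAC over a comodulogram window
#'
#' Unweighted mean of MI over grid cells whose centers lie inside both
#' the phase and amplitude windows (bounds inclusive).  The defaults are
#' the theta-gamma windows used for intrasite PAC summaries
#' (phase 3.5-12.5 Hz, amplitude 32-100 Hz).
#'
#' @param cmg a [comodulogram()].
#' @param phase_window,amp_window two-element numeric windows (Hz).
#' @return Mean MI scalar.
#' @export
mean_pac <- function(cmg, phase_window = c(3.5, 12.5),
                     amp_window = c(32, 100)) {
  stopifnot(inherits(cmg, "comodulogram"))
  pi_ <- cmg$phase_freqs >= phase_window[1L] & cmg$phase_freqs <= phase_window[2L]
  ai <- cmg$amp_freqs >= amp_window[1L] & cmg$amp_freqs <= amp_window[2L]
  if (!any(pi_) || !any(ai)) stop("window selects no comodulogram cells")
  mean(cmg$mi[pi_, ai])
}

#' Phase-binned amplitude curve
#'
#' Sorts the fast-oscillation envelope by the slow-oscillation phase and
#' averages it within equal-width phase bins over `[-pi, pi)` -- the
#' "amplitude vs. phase" curve whose depth of modulation tracks MI and
#' whose peak location defines the PAC phase shift.  Six bins of width
#' 2*pi/6 (about 1 radian) are used by default; exactly 1-radian bins
#' cannot tile the circle.
#'
#' @param phase_series,amp_series aligned [analytic()] series.
#' @param n_bins number of phase bins (>= 3).
#' @return An object of class `phase_amplitude_curve`: `bin_centers`
#'   (radians), `mean_amp`, `n_per_bin`.
#' @export
phase_amplitude_curve <- function(phase_series, amp_series, n_bins = 6) {
  stopifnot(inherits(phase_series, "analytic_series"),
            inherits(amp_series, "analytic_series"))
  if (n_bins < 3L) stop("n_bins must be at least 3")
  n <- length(phase_series$phase)
  if (length(amp_series$amplitude) != n)
    stop("phase and amplitude series have different lengths")
  g <- max(phase_series$guard_n, amp_series$guard_n)
  if (2L * g >= n) stop("series too short after transient trimming")
  idx <- (g + 1L):(n - g)
  phi <- phase_series$phase[idx]
  A <- amp_series$amplitude[idx]
  width <- 2 * pi / n_bins
  bin <- pmin(floor((phi + pi) / width) + 1L, n_bins)
  n_per_bin <- tabulate(bin, nbins = n_bins)
  if (any(n_per_bin == 0L) && length(idx) >= 100L * n_bins)
    warning("empty phase bin despite ample samples; check the phase band")
  mean_amp <- vapply(seq_len(n_bins), function(b)
    if (n_per_bin[b] > 0L) mean(A[bin == b]) else NA_real_, numeric(1L))
  structure(list(bin_centers = -pi + (seq_len(n_bins) - 0.5) * width,
                 mean_amp = mean_amp, n_per_bin = n_per_bin),
            class = "phase_amplitude_curve")
}

#' PAC phase shift of a phase-amplitude curve
#'
#' Circular first moment of the binned amplitude curve: the angle of
#' `sum_b mean_amp(b) * exp(i * center(b))` locates the preferred phase,
#' and the normalized modulus (resultant length) quantifies how peaked
#' the curve is.  A near-flat curve yields a resultant near 0 and is
#' flagged as degenerate (the angle is then unreliable).
#'
#' @param curve a [phase_amplitude_curve()].
#' @return An object of class `pac_phase_shift`: `angle` (radians in
#'   `[-pi, pi)`), `resultant_length` in `[0, 1]`, `degenerate` flag.
#' @export
pac_phase_shift <- function(curve) {
  stopifnot(inherits(curve, "phase_amplitude_curve"))
  ok <- !is.na(curve$mean_amp)
  if (sum(ok) < 3L) stop("need at least 3 non-empty phase bins")
  amp <- curve$mean_amp[ok]
  if (all(amp == 0)) stop("all-zero amplitude curve")
  z <- sum(amp * exp(1i * curve$bin_centers[ok]))
  r <- Mod(z) / sum(amp)
  ang <- Arg(z)
  if (ang >= pi) ang <- -pi
  structure(list(angle = ang, resultant_length = r, degenerate = r < 0.01),
            class = "pac_phase_shift")
}
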