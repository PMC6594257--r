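# Multivariate autoregressive modelling and generalized ("extended")
# partial directed coherence.
#
# An MVAR(p) model  x_t = sum_k A_k x_{t-k} + e_t,  cov(e) = Sigma,
# is fitted by multi-epoch least squares with BIC order selection.  The
# frequency-domain coefficient matrix
#   Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs)
# yields the noise-variance-weighted PDC from source channel j to sink i:
#   pdc[i,j](f) = (|Abar_ij(f)| / s_i) / sqrt(sum_k |Abar_kj(f)|^2 / s_k^2)
# with s_i = sqrt(Sigma_ii); squared entries sum to 1 down each source
# column at every frequency.

#' Construct an MVAR model object
#'
#' @param A list of lag coefficient matrices `A_1 .. A_p` (n x n each).
#' @param Sigma innovation covariance (n x n, symmetric positive
#'   definite).
#' @param fs sampling rate of the modelled data (Hz).
#' @param channels optional channel labels.
#' @return An object of class `mvar_model`.
#' @export
mvar_model <- function(A, Sigma, fs, channels = NULL) {
  if (!is.list(A) || length(A) < 1L) stop("'A' must be a non-empty list")
  n <- nrow(A[[1L]])
  ok <- vapply(A, function(a) is.matrix(a) && all(dim(a) == n), logical(1L))
  if (!all(ok)) stop("all lag matrices must be square of equal dimension")
  if (!isTRUE(all.equal(Sigma, t(Sigma), tolerance = 1e-8)) ||
      any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("'Sigma' must be symmetric positive definite")
  if (is.null(channels)) channels <- paste0("ch", seq_len(n))
  m <- structure(list(order = length(A), A = A, Sigma = Sigma, fs = fs,
                      channels = channels),
                 class = "mvar_model")
  m
}

#' Stability of an MVAR model
#'
#' Spectral radius of the companion matrix; the model is (strictly)
#' stable iff it is below 1.
#'
#' @param m an [mvar_model()] (or list of lag matrices).
#' @return The spectral radius.
#' @export
mvar_spectral_radius <- function(m) {
  A <- if (inherits(m, "mvar_model")) m$A else m
  n <- nrow(A[[1L]])
  p <- length(A)
  comp <- matrix(0, n * p, n * p)
  comp[seq_len(n), ] <- do.call(cbind, A)
  if (p > 1L)
    comp[(n + 1L):(n * p), seq_len(n * (p - 1L))] <- diag(n * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# least-squares fit at a fixed order over a list of epoch matrices
mvar_ls <- function(epochs, p) {
  n <- ncol(epochs[[1L]])
  XY <- lapply(epochs, function(e) {
    e <- scale(e, center = TRUE, scale = FALSE)
    Tlen <- nrow(e)
    if (Tlen <= p + n * p) return(NULL)
    Y <- e[(p + 1L):Tlen, , drop = FALSE]
    X <- do.call(cbind, lapply(seq_len(p), function(k)
      e[(p + 1L - k):(Tlen - k), , drop = FALSE]))
    list(X = X, Y = Y)
  })
  XY <- Filter(Negate(is.null), XY)
  if (length(XY) == 0L) stop("epochs too short for the requested order")
  X <- do.call(rbind, lapply(XY, `[[`, "X"))
  Y <- do.call(rbind, lapply(XY, `[[`, "Y"))
  B <- tryCatch(solve(crossprod(X), crossprod(X, Y)),
                error = function(e) stop("singular regressor matrix in MVAR fit"))
  E <- Y - X %*% B
  nobs <- nrow(Y)
  Sigma <- crossprod(E) / (nobs - n * p)
  A <- lapply(seq_len(p), function(k)
    t(B[((k - 1L) * n + 1L):(k * n), , drop = FALSE]))
  list(A = A, Sigma = Sigma, nobs = nobs,
       bic = nobs * determinant(Sigma, logarithm = TRUE)$modulus[1L] +
         log(nobs) * p * n * n)
}

#' Fit an MVAR model to epoched data
#'
#' Multi-epoch least squares (each epoch demeaned and regressed
#' separately, normal equations pooled) with the order selected by BIC
#' over `1..max_order`.
#'
#' @param epochs an [epoch_set()] or [multichannel_recording()].
#' @param max_order largest candidate order (lags).
#' @param order optional fixed order, bypassing selection.
#' @return An [mvar_model()] with extra fields `bic` (per candidate
#'   order) and `nobs`.
#' @export
fit_mvar <- function(epochs, max_order = 20, order = NULL) {
  epochs <- as_epoch_set(epochs)
  n <- length(epochs$channels)
  if (!is.null(order)) {
    fits <- list(mvar_ls(epochs$epochs, order))
    best <- 1L
    orders <- order
  } else {
    orders <- seq_len(max_order)
    fits <- lapply(orders, function(p) mvar_ls(epochs$epochs, p))
    best <- which.min(vapply(fits, `[[`, numeric(1L), "bic"))
  }
  f <- fits[[best]]
  m <- mvar_model(f$A, (f$Sigma + t(f$Sigma)) / 2, epochs$fs, epochs$channels)
  sr <- mvar_spectral_radius(m)
  if (sr >= 1)
    stop(sprintf("unstable MVAR fit (spectral radius %.3f); consider detrending or a shorter order", sr))
  m$bic <- stats::setNames(vapply(fits, `[[`, numeric(1L), "bic"), orders)
  m$nobs <- f$nobs
  m
}

# Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs), for a vector of
# frequencies; returns n x n x nfreq complex array
mvar_abar <- function(m, freqs) {
  n <- nrow(m$A[[1L]])
  out <- array(0i, dim = c(n, n, length(freqs)))
  for (k in seq_along(freqs)) {
    Ab <- diag(n) + 0i
    for (lag in seq_len(m$order))
      Ab <- Ab - m$A[[lag]] * exp(-2i * pi * freqs[k] * lag / m$fs)
    out[, , k] <- Ab
  }
  out
}

#' Extended (generalized) partial directed coherence
#'
#' Noise-variance-weighted PDC from an MVAR model: directed coupling
#' strength from each source channel to each sink channel as a function
#' of frequency, normalized so the squared entries of each source column
#' sum to 1.  Paths through other recorded channels do not contribute
#' (the measure is built from the direct coefficients only).
#'
#' @param m an [mvar_model()].
#' @param freqs frequency grid in Hz (default 0 to Nyquist in steps of
#'   `fs/512`).
#' @param weighted if `FALSE`, compute the classic (unweighted) PDC
#'   instead of the noise-variance-weighted form.
#' @return An object of class `directed_coherence`: `freqs`, `pdc`
#'   (array sink x source x frequency, entries in `[0, 1]`), `channels`.
#' @export
extended_pdc <- function(m, freqs = NULL, weighted = TRUE) {
  stopifnot(inherits(m, "mvar_model"))
  if (is.null(freqs)) freqs <- seq(0, m$fs / 2, by = m$fs / 512)
  s2 <- diag(m$Sigma)
  if (any(s2 <= 0)) stop("singular innovation covariance")
  wts <- if (weighted) 1 / s2 else rep(1, length(s2))
  Ab <- mvar_abar(m, freqs)
  n <- dim(Ab)[1L]
  pdc <- array(0, dim = dim(Ab),
               dimnames = list(m$channels, m$channels, NULL))
  for (k in seq_along(freqs)) {
    num <- sqrt(wts) * Mod(Ab[, , k])          # rows scaled by 1/s_i
    den <- sqrt(colSums(num^2))                # per source column
    pdc[, , k] <- sweep(num, 2L, den, "/")
  }
  structure(list(freqs = freqs, pdc = pdc, channels = m$channels,
                 weighted = weighted),
            class = "directed_coherence")
}

#' Band-mean directed coherence
#'
#' Mean PDC from `source` to `sink` over a half-open frequency band.
#'
#' @param d an [extended_pdc()] result.
#' @param band two-element numeric (Hz).
#' @param source,sink channel labels.
#' @return scalar mean PDC.
#' @export
band_mean_pdc <- function(d, band, source, sink) {
  stopifnot(inherits(d, "directed_coherence"))
  bins <- band_bins(d$freqs, band)
  if (length(bins) == 0L) stop("empty frequency band")
  i <- match(sink, d$channels)
  j <- match(source, d$channels)
  if (is.na(i) || is.na(j)) stop("unknown source or sink channel")
  mean(d$pdc[i, j, bins])
}
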