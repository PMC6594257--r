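# Coherence, partial coherence and global coherent-network efficiency.

chan_index <- function(S, label) {
  j <- match(label, S$channels)
  if (is.na(j)) stop(sprintf("channel '%s' not present", label))
  j
}

#' Magnitude-squared coherence between two channels
#'
#' `Coh(f) = |S_AB(f)|^2 / (S_AA(f) S_BB(f))` from a Welch cross-spectral
#' matrix; values in `[0, 1]`, with `Coh = 1` for a channel with itself.
#'
#' @param S a [cross_spectral_matrix()].
#' @param A,B channel labels.
#' @return An object of class `coherence_function`: `freqs`, `coh`,
#'   `pair`.
#' @export
coherence <- function(S, A, B) {
  stopifnot(inherits(S, "spectral_matrix"))
  a <- chan_index(S, A); b <- chan_index(S, B)
  saa <- Re(S$S[a, a, ]); sbb <- Re(S$S[b, b, ])
  bad <- which(saa <= 0 | sbb <= 0)
  if (length(bad) > 0L)
    stop(sprintf("zero autospectrum at f = %g Hz", S$freqs[bad[1L]]))
  coh <- Mod(S$S[a, b, ])^2 / (saa * sbb)
  coh <- pmin(coh, 1)
  structure(list(freqs = S$freqs, coh = coh, pair = c(A, B)),
            class = "coherence_function")
}

#' Coherence graph over a frequency band
#'
#' Builds the electrode network whose edge weights are band-mean
#' coherence values between all channel pairs.
#'
#' @param S a [cross_spectral_matrix()].
#' @param band two-element numeric band in Hz (half-open `[lo, hi)`).
#' @return An object of class `coherence_graph`: `nodes`, `weights`
#'   (symmetric matrix, unit diagonal, off-diagonal in `[0, 1]`), `band`.
#' @export
coherence_graph <- function(S, band) {
  stopifnot(inherits(S, "spectral_matrix"))
  bins <- band_bins(S$freqs, band)
  if (length(bins) == 0L) stop("empty frequency band")
  nch <- length(S$channels)
  W <- diag(1, nch)
  for (i in seq_len(nch - 1L)) {
    for (j in (i + 1L):nch) {
      cf <- coherence(S, S$channels[i], S$channels[j])
      W[i, j] <- W[j, i] <- mean(cf$coh[bins])
    }
  }
  dimnames(W) <- list(S$channels, S$channels)
  structure(list(nodes = S$channels, weights = W, band = band),
            class = "coherence_graph")
}

#' Global efficiency of a coherence network
#'
#' Each edge is assigned the distance `1 / weight` (infinite for zero
#' weight, so stronger coherence means shorter distance); shortest-path
#' distances `D` are computed over all node pairs and
#' `Eglob = mean(1 / D)` over unordered pairs.  With weights in
#' `[0, 1]`, `Eglob` lies in `[0, 1]` and equals 1 for a fully coherent
#' network.
#'
#' @param g a [coherence_graph()], or a symmetric numeric weight matrix.
#' @return Eglob scalar.
#' @export
global_efficiency <- function(g) {
  W <- if (inherits(g, "coherence_graph")) g$weights else as.matrix(g)
  n <- nrow(W)
  if (n < 2L) stop("global efficiency requires at least 2 nodes")
  if (any(W < 0)) stop("weights must be non-negative")
  D <- 1 / W
  diag(D) <- 0
  gr <- igraph::graph_from_adjacency_matrix(
    ifelse(is.finite(D) & D > 0, D, 0), mode = "undirected",
    weighted = TRUE, diag = FALSE)
  dist <- igraph::distances(gr, algorithm = "dijkstra")
  iu <- upper.tri(dist)
  mean(1 / dist[iu])
}

#' Partial coherence between two channels
#'
#' Coherence between `A` and `B` after removing the linear contribution
#' of every other recorded channel, computed from minors of the spectral
#' matrix: `|M_AB(f)| / sqrt(M_AA(f) * M_BB(f))`, where `M_AB` is the
#' determinant of `S(f)` with the A-th row and B-th column removed.
#' Frequencies where the spectral matrix is numerically singular
#' (condition number above `cond_max`) are masked with `NA` and a
#' warning.
#'
#' @param S a [cross_spectral_matrix()] with at least 2 channels (3+ for
#'   a result distinct from ordinary coherence).
#' @param A,B channel labels.
#' @param cond_max condition-number threshold for masking.
#' @return An object of class `coherence_function` (`coh` holds partial
#'   coherence, in `[0, 1]`).
#' @export
partial_coherence <- function(S, A, B, cond_max = 1e10) {
  stopifnot(inherits(S, "spectral_matrix"))
  a <- chan_index(S, A); b <- chan_index(S, B)
  if (a == b) stop("partial coherence requires two distinct channels")
  nfreq <- length(S$freqs)
  out <- numeric(nfreq)
  masked <- FALSE
  for (k in seq_len(nfreq)) {
    Sf <- S$S[, , k]
    sv <- svd(Sf, nu = 0, nv = 0)$d
    if (sv[length(sv)] <= 0 || sv[1L] / sv[length(sv)] > cond_max) {
      out[k] <- NA_real_
      masked <- TRUE
      next
    }
    mab <- Mod(det_complex(Sf[-a, -b, drop = FALSE]))
    maa <- Re(det_complex(Sf[-a, -a, drop = FALSE]))
    mbb <- Re(det_complex(Sf[-b, -b, drop = FALSE]))
    out[k] <- if (maa > 0 && mbb > 0) min(mab / sqrt(maa * mbb), 1) else NA_real_
  }
  if (masked)
    warning("near-singular spectral matrix: partial coherence masked at some frequencies")
  structure(list(freqs = S$freqs, coh = out, pair = c(A, B)),
            class = "coherence_function")
}

# determinant of a (small) complex matrix via LU with partial pivoting;
# base::det is real-only
det_complex <- function(M) {
  n <- nrow(M)
  if (n == 0L) return(1 + 0i)
  if (n == 1L) return(M[1L, 1L])
  d <- 1 + 0i
  A <- M
  for (k in seq_len(n - 1L)) {
    p <- which.max(Mod(A[k:n, k])) + k - 1L
    if (Mod(A[p, k]) == 0) return(0 + 0i)
    if (p != k) {
      tmp <- A[k, ]; A[k, ] <- A[p, ]; A[p, ] <- tmp
      d <- -d
    }
    d <- d * A[k, k]
    rows <- (k + 1L):n
    A[rows, ] <- A[rows, , drop = FALSE] -
      outer(A[rows, k] / A[k, k], A[k, ])
  }
  d * A[n, n]
}

#' Band-mean coherence
#'
#' Mean of a coherence (or partial-coherence) function over a half-open
#' frequency band.
#'
#' @param cf a [coherence()] / [partial_coherence()] result.
#' @param band two-element numeric (Hz).
#' @return scalar mean coherence (`NA` frequencies dropped).
#' @export
band_mean_coherence <- function(cf, band) {
  stopifnot(inherits(cf, "coherence_function"))
  bins <- band_bins(cf$freqs, band)
  if (length(bins) == 0L) stop("empty frequency band")
  mean(cf$coh[bins], na.rm = TRUE)
}
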