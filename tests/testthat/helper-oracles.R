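# Shared fixtures and independent oracles used across test files.

# exhaustive global-efficiency oracle: enumerate every simple path
# between each node pair and take the minimum total distance
brute_global_efficiency <- function(W) {
  n <- nrow(W)
  D <- 1 / W
  diag(D) <- 0
  shortest <- function(i, j) {
    best <- Inf
    visit <- function(node, dist, seen) {
      if (dist >= best) return(invisible(NULL))
      if (node == j) { best <<- dist; return(invisible(NULL)) }
      for (k in seq_len(n)) {
        if (!seen[k] && is.finite(D[node, k]))
          visit(k, dist + D[node, k], `[<-`(seen, k, TRUE))
      }
    }
    visit(i, 0, `[<-`(rep(FALSE, n), i, TRUE))
    best
  }
  vals <- c()
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      vals <- c(vals, 1 / shortest(i, j))
  mean(vals)
}

# white-noise multichannel recording
white_recording <- function(duration_s, n_channels = 1, fs = 512, seed = 1,
                            channels = paste0("ch", seq_len(n_channels))) {
  set.seed(seed)
  multichannel_recording(matrix(rnorm(duration_s * fs * n_channels),
                                ncol = n_channels),
                         fs = fs, channels = channels)
}

# 3-channel chain MVAR 1 -> 2 -> 3 with a resonance near 40 Hz driving
# channel 1; no direct 1 -> 3 coupling
chain_mvar_coeffs <- function(fs = 512, f0 = 40, r = 0.9) {
  A1 <- matrix(0, 3, 3); A2 <- matrix(0, 3, 3)
  A1[1, 1] <- 2 * r * cos(2 * pi * f0 / fs); A2[1, 1] <- -r^2
  A1[2, 1] <- 0.8; A1[2, 2] <- 0.3
  A1[3, 2] <- 0.8; A1[3, 3] <- 0.3
  list(A1, A2)
}
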