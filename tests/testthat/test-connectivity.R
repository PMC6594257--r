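fs <- 512

shared_spectral_matrix <- function(g = 1, duration = 120, seed = 1) {
  pair <- gen_coupled_pair(fs, duration, shared_gain = g, seed = seed)
  rec <- multichannel_recording(pair, fs = fs)
  cross_spectral_matrix(slice_epochs(rec, 4))
}

test_that("coherence matches the shared-signal closed form", {
  S <- shared_spectral_matrix(g = 1)
  expect_gte(S$n_blocks, 200)
  cf <- coherence(S, "x", "y")
  expect_true(all(cf$coh >= 0 & cf$coh <= 1))
  expect_equal(mean(cf$coh), 0.25, tolerance = 0.05)
  expect_equal(coherence(S, "x", "x")$coh, rep(1, length(S$freqs)))
  # symmetry and per-channel gain invariance
  expect_equal(coherence(S, "y", "x")$coh, cf$coh)
  S2 <- S
  S2$S[1, , ] <- S2$S[1, , ] * 3     # x scaled by 3: S_xy and S_xx rows
  S2$S[, 1, ] <- S2$S[, 1, ] * 3
  expect_equal(coherence(S2, "x", "y")$coh, cf$coh, tolerance = 1e-12)
})

test_that("independent channels show only the 1/n_blocks coherence bias", {
  S <- cross_spectral_matrix(slice_epochs(white_recording(120, 2, seed = 2),
                                          4))
  cf <- coherence(S, "ch1", "ch2")
  expect_lt(mean(cf$coh), 0.02)
})

test_that("coherence graph is symmetric and band-consistent", {
  rec <- white_recording(60, 3, seed = 3)
  S <- cross_spectral_matrix(slice_epochs(rec, 4))
  g <- coherence_graph(S, c(4, 70))
  expect_equal(g$weights, t(g$weights))
  expect_equal(unname(diag(g$weights)), rep(1, 3))
  expect_true(all(g$weights >= 0 & g$weights <= 1))
  # full-band weight = bin-count-weighted mean of split-band weights
  g1 <- coherence_graph(S, c(4, 37))
  g2 <- coherence_graph(S, c(37, 70))
  n1 <- sum(S$freqs >= 4 & S$freqs < 37)
  n2 <- sum(S$freqs >= 37 & S$freqs < 70)
  expect_equal(g$weights, (g1$weights * n1 + g2$weights * n2) / (n1 + n2),
               tolerance = 1e-12)
  # identical channels: all weights 1
  x <- rnorm(60 * fs)
  recid <- multichannel_recording(cbind(a = x, b = x, c = x), fs = fs)
  gid <- coherence_graph(cross_spectral_matrix(slice_epochs(recid, 4)),
                         c(4, 70))
  expect_equal(unname(gid$weights), matrix(1, 3, 3), tolerance = 1e-9)
})

test_that("global efficiency matches the worked example and brute force", {
  W <- matrix(c(1, 1, 0.1,
                1, 1, 1,
                0.1, 1, 1), 3, 3)
  expect_equal(global_efficiency(W), 5 / 6)
  expect_equal(global_efficiency(matrix(1, 4, 4)), 1)
  expect_lt(global_efficiency(matrix(1e-9, 5, 5) + diag(1 - 1e-9, 5)), 1e-6)
  set.seed(4)
  for (k in 1:100) {
    n <- sample(3:5, 1)
    W <- matrix(runif(n * n), n, n)
    W[sample(length(W), 3)] <- 0       # some absent edges
    W <- (W + t(W)) / 2
    diag(W) <- 1
    expect_equal(global_efficiency(W), brute_global_efficiency(W),
                 tolerance = 1e-12)
  }
  expect_error(global_efficiency(matrix(1, 1, 1)), "at least 2 nodes")
})

test_that("partial coherence reduces to sqrt(coherence) for 2 channels", {
  S <- shared_spectral_matrix(g = 1, seed = 5)
  cf <- coherence(S, "x", "y")
  pc <- partial_coherence(S, "x", "y")
  expect_equal(pc$coh, sqrt(cf$coh), tolerance = 1e-10)
})

test_that("partial coherence removes the indirect link of a chain", {
  A <- chain_mvar_coeffs()
  X <- gen_mvar_network(A, diag(3), fs = fs, duration_s = 120, seed = 6)
  rec <- multichannel_recording(X, fs = fs, channels = c("c1", "c2", "c3"))
  S <- cross_spectral_matrix(slice_epochs(rec, 4))
  driven <- S$freqs >= 35 & S$freqs <= 45
  expect_gt(mean(coherence(S, "c1", "c3")$coh[driven]), 0.3)
  expect_lt(mean(partial_coherence(S, "c1", "c3")$coh[driven],
                 na.rm = TRUE), 0.1)
  # fully independent channels: partial coherence near zero
  Si <- cross_spectral_matrix(slice_epochs(white_recording(120, 3, seed = 7),
                                           4))
  expect_lt(mean(partial_coherence(Si, "ch1", "ch3")$coh, na.rm = TRUE), 0.1)
})

test_that("band_mean_coherence respects half-open bands", {
  S <- shared_spectral_matrix(g = 1, duration = 40, seed = 8)
  cf <- coherence(S, "x", "y")
  bins <- S$freqs >= 30 & S$freqs < 50
  expect_equal(band_mean_coherence(cf, c(30, 50)), mean(cf$coh[bins]))
  expect_error(band_mean_coherence(cf, c(400, 500)), "empty")
})
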