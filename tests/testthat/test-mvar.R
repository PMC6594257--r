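fs <- 512

biv_coeffs <- function() matrix(c(0.5, 0.5, 0, 0.5), 2, 2)

test_that("least squares recovers known MVAR(2) coefficients", {
  A <- list(matrix(c(0.4, 0.3, 0, 0.4), 2, 2),
            matrix(c(-0.2, 0, 0.1, -0.2), 2, 2))
  X <- gen_mvar_network(A, diag(2), fs = fs, duration_s = 60, seed = 1)
  rec <- multichannel_recording(X, fs = fs)
  m <- fit_mvar(slice_epochs(rec, 8), max_order = 6)
  expect_equal(m$order, 2L)
  expect_lt(sqrt(mean((m$A[[1]] - A[[1]])^2)), 0.05)
  expect_lt(sqrt(mean((m$A[[2]] - A[[2]])^2)), 0.05)
  expect_lt(max(abs(m$Sigma - diag(2))) / 1, 0.1)   # Sigma within 10%
  expect_lt(mvar_spectral_radius(m), 1)
})

test_that("white noise yields a low selected order and null coefficients", {
  rec <- white_recording(60, 3, seed = 2)
  m <- fit_mvar(slice_epochs(rec, 8), max_order = 8)
  expect_lte(m$order, 2L)
  expect_lt(max(abs(unlist(m$A))), 0.05)
})

test_that("refitting model-generated data reproduces Sigma", {
  Sigma <- matrix(c(1, 0.3, 0.3, 0.8), 2, 2)
  A <- list(biv_coeffs())
  X <- gen_mvar_network(A, Sigma, fs = fs, duration_s = 60, seed = 3)
  m <- fit_mvar(multichannel_recording(X, fs = fs), order = 1)
  expect_lt(max(abs(m$Sigma - Sigma) / max(Sigma)), 0.1)
})

test_that("extended PDC resolves direction in the bivariate worked model", {
  A1 <- biv_coeffs()
  truth <- mvar_model(list(A1), diag(2), fs = fs)
  d0 <- extended_pdc(truth, freqs = 0:100)
  expect_equal(max(d0$pdc[1, 2, ]), 0)             # no 2 -> 1 coupling
  expect_gt(min(d0$pdc[2, 1, ]), 0.1)              # 1 -> 2 present
  X <- gen_mvar_network(list(A1), diag(2), fs = fs, duration_s = 60,
                        seed = 4)
  m <- fit_mvar(multichannel_recording(X, fs = fs), max_order = 5)
  d <- extended_pdc(m, freqs = 0:100)
  expect_lt(sqrt(mean((d$pdc - d0$pdc)^2)), 0.05)
  expect_equal(band_mean_pdc(d, c(30, 50), source = "ch2", sink = "ch1"), 0,
               tolerance = 0.05)
})

test_that("PDC normalization and trivial identities hold", {
  Adiag <- list(diag(c(0.5, -0.3, 0.2)))
  d <- extended_pdc(mvar_model(Adiag, diag(3), fs = fs), freqs = 0:100)
  off <- d$pdc
  for (k in seq_len(dim(off)[3])) diag(off[, , k]) <- 0
  expect_equal(max(off), 0)                        # diagonal model
  A1 <- biv_coeffs()
  d2 <- extended_pdc(mvar_model(list(A1), diag(c(1, 4)), fs = fs),
                     freqs = 0:100)
  norms <- apply(d2$pdc^2, c(2, 3), sum)
  expect_equal(unname(norms), matrix(1, 2, 101), tolerance = 1e-12)
  # constant field band mean
  expect_equal(band_mean_pdc(d2, c(30, 50), "ch1", "ch2"),
               mean(d2$pdc[2, 1, d2$freqs >= 30 & d2$freqs < 50]))
  expect_identical(sum(d2$freqs >= 30 & d2$freqs < 50), 20L)
  expect_identical(sum(d2$freqs >= 50 & d2$freqs < 100), 50L)
})

test_that("extended PDC recovers sparse random directed networks", {
  set.seed(5)
  hits <- 0L; total <- 0L
  for (k in 1:8) {
    n <- sample(4:6, 1)
    repeat {
      A1 <- diag(runif(n, 0.2, 0.4))
      edges <- which(upper.tri(A1) | lower.tri(A1))
      on <- sample(edges, n)                    # n random directed edges
      A1[on] <- 0.35 * sample(c(-1, 1), n, replace = TRUE)
      if (mvar_spectral_radius(list(A1)) < 0.95) break
    }
    X <- gen_mvar_network(list(A1), diag(n), fs = fs, duration_s = 40,
                          seed = 100 + k)
    m <- fit_mvar(multichannel_recording(X, fs = fs), order = 1)
    d <- extended_pdc(m, freqs = seq(0, 100, 2))
    est <- apply(d$pdc, c(1, 2), mean) > 0.1
    diag(est) <- FALSE
    truth <- A1 != 0
    diag(truth) <- FALSE
    hits <- hits + sum(est == truth)
    total <- total + sum(!diag(n))
  }
  expect_gte(hits / total, 0.95)
})

test_that("MVAR contract errors fire", {
  expect_error(mvar_model(list(matrix(2, 1, 1)), matrix(0, 1, 1), fs),
               "positive definite")
  expect_error(gen_mvar_network(list(matrix(1.2, 1, 1)), diag(1),
                                fs = fs, duration_s = 1), "unstable")
  rec <- white_recording(2, 2, seed = 6)
  expect_error(fit_mvar(slice_epochs(rec, 0.0625), max_order = 40),
               "too short")
})
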