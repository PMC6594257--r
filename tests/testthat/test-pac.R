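fs <- 512

mi_from_signal <- function(x, f_theta = 7.5, f_gamma = 52) {
  phs <- analytic(x, fs, f_theta, 1)
  ams <- analytic(x, fs, f_gamma, f_theta + 2)
  modulation_index(phs, ams)
}

test_that("MI equals m/2 for a modulated tone and is scale-invariant", {
  x <- as.numeric(gen_pac_channel(fs, 40, m = 0.5, snr = 25, seed = 1))
  mi <- mi_from_signal(x)
  expect_equal(mi, 0.25, tolerance = 0.02)
  expect_equal(mi_from_signal(10 * x), mi, tolerance = 1e-10)
})

test_that("MI vanishes without coupling and for uniform phase sweeps", {
  x0 <- as.numeric(gen_pac_channel(fs, 40, m = 0, snr = 25, seed = 2))
  expect_lt(mi_from_signal(x0), 0.05)
  set.seed(3)                       # independent phase and amplitude sources
  p1 <- analytic(rnorm(60 * fs), fs, 8, 1)
  a2 <- analytic(rnorm(60 * fs), fs, 52, 10)
  expect_lt(modulation_index(p1, a2), 0.05)
})

test_that("MI increases with modulation depth and tracks curve depth", {
  ms <- c(0.2, 0.5, 0.8)
  res <- vapply(seq_along(ms), function(i) {
    x <- as.numeric(gen_pac_channel(fs, 30, m = ms[i], snr = 25,
                                    seed = 10 + i))
    phs <- analytic(x, fs, 7.5, 1)
    ams <- analytic(x, fs, 52, 9.5)
    curve <- phase_amplitude_curve(phs, ams)
    c(mi = modulation_index(phs, ams),
      depth = diff(range(curve$mean_amp)))
  }, numeric(2L))
  expect_true(all(diff(res["mi", ]) > 0))
  expect_identical(order(res["mi", ]), order(res["depth", ]))
})

test_that("MI contract errors fire", {
  p1 <- analytic(rnorm(10 * fs), fs, 8, 1)
  a2 <- analytic(rnorm(11 * fs), fs, 52, 10)
  expect_error(modulation_index(p1, a2), "different lengths")
})

test_that("comodulogram peaks at the coupled cell and stays flat on noise", {
  x <- gen_pac_channel(fs, 60, f_theta = 7.5, f_gamma = 52, m = 0.5,
                       snr = 25, seed = 4)
  rec <- multichannel_recording(cbind(C = as.numeric(x)), fs = fs)
  cm <- comodulogram(rec, "C")
  peak <- which(cm$mi == max(cm$mi), arr.ind = TRUE)
  expect_true(abs(cm$phase_freqs[peak[1]] - 7.5) <= 2)
  expect_true(abs(cm$amp_freqs[peak[2]] - 52) <= 5)
  expect_true(all(cm$mi >= 0 & cm$mi <= 1))
  wn <- white_recording(60, 1, seed = 5, channels = "C")
  cmn <- comodulogram(wn, "C")
  expect_lt(max(cmn$mi), 0.05)
  expect_error(comodulogram(rec, "C", amp_grid = seq(100, 300, 5)),
               "Nyquist")
})

test_that("fast comodulogram path agrees with the direct analytic path", {
  x <- gen_pac_channel(fs, 40, m = 0.4, snr = 25, seed = 6)
  rec <- multichannel_recording(cbind(C = as.numeric(x)), fs = fs)
  cm <- comodulogram(rec, "C", phase_grid = 8, amp_grid = c(50, 80))
  phs <- analytic(as.numeric(x), fs, 8, 1)
  for (fh in c(50, 80)) {
    ams <- analytic(as.numeric(x), fs, fh, 10)
    expect_lt(abs(cm$mi["8", as.character(fh)] -
                  modulation_index(phs, ams)), 0.005)
  }
})

test_that("mean_pac selects the documented window cells", {
  mi <- matrix(seq_len(6 * 39), 6, 39)
  cmg <- structure(list(phase_freqs = seq(2, 12, 2),
                        amp_freqs = seq(10, 200, 5), mi = mi,
                        phase_channel = "a", amp_channel = "a"),
                   class = "comodulogram")
  sel_p <- seq(2, 12, 2) >= 3.5 & seq(2, 12, 2) <= 12.5
  sel_a <- seq(10, 200, 5) >= 32 & seq(10, 200, 5) <= 100
  expect_identical(seq(2, 12, 2)[sel_p], c(4, 6, 8, 10, 12))
  expect_identical(seq(10, 200, 5)[sel_a], seq(35, 100, 5))
  expect_equal(mean_pac(cmg), mean(mi[sel_p, sel_a]))
  cmg$mi[] <- 0.07
  expect_equal(mean_pac(cmg), 0.07)                      # constant field
  expect_equal(mean_pac(cmg, c(6, 6), c(50, 50)), 0.07)  # singleton
  expect_error(mean_pac(cmg, c(13, 14), c(32, 100)), "no comodulogram cells")
})

test_that("phase-amplitude curve recovers a cosine modulator", {
  n <- 120 * fs
  set.seed(7)
  phi <- runif(n, -pi, pi)
  mk <- function(phase, amplitude)
    structure(list(phase = phase, amplitude = amplitude, fs = fs,
                   f_center = NA, f_halfwidth = NA, guard_n = 0L),
              class = "analytic_series")
  curve <- phase_amplitude_curve(mk(phi, 1 + 0.5 * cos(phi)),
                                 mk(phi, 1 + 0.5 * cos(phi)))
  # binned expectation: cosine attenuated by the bin-width sinc factor
  w <- 2 * pi / 6
  expected <- 1 + 0.5 * sin(w / 2) / (w / 2) * cos(curve$bin_centers)
  expect_equal(curve$mean_amp, expected, tolerance = 0.01)
  expect_lt(abs(curve$bin_centers[which.max(curve$mean_amp)]), w)
  expect_equal(sum(curve$n_per_bin), n)
  flat <- phase_amplitude_curve(mk(phi, rep(1, n)), mk(phi, rep(2, n)))
  expect_equal(diff(range(flat$mean_amp)), 0, tolerance = 1e-12)
  doubled <- phase_amplitude_curve(mk(phi, rep(1, n)),
                                   mk(phi, 2 * (1 + 0.5 * cos(phi))))
  base <- phase_amplitude_curve(mk(phi, rep(1, n)),
                                mk(phi, 1 + 0.5 * cos(phi)))
  expect_equal(doubled$mean_amp, 2 * base$mean_amp)
})

test_that("pac phase shift finds the preferred phase", {
  centers <- -pi + (seq_len(18) - 0.5) * 2 * pi / 18
  mk_curve <- function(amp)
    structure(list(bin_centers = centers, mean_amp = amp,
                   n_per_bin = rep(100L, 18)),
              class = "phase_amplitude_curve")
  s0 <- pac_phase_shift(mk_curve(1 + 0.5 * cos(centers)))
  expect_equal(s0$angle, 0, tolerance = 1e-10)
  expect_false(s0$degenerate)
  s90 <- pac_phase_shift(mk_curve(1 + 0.5 * cos(centers - pi / 2)))
  expect_equal(s90$angle, pi / 2, tolerance = 2 * pi / 18 / 2)
  flat <- pac_phase_shift(mk_curve(rep(1, 18)))
  expect_lt(flat$resultant_length, 1e-10)
  expect_true(flat$degenerate)
  expect_error(pac_phase_shift(mk_curve(rep(0, 18))), "all-zero")
})

test_that("intersite MI of independent channels is near zero", {
  rec <- white_recording(60, 2, seed = 8, channels = c("A", "B"))
  cm <- comodulogram(rec, "A", "B", phase_grid = c(6, 8),
                     amp_grid = c(50, 55))
  expect_lt(max(cm$mi), 0.05)
})
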