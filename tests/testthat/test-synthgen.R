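fs <- 512

test_that("generators are deterministic in their seed", {
  expect_identical(gen_background(fs, 5, 1, seed = 7),
                   gen_background(fs, 5, 1, seed = 7))
  expect_false(isTRUE(all.equal(gen_background(fs, 5, 1, seed = 7),
                                gen_background(fs, 5, 1, seed = 8))))
  expect_identical(as.numeric(gen_pac_channel(fs, 5, seed = 3)),
                   as.numeric(gen_pac_channel(fs, 5, seed = 3)))
  expect_identical(gen_coupled_pair(fs, 5, 1, seed = 4),
                   gen_coupled_pair(fs, 5, 1, seed = 4))
  A <- list(matrix(c(0.5, 0.5, 0, 0.5), 2, 2))
  expect_identical(gen_mvar_network(A, diag(2), fs, 5, seed = 5),
                   gen_mvar_network(A, diag(2), fs, 5, seed = 5))
})

test_that("background noise has the requested spectral slope", {
  w <- gen_background(fs, 180, exponent = 0, seed = 1)
  expect_equal(sd(w), 1, tolerance = 0.02)
  ps <- welch_psd(slice_epochs(multichannel_recording(cbind(a = w), fs), 8))
  sel <- ps$freqs >= 5 & ps$freqs <= 200
  expect_lt(max(ps$power[sel, 1]) / min(ps$power[sel, 1]), 1.5)
  pink <- gen_background(fs, 180, exponent = 1, seed = 2)
  psp <- welch_psd(slice_epochs(multichannel_recording(cbind(a = pink), fs),
                                8))
  selp <- psp$freqs >= 2 & psp$freqs <= 100
  slope <- coef(lm(log10(psp$power[selp, 1]) ~ log10(psp$freqs[selp])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.1)
  expect_error(gen_background(fs, 1, exponent = 3), "exponent")
})

test_that("PAC channel carries ground-truth MI = m/2 at study levels", {
  # buffer-level depth 0.24 -> MI ~ 0.12; treated-level 0.14 -> ~ 0.07
  for (m in c(0.24, 0.14)) {
    x <- gen_pac_channel(fs, 60, m = m, seed = 21)
    expect_equal(attr(x, "true_mi"), m / 2)
    phs <- analytic(as.numeric(x), fs, 7.5, 1)
    ams <- analytic(as.numeric(x), fs, 52, 9.5)
    expect_equal(modulation_index(phs, ams), m / 2, tolerance = 0.02)
  }
  expect_error(gen_pac_channel(fs, 10, m = 1.2), "\\[0, 1\\]")
  expect_error(gen_pac_channel(fs, 10, f_theta = 30, f_gamma = 50),
               "exceed")
})

test_that("PAC survives theta drift and a broadband gamma carrier", {
  x <- gen_pac_channel(fs, 60, m = 0.5, seed = 22, theta_drift = 0.5,
                       gamma_bw = 16)
  phs <- analytic(as.numeric(x), fs, 7.5, 2)
  ams <- analytic(as.numeric(x), fs, 52, 12)
  mi <- modulation_index(phs, ams)
  # fixed analysis bands only partially track the wandering oscillators,
  # so the estimate is attenuated below m/2 but must stay strong
  expect_gt(mi, 0.6 * 0.25)
  expect_lt(mi, 0.25 + 0.02)
})

test_that("coupled pair coherence follows (g^2/(g^2+1))^2 monotonically", {
  est <- vapply(c(0, 0.5, 1, 2), function(g) {
    pair <- gen_coupled_pair(fs, 120, g, seed = 30 + round(10 * g))
    S <- cross_spectral_matrix(slice_epochs(
      multichannel_recording(pair, fs = fs), 4))
    mean(coherence(S, "x", "y")$coh)
  }, numeric(1L))
  truth <- (c(0, 0.5, 1, 2)^2 / (c(0, 0.5, 1, 2)^2 + 1))^2
  expect_equal(est[3], 0.25, tolerance = 0.05)
  expect_lt(est[1], 0.02)
  expect_true(all(diff(est) > 0))
  expect_equal(est, truth, tolerance = 0.06)
  expect_equal(attr(gen_coupled_pair(fs, 1, 1, 1), "true_coherence"), 0.25)
})

test_that("simulated MVAR networks reproduce their closed-form PDC", {
  A1 <- matrix(c(0.5, 0.5, 0, 0.5), 2, 2)
  X <- gen_mvar_network(list(A1), diag(2), fs = fs, duration_s = 60,
                        seed = 40)
  m <- fit_mvar(multichannel_recording(X, fs = fs), max_order = 5)
  d <- extended_pdc(m, freqs = 0:100)
  d0 <- extended_pdc(mvar_model(list(A1), diag(2), fs = fs), freqs = 0:100)
  expect_lt(sqrt(mean((d$pdc - d0$pdc)^2)), 0.05)
  # no cross terms -> off-diagonal band-mean PDC below noise threshold
  Xn <- gen_mvar_network(list(diag(c(0.4, 0.4))), diag(2), fs = fs,
                         duration_s = 60, seed = 41)
  mn <- fit_mvar(multichannel_recording(Xn, fs = fs), max_order = 5)
  dn <- extended_pdc(mn, freqs = 0:100)
  expect_lt(band_mean_pdc(dn, c(30, 50), "ch1", "ch2"), 0.1)
  expect_lt(band_mean_pdc(dn, c(30, 50), "ch2", "ch1"), 0.1)
})

test_that("cohort generation matches its configuration and ground truth", {
  cfg <- cohort_config(n_buffer = 2, n_k18 = 3, weeks = c(1, 2),
                       duration_s = 4, seed = 50)
  coh <- gen_cohort(cfg)
  expect_length(coh$recordings, 10L)
  rec <- coh$recordings[[1L]]
  expect_identical(rec$channels,
                   c("FL", "FR", "CA1L", "CA1R", "CA3L", "CA3R"))
  expect_equal(nrow(rec$data), 4 * fs)
  expect_identical(rec$meta$group, "buffer")
  gt <- coh$ground_truth
  expect_length(gt, 5L)
  for (a in names(gt))
    expect_equal(gt[[a]]$mi, gt[[a]]$pac_depth / 2)
  # group contrasts present in the ground truth
  expect_lt(gt$k18_1$theta_peak[["CA1R"]], gt$buffer_1$theta_peak[["CA1R"]])
  # determinism of the full cohort
  coh2 <- gen_cohort(cfg)
  expect_identical(coh$recordings[[5L]]$data, coh2$recordings[[5L]]$data)
  expect_error(cohort_config(buffer = within(
    netdyn:::default_group_params("buffer"), pac_depth["CA1L"] <- 2)),
    "pac_depth")
})

test_that("cohort directory round trip preserves recordings", {
  cfg <- cohort_config(n_buffer = 1, n_k18 = 1, duration_s = 2, seed = 60)
  coh <- gen_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir, format = "csv")
  back <- read_cohort(dir)
  expect_length(back$recordings, 2L)
  grp <- vapply(back$recordings, function(r) r$meta$group, character(1L))
  orig <- coh$recordings[[which(vapply(coh$recordings,
                                       function(r) r$meta$group,
                                       character(1L)) == grp[1L])]]
  expect_equal(back$recordings[[1L]]$data, orig$data, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_false(is.null(back$ground_truth))
})

test_that("estimator bias shrinks as recording duration grows", {
  durs <- c(15, 60)
  mi_err <- vapply(durs, function(d) mean(vapply(1:3, function(r) {
    x <- gen_pac_channel(fs, d, m = 0.4, seed = 500 + r)
    phs <- analytic(as.numeric(x), fs, 7.5, 1)
    ams <- analytic(as.numeric(x), fs, 52, 9.5)
    abs(modulation_index(phs, ams) - 0.2)
  }, numeric(1L))), numeric(1L))
  expect_lt(mi_err[2], mi_err[1])
  coh_err <- vapply(durs, function(d) mean(vapply(1:3, function(r) {
    pair <- gen_coupled_pair(fs, d, 1, seed = 510 + r)
    S <- cross_spectral_matrix(slice_epochs(
      multichannel_recording(pair, fs = fs), 3))
    abs(mean(coherence(S, "x", "y")$coh) - 0.25)
  }, numeric(1L))), numeric(1L))
  expect_lt(coh_err[2], coh_err[1])
  A1 <- matrix(c(0.5, 0.5, 0, 0.5), 2, 2)
  d0 <- extended_pdc(mvar_model(list(A1), diag(2), fs = fs), freqs = 0:100)
  pdc_err <- vapply(durs, function(d) mean(vapply(1:3, function(r) {
    X <- gen_mvar_network(list(A1), diag(2), fs = fs, duration_s = d,
                          seed = 520 + r)
    m <- fit_mvar(multichannel_recording(X, fs = fs), order = 1)
    sqrt(mean((extended_pdc(m, freqs = 0:100)$pdc - d0$pdc)^2))
  }, numeric(1L))), numeric(1L))
  expect_lt(pdc_err[2], pdc_err[1])
})
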