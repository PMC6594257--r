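# Synthetic recordings and two-group cohorts with known ground truth.
#
# The generator emulates vigilance-wake rodent LFP: a 1/f background, a
# hippocampal theta oscillator, theta-phase-modulated gamma, 50 Hz line
# interference, shared cross-channel components (tunable coherence),
# and lagged directed coupling (asymmetric PDC).  Group-level defaults
# encode the studied contrasts: a leftward theta-peak shift, reduced
# ipsilateral CA1 PAC depth, reduced CA1L-CA1R shared gain, and reduced
# CA1R->CA1L directed gamma flow in the treated group.

# evaluate `expr` under a fixed RNG seed, restoring caller RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate 1/f background noise
#'
#' Gaussian noise whose power spectrum falls as `1/f^exponent`,
#' normalized to unit variance.  `exponent = 0` gives white noise;
#' `exponent = 1` the pink background typical of LFP.
#'
#' @param fs sampling rate (Hz).
#' @param duration_s length in seconds.
#' @param exponent spectral slope in `[0, 2]`.
#' @param seed RNG seed (deterministic output for a given seed).
#' @return numeric vector of `fs * duration_s` samples.
#' @export
gen_background <- function(fs, duration_s, exponent = 1, seed = 1) {
  if (exponent < 0 || exponent > 2) stop("exponent must be in [0, 2]")
  n <- as.integer(round(fs * duration_s))
  with_seed(seed, {
    w <- rnorm(n)
    if (exponent == 0) return(w)
    W <- fft(w)
    f <- c(1, seq_len(n - 1L))           # avoid DC blow-up
    f <- pmin(f, n - f + 1)              # symmetric |f| for the two halves
    W <- W / f^(exponent / 2)
    W[1L] <- 0
    x <- Re(fft(W, inverse = TRUE) / n)
    (x - mean(x)) / sd(x)
  })
}

#' Generate a theta-gamma PAC channel
#'
#' `s(t) = A_th cos(2 pi f_th t + ph0)
#'        + (1 + m cos(2 pi f_th t + ph0)) A_g cos(2 pi f_g t + psi)
#'        + background`,
#' so the gamma envelope is modulated by the theta phase with normalized
#' ground-truth MI exactly `m / 2`.  `snr` is the ratio of oscillatory
#' power (theta + gamma) to background power.
#'
#' @param fs sampling rate (Hz).
#' @param duration_s length in seconds.
#' @param f_theta,f_gamma oscillator frequencies (Hz); `f_gamma` must
#'   exceed `2 * f_theta`.
#' @param m modulation depth in `[0, 1]`.
#' @param snr oscillation-to-background power ratio.
#' @param seed RNG seed.
#' @param theta_amp,gamma_amp oscillator amplitudes.
#' @param noise_exponent spectral slope of the background.
#' @param theta_drift peak excursion (Hz) of a slow (< 0.2 Hz) random
#'   drift of the theta frequency; 0 gives a pure tone.  Real rodent
#'   theta wanders around its peak, spreading coupling over neighbouring
#'   comodulogram cells.
#' @param gamma_bw full bandwidth (Hz) of the gamma carrier; 0 gives a
#'   pure tone, > 0 a narrowband-noise carrier (burst-like gamma).  The
#'   carrier envelope is independent of the theta phase, so the
#'   ground-truth MI remains `m / 2`.
#' @return numeric vector of samples; attributes `true_mi` (= m/2),
#'   `f_theta`, `f_gamma`.
#' @export
gen_pac_channel <- function(fs, duration_s, f_theta = 7.5, f_gamma = 52,
                            m = 0.24, snr = 10, seed = 1,
                            theta_amp = 1, gamma_amp = 1,
                            noise_exponent = 1, theta_drift = 0,
                            gamma_bw = 0) {
  if (m < 0 || m > 1) stop("modulation depth m must be in [0, 1]")
  if (f_gamma <= 2 * f_theta) stop("f_gamma must exceed 2 * f_theta")
  n <- as.integer(round(fs * duration_s))
  t <- (0:(n - 1L)) / fs
  ph <- with_seed(seed, runif(2, -pi, pi))
  if (theta_drift > 0) {
    # slow AR(1) drift, corner frequency ~ fs*(1-a)/(2*pi) ~ 0.04 Hz
    dev <- with_seed(seed + 2L,
                     as.numeric(stats::filter(rnorm(n), 0.9995,
                                              method = "recursive")))
    dev <- dev / max(stats::sd(dev), 1e-12)
    finst <- f_theta + theta_drift * pmax(-1.5, pmin(1.5, dev))
    phase_th <- ph[1L] + 2 * pi * cumsum(finst) / fs
  } else {
    phase_th <- ph[1L] + 2 * pi * f_theta * t
  }
  th <- theta_amp * cos(phase_th)
  carrier <- if (gamma_bw > 0) {
    gc <- bandpass(gen_background(fs, duration_s, 0, seed = seed + 3L),
                   fs, f_gamma - gamma_bw / 2, f_gamma + gamma_bw / 2)
    gc * gamma_amp / (sqrt(2) * max(stats::sd(gc), 1e-12))
  } else {
    gamma_amp * cos(2 * pi * f_gamma * t + ph[2L])
  }
  ga <- (1 + m * cos(phase_th)) * carrier
  osc <- th + ga
  bg <- gen_background(fs, duration_s, noise_exponent, seed = seed + 1L)
  bg <- bg * sqrt(var(osc) / snr)
  structure(osc + bg, true_mi = m / 2, f_theta = f_theta, f_gamma = f_gamma)
}

#' Generate a pair of channels with controlled coherence
#'
#' `x = g s + n1`, `y = g s + n2` with `s`, `n1`, `n2` independent
#' unit-variance white noise; the population magnitude-squared coherence
#' is `(g^2 / (g^2 + 1))^2` at every frequency.
#'
#' @param fs sampling rate (Hz).
#' @param duration_s length in seconds.
#' @param shared_gain `g >= 0`.
#' @param seed RNG seed.
#' @return two-column matrix; attribute `true_coherence`.
#' @export
gen_coupled_pair <- function(fs, duration_s, shared_gain = 1, seed = 1) {
  if (shared_gain < 0) stop("shared_gain must be non-negative")
  n <- as.integer(round(fs * duration_s))
  with_seed(seed, {
    s <- rnorm(n); n1 <- rnorm(n); n2 <- rnorm(n)
    out <- cbind(x = shared_gain * s + n1, y = shared_gain * s + n2)
    attr(out, "true_coherence") <-
      (shared_gain^2 / (shared_gain^2 + 1))^2
    out
  })
}

#' Simulate an MVAR network
#'
#' Generates a realization of a stable MVAR model (Gaussian innovations
#' with covariance `Sigma`), discarding a burn-in of 10 times the model
#' order.
#'
#' @param A list of lag coefficient matrices, or an [mvar_model()].
#' @param Sigma innovation covariance (ignored when `A` is a model).
#' @param fs sampling rate (Hz).
#' @param duration_s length in seconds.
#' @param seed RNG seed.
#' @return matrix (samples x channels).
#' @export
gen_mvar_network <- function(A, Sigma = NULL, fs = 512, duration_s = 60,
                             seed = 1) {
  if (inherits(A, "mvar_model")) {
    Sigma <- A$Sigma
    A <- A$A
  }
  n <- nrow(A[[1L]])
  p <- length(A)
  if (mvar_spectral_radius(A) >= 1) stop("unstable MVAR coefficients")
  if (is.null(Sigma)) Sigma <- diag(n)
  L <- chol(Sigma)
  nt <- as.integer(round(fs * duration_s))
  burn <- max(10L * p, 100L)
  with_seed(seed, {
    E <- matrix(rnorm((nt + burn) * n), ncol = n) %*% L
    X <- matrix(0, nt + burn, n)
    for (t in (p + 1L):(nt + burn)) {
      xt <- E[t, ]
      for (k in seq_len(p)) xt <- xt + A[[k]] %*% X[t - k, ]
      X[t, ] <- xt
    }
    X[(burn + 1L):(burn + nt), , drop = FALSE]
  })
}

#' Default per-group channel-model parameters
#'
#' Starting point for [cohort_config()]: named per-channel vectors of
#' theta peak frequency, oscillator amplitudes and PAC depth, shared
#' gains per channel pair, and directed lagged couplings.  The treated
#' group ("k18") differs from control ("buffer") in the CA1 theta peak
#' (7.0 vs 7.5 Hz), CA1R PAC depth (0.14 vs 0.24), CA1L-CA1R shared
#' gain, and CA1R->CA1L directed gain.
#'
#' @param group `"buffer"` or `"k18"`.
#' @return Named list of group parameters.
#' @export
default_group_params <- function(group = c("buffer", "k18")) {
  group <- match.arg(group)
  ch <- c("FL", "FR", "CA1L", "CA1R", "CA3L", "CA3R")
  theta_peak <- stats::setNames(rep(7.5, 6L), ch)
  theta_amp <- stats::setNames(c(0.4, 0.4, 1.0, 1.0, 0.8, 0.8), ch)
  gamma_amp <- stats::setNames(c(0.4, 0.4, 0.8, 0.8, 0.6, 0.6), ch)
  pac_depth <- stats::setNames(c(0.10, 0.10, 0.24, 0.24, 0.15, 0.15), ch)
  shared_gain <- c("FL-FR" = 0.6, "CA3L-CA3R" = 0.6, "CA1L-CA1R" = 0.8)
  directed <- list(list(from = "CA1R", to = "CA1L", gain = 0.5,
                        band = c(30, 100), delay = 3L))
  if (group == "k18") {
    theta_peak[c("CA1L", "CA1R")] <- 7.0     # leftward theta shift
    pac_depth["CA1R"] <- 0.14                # reduced ipsilateral PAC
    pac_depth["CA1L"] <- 0.22
    shared_gain["CA1L-CA1R"] <- 0.4          # reduced interhemispheric coherence
    directed[[1L]]$gain <- 0.15              # reduced CA1R->CA1L gamma flow
  }
  list(theta_peak = theta_peak, theta_amp = theta_amp,
       gamma_amp = gamma_amp, gamma_center = stats::setNames(rep(52, 6L), ch),
       pac_depth = pac_depth, shared_gain = shared_gain, directed = directed)
}

#' Cohort configuration
#'
#' Assembles and validates the parameters of a synthetic two-group
#' cohort.  Group defaults encode the studied effect directions: the
#' treated ("k18") group has a 7.0 vs 7.5 Hz CA1 theta peak, CA1R PAC
#' depth 0.14 vs 0.24 (ground-truth MI 0.07 vs 0.12), a reduced
#' CA1L-CA1R shared gain and reduced CA1R->CA1L directed gamma coupling.
#' Between-animal variability is injected as lognormal multipliers
#' (`animal_sd`) on PAC depth, theta amplitude and shared gains.
#'
#' @param n_buffer,n_k18 animals per group.
#' @param weeks integer vector of session weeks.
#' @param fs sampling rate (Hz).
#' @param duration_s session length in seconds.
#' @param buffer,k18 per-group parameter lists (see
#'   `netdyn:::default_group_params`).
#' @param line_noise_amp 50 Hz line amplitude as a fraction of
#'   background RMS.
#' @param noise_exponent background spectral slope.
#' @param snr oscillation-to-background power ratio.
#' @param animal_sd lognormal sd of between-animal multipliers.
#' @param theta_drift,gamma_bw realism parameters passed to
#'   [gen_pac_channel()]: slow theta-frequency wander (Hz) and gamma
#'   carrier bandwidth (Hz).
#' @param shared_exponent spectral slope of the shared (coherence)
#'   sources; steeper than the private background so they act mainly at
#'   low frequencies.
#' @param seed RNG seed for the whole cohort.
#' @return A validated `cohort_config` object.
#' @export
cohort_config <- function(n_buffer = 7, n_k18 = 8, weeks = 1, fs = 512,
                          duration_s = 300,
                          buffer = default_group_params("buffer"),
                          k18 = default_group_params("k18"),
                          line_noise_amp = 0.1, noise_exponent = 1,
                          snr = 10, animal_sd = 0.15,
                          theta_drift = 0.8, gamma_bw = 16,
                          shared_exponent = 2, seed = 1) {
  cfg <- list(n_buffer = n_buffer, n_k18 = n_k18, weeks = weeks, fs = fs,
              duration_s = duration_s,
              groups = list(buffer = buffer, k18 = k18),
              line_noise_amp = line_noise_amp,
              noise_exponent = noise_exponent, snr = snr,
              animal_sd = animal_sd,
              theta_drift = theta_drift, gamma_bw = gamma_bw,
              shared_exponent = shared_exponent, seed = seed,
              channels = names(buffer$theta_peak))
  for (g in cfg$groups) {
    if (any(g$pac_depth < 0 | g$pac_depth > 1))
      stop("pac_depth must be in [0, 1]")
    if (any(!is.finite(unlist(g$shared_gain))))
      stop("shared gains must be finite")
    if (any(c(g$theta_peak, g$gamma_center) * 2 >= fs))
      stop("fs must exceed twice every oscillator frequency")
  }
  structure(cfg, class = "cohort_config")
}

# one synthetic session: 6 channels for a single animal and week
gen_session <- function(cfg, gp, mult, seed) {
  fs <- cfg$fs
  n <- as.integer(round(fs * cfg$duration_s))
  t <- (0:(n - 1L)) / fs
  ch <- cfg$channels
  nch <- length(ch)
  X <- matrix(0, n, nch, dimnames = list(NULL, ch))
  priv <- matrix(0, n, nch)              # private backgrounds (directed sources)
  sub <- 0L
  nxt <- function() { sub <<- sub + 1L; seed + sub }
  for (j in seq_len(nch)) {
    c_ <- ch[j]
    m <- min(1, gp$pac_depth[c_] * mult$pac[c_])
    x <- gen_pac_channel(fs, cfg$duration_s,
                         f_theta = gp$theta_peak[c_],
                         f_gamma = gp$gamma_center[c_],
                         m = m, snr = cfg$snr, seed = nxt(),
                         theta_amp = gp$theta_amp[c_] * mult$theta[c_],
                         gamma_amp = gp$gamma_amp[c_],
                         noise_exponent = cfg$noise_exponent,
                         theta_drift = cfg$theta_drift,
                         gamma_bw = cfg$gamma_bw)
    priv[, j] <- gen_background(fs, cfg$duration_s, cfg$noise_exponent,
                                seed = nxt())
    X[, j] <- as.numeric(x) + 0.3 * priv[, j]
  }
  # shared components -> cross-channel coherence; steeper spectrum than
  # the private background so interhemispheric gain differences act on
  # the low-frequency coherence bands, not on the gamma envelope
  for (pair in names(gp$shared_gain)) {
    ab <- strsplit(pair, "-", fixed = TRUE)[[1L]]
    s <- gen_background(fs, cfg$duration_s, cfg$shared_exponent, seed = nxt())
    g <- gp$shared_gain[[pair]] * mult$shared[[pair]]
    X[, ab[1L]] <- X[, ab[1L]] + g * s
    X[, ab[2L]] <- X[, ab[2L]] + g * s
  }
  # lagged directed coupling (gamma-band noise transfer)
  for (d in gp$directed) {
    src <- bandpass(priv[, match(d$from, ch)], fs, d$band[1L], d$band[2L])
    lag <- d$delay
    X[, d$to] <- X[, d$to] + d$gain * c(rep(0, lag), src[seq_len(n - lag)])
  }
  # 50 Hz line interference on every channel
  amp <- cfg$line_noise_amp * sqrt(2)
  phl <- with_seed(nxt(), runif(1, -pi, pi))
  X + amp * sin(2 * pi * 50 * t + phl)
}

#' Generate a synthetic two-group cohort
#'
#' Produces one 6-channel recording per animal and week, assembled from
#' the primitive generators with group-specific parameters, together
#' with the ground truth implied by the configuration (theta peaks,
#' per-animal PAC depth and MI = m/2, nominal shared-pair coherence,
#' directed adjacency).
#'
#' @param cfg a [cohort_config()].
#' @return list with `recordings` (flat list of
#'   [multichannel_recording()] with `meta` holding animal/group/week),
#'   `ground_truth`, `config`.
#' @export
gen_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  base <- (cfg$seed %% 1000003L) * 1000L
  recs <- list()
  gt <- list()
  animals <- c(paste0("buffer_", seq_len(cfg$n_buffer)),
               paste0("k18_", seq_len(cfg$n_k18)))
  groups <- c(rep("buffer", cfg$n_buffer), rep("k18", cfg$n_k18))
  for (a in seq_along(animals)) {
    gp <- cfg$groups[[groups[a]]]
    mult <- with_seed(base + a, list(
      pac = stats::setNames(exp(rnorm(length(cfg$channels), 0, cfg$animal_sd)),
                            cfg$channels),
      theta = stats::setNames(exp(rnorm(length(cfg$channels), 0, cfg$animal_sd)),
                              cfg$channels),
      shared = lapply(stats::setNames(nm = names(gp$shared_gain)),
                      function(p) exp(rnorm(1, 0, cfg$animal_sd)))))
    m_eff <- pmin(1, gp$pac_depth * mult$pac)
    gt[[animals[a]]] <- list(
      group = groups[a],
      theta_peak = gp$theta_peak,
      pac_depth = m_eff,
      mi = m_eff / 2,
      shared_gain = lapply(stats::setNames(nm = names(gp$shared_gain)),
                           function(p) gp$shared_gain[[p]] * mult$shared[[p]]),
      nominal_coherence = lapply(
        stats::setNames(nm = names(gp$shared_gain)),
        function(p) {
          g <- gp$shared_gain[[p]] * mult$shared[[p]]
          (g^2 / (g^2 + 1))^2
        }),
      directed = lapply(gp$directed, function(d)
        d[c("from", "to", "gain", "band", "delay")]))
    for (w in cfg$weeks) {
      X <- gen_session(cfg, gp, mult, seed = base + 1000L * a + w)
      recs[[length(recs) + 1L]] <- multichannel_recording(
        X, fs = cfg$fs, channels = cfg$channels,
        meta = list(animal = animals[a], group = groups[a], week = w))
    }
  }
  list(recordings = recs, ground_truth = gt, config = cfg)
}

#' Write / read a cohort directory tree
#'
#' Lays a cohort out as `dir/<group>/<animal>/week<k>.<ext>` plus
#' `ground_truth.json`; `read_cohort()` restores the recordings and
#' ground truth.
#'
#' @param cohort a [gen_cohort()] result.
#' @param dir destination directory.
#' @param format `"csv"` or `"edf"`.
#' @return `dir` (write) or a cohort-shaped list (read), invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  for (rec in cohort$recordings) {
    d <- file.path(dir, rec$meta$group, rec$meta$animal)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_recording(rec, file.path(d, sprintf("week%d.%s", rec$meta$week,
                                              format)))
  }
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "^week[0-9]+\\.(csv|edf)$",
                      recursive = TRUE, full.names = TRUE)
  if (length(files) == 0L) stop("no recordings found under ", dir)
  recs <- lapply(files, function(f) {
    parts <- strsplit(f, .Platform$file.sep, fixed = TRUE)[[1L]]
    np <- length(parts)
    rec <- read_recording(f)
    rec$meta <- list(animal = parts[np - 1L], group = parts[np - 2L],
                     week = as.integer(sub("^week([0-9]+)\\..*$", "\\1",
                                           parts[np])))
    rec
  })
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path) else NULL
  list(recordings = recs, ground_truth = gt, config = NULL)
}
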