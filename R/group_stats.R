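# Group-comparison layer: two-sample t-tests with 95% CIs, circular
# means, and the Watson-Williams test for circular data.

#' Mean with 95% confidence interval
#'
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)`.
#'
#' @param values numeric vector, `n >= 2`.
#' @return list with `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
summarize_ci <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 finite values for a confidence interval")
  m <- mean(values)
  half <- qt(0.975, n - 1L) * sd(values) / sqrt(n)
  list(mean = m, ci_lo = m - half, ci_hi = m + half, n = n)
}

group_comparison <- function(metric, stat_name, stat, df, p,
                             mean_a, mean_b, ci_a, ci_b, n_a, n_b,
                             note = NA_character_) {
  structure(list(metric = metric, stat_name = stat_name, stat = stat,
                 df = df, p = p, mean_a = mean_a, mean_b = mean_b,
                 ci_a = ci_a, ci_b = ci_b, n_a = n_a, n_b = n_b,
                 significant = is.finite(p) && p < 0.05, note = note),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  stars <- if (!is.finite(x$p)) "" else if (x$p < 0.01) " **"
           else if (x$p < 0.05) " *" else ""
  cat(sprintf("<group_comparison> %s: %s = %.3f (df %s), p = %.4g%s\n",
              x$metric, x$stat_name, x$stat,
              paste(format(x$df), collapse = ","), x$p, stars))
  cat(sprintf("  group A: %.4g [%.4g, %.4g] (n=%d) | group B: %.4g [%.4g, %.4g] (n=%d)\n",
              x$mean_a, x$ci_a[1L], x$ci_a[2L], x$n_a,
              x$mean_b, x$ci_b[1L], x$ci_b[2L], x$n_b))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Two-sample t-test with group summaries
#'
#' Classic pooled-variance two-sided t-test (Welch correction optional),
#' returning the statistic, degrees of freedom, p value and per-group
#' means with 95% confidence intervals.  When both groups have zero
#' variance and equal means, `p = 1` by convention.
#'
#' @param a,b numeric samples (`n >= 2` each).
#' @param metric label carried into the result.
#' @param welch if `TRUE`, use the Welch (unequal-variance) correction.
#' @return A `group_comparison` object.
#' @export
two_sample_t <- function(a, b, metric = "metric", welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 finite values")
  ca <- summarize_ci(a); cb <- summarize_ci(b)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(group_comparison(metric, "t", 0, length(a) + length(b) - 2L, 1,
                              ca$mean, cb$mean, c(ca$ci_lo, ca$ci_hi),
                              c(cb$ci_lo, cb$ci_hi), ca$n, cb$n,
                              note = "zero variance in both groups"))
    return(group_comparison(metric, "t", Inf, length(a) + length(b) - 2L, 0,
                            ca$mean, cb$mean, c(ca$ci_lo, ca$ci_hi),
                            c(cb$ci_lo, cb$ci_hi), ca$n, cb$n,
                            note = "zero variance, unequal means"))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  group_comparison(metric, "t", unname(tt$statistic), unname(tt$parameter),
                   tt$p.value, ca$mean, cb$mean,
                   c(ca$ci_lo, ca$ci_hi), c(cb$ci_lo, cb$ci_hi), ca$n, cb$n)
}

wrap_angle <- function(theta) {
  out <- atan2(sin(theta), cos(theta))
  out[out >= pi] <- -pi
  out
}

#' Circular mean and resultant length
#'
#' Argument and modulus of the mean of `exp(i * angles)`.  A resultant
#' length of (numerically) zero leaves the mean direction undefined; the
#' angle is then `NA` and the result flagged.
#'
#' @param angles numeric vector of angles in radians.
#' @return list with `angle` (radians in `[-pi, pi)`, `NA` if
#'   undefined), `resultant_length`, `n`, `defined`.
#' @export
circular_mean <- function(angles) {
  angles <- wrap_angle(angles[is.finite(angles)])
  if (length(angles) < 1L) stop("need at least 1 finite angle")
  z <- mean(exp(1i * angles))
  r <- Mod(z)
  defined <- r > 1e-10
  list(angle = if (defined) wrap_angle(Arg(z)) else NA_real_,
       resultant_length = r, n = length(angles), defined = defined)
}

# maximum-likelihood concentration for a von Mises sample, from the mean
# resultant length (Fisher 1993 approximations)
vm_kappa <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal mean directions
#'
#' One-way circular ANOVA comparing the mean directions of two circular
#' samples, with the standard concentration correction
#' `K = 1 + 3/(8*kappa)`; the statistic is referred to `F(1, n-2)`.
#' The test assumes reasonably concentrated samples; if the pooled mean
#' resultant length falls below `r_min` the result is still returned but
#' flagged as violating the assumption.
#'
#' @param a,b numeric vectors of angles in radians.
#' @param metric label carried into the result.
#' @param r_min validity threshold on the pooled within-group resultant
#'   length (default 0.45).
#' @return A `group_comparison` object (`stat_name = "F"`); group means
#'   are circular means and the per-group `ci` fields hold the circular
#'   mean +/- a 95% normal-approximation arc.
#' @export
watson_williams <- function(a, b, metric = "phase", r_min = 0.45) {
  a <- wrap_angle(a[is.finite(a)]); b <- wrap_angle(b[is.finite(b)])
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 angles")
  R1 <- Mod(sum(exp(1i * a)))
  R2 <- Mod(sum(exp(1i * b)))
  R <- Mod(sum(exp(1i * c(a, b))))
  rw <- (R1 + R2) / n
  kappa <- vm_kappa(rw)
  K <- 1 + 3 / (8 * kappa)
  denom <- n - R1 - R2
  Fstat <- if (denom <= 0) Inf else K * (n - 2) * (R1 + R2 - R) / denom
  Fstat <- max(Fstat, 0)
  p <- pf(Fstat, 1, n - 2, lower.tail = FALSE)
  ma <- circular_mean(a); mb <- circular_mean(b)
  arc <- function(cm, nn) {
    if (!cm$defined || cm$resultant_length >= 1) return(c(cm$angle, cm$angle))
    se <- sqrt(-2 * log(cm$resultant_length) / nn)  # wrapped-normal approx
    c(cm$angle - 1.96 * se, cm$angle + 1.96 * se)
  }
  note <- if (rw < r_min)
    sprintf("assumption violated: mean resultant %.2f < %.2f", rw, r_min)
  else NA_character_
  group_comparison(metric, "F", Fstat, c(1, n - 2), p,
                   ma$angle, mb$angle, arc(ma, n1), arc(mb, n2), n1, n2,
                   note = note)
}

#' Draw von Mises random angles
#'
#' Best-Fisher rejection sampler; used for calibration and power
#' simulations of the circular tests.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0); `kappa = 0` gives uniform angles.
#' @return numeric vector of angles in `[-pi, pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (kappa == 0) return(wrap_angle(runif(n, -pi, pi)))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      i <- i + 1L
      out[i] <- sign(u3 - 0.5) * acos(f) + mu
    }
  }
  wrap_angle(out)
}
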