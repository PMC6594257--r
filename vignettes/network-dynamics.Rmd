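---
title: "Methods: spectra, coupling and directed connectivity in netdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectra, coupling and directed connectivity in netdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`netdyn` implements a complete functional-network analysis for
multichannel rodent EEG/LFP: Welch relative power, theta–gamma
phase–amplitude coupling, coherence and partial coherence, global
network efficiency, and MVAR-based directed coherence, together with a
synthetic cohort generator that provides ground truth for every one of
those estimators. This vignette explains the models, the estimator
conventions the package commits to, the tunable parameters and their
defaults, and what the synthetic validation does and does not
demonstrate about real recordings.

## Preprocessing

Line interference is removed with a linear-phase FIR band-stop filter
(default 50 ± 1 Hz, order `3·fs/bw` ≈ 768 taps at 512 Hz). Narrowband
components for coupling analysis use windowed-sinc bandpass filters with
a transition width of 2 Hz (capped at the passband width for the 2
Hz-wide theta phase bands). Every filter is applied twice
(forward–forward with exact integer group-delay compensation), so the
net phase response is identically zero — an essential property, since a
phase-shifted theta reference would bias both the modulation index and
the PAC phase shift. Two passes double the stopband attenuation (the 50
Hz notch reaches ≈ 56 dB) at the cost of doubled (still sub-dB) passband
ripple.

FIR edge transients are strictly finite: after two passes no output
sample further than twice the filter length from an edge is affected by
the boundary. The package therefore filters the *continuous* recording,
flags a guard of `2 × filter length` samples at each end, and only then
applies epoch masks. Filtering 8-s epochs individually would be
unusable here: the ≈ 850-tap theta-band filters would contaminate most
of every epoch.

Artifact handling is amplitude-based: epochs are retained when every
channel stays below 1000 µV peak (movement/chewing spikes) and above
1 µV peak-to-peak range (electrode drop-out). Vigilance-state scoring is
out of scope; the thresholds stand in for the reference design's
"continuous, waking, artefact-free" selection and are configurable
(`amp_thresh`, `flat_thresh`).

## Spectra

`welch_psd()` averages Hann-windowed 512-sample periodograms with 50 %
overlap across all retained epochs; at 512 Hz this gives exactly 1.0 Hz
bins. Power is reported as spectral density (units²/Hz) and, after
`relative_power()`, as the fraction of total power over 1–256 Hz per
channel, which removes per-animal gain differences. All band edges in
the package are half-open `[lo, hi)` so adjacent bands such as 4–6 and
6–8 Hz partition without double counting. The theta descriptor used for
group comparison is the power-weighted center of mass over a closed
4–12 Hz band: a pure shift statistic that is insensitive to overall
theta power.

The 50 % overlap is the standard bias/variance compromise and is
configurable; the averaged-periodogram count `n_blocks` is carried in
the result because the magnitude-squared coherence estimator has a known
`1/n_blocks` bias floor that several tests check against.

## Phase–amplitude coupling

For a phase band centred on `f_L` (half-width 1 Hz, matching the 2 Hz
comodulogram step) and an amplitude band centred on `f_H`, the package
computes the analytic signals and the normalized mean-vector-length
modulation index

```
MI = | mean( A_H(t) · exp(i φ_L(t)) ) | / mean( A_H(t) ).
```

Two conventions deserve note. First, the mean is taken *before* the
modulus — the literal "mean absolute value of z(t)" reduces to the mean
envelope, carrying no phase information. Second, the normalization by
the mean envelope makes MI dimensionless in [0, 1], invariant under
amplitude rescaling, and equal to exactly `m/2` for an envelope
`A ∝ 1 + m·cos φ`; reported group levels of ~0.12 vs ~0.07 then map to
modulation depths 0.24 vs 0.14.

The amplitude band half-width follows `max(5, f_L + 2)` Hz so that the
modulation sidebands at `f_H ± f_L` pass — without them the envelope is
flat and MI is destroyed regardless of true coupling. At the bottom of
the amplitude grid (`f_H` near 10 Hz) this band would cross 0 Hz; its
lower edge is clamped to 1 Hz and such cells are interpretable only as
noise floor. Phases are wrapped to `[−π, π)` everywhere.

MI is computed by default from one mean vector pooled over all retained
epoch samples (`epoch_mode = "pooled"`). The alternative
(`"per_epoch"`, averaging per-epoch MI values) is provided, but for
short windows every per-epoch MI carries a `≈ √(π/4)/√(T·B)` noise
floor that inflates the average; pooling keeps the floor at the
whole-session level. On the 5-minute default sessions the two agree
closely; at the 60-s scale used in the replicated simulations pooling
is clearly preferable.

Phase-binned amplitude curves use 6 equal bins of width 2π/6 ≈ 1.05 rad
(exact 1-radian bins cannot tile the circle; the bin count is
configurable). The PAC phase shift is the circular first moment of the
binned curve; its resultant length acts as a reliability flag —
near-flat curves are marked degenerate rather than reported with a
meaningless angle.

### Computational note

A comodulogram needs hundreds of narrowband analytic signals per
recording. The package computes each one from a single cached FIR
frequency response restricted to the band's spectral support, folded
onto a small inverse FFT — an exact, decimated evaluation of the same
two-pass filter (band-limited signals are fully represented at the
reduced rate; agreement with the direct path is verified in the tests
to ≈ 1e-4). This makes the 234-cell grid run in under a second per
channel-minute and the 100-replicate power study feasible on one CPU.

## Coherence, partial coherence and Eglob

Magnitude-squared coherence `|S_AB|²/(S_AA·S_BB)` is computed from the
Welch cross-spectral matrix (Hermitian by construction, with the Welch
PSD on its diagonal). Partial coherence uses minors of the full
spectral matrix, `|M_AB|/√(M_AA·M_BB)`, which removes the linear
contribution of all other recorded channels; the square root is
required for a [0, 1]-bounded quantity consistent with the 2-channel
limit (where the expression reduces to `√Coh`). Frequencies at which
the spectral matrix is numerically singular (condition number > 1e10)
are masked rather than extrapolated.

The coherence graph takes band-mean coherence (default 4–70 Hz) as edge
weights. Global efficiency converts weights to distances as
`d = 1/weight` and averages inverse shortest-path distances over all
electrode pairs. The inversion is deliberate: treating coherence
*itself* as a distance would make Eglob fall as synchrony rises,
contradicting its use as a "more coherent network = more efficient"
summary. With weights in [0, 1], Eglob is also in [0, 1]. Eglob can be
evaluated per frequency or on the band-mean graph; the band-mean form
is the default.

## Directed coherence

An MVAR(p) model `x_t = Σ_k A_k x_{t−k} + e_t` is fitted by multi-epoch
least squares (epochs demeaned and regressed separately, normal
equations pooled) with order selected by BIC over 1..20 — parsimony
matters for 8-s epochs. Fits with companion-matrix spectral radius ≥ 1
are rejected with advice rather than silently returned. The
noise-variance-weighted ("generalized", here *extended*) PDC is

```
PDC_{i←j}(f) = (|Ā_ij(f)| / σ_i) / sqrt( Σ_k |Ā_kj(f)|² / σ_k² ),
```

with `Ā(f) = I − Σ_k A_k e^{−2πi f k / fs}` and `σ_i² = Σ_ii`. Squared
entries sum to one down each source column at every frequency. The
weighting makes the measure scale-invariant across channels of unequal
noise level; the classic unweighted PDC is available via
`weighted = FALSE` for sensitivity analysis. Band summaries default to
30–50 and 50–100 Hz.

## Group statistics

Each metric is reduced to one value per animal and week (the animal is
the unit of analysis) and compared between groups per week with the
pooled two-sample t-test (Welch correction optional); results carry
means, 95 % CIs (`mean ± t₀.₉₇₅,ₙ₋₁·sd/√n`), and a significance flag at
α = 0.05 (`*` < 0.05, `**` < 0.01 in rendered panels). No
multiple-testing correction is applied, mirroring the per-week,
per-metric design; the comparison table reports every test so the count
is auditable. Circular phase-shift data use the Watson–Williams F test
with the standard `1 + 3/(8κ̂)` concentration correction; samples whose
pooled mean resultant falls below 0.45 violate the test's concentration
assumption and are returned flagged rather than suppressed. Both tests'
type-I calibration is verified by simulation in the acceptance suite.

## The synthetic cohort

`gen_cohort()` builds 6-channel sessions from primitive generators,
each with an analytically known target:

- `gen_background()` — unit-variance 1/f^α noise (α = 1 default);
- `gen_pac_channel()` — theta oscillator plus theta-phase-modulated
  gamma with ground-truth MI = m/2. Two realism parameters spread the
  coupling over neighbouring comodulogram cells the way real data does:
  a slow (≈ 0.04 Hz) AR(1) wander of the theta frequency (peak
  excursion 0.8 Hz) and a narrowband-noise gamma carrier (16 Hz
  bandwidth) whose envelope is independent of theta phase, leaving the
  ground-truth MI unchanged;
- `gen_coupled_pair()` — common-source channels with closed-form
  magnitude-squared coherence `(g²/(g²+1))²`;
- `gen_mvar_network()` — realizations of stable MVAR models with
  closed-form PDC.

Group defaults encode the studied contrasts: control vs treated theta
peak 7.5 vs 7.0 Hz at CA1, CA1R PAC depth 0.24 vs 0.14 (MI 0.12 vs
0.07), CA1L–CA1R shared gain 0.8 vs 0.4, CA1R→CA1L lagged gamma-band
coupling 0.5 vs 0.15; cohort sizes 7 vs 8. Between-animal heterogeneity
enters as lognormal multipliers (σ = 0.15) on PAC depth, theta
amplitude and shared gains. The shared (coherence-generating) sources
use a steeper 1/f² spectrum than the private backgrounds: shared drive
between hemispheres is predominantly low-frequency, and this keeps the
*group difference* in shared gain from leaking into the gamma envelope,
where it would act as an opposing PAC artifact. 50 Hz line interference
(10 % of background RMS) is always present so the notch stage is
exercised end to end.

Problem sizes: package sessions default to 300 s (all estimators
converge well within that at 512 Hz); the replicated power studies in
the tests and the acceptance script use 60-s sessions and 100 cohort
replicates, which keeps the full suite within desk-scale runtimes while
the CA1R PAC contrast remains detectable with approximately 95 % power
at n = 7 vs 8.

What passing these simulations shows: the estimators are correctly
implemented (they recover closed forms), correctly calibrated (null
rejection at α), and sensitive enough to recover the encoded effect
sizes through the full pipeline. What they do not show: robustness to
real-data features the generator omits — non-sinusoidal theta (which
produces spurious harmonic PAC), vigilance-state mixing, volume
conduction with realistic head geometry, electrode impedance drift, and
movement artifacts more structured than amplitude spikes. Conclusions
about real recordings still require the usual controls (surrogate
testing for PAC, artifact audit) that are out of scope here.

## Numerical choices and degenerate inputs

- FFT-based convolution with explicit zero padding; decimated band
  evaluation only when the band support allows it without aliasing.
- Half-open band bins everywhere except the theta center of mass
  (closed band, so a uniform 4–12 Hz spectrum yields exactly 8.0 Hz).
- Coherence estimates are clipped into [0, 1]; partial coherence masks
  ill-conditioned frequencies with `NA` and a warning.
- Zero-variance t-test inputs: equal means give p = 1 by convention,
  unequal means p = 0, both flagged in the result note.
- Circular means with (numerically) zero resultant return an `NA` angle
  with a `defined = FALSE` flag.
- Empty epoch selections, zero envelopes, unstable MVAR fits, singular
  innovation covariances and out-of-Nyquist grids all raise immediate,
  specific errors rather than propagating nonsense.

## Known limitations

Partial coherence via explicit minors is O(n³) per frequency per pair —
fine for 6 electrodes, not for high-density arrays. The MVAR fit
assumes within-session stationarity; time-varying extensions are out of
scope, as are multitaper spectra, Tort's KL-divergence MI,
surrogate-based PAC significance and the directed transfer function.
The EDF writer covers the plain 16-bit continuous profile only (no
EDF+ annotations), recording in 1-s records and padding the final
record (the true sample count is preserved in the header).
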