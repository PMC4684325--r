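---
title: "Spectro-temporal encoding models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectro-temporal encoding models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strfkit)
```

## The model

strfkit describes the time-varying firing rate of an auditory neuron as the
output of a chain of signal transformations applied to the sound:

```
waveform -> cochlear filterbank -> log compression -> spectral filter
         -> [short-term plasticity] -> temporal filter -> [output sigmoid]
         -> predicted rate y(t)
```

Each stage is a *module* with named parameters; the output of one module is
the input of the next. Between every pair of modules the signal is
normalized per channel — standardized by the mean and SD measured on the
estimation data and shifted so its minimum there is zero — and those frozen
moments are re-applied to any new stimulus. Normalization keeps every
module's input on a unit scale, which is what makes a shared initial descent
step size of 1 meaningful across modules of very different physical units.

**Cochlear frontend.** Each of `C` channels is a fourth-power cascade of the
second-order bandpass section `G(s) = K s / (s^2 + (w0/Q) s + w0^2)` with
`w0 = 2*pi*f_i`, center frequencies spaced geometrically across
`f_low`–`f_high` (default 18 channels over 200–20,000 Hz), and a single
quality factor `Q = [(f_high/f_low)^(1/(C-1)) - 1]^(-1)` tying bandwidth to
channel spacing (`Q = 3.214` for the default grid). `K` is chosen per
channel for unit peak gain — the absolute gain is arbitrary because the
downstream normalization absorbs it. Filters are applied by multiplication
in the frequency domain on the full-signal FFT; the channel envelope is the
magnitude of the analytic signal, smoothed with a boxcar over one output bin
and decimated to the bin rate (default 100 Hz). The envelope is compressed
as `log(x + phi1)` with a single fitted offset `phi1 > 0` (envelope units;
small values compress hard).

**Linear spectro-temporal stage.** Four families of increasing constraint:

* *FIR*: an explicit `C x U` weight matrix over frequency and time lag
  (default memory `U = 15` bins = 150 ms at 100 Hz) plus a baseline `b` —
  270 weights for the default grid, 276 parameters for the full chain.
* *Factorized*: `H = Hs %*% Ht` with a `C x D` spectral matrix and `D x U`
  temporal matrix; rank at most `D`.
* *Parameterized spectral*: each spectral channel is a Gaussian
  (`f0` center in Hz, `sigma` bandwidth in Hz; 2 parameters) or a Morlet
  wavelet adding a sideband wavenumber `z` (3 parameters).
* *Parameterized temporal*: per channel, either a difference of
  exponentials (6 parameters: two gains, decay constants in bins, onset
  latencies in bins) or a rational pole-zero transfer function
  `G(s) = A exp(-l s) prod(s - z_k) / prod(s + p_m)` with real positive
  poles (1/s), real zeros, gain `A` and latency `l` in seconds
  (`2 + P + Z` parameters). The impulse response is a causal sum of
  decaying exponentials obtained by partial fractions, shifted by `l`
  (fractional delays allowed), sampled at bin centers. Repeated poles are
  perturbed apart by one part in 10^6 rather than handled with polynomial
  terms. A model named `P3Z1x3` is a 3-pole/1-zero kernel on each of 3
  Gaussian spectral channels: 29 free parameters against the FIR's 276.

**Short-term plasticity (optional).** Each spectral channel drives a
simulated synapse whose available-vesicle fraction `d(t)` starts at 1, is
depleted by the previous input in proportion to the release fraction `nu`
(depression, `nu > 0`; facilitation uses `nu < 0` against `2 - d`) and
recovers with time constant `tau_rec` (bins). The channel input is rectified
at zero and shifted by a baseline presynaptic level `s0` before the
recursion, and the output is `d(t)` times that shifted input; `d` is clipped
to [0, 2] for stability. 3 parameters per channel.

**Output nonlinearity (optional).** The double-exponential sigmoid
`y = phi1 + phi2 * exp(-exp(phi3 * (x - phi4)))`, spanning the asymptotes
`phi1` and `phi1 + phi2`; `phi3 < 0` gives a rising response. It models
spike threshold and saturation, and absorbs the output scale and offset
that parameterized temporal kernels do not carry explicitly.

**Parameter accounting.** The FIR and free factorized temporal filters
carry an explicit baseline `b`; parameterized kernels do not (their offset
lives in the sigmoid). This convention is the only one that makes the
standard totals mutually consistent: 276 for the full FIR chain (270
weights + b + compression + 4 sigmoid parameters), 29 for `P3Z1x3`, 13 for
`P3Z1x1`, 54 extra for plasticity on 18 channels. Note the same convention
prices a `D = 3` factorized chain at 105 parameters.

## The fitting algorithm

`strf()` fits every module by nested coordinate descent against a shrunken
normalized mean squared error. NMSE is
`e_mse = sum((p - r)^2) / sum((r - rbar)^2)` (0 = perfect, 1 = chance); its
standard error `sigma` is estimated by a delete-one-fold jackknife over 10
contiguous temporal segments (contiguous so that autocorrelation stays
within folds), and the fitted cost is
`e = 1 - (1 - e_mse) * max(0, 1 - (sigma / (1 - e_mse))^2)`:
a reliable improvement passes through, an unreliable one is shrunk back to
chance level. When `e_mse >= 1` the cost is reported as `e_mse` itself so
the descent still sees a gradient on the wrong side of chance; the shrunken
cost therefore lies in [0, 1] only in the sub-chance regime. A per-bin
Poisson negative log-likelihood is available as an alternative cost.

The schedule: (1) remove the output sigmoid; (2) with stop criterion
`epsilon = 1e-3`, visit each module in chain order; weight-matrix modules
use *non-greedy* descent (probe every parameter at +/- a shared step
`delta`, accept only the single best improving step; `delta` starts at 1,
grows 10% on success, halves on failure, floors at 1e-6; at most 10
accepted steps per visit), parameterized modules use *greedy* descent (each
parameter iterated to its own stop condition with its own step); (3) repeat
passes until no module improves by more than `epsilon`, then multiply
`epsilon` by 0.7; (4) stop at `epsilon <= 1e-4`, restore the sigmoid, and
repeat the whole schedule down to `epsilon <= 1e-6`. Accepted-step costs
are non-increasing by construction and the procedure is fully
deterministic: rerunning a fit reproduces it bit for bit.

Descent operates on internally rescaled coordinates so that `delta = 1` is
a sensible first probe everywhere: spectral centers and bandwidths in log2
Hz (probes are octave steps), poles and plasticity recovery times on a log
scale, latencies in milliseconds, kernel gains through `asinh` (log-like
range with smooth sign crossing), compression offsets in log units. Weight
matrices and sigmoid parameters are probed raw, which works because their
inputs are normalized.

Three initialization choices matter and were settled on simulated neurons:

* *Linear-phase calibration.* While the sigmoid is removed, a chain whose
  temporal stage is parameterized has no baseline or free scale, so its
  raw NMSE is dominated by the response mean, which no coordinate can fix;
  the phase-1 cost therefore scores affinely calibrated predictions
  (least-squares gain and offset), both of which merge into the sigmoid
  when it returns.
* *Pole/latency grid.* Decay rate and latency are strongly coupled —
  axis-aligned probes cannot cross between their basins — so the pole-zero
  stage starts from the best of a small deterministic grid (pole scale 5 to
  80 1/s, latency 0 to 20 ms) under the phase-1 cost.
* *Sigmoid placement.* At phase-2 entry the sigmoid is placed by a
  deterministic grid over slope (+/- 0.5, 1, 2) and inflection (quantiles
  of the linear output); a badly oriented start is a strong attractor
  toward a constant prediction. Because a strongly rectifying neuron can
  make the phase-1 optimum a poor start for the nonlinear model, the
  phase-1 state also competes at this point against a fresh initialization
  under the full cost, and the better start is kept. Remaining
  initializations: FIR and factorized temporal weights start at zero with
  `b` at the mean response; factorized spectral weights start uniform at
  `1/C` (an all-zero factorization is a coordinate-descent deadlock);
  Gaussian centers start at the channel most correlated with the response,
  with bandwidth twice the local channel spacing.

## Evaluation machinery

*Prediction correlation* is Pearson's R between predicted and observed
PSTH. *Response SNR* splits single-trial variance into stimulus-locked
variance (mean covariance between distinct trials) and noise, with negative
covariance estimates clipped at zero and identical trials reported as
infinite SNR. *Noise-corrected correlation* divides the mean single-trial
correlation by the square root of the trial-to-trial response correlation
(TTRC, mean Pearson R over unique trial pairs): under additive noise
`E[corr(r_i, p)] = R_true * sqrt(TTRC)`, so this quotient recovers the
correlation against the noiseless response — dividing by TTRC itself, a
form sometimes written, overcorrects by a further `1/sqrt(TTRC)` and fails
the recovery check the test suite performs by simulation. *Infinite-data
extrapolation* fits `1/R_T^2 = 1/R_inf^2 + A/T` by least squares on
correlations measured at several estimation-set sizes (the noise term is
additive in inverse square correlation; `A >= 0` enforced) and reports
`R_inf = intercept^(-1/2)`, erroring rather than clipping when the
intercept is nonpositive. *Pareto fronts* return the models not dominated
in (parameter count, performance), computed by a sorted sweep and checked
in the tests against an all-pairs oracle; exact ties are both retained.
*Model comparison* uses the exact two-sided sign test on paired per-neuron
scores.

## The synthetic-data generator

Real recordings of this kind are rarely redistributable, so the package
ships a seeded generator that emulates the standard experimental design:
40 three-second estimation stimuli with 5 repetitions and 2 three-second
validation stimuli with 20 repetitions, binned at 100 Hz. Stimuli are
modulation-limited noise — white Gaussian spectrograms low-pass masked in
the 2-D Fourier domain (temporal modulations below 20 Hz, spectral
modulations below 0.25 cycles/channel), shifted nonnegative and scaled to
unit mean — mimicking 1/f-style spectro-temporal noise rather than
vocalizations. Ground-truth neurons are full model chains with known
parameters drawn deterministically from the seed within ranges typical of
cortical neurons (centers in the interior of the band, bandwidths 20–45% of
center, dominant poles tens of 1/s, latencies up to 20 ms, sigmoid
amplitudes of 15–25 spikes/s). The sigmoid's inflection is calibrated to
the 55th–80th percentile of the linear drive it actually receives, with a
rising slope — a blind draw tends to produce a saturated, always-on neuron
that no real PSTH resembles, whereas this operating point yields sparse
positively driven responses in the regime where linear models explain a
substantial minority of response variance.

Each trial adds independent Gaussian rate noise whose variance is set from
the designed response SNR (`noise_sd = sd(signal)/sqrt(SNR)`); a Poisson
spiking mode exists for likelihood-based costs. An optional stimulus-locked
component that no linear model can capture — a squared, rescaled second
linear projection of the stimulus, frozen on the estimation set — carries a
configurable fraction (default 0.2) of the signal variance, standing in for
the residual nonlinear response of real neurons. Designed SNR levels
bracket the usual inclusion cut of 0.005.

What passing tests on this generator do *not* show: robustness to
non-Gaussian, non-additive neural noise, to behavioral-state drift, or to
the higher-order structure of natural vocalizations; the generator's
neurons are by construction inside (or one squared term outside) the model
family.

## Problem sizes used by the heavy analyses

The simulation analyses in the test suite and the acceptance script use
desk-scale versions of the full design, chosen once: noiseless parameter
recovery on 10 estimation stimuli (3,000 bins); architecture
identification on three SNR-1 neurons with 10 stimuli; the data-scaling
comparison on three low-SNR neurons (single-trial SNR 0.02–0.1, the range
retained by the inclusion cut) with 20 stimuli, comparing 10% against 100%
of the estimation set. Trial counts, binning, stimulus statistics and noise
levels follow the full design throughout.

## Known limitations

* Coordinate descent is a local method; the grid initializations above
  remove the failure modes we observed on simulated neurons, but strongly
  multi-peaked spectral tuning fitted with too few channels can still lodge
  in secondary basins.
* The shrinkage cost deliberately flattens sub-noise improvements; for very
  low SNR targets the FIR stage may accept no steps at all, which is the
  intended regularization but means "no fit" rather than "a bad fit".
* Gains and sigmoid slopes are individually unidentifiable up to paired
  sign/scale flips (the composed prediction is unchanged); recovery reports
  should be read on identifiable quantities — centers, bandwidths, poles,
  latencies.
* The cochlear frontend is a filterbank abstraction; detailed transduction
  models (adaptation, suppression) are out of scope.
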