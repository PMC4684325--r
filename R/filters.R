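#' Finite impulse response (FIR) spectro-temporal kernel
#'
#' The classical STRF: a `C x U` weight matrix over frequency channels and
#' time lags plus a baseline offset `b`.
#'
#' @param H numeric `C x U` weight matrix (lag 1 column = zero delay).
#' @param b baseline offset in rate units.
#' @param bin_duration bin duration in seconds (bookkeeping only).
#' @export
fir_kernel <- function(H, b = 0, bin_duration = 0.010) {
  H <- as.matrix(H)
  if (!all(is.finite(H)) || !is.finite(b)) stop("kernel weights must be finite")
  structure(list(H = H, b = b, bin_duration = bin_duration),
            class = "fir_kernel")
}

# shared causal convolution: out(t) = sum_i sum_f H[f,i] x[f, t-i+1],
# zero-padded before stimulus onset.
causal_conv <- function(X, H) {
  as.numeric(causal_conv_cpp(as.matrix(X), as.matrix(H)))
}

#' Predicted rate of a FIR spectro-temporal filter
#'
#' `y(t) = b + sum_i sum_f h_fi x_f(t - (i-1))`: convolution with the stimulus
#' in time (causal, zero-padded before onset) and summation across frequency.
#'
#' @param spec a [spectrogram()] or channel-by-time matrix.
#' @param k a [fir_kernel()].
#' @return Numeric rate sequence, one value per stimulus bin.
#' @export
fir_predict <- function(spec, k) {
  X <- if (inherits(spec, "spectrogram")) spec$values else as.matrix(spec)
  if (nrow(X) != nrow(k$H))
    stop("shape error: spectrogram has ", nrow(X), " channels, kernel expects ",
         nrow(k$H))
  k$b + causal_conv(X, k$H)
}

#' Project a spectrogram onto spectral channels
#'
#' `s_j(t) = sum_f h_sj(f) x_f(t)`: maps the C-dimensional spectrogram into a
#' D-dimensional spectral subspace.
#'
#' @param spec a [spectrogram()] or matrix.
#' @param Hs `C x D` spectral weighting matrix (columns are channels).
#' @return `D x T` matrix of channel signals.
#' @export
spectral_project <- function(spec, Hs) {
  X <- if (inherits(spec, "spectrogram")) spec$values else as.matrix(spec)
  Hs <- as.matrix(Hs)
  if (nrow(X) != nrow(Hs))
    stop("shape error: Hs must have one row per spectrogram channel")
  crossprod(Hs, X)
}

#' Compose a factorized kernel into its full FIR matrix
#'
#' `H = Hs Ht`; the result has rank at most `D`.
#'
#' @param Hs `C x D` spectral weighting matrix.
#' @param Ht `D x U` temporal filtering matrix.
#' @return `C x U` matrix.
#' @export
compose_factorized <- function(Hs, Ht) {
  Hs <- as.matrix(Hs)
  Ht <- as.matrix(Ht)
  if (ncol(Hs) != nrow(Ht))
    stop("shape error: ncol(Hs) must equal nrow(Ht)")
  Hs %*% Ht
}

#' Predicted rate of a factorized spectro-temporal filter
#'
#' Projects the spectrogram onto `D` spectral channels, convolves each channel
#' with its temporal filter (row `j` of `Ht`), sums across channels and adds
#' the baseline. Identical to [fir_predict()] on the composed matrix.
#'
#' @inheritParams spectral_project
#' @param Ht `D x U` temporal filtering matrix.
#' @param b baseline offset.
#' @return Numeric rate sequence.
#' @export
factorized_predict <- function(spec, Hs, Ht, b = 0) {
  S <- spectral_project(spec, Hs)
  b + causal_conv(S, as.matrix(Ht))
}

#' Gaussian spectral weights
#'
#' One spectral channel parameterized by center frequency and bandwidth:
#' `h(f) = (1 / (sigma * sqrt(2*pi))) * exp(-(f - f0)^2 / (2 sigma^2))`
#' evaluated on the filterbank frequency grid.
#'
#' @param f0 center frequency in Hz.
#' @param sigma bandwidth in Hz (> 0).
#' @param grid numeric vector of channel center frequencies in Hz.
#' @return Numeric weight vector, one weight per grid frequency.
#' @export
gaussian_weights <- function(f0, sigma, grid) {
  if (sigma <= 0) stop("domain error: sigma must be > 0")
  exp(-(grid - f0)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

#' Morlet spectral weights
#'
#' `h(f) = Re[ exp(-(f - f0)^2 / sigma^2 - i z (f - f0)) ]`, i.e. a Gaussian
#' envelope (note: variance convention without the factor 2) carrying an
#' oscillation of wavenumber `z`, which gives inhibitory sidebands.
#'
#' @inheritParams gaussian_weights
#' @param z sideband wavenumber (radians per Hz).
#' @export
morlet_weights <- function(f0, sigma, z, grid) {
  if (sigma <= 0) stop("domain error: sigma must be > 0")
  exp(-(grid - f0)^2 / sigma^2) * cos(z * (grid - f0))
}

#' Difference-of-exponentials temporal kernel
#'
#' `h(i) = A1 exp(-(i - theta1)/tau1) - A2 exp(-(i - theta2)/tau2)` over lags
#' `i = 0 ... U-1` (units of bins); each exponential term is zero before its
#' own onset latency `theta`.
#'
#' @param A1,A2 gains of the positive and negative lobes.
#' @param tau1,tau2 decay constants in bins (> 0).
#' @param theta1,theta2 onset latencies in bins.
#' @param U kernel length in bins.
#' @return Numeric kernel of length `U` (element k corresponds to lag i = k-1).
#' @export
diff_exp_kernel <- function(A1, tau1, theta1, A2, tau2, theta2, U) {
  if (tau1 <= 0 || tau2 <= 0) stop("domain error: tau must be > 0")
  i <- 0:(U - 1)
  pos <- ifelse(i >= theta1, A1 * exp(-(i - theta1) / tau1), 0)
  neg <- ifelse(i >= theta2, A2 * exp(-(i - theta2) / tau2), 0)
  pos - neg
}

#' Pole-zero (rational transfer function) temporal kernel
#'
#' The continuous-time filter `G(s) = A exp(-l s) prod_k (s - z_k) /
#' prod_m (s + p_m)` with real positive poles (so the impulse response is a
#' causal sum of decaying exponentials) and `Z <= P - 1` zeros. The impulse
#' response is obtained by partial-fraction expansion, shifted by the latency
#' `l`, sampled at bin centers and truncated to `U` bins.
#'
#' @param A gain.
#' @param l latency (delay) in seconds, >= 0; fractional delays are allowed.
#' @param poles vector of `P >= 1` positive pole rates (1/s).
#' @param zeros vector of `Z <= P - 1` real zero rates (1/s); may be empty.
#' @param U kernel length in bins.
#' @param bin_duration bin duration in seconds.
#' @return Numeric kernel of length `U`.
#' @export
pole_zero_kernel <- function(A, l, poles, zeros = numeric(0), U,
                             bin_duration = 0.010) {
  P <- length(poles)
  Z <- length(zeros)
  if (P < 1) stop("improper filter: at least one pole required")
  if (Z >= P) stop("improper filter: need Z <= P - 1")
  if (any(poles <= 0)) stop("instability: poles must be positive")
  if (l < 0) stop("latency must be >= 0")
  if (A == 0) return(numeric(U))
  # nudge repeated poles apart so first-order partial fractions suffice
  poles <- sort(poles)
  for (m in seq_len(P)[-1]) {
    if (poles[m] - poles[m - 1] < 1e-6 * poles[m])
      poles[m] <- poles[m - 1] * (1 + 1e-6)
  }
  # residue of G at s = -p_m (first-order poles)
  resid <- vapply(seq_len(P), function(m) {
    num <- if (Z > 0) prod(-poles[m] - zeros) else 1
    den <- prod(poles[-m] - poles[m])
    if (P == 1) den <- 1
    A * num / den
  }, numeric(1))
  tt <- ((1:U) - 0.5) * bin_duration
  h <- numeric(U)
  on_time <- tt >= l
  for (m in seq_len(P))
    h[on_time] <- h[on_time] + resid[m] * exp(-poles[m] * (tt[on_time] - l))
  h
}
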