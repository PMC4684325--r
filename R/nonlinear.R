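#' Double-exponential output nonlinearity
#'
#' `y(t) = phi1 + phi2 * exp(-exp(phi3 * (x(t) - phi4)))`: a sigmoid between
#' the asymptotes `phi1` and `phi1 + phi2` modeling spike threshold and
#' saturation. `phi3` sets the slope (negative values give a rising sigmoid)
#' and `phi4` the inflection offset.
#'
#' @param x numeric input sequence (linear model output).
#' @param phi1 baseline rate.
#' @param phi2 response amplitude.
#' @param phi3 slope (1/input units).
#' @param phi4 inflection offset (input units).
#' @return Numeric sequence of the same length as `x`.
#' @export
dexp_apply <- function(x, phi1, phi2, phi3, phi4) {
  u <- phi3 * (x - phi4)
  u <- pmin(pmax(u, -30), 30)
  phi1 + phi2 * exp(-exp(u))
}

#' Short-term synaptic plasticity dynamics
#'
#' Each channel drives a simulated synapse whose fraction of available
#' vesicles `d(t)` is depleted by previous input and recovers with time
#' constant `tau_rec`:
#' depression (`nu > 0`): `d(t) = d(t-1) - nu s(t-1) d(t-1) + (1 - d(t-1))/tau`;
#' facilitation (`nu < 0`): the depletion term becomes `-nu s(t-1) (2 - d(t-1))`.
#' The input is rectified at zero, shifted by the baseline presynaptic level
#' `s0`, and the output is `d(t) * (s(t) + s0)`. `d` starts at 1 and is
#' clipped to \[0, 2\].
#'
#' @param s channel signal: numeric vector (one channel) or `D x T` matrix.
#' @param nu release fraction per channel; `nu > 0` depression, `nu < 0`
#'   facilitation, `|nu| <= 1`.
#' @param tau_rec recovery time constant per channel, in bins (> 0).
#' @param s0 baseline presynaptic level per channel (>= 0).
#' @return List with `output` (same shape as `s`) and `d` (vesicle fraction
#'   trajectory, same shape).
#' @export
stp_apply <- function(s, nu, tau_rec, s0 = 0) {
  vec <- is.null(dim(s))
  S <- if (vec) matrix(s, nrow = 1) else as.matrix(s)
  D <- nrow(S)
  nu <- rep_len(nu, D)
  tau_rec <- rep_len(tau_rec, D)
  s0 <- rep_len(s0, D)
  if (any(tau_rec <= 0)) stop("domain error: tau_rec must be > 0")
  if (any(abs(nu) > 1)) stop("domain error: |nu| <= 1 required")
  Sd <- pmax(S, 0) + s0
  d <- stp_recurse_cpp(Sd, nu, tau_rec)
  out <- d * Sd
  if (vec) list(output = drop(out), d = drop(d))
  else list(output = out, d = d)
}
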