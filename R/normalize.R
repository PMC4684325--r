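#' Inter-module signal normalization
#'
#' Signals crossing a module boundary are standardized per channel using
#' moments estimated on the estimation data and shifted so that the minimum of
#' the standardized estimation signal is zero:
#' `y_i(t) = (x_i(t) - mu_i)/sigma_i - z_i`, with
#' `z_i = min_t (x_i(t) - mu_i)/sigma_i`. This keeps signals bounded and
#' positive-definite on the estimation set; the same frozen `(mu, sigma, z)`
#' are re-applied to validation data, where negative outputs are permitted.
#' Channels with near-zero variance (sd below 1e-12) pass through with
#' `sigma` replaced by 1.
#'
#' @param signal numeric vector (one channel) or channels-by-time matrix.
#' @return `fit_normalization` returns a `"normalization_state"` list with
#'   per-channel `mu`, `sigma`, `z`; `apply_normalization` returns the
#'   normalized signal in the shape of its input.
#' @export
fit_normalization <- function(signal) {
  vec <- is.null(dim(signal))
  X <- if (vec) matrix(signal, nrow = 1) else as.matrix(signal)
  if (ncol(X) < 1) stop("empty signal")
  mu <- rowMeans(X)
  sigma <- sqrt(rowSums((X - mu)^2) / max(ncol(X) - 1, 1))
  degenerate <- !is.finite(sigma) | sigma < 1e-12
  sigma[degenerate] <- 1
  m <- (X - mu) / sigma
  z <- apply(m, 1, min)
  structure(list(mu = mu, sigma = sigma, z = z, degenerate = degenerate),
            class = "normalization_state")
}

#' @rdname fit_normalization
#' @param state a state returned by `fit_normalization`, frozen on the
#'   estimation data.
#' @export
apply_normalization <- function(signal, state) {
  stopifnot(inherits(state, "normalization_state"))
  vec <- is.null(dim(signal))
  X <- if (vec) matrix(signal, nrow = 1) else as.matrix(signal)
  if (nrow(X) != length(state$mu))
    stop("shape error: state has ", length(state$mu), " channels")
  out <- (X - state$mu) / state$sigma - state$z
  if (vec) drop(out) else out
}
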