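#' Normalized mean squared error
#'
#' `e_mse = sum (p - r)^2 / sum (r - rbar)^2`; 0 is a perfect prediction and
#' 1 the level of a random (constant-at-the-mean) prediction.
#'
#' @param p predicted rate sequence.
#' @param r observed rate sequence (the PSTH); must not be constant.
#' @return Scalar NMSE.
#' @export
nmse <- function(p, r) {
  if (length(p) != length(r)) stop("shape error: unequal lengths")
  if (length(r) < 2) stop("need at least 2 bins")
  den <- sum((r - mean(r))^2)
  if (den <= 0) stop("degenerate target: response is constant")
  sum((p - r)^2) / den
}

# contiguous temporal fold ids (1-based) and the per-deleted-fold NMSE
# denominators, precomputed once per target
make_folds <- function(Tn, folds) {
  if (Tn < folds) stop("fold error: signal shorter than fold count")
  rep(seq_len(folds), each = ceiling(Tn / folds), length.out = Tn)
}

fold_denominators <- function(r, fold, folds) {
  vapply(seq_len(folds), function(k) {
    rk <- r[fold != k]
    sum((rk - mean(rk))^2)
  }, numeric(1))
}

#' Jackknife-shrunken NMSE cost
#'
#' The fitting cost: NMSE scaled toward 1 according to its reliability.
#' The standard error `sigma_mse` of the NMSE is estimated by a
#' delete-one-fold jackknife over contiguous temporal segments, and the
#' shrunken cost is
#' `e = 1 - (1 - e_mse) * max(0, 1 - (sigma_mse / (1 - e_mse))^2)`,
#' so an unreliable improvement (`sigma_mse >> 1 - e_mse`) is shrunk back to
#' chance level 1, while `sigma_mse = 0` leaves the NMSE untouched.
#'
#' @inheritParams nmse
#' @param folds number of jackknife folds (default 10).
#' @return A list of class `"cost_value"` with `e_mse`, `sigma_mse` and the
#'   shrunken cost `e`.
#' @export
shrunken_cost <- function(p, r, folds = 10) {
  if (length(p) != length(r)) stop("shape error: unequal lengths")
  fold <- make_folds(length(r), folds)
  den_all <- sum((r - mean(r))^2)
  if (den_all <= 0) stop("degenerate target: response is constant")
  den_fold <- fold_denominators(r, fold, folds)
  v <- shrunk_cost_cpp(as.numeric(p), as.numeric(r), as.integer(fold) - 1L,
                       as.integer(folds), den_fold, den_all)
  structure(list(e_mse = unname(v["e_mse"]), sigma_mse = unname(v["sigma_mse"]),
                 e = unname(v["e"])), class = "cost_value")
}

#' @export
print.cost_value <- function(x, ...) {
  cat(sprintf("cost: e = %.4g (NMSE %.4g, jackknife SE %.3g)\n",
              x$e, x$e_mse, x$sigma_mse))
  invisible(x)
}

#' Poisson negative log-likelihood cost
#'
#' `sum_t [ p(t) - r(t) log p(t) ]` up to data-only constants: the negative
#' log-likelihood of the observed rates under Poisson spiking with predicted
#' intensity `p`. Predictions are floored at a small positive value so the
#' logarithm is defined.
#'
#' @inheritParams nmse
#' @param floor lower bound applied to `p` (default 1e-12).
#' @return Scalar cost (lower is better).
#' @export
poisson_nlogl <- function(p, r, floor = 1e-12) {
  if (length(p) != length(r)) stop("shape error: unequal lengths")
  if (any(r < 0)) stop("data error: negative rates in r")
  p <- pmax(p, floor)
  sum(p - r * log(p))
}
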