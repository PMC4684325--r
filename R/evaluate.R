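#' Prediction correlation
#'
#' Pearson's R between the predicted and observed PSTH, the primary
#' performance metric for encoding models.
#'
#' @param p predicted rate sequence.
#' @param r observed rate sequence.
#' @return Scalar correlation in \[-1, 1\].
#' @export
prediction_correlation <- function(p, r) {
  if (length(p) != length(r)) stop("shape error: unequal lengths")
  if (length(p) < 3) stop("need at least 3 bins")
  if (stats::sd(p) == 0 || stats::sd(r) == 0)
    stop("undefined correlation: constant input")
  stats::cor(p, r)
}

#' Trial-to-trial response correlation (TTRC)
#'
#' Mean Pearson correlation between all unique trial pairs; 1 for perfectly
#' repeatable responses, near 0 for pure noise. Used to correct prediction
#' correlations for the finite sampling of the validation response.
#'
#' @param trials `M x T` trial-by-time response matrix, `M >= 2`.
#' @return Scalar TTRC.
#' @export
ttrc <- function(trials) {
  trials <- as.matrix(trials)
  M <- nrow(trials)
  if (M < 2) stop("insufficient trials: need M >= 2")
  sds <- apply(trials, 1, stats::sd)
  vals <- c()
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      if (sds[i] == 0 || sds[j] == 0) {
        warning("constant trial skipped in TTRC pair (", i, ",", j, ")")
        next
      }
      vals <- c(vals, stats::cor(trials[i, ], trials[j, ]))
    }
  }
  if (length(vals) == 0) stop("all trial pairs degenerate")
  mean(vals)
}

#' Noise-corrected prediction correlation
#'
#' Mean correlation between the prediction and each single-trial response,
#' normalized by the square root of the TTRC: an estimate of the correlation
#' the model would achieve against a noiseless response. Under additive
#' trial-to-trial noise, `corr(r_i, p) = R_true * sqrt(TTRC)` in expectation,
#' so dividing the mean single-trial correlation by `sqrt(TTRC)` recovers
#' the noiseless correlation `R_true` (dividing by the TTRC itself would
#' overcorrect by a further `1/sqrt(TTRC)`; see the methods vignette).
#'
#' @param p predicted rate sequence.
#' @param trials `M x T` response trials.
#' @return Scalar normalized correlation.
#' @export
normalized_correlation <- function(p, trials) {
  trials <- as.matrix(trials)
  tt <- ttrc(trials)
  if (tt <= 0)
    stop("instability: TTRC <= 0, normalized correlation undefined")
  cc <- apply(trials, 1, function(ri) {
    if (stats::sd(ri) == 0 || stats::sd(p) == 0) return(NA_real_)
    stats::cor(ri, p)
  })
  mean(cc, na.rm = TRUE) / sqrt(tt)
}

#' Response signal-to-noise ratio
#'
#' Assuming additive trial-to-trial noise, the total single-trial variance
#' splits into stimulus-locked ("actual") variance — estimated as the mean
#' covariance between distinct trials — and noise variance;
#' `SNR = sigma_actual^2 / (sigma_r^2 - sigma_actual^2)`. Negative covariance
#' estimates are clipped to zero; identical trials give `snr = Inf`.
#'
#' @param trials `M x T` response trials, `M >= 2`.
#' @return List of class `"snr_result"` with `sigma_r2`, `sigma_actual2`,
#'   `snr`.
#' @export
response_snr <- function(trials) {
  trials <- as.matrix(trials)
  M <- nrow(trials)
  if (M < 2) stop("insufficient trials: need M >= 2")
  cv <- stats::cov(t(trials))
  sigma_r2 <- mean(diag(cv))
  sigma_actual2 <- max(mean(cv[upper.tri(cv)]), 0)
  noise <- sigma_r2 - sigma_actual2
  snr <- if (noise <= 0) Inf else sigma_actual2 / noise
  structure(list(sigma_r2 = sigma_r2, sigma_actual2 = sigma_actual2,
                 snr = max(snr, 0)),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("response SNR = %.4g (signal var %.4g / noise var %.4g)\n",
              x$snr, x$sigma_actual2, x$sigma_r2 - x$sigma_actual2))
  invisible(x)
}

#' Extrapolate prediction correlation to infinite estimation data
#'
#' Under additive estimation noise whose prediction-error variance falls as
#' 1/T, inverse squared prediction correlation is linear in inverse sample
#' count: `1/R_T^2 = 1/R_inf^2 + A/T`. Fitting that line to correlations
#' measured at several estimation-set sizes yields the asymptote `R_inf`.
#'
#' @param T_values estimation sample counts (>= 3 distinct values).
#' @param R_T mean prediction correlations at those sample counts, in (0, 1].
#' @return List of class `"extrapolation_fit"` with `R_inf`, `A`, the fit
#'   inputs and the fitted line coefficients.
#' @export
extrapolate_rinf <- function(T_values, R_T) {
  if (length(T_values) != length(R_T)) stop("shape error: unequal lengths")
  if (length(unique(T_values)) < 3)
    stop("need at least 3 distinct estimation sizes")
  if (any(R_T <= 0) || any(R_T > 1)) stop("R_T values must lie in (0, 1]")
  y <- 1 / R_T^2
  x <- 1 / T_values
  fit <- stats::lm(y ~ x)
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  if (intercept <= 0)
    stop("extrapolation failure: nonpositive intercept (1/R_inf^2 = ",
         signif(intercept, 4), ")")
  if (slope < -1e-8 * intercept)
    warning("negative noise slope A clipped to 0")
  A <- max(slope, 0)
  structure(list(R_inf = intercept^(-1 / 2), A = A,
                 T_values = T_values, R_T = R_T,
                 intercept = intercept, slope = slope),
            class = "extrapolation_fit")
}

#' @export
print.extrapolation_fit <- function(x, ...) {
  cat(sprintf("infinite-data extrapolation: R_inf = %.4f (A = %.4g, %d sizes)\n",
              x$R_inf, x$A, length(x$T_values)))
  invisible(x)
}

#' Pareto front of model complexity versus performance
#'
#' Returns the non-dominated subset of (parameter count, performance) points:
#' a model is on the front iff no other model has at most its parameter count
#' and at least its performance, with one of the two strict. Ties (equal
#' count and performance) are both retained. The front is returned sorted by
#' parameter count, so its performance is non-decreasing.
#'
#' @param points data.frame with columns `param_count`, `performance` and
#'   optionally `model_name`.
#' @return The rows of `points` on the front, ordered by `param_count`.
#' @export
pareto_front <- function(points) {
  points <- as.data.frame(points)
  if (nrow(points) == 0) stop("empty point set")
  ord <- order(points$param_count, -points$performance)
  pts <- points[ord, , drop = FALSE]
  # sorted sweep: within a parameter-count group only the maximal performance
  # survives (ties retained); across groups it must strictly beat every
  # cheaper model's performance
  keep <- logical(nrow(pts))
  best_prev <- -Inf
  i <- 1
  while (i <= nrow(pts)) {
    grp <- which(pts$param_count == pts$param_count[i])
    grp <- grp[grp >= i]
    gmax <- pts$performance[grp[1]]
    keep[grp] <- pts$performance[grp] == gmax & gmax > best_prev
    best_prev <- max(best_prev, gmax)
    i <- grp[length(grp)] + 1
  }
  out <- pts[keep, , drop = FALSE]
  out[order(out$param_count, out$performance), , drop = FALSE]
}

#' Paired comparison of two models across neurons
#'
#' Two-sided exact sign test on the paired per-neuron score differences,
#' with the mean difference and its standard error.
#'
#' @param scores_a,scores_b paired per-neuron scores (same neurons, same
#'   order), `n >= 6`.
#' @return List with `mean_diff`, `se_diff`, `p_value`, `n_nonzero`.
#' @export
compare_models <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("shape error: unequal lengths")
  if (length(scores_a) < 6) stop("need at least 6 paired scores")
  d <- scores_a - scores_b
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(list(mean_diff = 0, se_diff = 0, p_value = 1,
                n_nonzero = 0L))
  }
  bt <- stats::binom.test(sum(nz > 0), length(nz), 0.5,
                          alternative = "two.sided")
  list(mean_diff = mean(d),
       se_diff = stats::sd(d) / sqrt(length(d)),
       p_value = bt$p.value,
       n_nonzero = length(nz))
}
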