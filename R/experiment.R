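#' Subsample the estimation data of a benchmark suite
#'
#' Keeps a contiguous prefix of whole estimation stimuli (never scattered
#' bins), emulating shorter recording sessions for data-size analyses.
#'
#' @param suite an [make_benchmark_suite()] result.
#' @param fraction fraction of estimation stimuli to keep (0, 1].
#' @return The suite with truncated estimation stimulus and trials.
#' @export
subsample_estimation <- function(suite, fraction) {
  stopifnot(inherits(suite, "strf_benchmark"))
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  n_keep <- max(1, round(fraction * suite$config$n_est_stimuli))
  bins <- n_keep * suite$stim_bins
  suite$est_stim$values <- suite$est_stim$values[, seq_len(bins), drop = FALSE]
  suite$neurons <- lapply(suite$neurons, function(n) {
    n$est_trials <- n$est_trials[, seq_len(bins), drop = FALSE]
    n
  })
  suite$config$n_est_stimuli <- n_keep
  suite
}

#' Fit and score a model grid on a benchmark suite
#'
#' For every (neuron, model, estimation fraction) cell: fits the model on the
#' (possibly subsampled) estimation data, predicts the validation response,
#' and records one row of scores. Per-cell failures are caught and recorded
#' as failed rows rather than aborting the grid. The whole experiment is
#' deterministic given the suite.
#'
#' @param suite an [make_benchmark_suite()] result.
#' @param models named list of [strf_model()] chains to fit.
#' @param fractions estimation-data fractions to evaluate (default 1).
#' @param control an [strf_control()].
#' @param out_dir optional directory: writes `scores.csv` and one fitted
#'   model JSON per cell.
#' @return data.frame with one row per cell: `neuron_id`, `model_name`,
#'   `fraction`, `param_count`, `r_est`, `r_val`, `r_val_normalized`, `snr`,
#'   `nmse_val`, `nlogl_val`, `ok`. A model whose fitted prediction is
#'   constant (the shrinkage cost can legitimately reject every step on
#'   very noisy data) carries no stimulus information and is scored with
#'   correlation 0.
#' @export
run_experiment <- function(suite, models, fractions = 1,
                           control = strf_control(), out_dir = NULL) {
  stopifnot(inherits(suite, "strf_benchmark"))
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "name")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  score_cor <- function(p, r) {
    cc <- suppressWarnings(stats::cor(p, r))
    if (!is.finite(cc)) 0 else cc
  }
  rows <- list()
  for (frac in fractions) {
    sub <- if (frac < 1) subsample_estimation(suite, frac) else suite
    for (n in sub$neurons) {
      est_psth <- psth(n$est_trials)
      val_psth <- psth(n$val_trials)
      snr_est <- response_snr(n$est_trials)$snr
      for (mn in names(models)) {
        row <- data.frame(neuron_id = n$id, model_name = mn, fraction = frac,
                          param_count = count_parameters(models[[mn]]),
                          r_est = NA_real_, r_val = NA_real_,
                          r_val_normalized = NA_real_, snr = snr_est,
                          nmse_val = NA_real_, nlogl_val = NA_real_,
                          ok = FALSE)
        res <- tryCatch({
          fit <- strf(models[[mn]], sub$est_stim, n$est_trials,
                      control = control)
          pv <- predict(fit, suite$val_stim)
          row$r_est <- score_cor(fitted(fit), est_psth)
          row$r_val <- score_cor(pv, val_psth)
          row$r_val_normalized <- tryCatch(
            normalized_correlation(pv, n$val_trials),
            error = function(e) NA_real_)
          row$nmse_val <- nmse(pv, val_psth)
          row$nlogl_val <- poisson_nlogl(pmax(pv, 1e-6), pmax(val_psth, 0)) /
            length(pv)
          row$ok <- TRUE
          if (!is.null(out_dir))
            serialize_chain(fit$chain,
                            file.path(out_dir, sprintf("%s_%s_f%03d.json",
                                                       n$id, mn,
                                                       round(frac * 100))))
          row
        }, error = function(e) {
          row$model_name <- mn
          attr(row, "error") <- conditionMessage(e)
          row
        })
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  scores <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
  scores
}

#' Infinite-data extrapolation experiment on a benchmark suite
#'
#' Fits one model at several estimation-data fractions, averages the
#' validation prediction correlation over neurons at each size, and fits the
#' inverse-square law to extrapolate the infinite-data asymptote.
#'
#' @inheritParams run_experiment
#' @param model a single [strf_model()] chain.
#' @param fractions at least 3 distinct estimation fractions.
#' @return List with the scores table, the per-size mean correlations and
#'   the [extrapolate_rinf()] fit.
#' @export
extrapolation_experiment <- function(suite, model, fractions = c(0.1, 0.25, 0.5, 1),
                                     control = strf_control()) {
  scores <- run_experiment(suite, stats::setNames(list(model), model$name),
                           fractions = fractions, control = control)
  ok <- scores[scores$ok & is.finite(scores$r_val) & scores$r_val > 0, ]
  agg <- stats::aggregate(r_val ~ fraction, data = ok, FUN = mean)
  bins_total <- ncol(suite$est_stim$values)
  T_values <- round(agg$fraction * bins_total)
  fit <- extrapolate_rinf(T_values, pmin(agg$r_val, 1))
  list(scores = scores, T_values = T_values, R_T = agg$r_val, fit = fit)
}
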