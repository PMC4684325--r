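#' Modulation-limited noise stimulus
#'
#' Generates a nonnegative spectrogram whose spectro-temporal modulation
#' content is concentrated below the given cutoffs, emulating 1/f-style
#' noise built by low-pass filtering the spectrogram of white noise: a white
#' Gaussian channel-by-time matrix is masked in the 2-D Fourier domain
#' (temporal modulations above `temporal_cutoff` Hz and spectral modulations
#' above `spectral_cutoff` cycles/channel removed), shifted to be
#' nonnegative and scaled to unit mean.
#'
#' @param C number of channels.
#' @param T_bins number of time bins (>= 16).
#' @param temporal_cutoff temporal modulation cutoff in Hz (below the bin
#'   Nyquist).
#' @param spectral_cutoff spectral modulation cutoff in cycles/channel
#'   (<= 0.5).
#' @param bin_duration bin duration in seconds.
#' @param f_low,f_high frequency band of the channel grid.
#' @param seed integer seed; the same seed reproduces the same stimulus.
#' @return A [spectrogram()].
#' @export
generate_modulation_noise <- function(C = 18, T_bins = 300,
                                      temporal_cutoff = 20,
                                      spectral_cutoff = 0.25,
                                      bin_duration = 0.010,
                                      f_low = 200, f_high = 20000,
                                      seed = 1) {
  if (T_bins < 16) stop("config error: need T_bins >= 16")
  if (temporal_cutoff <= 0 || temporal_cutoff >= 0.5 / bin_duration)
    stop("config error: temporal_cutoff must lie below the bin Nyquist")
  if (spectral_cutoff <= 0 || spectral_cutoff > 0.5)
    stop("config error: spectral_cutoff must lie in (0, 0.5]")
  z <- with_seed(seed, matrix(stats::rnorm(C * T_bins), C, T_bins))
  ft <- (seq_len(T_bins) - 1)
  ft <- ifelse(ft > T_bins / 2, ft - T_bins, ft) / (T_bins * bin_duration)
  fs <- (seq_len(C) - 1)
  fs <- ifelse(fs > C / 2, fs - C, fs) / C
  mask <- outer(abs(fs) <= spectral_cutoff, abs(ft) <= temporal_cutoff)
  Z <- stats::fft(z) * mask
  y <- Re(stats::fft(Z, inverse = TRUE)) / length(Z)
  y <- y - min(y)
  if (mean(y) > 0) y <- y / mean(y)
  spectrogram(y, center_frequencies(C, f_low, f_high), bin_duration)
}

#' Define a ground-truth simulated neuron
#'
#' Wraps a fully parameterized model chain into a response generator with a
#' known decomposition `r(t) = r_lin(t) + r_res(t) + noise`: `r_lin` is the
#' chain's prediction, `r_res` an optional stimulus-locked distortion that no
#' linear model can capture (a squared, rescaled second linear projection of
#' the stimulus, frozen on the estimation stimulus), and the per-trial noise
#' is Gaussian (or Poisson) with variance set from the designed response SNR.
#'
#' @param chain a model chain with chosen (true) parameters.
#' @param est_stim estimation stimulus ([spectrogram()]); used to fit the
#'   chain normalization and freeze the `r_res` scaling and noise variance.
#' @param snr designed response signal-to-noise ratio
#'   (signal variance / single-trial noise variance).
#' @param rres_frac fraction of signal variance carried by the unmodelable
#'   component `r_res` (default 0.2).
#' @param noise `"gaussian"` (additive rate noise, default) or `"poisson"`.
#' @param seed seed for the frozen `r_res` projection.
#' @return Object of class `"ground_truth_neuron"`.
#' @export
ground_truth_neuron <- function(chain, est_stim, snr = 1, rres_frac = 0.2,
                                noise = c("gaussian", "poisson"), seed = 1) {
  noise <- match.arg(noise)
  stopifnot(inherits(chain, "strf_chain"))
  if (rres_frac < 0 || rres_frac >= 1) stop("rres_frac must lie in [0, 1)")
  chain <- fit_chain_normalization(chain, est_stim)
  X <- est_stim$values
  r_lin <- chain_predict(chain, est_stim)
  wres <- with_seed(seed + 211L, stats::rnorm(nrow(X)))
  rres_center <- mean(drop(wres %*% X))
  rres_scale <- 0
  if (rres_frac > 0) {
    v <- (drop(wres %*% X) - rres_center)^2
    target_var <- rres_frac / (1 - rres_frac) * stats::var(r_lin)
    rres_scale <- sqrt(target_var / max(stats::var(v), 1e-12))
  }
  signal <- r_lin + rres_scale * (drop(wres %*% X) - rres_center)^2
  noise_sd <- sqrt(stats::var(signal) / snr)
  structure(list(chain = chain, snr = snr, rres_frac = rres_frac,
                 wres = wres, rres_center = rres_center,
                 rres_scale = rres_scale, noise = noise,
                 noise_sd = noise_sd),
            class = "ground_truth_neuron")
}

# noiseless stimulus-locked response of a ground-truth neuron
neuron_signal <- function(neuron, stim) {
  X <- if (inherits(stim, "spectrogram")) stim$values else as.matrix(stim)
  r_lin <- chain_predict(neuron$chain, stim)
  r_lin + neuron$rres_scale * (drop(neuron$wres %*% X) - neuron$rres_center)^2
}

#' Simulate response trials of a ground-truth neuron
#'
#' Each trial is the neuron's noiseless stimulus-locked response plus an
#' independent noise draw (Gaussian with the neuron's designed SD, or
#' Poisson counts around the rectified rate).
#'
#' @param neuron a [ground_truth_neuron()].
#' @param stim stimulus [spectrogram()].
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @return `n_trials x T` matrix of trial responses.
#' @export
simulate_trials <- function(neuron, stim, n_trials, seed = 1) {
  stopifnot(inherits(neuron, "ground_truth_neuron"))
  signal <- neuron_signal(neuron, stim)
  Tn <- length(signal)
  with_seed(seed, {
    if (neuron$noise == "gaussian") {
      t(vapply(seq_len(n_trials), function(i)
        signal + stats::rnorm(Tn, 0, neuron$noise_sd), numeric(Tn)))
    } else {
      if (any(signal < 0))
        warning("negative rates rectified for Poisson trials")
      lam <- pmax(signal, 0)
      t(vapply(seq_len(n_trials), function(i)
        stats::rpois(Tn, lam) * 1.0, numeric(Tn)))
    }
  })
}

#' Trial-averaged response (PSTH)
#'
#' @param trials trial-by-time matrix.
#' @return Numeric vector of per-bin trial means.
#' @export
psth <- function(trials) colMeans(as.matrix(trials))

# Place the truth chain's output nonlinearity at a realistic operating
# point: inflection in the upper quantiles of the linear drive and a rising
# slope, giving the sparse, positively driven firing typical of cortical
# PSTHs (a blind inflection draw tends to saturate the synthetic neuron,
# which no real recording resembles).
calibrate_dexp_operating_point <- function(chain, est_stim, seed) {
  types <- vapply(chain$modules, `[[`, "", "type")
  kd <- which(types == "dexp")
  if (length(kd) != 1) return(chain)
  dx <- forward_prefix(chain, est_stim$values, seq_along(chain$modules), kd)
  draws <- with_seed(seed, stats::runif(2))
  m <- chain$modules[[kd]]
  m$phi4 <- stats::quantile(dx, 0.55 + 0.25 * draws[1], names = FALSE)
  m$phi3 <- -(0.7 + 0.6 * draws[2])
  chain$modules[[kd]] <- m
  chain
}

# truth chains for the benchmark architectures; parameters drawn
# deterministically from the seed within ranges typical of cortical neurons
benchmark_truth_chain <- function(arch, C, U, bin_duration, cf, seed) {
  with_seed(seed, {
    dexp_pars <- list(phi1 = 1 + stats::runif(1), phi2 = 15 + stats::runif(1, 0, 10),
                      phi3 = -(0.8 + stats::runif(1, 0, 0.8)),
                      phi4 = 1 + stats::runif(1, 0, 1))
    f0_pool <- exp(stats::runif(5, log(cf[3]), log(cf[C - 3])))
    mk <- function(filter, D, P = 3, Z = 1, stp = FALSE, temporal = "polezero") {
      ch <- strf_model(filter, temporal = temporal, D = D, C = C, U = U,
                       P = P, Z = Z, stp = stp, dexp = TRUE,
                       bin_duration = bin_duration)
      for (m in seq_along(ch$modules)) {
        mod <- ch$modules[[m]]
        ch$modules[[m]] <- switch(mod$type,
          gaussian = {
            mod$f0 <- sort(f0_pool[seq_len(D)])
            mod$sigma <- mod$f0 * stats::runif(D, 0.2, 0.45)
            mod
          },
          polezero = {
            base <- matrix(stats::runif(D * P, 1, 2.2), D, P) *
              matrix(rep(c(12, 45, 150)[seq_len(P)], each = D), D, P)
            mod$poles <- base
            if (Z > 0) mod$zeros <- matrix(stats::runif(D * Z, -5, 5), D, Z)
            mod$A <- stats::runif(D, 0.5, 1.5) * rep_len(c(1, -0.5, 0.8), D) * 50
            mod$l <- stats::runif(D, 0, 0.02)
            mod
          },
          stp = {
            D2 <- length(mod$nu)
            mod$nu <- stats::runif(D2, 0.15, 0.4)
            mod$tau_rec <- stats::runif(D2, 8, 20)
            mod$s0 <- stats::runif(D2, 0.2, 0.8)
            mod
          },
          dexp = {
            mod[c("phi1", "phi2", "phi3", "phi4")] <- dexp_pars
            mod
          },
          logcomp = {
            mod$phi1 <- 1
            mod
          },
          mod)
      }
      ch
    }
    if (arch == "fir_random") {
      ch <- strf_model("fir", C = C, U = U, dexp = TRUE,
                       bin_duration = bin_duration)
      # smooth random STRF: two Gaussian x difference-of-exponentials factors
      H <- matrix(0, C, U)
      for (q in 1:2) {
        w <- gaussian_weights(f0_pool[q], f0_pool[q] * 0.3, cf)
        k <- diff_exp_kernel(1, stats::runif(1, 2, 5), stats::runif(1, 0, 2),
                             0.6, stats::runif(1, 4, 8), stats::runif(1, 1, 4), U)
        H <- H + (if (q == 1) 1 else -0.7) * outer(w, k)
      }
      H <- H / max(stats::sd(H), 1e-12) * 2
      im <- which(vapply(ch$modules, `[[`, "", "type") == "fir")
      ch$modules[[im]]$H <- H
      ch$modules[[im]]$b <- 0
      id <- which(vapply(ch$modules, `[[`, "", "type") == "dexp")
      ch$modules[[id]][c("phi1", "phi2", "phi3", "phi4")] <- dexp_pars
      ch$name <- "truth-FIR"
      ch
    } else {
      switch(arch,
        gauss1_p1z0 = mk("gaussian", 1, P = 1, Z = 0),
        gauss1_p3z1 = mk("gaussian", 1, P = 3, Z = 1),
        gauss2_p3z1 = mk("gaussian", 2, P = 3, Z = 1),
        gauss3_p3z1 = mk("gaussian", 3, P = 3, Z = 1),
        gauss1_p3z1_stp = mk("gaussian", 1, P = 3, Z = 1, stp = TRUE),
        gauss2_p3z1_stp = mk("gaussian", 2, P = 3, Z = 1, stp = TRUE),
        stop("unknown architecture: ", arch))
    }
  })
}

#' Generate a seeded benchmark suite of simulated neurons
#'
#' Builds an estimation/validation stimulus pair of modulation-limited noise
#' and a population of ground-truth neurons spanning several architectures
#' and response SNR levels, mirroring the usual recording design: by default
#' 40 x 3 s estimation stimulation with 5 repetitions and 2 x 3 s validation
#' stimulation with 20 repetitions at 100 Hz binning, with SNR levels
#' bracketing the usual inclusion cut of 0.005.
#'
#' @param config optional list overriding defaults: `architectures`
#'   (character vector of truth architectures), `snr` (recycled across
#'   neurons), `rres_frac`, `n_est_stimuli`, `n_val_stimuli`,
#'   `stim_duration` (s), `est_trials`, `val_trials`, `C`, `U`,
#'   `bin_duration`.
#' @param seed integer master seed; everything the suite contains is a pure
#'   function of `(config, seed)`.
#' @return List of class `"strf_benchmark"` with `est_stim`, `val_stim`, and
#'   `neurons` (each with its generator, trial matrices and design metadata).
#' @export
make_benchmark_suite <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    architectures = c("gauss1_p3z1", "gauss2_p3z1", "gauss3_p3z1",
                      "gauss1_p1z0", "fir_random"),
    snr = c(1, 0.1, 1, 0.01, 0.003),
    rres_frac = 0.2,
    n_est_stimuli = 40, n_val_stimuli = 2, stim_duration = 3,
    est_trials = 5, val_trials = 20,
    C = 18, U = 15, bin_duration = 0.010), config)
  stim_bins <- round(cfg$stim_duration / cfg$bin_duration)
  est_bins <- cfg$n_est_stimuli * stim_bins
  val_bins <- cfg$n_val_stimuli * stim_bins
  est_stim <- generate_modulation_noise(cfg$C, est_bins,
                                        bin_duration = cfg$bin_duration,
                                        seed = seed)
  val_stim <- generate_modulation_noise(cfg$C, val_bins,
                                        bin_duration = cfg$bin_duration,
                                        seed = seed + 5000L)
  cf <- est_stim$center_freqs
  snr <- rep_len(cfg$snr, length(cfg$architectures))
  neurons <- lapply(seq_along(cfg$architectures), function(i) {
    arch <- cfg$architectures[i]
    truth <- benchmark_truth_chain(arch, cfg$C, cfg$U, cfg$bin_duration, cf,
                                   seed + 97L * i)
    truth <- calibrate_dexp_operating_point(truth, est_stim, seed + 13L * i)
    neuron <- ground_truth_neuron(truth, est_stim, snr = snr[i],
                                  rres_frac = cfg$rres_frac,
                                  seed = seed + 31L * i)
    list(id = sprintf("n%02d_%s", i, arch), architecture = arch,
         snr_design = snr[i], neuron = neuron,
         est_trials = simulate_trials(neuron, est_stim, cfg$est_trials,
                                      seed + 1000L + i),
         val_trials = simulate_trials(neuron, val_stim, cfg$val_trials,
                                      seed + 2000L + i))
  })
  structure(list(est_stim = est_stim, val_stim = val_stim,
                 neurons = neurons, config = cfg,
                 stim_bins = stim_bins, seed = as.integer(seed)),
            class = "strf_benchmark")
}

#' @export
print.strf_benchmark <- function(x, ...) {
  cat(sprintf("benchmark suite: %d neurons, est %d bins x %d trials, val %d bins x %d trials\n",
              length(x$neurons), ncol(x$est_stim$values), x$config$est_trials,
              ncol(x$val_stim$values), x$config$val_trials))
  for (n in x$neurons)
    cat(sprintf("  %s (design SNR %.3g)\n", n$id, n$snr_design))
  invisible(x)
}

#' Compare fitted and ground-truth chain parameters
#'
#' Tabulates truth and estimate for each interpretable parameter of matching
#' architectures. Spectral channels are matched by sorting on center
#' frequency, resolving the permutation ambiguity of multi-channel fits; the
#' same channel order is applied to the temporal and plasticity stages.
#'
#' @param fitted_chain,truth_chain chains of the same architecture (an
#'   `"strf"` fit is accepted for `fitted_chain`).
#' @return data.frame with `parameter`, `truth`, `estimate`, `abs_error`,
#'   `rel_error`.
#' @export
parameter_recovery_report <- function(fitted_chain, truth_chain) {
  if (inherits(fitted_chain, "strf")) fitted_chain <- fitted_chain$chain
  ft <- vapply(fitted_chain$modules, `[[`, "", "type")
  tt <- vapply(truth_chain$modules, `[[`, "", "type")
  if (!identical(ft, tt))
    stop("comparison error: architectures differ (",
         paste(ft, collapse = ","), " vs ", paste(tt, collapse = ","), ")")
  ord_of <- function(chain) {
    i <- which(vapply(chain$modules, `[[`, "", "type") %in%
                 c("gaussian", "morlet"))
    if (length(i) == 1) order(chain$modules[[i[1]]]$f0) else NULL
  }
  of <- ord_of(fitted_chain)
  ot <- ord_of(truth_chain)
  rows <- list()
  add <- function(name, tr, est) {
    rows[[length(rows) + 1]] <<- data.frame(
      parameter = name, truth = tr, estimate = est,
      abs_error = abs(est - tr),
      rel_error = ifelse(tr != 0, abs(est - tr) / abs(tr), NA_real_))
  }
  for (m in seq_along(ft)) {
    fm <- fitted_chain$modules[[m]]
    tm <- truth_chain$modules[[m]]
    chan_par <- function(x, ord) if (is.null(ord)) x else x[ord]
    switch(fm$type,
      logcomp = add("logcomp.phi1", tm$phi1, fm$phi1),
      dexp = for (nm in c("phi1", "phi2", "phi3", "phi4"))
        add(paste0("dexp.", nm), tm[[nm]], fm[[nm]]),
      gaussian = ,
      morlet = {
        for (nm in intersect(names(fm), c("f0", "sigma", "z"))) {
          tv <- chan_par(tm[[nm]], ot)
          fv <- chan_par(fm[[nm]], of)
          for (j in seq_along(tv))
            add(sprintf("%s.%s.%d", fm$type, nm, j), tv[j], fv[j])
        }
      },
      stp = for (nm in c("nu", "tau_rec", "s0")) {
        tv <- chan_par(tm[[nm]], ot)
        fv <- chan_par(fm[[nm]], of)
        for (j in seq_along(tv))
          add(sprintf("stp.%s.%d", nm, j), tv[j], fv[j])
      },
      polezero = {
        for (j in seq_along(fm$A)) {
          jt <- if (is.null(ot)) j else ot[j]
          jf <- if (is.null(of)) j else of[j]
          add(sprintf("polezero.A.%d", j), tm$A[jt], fm$A[jf])
          add(sprintf("polezero.l.%d", j), tm$l[jt], fm$l[jf])
          tp <- sort(tm$poles[jt, ])
          fp <- sort(fm$poles[jf, ])
          for (q in seq_along(tp))
            add(sprintf("polezero.pole%d.%d", q, j), tp[q], fp[q])
          if (fm$Z > 0) for (q in seq_len(fm$Z))
            add(sprintf("polezero.zero%d.%d", q, j),
                tm$zeros[jt, q], fm$zeros[jf, q])
        }
      },
      diffexp = for (nm in c("A1", "tau1", "theta1", "A2", "tau2", "theta2")) {
        tv <- chan_par(tm[[nm]], ot)
        fv <- chan_par(fm[[nm]], of)
        for (j in seq_along(tv))
          add(sprintf("diffexp.%s.%d", nm, j), tv[j], fv[j])
      },
      fir = add("fir.b", tm$b, fm$b),
      temporal = add("temporal.b", tm$b, fm$b),
      spectral = NULL)
  }
  do.call(rbind, rows)
}
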