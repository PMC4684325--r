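# Parameter vector adapters ----------------------------------------------
#
# Each module exposes its free parameters to the descent on an internal scale
# chosen so that the initial probe step delta0 = 1 is meaningful: spectral
# centers and bandwidths in log2 Hz (octave steps), poles and STP recovery
# times on a natural-log scale, latencies in milliseconds. Weight matrices and
# sigmoid parameters are fitted raw (signals crossing module boundaries are
# normalized to unit scale, which makes unit steps meaningful there too).

get_theta <- function(mod) {
  switch(mod$type,
    logcomp = log(mod$phi1),
    fir = c(as.numeric(mod$H), mod$b),
    spectral = as.numeric(mod$Hs),
    temporal = c(as.numeric(mod$Ht), mod$b),
    gaussian = as.numeric(rbind(log2(mod$f0), log2(mod$sigma))),
    morlet = as.numeric(rbind(log2(mod$f0), log2(mod$sigma), 1000 * mod$z)),
    stp = as.numeric(rbind(mod$nu, log(mod$tau_rec), mod$s0)),
    diffexp = as.numeric(rbind(asinh(mod$A1), log(mod$tau1), mod$theta1,
                               asinh(mod$A2), log(mod$tau2), mod$theta2)),
    polezero = as.numeric(rbind(asinh(mod$A), 1000 * mod$l,
                                t(log(mod$poles)),
                                if (mod$Z > 0) t(mod$zeros) else NULL)),
    dexp = c(mod$phi1, mod$phi2, mod$phi3, mod$phi4),
    stop("unknown module type"))
}

set_theta <- function(mod, theta, chain) {
  f_low <- min(chain$center_freqs)
  f_high <- max(chain$center_freqs)
  switch(mod$type,
    logcomp = {
      mod$phi1 <- exp(theta)
      mod
    },
    fir = {
      n <- length(mod$H)
      mod$H <- matrix(theta[seq_len(n)], nrow(mod$H), ncol(mod$H))
      mod$b <- theta[n + 1]
      mod
    },
    spectral = {
      mod$Hs <- matrix(theta, nrow(mod$Hs), ncol(mod$Hs))
      mod
    },
    temporal = {
      n <- length(mod$Ht)
      mod$Ht <- matrix(theta[seq_len(n)], nrow(mod$Ht), ncol(mod$Ht))
      mod$b <- theta[n + 1]
      mod
    },
    gaussian = {
      th <- matrix(theta, 2)
      mod$f0 <- pmin(pmax(2^th[1, ], f_low / 2), 2 * f_high)
      mod$sigma <- 2^th[2, ]
      mod
    },
    morlet = {
      th <- matrix(theta, 3)
      mod$f0 <- pmin(pmax(2^th[1, ], f_low / 2), 2 * f_high)
      mod$sigma <- 2^th[2, ]
      mod$z <- th[3, ] / 1000
      mod
    },
    stp = {
      th <- matrix(theta, 3)
      mod$nu <- pmin(pmax(th[1, ], -1), 1)
      mod$tau_rec <- exp(th[2, ])
      mod$s0 <- pmax(th[3, ], 0)
      mod
    },
    diffexp = {
      th <- matrix(theta, 6)
      mod$A1 <- sinh(th[1, ])
      mod$tau1 <- exp(th[2, ])
      mod$theta1 <- pmin(pmax(th[3, ], 0), chain$U)
      mod$A2 <- sinh(th[4, ])
      mod$tau2 <- exp(th[5, ])
      mod$theta2 <- pmin(pmax(th[6, ], 0), chain$U)
      mod
    },
    polezero = {
      th <- matrix(theta, 2 + mod$P + mod$Z)
      mod$A <- sinh(th[1, ])
      mod$l <- pmax(th[2, ], 0) / 1000
      mod$poles <- t(exp(th[3:(2 + mod$P), , drop = FALSE]))
      if (mod$Z > 0)
        mod$zeros <- t(th[(3 + mod$P):(2 + mod$P + mod$Z), , drop = FALSE])
      mod
    },
    dexp = {
      mod$phi1 <- theta[1]
      mod$phi2 <- theta[2]
      mod$phi3 <- theta[3]
      mod$phi4 <- theta[4]
      mod
    },
    stop("unknown module type"))
}

# Initialization ----------------------------------------------------------

init_chain_params <- function(chain, X, r) {
  cf <- chain$center_freqs
  C <- chain$C
  rbar <- mean(r)
  for (m in seq_along(chain$modules)) {
    mod <- chain$modules[[m]]
    chain$modules[[m]] <- switch(mod$type,
      logcomp = {
        mod$phi1 <- 1
        mod
      },
      fir = {
        mod$H[] <- 0
        mod$b <- rbar
        mod
      },
      temporal = {
        mod$Ht[] <- 0
        mod$b <- rbar
        mod
      },
      spectral = {
        mod$Hs[] <- 1 / C
        mod
      },
      gaussian = ,
      morlet = {
        cc <- abs(apply(X, 1, function(z)
          suppressWarnings(stats::cor(z, r))))
        cc[!is.finite(cc)] <- 0
        i0 <- which.max(cc)
        lo <- max(i0 - 1, 1)
        hi <- min(i0 + 1, C)
        spacing <- (cf[hi] - cf[lo]) / max(hi - lo, 1)
        D <- length(mod$f0)
        mod$f0 <- rep(cf[i0], D)
        mod$sigma <- rep(2 * spacing, D)
        if (mod$type == "morlet") mod$z <- rep(0, D)
        mod
      },
      stp = {
        D <- length(mod$nu)
        mod$nu <- rep(0, D)
        mod$tau_rec <- rep(0.1 / chain$bin_duration, D)
        mod$s0 <- rep(0, D)
        mod
      },
      polezero = {
        D <- length(mod$A)
        chain$modules[[m]] <- mod_polezero(D, mod$P, mod$Z)
        chain$modules[[m]]
      },
      diffexp = {
        chain$modules[[m]] <- mod_diffexp(length(mod$A1))
        chain$modules[[m]]
      },
      dexp = mod_dexp())
  }
  # scale-aware gain for parameterized temporal kernels: with unit gain the
  # partial-fraction residues make kernels tiny relative to the target, so
  # the gain is initialized to match output and target standard deviations
  act <- which(vapply(chain$modules, `[[`, "", "type") != "dexp")
  kt <- which(vapply(chain$modules[act], `[[`, "", "type") %in%
                c("polezero", "diffexp"))
  if (length(kt) == 1) {
    input <- forward_prefix(chain, X, act, kt)
    out <- module_forward(chain$modules[[act[kt]]], input, chain)
    g <- stats::sd(r) / max(stats::sd(out), 1e-9)
    mod <- chain$modules[[act[kt]]]
    if (mod$type == "polezero") mod$A <- rep(g, length(mod$A))
    else mod$A1 <- rep(g, length(mod$A1))
    chain$modules[[act[kt]]] <- mod
  }
  chain
}

# Coarse deterministic initialization of the pole-zero temporal stage:
# decay-rate scale and latency are strongly coupled (an axis-aligned descent
# cannot cross the valley between basins), so the start point is chosen from
# a small grid under the linear-phase cost before any descent.
grid_init_polezero <- function(chain, X, r, ctx) {
  types <- vapply(chain$modules, `[[`, "", "type")
  kpz <- which(types == "polezero")
  if (length(kpz) != 1) return(chain)
  act <- which(types != "dexp")
  k <- match(kpz, act)
  input <- forward_prefix(chain, X, act, k)
  mod <- chain$modules[[kpz]]
  D <- length(mod$A)
  ctx$affine <- TRUE
  best <- NULL
  for (p0 in c(5, 10, 20, 40, 80)) {
    for (l_ms in c(0, 5, 10, 15, 20)) {
      m2 <- mod
      m2$poles <- matrix(rep(p0 * c(1, 3, 10)[seq_len(mod$P)], each = D),
                         D, mod$P)
      m2$l <- rep(l_ms / 1000, D)
      out <- module_forward(m2, input, chain)
      cc <- cost_pred(out, ctx)
      if (is.null(best) || cc < best$cost)
        best <- list(cost = cc, mod = m2)
    }
  }
  chain$modules[[kpz]] <- best$mod
  chain
}

# Fitting internals -------------------------------------------------------

# normalized input to the k-th active module
forward_prefix <- function(chain, X, act, k) {
  out <- X
  if (k == 1) return(out)
  for (kk in seq_len(k - 1)) {
    out <- module_forward(chain$modules[[act[kk]]], out, chain)
    st <- fit_normalization(out)
    out <- apply_normalization(out, st)
  }
  out
}

build_lag_design <- function(S, U) {
  Cc <- nrow(S)
  Tn <- ncol(S)
  Xl <- matrix(0, Tn, Cc * U + 1)
  for (i in seq_len(U)) {
    Xl[i:Tn, ((i - 1) * Cc + 1):(i * Cc)] <- t(S[, 1:(Tn - i + 1), drop = FALSE])
  }
  Xl[, Cc * U + 1] <- 1
  Xl
}

make_cost_ctx <- function(r, folds, cost_name) {
  den_all <- sum((r - mean(r))^2)
  if (den_all <= 0) stop("degenerate target: response is constant")
  fold <- make_folds(length(r), folds)
  list(r = r, Tn = length(r), fold0 = as.integer(fold) - 1L,
       nfold = as.integer(folds),
       den_fold = fold_denominators(r, fold, folds),
       den_all = den_all, cost_name = cost_name)
}

cost_pred <- function(pred, ctx) {
  if (any(!is.finite(pred))) return(Inf)
  if (ctx$cost_name == "nmse") {
    norm_dexp_cost_cpp(pred, ctx$r, ctx$fold0, ctx$nfold, ctx$den_fold,
                       ctx$den_all, FALSE, numeric(0),
                       isTRUE(ctx$affine))[1]
  } else {
    poisson_nlogl(pred, ctx$r) / ctx$Tn
  }
}

visit_module <- function(chain, act, k, X, ctx, control, eps) {
  m_idx <- act[k]
  mod <- chain$modules[[m_idx]]
  n_act <- length(act)
  input <- forward_prefix(chain, X, act, k)
  last_type <- chain$modules[[act[n_act]]]$type
  fast <- ctx$cost_name == "nmse" &&
    mod$type %in% c("fir", "temporal") &&
    (k == n_act || (k == n_act - 1 && last_type == "dexp"))
  if (fast) {
    use_dexp <- k == n_act - 1
    dpar <- if (use_dexp) {
      dm <- chain$modules[[act[n_act]]]
      c(dm$phi1, dm$phi2, dm$phi3, dm$phi4)
    } else numeric(0)
    W <- if (mod$type == "fir") mod$H else mod$Ht
    Xl <- build_lag_design(input, ncol(W))
    theta <- c(as.numeric(W), mod$b)
    env <- new.env()
    env$out0 <- as.numeric(Xl %*% theta)
    fn <- function(th) {
      lin <- as.numeric(Xl %*% th)
      norm_dexp_cost_cpp(lin, ctx$r, ctx$fold0, ctx$nfold, ctx$den_fold,
                         ctx$den_all, use_dexp, dpar)[1]
    }
    sweep_fn <- function(par, delta) {
      linear_sweep_cpp(Xl, env$out0, delta, ctx$r, ctx$fold0, ctx$nfold,
                       ctx$den_fold, ctx$den_all, use_dexp, dpar)
    }
    accept_fn <- function(j, sign, delta) {
      env$out0 <- env$out0 + sign * delta * Xl[, j]
    }
    res <- descent_nongreedy(theta, fn, control, eps, sweep_fn, accept_fn)
    n <- length(W)
    if (mod$type == "fir") {
      mod$H <- matrix(res$par[seq_len(n)], nrow(W), ncol(W))
    } else {
      mod$Ht <- matrix(res$par[seq_len(n)], nrow(W), ncol(W))
    }
    mod$b <- res$par[n + 1]
    chain$modules[[m_idx]] <- mod
    return(list(chain = chain, improvement = res$improvement,
                steps = res$steps, cost = res$cost))
  }
  downstream <- function(out) {
    kk <- k
    while (kk < n_act) {
      st <- fit_normalization(out)
      out <- apply_normalization(out, st)
      kk <- kk + 1
      out <- module_forward(chain$modules[[act[kk]]], out, chain)
    }
    out
  }
  fn <- function(theta) {
    md <- tryCatch(set_theta(mod, theta, chain), error = function(e) NULL)
    if (is.null(md)) return(Inf)
    out <- tryCatch(module_forward(md, input, chain), error = function(e) NULL)
    if (is.null(out)) return(Inf)
    cost_pred(downstream(out), ctx)
  }
  theta <- get_theta(mod)
  res <- if (mod$type %in% greedy_types) {
    descent_greedy(theta, fn, control, eps)
  } else {
    descent_nongreedy(theta, fn, control, eps)
  }
  chain$modules[[m_idx]] <- set_theta(mod, res$par, chain)
  list(chain = chain, improvement = res$improvement, steps = res$steps,
       cost = res$cost)
}

#' Fit a spectro-temporal encoding model by nested coordinate descent
#'
#' Fits every module of a model chain to a neural response by the boosting-
#' style algorithm used throughout the package: the output nonlinearity is
#' first removed and all remaining modules are visited in chain order, each
#' optimized by coordinate descent (non-greedy for weight-matrix modules,
#' greedy per-parameter for parameterized modules) against the
#' jackknife-shrunken normalized mean squared error; the stop criterion
#' epsilon starts at `control$eps0` and is tightened by 30% per round to a
#' floor of 1e-4. The output nonlinearity is then restored and the whole
#' schedule repeats to a floor of 1e-6. Inter-module signals are normalized
#' on the estimation data and the normalization is frozen for prediction on
#' new stimuli.
#'
#' @param chain an [strf_model()] chain (its current parameters are used only
#'   as structure; they are re-initialized from the data).
#' @param stimulus estimation stimulus: [spectrogram()] or channel-by-time
#'   matrix.
#' @param response estimation response: trial-by-time matrix (the PSTH is its
#'   column mean) or a PSTH vector, binned like the stimulus.
#' @param control an [strf_control()].
#' @param cost `"nmse"` (shrunken normalized mean squared error, default) or
#'   `"nlogl"` (per-bin Poisson negative log-likelihood).
#' @return Object of class `"strf"` with the fitted chain, the fit trace and
#'   the usual modelling methods (`print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`).
#' @export
strf <- function(chain, stimulus, response, control = strf_control(),
                 cost = c("nmse", "nlogl")) {
  cost <- match.arg(cost)
  stopifnot(inherits(chain, "strf_chain"))
  X <- if (inherits(stimulus, "spectrogram")) stimulus$values else as.matrix(stimulus)
  r <- if (is.matrix(response)) colMeans(response) else as.numeric(response)
  if (ncol(X) != length(r))
    stop("data error: stimulus has ", ncol(X), " bins, response ", length(r))
  if (length(r) < control$jackknife_folds)
    stop("data error: response shorter than the jackknife fold count")
  ctx <- make_cost_ctx(r, control$jackknife_folds, cost)
  chain <- init_chain_params(chain, X, r)
  chain <- grid_init_polezero(chain, X, r, ctx)
  types <- vapply(chain$modules, `[[`, "", "type")
  has_dexp <- types[length(types)] == "dexp"
  act_full <- seq_along(chain$modules)
  act1 <- if (has_dexp) act_full[-length(act_full)] else act_full
  phases <- list(list(act = act1, floor = control$eps_floor_nonl_off),
                 list(act = act_full, floor = control$eps_floor_nonl_on))
  trace <- list()
  for (ph in seq_along(phases)) {
    act <- phases[[ph]]$act
    # while the output nonlinearity is absent, chains whose temporal stage
    # carries no baseline parameter are scored on affinely calibrated
    # predictions (scale and offset later merge into the nonlinearity)
    last_type <- chain$modules[[act[length(act)]]]$type
    ctx$affine <- last_type %in% c("polezero", "diffexp")
    if (ph == 2 && has_dexp) {
      kd <- length(act)
      # initialize the sigmoid by a deterministic grid over slope and
      # inflection: a badly oriented or badly placed nonlinearity at phase-2
      # entry is a strong attractor toward the constant-prediction plateau
      grid_init_dexp <- function(cand) {
        dx_in <- forward_prefix(cand, X, act, kd)
        best <- NULL
        for (phi3 in c(-2, -1, -0.5, 0.5, 1, 2)) {
          for (phi4 in stats::quantile(dx_in, c(0.25, 0.5, 0.75, 0.9),
                                       names = FALSE)) {
            # baseline and amplitude enter linearly: solve them exactly,
            # which keeps the start sane at any response SNR
            g <- exp(-exp(pmin(pmax(phi3 * (dx_in - phi4), -30), 30)))
            M <- cbind(1, g)
            cf <- tryCatch(solve(crossprod(M), crossprod(M, r)),
                           error = function(e) NULL)
            if (is.null(cf)) next
            cc <- cost_pred(cf[1] + cf[2] * g, ctx)
            if (is.null(best) || cc < best$cost)
              best <- list(cost = cc, phi1 = cf[1], phi2 = cf[2],
                           phi3 = phi3, phi4 = phi4)
          }
        }
        cand$modules[[act[kd]]] <- mod_dexp(phi1 = best$phi1,
                                            phi2 = best$phi2,
                                            phi3 = best$phi3,
                                            phi4 = best$phi4)
        list(chain = cand, cost = best$cost)
      }
      # the linear-phase optimum can be a poor start for the nonlinear model
      # (strong output rectification decorrelates the two criteria), so the
      # phase-1 state competes against a fresh initialization under the full
      # phase-2 cost and the better start is kept
      c1 <- grid_init_dexp(chain)
      c2 <- grid_init_dexp(init_chain_params(chain, X, r))
      chain <- if (c1$cost <= c2$cost) c1$chain else c2$chain
    }
    eps <- control$eps0
    round <- 0L
    while (eps > phases[[ph]]$floor) {
      round <- round + 1L
      for (pass in seq_len(control$max_passes)) {
        pass_impr <- 0
        for (k in seq_along(act)) {
          res <- visit_module(chain, act, k, X, ctx, control, eps)
          chain <- res$chain
          pass_impr <- pass_impr + res$improvement
          trace[[length(trace) + 1]] <- data.frame(
            phase = ph, round = round, epsilon = eps, pass = pass,
            module = chain$modules[[act[k]]]$type, steps = res$steps,
            cost = res$cost)
        }
        if (pass_impr <= eps) break
      }
      eps <- eps * control$eps_decay
    }
  }
  chain <- fit_chain_normalization(chain, X)
  pred <- chain_predict(chain, X)
  fit_cost <- if (cost == "nmse") shrunken_cost(pred, r, control$jackknife_folds)
              else poisson_nlogl(pred, r) / length(r)
  structure(list(chain = chain, call = match.call(), control = control,
                 cost_name = cost, trace = do.call(rbind, trace),
                 target = r, fitted_values = pred, cost = fit_cost),
            class = "strf")
}

# Methods -----------------------------------------------------------------

#' @export
print.strf <- function(x, ...) {
  r_est <- suppressWarnings(stats::cor(x$fitted_values, x$target))
  e <- if (x$cost_name == "nmse") x$cost$e else x$cost
  cat(sprintf("strf fit: model \"%s\", %d free parameters\n",
              x$chain$name, count_parameters(x$chain)))
  cat(sprintf("  estimation cost (%s): %.4g; estimation correlation R = %.3f\n",
              x$cost_name, e, r_est))
  invisible(x)
}

#' @export
summary.strf <- function(object, ...) {
  out <- list(name = object$chain$name,
              n_parameters = count_parameters(object$chain),
              cost_name = object$cost_name,
              cost = object$cost,
              r_est = suppressWarnings(stats::cor(object$fitted_values,
                                                  object$target)),
              nmse_est = nmse(object$fitted_values, object$target),
              modules = vapply(object$chain$modules, `[[`, "", "type"),
              coef = coef(object))
  class(out) <- "summary.strf"
  out
}

#' @export
print.summary.strf <- function(x, ...) {
  cat(sprintf("strf fit \"%s\" (%d parameters; modules: %s)\n", x$name,
              x$n_parameters, paste(x$modules, collapse = " -> ")))
  cat(sprintf("  estimation: R = %.3f, NMSE = %.3f\n", x$r_est, x$nmse_est))
  cat("  coefficients:\n")
  print(utils::head(x$coef, 30))
  if (length(x$coef) > 30) cat("  ...", length(x$coef), "in total\n")
  invisible(x)
}

#' @export
coef.strf <- function(object, ...) {
  out <- c()
  for (mod in object$chain$modules) {
    pars <- mod[setdiff(names(mod), c("type", "P", "Z"))]
    for (nm in names(pars)) {
      v <- as.numeric(pars[[nm]])
      if (length(v) == 0) next
      names(v) <- if (length(v) == 1) paste(mod$type, nm, sep = ".")
                  else paste(mod$type, nm, seq_along(v), sep = ".")
      out <- c(out, v)
    }
  }
  out
}

#' @export
fitted.strf <- function(object, ...) object$fitted_values

#' @export
residuals.strf <- function(object, ...) object$target - object$fitted_values

#' @export
predict.strf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  chain_predict(object$chain, newdata)
}

#' Effective spectro-temporal weight matrix of a chain's linear stage
#'
#' Composes the spectral stage (weight matrix or parameterized tuning curves)
#' with the temporal stage (weight matrix or parameterized kernels) into the
#' equivalent `C x U` filter, for display and interpretation. For a full FIR
#' stage the matrix is returned directly. Inter-module normalization scaling
#' is not folded in.
#'
#' @param chain an `"strf_chain"` or fitted `"strf"`.
#' @return `C x U` numeric matrix.
#' @export
strf_matrix <- function(chain) {
  if (inherits(chain, "strf")) chain <- chain$chain
  types <- vapply(chain$modules, `[[`, "", "type")
  if ("fir" %in% types) return(chain$modules[[which(types == "fir")]]$H)
  sp <- chain$modules[[which(types %in% c("spectral", "gaussian", "morlet"))[1]]]
  W <- switch(sp$type,
    spectral = sp$Hs,
    gaussian = vapply(seq_along(sp$f0), function(j)
      gaussian_weights(sp$f0[j], sp$sigma[j], chain$center_freqs),
      numeric(length(chain$center_freqs))),
    morlet = vapply(seq_along(sp$f0), function(j)
      morlet_weights(sp$f0[j], sp$sigma[j], sp$z[j], chain$center_freqs),
      numeric(length(chain$center_freqs))))
  tm <- chain$modules[[which(types %in% c("temporal", "diffexp", "polezero"))[1]]]
  K <- switch(tm$type,
    temporal = tm$Ht,
    diffexp = t(vapply(seq_along(tm$A1), function(j)
      diff_exp_kernel(tm$A1[j], tm$tau1[j], tm$theta1[j], tm$A2[j],
                      tm$tau2[j], tm$theta2[j], chain$U), numeric(chain$U))),
    polezero = t(vapply(seq_along(tm$A), function(j)
      pole_zero_kernel(tm$A[j], tm$l[j], tm$poles[j, ], tm$zeros[j, ],
                       chain$U, chain$bin_duration), numeric(chain$U))))
  as.matrix(W) %*% as.matrix(K)
}

#' @export
plot.strf <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  H <- strf_matrix(x$chain)
  graphics::image(x = (seq_len(ncol(H)) - 1) * x$chain$bin_duration * 1000,
                  y = seq_len(nrow(H)), z = t(H),
                  xlab = "lag (ms)", ylab = "channel",
                  main = sprintf("STRF (%s)", x$chain$name),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"))
  tt <- seq_along(x$target) * x$chain$bin_duration
  graphics::plot(tt, x$target, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "rate",
                 main = "estimation PSTH (grey) and prediction (red)")
  graphics::lines(tt, x$fitted_values, col = "red")
  invisible(x)
}

#' Simulate noisy response trials from a fitted model
#'
#' Draws `nsim` trials of the model's predicted rate plus independent
#' Gaussian noise, by default with the standard deviation of the estimation
#' residuals.
#'
#' @param object a fitted `"strf"`.
#' @param nsim number of trials.
#' @param seed integer seed (the global RNG state is restored afterwards).
#' @param newdata optional stimulus for the simulated trials.
#' @param noise_sd noise standard deviation; defaults to the residual SD.
#' @param ... unused.
#' @return `nsim x T` matrix of simulated trials.
#' @export
simulate.strf <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                          noise_sd = NULL, ...) {
  mu <- predict(object, newdata)
  if (is.null(noise_sd)) noise_sd <- stats::sd(residuals(object))
  draw <- function() {
    t(vapply(seq_len(nsim), function(i)
      mu + stats::rnorm(length(mu), 0, noise_sd), numeric(length(mu))))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
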