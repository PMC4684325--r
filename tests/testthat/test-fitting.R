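test_that("NMSE matches hand-computed values", {
  r <- c(0, 1, 2)
  expect_equal(nmse(r, r), 0)
  expect_equal(nmse(rep(mean(r), 3), r), 1)
  expect_equal(nmse(c(0, 0, 0), r), 2.5)
  expect_error(nmse(1:3, rep(2, 3)), "degenerate target")
  expect_error(nmse(1:3, 1:4), "shape error")
})

test_that("shrinkage scales the NMSE by its jackknife reliability", {
  # exactly periodic data with a perfect prediction: all folds identical
  r <- rep(sin(2 * pi * (1:10) / 10), 10)
  cv <- shrunken_cost(r, r, folds = 10)
  expect_equal(cv$sigma_mse, 0)
  expect_equal(cv$e, 0)
  expect_equal(cv$e_mse, 0)
  # random instances: shrinkage never decreases the cost, e stays in [e_mse, 1]
  set.seed(41)
  for (i in 1:20) {
    r <- rnorm(100)
    p <- r + rnorm(100, sd = runif(1, 0.1, 1))
    cv <- shrunken_cost(p, r)
    if (cv$e_mse < 1) {
      expect_gte(cv$e, cv$e_mse)
      expect_lte(cv$e, 1)
    }
  }
  # unreliable improvement is fully shrunk to chance level: errors
  # concentrated in one fold make the fold estimates wildly inconsistent
  set.seed(42)
  r <- rnorm(100)
  p <- r
  p[1:10] <- r[1:10] + 3
  cv <- shrunken_cost(p, r, folds = 10)
  expect_lt(cv$e_mse, 1)
  expect_gt(cv$sigma_mse, 1 - cv$e_mse)
  expect_equal(cv$e, 1)
  expect_error(shrunken_cost(1:5, 1:5, folds = 10), "fold error")
})

test_that("Poisson negative log-likelihood behaves as a proper cost", {
  r <- c(2, 5, 3)
  # minimal over scalar rescalings at the true rate (calculus oracle:
  # d/dc sum(c*r - r*log(c*r)) = sum(r) - sum(r)/c = 0 at c = 1)
  costs <- vapply(c(0.5, 0.8, 1, 1.25, 2),
                  function(cc) poisson_nlogl(cc * r, r), numeric(1))
  expect_equal(which.min(costs), 3L)
  expect_true(is.finite(poisson_nlogl(rep(mean(r), 3), r)))
  expect_gt(poisson_nlogl(rep(1e-14, 3), r), 1e2)
  expect_error(poisson_nlogl(r, c(-1, 2, 3)), "data error")
})

test_that("non-greedy descent converges on a quadratic and idles at optima", {
  ctrl <- strf_control(max_steps_per_visit = 1000)
  fn <- function(th) (th[1] - 2)^2
  res <- descent_nongreedy(0, fn, ctrl, eps = 1e-12)
  expect_lt(abs(res$par - 2), 1e-3)
  # already at the optimum: no steps taken
  res0 <- descent_nongreedy(2, fn, ctrl, eps = 1e-12)
  expect_identical(res0$steps, 0L)
  expect_identical(res0$par, 2)
  # accepted-step costs strictly decrease
  seen <- c()
  fn2 <- function(th) {
    v <- (th[1] + 1)^2 + (th[2] - 3)^2
    v
  }
  res2 <- descent_nongreedy(c(0, 0), fn2, ctrl, eps = 1e-12)
  expect_lt(max(abs(res2$par - c(-1, 3))), 1e-2)
  expect_equal(res2$cost, fn2(res2$par))
})

test_that("greedy descent iterates each coordinate independently", {
  ctrl <- strf_control(max_steps_per_visit = 1000)
  fn <- function(th) (th[1] - 1.5)^2 + 4 * (th[2] + 0.75)^2
  res <- descent_greedy(c(0, 0), fn, ctrl, eps = 1e-12)
  expect_lt(max(abs(res$par - c(1.5, -0.75))), 1e-2)
  # a flat coordinate shrinks its step to the floor without updates
  fn2 <- function(th) (th[2] - 1)^2
  res2 <- descent_greedy(c(0.3, 0), fn2, ctrl, eps = 1e-12)
  expect_equal(res2$par[1], 0.3)
  expect_lt(abs(res2$par[2] - 1), 1e-2)
})

test_that("repeated descent visits solve least squares to the closed form", {
  set.seed(43)
  x <- rnorm(60)
  y <- 1.2 - 0.7 * x + rnorm(60, sd = 0.05)
  fn <- function(th) mean((y - th[1] - th[2] * x)^2)
  th <- c(0, 0)
  ctrl <- strf_control()
  eps <- ctrl$eps0
  while (eps > 1e-7) {
    repeat {
      res <- descent_nongreedy(th, fn, ctrl, eps = eps)
      th <- res$par
      if (res$improvement <= eps) break
    }
    eps <- eps * ctrl$eps_decay
  }
  ref <- unname(coef(lm(y ~ x)))
  expect_lt(max(abs(th - ref)), 1e-3)
})

test_that("fitting a known FIR neuron recovers its held-out predictions", {
  set.seed(44)
  C <- 6; U <- 5
  est <- rand_spec(C, 1200, seed = 44, f_high = 8000)
  val <- rand_spec(C, 300, seed = 45, f_high = 8000)
  truth <- strf_model("fir", C = C, U = U, compression = FALSE, dexp = FALSE)
  i <- which(vapply(truth$modules, `[[`, "", "type") == "fir")
  truth$modules[[i]]$H <- matrix(rnorm(C * U), C, U)
  truth$modules[[i]]$b <- 3
  truth <- fit_chain_normalization(truth, est)
  r_est <- chain_predict(truth, est)
  r_val <- chain_predict(truth, val)
  fit <- strf(strf_model("fir", C = C, U = U, compression = FALSE,
                         dexp = FALSE), est, r_est)
  expect_lt(nmse(predict(fit, val), r_val), 0.01)
})

test_that("the fit trace is non-increasing within each phase", {
  suite <- make_benchmark_suite(list(n_est_stimuli = 3,
                                     architectures = "gauss1_p1z0",
                                     snr = 5, rres_frac = 0), seed = 46)
  n <- suite$neurons[[1]]
  fit <- strf(strf_model("gaussian", D = 1, P = 1, Z = 0),
              suite$est_stim, n$est_trials)
  for (ph in unique(fit$trace$phase)) {
    cc <- fit$trace$cost[fit$trace$phase == ph]
    expect_true(all(diff(cc) <= 1e-12))
  }
  # refitting the same data is bit-identical (deterministic descent)
  fit2 <- strf(strf_model("gaussian", D = 1, P = 1, Z = 0),
               suite$est_stim, n$est_trials)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fitted(fit), fitted(fit2))
})

test_that("the modelling methods expose the fit consistently", {
  suite <- make_benchmark_suite(list(n_est_stimuli = 2,
                                     architectures = "gauss1_p1z0",
                                     snr = 10, rres_frac = 0), seed = 47)
  n <- suite$neurons[[1]]
  fit <- strf(strf_model("gaussian", D = 1, P = 1, Z = 0),
              suite$est_stim, n$est_trials)
  expect_s3_class(fit, "strf")
  expect_output(print(fit), "strf fit")
  expect_output(print(summary(fit)), "coefficients")
  expect_equal(fitted(fit) + residuals(fit), fit$target)
  expect_named(coef(fit))
  expect_equal(predict(fit), fitted(fit))
  pv <- predict(fit, suite$val_stim)
  expect_length(pv, ncol(suite$val_stim$values))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(3, length(fitted(fit))))
  sim2 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(sim, sim2)
  H <- strf_matrix(fit)
  expect_equal(dim(H), c(18, 15))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
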