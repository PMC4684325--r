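test_that("FIR prediction matches the brute-force double sum", {
  set.seed(11)
  for (rep in 1:5) {
    X <- matrix(rnorm(3 * 20), 3, 20)
    H <- matrix(rnorm(15), 3, 5)
    b <- rnorm(1)
    expect_equal(fir_predict(X, fir_kernel(H, b)), fir_oracle(X, H, b),
                 tolerance = 1e-12)
  }
})

test_that("FIR handles constant, impulse and mismatched inputs", {
  X <- matrix(0, 2, 10)
  expect_equal(fir_predict(X, fir_kernel(matrix(0, 2, 4), b = 0.5)),
               rep(0.5, 10))
  # impulse at t0 traces row f of H
  X[1, 4] <- 1
  H <- matrix(rnorm(8), 2, 4)
  y <- fir_predict(X, fir_kernel(H, b = 2))
  expect_equal(y[4:7], 2 + H[1, ])
  expect_equal(y[1:3], rep(2, 3))
  expect_error(fir_predict(matrix(0, 3, 10), fir_kernel(H)), "shape error")
})

test_that("spectral projection is the expected linear map", {
  X <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(spectral_project(X, diag(4)), X)
  expect_equal(drop(spectral_project(X, matrix(1, 4, 1))), colSums(X))
  Hs <- matrix(rnorm(8), 4, 2)
  oracle <- matrix(0, 2, 6)
  for (j in 1:2) for (t in 1:6) oracle[j, t] <- sum(Hs[, j] * X[, t])
  expect_equal(unname(spectral_project(X, Hs)), oracle)
  expect_error(spectral_project(X, matrix(1, 3, 2)), "shape error")
})

test_that("factorized kernels compose to a low-rank FIR matrix", {
  set.seed(12)
  Hs <- matrix(rnorm(10), 5, 2)
  Ht <- matrix(rnorm(8), 2, 4)
  H <- compose_factorized(Hs, Ht)
  expect_equal(dim(H), c(5, 4))
  expect_lte(sum(svd(H)$d > 1e-10), 2)
  expect_equal(compose_factorized(Hs[, 1, drop = FALSE],
                                  Ht[1, , drop = FALSE]),
               outer(Hs[, 1], Ht[1, ]))
  expect_equal(compose_factorized(diag(2), Ht), Ht)
  expect_error(compose_factorized(Hs, matrix(1, 3, 4)), "shape error")
})

test_that("factorized prediction equals FIR on the composed matrix", {
  set.seed(13)
  for (rep in 1:5) {
    X <- matrix(rnorm(4 * 30), 4, 30)
    Hs <- matrix(rnorm(8), 4, 2)
    Ht <- matrix(rnorm(12), 2, 6)
    b <- rnorm(1)
    expect_lt(max(abs(factorized_predict(X, Hs, Ht, b) -
                        fir_predict(X, fir_kernel(compose_factorized(Hs, Ht), b)))),
              1e-10)
  }
  # degenerate cases
  X <- matrix(rnorm(3 * 10), 3, 10)
  expect_equal(factorized_predict(X, matrix(1, 3, 1), matrix(0, 1, 4), b = 2),
               rep(2, 10))
  expect_equal(factorized_predict(X, matrix(1, 3, 1), matrix(1, 1, 3)),
               fir_predict(X, fir_kernel(matrix(1, 3, 3))))
})

test_that("Gaussian spectral weights follow the normal density formula", {
  grid <- seq(100, 900, by = 200)
  w <- gaussian_weights(500, 150, grid)
  expect_equal(which.max(w), 3)
  expect_equal(w[3], 1 / (150 * sqrt(2 * pi)))
  expect_equal(gaussian_weights(500, 100, c(400, 600)),
               rep(exp(-100^2 / (2 * 100^2)) / (100 * sqrt(2 * pi)), 2))
  expect_equal(w, exp(-(grid - 500)^2 / (2 * 150^2)) / (150 * sqrt(2 * pi)))
  expect_true(all(w > 0))
  expect_error(gaussian_weights(500, 0, grid), "domain error")
})

test_that("Morlet spectral weights follow the real wavelet formula", {
  grid <- seq(200, 1800, by = 100)
  expect_equal(morlet_weights(1000, 300, 0.01, grid)[grid == 1000], 1)
  expect_equal(morlet_weights(1000, 300, 0, grid),
               exp(-(grid - 1000)^2 / 300^2))
  set.seed(14)
  f0 <- 800; sig <- 250; z <- 0.02
  oracle <- Re(exp(-(grid - f0)^2 / sig^2 - 1i * z * (grid - f0)))
  expect_equal(morlet_weights(f0, sig, z, grid), oracle)
  expect_error(morlet_weights(1000, -1, 0, grid), "domain error")
})

test_that("difference-of-exponentials kernel gates each lobe at its onset", {
  k <- diff_exp_kernel(2, 5, 0, 0, 1, 0, 10)
  expect_equal(k[1], 2)
  expect_equal(k, 2 * exp(-(0:9) / 5))
  k2 <- diff_exp_kernel(1, 5, 3, 1, 2, 5, 12)
  expect_equal(k2[1:3], rep(0, 3))     # before both onsets
  i <- 0:11
  oracle <- ifelse(i >= 3, exp(-(i - 3) / 5), 0) -
    ifelse(i >= 5, exp(-(i - 5) / 2), 0)
  expect_equal(k2, oracle)
  # peak location matches a dense-scan oracle
  k3 <- diff_exp_kernel(1, 5, 0, 1, 1, 0, 40)
  dense <- function(x) exp(-x / 5) - exp(-x)
  expect_equal(which.max(k3) - 1, which.max(dense(0:39)) - 1)
  expect_error(diff_exp_kernel(1, -2, 0, 0, 1, 0, 5), "domain error")
})

test_that("pole-zero kernels match closed-form inverse transforms", {
  tau <- 0.01
  U <- 30
  tt <- ((1:U) - 0.5) * tau
  # P1Z0: A / (s + p)  ->  A exp(-p t)
  k1 <- pole_zero_kernel(2, 0, poles = 25, U = U, bin_duration = tau)
  expect_lt(max(abs(k1 - 2 * exp(-25 * tt))) / max(abs(k1)), 1e-6)
  # P2Z0 distinct poles: A (e^{-p1 t} - e^{-p2 t}) / (p2 - p1)
  p <- c(20, 90)
  k2 <- pole_zero_kernel(3, 0, poles = p, U = U, bin_duration = tau)
  oracle <- 3 * (exp(-p[1] * tt) - exp(-p[2] * tt)) / (p[2] - p[1])
  expect_lt(max(abs(k2 - oracle)) / max(abs(oracle)), 1e-6)
  expect_equal(pole_zero_kernel(0, 0, poles = c(10, 20), U = 5), rep(0, 5))
  expect_error(pole_zero_kernel(1, 0, poles = 10, zeros = c(1, 2), U = 5),
               "improper")
  expect_error(pole_zero_kernel(1, 0, poles = -5, U = 5), "instability")
})

test_that("latency shifts and repeated poles are handled", {
  tau <- 0.01
  k <- pole_zero_kernel(1, 0.025, poles = 30, U = 20, bin_duration = tau)
  expect_equal(k[1:2], c(0, 0))  # bins centred before l = 25 ms
  expect_gt(abs(k[3]), 0)
  # repeated poles are perturbed rather than failing
  kr <- pole_zero_kernel(1, 0, poles = c(40, 40), U = 20, bin_duration = tau)
  expect_true(all(is.finite(kr)))
  tt <- ((1:20) - 0.5) * tau
  expect_lt(max(abs(kr - tt * exp(-40 * tt))) / max(tt * exp(-40 * tt)), 1e-3)
})

test_that("pole-zero kernels decay toward zero at long lags", {
  k <- pole_zero_kernel(5, 0, poles = c(15, 60, 200), zeros = 3,
                        U = 100, bin_duration = 0.01)
  expect_lt(abs(k[100]), max(abs(k)) * 1e-3)
})

test_that("two P1Z0 channels reproduce a difference-of-exponentials kernel", {
  tau <- 0.01
  U <- 15
  tau1 <- 5; tau2 <- 1.5  # decay constants in bins
  A1 <- 2; A2 <- 1.2
  de <- diff_exp_kernel(A1, tau1, 0, A2, tau2, 0, U)
  # same Gaussian channel duplicated with +/- gains and matched poles;
  # gains corrected for bin-centre sampling of the continuous kernels
  k1 <- pole_zero_kernel(A1 * exp(0.5 / tau1), 0, poles = 1 / (tau1 * tau),
                         U = U, bin_duration = tau)
  k2 <- pole_zero_kernel(A2 * exp(0.5 / tau2), 0, poles = 1 / (tau2 * tau),
                         U = U, bin_duration = tau)
  expect_equal(k1 - k2, de, tolerance = 1e-12)
  # and through the prediction path: D = 2 factorized structure
  set.seed(15)
  X <- matrix(abs(rnorm(6 * 40)), 6, 40)
  w <- gaussian_weights(1000, 300, center_frequencies(6, 200, 8000))
  y2 <- factorized_predict(X, cbind(w, w), rbind(k1, -k2))
  y1 <- factorized_predict(X, cbind(w), rbind(de))
  expect_equal(y2, y1, tolerance = 1e-10)
})

test_that("temporal kernels are causal through the prediction path", {
  X <- matrix(0, 2, 15)
  X[, 8] <- 1  # impulse at bin 8
  H <- matrix(rnorm(10, sd = 1), 2, 5)
  y <- fir_predict(X, fir_kernel(H, 0))
  expect_equal(y[1:7], rep(0, 7))
})
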