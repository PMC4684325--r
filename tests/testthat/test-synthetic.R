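test_that("modulation noise is seeded, nonnegative and band-limited", {
  a <- generate_modulation_noise(12, 256, seed = 61)
  b <- generate_modulation_noise(12, 256, seed = 61)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values,
                         generate_modulation_noise(12, 256, seed = 62)$values))
  expect_true(all(a$values >= 0))
  # temporal power above the cutoff (DC excluded) is a negligible fraction
  for (ch in c(1, 6, 12)) {
    pw <- Mod(fft(a$values[ch, ]))^2
    freq <- (seq_along(pw) - 1) / (256 * a$bin_duration)
    freq <- pmin(freq, 1 / a$bin_duration - freq)
    above <- sum(pw[freq > 20 & freq < 50]) / sum(pw[-1])
    expect_lt(above, 0.05)
  }
  expect_error(generate_modulation_noise(12, 8), "T_bins")
  expect_error(generate_modulation_noise(12, 256, temporal_cutoff = 100),
               "Nyquist")
})

test_that("simulated trials decompose into signal plus seeded noise", {
  est <- generate_modulation_noise(18, 600, seed = 63)
  truth <- strfkit:::benchmark_truth_chain("gauss1_p3z1", 18, 15, 0.01,
                                           est$center_freqs, 64)
  nz <- ground_truth_neuron(truth, est, snr = Inf, rres_frac = 0)
  tr <- simulate_trials(nz, est, 4, seed = 1)
  expect_equal(tr[1, ], tr[4, ])       # zero noise: identical trials
  expect_equal(ttrc(tr), 1)
  n1 <- ground_truth_neuron(truth, est, snr = 0.5, rres_frac = 0.2)
  t1 <- simulate_trials(n1, est, 5, seed = 9)
  t2 <- simulate_trials(n1, est, 5, seed = 9)
  expect_identical(t1, t2)
  expect_false(identical(t1, simulate_trials(n1, est, 5, seed = 10)))
})

test_that("the PSTH converges to the noiseless signal as trials accumulate", {
  est <- generate_modulation_noise(18, 150, seed = 65)
  truth <- strfkit:::benchmark_truth_chain("gauss1_p1z0", 18, 15, 0.01,
                                           est$center_freqs, 66)
  n <- ground_truth_neuron(truth, est, snr = 1, rres_frac = 0.2)
  signal <- strfkit:::neuron_signal(n, est)
  dev <- vapply(c(100, 10000), function(M) {
    max(abs(psth(simulate_trials(n, est, M, seed = 2)) - signal))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2], dev[1] / 3)  # ~ 1/sqrt(M) shrinkage
})

test_that("measured response SNR tracks the designed level", {
  est <- generate_modulation_noise(18, 3000, seed = 67)
  truth <- strfkit:::benchmark_truth_chain("gauss1_p3z1", 18, 15, 0.01,
                                           est$center_freqs, 68)
  n <- ground_truth_neuron(truth, est, snr = 0.5, rres_frac = 0.2)
  tr <- simulate_trials(n, est, 10, seed = 3)
  expect_equal(response_snr(tr)$snr, 0.5, tolerance = 0.2)
})

test_that("benchmark suites are pure functions of config and seed", {
  cfg <- list(n_est_stimuli = 3, architectures = c("gauss1_p1z0", "fir_random"),
              snr = c(1, 0.1))
  s1 <- make_benchmark_suite(cfg, seed = 70)
  s2 <- make_benchmark_suite(cfg, seed = 70)
  expect_identical(s1$est_stim$values, s2$est_stim$values)
  expect_identical(s1$neurons[[1]]$est_trials, s2$neurons[[1]]$est_trials)
  expect_identical(serialize_chain(s1$neurons[[2]]$neuron$chain),
                   serialize_chain(s2$neurons[[2]]$neuron$chain))
  expect_false(identical(s1$neurons[[1]]$est_trials,
                         make_benchmark_suite(cfg, 71)$neurons[[1]]$est_trials))
})

test_that("designed SNR levels are recovered in rank order", {
  suite <- make_benchmark_suite(list(
    architectures = rep("gauss1_p3z1", 4),
    snr = c(0.003, 0.01, 0.1, 1), n_est_stimuli = 10), seed = 72)
  measured <- vapply(suite$neurons, function(n)
    response_snr(n$est_trials)$snr, numeric(1))
  expect_identical(order(measured), 1:4)
})

test_that("generator chains carry the advertised parameter counts", {
  suite <- make_benchmark_suite(list(
    architectures = c("fir_random", "gauss1_p1z0", "gauss3_p3z1",
                      "gauss1_p3z1_stp"),
    snr = 1, n_est_stimuli = 2), seed = 73)
  counts <- vapply(suite$neurons, function(n)
    count_parameters(n$neuron$chain), integer(1))
  expect_identical(counts, c(276L, 10L, 29L, 16L))
})

test_that("recovery reports align channels and flag mismatched architectures", {
  ch <- strf_model("gaussian", D = 2)
  i <- which(vapply(ch$modules, `[[`, "", "type") == "gaussian")
  ch$modules[[i]]$f0 <- c(500, 2000)
  ch$modules[[i]]$sigma <- c(100, 400)
  rep0 <- parameter_recovery_report(ch, ch)
  expect_true(all(rep0$abs_error == 0))
  # permuted channels are re-matched by sorted center frequency
  perm <- ch
  perm$modules[[i]]$f0 <- c(2000, 500)
  perm$modules[[i]]$sigma <- c(400, 100)
  it <- which(vapply(ch$modules, `[[`, "", "type") == "polezero")
  perm$modules[[it]]$A <- rev(perm$modules[[it]]$A)
  rep1 <- parameter_recovery_report(perm, ch)
  expect_true(all(rep1$abs_error[grepl("gaussian", rep1$parameter)] == 0))
  expect_error(parameter_recovery_report(strf_model("fir"), ch),
               "comparison error")
})

test_that("experiment grids produce one scored row per cell, deterministically", {
  suite <- make_benchmark_suite(list(n_est_stimuli = 2, stim_duration = 1,
                                     architectures = "gauss1_p1z0",
                                     snr = 5, rres_frac = 0), seed = 74)
  models <- list(P1Z0x1 = strf_model("gaussian", D = 1, P = 1, Z = 0))
  ctrl <- strf_control(max_passes = 2)
  sc <- run_experiment(suite, models, control = ctrl)
  expect_identical(nrow(sc), 1L)
  expect_true(all(sc$ok))
  expect_true(all(is.finite(sc$r_val)))
  sc2 <- run_experiment(suite, models, control = ctrl)
  expect_identical(sc, sc2)
  # subsampling keeps whole stimuli
  sub <- subsample_estimation(suite, 0.5)
  expect_identical(ncol(sub$est_stim$values), 100L)
  expect_identical(ncol(sub$neurons[[1]]$est_trials), 100L)
})
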