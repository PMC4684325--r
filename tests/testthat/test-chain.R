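test_that("parameter accounting reproduces the standard model counts", {
  expect_identical(count_parameters(strf_model("fir")), 276L)
  # core FIR weight matrix: total minus baseline, compression and output NL
  expect_identical(count_parameters(strf_model("fir", compression = FALSE,
                                               dexp = FALSE)) - 1L, 270L)
  expect_identical(count_parameters(strf_model("gaussian", D = 3)), 29L)
  expect_identical(count_parameters(strf_model("gaussian", D = 1)), 13L)
  expect_identical(count_parameters(strf_model("fir", stp = TRUE)) -
                     count_parameters(strf_model("fir")), 54L)
  # difference of exponentials: 6 per spectral channel (plus 2 Gaussian)
  expect_identical(count_parameters(strf_model("gaussian", temporal = "diffexp",
                                               D = 1)), 13L)
  expect_identical(count_parameters(strf_model("gaussian", temporal = "diffexp",
                                               D = 3)) -
                     count_parameters(strf_model("gaussian", temporal = "diffexp",
                                                 D = 2)), 8L)
  # factorized: D (C + U) + b + compression + output NL
  expect_identical(count_parameters(strf_model("factorized", temporal = "weights",
                                               D = 3)),
                   3L * (18L + 15L) + 1L + 1L + 4L)
  expect_identical(count_parameters(strf_model("morlet", D = 3)),
                   3L * 3L + 3L * 6L + 1L + 4L)
})

test_that("normalization standardizes and min-shifts on estimation data", {
  st <- fit_normalization(c(1, 2, 3))
  out <- apply_normalization(c(1, 2, 3), st)
  expect_equal(min(out), 0)
  expect_equal(sd(out), 1)
  # frozen semantics: validation values below the estimation minimum go negative
  expect_lt(apply_normalization(0, st), 0)
  # moments match direct oracles on a random matrix
  set.seed(31)
  X <- matrix(rnorm(5 * 40), 5, 40)
  st2 <- fit_normalization(X)
  expect_equal(st2$mu, rowMeans(X))
  expect_equal(st2$sigma, apply(X, 1, sd))
  out2 <- apply_normalization(X, st2)
  expect_equal(apply(out2, 1, min), rep(0, 5))
  # idempotence: re-fitting on normalized output gives sd 1, min 0
  st3 <- fit_normalization(out2)
  expect_equal(st3$sigma, rep(1, 5))
  expect_equal(apply(apply_normalization(out2, st3), 1, min), rep(0, 5))
  # degenerate channel passes through with sigma replaced by 1
  st4 <- fit_normalization(matrix(2, 1, 10))
  expect_true(st4$degenerate)
  expect_equal(st4$sigma, 1)
})

test_that("chain prediction is deterministic and requires fitted normalization", {
  sp <- rand_spec(18, 120, seed = 32)
  ch <- strf_model("gaussian", D = 2)
  expect_error(chain_predict(ch, sp), "state error")
  ch <- fit_chain_normalization(ch, sp)
  y1 <- chain_predict(ch, sp)
  y2 <- chain_predict(ch, sp)
  expect_identical(y1, y2)
  expect_length(y1, 120)
  # zero stimulus through a fitted chain gives a constant output once the
  # temporal kernel's zero-padded memory has filled
  z <- chain_predict(ch, matrix(0, 18, 50))
  expect_equal(diff(range(z[15:50])), 0)
})

test_that("a linear-only chain merges into a single denormalized FIR filter", {
  set.seed(33)
  sp <- rand_spec(6, 200, seed = 33)
  ch <- strf_model("factorized", temporal = "weights", D = 2, C = 6, U = 4,
                   compression = FALSE, dexp = FALSE)
  i_s <- which(vapply(ch$modules, `[[`, "", "type") == "spectral")
  i_t <- which(vapply(ch$modules, `[[`, "", "type") == "temporal")
  ch$modules[[i_s]]$Hs <- matrix(rnorm(12), 6, 2)
  ch$modules[[i_t]]$Ht <- matrix(rnorm(8), 2, 4)
  ch$modules[[i_t]]$b <- 1.5
  ch <- fit_chain_normalization(ch, sp)
  y <- chain_predict(ch, sp)
  # oracle: algebraic merge of the normalization scaling into the weights
  st <- ch$norm[[1]]
  Hs <- ch$modules[[i_s]]$Hs
  Ht <- ch$modules[[i_t]]$Ht
  H_eff <- sweep(Hs, 2, st$sigma, "/") %*% Ht
  b_eff <- 1.5 + sum((-st$mu / st$sigma - st$z) * rowSums(Ht))
  # the merge is exact once the kernel's zero-padded memory has filled
  expect_equal(y[4:200], fir_predict(sp, fir_kernel(H_eff, b_eff))[4:200],
               tolerance = 1e-10)
})

test_that("chains serialize to JSON and back with identical predictions", {
  sp <- rand_spec(18, 80, seed = 34)
  ch <- strf_model("gaussian", D = 3, stp = TRUE)
  ch <- fit_chain_normalization(ch, sp)
  txt <- serialize_chain(ch)
  ch2 <- deserialize_chain(txt)
  expect_identical(chain_predict(ch2, sp), chain_predict(ch, sp))
  expect_identical(count_parameters(ch2), count_parameters(ch))
  # file round trip
  path <- tempfile(fileext = ".json")
  serialize_chain(ch, path)
  ch3 <- read_chain_json(path)
  expect_identical(chain_predict(ch3, sp), chain_predict(ch, sp))
  unlink(path)
})

test_that("malformed chain documents fail with informative errors", {
  ch <- strf_model("gaussian", D = 1)
  txt <- serialize_chain(ch)
  doc <- jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyMatrix = FALSE)
  doc$center_freqs <- NULL
  expect_error(deserialize_chain(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "center_freqs")
  doc2 <- jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyMatrix = FALSE)
  doc2$format_version <- "99.0"
  expect_error(deserialize_chain(jsonlite::toJSON(doc2, auto_unbox = TRUE)),
               "incompatible")
  expect_error(deserialize_chain("{\"foo\": 1}"), "format_version")
})

test_that("waveform input is routed through the cochlear frontend", {
  ch <- strf_model("gaussian", D = 1, C = 8, f_low = 300, f_high = 6000,
                   bin_duration = 0.01)
  w <- tone_wave(1000, 0.5, 16000)
  cfg <- cochlear_config(C = 8, f_low = 300, f_high = 6000,
                         bin_duration = 0.01)
  sp <- apply_filterbank(w, cfg)
  ch <- fit_chain_normalization(ch, sp)
  expect_equal(chain_predict(ch, w), chain_predict(ch, sp))
})
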