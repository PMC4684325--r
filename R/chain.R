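# Module specs -----------------------------------------------------------
#
# A model chain is an ordered list of module specs. Each spec is a plain list
# with a `type` field and named parameters; `greedy_modules` lists the types
# fitted by greedy (per-parameter) coordinate descent, the rest are fitted by
# non-greedy (best-single-step) descent.

greedy_types <- c("logcomp", "gaussian", "morlet", "diffexp", "polezero",
                  "stp", "dexp")

mod_logcomp <- function(phi1 = 1) list(type = "logcomp", phi1 = phi1)

mod_fir <- function(C, U, H = matrix(0, C, U), b = 0)
  list(type = "fir", H = H, b = b)

mod_spectral <- function(C, D, Hs = matrix(0, C, D))
  list(type = "spectral", Hs = Hs)

mod_gaussian <- function(f0, sigma)
  list(type = "gaussian", f0 = f0, sigma = sigma)

mod_morlet <- function(f0, sigma, z)
  list(type = "morlet", f0 = f0, sigma = sigma, z = z)

mod_stp <- function(D, nu = rep(0, D), tau_rec = rep(10, D), s0 = rep(0, D))
  list(type = "stp", nu = nu, tau_rec = tau_rec, s0 = s0)

mod_temporal <- function(D, U, Ht = matrix(0, D, U), b = 0)
  list(type = "temporal", Ht = Ht, b = b)

mod_diffexp <- function(D, A1 = rep(1, D), tau1 = rep(5, D),
                        theta1 = rep(0, D), A2 = rep(0, D),
                        tau2 = rep(1, D), theta2 = rep(0, D))
  list(type = "diffexp", A1 = A1, tau1 = tau1, theta1 = theta1,
       A2 = A2, tau2 = tau2, theta2 = theta2)

mod_polezero <- function(D, P, Z, A = rep(1, D), l = rep(0, D),
                         poles = NULL, zeros = NULL) {
  if (is.null(poles)) poles <- matrix(rep(c(10, 30, 100)[seq_len(P)],
                                          each = D), D, P)
  if (is.null(zeros)) zeros <- matrix(0, D, Z)
  list(type = "polezero", P = P, Z = Z, A = A, l = l,
       poles = as.matrix(poles), zeros = as.matrix(zeros))
}

mod_dexp <- function(phi1 = 0, phi2 = 1, phi3 = 1, phi4 = 0)
  list(type = "dexp", phi1 = phi1, phi2 = phi2, phi3 = phi3, phi4 = phi4)

# number of signal channels leaving a module, given channels entering
module_out_channels <- function(mod, n_in) {
  switch(mod$type,
    logcomp = n_in,
    stp = n_in,
    fir = 1L,
    spectral = ncol(mod$Hs),
    gaussian = length(mod$f0),
    morlet = length(mod$f0),
    temporal = 1L,
    diffexp = 1L,
    polezero = 1L,
    dexp = 1L,
    stop("unknown module type: ", mod$type))
}

#' Construct an encoding-model chain
#'
#' Builds the standard module sequence used throughout the package:
#' logarithmic input compression, a spectral stage, optional short-term
#' plasticity, a temporal stage, and an optional double-exponential output
#' nonlinearity. The `"fir"` spectral stage subsumes the temporal stage in a
#' single full weight matrix. Model names follow the PkZm convention, e.g.
#' `"P3Z1x3"` is a 3-pole/1-zero temporal kernel on 3 Gaussian spectral
#' channels.
#'
#' @param filter one of `"fir"`, `"factorized"`, `"gaussian"`, `"morlet"` —
#'   the linear spectro-temporal stage family.
#' @param temporal for parameterized spectral stages: `"polezero"`,
#'   `"diffexp"`, or `"weights"` (free factorized temporal filter).
#' @param D number of spectral channels (ignored for `"fir"`).
#' @param C input spectrogram channel count.
#' @param U temporal kernel memory in bins.
#' @param P,Z pole and zero counts for the pole-zero temporal stage.
#' @param stp include a short-term plasticity stage before temporal filtering.
#' @param dexp include the double-exponential output nonlinearity.
#' @param compression include logarithmic input compression.
#' @param f_low,f_high,bin_duration spectrogram frequency band and bin size.
#' @return Object of class `"strf_chain"`.
#' @export
#' @examples
#' count_parameters(strf_model("fir"))        # 276
#' count_parameters(strf_model("gaussian", D = 3))  # 29
strf_model <- function(filter = c("gaussian", "fir", "factorized", "morlet"),
                       temporal = c("polezero", "diffexp", "weights"),
                       D = 3, C = 18, U = 15, P = 3, Z = 1,
                       stp = FALSE, dexp = TRUE, compression = TRUE,
                       f_low = 200, f_high = 20000, bin_duration = 0.010) {
  filter <- match.arg(filter)
  temporal <- match.arg(temporal)
  cf <- center_frequencies(C, f_low, f_high)
  modules <- list()
  if (compression) modules <- c(modules, list(mod_logcomp()))
  if (filter == "fir") {
    if (stp) modules <- c(modules, list(mod_stp(C)))
    modules <- c(modules, list(mod_fir(C, U)))
    name <- if (stp) "FIR-STP" else "FIR"
  } else {
    spec_mod <- switch(filter,
      factorized = mod_spectral(C, D),
      gaussian = {
        mid <- cf[round(C / 2)]
        mod_gaussian(f0 = rep(mid, D), sigma = rep(mid / 2, D))
      },
      morlet = {
        mid <- cf[round(C / 2)]
        mod_morlet(f0 = rep(mid, D), sigma = rep(mid / 2, D), z = rep(0, D))
      })
    modules <- c(modules, list(spec_mod))
    if (stp) modules <- c(modules, list(mod_stp(D)))
    temp_mod <- switch(temporal,
      weights = mod_temporal(D, U),
      diffexp = mod_diffexp(D),
      polezero = mod_polezero(D, P, Z))
    modules <- c(modules, list(temp_mod))
    base <- switch(filter, factorized = "FAC", gaussian = "", morlet = "M")
    tname <- switch(temporal, weights = "FACT", diffexp = "DOE",
                    polezero = sprintf("P%dZ%d", P, Z))
    name <- sprintf("%s%sx%d%s", base, tname, D, if (stp) "-STP" else "")
  }
  if (dexp) modules <- c(modules, list(mod_dexp()))
  structure(list(modules = modules, C = C, U = U, D = D,
                 bin_duration = bin_duration, center_freqs = cf,
                 name = name, norm = NULL),
            class = "strf_chain")
}

#' @export
print.strf_chain <- function(x, ...) {
  types <- vapply(x$modules, `[[`, "", "type")
  cat(sprintf("strf_chain \"%s\": %s (%d free parameters%s)\n", x$name,
              paste(types, collapse = " -> "), count_parameters(x),
              if (is.null(x$norm)) ", normalization unfitted" else ""))
  invisible(x)
}

#' Count the free parameters of a model chain
#'
#' Uses the accounting convention of the model-comparison analyses: the full
#' FIR and free factorized temporal filters carry an explicit baseline `b`
#' (FIR: C*U + 1), parameterized kernels do not (their offset is absorbed by
#' the output nonlinearity); log compression adds 1, the double-exponential
#' nonlinearity 4, short-term plasticity 3 per channel, Gaussian spectral 2
#' per channel, Morlet 3, difference of exponentials 6, and a PkZm kernel
#' `2 + k + m` per channel.
#'
#' @param chain an `"strf_chain"`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(chain) {
  stopifnot(inherits(chain, "strf_chain"))
  n <- 0L
  for (mod in chain$modules) {
    n <- n + switch(mod$type,
      logcomp = 1L,
      fir = length(mod$H) + 1L,
      spectral = length(mod$Hs),
      gaussian = 2L * length(mod$f0),
      morlet = 3L * length(mod$f0),
      stp = 3L * length(mod$nu),
      temporal = length(mod$Ht) + 1L,
      diffexp = 6L * length(mod$A1),
      polezero = (2L + mod$P + mod$Z) * length(mod$A),
      dexp = 4L)
  }
  as.integer(n)
}

# Forward pass ------------------------------------------------------------

module_forward <- function(mod, input, chain) {
  switch(mod$type,
    logcomp = {
      if (mod$phi1 <= 0) stop("domain error: phi1 must be > 0")
      log(pmax(input, 0) + mod$phi1)
    },
    fir = mod$b + causal_conv(input, mod$H),
    spectral = crossprod(mod$Hs, input),
    gaussian = {
      W <- vapply(seq_along(mod$f0), function(j)
        gaussian_weights(mod$f0[j], mod$sigma[j], chain$center_freqs),
        numeric(length(chain$center_freqs)))
      crossprod(W, input)
    },
    morlet = {
      W <- vapply(seq_along(mod$f0), function(j)
        morlet_weights(mod$f0[j], mod$sigma[j], mod$z[j], chain$center_freqs),
        numeric(length(chain$center_freqs)))
      crossprod(W, input)
    },
    stp = stp_apply(input, mod$nu, mod$tau_rec, mod$s0)$output,
    temporal = mod$b + causal_conv(input, mod$Ht),
    diffexp = {
      K <- t(vapply(seq_along(mod$A1), function(j)
        diff_exp_kernel(mod$A1[j], mod$tau1[j], mod$theta1[j],
                        mod$A2[j], mod$tau2[j], mod$theta2[j], chain$U),
        numeric(chain$U)))
      causal_conv(input, K)
    },
    polezero = {
      K <- t(vapply(seq_along(mod$A), function(j)
        pole_zero_kernel(mod$A[j], mod$l[j], mod$poles[j, ], mod$zeros[j, ],
                         chain$U, chain$bin_duration),
        numeric(chain$U)))
      causal_conv(input, K)
    },
    dexp = dexp_apply(input, mod$phi1, mod$phi2, mod$phi3, mod$phi4),
    stop("unknown module type: ", mod$type))
}

# Full forward pass with normalization at every inter-module boundary.
# refit = TRUE recomputes the normalization states (estimation data);
# otherwise `states` (frozen on the estimation set) are applied.
chain_forward <- function(chain, X, states = NULL, refit = is.null(states)) {
  n <- length(chain$modules)
  out <- X
  new_states <- vector("list", max(n - 1, 0))
  for (m in seq_len(n)) {
    out <- module_forward(chain$modules[[m]], out, chain)
    if (m < n) {
      st <- if (refit) fit_normalization(out) else states[[m]]
      new_states[[m]] <- st
      out <- apply_normalization(out, st)
    }
  }
  list(output = if (is.null(dim(out))) out else drop(out), states = new_states)
}

#' Fit the inter-module normalization states of a chain on estimation data
#'
#' Runs the chain forward on the estimation stimulus and freezes the
#' per-boundary normalization moments, which are then reused for any other
#' stimulus (see [fit_normalization()]).
#'
#' @param chain an `"strf_chain"`.
#' @param stimulus a [spectrogram()] (or matrix) of estimation data.
#' @return The chain with `$norm` populated.
#' @export
fit_chain_normalization <- function(chain, stimulus) {
  X <- if (inherits(stimulus, "spectrogram")) stimulus$values else as.matrix(stimulus)
  chain$norm <- chain_forward(chain, X, refit = TRUE)$states
  chain
}

#' Predict the time-varying firing rate of a model chain
#'
#' Deterministic composition of the chain's module outputs with the frozen
#' inter-module normalization applied at each boundary. The chain's
#' normalization must have been fitted on estimation data first (either by
#' [strf()] or [fit_chain_normalization()]).
#'
#' @param chain a fitted `"strf_chain"`.
#' @param stimulus a [spectrogram()], channel-by-time matrix, or
#'   [waveform()] (a waveform is first passed through the cochlear filterbank
#'   matching the chain's frequency grid).
#' @return Numeric predicted rate, one value per stimulus bin.
#' @export
chain_predict <- function(chain, stimulus) {
  stopifnot(inherits(chain, "strf_chain"))
  if (inherits(stimulus, "waveform")) {
    cfg <- cochlear_config(C = chain$C, f_low = min(chain$center_freqs),
                           f_high = max(chain$center_freqs),
                           bin_duration = chain$bin_duration)
    stimulus <- apply_filterbank(stimulus, cfg)
  }
  X <- if (inherits(stimulus, "spectrogram")) stimulus$values else as.matrix(stimulus)
  if (length(chain$modules) > 1 && is.null(chain$norm))
    stop("state error: chain normalization is unfitted; ",
         "call fit_chain_normalization() or strf() first")
  chain_forward(chain, X, states = chain$norm, refit = FALSE)$output
}

# Serialization -----------------------------------------------------------

chain_format_version <- "1.0"

#' Serialize / deserialize a model chain as JSON
#'
#' The JSON document carries a format version, the chain metadata and every
#' module's named parameters at full double precision, so a round trip
#' reproduces predictions exactly.
#'
#' @param chain an `"strf_chain"`.
#' @param path file path; for `serialize_chain` omit to get a JSON string.
#' @return `deserialize_chain`/`read_chain_json` return an `"strf_chain"`.
#' @export
serialize_chain <- function(chain, path = NULL) {
  stopifnot(inherits(chain, "strf_chain"))
  doc <- list(format_version = chain_format_version,
              name = chain$name,
              C = chain$C, U = chain$U, D = chain$D,
              bin_duration = chain$bin_duration,
              center_freqs = chain$center_freqs,
              modules = lapply(chain$modules, function(m) {
                m[vapply(m, is.matrix, TRUE)] <-
                  lapply(m[vapply(m, is.matrix, TRUE)], function(x)
                    list(dim = dim(x), data = as.numeric(x)))
                m
              }),
              norm = if (is.null(chain$norm)) NULL else
                lapply(chain$norm, function(s)
                  list(mu = s$mu, sigma = s$sigma, z = s$z,
                       degenerate = s$degenerate)))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' @rdname serialize_chain
#' @param text JSON string, as produced by `serialize_chain`.
#' @export
deserialize_chain <- function(text) {
  doc <- jsonlite::fromJSON(text, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(doc$format_version))
    stop("parse error at 'format_version': field missing")
  if (!identical(doc$format_version, chain_format_version))
    stop("incompatible chain format version '", doc$format_version,
         "' (expected '", chain_format_version, "')")
  for (f in c("name", "C", "U", "bin_duration", "center_freqs", "modules"))
    if (is.null(doc[[f]])) stop("parse error at '", f, "': field missing")
  modules <- lapply(seq_along(doc$modules), function(i) {
    m <- doc$modules[[i]]
    if (is.null(m$type))
      stop("parse error at 'modules[", i, "].type': field missing")
    for (k in names(m)) {
      if (is.list(m[[k]]) && !is.null(m[[k]]$dim))
        m[[k]] <- matrix(m[[k]]$data, m[[k]]$dim[1], m[[k]]$dim[2])
    }
    m
  })
  norm <- NULL
  if (!is.null(doc$norm))
    norm <- lapply(doc$norm, function(s)
      structure(list(mu = s$mu, sigma = s$sigma, z = s$z,
                     degenerate = as.logical(s$degenerate)),
                class = "normalization_state"))
  structure(list(modules = modules, C = doc$C, U = doc$U, D = doc$D,
                 bin_duration = doc$bin_duration,
                 center_freqs = doc$center_freqs,
                 name = doc$name, norm = norm),
            class = "strf_chain")
}

#' @rdname serialize_chain
#' @export
read_chain_json <- function(path) {
  deserialize_chain(paste(readLines(path), collapse = "\n"))
}
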