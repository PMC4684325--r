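#' Logarithmically spaced filterbank center frequencies
#'
#' Channel center frequencies are spaced geometrically between the band edges,
#' with the first channel at `f_low` and the last at `f_high` (the default
#' band, 18 channels over 200-20,000 Hz, matches the standard cortical
#' spectrogram used throughout the package).
#'
#' @param C number of channels (>= 2).
#' @param f_low,f_high band edges in Hz, `0 < f_low < f_high`.
#' @return Numeric vector of `C` center frequencies in Hz.
#' @export
#' @examples
#' center_frequencies(18, 200, 20000)
center_frequencies <- function(C, f_low, f_high) {
  if (!is.numeric(C) || length(C) != 1 || C < 2 || C != round(C))
    stop("invalid config: C must be an integer >= 2")
  if (f_low <= 0 || f_low >= f_high)
    stop("invalid config: need 0 < f_low < f_high")
  ratio <- (f_high / f_low)^(1 / (C - 1))
  f_low * ratio^(0:(C - 1))
}

#' Shared quality factor of the gammatone filterbank
#'
#' All channels share a single dimensionless quality factor tied to the
#' channel spacing, `Q = [ (f_high/f_low)^(1/(C-1)) - 1 ]^(-1)`, so that
#' neighboring filters overlap consistently across the band.
#'
#' @inheritParams center_frequencies
#' @return The scalar Q.
#' @export
shared_q <- function(C, f_low, f_high) {
  if (!is.numeric(C) || length(C) != 1 || C < 2 || C != round(C))
    stop("invalid config: C must be an integer >= 2")
  if (f_low <= 0 || f_low >= f_high)
    stop("invalid config: need 0 < f_low < f_high")
  1 / ((f_high / f_low)^(1 / (C - 1)) - 1)
}

#' Cochlear filterbank configuration
#'
#' @param C channel count.
#' @param f_low,f_high band edges in Hz.
#' @param Q quality factor shared by all channels; defaults to [shared_q()].
#' @param bin_duration output spectrogram bin duration in seconds (default
#'   0.010, i.e. a 100 Hz bin rate; 200 or 400 Hz are the usual alternatives).
#' @return A list of class `"cochlear_config"`.
#' @export
cochlear_config <- function(C = 18, f_low = 200, f_high = 20000,
                            Q = shared_q(C, f_low, f_high),
                            bin_duration = 0.010) {
  if (C < 1) stop("invalid config: C >= 1 required")
  if (Q <= 0) stop("invalid config: Q > 0 required")
  if (bin_duration <= 0) stop("invalid config: bin_duration > 0 required")
  structure(list(C = C, f_low = f_low, f_high = f_high, Q = Q,
                 bin_duration = bin_duration,
                 center_freqs = center_frequencies(C, f_low, f_high)),
            class = "cochlear_config")
}

#' Acoustic waveform container
#'
#' @param samples numeric vector of amplitudes.
#' @param rate sampling rate in samples/second.
#' @export
waveform <- function(samples, rate) {
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  if (length(samples) < 1) stop("waveform must contain at least one sample")
  if (!all(is.finite(samples))) stop("data error: non-finite samples")
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "waveform")
}

# Frequency response of one second-order gammatone channel on an FFT grid.
# G(s) = [K s / (s^2 + (w0/Q) s + w0^2)]^4 at s = i*omega, with K = w0/Q so
# that the peak gain (at omega = w0) is exactly 1.
gammatone_response <- function(omega, f0, Q) {
  w0 <- 2 * pi * f0
  K <- w0 / Q
  s <- 1i * omega
  g2 <- K * s / (s^2 + (w0 / Q) * s + w0^2)
  g2^4
}

#' Bandpass-filtered waveforms of the gammatone filterbank
#'
#' Applies each second-order gammatone channel to the waveform by
#' frequency-domain multiplication (full-signal FFT) and returns the real
#' filtered signals before envelope extraction. This is the linear stage of
#' [apply_filterbank()], exposed for inspection and testing.
#'
#' @param wave a [waveform()].
#' @param cfg a [cochlear_config()].
#' @return Numeric matrix, `C` channels by `length(wave$samples)` samples.
#' @export
gammatone_filter <- function(wave, cfg) {
  stopifnot(inherits(wave, "waveform"), inherits(cfg, "cochlear_config"))
  x <- wave$samples
  n <- length(x)
  freqs <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n * wave$rate
  omega <- 2 * pi * freqs
  X <- stats::fft(x)
  out <- matrix(0, cfg$C, n)
  for (i in seq_len(cfg$C)) {
    G <- gammatone_response(omega, cfg$center_freqs[i], cfg$Q)
    out[i, ] <- Re(stats::fft(X * G, inverse = TRUE)) / n
  }
  out
}

# Analytic-signal envelopes of the filtered channels (magnitude of the
# Hilbert transform), computed directly in the frequency domain.
gammatone_envelope <- function(wave, cfg) {
  x <- wave$samples
  n <- length(x)
  freqs <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n * wave$rate
  omega <- 2 * pi * freqs
  X <- stats::fft(x)
  # analytic-signal weights: double positive frequencies, zero negatives
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  env <- matrix(0, cfg$C, n)
  for (i in seq_len(cfg$C)) {
    G <- gammatone_response(omega, cfg$center_freqs[i], cfg$Q)
    env[i, ] <- Mod(stats::fft(X * G * h, inverse = TRUE) / n)
  }
  env
}

#' Convert an acoustic waveform to a compressed-ready spectrogram
#'
#' Each channel of the second-order gammatone filterbank is applied in the
#' frequency domain; the channel envelope is the magnitude of the analytic
#' signal of the filtered waveform, then smoothed with a boxcar over one
#' output bin and decimated to the bin rate.
#'
#' @param wave a [waveform()].
#' @param cfg a [cochlear_config()].
#' @return A [spectrogram()] with `T = floor(duration / bin_duration)` bins.
#' @export
apply_filterbank <- function(wave, cfg) {
  stopifnot(inherits(wave, "waveform"), inherits(cfg, "cochlear_config"))
  if (!all(is.finite(wave$samples))) stop("data error: non-finite samples")
  spb <- wave$rate * cfg$bin_duration  # samples per output bin
  nbins <- floor(length(wave$samples) / spb)
  if (nbins < 1) stop("empty output: waveform shorter than one bin")
  env <- gammatone_envelope(wave, cfg)
  vals <- matrix(0, cfg$C, nbins)
  edges <- round(spb * (0:nbins))
  for (b in seq_len(nbins)) {
    idx <- (edges[b] + 1):edges[b + 1]
    vals[, b] <- rowMeans(env[, idx, drop = FALSE])
  }
  vals[vals < 0] <- 0
  spectrogram(vals, cfg$center_freqs, cfg$bin_duration)
}

#' Logarithmic envelope compression
#'
#' Elementwise `log(x + phi1)`. The single offset parameter `phi1 > 0` sets
#' the amount of compression (small values compress strongly) and keeps the
#' logarithm defined at zero input.
#'
#' @param spec a [spectrogram()] (or nonnegative matrix).
#' @param phi1 positive additive offset in envelope units.
#' @return Object of the same type with compressed values.
#' @export
log_compress <- function(spec, phi1 = 1) {
  if (!is.numeric(phi1) || phi1 <= 0) stop("domain error: phi1 must be > 0")
  v <- if (inherits(spec, "spectrogram")) spec$values else spec
  if (any(v < 0)) stop("log_compress expects nonnegative envelopes")
  out <- log(v + phi1)
  if (inherits(spec, "spectrogram")) {
    spec$values <- out
    spec
  } else out
}

#' Read and write PCM WAV files
#'
#' A minimal RIFF/WAVE codec supporting uncompressed 16- and 24-bit integer
#' PCM and 32-bit IEEE float, mono or multichannel (channels are averaged on
#' read). Samples are scaled to \[-1, 1\].
#'
#' @param path file path.
#' @return `read_wav` returns a [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      extra <- sz - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: missing fmt or data chunk")
  x <- switch(as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                   endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) / 3
      b <- matrix(as.integer(data_raw), 3, n)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v[v >= 2^23] <- v[v >= 2^23] - 2^24
      v / 2^23
    },
    "32" = {
      if (fmt$audio_format == 3)
        readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
      else
        readBin(data_raw, "integer", length(data_raw) / 4, 4,
                endian = "little") / 2^31
    },
    stop("unsupported WAV bit depth: ", fmt$bits))
  if (fmt$n_channels > 1)
    x <- rowMeans(matrix(x, ncol = fmt$n_channels, byrow = TRUE))
  waveform(x, fmt$rate)
}

#' @rdname read_wav
#' @param wave a [waveform()] with samples in \[-1, 1\].
#' @export
write_wav <- function(wave, path) {
  stopifnot(inherits(wave, "waveform"))
  x <- pmax(pmin(wave$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(1), con, 2, endian = "little")  # PCM
  writeBin(as.integer(1), con, 2, endian = "little")  # mono
  writeBin(as.integer(wave$rate), con, 4, endian = "little")
  writeBin(as.integer(wave$rate * 2), con, 4, endian = "little")
  writeBin(as.integer(2), con, 2, endian = "little")
  writeBin(as.integer(16), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
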