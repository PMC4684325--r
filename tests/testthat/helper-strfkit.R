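# shared fixtures and independent oracles, built in code

rand_spec <- function(C, Tn, seed = 1, f_low = 200, f_high = 20000,
                      bin_duration = 0.01) {
  set.seed(seed)
  spectrogram(matrix(abs(rnorm(C * Tn)), C, Tn),
              center_frequencies(max(C, 2), f_low, f_high)[seq_len(C)],
              bin_duration)
}

# brute-force nested-loop FIR prediction oracle
fir_oracle <- function(X, H, b) {
  C <- nrow(X); Tn <- ncol(X); U <- ncol(H)
  y <- rep(b, Tn)
  for (t in seq_len(Tn)) {
    for (i in seq_len(U)) {
      tt <- t - (i - 1)
      if (tt >= 1) for (f in seq_len(C)) y[t] <- y[t] + H[f, i] * X[f, tt]
    }
  }
  y
}

# all-pairs dominance oracle for the Pareto front
pareto_oracle <- function(pts) {
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    !any(vapply(seq_len(nrow(pts)), function(j) {
      if (j == i) return(FALSE)
      pts$param_count[j] <= pts$param_count[i] &&
        pts$performance[j] >= pts$performance[i] &&
        (pts$param_count[j] < pts$param_count[i] ||
           pts$performance[j] > pts$performance[i])
    }, logical(1)))
  }, logical(1))
  out <- pts[keep, , drop = FALSE]
  out[order(out$param_count, out$performance), , drop = FALSE]
}

# tiny pure-tone waveform
tone_wave <- function(freq, duration, rate = 48000, amp = 1) {
  waveform(amp * sin(2 * pi * freq * (seq_len(round(duration * rate)) - 1) / rate),
           rate)
}
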