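# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pure tone recording; integer n_cycles keeps it periodic so FFT-based
# resampling round-trips cleanly.
make_tone <- function(freq, duration = 2, rate = 8000, amp = 1, noise = 0,
                      site = "unknown", subject_id = "tone") {
  n <- round(duration * rate)
  x <- amp * sin(2 * pi * freq * (seq_len(n) - 1) / rate)
  if (noise > 0) x <- x + stats::rnorm(n, 0, noise)
  pcg_recording(x, rate, site = site, subject_id = subject_id)
}

# FFT-peak oracle: frequency of the dominant DFT bin.
fft_peak <- function(x, rate) {
  n <- length(x)
  mag <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  (which.max(mag) - 1) * rate / n
}

# Polynomial coefficients (ascending powers of z^-1) from pole locations;
# used to plant known resonances in LPC fits.
poly_from_poles <- function(poles) {
  coefs <- 1
  for (p in poles) {
    coefs <- c(coefs, 0) - c(0, p * coefs)
  }
  stopifnot(max(abs(Im(coefs))) < 1e-10)
  Re(coefs)
}

# Build an lpc_fit object with planted poles (conjugates added
# automatically) without running an estimator.
planted_fit <- function(radii, freqs_hz, rate, gain = 1) {
  ang <- 2 * pi * freqs_hz / rate
  poles <- c(radii * exp(1i * ang), radii * exp(-1i * ang))
  coefs <- poly_from_poles(poles)           # A(z) = 1 + c1 z^-1 + ...
  a <- -coefs[-1]                           # predictor convention
  structure(list(coefficients = a, gain = gain, order = length(a),
                 stable = all(radii < 1)),
            class = "lpc_fit")
}

# Direct normal-equations LPC oracle (Yule-Walker on the same tapered
# frame), independent of the Levinson-Durbin path.
lpc_oracle <- function(frame, order) {
  n <- length(frame)
  r <- vapply(0:order, function(k)
    sum(frame[seq_len(n - k)] * frame[(k + 1):n]), numeric(1))
  R <- stats::toeplitz(r[seq_len(order)])
  as.numeric(solve(R, r[2:(order + 1)]))
}

# Spectrogram object with planted magnitudes, for entropy/energy oracles.
planted_spectrogram <- function(S, rate = 8000) {
  nt <- ncol(S)
  structure(
    list(S = S, bin_freqs = seq(0, rate / 2, length.out = nrow(S)),
         frame_times = (seq_len(nt) - 0.5) * 0.016,
         params = list(rate = rate, window_s = 0.032, hop = 128,
                       nfft = 2 * (nrow(S) - 1), window = "hann",
                       window_length = 256)),
    class = "spectrogram")
}

# Loop-based entropy/energy oracles (element-wise, no vectorized reuse).
entropy_oracle <- function(S, eps) {
  tot <- 0
  for (i in seq_len(nrow(S)))
    for (j in seq_len(ncol(S)))
      tot <- tot + log(S[i, j]^2 + eps)
  tot
}
energy_oracle <- function(S) {
  tot <- 0
  for (i in seq_len(nrow(S)))
    for (j in seq_len(ncol(S)))
      tot <- tot + S[i, j]^2
  tot
}

# Hand-executed Holm step-down, written independently of the package code.
holm_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * sorted[i])
    adj[i] <- min(1, running)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# A tiny cohort for pipeline-level tests: small but with both groups at
# every site.
small_cohort <- function(n_normal = 6, n_pah = 5, seed = 11, duration = 20,
                         ...) {
  synth_cohort(synth_config(n_normal = n_normal, n_pah = n_pah,
                            duration = duration, seed = seed, ...))
}
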