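#' Short-time Fourier transform magnitude spectrogram
#'
#' @param x Numeric waveform.
#' @param rate Sampling rate in Hz.
#' @param window_s Analysis window length in seconds (default 0.032,
#'   mirroring the LPC framing).
#' @param hop_frac Hop as a fraction of the window (default 0.5).
#' @param nfft FFT size; default next power of two >= window length.
#' @param window Analysis taper: `"hann"` (default), `"hamming"`, or
#'   `"rectangular"`.
#' @return A `spectrogram`: list with `S` (non-negative magnitude matrix,
#'   frequency bins x time frames), `bin_freqs` (Hz), `frame_times`
#'   (window centers, s), and `params`.
#' @export
compute_spectrogram <- function(x, rate, window_s = 0.032, hop_frac = 0.5,
                                nfft = NULL,
                                window = c("hann", "hamming", "rectangular")) {
  window <- match.arg(window)
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty signal")
  wl <- as.integer(round(window_s * rate))
  if (wl < 2L) stop("analysis window is below two samples")
  if (wl > length(x))
    stop("analysis window is longer than the signal")
  hop <- max(1L, as.integer(round(wl * hop_frac)))
  if (is.null(nfft)) nfft <- 2^ceiling(log2(wl))
  nfft <- as.integer(nfft)
  if (nfft < wl) stop("nfft must be at least the window length")
  w <- switch(window,
    hann    = 0.5 - 0.5 * cos(2 * pi * (seq_len(wl) - 1) / (wl - 1)),
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(wl) - 1) / (wl - 1)),
    rectangular = rep(1, wl))
  starts <- seq(1L, length(x) - wl + 1L, by = hop)
  idx <- outer(seq_len(wl) - 1L, starts, `+`)
  frames <- matrix(x[idx], nrow = wl) * w
  if (nfft > wl)
    frames <- rbind(frames, matrix(0, nfft - wl, ncol(frames)))
  spec <- stats::mvfft(frames)
  n_bins <- nfft %/% 2L + 1L
  structure(
    list(S = Mod(spec[seq_len(n_bins), , drop = FALSE]),
         bin_freqs = (seq_len(n_bins) - 1) * rate / nfft,
         frame_times = (starts - 1 + (wl - 1) / 2) / rate,
         params = list(rate = rate, window_s = window_s, hop = hop,
                       nfft = nfft, window = window, window_length = wl)),
    class = "spectrogram")
}

# Frame selector for a time segment [t0, t1) on spectrogram frame centers.
segment_frames <- function(spec, segment) {
  if (is.null(segment)) return(seq_along(spec$frame_times))
  if (length(segment) != 2L || segment[2] <= segment[1])
    stop("segment must be an increasing (start, end) pair in seconds")
  which(spec$frame_times >= segment[1] & spec$frame_times < segment[2])
}

# Floor constant used inside log(S^2 + eps): relative to the spectrogram's
# maximum squared magnitude so silent replica frames stay finite. Computed
# from the WHOLE spectrogram, never per segment, so entropy is additive
# across partitions of the same spectrogram.
entropy_floor <- function(spec, eps_rel = 1e-12) {
  m <- max(spec$S)^2
  if (m > 0) m * eps_rel else .Machine$double.xmin
}

#' Spectrogram log-power entropy of a time segment
#'
#' The feature is the sum of `log(S^2 + eps)` over every time-frequency bin
#' of the segment (natural log; `eps` is a floor constant, `eps_rel` times
#' the spectrogram's maximum squared magnitude, so exact zeros stay
#' finite). A spectrum concentrated in few bins leaves most bins at the
#' floor and yields a LOW value; energy spread across many bins yields a
#' high value — low entropy signals an ordered, vowel-like pattern.
#'
#' @param spec A [compute_spectrogram()] result.
#' @param segment `c(start, end)` in seconds (frames with center in
#'   `[start, end)`), or `NULL` for the whole spectrogram.
#' @param eps_rel Relative floor constant (default 1e-12).
#' @return The entropy (log-power units), a finite scalar.
#' @export
entropy_feature <- function(spec, segment = NULL, eps_rel = 1e-12) {
  stopifnot(inherits(spec, "spectrogram"))
  idx <- segment_frames(spec, segment)
  if (length(idx) == 0L) stop("segment contains no spectrogram frames")
  sum(log(spec$S[, idx, drop = FALSE]^2 + entropy_floor(spec, eps_rel)))
}

#' Spectrogram energy of a time segment
#'
#' Sum of squared magnitudes over the segment's time-frequency bins.
#'
#' @inheritParams entropy_feature
#' @return Non-negative scalar energy.
#' @export
energy_feature <- function(spec, segment = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  idx <- segment_frames(spec, segment)
  if (length(idx) == 0L) stop("segment contains no spectrogram frames")
  sum(spec$S[, idx, drop = FALSE]^2)
}

#' Relative spectral power in a frequency band
#'
#' Periodogram power inside `band` divided by total power; the comparator
#' feature from earlier narrow-band work (21-22 Hz at the 2LICS).
#'
#' @param x Numeric waveform.
#' @param rate Sampling rate in Hz.
#' @param band `c(low, high)` in Hz, strictly inside `(0, rate/2)`.
#' @return Relative power in `[0, 1]`.
#' @export
relative_band_power <- function(x, rate, band = c(21, 22)) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty signal")
  if (length(band) != 2L || band[1] >= band[2] || band[1] < 0 ||
      band[2] > rate / 2)
    stop("band must be an increasing pair inside (0, rate/2)")
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  n_bins <- n %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1) * rate / n
  P <- P[seq_len(n_bins)]
  total <- sum(P)
  if (total == 0) return(0)
  sum(P[freqs >= band[1] & freqs <= band[2]]) / total
}

#' Per-spectrogram-frame feature series for all formants of a recording
#'
#' Runs the front half of the pipeline once (normalize, resample, formant
#' tracking, sine-wave replica, spectrogram per formant) and returns, per
#' formant, the per-STFT-frame entropy and energy contributions. Any
#' segment feature is then a cheap sum over frames, which is what makes the
#' window-length sweep affordable: the audio analysis runs once per
#' recording, not once per window length.
#'
#' @param rec A [pcg_recording()].
#' @param analysis_rate,order,frame_duration,max_formants,radius_floor,taper
#'   Passed to [track_formants()].
#' @param window_s,hop_frac,window Passed to [compute_spectrogram()].
#' @param eps_rel Entropy floor constant, see [entropy_feature()].
#' @return List with `frame_times`, `entropy` and `energy`
#'   (n_stft_frames x n_formants matrices of per-frame contributions),
#'   `duration` (the source recording's duration in seconds, which governs
#'   `floor(duration / L)` segment counts; the trailing partial analysis
#'   frame carries no spectrogram frames), and `track`.
#' @export
formant_feature_frames <- function(rec, analysis_rate = 8000, order = 8L,
                                   frame_duration = 0.032, max_formants = 4L,
                                   radius_floor = 0.7, taper = "hamming",
                                   window_s = 0.032, hop_frac = 0.5,
                                   window = "hann", eps_rel = 1e-12) {
  track <- track_formants(rec, order = order, analysis_rate = analysis_rate,
                          frame_duration = frame_duration,
                          max_formants = max_formants,
                          radius_floor = radius_floor, taper = taper)
  replica <- synthesize_replica(track)
  ent <- ener <- NULL
  frame_times <- NULL
  for (f in seq_len(max_formants)) {
    spec <- compute_spectrogram(replica$waveforms[, f], replica$rate,
                                window_s = window_s, hop_frac = hop_frac,
                                window = window)
    eps <- entropy_floor(spec, eps_rel)
    e_frames <- colSums(log(spec$S^2 + eps))
    p_frames <- colSums(spec$S^2)
    if (is.null(ent)) {
      frame_times <- spec$frame_times
      ent <- matrix(0, length(e_frames), max_formants)
      ener <- matrix(0, length(e_frames), max_formants)
    }
    ent[, f] <- e_frames
    ener[, f] <- p_frames
  }
  list(frame_times = frame_times, entropy = ent, energy = ener,
       duration = pcg_duration(rec), track = track)
}

# Mean-over-disjoint-segments of a per-frame contribution series.
# Segments are [0, L), [L, 2L), ...; floor(duration / L) of them; a partial
# tail is discarded. `combine` is sum for entropy/energy.
segment_mean <- function(frame_times, contrib, duration, L) {
  n_seg <- floor(duration / L + 1e-9)
  if (n_seg < 1L)
    stop("window length L exceeds the analyzed duration")
  vals <- vapply(seq_len(n_seg), function(j) {
    idx <- frame_times >= (j - 1) * L & frame_times < j * L
    sum(contrib[idx])
  }, numeric(1))
  mean(vals)
}

#' Windowed speech-spectral feature of one formant
#'
#' Full single-recording pipeline: resample to the analysis rate, track
#' formants, synthesize the sine-wave replica of formant `formant`, compute
#' its spectrogram, evaluate the feature on each of the
#' `floor(duration / L)` disjoint segments of length `L`, and return the
#' arithmetic mean (a partial tail segment is discarded).
#'
#' For `kind = "relative_power"` the feature is computed on the resampled
#' original waveform (it is a whole-sound comparator, not a replica
#' feature) and `formant` is ignored.
#'
#' @param rec A [pcg_recording()].
#' @param formant Formant index 1..4.
#' @param kind `"entropy"`, `"energy"`, or `"relative_power"`.
#' @param L Segment (window) length in seconds, `1 <= L <= duration`.
#' @param band Frequency band for `kind = "relative_power"`.
#' @param ... Passed to [formant_feature_frames()].
#' @return Scalar feature value.
#' @export
windowed_feature <- function(rec, formant = 1L,
                             kind = c("entropy", "energy", "relative_power"),
                             L = 10, band = c(21, 22), ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "pcg_recording"))
  dur <- pcg_duration(rec)
  if (L <= 0 || L > dur + 1e-9)
    stop("window length L must lie in (0, recording duration]")
  if (kind == "relative_power") {
    rec8 <- pcg_resample(pcg_normalize(rec), 8000)
    n_seg <- floor(pcg_duration(rec8) / L + 1e-9)
    seg_len <- floor(L * rec8$rate)
    vals <- vapply(seq_len(n_seg), function(j) {
      seg <- rec8$samples[((j - 1) * seg_len + 1):(j * seg_len)]
      relative_band_power(seg, rec8$rate, band)
    }, numeric(1))
    return(mean(vals))
  }
  ff <- formant_feature_frames(rec, ...)
  contrib <- if (kind == "entropy") ff$entropy[, formant] else ff$energy[, formant]
  segment_mean(ff$frame_times, contrib, ff$duration, L)
}
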