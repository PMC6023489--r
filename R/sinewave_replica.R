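#' Synthesize the sine-wave replica of a formant track
#'
#' Each formant trajectory is rendered as a single time-varying sinusoid:
#' frequency and amplitude are linearly interpolated between frame centers
#' (held constant before the first and after the last center), and the
#' oscillator phase is the cumulative sum of instantaneous frequency, so
#' phase is continuous everywhere. Frames in which a formant is absent
#' synthesize silence: their samples are zeroed after interpolation. The
#' replica therefore keeps only the formant trajectories and discards all
#' other structure of the source sound.
#'
#' @param track A [track_formants()] result.
#' @param rate Synthesis rate in Hz; defaults to the analysis rate so
#'   spectrogram grids stay comparable.
#' @return A `sinusoid_replica`: list with `waveforms` (a samples x
#'   n_formants matrix, one column per formant, spanning exactly the framed
#'   portion of the source), `rate`, and `n_formants`.
#' @export
synthesize_replica <- function(track, rate = track$rate) {
  stopifnot(inherits(track, "formant_track"))
  if (track$n_frames < 1L) stop("empty formant track")
  n_formants <- ncol(track$freqs)
  flen <- round(track$frame_duration * rate)
  n <- as.integer(track$n_frames * flen)
  t_samp <- (seq_len(n) - 0.5) / rate
  waves <- matrix(0, n, n_formants)
  # frame index of each sample, for silencing absent frames
  frame_of <- pmin(track$n_frames, floor((seq_len(n) - 1) / flen) + 1L)
  for (f in seq_len(n_formants)) {
    fr <- track$freqs[, f]
    am <- track$amps[, f]
    ok <- !is.na(fr)
    if (!any(ok)) next
    centers <- track$frame_times[ok]
    freq_i <- if (sum(ok) == 1L) rep(fr[ok], n) else
      stats::approx(centers, fr[ok], xout = t_samp, rule = 2)$y
    amp_frames <- ifelse(is.na(am), 0, am)
    amp_i <- if (track$n_frames == 1L) rep(amp_frames, n) else
      stats::approx(track$frame_times, amp_frames, xout = t_samp, rule = 2)$y
    phase <- 2 * pi * cumsum(freq_i) / rate
    w <- amp_i * cos(phase)
    w[!ok[frame_of]] <- 0
    waves[, f] <- w
  }
  if (all(is.na(track$freqs)))
    warning("all formants absent: replica is silent")
  structure(list(waveforms = waves, rate = rate, n_formants = n_formants),
            class = "sinusoid_replica")
}

#' @export
print.sinusoid_replica <- function(x, ...) {
  cat(sprintf("<sinusoid_replica> %d formants, %.3f s @ %g Hz\n",
              x$n_formants, nrow(x$waveforms) / x$rate, x$rate))
  invisible(x)
}

#' Export replica waveforms as WAV files for audition
#'
#' Writes one 16-bit PCM file per formant, named
#' `<prefix>_formant<k>.wav`. Waveforms are jointly scaled by the replica's
#' global peak so relative formant levels are preserved.
#'
#' @param replica A [synthesize_replica()] result.
#' @param prefix Output path prefix (directory must exist).
#' @return Character vector of written paths, invisibly.
#' @export
write_replica_wavs <- function(replica, prefix) {
  stopifnot(inherits(replica, "sinusoid_replica"))
  peak <- max(abs(replica$waveforms))
  scale <- if (peak > 0) peak else 1
  paths <- character(replica$n_formants)
  for (f in seq_len(replica$n_formants)) {
    rec <- pcg_recording(replica$waveforms[, f] / scale, replica$rate)
    paths[f] <- paste0(prefix, "_formant", f, ".wav")
    write_wav(rec, paths[f])
  }
  invisible(paths)
}
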