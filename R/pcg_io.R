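#' Construct a phonocardiogram recording object
#'
#' A `pcg_recording` bundles a mono heart-sound waveform with its sampling
#' rate, the auscultation site it was captured at, and a subject identifier.
#' Samples are dimensionless amplitudes; analysis code normalizes them to
#' peak 1 so that features never depend on stethoscope gain.
#'
#' @param samples Numeric vector of finite amplitudes (one channel).
#' @param rate Sampling rate in Hz (> 0).
#' @param site Auscultation site, one of `"apex"`, `"2LICS"`, `"2RICS"`,
#'   `"4LICS"`, or `"unknown"`.
#' @param subject_id Opaque subject identifier string.
#' @return An object of class `pcg_recording` with fields `samples`, `rate`,
#'   `site`, `subject_id`.
#' @export
pcg_recording <- function(samples, rate, site = "unknown", subject_id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("sampling rate must be a single positive number")
  site <- match.arg(site, c("apex", "2LICS", "2RICS", "4LICS", "unknown"))
  structure(
    list(samples = samples, rate = as.numeric(rate), site = site,
         subject_id = as.character(subject_id)),
    class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> subject=%s site=%s %.3f s @ %g Hz (%d samples)\n",
              x$subject_id, x$site, length(x$samples) / x$rate, x$rate,
              length(x$samples)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `pcg_recording`.
#' @return Duration in seconds.
#' @export
pcg_duration <- function(rec) length(rec$samples) / rec$rate

#' Normalize a recording to unit peak amplitude
#'
#' Stethoscope gain is arbitrary, so all analysis runs on peak-normalized
#' signals. A silent recording is returned unchanged.
#'
#' @param rec A `pcg_recording`.
#' @return The recording with `max(abs(samples)) == 1` (unless silent).
#' @export
pcg_normalize <- function(rec) {
  peak <- max(abs(rec$samples))
  if (peak > 0) rec$samples <- rec$samples / peak
  rec
}

# ---------------------------------------------------------------------------
# WAV I/O. No WAV reader ships with base R, so a minimal RIFF/WAVE PCM
# parser lives here. Supports uncompressed integer PCM (8/16/24/32 bit) and
# IEEE float (32/64 bit), mono only; writes 16-bit PCM.
# ---------------------------------------------------------------------------

#' Read a mono PCM WAV file
#'
#' @param path Path to a RIFF/WAVE file containing uncompressed PCM
#'   (8/16/24/32-bit integer) or IEEE-float (32/64-bit) audio.
#' @param site,subject_id Metadata attached to the returned recording.
#' @return A [pcg_recording()] with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path, site = "unknown", subject_id = NA_character_) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1L, 256L))
      u32 <- function(off) sum(as.numeric(body[off + 1:4]) * 256^(0:3))
      fmt <- list(audio_format = u16(0L), n_channels = u16(2L),
                  rate = u32(4L), bits = u16(14L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      seek(con, sz + sz %% 2L, origin = "current")  # chunks are word-aligned
      next
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1L)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw)) stop("WAV file has no data chunk: ", path)
  if (fmt$n_channels != 1L)
    stop(sprintf("expected a mono recording but '%s' has %d channels",
                 path, fmt$n_channels))
  if (!fmt$audio_format %in% c(1L, 3L))
    stop("unsupported (compressed?) WAV codec in ", path,
         ": only PCM and IEEE float are readable")

  samples <- if (fmt$audio_format == 3L) {
    readBin(data_raw, "double", length(data_raw) %/% (fmt$bits / 8),
            size = fmt$bits / 8, endian = "little")
  } else if (fmt$bits == 8L) {
    # 8-bit PCM is unsigned
    (as.numeric(readBin(data_raw, "integer", length(data_raw), 1L,
                        signed = FALSE)) - 128) / 128
  } else if (fmt$bits == 16L) {
    # 32767 matches the writer's scale so round trips are exact
    readBin(data_raw, "integer", length(data_raw) %/% 2L, 2L,
            endian = "little") / 32767
  } else if (fmt$bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.numeric(data_raw[seq_len(3L * n)]), nrow = 3L)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    ifelse(v >= 2^23, v - 2^24, v) / 2^23
  } else if (fmt$bits == 32L) {
    readBin(data_raw, "integer", length(data_raw) %/% 4L, 4L,
            endian = "little") / 2^31
  } else stop("unsupported PCM bit depth: ", fmt$bits)

  pcg_recording(samples, fmt$rate, site = site, subject_id = subject_id)
}

#' Write a recording as 16-bit PCM WAV
#'
#' Samples are clipped to `[-1, 1]` and quantized to 16 bits.
#'
#' @param rec A [pcg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "pcg_recording"))
  x <- pmin(pmax(rec$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  wr16 <- function(v) writeBin(as.integer(v), con, 2L, endian = "little")
  wr32 <- function(v) writeBin(as.integer(v), con, 4L, endian = "little")
  writeChar("RIFF", con, eos = NULL); wr32(36L + n_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wr32(16L)
  wr16(1L); wr16(1L)                       # PCM, mono
  wr32(as.integer(round(rec$rate)))
  wr32(as.integer(round(rec$rate)) * 2L)   # byte rate
  wr16(2L); wr16(16L)                      # block align, bits
  writeChar("data", con, eos = NULL); wr32(n_bytes)
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

#' Band-limited resampling of a recording
#'
#' Resamples via the Fourier method: the DFT of the signal is truncated or
#' zero-padded to the new length, which is exact band-limited (sinc)
#' interpolation under the periodic-extension convention and introduces no
#' aliasing for content below the lower Nyquist frequency.
#'
#' @param rec A [pcg_recording()].
#' @param target_rate New sampling rate in Hz (> 0).
#' @return The resampled recording; duration is preserved to within one
#'   sample period.
#' @export
pcg_resample <- function(rec, target_rate) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop("target_rate must be a single positive number")
  if (target_rate == rec$rate) return(rec)
  x <- rec$samples
  n <- length(x)
  n_out <- max(1L, as.integer(round(n * target_rate / rec$rate)))
  X <- stats::fft(x)
  Y <- complex(n_out)
  nk <- min(n, n_out)
  n_pos <- (nk + 1L) %/% 2L            # positive-frequency bins beyond DC
  Y[1L] <- X[1L]
  if (n_pos >= 1L) {
    Y[2L:(n_pos + 1L)] <- X[2L:(n_pos + 1L)]
    Y[(n_out - n_pos + 1L):n_out] <- X[(n - n_pos + 1L):n]
  }
  if (nk %% 2L == 0L) {
    # shared Nyquist bin: split when upsampling, fold when downsampling
    if (n_out > n) {
      half <- X[n %/% 2L + 1L] / 2
      Y[n %/% 2L + 1L] <- half
      Y[n_out - n %/% 2L + 1L] <- Conj(half)
    } else {
      Y[n_out %/% 2L + 1L] <- X[n_out %/% 2L + 1L] + X[n - n_out %/% 2L + 1L]
    }
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  pcg_recording(y, target_rate, site = rec$site, subject_id = rec$subject_id)
}

#' Split a recording into consecutive fixed-length frames
#'
#' Frames are non-overlapping and rectangular; any trailing partial frame is
#' discarded rather than zero-padded, so every frame is full length.
#'
#' @param rec A [pcg_recording()].
#' @param frame_duration Frame length in seconds (default 0.032, i.e. 256
#'   samples at 8 kHz).
#' @return A `frame_sequence`: list with `frames` (a `frame_length` x
#'   `n_frames` matrix, one frame per column), `frame_duration`,
#'   `frame_length`, `rate`, and `frame_times` (frame centers in seconds).
#' @export
frame_signal <- function(rec, frame_duration = 0.032) {
  stopifnot(inherits(rec, "pcg_recording"))
  flen <- as.integer(round(frame_duration * rec$rate))
  if (flen < 1L) stop("frame_duration is below one sample period")
  n <- length(rec$samples)
  if (n < flen)
    stop(sprintf("recording (%.4f s) is shorter than one frame (%.4f s)",
                 n / rec$rate, frame_duration))
  n_frames <- n %/% flen
  frames <- matrix(rec$samples[seq_len(n_frames * flen)], nrow = flen)
  structure(
    list(frames = frames, frame_duration = frame_duration,
         frame_length = flen, rate = rec$rate, n_frames = n_frames,
         frame_times = (seq_len(n_frames) - 0.5) * flen / rec$rate),
    class = "frame_sequence")
}

#' Read a cohort metadata table
#'
#' The on-disk cohort format is a delimited text table with header columns
#' `subject_id`, `site`, `mPAp_mmHg`, `PAWp_mmHg`, `wav_path` (one row per
#' recording). Relative `wav_path` entries are resolved against the
#' directory containing the metadata file.
#'
#' @param path Path to the metadata table (tab- or comma-separated).
#' @return A data.frame with the five columns above plus `group` (see
#'   [pah_group()]).
#' @export
read_cohort_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "site", "mPAp_mmHg", "PAWp_mmHg", "wav_path")
  missing <- setdiff(need, names(md))
  if (length(missing))
    stop("metadata is missing required columns: ",
         paste(missing, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", md$wav_path)
  md$wav_path[rel] <- file.path(dirname(path), md$wav_path[rel])
  md$group <- pah_group(md$mPAp_mmHg, md$PAWp_mmHg)
  md
}
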