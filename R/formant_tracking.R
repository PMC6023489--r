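#' Fit a linear-predictive-coding (LPC) model to one frame
#'
#' Autocorrelation-method LPC: the frame is tapered, its autocorrelation
#' computed up to lag `order`, and the Levinson-Durbin recursion solves the
#' normal equations for the coefficients `a` of the one-step predictor
#' `x[t] ~ sum(a[k] * x[t - k])`. The prediction polynomial is
#' `A(z) = 1 - sum(a[k] z^-k)` (leading coefficient 1).
#'
#' @param frame Numeric vector, one analysis frame (length > `order`).
#' @param order Predictor order (default 8).
#' @param taper Taper applied before autocorrelation: `"hamming"` (default),
#'   `"hann"`, or `"rectangular"`. Un-tapered autocorrelation LPC is
#'   edge-biased, hence the taper default.
#' @return An `lpc_fit`: list with `coefficients` (length `order`, predictor
#'   convention above), `gain` (square root of the final prediction-error
#'   power, >= 0), `order`, and `stable` (TRUE when all characteristic roots
#'   lie strictly inside the unit circle).
#' @export
lpc_fit <- function(frame, order = 8L,
                    taper = c("hamming", "hann", "rectangular")) {
  taper <- match.arg(taper)
  frame <- as.numeric(frame)
  n <- length(frame)
  if (n <= order) stop("frame length must exceed the LPC order")
  if (stats::sd(frame) == 0)
    stop("degenerate (constant) frame: LPC fit is undefined")
  w <- switch(taper,
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)),
    hann    = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)),
    rectangular = rep(1, n))
  x <- frame * w
  r <- vapply(0:order, function(k) sum(x[seq_len(n - k)] * x[(k + 1):n]),
              numeric(1))
  if (r[1] <= 0) stop("degenerate frame: zero energy after tapering")
  lev <- levinson_durbin(r, order)
  a <- lev$a
  roots <- lpc_roots(a)
  structure(
    list(coefficients = a, gain = sqrt(max(lev$err, 0)), order = order,
         stable = all(Mod(roots) < 1)),
    class = "lpc_fit")
}

# Levinson-Durbin recursion on autocorrelations r[0..p] (1-indexed input).
# Returns predictor coefficients a (x_t ~ sum a_k x_{t-k}) and the final
# prediction-error power.
levinson_durbin <- function(r, p) {
  a <- numeric(p)
  err <- r[1]
  for (i in seq_len(p)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[seq_len(i - 1)] * r[i:2])
    k <- acc / err
    if (!is.finite(k)) stop("Levinson-Durbin recursion broke down")
    new_a <- a
    new_a[i] <- k
    if (i > 1) new_a[seq_len(i - 1)] <- a[seq_len(i - 1)] - k * a[(i - 1):1]
    a <- new_a
    err <- err * (1 - k^2)
  }
  list(a = a, err = err)
}

# Roots of the prediction polynomial A(z) = 1 - sum(a_k z^-k), i.e. of
# z^p - a_1 z^(p-1) - ... - a_p.
lpc_roots <- function(a) {
  polyroot(c(-rev(a), 1))
}

#' Convert an LPC fit to formant frequencies and amplitudes
#'
#' Each conjugate pole pair of the all-pole model is a candidate resonance:
#' frequency is the pole angle mapped to Hz, amplitude is the all-pole
#' spectral envelope `gain / |A(e^{i w})|` evaluated at that frequency.
#' Broad-bandwidth poles (radius below `radius_floor`) are discarded as
#' non-resonant, the `max_formants` strongest survivors by envelope
#' amplitude are kept, and results are sorted ascending by frequency. Fewer
#' than `max_formants` resonances are returned as-is; nothing is fabricated.
#'
#' @param fit An [lpc_fit()].
#' @param rate Sampling rate in Hz of the analyzed signal.
#' @param max_formants Maximum number of resonances to report (default 4).
#' @param radius_floor Minimum pole radius to count as a resonance
#'   (default 0.7).
#' @return A data.frame with columns `frequency` (Hz, strictly inside
#'   `(0, rate/2)`) and `amplitude`; zero rows when no resonance qualifies.
#' @export
formants_from_fit <- function(fit, rate, max_formants = 4L,
                              radius_floor = 0.7) {
  stopifnot(inherits(fit, "lpc_fit"))
  roots <- lpc_roots(fit$coefficients)
  ang_tol <- 1e-6
  keep <- Im(roots) > 0 &
    Mod(roots) >= radius_floor &
    Arg(roots) > ang_tol & Arg(roots) < pi - ang_tol
  roots <- roots[keep]
  if (length(roots) == 0L)
    return(data.frame(frequency = numeric(0), amplitude = numeric(0)))
  freq <- Arg(roots) * rate / (2 * pi)
  a <- fit$coefficients
  amp <- vapply(Arg(roots), function(w) {
    A <- 1 - sum(a * exp(-1i * w * seq_along(a)))
    fit$gain / Mod(A)
  }, numeric(1))
  ord <- order(amp, decreasing = TRUE)[seq_len(min(max_formants, length(amp)))]
  out <- data.frame(frequency = freq[ord], amplitude = amp[ord])
  out[order(out$frequency), , drop = FALSE]
}

#' Track formant trajectories across a recording
#'
#' The recording is peak-normalized, resampled to `analysis_rate` if
#' needed, cut into non-overlapping 32-ms frames, and each frame is fitted
#' with an LPC model whose strongest resonances become the per-frame
#' formants. Frames that are degenerate (constant/silent) or yield no
#' resonance keep their row with `NA` markers, so the frame count is always
#' `floor(duration / frame_duration)`.
#'
#' @param rec A [pcg_recording()].
#' @param order LPC order (default 8).
#' @param analysis_rate Analysis sampling rate in Hz (default 8000).
#' @param frame_duration Analysis frame length in seconds (default 0.032).
#' @param max_formants Formant slots per frame (default 4).
#' @param radius_floor Pole-radius floor, see [formants_from_fit()].
#' @param taper Frame taper, see [lpc_fit()].
#' @return A `formant_track`: list with `frame_times` (centers, s), `freqs`
#'   and `amps` (`n_frames` x `max_formants` matrices, `NA` = absent,
#'   frequencies row-sorted ascending), `rate`, `n_frames`,
#'   `frame_duration`, and `n_degenerate` (count of skipped frames).
#' @export
track_formants <- function(rec, order = 8L, analysis_rate = 8000,
                           frame_duration = 0.032, max_formants = 4L,
                           radius_floor = 0.7,
                           taper = c("hamming", "hann", "rectangular")) {
  stopifnot(inherits(rec, "pcg_recording"))
  taper <- match.arg(taper)
  rec <- pcg_normalize(rec)
  if (rec$rate != analysis_rate) rec <- pcg_resample(rec, analysis_rate)
  fs <- frame_signal(rec, frame_duration)
  nf <- fs$n_frames
  flen <- fs$frame_length
  freqs <- matrix(NA_real_, nf, max_formants)
  amps <- matrix(NA_real_, nf, max_formants)

  # Vectorized autocorrelation-method LPC across all frames at once:
  # taper every frame, then compute lags 0..order with shifted column sums.
  w <- switch(taper,
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1)),
    hann    = 0.5 - 0.5 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1)),
    rectangular = rep(1, flen))
  X <- fs$frames * w
  R <- vapply(0:order, function(k)
    colSums(X[seq_len(flen - k), , drop = FALSE] *
            X[(k + 1):flen, , drop = FALSE]), numeric(nf))
  degenerate <- apply(fs$frames, 2, function(fr) fr[1] == fr) |>
    matrix(nrow = flen) |> colSums() == flen
  degenerate <- degenerate | R[, 1] <= 0
  n_degenerate <- sum(degenerate)

  ang_tol <- 1e-6
  hseq <- seq_len(order)
  for (i in which(!degenerate)) {
    lev <- levinson_durbin(R[i, ], order)
    a <- lev$a
    roots <- lpc_roots(a)
    keep <- Im(roots) > 0 & Mod(roots) >= radius_floor &
      Arg(roots) > ang_tol & Arg(roots) < pi - ang_tol
    if (!any(keep)) next
    ang <- Arg(roots[keep])
    gain <- sqrt(max(lev$err, 0))
    amp <- gain / Mod(1 - exp(-1i * outer(ang, hseq)) %*% a)
    sel <- order(amp, decreasing = TRUE)[seq_len(min(max_formants, length(amp)))]
    ord <- sel[order(ang[sel])]
    freqs[i, seq_along(ord)] <- ang[ord] * analysis_rate / (2 * pi)
    amps[i, seq_along(ord)] <- amp[ord]
  }
  structure(
    list(frame_times = fs$frame_times, freqs = freqs, amps = amps,
         rate = analysis_rate, n_frames = nf,
         frame_duration = frame_duration, n_degenerate = n_degenerate),
    class = "formant_track")
}

#' @export
print.formant_track <- function(x, ...) {
  cat(sprintf("<formant_track> %d frames x %d formants @ %g Hz (%d degenerate)\n",
              x$n_frames, ncol(x$freqs), x$rate, x$n_degenerate))
  invisible(x)
}

#' Write a formant track to a delimited text file
#'
#' Columns: `time_s`, `f1_hz`..`f4_hz`, `a1`..`a4`; absent formants are the
#' sentinel `NA`. One file per recording.
#'
#' @param track A [track_formants()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_formant_track <- function(track, path) {
  stopifnot(inherits(track, "formant_track"))
  k <- ncol(track$freqs)
  df <- data.frame(time_s = track$frame_times, track$freqs, track$amps)
  names(df) <- c("time_s", paste0("f", seq_len(k), "_hz"),
                 paste0("a", seq_len(k)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a formant track written by [write_formant_track()]
#' @param path Input path.
#' @param rate Analysis rate the track was computed at (Hz, default 8000).
#' @param frame_duration Frame length in seconds (default 0.032).
#' @return A `formant_track`.
#' @export
read_formant_track <- function(path, rate = 8000, frame_duration = 0.032) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  k <- (ncol(df) - 1L) %/% 2L
  structure(
    list(frame_times = df$time_s,
         freqs = as.matrix(df[, 1L + seq_len(k), drop = FALSE]),
         amps = as.matrix(df[, 1L + k + seq_len(k), drop = FALSE]),
         rate = rate, n_frames = nrow(df), frame_duration = frame_duration,
         n_degenerate = sum(apply(df[, -1, drop = FALSE], 1,
                                  function(r) all(is.na(r))))),
    class = "formant_track")
}
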