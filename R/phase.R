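#' Multichannel electrogram set
#'
#' Container for per-node electrogram time series. One channel per mesh node.
#'
#' @param samples numeric matrix, channels x time.
#' @param fs sampling rate in Hz (> 0).
#' @param node_map integer vector mapping channel -> node index (defaults to
#'   1..channels).
#' @return object of class \code{egm_set}.
#' @export
egm_set <- function(samples, fs, node_map = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("egm_set: fs must be a positive scalar")
  if (any(!is.finite(samples))) stop("egm_set: non-finite samples")
  if (is.null(node_map)) node_map <- seq_len(nrow(samples))
  if (length(node_map) != nrow(samples))
    stop("egm_set: node_map length must equal channel count")
  structure(list(samples = samples, fs = fs, node_map = as.integer(node_map)),
            class = "egm_set")
}

#' @export
print.egm_set <- function(x, ...) {
  cat(sprintf("egm_set: %d channels x %d samples @ %.1f Hz\n",
              nrow(x$samples), ncol(x$samples), x$fs))
  invisible(x)
}

#' Sequence of wrapped phase frames
#'
#' @param phase numeric matrix, frames x nodes, values in (-pi, pi].
#' @param frame_rate frames per second.
#' @param projection optional \code{\link{grid_projection}}.
#' @param mesh optional \code{\link{tri_mesh}}.
#' @return object of class \code{phase_sequence}.
#' @export
phase_sequence <- function(phase, frame_rate, projection = NULL, mesh = NULL) {
  phase <- as.matrix(phase)
  if (nrow(phase) < 1L) stop("phase_sequence: need at least one frame")
  ok <- is.finite(phase)
  if (any(phase[ok] > pi + 1e-9) || any(phase[ok] <= -pi - 1e-9))
    stop("phase_sequence: values must be wrapped to (-pi, pi]")
  structure(list(phase = phase, frame_rate = frame_rate,
                 projection = projection, mesh = mesh),
            class = "phase_sequence")
}

#' @export
print.phase_sequence <- function(x, ...) {
  cat(sprintf("phase_sequence: %d frames x %d nodes @ %.1f Hz\n",
              nrow(x$phase), ncol(x$phase), x$frame_rate))
  invisible(x)
}

#' Cubic-spline resampling of an electrogram set
#'
#' Resamples every channel to a new rate with a cubic spline through the
#' original samples (endpoints preserved). Used to bring clinical recordings
#' down to the 512 Hz analysis rate.
#'
#' @param egm an \code{\link{egm_set}}.
#' @param fs_out target sampling rate in Hz.
#' @return a resampled \code{\link{egm_set}}.
#' @export
resample_cubic <- function(egm, fs_out) {
  if (!is.numeric(fs_out) || length(fs_out) != 1L || fs_out <= 0)
    stop("resample_cubic: fs_out must be positive")
  n <- ncol(egm$samples)
  if (fs_out == egm$fs) return(egm)
  t_in <- (seq_len(n) - 1) / egm$fs
  t_out <- seq(0, t_in[n], by = 1 / fs_out)
  out <- t(apply(egm$samples, 1, function(y)
    stats::spline(t_in, y, xout = t_out, method = "fmm")$y))
  egm_set(out, fs_out, egm$node_map)
}

#' Dominant frequency of a single channel
#'
#' Frequency of the largest spectral-magnitude peak inside a band. The record
#' is linearly detrended, Hann-windowed and zero-padded to a frequency
#' resolution of at least 0.05 Hz before the FFT.
#'
#' @param x numeric vector (at least one second of data).
#' @param fs sampling rate in Hz.
#' @param band numeric length-2, search band in Hz (default 3--15 Hz, the
#'   physiological AF range).
#' @return dominant frequency in Hz.
#' @export
dominant_frequency <- function(x, fs, band = c(3, 15)) {
  n <- length(x)
  if (n < fs) stop("dominant_frequency: need at least 1 s of data")
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("dominant_frequency: band must lie within (0, fs/2)")
  if (all(x == 0)) stop("dominant_frequency: no dominant peak (all-zero signal)")
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), x)
  xd <- fit$residuals
  w <- 0.5 - 0.5 * cos(2 * pi * (t - 1) / (n - 1))   # Hann
  xw <- xd * w
  nfft <- max(n, ceiling(fs / 0.05))
  mag <- Mod(stats::fft(c(xw, rep(0, nfft - n))))
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0L || max(mag[sel]) <= 0)
    stop("dominant_frequency: no dominant peak in band")
  freqs[sel[which.max(mag[sel])]]
}

#' Sinusoidal recomposition of an electrogram
#'
#' Rebuilds the signal as a superposition of single-cycle negative-cosine
#' wavelets of period \code{cycle_length} (the local atrial cycle length, in
#' seconds), one inserted at every sample with amplitude proportional to the
#' negative slope of the input there (samples with non-negative slope
#' contribute nothing). This unmasks wavefront propagation by turning sharp
#' activation downstrokes into smooth oscillations at the local rate.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param cycle_length cycle length in seconds (> 0, shorter than the record).
#' @return numeric vector, same length as \code{x}.
#' @export
sinusoidal_recomposition <- function(x, fs, cycle_length) {
  n <- length(x)
  if (cycle_length <= 0) stop("sinusoidal_recomposition: cycle_length must be > 0")
  Tn <- round(cycle_length * fs)
  if (Tn > n) stop("sinusoidal_recomposition: cycle_length longer than the record")
  if (Tn < 4) stop("sinusoidal_recomposition: cycle_length too short for fs")
  slope <- c(diff(x), 0) * fs
  amp <- pmax(-slope, 0)
  h <- floor(Tn / 2)
  tau <- (-h):h
  kern <- -cos(2 * pi * tau / Tn)
  out <- stats::filter(amp, kern, method = "convolution", sides = 2)
  out[is.na(out)] <- 0
  as.numeric(out) * 2 / Tn
}

#' Instantaneous phase via the analytic signal
#'
#' Builds the analytic signal of a (mean-subtracted) record in the frequency
#' domain and returns its instantaneous amplitude and phase,
#' \code{phase = atan2(h, f)} wrapped to \code{(-pi, pi]}. Edge frames (first
#' and last 5 percent) are unreliable because of the transform's circular
#' boundary; they are flagged in the returned object.
#'
#' @param x numeric vector, length >= 8.
#' @return object of class \code{analytic_signal}: list with \code{f} (real
#'   part, mean-subtracted input), \code{h} (quadrature part),
#'   \code{amplitude}, \code{phase}, and logical \code{edge} flags.
#' @export
instantaneous_phase <- function(x) {
  n <- length(x)
  if (n < 8L) stop("instantaneous_phase: need at least 8 samples")
  x <- x - mean(x)
  if (all(abs(x) < 1e-14)) stop("instantaneous_phase: phase undefined (constant signal)")
  X <- stats::fft(x)
  mult <- numeric(n)
  if (n %% 2 == 0) {
    mult[1] <- 1; mult[n / 2 + 1] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[1] <- 1
    mult[2:((n + 1) / 2)] <- 2
  }
  a <- stats::fft(X * mult, inverse = TRUE) / n
  h <- Im(a)
  phase <- wrap_phase(atan2(h, x))
  edge <- rep(FALSE, n)
  m <- ceiling(0.05 * n)
  edge[c(seq_len(m), (n - m + 1):n)] <- TRUE
  structure(list(f = x, h = h, amplitude = Mod(complex(real = x, imaginary = h)),
                 phase = phase, edge = edge),
            class = "analytic_signal")
}

#' Electrogram set to phase frames
#'
#' The full phase-computation pipeline: per channel, cubic-spline resampling
#' to \code{fs_out}, dominant-frequency estimation, sinusoidal recomposition
#' with cycle length \code{1/DF}, and Hilbert instantaneous phase. Channels
#' are stacked into a frames x nodes \code{\link{phase_sequence}}.
#'
#' Channels that fail (e.g. constant signals) are set to \code{NA} with a
#' warning naming them; the pipeline errors if more than 10 percent of
#' channels fail.
#'
#' @param egm an \code{\link{egm_set}}.
#' @param fs_out analysis rate in Hz (default 512).
#' @param df_band dominant-frequency search band in Hz (default 3--15).
#' @param projection,mesh optional geometry attached to the result.
#' @return a \code{\link{phase_sequence}}. Attribute \code{edge_frames} marks
#'   frames within one cycle length (or 5 percent) of either end, where the
#'   transform edges make phase unreliable.
#' @export
phase_field <- function(egm, fs_out = 512, df_band = c(3, 15),
                        projection = NULL, mesh = NULL) {
  egm <- resample_cubic(egm, fs_out)
  nch <- nrow(egm$samples)
  nt <- ncol(egm$samples)
  ph <- matrix(NA_real_, nt, nch)
  failed <- character(0)
  max_cycle <- 0
  for (ch in seq_len(nch)) {
    res <- tryCatch({
      x <- egm$samples[ch, ]
      df <- dominant_frequency(x, egm$fs, df_band)
      rec <- sinusoidal_recomposition(x, egm$fs, 1 / df)
      list(phase = instantaneous_phase(rec)$phase, cycle = fs_out / df)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("channel %d (node %d): %s",
                                  ch, egm$node_map[ch], conditionMessage(res)))
    } else {
      ph[, ch] <- res$phase
      max_cycle <- max(max_cycle, res$cycle)
    }
  }
  if (length(failed) > 0.1 * nch)
    stop("phase_field: more than 10% of channels failed:\n  ",
         paste(failed, collapse = "\n  "))
  if (length(failed) > 0)
    warning("phase_field: ", length(failed), " channel(s) failed:\n  ",
            paste(failed, collapse = "\n  "))
  # order columns by node
  ord <- order(egm$node_map)
  ps <- phase_sequence(ph[, ord, drop = FALSE], fs_out,
                       projection = projection, mesh = mesh)
  m <- max(ceiling(0.05 * nt), ceiling(max_cycle))
  edge <- rep(FALSE, nt)
  edge[c(seq_len(min(m, nt)), max(nt - m + 1, 1):nt)] <- TRUE
  attr(ps, "edge_frames") <- edge
  ps
}
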