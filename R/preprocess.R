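#' Preprocessing configuration
#'
#' Parameters of the epoch-cleaning pipeline: band-pass edges, the absolute
#' amplitude threshold for trial rejection, the pre-stimulus baseline window,
#' and the retention window to extract. All windows are half-open
#' `[start, stop)` in seconds relative to memory-array onset; the retention
#' default (0.2, 3.2) s runs from memory-array offset (the array is shown for
#' 200 ms) to probe onset.
#'
#' @param band band-pass edges in Hz, default `c(0.5, 45)`.
#' @param reject_uv absolute amplitude rejection threshold in microvolts,
#'   default 100.
#' @param baseline_window baseline window in seconds, default `c(-0.1, 0)`.
#' @param retention_window retention window in seconds, default `c(0.2, 3.2)`.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(band = c(0.5, 45), reject_uv = 100,
                              baseline_window = c(-0.1, 0),
                              retention_window = c(0.2, 3.2)) {
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L])
    stop("invalid `band`: need 0 < low < high", call. = FALSE)
  if (reject_uv <= 0)
    stop("invalid `reject_uv`: must be > 0", call. = FALSE)
  structure(list(band = band, reject_uv = reject_uv,
                 baseline_window = baseline_window,
                 retention_window = retention_window),
            class = "preprocess_config")
}

#' Re-reference an epoch array to the common average
#'
#' Subtracts, at every trial and sample, the instantaneous mean across
#' channels. This package uses the average reference throughout (a reference
#' choice that needs no head model); after it the cross-channel mean is zero
#' everywhere.
#'
#' @param e an [epoch_array()] with at least two channels.
#' @return the re-referenced `epoch_array` (same shape).
#' @export
rereference_average <- function(e) {
  stopifnot(inherits(e, "epoch_array"))
  d <- dim(e$data)
  if (d[2L] < 2L)
    stop("average re-referencing needs at least 2 channels", call. = FALSE)
  perm <- aperm(e$data, c(2L, 1L, 3L))             # channels x trials x samples
  m <- colMeans(perm)                              # trials x samples
  perm <- perm - rep(m, each = d[2L])
  e$data <- aperm(perm, c(2L, 1L, 3L))
  e
}

#' Zero-phase band-pass filter
#'
#' Band-passes every trial and channel with a 4th-order Butterworth filter
#' applied with zero phase: each epoch is zero-padded and multiplied in the
#' frequency domain by the filter's squared magnitude response
#' `|H(f)|^2` -- the transfer function of one forward and one backward pass
#' of the filter -- so there is no group delay. The contract is the
#' attenuation behavior: a sinusoid inside the passband keeps at least 90% of
#' its amplitude, one at twice the upper edge keeps at most 10% (away from
#' edge transients).
#'
#' @param e an [epoch_array()].
#' @param band `(low, high)` in Hz; both edges must be below the Nyquist
#'   frequency `fs/2`.
#' @return the filtered `epoch_array`.
#' @export
bandpass <- function(e, band = c(0.5, 45)) {
  stopifnot(inherits(e, "epoch_array"))
  nyq <- e$fs / 2
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L] || band[2L] >= nyq)
    stop(sprintf("invalid band (%g, %g) Hz for fs = %g Hz: need 0 < low < high < fs/2",
                 band[1L], band[2L], e$fs), call. = FALSE)
  bf <- signal::butter(4, band / nyq, type = "pass")
  d <- dim(e$data)
  ns <- d[3L]
  X <- matrix(aperm(e$data, c(3L, 1L, 2L)), ns, d[1L] * d[2L])
  # zero-pad by 2 s so the filter's impulse response decays within the pad
  npad <- ns + 2L * round(e$fs)
  gain <- .butter_sq_gain(bf, npad)
  Y <- .apply_real_gain(rbind(X, matrix(0, npad - ns, ncol(X))), gain)
  e$data <- aperm(array(Y[seq_len(ns), , drop = FALSE], c(ns, d[1L], d[2L])),
                  c(2L, 3L, 1L))
  e
}

# |H(e^{i w})|^2 of a digital filter on the length-n FFT grid (even-symmetric
# real gain, i.e. exactly zero phase)
.butter_sq_gain <- function(bf, n) {
  w <- 2 * pi * (seq_len(n) - 1L) / n
  ejw <- exp(-1i * outer(w, seq_along(bf$b) - 1L))
  H <- as.vector(ejw %*% bf$b) / as.vector(ejw %*% bf$a)
  Re(H * Conj(H))
}

# multiply the spectrum of every (real) column by an even-symmetric real
# gain; pairs of columns share one complex FFT
.apply_real_gain <- function(X, gain) {
  n <- nrow(X); m <- ncol(X)
  odd_m <- m %% 2L == 1L
  if (odd_m) X <- cbind(X, 0)
  odd <- seq.int(1L, ncol(X), by = 2L)
  Fc <- stats::mvfft(X[, odd, drop = FALSE] + 1i * X[, odd + 1L, drop = FALSE])
  Yc <- stats::mvfft(gain * Fc, inverse = TRUE) / n
  Y <- matrix(0, n, ncol(X))
  Y[, odd] <- Re(Yc)
  Y[, odd + 1L] <- Im(Yc)
  if (odd_m) Y <- Y[, -ncol(Y), drop = FALSE]
  Y
}

#' Baseline-correct each trial and channel
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default the 100 ms preceding memory-array onset).
#'
#' @param e an [epoch_array()].
#' @param window baseline window `(start, stop)` in seconds relative to
#'   memory-array onset; must lie inside the epoch.
#' @return the corrected `epoch_array`.
#' @export
baseline_correct <- function(e, window = c(-0.1, 0)) {
  stopifnot(inherits(e, "epoch_array"))
  idx <- .window_index(e, window, "baseline_window")
  d <- dim(e$data)
  seg <- matrix(e$data[, , idx, drop = FALSE], d[1L] * d[2L], length(idx))
  m <- rowMeans(seg)                               # trial x channel means
  e$data <- e$data - c(m)                          # recycles along samples
  e
}

#' Reject trials exceeding an absolute amplitude threshold
#'
#' A trial is rejected if its peak absolute amplitude across all channels and
#' samples exceeds `threshold_uv`. Behavioral alignment is preserved through
#' `trial_ids`.
#'
#' @param e an [epoch_array()].
#' @param threshold_uv rejection threshold in microvolts (> 0), default 100.
#' @return list with `epochs` (the retained-trial `epoch_array`) and
#'   `rejected` (trial ids of removed trials).
#' @export
reject_artifacts <- function(e, threshold_uv = 100) {
  stopifnot(inherits(e, "epoch_array"))
  if (threshold_uv <= 0) stop("`threshold_uv` must be > 0", call. = FALSE)
  d <- dim(e$data)
  flat <- matrix(abs(e$data), d[1L], d[2L] * d[3L])
  peak <- apply(flat, 1L, max)
  keep <- peak <= threshold_uv
  if (!any(keep))
    stop(sprintf("all trials rejected for subject %s session %s at %g microvolts",
                 e$subject, e$session, threshold_uv), call. = FALSE)
  rejected <- e$trial_ids[!keep]
  e$data <- e$data[keep, , , drop = FALSE]
  e$trial_ids <- e$trial_ids[keep]
  list(epochs = e, rejected = rejected)
}

#' Extract the retention-period segment
#'
#' Cuts the maintenance interval (default (0.2, 3.2) s, i.e. memory-array
#' offset to probe onset) out of each epoch. The result has exactly
#' `round(fs * duration)` samples and an updated `t0`; all other metadata is
#' unchanged.
#'
#' @param e an [epoch_array()].
#' @param window retention window `(start, stop)` in seconds; must lie inside
#'   the epoch.
#' @return the cut `epoch_array`.
#' @export
extract_retention <- function(e, window = c(0.2, 3.2)) {
  stopifnot(inherits(e, "epoch_array"))
  idx <- .window_index(e, window, "retention_window")
  e$data <- e$data[, , idx, drop = FALSE]
  e$t0 <- window[1L]
  e
}

#' Full preprocessing pipeline for one epoch block
#'
#' Runs average re-referencing, zero-phase band-pass filtering, baseline
#' correction, amplitude-threshold artifact rejection, and retention-window
#' extraction, in that fixed order.
#'
#' @param e an [epoch_array()].
#' @param cfg a [preprocess_config()].
#' @return list with `epochs` (clean retention-period `epoch_array`) and
#'   `rejected` (trial ids removed by artifact rejection).
#' @export
preprocess <- function(e, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  e <- rereference_average(e)
  e <- bandpass(e, cfg$band)
  e <- baseline_correct(e, cfg$baseline_window)
  r <- reject_artifacts(e, cfg$reject_uv)
  list(epochs = extract_retention(r$epochs, cfg$retention_window),
       rejected = r$rejected)
}
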