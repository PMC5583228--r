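#' Welch power spectral density of a single-channel segment
#'
#' Averages one-sided periodograms of windowed, overlapping segments
#' (Welch's method) and restricts the result to the analysis band. Power is
#' density-scaled: for stationary noise the integral of the PSD over the full
#' band approximates the signal variance.
#'
#' @param x numeric vector, one trial of one channel.
#' @param fs sampling rate in Hz.
#' @param segment_s Welch segment length in seconds (default 1, giving 1 Hz
#'   resolution).
#' @param overlap_frac fractional overlap between consecutive segments
#'   (default 0.5).
#' @param window_name taper: `"hamming"` (default), `"hann"` or `"rect"`.
#' @param band frequency band to keep, inclusive (default `c(0.5, 45)` Hz).
#' @return object of class `power_spectrum`: list with `frequencies`
#'   (Hz, ascending), `psd` (non-negative densities) and `band`.
#' @examples
#' fs <- 250
#' t <- seq(0, 3, length.out = 3 * fs + 1)[-1]
#' p <- welch_psd(sin(2 * pi * 10 * t), fs)
#' p$frequencies[which.max(p$psd)]  # 10
#' @export
welch_psd <- function(x, fs, segment_s = 1, overlap_frac = 0.5,
                      window_name = "hamming", band = c(0.5, 45)) {
  nseg <- round(fs * segment_s)
  if (length(x) < nseg)
    stop(sprintf("segment of %d samples is shorter than one Welch window (%d samples)",
                 length(x), nseg), call. = FALSE)
  res <- .welch_matrix(matrix(x, ncol = 1L), fs, segment_s, overlap_frac,
                       window_name, band)
  structure(list(frequencies = res$frequencies, psd = as.vector(res$psd),
                 band = band),
            class = "power_spectrum")
}

.window_taper <- function(name, n) {
  k <- seq_len(n) - 1L
  switch(name,
    hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1L)),
    hann    = 0.5 - 0.5 * cos(2 * pi * k / (n - 1L)),
    rect    = rep(1, n),
    stop(sprintf("unknown window '%s'", name), call. = FALSE))
}

# Vectorized Welch core: X is samples x series; returns band frequencies and
# a bins x series PSD matrix. The periodograms of all segments of all series
# are computed in one pass as a dense DFT restricted to the band bins (a
# BLAS matrix product -- only ~45 of the bins are needed, which beats a full
# FFT and keeps everything real).
.welch_matrix <- function(X, fs, segment_s = 1, overlap_frac = 0.5,
                          window_name = "hamming", band = c(0.5, 45)) {
  ns <- nrow(X); m <- ncol(X)
  nseg <- round(fs * segment_s)
  step <- max(1L, round(nseg * (1 - overlap_frac)))
  starts <- seq.int(1L, ns - nseg + 1L, by = step)
  nstart <- length(starts)
  win <- .window_taper(window_name, nseg)
  U <- sum(win^2)
  # columns ordered series-major: (series 1: seg 1..nstart, series 2: ...)
  idx_rows <- as.vector(outer(seq_len(nseg) - 1L, starts, `+`))
  big <- matrix(X[idx_rows, , drop = FALSE], nseg) * win
  half <- floor(nseg / 2) + 1L
  freq_all <- (seq_len(half) - 1L) * fs / nseg
  keep <- which(freq_all >= band[1L] & freq_all <= band[2L])
  ang <- outer(2 * pi * freq_all[keep] / fs, seq_len(nseg) - 1L)
  P <- ((cos(ang) %*% big)^2 + (sin(ang) %*% big)^2) / (fs * U)
  # one-sided: double everything but DC (and Nyquist when nseg is even)
  dbl <- keep != 1L & !(nseg %% 2L == 0L & keep == half)
  P[dbl, ] <- 2 * P[dbl, ]
  # average over the nstart consecutive segment columns of each series
  acc <- P[, seq.int(1L, by = nstart, length.out = m), drop = FALSE]
  if (nstart > 1L)
    for (j in 2L:nstart)
      acc <- acc + P[, seq.int(j, by = nstart, length.out = m), drop = FALSE]
  acc <- acc / nstart
  list(frequencies = freq_all[keep], psd = acc)
}

#' Normalize a power spectrum to unit total power
#'
#' Divides each bin by the summed power over the analysis band, turning the
#' spectrum into a probability distribution across frequency bins.
#'
#' @param p a `power_spectrum`.
#' @return the normalized `power_spectrum` (bins sum to 1).
#' @export
normalize_psd <- function(p) {
  stopifnot(inherits(p, "power_spectrum"))
  tot <- sum(p$psd)
  if (tot <= 0)
    stop("degenerate spectrum: total power is zero", call. = FALSE)
  p$psd <- p$psd / tot
  p
}

# Shannon entropy in dit of a probability vector, 0*log(0) := 0
.entropy_dit <- function(p) {
  p <- p[p > 0]
  -sum(p * log10(p))
}

#' Spectral entropy of a normalized spectrum, in dit
#'
#' Shannon entropy of the normalized power distribution across frequency
#' bins, with a base-10 logarithm so the unit is the dit (decimal digit):
#' `SEn = -sum(p * log10(p))`, with `0 * log(0) := 0`. It measures the
#' uniformity of the spectrum -- 0 for power concentrated in a single bin,
#' `log10(N)` for a perfectly flat spectrum over `N` bins.
#'
#' @param p a normalized `power_spectrum` (see [normalize_psd()]) or a bare
#'   numeric probability vector summing to 1 (tolerance `1e-6`).
#' @return spectral entropy in dit.
#' @examples
#' spectral_entropy(rep(0.1, 10))  # 1 dit
#' @export
spectral_entropy <- function(p) {
  v <- if (inherits(p, "power_spectrum")) p$psd else p
  if (!is.numeric(v) || any(v < 0))
    stop("spectral entropy needs a non-negative probability vector", call. = FALSE)
  if (abs(sum(v) - 1) > 1e-6)
    stop("spectrum is not normalized: bins must sum to 1 (see normalize_psd)", call. = FALSE)
  .entropy_dit(v)
}

#' Per-channel spectral entropy features for one subject/session
#'
#' Computes the spectral entropy of every channel of a retention-period epoch
#' block. Two aggregations across trials are available: `"trial_mean"`
#' (default) computes one entropy per trial and averages them;
#' `"mean_psd"` averages the normalized per-trial spectra first and takes the
#' entropy of the mean spectrum. For identical trials the two agree exactly.
#'
#' @param e an [epoch_array()] of retention segments.
#' @param segment_s,overlap_frac,window_name,band Welch parameters, see
#'   [welch_psd()].
#' @param aggregation `"trial_mean"` or `"mean_psd"`.
#' @return data frame `subject, session, channel, sen, n_trials` with one row
#'   per channel; `sen` in dit.
#' @export
subject_entropy <- function(e, segment_s = 1, overlap_frac = 0.5,
                            window_name = "hamming", band = c(0.5, 45),
                            aggregation = c("trial_mean", "mean_psd")) {
  stopifnot(inherits(e, "epoch_array"))
  aggregation <- match.arg(aggregation)
  d <- dim(e$data)
  if (d[1L] == 0L)
    stop(sprintf("no retained trials for subject %s session %s",
                 e$subject, e$session), call. = FALSE)
  # samples x (trials*channels), trials fastest
  X <- matrix(aperm(e$data, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L])
  res <- .welch_matrix(X, e$fs, segment_s, overlap_frac, window_name, band)
  P <- res$psd
  tot <- colSums(P)
  if (any(tot <= 0))
    stop("degenerate spectrum: a trial has zero band power", call. = FALSE)
  P <- sweep(P, 2L, tot, `/`)
  sen <- if (aggregation == "trial_mean") {
    per_trial <- -colSums(ifelse(P > 0, P * log10(P), 0))
    colMeans(matrix(per_trial, d[1L], d[2L]))
  } else {
    apply(array(P, c(nrow(P), d[1L], d[2L])), 3L, function(M)
      .entropy_dit(rowMeans(M)))
  }
  data.frame(subject = e$subject, session = e$session, channel = e$channels,
             sen = sen, n_trials = d[1L])
}

#' Entropy features for a whole cohort
#'
#' Convenience wrapper applying [subject_entropy()] to every subject/session
#' block of a list of epoch arrays and binding the results.
#'
#' @param epochs list of [epoch_array()] objects.
#' @param ... passed to [subject_entropy()].
#' @return stacked feature data frame.
#' @export
cohort_entropy <- function(epochs, ...) {
  do.call(rbind, c(lapply(epochs, subject_entropy, ...), make.row.names = FALSE))
}
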