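#' Epoched EEG container
#'
#' An `epoch_array` holds one subject/session block of epoched EEG as a
#' `trials x channels x samples` numeric array (microvolts) together with the
#' metadata the pipeline needs: sampling rate, ordered channel labels, the
#' epoch start time relative to memory-array onset, and trial identifiers that
#' keep the rows aligned with the trial-level behavior table.
#'
#' @param subject subject identifier (scalar).
#' @param session session identifier, typically 1 (before training) or 2
#'   (after training).
#' @param data numeric array, `trials x channels x samples`, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channels character vector of unique channel labels; its length must
#'   equal the channel dimension of `data`.
#' @param t0 epoch start time in seconds relative to memory-array onset
#'   (negative values mean the epoch starts before the stimulus).
#' @param trial_ids optional vector of unique trial identifiers aligning rows
#'   of `data` to the behavior table; defaults to `1:n_trials`.
#'
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(subject, session, data, fs, channels, t0,
                        trial_ids = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)", call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` contains non-finite samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar sampling rate", call. = FALSE)
  channels <- as.character(channels)
  if (length(channels) != dim(data)[2L])
    stop("length(channels) must equal the channel dimension of `data`", call. = FALSE)
  if (anyDuplicated(channels))
    stop("`channels` must be unique", call. = FALSE)
  if (is.null(trial_ids)) trial_ids <- seq_len(dim(data)[1L])
  if (length(trial_ids) != dim(data)[1L] || anyDuplicated(trial_ids))
    stop("`trial_ids` must be unique and align with the trial dimension", call. = FALSE)
  structure(
    list(subject = subject, session = session, data = data, fs = fs,
         channels = channels, t0 = t0, trial_ids = trial_ids),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_array> subject %s session %s: %d trials x %d channels x %d samples @ %g Hz, t0 = %g s\n",
    x$subject, x$session, d[1L], d[2L], d[3L], x$fs, x$t0))
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

# epoch duration helpers (seconds)
.epoch_end <- function(e) e$t0 + dim(e$data)[3L] / e$fs

# sample index range for a half-open time window [start, stop) relative to
# memory-array onset; errors if the window leaves the epoch
.window_index <- function(e, window, what = "window") {
  if (length(window) != 2L || window[2L] <= window[1L])
    stop(sprintf("`%s` must be an increasing (start, stop) pair", what), call. = FALSE)
  i0 <- round((window[1L] - e$t0) * e$fs) + 1L
  len <- round((window[2L] - window[1L]) * e$fs)
  if (i0 < 1L || i0 + len - 1L > dim(e$data)[3L])
    stop(sprintf("%s (%g, %g) s lies outside the epoch (%g, %g) s",
                 what, window[1L], window[2L], e$t0, .epoch_end(e)), call. = FALSE)
  seq.int(i0, i0 + len - 1L)
}
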