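#' Write a cohort to an on-disk fixture file set
#'
#' Serializes a cohort to a directory holding one EEG container
#' (`eeg.rds`: a group per subject/session with datasets `data`, `fs`,
#' `channels`, `t0`, `trial_ids`) plus plain-text tables `behavior.csv` and
#' `ground_truth.csv`. Floating-point EEG arrays round-trip bit-exactly; CSV
#' doubles are written with 17 significant digits so they re-read exactly.
#'
#' @param cohort a `wm_cohort` as returned by [generate_cohort()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_fixture()]
#' @export
write_fixture <- function(cohort, path) {
  stopifnot(inherits(cohort, "wm_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  groups <- lapply(cohort$epochs, function(e)
    list(data = e$data, fs = e$fs, channels = e$channels, t0 = e$t0,
         trial_ids = e$trial_ids, subject = e$subject, session = e$session))
  container <- list(format = "wmentropy-eeg-v1", groups = groups,
                    config = cohort$config, artifact_log = cohort$artifact_log)
  saveRDS(container, file.path(path, "eeg.rds"))
  .write_csv_exact(cohort$behavior, file.path(path, "behavior.csv"))
  .write_csv_exact(cohort$truth, file.path(path, "ground_truth.csv"))
  invisible(path)
}

# CSV writer that preserves doubles exactly (17 significant digits)
.write_csv_exact <- function(df, file) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
}

#' Read a cohort fixture written by [write_fixture()]
#'
#' @param path fixture directory.
#' @return a `wm_cohort`, field-for-field equal to the one written.
#' @export
read_fixture <- function(path) {
  eeg_path <- file.path(path, "eeg.rds")
  if (!file.exists(eeg_path))
    stop(sprintf("malformed fixture: missing EEG container '%s'", eeg_path), call. = FALSE)
  container <- readRDS(eeg_path)
  if (!identical(container$format, "wmentropy-eeg-v1"))
    stop("malformed fixture: unrecognized EEG container format", call. = FALSE)
  need <- c("data", "fs", "channels", "t0", "trial_ids", "subject", "session")
  epochs <- lapply(seq_along(container$groups), function(i) {
    g <- container$groups[[i]]
    missing <- setdiff(need, names(g))
    if (length(missing))
      stop(sprintf("malformed fixture: group '%s' missing dataset `%s`",
                   names(container$groups)[i], missing[1L]), call. = FALSE)
    epoch_array(g$subject, g$session, g$data, g$fs, g$channels, g$t0, g$trial_ids)
  })
  names(epochs) <- names(container$groups)
  behavior <- utils::read.csv(file.path(path, "behavior.csv"))
  truth <- utils::read.csv(file.path(path, "ground_truth.csv"))
  structure(
    list(epochs = epochs, behavior = behavior, truth = truth,
         artifact_log = container$artifact_log, config = container$config),
    class = "wm_cohort")
}
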