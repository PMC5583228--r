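#' Signed Residual Time (SRT) score of a trial block
#'
#' Speed-accuracy trade-off score: each trial contributes
#' `(2 * accuracy - 1) * (mt - rt)` -- a correct response earns the residual
#' time, an incorrect one loses it. Trials without a response (missing `rt`)
#' are treated as incorrect with `rt = mt`, hence contribute zero.
#'
#' @param trials data frame with columns `accuracy` (0/1), `rt` (seconds,
#'   `NA` for omissions) and `mt` (maximum allowed time, seconds).
#' @return total SRT score in seconds.
#' @examples
#' srt_score(data.frame(accuracy = 1, rt = 0.5, mt = 2))  # +1.5
#' @export
srt_score <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("empty trial list: SRT needs at least one trial", call. = FALSE)
  stopifnot(all(c("accuracy", "rt", "mt") %in% names(trials)))
  acc <- trials$accuracy
  rt <- trials$rt
  omitted <- is.na(rt)
  rt[omitted] <- trials$mt[omitted]
  acc[omitted] <- 0
  sum((2 * acc - 1) * (trials$mt - rt))
}

#' Per-subject/session SRT scores from a trial table
#'
#' @param behavior trial-level behavior table (`subject, session, trial,
#'   load, hand, accuracy, rt, mt`).
#' @return data frame `subject, session, srt`.
#' @export
srt_table <- function(behavior) {
  stopifnot(all(c("subject", "session") %in% names(behavior)))
  parts <- split(behavior, behavior[c("subject", "session")], drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(b)
    data.frame(subject = b$subject[1L], session = b$session[1L],
               srt = srt_score(b))))
  out <- out[order(out$session, out$subject), ]
  rownames(out) <- NULL
  out
}

#' Standardize SRT scores within a session and assign performance groups
#'
#' Computes z-scores `(x - mean) / sd` with the sample (n-1) standard
#' deviation and labels subjects with `z > 0` as the high-performance group,
#' the rest (including `z == 0` exactly) as low.
#'
#' @param scores data frame for one session with columns `subject` and `srt`.
#' @return the input with added columns `z` and `group`
#'   (factor `low`/`high`).
#' @export
zscore_group <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("subject", "srt") %in% names(scores)))
  if (nrow(scores) < 2L)
    stop("z-scoring needs at least 2 subjects", call. = FALSE)
  if (length(unique(scores$session)) > 1L)
    stop("zscore_group standardizes one session at a time", call. = FALSE)
  s <- stats::sd(scores$srt)
  if (s == 0)
    stop("degenerate cohort: zero SRT variance, groups undefined", call. = FALSE)
  scores$z <- (scores$srt - mean(scores$srt)) / s
  scores$group <- factor(ifelse(scores$z > 0, "high", "low"),
                         levels = c("low", "high"))
  scores
}

#' SRT scores, z-scores and groups for all sessions
#'
#' @param behavior trial-level behavior table.
#' @return data frame `subject, session, srt, z, group`, z-scored within each
#'   session.
#' @export
score_sessions <- function(behavior) {
  scores <- srt_table(behavior)
  out <- do.call(rbind, lapply(split(scores, scores$session), zscore_group))
  rownames(out) <- NULL
  out
}

#' Training-induced change rate
#'
#' Symmetric percent change between a pre-training value `t_before` and a
#' post-training value `t_after`:
#' `CR = 2 * (t_after - t_before) / (t_after + t_before) * 100`.
#' Undefined when the two values cancel.
#'
#' @param t_before,t_after numeric scores (vectorized).
#' @return change rate in percent.
#' @examples
#' change_rate(1, 3)  # 100
#' @export
change_rate <- function(t_before, t_after) {
  denom <- t_before + t_after
  if (any(denom == 0))
    stop("undefined change rate: t_before + t_after = 0", call. = FALSE)
  2 * (t_after - t_before) / denom * 100
}

#' Per-subject change-rate consistency between SRT and spectral entropy
#'
#' For every subject, computes the change rate of the SRT score and of the
#' selected channel's spectral entropy from session 1 to session 2, and
#' counts subjects whose two change rates share a sign ("consistent"). A
#' change rate of exactly zero is counted as inconsistent and flagged with a
#' warning.
#'
#' @param scores data frame `subject, session, srt` covering both sessions.
#' @param features entropy feature table (`subject, session, channel, sen`).
#' @param channel channel label whose entropy is tracked.
#' @return list of class `change_report`: `per_subject` data frame
#'   (`subject, cr_srt, cr_sen, consistent`) and `counts`
#'   (`increased, decreased, consistent, inconsistent`, summing to n).
#' @export
consistency_report <- function(scores, features, channel) {
  feats <- features[features$channel == channel, ]
  subjects <- sort(unique(scores$subject))
  rows <- lapply(subjects, function(s) {
    srt1 <- scores$srt[scores$subject == s & scores$session == 1]
    srt2 <- scores$srt[scores$subject == s & scores$session == 2]
    sen1 <- feats$sen[feats$subject == s & feats$session == 1]
    sen2 <- feats$sen[feats$subject == s & feats$session == 2]
    if (length(srt1) != 1L || length(srt2) != 1L)
      stop(sprintf("subject %s is missing an SRT session", s), call. = FALSE)
    if (length(sen1) != 1L || length(sen2) != 1L)
      stop(sprintf("subject %s is missing entropy on channel %s for a session",
                   s, channel), call. = FALSE)
    data.frame(subject = s,
               cr_srt = change_rate(srt1, srt2),
               cr_sen = change_rate(sen1, sen2))
  })
  per <- do.call(rbind, rows)
  per$consistent <- per$cr_srt * per$cr_sen > 0
  if (any(per$cr_srt == 0 | per$cr_sen == 0))
    warning("change rate exactly zero for some subject: counted inconsistent")
  counts <- c(increased = sum(per$cr_srt > 0),
              decreased = sum(per$cr_srt <= 0),
              consistent = sum(per$consistent),
              inconsistent = sum(!per$consistent))
  structure(list(per_subject = per, counts = counts, channel = channel),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  n <- nrow(x$per_subject)
  cat(sprintf("<change_report> channel %s: %d/%d SRT increased, %d/%d consistent with entropy\n",
              x$channel, x$counts[["increased"]], n, x$counts[["consistent"]], n))
  invisible(x)
}
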