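#' Spearman rank correlation with a t-approximation p-value
#'
#' For tie-free data uses the classical closed form
#' `r = 1 - 6 * sum(d^2) / (m * (m^2 - 1))` on the rank differences `d`; with
#' ties it falls back to the product-moment correlation of mid-ranks, which
#' reduces to the closed form when no ties are present. The two-sided p-value
#' uses the t approximation `t = r * sqrt((m - 2) / (1 - r^2))` on `m - 2`
#' degrees of freedom.
#'
#' @param x,y paired numeric vectors, at least 3 observations.
#' @return list with elements `r` and `p`.
#' @examples
#' spearman_r(1:3, 3:1)$r  # -1
#' @export
spearman_r <- function(x, y) {
  m <- length(x)
  if (m != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (m < 3L)
    stop("undefined correlation: need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  ties <- anyDuplicated(rx) || anyDuplicated(ry)
  r <- if (!ties) {
    1 - 6 * sum((rx - ry)^2) / (m * (m^2 - 1))
  } else {
    stats::cor(rx, ry)
  }
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((m - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), m - 2)
  }
  list(r = r, p = p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR control: returns adjusted p-values (q-values) and rejection
#' flags at level `alpha` (`reject` iff `q <= alpha`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (adjusted p-values) and `reject` (logical).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = q <= alpha)
}

#' Channel-wise entropy-to-SRT correlation map ("fingerprint")
#'
#' Correlates each channel's spectral entropy with the SRT score across
#' subjects (Spearman), adjusts the per-channel p-values with
#' Benjamini-Hochberg across channels, and selects the channel with the
#' largest absolute correlation. Scope `"session1"`/`"session2"` correlates
#' within one session (one observation per subject); `"merged"` pools both
#' sessions (one observation per subject-session pair).
#'
#' @param features entropy feature table (`subject, session, channel, sen`).
#' @param scores SRT score table (`subject, session, srt`).
#' @param scope `"merged"` (default), `"session1"` or `"session2"`.
#' @param alpha FDR level used for the rejection flags (default 0.05).
#' @return data frame of class `correlation_map` with columns
#'   `channel, r, p, q, reject, scope`, and attributes `best_channel` (label
#'   attaining `max |r|`; ties resolved to the lexicographically smallest
#'   label with a message) and `scope`.
#' @export
fingerprint <- function(features, scores, scope = c("merged", "session1", "session2"),
                        alpha = 0.05) {
  scope <- match.arg(scope)
  if (scope != "merged") {
    keep <- as.integer(sub("session", "", scope))
    features <- features[features$session == keep, ]
    scores <- scores[scores$session == keep, ]
  }
  key_f <- unique(paste(features$subject, features$session))
  key_s <- paste(scores$subject, scores$session)
  bad <- setdiff(key_f, key_s)
  if (length(bad))
    stop(sprintf("pairing error: no SRT score for subject/session pair(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  channels <- unique(features$channel)
  rows <- lapply(channels, function(ch) {
    f <- features[features$channel == ch, ]
    srt <- scores$srt[match(paste(f$subject, f$session), key_s)]
    est <- spearman_r(f$sen, srt)
    data.frame(channel = ch, r = est$r, p = est$p)
  })
  map <- do.call(rbind, rows)
  adj <- fdr_bh(map$p, alpha)
  map$q <- adj$q
  map$reject <- adj$reject
  map$scope <- scope
  best <- map$channel[abs(map$r) == max(abs(map$r))]
  if (length(best) > 1L) {
    best <- sort(best)[1L]
    message(sprintf("tie on max |r|; selecting lexicographically smallest channel '%s'", best))
  }
  structure(map, class = c("correlation_map", "data.frame"),
            best_channel = best, scope = scope)
}

#' Best channel of a correlation map
#' @param map a `correlation_map`.
#' @return channel label attaining the maximum absolute correlation.
#' @export
best_channel <- function(map) attr(map, "best_channel")
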