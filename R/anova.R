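#' Two-way repeated-measures ANOVA (hand x load) with Greenhouse-Geisser
#' correction
#'
#' Classical within-subject F tests for a balanced two-factor repeated
#' measures design with one observation per subject and cell: main effects of
#' response hand (2 levels) and memory load (3 levels) and their interaction.
#' Sphericity of each multi-level effect is tested with Mauchly's criterion;
#' when it is rejected at 0.05, the Greenhouse-Geisser epsilon shrinks the
#' degrees of freedom used for the p-value. Two-level effects are always
#' spherical (`gg_epsilon = 1`). Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data data frame with columns `subject`, `hand`, `load`, `value`;
#'   every subject must contribute exactly one value per hand x load cell.
#' @return data frame with one row per effect (`hand`, `load`, `hand:load`)
#'   and columns `F`, `df_num`, `df_den`, `gg_epsilon`, `mauchly_p`,
#'   `gg_applied`, `p`, `partial_eta_sq`. Effects whose sum of squares is
#'   exactly zero report `F = 0`.
#' @export
rm_anova_2x3 <- function(data) {
  stopifnot(all(c("subject", "hand", "load", "value") %in% names(data)))
  data$subject <- factor(data$subject)
  data$hand <- factor(data$hand)
  data$load <- factor(data$load)
  n <- nlevels(data$subject)
  a <- nlevels(data$hand)
  b <- nlevels(data$load)
  counts <- table(data$subject, data$hand, data$load)
  if (any(counts != 1L))
    stop("incomplete design: every subject needs exactly one value per hand x load cell",
         call. = FALSE)

  # n x (a*b) cell matrix, hand-major / load-minor column order
  data <- data[order(data$subject, data$hand, data$load), ]
  Y <- matrix(data$value, nrow = n, ncol = a * b, byrow = TRUE)

  gm <- mean(Y)
  m_s <- rowMeans(Y)
  cellm <- colMeans(Y)
  M_ab <- matrix(cellm, a, b, byrow = TRUE)          # hand x load cell means
  m_a <- rowMeans(M_ab)
  m_b <- colMeans(M_ab)

  ss_A <- n * b * sum((m_a - gm)^2)
  ss_B <- n * a * sum((m_b - gm)^2)
  ss_AB <- n * sum((sweep(sweep(M_ab, 1L, m_a), 2L, m_b) + gm)^2)

  # subject x factor interaction (error) terms
  Y_a <- vapply(seq_len(a), function(i)
    rowMeans(Y[, ((i - 1L) * b + 1L):(i * b), drop = FALSE]), numeric(n))
  Y_b <- vapply(seq_len(b), function(j)
    rowMeans(Y[, seq.int(j, a * b, by = b), drop = FALSE]), numeric(n))
  ss_AS <- b * sum((Y_a - outer(m_s, rep(1, a)) - outer(rep(1, n), m_a) + gm)^2)
  ss_BS <- a * sum((Y_b - outer(m_s, rep(1, b)) - outer(rep(1, n), m_b) + gm)^2)
  ss_total <- sum((Y - gm)^2)
  ss_S <- a * b * sum((m_s - gm)^2)
  ss_ABS <- ss_total - ss_S - ss_A - ss_B - ss_AB - ss_AS - ss_BS
  ss_ABS <- max(ss_ABS, 0)

  eff <- function(name, ss_e, df1, ss_err, df2, eps_info) {
    f_val <- if (ss_e <= 1e-12 * max(1, ss_total)) 0
             else (ss_e / df1) / (ss_err / df2)
    gg_applied <- isTRUE(eps_info$mauchly_p < 0.05)
    p <- if (gg_applied)
      stats::pf(f_val, eps_info$eps * df1, eps_info$eps * df2, lower.tail = FALSE)
    else
      stats::pf(f_val, df1, df2, lower.tail = FALSE)
    data.frame(effect = name, F = f_val, df_num = df1, df_den = df2,
               gg_epsilon = eps_info$eps, mauchly_p = eps_info$mauchly_p,
               gg_applied = gg_applied, p = p,
               partial_eta_sq = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0)
  }

  eps_A <- if (a == 2L) list(eps = 1, mauchly_p = NA_real_)
           else .gg_epsilon(Y_a, n)
  eps_B <- if (b == 2L) list(eps = 1, mauchly_p = NA_real_)
           else .gg_epsilon(Y_b, n)
  # interaction contrast variables: kron of the two factors' contrasts
  C_ab <- kronecker(.orth_contrasts(a), .orth_contrasts(b))
  eps_AB <- if ((a - 1L) * (b - 1L) == 1L) list(eps = 1, mauchly_p = NA_real_)
            else .gg_epsilon_mat(Y %*% C_ab, n)

  out <- rbind(
    eff("hand", ss_A, a - 1L, ss_AS, (a - 1L) * (n - 1L), eps_A),
    eff("load", ss_B, b - 1L, ss_BS, (b - 1L) * (n - 1L), eps_B),
    eff("hand:load", ss_AB, (a - 1L) * (b - 1L), ss_ABS,
        (a - 1L) * (b - 1L) * (n - 1L), eps_AB))
  rownames(out) <- NULL
  out
}

# orthonormal polynomial-free contrasts (Helmert, normalized) for k levels
.orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2L, sqrt(colSums(C^2)), `/`)
}

# Greenhouse-Geisser epsilon + Mauchly p from an n x k matrix of level scores
.gg_epsilon <- function(Ylev, n) {
  k <- ncol(Ylev)
  .gg_epsilon_mat(Ylev %*% .orth_contrasts(k), n)
}

# D: n x p matrix of orthonormal contrast variables
.gg_epsilon_mat <- function(D, n) {
  p <- ncol(D)
  S <- stats::cov(D)
  tr <- sum(diag(S))
  eps <- if (tr <= 0) 1 else min(1, tr^2 / (p * sum(S^2)))
  detS <- det(S)
  mauchly_p <- NA_real_
  if (is.finite(detS) && detS > 0 && tr > 0 && n > p) {
    W <- detS / (tr / p)^p
    chi <- -((n - 1) - (2 * p^2 + p + 2) / (6 * p)) * log(W)
    df <- p * (p + 1) / 2 - 1
    mauchly_p <- stats::pchisq(chi, df, lower.tail = FALSE)
  }
  list(eps = eps, mauchly_p = mauchly_p)
}

#' Cell-wise SRT table for the hand x load repeated-measures analysis
#'
#' Aggregates the trial-level behavior table of one session into one value
#' per subject, hand and memory load. The dependent value is the mean
#' per-trial signed residual time within the cell (trial counts per cell vary
#' when loads and hands are drawn at random, so the mean rather than the raw
#' sum keeps cells comparable).
#'
#' @param behavior trial table of one session.
#' @return data frame `subject, hand, load, value` ready for
#'   [rm_anova_2x3()].
#' @export
srt_cells <- function(behavior) {
  stopifnot(all(c("subject", "hand", "load", "accuracy", "rt", "mt") %in% names(behavior)))
  per_trial <- (2 * behavior$accuracy - 1) * (behavior$mt - behavior$rt)
  out <- stats::aggregate(list(value = per_trial),
                          by = list(subject = behavior$subject,
                                    hand = behavior$hand,
                                    load = behavior$load),
                          FUN = mean)
  out[order(out$subject, out$hand, out$load), ]
}
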