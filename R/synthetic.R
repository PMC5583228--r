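#' Configuration for the synthetic working-memory cohort generator
#'
#' Describes a simulated delayed-match-to-sample study: a cohort of subjects
#' measured in two sessions (before/after training), each session a block of
#' trials at three memory loads, with multi-channel retention-period EEG whose
#' spectral uniformity on one designated target channel is coupled to the same
#' latent ability that drives accuracy and response latency.
#'
#' @param n_subjects number of subjects (default 20).
#' @param n_sessions number of sessions per subject (default 2; session 2 is
#'   "after training").
#' @param trials_per_session trials per subject and session (default 60).
#' @param loads memory-load set, items per memory array, sampled
#'   equiprobably per trial (default `c(2, 4, 8)`).
#' @param n_channels number of EEG channels (default 64; 16 is a convenient
#'   desk-scale subset that still contains the default target channel).
#' @param fs sampling rate in Hz (default 250; 1000 mimics a research-grade
#'   recording).
#' @param retention_s retention-interval duration in seconds (default 3).
#' @param target_channel label of the channel whose spectrum is coupled to
#'   ability (default `"FC4"`, a right fronto-central site).
#' @param coupling target Spearman rank correlation in `[0, 1]` between
#'   latent ability and target-channel spectral entropy (default 0.8).
#' @param training_gain mean ability increment from session 1 to session 2
#'   (default 0.5 on the standard-normal ability scale).
#' @param artifact_rate fraction of trials receiving a large-amplitude
#'   (> 100 microvolt) transient (default 0).
#' @param mt maximum allowable response time in seconds (default 3).
#' @param seed integer RNG seed; all randomness in the generator flows from it.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 20, n_sessions = 2,
                         trials_per_session = 60, loads = c(2, 4, 8),
                         n_channels = 64, fs = 250, retention_s = 3,
                         target_channel = "FC4", coupling = 0.8,
                         training_gain = 0.5, artifact_rate = 0,
                         mt = 3, seed = 1) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
      stop(sprintf("invalid `%s`: must be an integer count >= 1", nm), call. = FALSE)
  }
  chk_count(n_subjects, "n_subjects"); chk_count(n_sessions, "n_sessions")
  chk_count(trials_per_session, "trials_per_session")
  chk_count(n_channels, "n_channels")
  if (!is.numeric(loads) || length(loads) < 1L || any(loads < 1))
    stop("invalid `loads`: must be a set of item counts >= 1", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0)
    stop("invalid `fs`: must be a positive sampling rate", call. = FALSE)
  if (!is.numeric(retention_s) || retention_s <= 0)
    stop("invalid `retention_s`: must be positive", call. = FALSE)
  n_ret <- fs * retention_s
  if (abs(n_ret - round(n_ret)) > 1e-9 || n_ret < 64)
    stop("invalid `retention_s`: fs * retention_s must be an integer >= 64", call. = FALSE)
  if (!is.numeric(coupling) || coupling < 0 || coupling > 1)
    stop("invalid `coupling`: must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(artifact_rate) || artifact_rate < 0 || artifact_rate > 1)
    stop("invalid `artifact_rate`: must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(mt) || mt <= 0)
    stop("invalid `mt`: must be a positive time limit in seconds", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("invalid `seed`: must be a single integer", call. = FALSE)
  channels <- synth_channels(n_channels)
  if (!target_channel %in% channels)
    stop(sprintf("invalid `target_channel`: '%s' is not among the %d generated channel labels",
                 target_channel, n_channels), call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), n_sessions = as.integer(n_sessions),
         trials_per_session = as.integer(trials_per_session), loads = loads,
         n_channels = as.integer(n_channels), fs = fs, retention_s = retention_s,
         target_channel = target_channel, coupling = coupling,
         training_gain = training_gain, artifact_rate = artifact_rate,
         mt = mt, seed = as.integer(seed)),
    class = "synth_config")
}

#' Channel labels used by the generator
#'
#' Returns the first `n` labels of a fixed extended 10-20 ordering. The order
#' starts with the classic 19-channel montage augmented with the fronto-central
#' row, so small test montages (e.g. 16 channels) still contain `FC4`.
#'
#' @param n number of labels (1-64).
#' @return character vector of `n` unique channel labels.
#' @export
synth_channels <- function(n) {
  base <- c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8", "FC3", "FCZ", "FC4",
            "T7", "C3", "CZ", "C4", "T8", "P7", "P3", "PZ", "P4", "P8",
            "O1", "OZ", "O2", "AF3", "AF4", "F5", "F1", "F2", "F6",
            "FT7", "FC5", "FC1", "FC2", "FC6", "FT8", "C5", "C1", "C2", "C6",
            "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
            "P5", "P1", "P2", "P6", "PO7", "PO5", "PO3", "POZ", "PO4", "PO6",
            "PO8", "FPZ", "AF7", "AF8", "M1", "M2")
  if (n > length(base))
    stop(sprintf("invalid `n_channels`: at most %d labels available", length(base)),
         call. = FALSE)
  base[seq_len(n)]
}

# fixed generator constants: spectral mixture shape, behavior model, epoch
# layout. These are part of the simulated study design, not user dials.
.synth_const <- list(
  session_sd   = 0.2,    # within-subject session-to-session ability noise (sd)
  trait_share  = 0.9,    # stable-subject-trait share of the non-ability
                         # spectral variance (test-retest reliability of
                         # EEG spectral features is ~0.9)
  w_lo         = 0.10,   # alpha-bump mixing weight range
  w_hi         = 0.90,
  w_slope      = 1.5,    # logistic slope of the ability -> bump-weight map
  sig_frac     = 0.6,    # share of band power in the (flat vs bump) mixture
  bump_hz      = 10,     # alpha-band bump center (Hz) and width (sd, Hz)
  bump_sd      = 1,
  band         = c(0.5, 45),
  amp_uv       = 15,     # target per-channel signal sd in microvolts
  acc_b0       = 3,      # P(correct) = plogis(b0 + b1*ability - b2*log2(load))
  acc_b1       = 1,
  acc_b2       = 0.8,
  rt_meanlog   = 0,      # latency ~ lognormal, median exp(meanlog - slope*ability)
  rt_slope     = 0.25,
  rt_sdlog     = 0.3,
  artifact_uv  = 150,    # injected transient amplitude and duration
  artifact_s   = 0.2,
  epoch_t0     = -0.1,   # generated epoch spans (-0.1, 3.5) s around stimulus
  epoch_t1     = 3.5
)

# Spectral shape of a trial on a channel with bump weight w: a 1/f background
# plus a (1-w)-flat / w-alpha-bump mixture, supported on the analysis band.
# Returned values are unnormalized power densities.
.psd_shape <- function(f, w) {
  k <- .synth_const
  band <- k$band
  inband <- f >= band[1L] & f <= band[2L]
  flat <- 1 / diff(band)
  bump <- stats::dnorm(f, k$bump_hz, k$bump_sd)
  bg <- (1 / pmax(f, band[1L])) / log(band[2L] / band[1L])
  p <- (1 - k$sig_frac) * bg + k$sig_frac * ((1 - w) * flat + w * bump)
  p[!inband] <- 0
  p
}

#' Spectral entropy implied by a bump weight
#'
#' Deterministic map from the generator's latent bump-mixing weight `w` to the
#' spectral entropy (in dit) of the corresponding model spectrum, evaluated on
#' a 1-Hz Welch-style grid over the analysis band. Used to check, from ground
#' truth alone, how strongly ability and entropy are coupled.
#'
#' @param w numeric vector of mixing weights in `[0, 1]`.
#' @return numeric vector of entropies in dit.
#' @export
implied_entropy <- function(w) {
  f <- seq(1, 45, by = 1)
  vapply(w, function(wi) {
    p <- .psd_shape(f, wi)
    p <- p / sum(p)
    .entropy_dit(p)
  }, numeric(1))
}

# Latent ground truth: per subject/session ability and target-channel bump
# weight, drawn so that rank-cor(ability, entropy) approaches cfg$coupling.
# Must be the FIRST draws after set.seed so generate_ground_truth() and
# generate_cohort() agree.
.synth_truth <- function(cfg) {
  k <- .synth_const
  n <- cfg$n_subjects; S <- cfg$n_sessions
  a0 <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * S, sd = k$session_sd), n, S)
  gain <- cfg$training_gain * (col(eps) == 2)
  ability <- a0 + gain + eps
  # Gaussian copula: Pearson rho giving the requested Spearman coupling
  rho <- 2 * sin(pi * cfg$coupling / 6)
  sd_a <- sqrt(1 + k$session_sd^2)
  # the non-ability part of the spectral drive is mostly a stable subject
  # trait (EEG spectral features have high test-retest reliability), with a
  # small session-specific remainder
  u <- stats::rnorm(n)                       # stable spectral trait
  v <- matrix(stats::rnorm(n * S), n, S)     # session-specific remainder
  resid <- sqrt(k$trait_share) * u + sqrt(1 - k$trait_share) * v
  e <- rho * (ability / sd_a) + sqrt(1 - rho^2) * resid
  w <- k$w_lo + (k$w_hi - k$w_lo) * stats::plogis(-k$w_slope * e)
  data.frame(
    subject = rep(seq_len(n), times = S),
    session = rep(seq_len(S), each = n),
    ability = as.vector(ability),
    entropy_driver = as.vector(w))
}

#' Ground truth of a synthetic cohort without synthesizing EEG
#'
#' Draws only the latent per-subject/session ability and the target-channel
#' spectral mixing weight (the `entropy_driver`), using the same RNG stream as
#' [generate_cohort()]: for a given configuration the returned table is
#' identical to the `truth` component of the full cohort.
#'
#' @param cfg a [synth_config()].
#' @return data frame `subject, session, ability, entropy_driver`.
#' @export
generate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  .synth_truth(cfg)
}

# behavior for one subject/session given ability a (scalar)
.synth_behavior_block <- function(cfg, subject, session, a) {
  k <- .synth_const
  nt <- cfg$trials_per_session
  load <- sample(cfg$loads, nt, replace = TRUE)
  hand <- sample(c("left", "right"), nt, replace = TRUE)
  p_correct <- stats::plogis(k$acc_b0 + k$acc_b1 * a - k$acc_b2 * log2(load))
  accuracy <- stats::rbinom(nt, 1, p_correct)
  rt <- stats::rlnorm(nt, meanlog = k$rt_meanlog - k$rt_slope * a, sdlog = k$rt_sdlog)
  rt <- pmin(pmax(rt, 0), cfg$mt)
  data.frame(subject = subject, session = session, trial = seq_len(nt),
             load = load, hand = hand, accuracy = accuracy,
             rt = rt, mt = cfg$mt)
}

# Colored-noise synthesis for one subject/session: inverse-FFT with uniform
# random phases, spectrum shaped per channel by its bump weight. Returns a
# trials x channels x samples array in microvolts.
.synth_eeg_block <- function(cfg, w_by_channel) {
  k <- .synth_const
  nt <- cfg$trials_per_session
  nch <- cfg$n_channels
  n <- round((k$epoch_t1 - k$epoch_t0) * cfg$fs)
  K <- floor((n - 1) / 2)                      # independent positive-freq bins
  f <- seq_len(K) * cfg$fs / n
  keep <- which(f >= k$band[1L] & f <= k$band[2L])
  nb <- length(keep)
  # amplitude per (band bin, channel), scaled so each channel sd = amp_uv
  amp <- vapply(w_by_channel, function(w) sqrt(.psd_shape(f[keep], w)), numeric(nb))
  scl <- k$amp_uv / sqrt(2 * colSums(amp^2) / n^2)
  amp <- sweep(amp, 2L, scl, `*`)
  m <- nt * nch
  ph <- matrix(stats::runif(nb * m), nb, m)
  A <- amp[, rep(seq_len(nch), each = nt), drop = FALSE]
  Z <- complex(real = A * cospi(2 * ph), imaginary = A * sinpi(2 * ph))
  dim(Z) <- dim(ph)
  # pack pairs of real outputs into one complex inverse FFT:
  # ifft(H1 + i*H2) = x1 + i*x2 for Hermitian H1, H2
  odd_m <- m %% 2L == 1L
  if (odd_m) Z <- cbind(Z, 0)
  odd <- seq.int(1L, ncol(Z), by = 2L)
  Z1 <- Z[, odd, drop = FALSE]; Z2 <- Z[, odd + 1L, drop = FALSE]
  Xf <- matrix(0 + 0i, n, length(odd))
  Xf[keep + 1L, ] <- Z1 + 1i * Z2
  Xf[n + 1L - keep, ] <- Conj(Z1) + 1i * Conj(Z2)
  xc <- stats::mvfft(Xf, inverse = TRUE) / n
  x <- matrix(0, n, ncol(Z))
  x[, odd] <- Re(xc)
  x[, odd + 1L] <- Im(xc)
  if (odd_m) x <- x[, -ncol(x), drop = FALSE]
  aperm(array(x, c(n, nt, nch)), c(2L, 3L, 1L))
}

#' Generate a synthetic working-memory cohort
#'
#' Produces epoched EEG, a trial-level behavior table, and the latent ground
#' truth for a simulated two-session delayed-match-to-sample study. A latent
#' per-subject ability (shifted by `training_gain` in session 2) drives both
#' behavior -- accuracy through a logistic model decreasing in memory load,
#' latency through a lognormal whose median decreases with ability -- and the
#' spectral uniformity of the designated target channel: higher ability means
#' a flatter retention-period spectrum, hence higher spectral entropy, with
#' the rank correlation between ability and entropy dialed by `coupling`.
#' Non-target channels draw independent mixing weights. Trial time series are
#' synthesized by inverse Fourier transform with independent uniform random
#' phases (a circularly stationary surrogate whose expected spectrum is the
#' model spectrum exactly). Epochs span (-0.1, 3.5) s around memory-array
#' onset. With probability `artifact_rate` a trial receives a 150 microvolt,
#' 200 ms square transient on one random channel.
#'
#' @param cfg a [synth_config()].
#' @return A list of class `wm_cohort` with components `epochs` (list of
#'   [epoch_array()] objects, one per subject/session), `behavior` (trial
#'   table: subject, session, trial, load, hand, accuracy, rt, mt), `truth`
#'   (subject, session, ability, entropy_driver), `artifact_log` (subject,
#'   session, trial of each injected transient), and `config`.
#' @examples
#' cohort <- generate_cohort(synth_config(n_subjects = 3, n_channels = 16,
#'                                        trials_per_session = 8, seed = 1))
#' names(cohort$epochs)
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  k <- .synth_const
  set.seed(cfg$seed)
  truth <- .synth_truth(cfg)
  n <- cfg$n_subjects; S <- cfg$n_sessions; nch <- cfg$n_channels
  channels <- synth_channels(nch)
  tgt <- match(cfg$target_channel, channels)
  # independent bump weights for non-target channels, same marginal
  w_other <- array(
    k$w_lo + (k$w_hi - k$w_lo) * stats::plogis(-k$w_slope * stats::rnorm(n * S * (nch - 1L))),
    c(nch - 1L, n * S))
  behavior <- vector("list", n * S)
  epochs <- vector("list", n * S)
  art <- list()
  n_art_samp <- round(k$artifact_s * cfg$fs)
  n_samp <- round((k$epoch_t1 - k$epoch_t0) * cfg$fs)
  idx <- 0L
  for (s in seq_len(S)) {
    for (i in seq_len(n)) {
      idx <- idx + 1L
      row <- truth$subject == i & truth$session == s
      a <- truth$ability[row]
      behavior[[idx]] <- .synth_behavior_block(cfg, i, s, a)
      w_ch <- numeric(nch)
      w_ch[tgt] <- truth$entropy_driver[row]
      w_ch[-tgt] <- w_other[, (s - 1L) * n + i]
      dat <- .synth_eeg_block(cfg, w_ch)
      if (cfg$artifact_rate > 0) {
        hit <- which(stats::runif(cfg$trials_per_session) < cfg$artifact_rate)
        for (tr in hit) {
          ch <- sample.int(nch, 1L)
          at <- sample.int(n_samp - n_art_samp, 1L)
          dat[tr, ch, at:(at + n_art_samp - 1L)] <-
            dat[tr, ch, at:(at + n_art_samp - 1L)] + k$artifact_uv
        }
        if (length(hit))
          art[[length(art) + 1L]] <- data.frame(subject = i, session = s, trial = hit)
      }
      epochs[[idx]] <- epoch_array(i, s, dat, cfg$fs, channels, k$epoch_t0)
      names(epochs)[idx] <- sprintf("S%02d.%d", i, s)
    }
  }
  artifact_log <- if (length(art)) do.call(rbind, art)
                  else data.frame(subject = integer(), session = integer(), trial = integer())
  structure(
    list(epochs = epochs, behavior = do.call(rbind, behavior), truth = truth,
         artifact_log = artifact_log, config = cfg),
    class = "wm_cohort")
}

#' @export
print.wm_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<wm_cohort> %d subjects x %d sessions x %d trials, %d channels @ %g Hz (seed %d)\n",
    cfg$n_subjects, cfg$n_sessions, cfg$trials_per_session, cfg$n_channels,
    cfg$fs, cfg$seed))
  invisible(x)
}
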