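# Small seeded cohorts for module tests (desk-scale montage containing the
# target label "F3" so the EEG synthesis stays cheap).
small_cohort <- function(seed = 1, n_subjects = 6, n_channels = 4, trials = 12, ...) {
  generate_cohort(synth_config(
    n_subjects = n_subjects, n_channels = n_channels,
    trials_per_session = trials, target_channel = "F3", seed = seed, ...))
}

retention_all <- function(cohort) lapply(cohort$epochs, extract_retention)

# build an epoch_array from a samples-last array without generator machinery
toy_epochs <- function(arr, fs = 250, t0 = -0.1,
                       channels = paste0("CH", seq_len(dim(arr)[2]))) {
  epoch_array(1, 1, arr, fs, channels, t0)
}

# --- independent oracles -----------------------------------------------------

# product-moment correlation of mid-ranks, written out from first principles
pm_rank_cor_oracle <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  da <- ra - mean(ra); db <- rb - mean(rb)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# normalized Mann-Whitney U statistic (ties get half credit)
mw_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "high"]; neg <- scores[labels == "low"]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}
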