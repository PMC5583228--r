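test_that("invalid configurations are refused with the offending field named", {
  expect_error(synth_config(n_subjects = 0), "n_subjects")
  expect_error(synth_config(coupling = 1.5), "coupling")
  expect_error(synth_config(artifact_rate = -0.1), "artifact_rate")
  expect_error(synth_config(fs = 250, retention_s = 0.1), "retention_s")
  expect_error(synth_config(n_channels = 4, target_channel = "FC4"),
               "target_channel")
})

test_that("equal seeds give bit-identical cohorts", {
  a <- small_cohort(seed = 7)
  b <- small_cohort(seed = 7)
  expect_identical(a$epochs, b$epochs)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$truth, b$truth)
  c <- small_cohort(seed = 8)
  expect_false(identical(a$epochs[[1]]$data, c$epochs[[1]]$data))
})

test_that("ground truth can be drawn without EEG and matches the full cohort", {
  cfg <- synth_config(n_subjects = 5, n_channels = 4, target_channel = "F3",
                      trials_per_session = 6, seed = 11)
  expect_identical(generate_ground_truth(cfg), generate_cohort(cfg)$truth)
})

test_that("zero coupling decouples ability from target-channel entropy", {
  co <- generate_cohort(synth_config(n_subjects = 20, n_channels = 4,
                                     target_channel = "F3", coupling = 0,
                                     seed = 1))
  feats <- cohort_entropy(retention_all(co))
  f <- feats[feats$channel == "F3" & feats$session == 1, ]
  a <- co$truth$ability[co$truth$session == 1]
  # two-sided 95% null band for Spearman at n = 20
  expect_lt(abs(cor(a, f$sen, method = "spearman")), 0.45)
})

test_that("realized ground-truth coupling approaches the dialed value at large n", {
  tr <- generate_ground_truth(synth_config(n_subjects = 200, coupling = 0.8,
                                           seed = 3))
  s1 <- tr$session == 1
  r <- cor(tr$ability[s1], implied_entropy(tr$entropy_driver[s1]),
           method = "spearman")
  expect_lt(abs(r - 0.8), 0.1)
})

test_that("mean realized coupling increases with the coupling dial", {
  mean_abs_r <- vapply(c(0, 0.4, 0.8), function(cp) {
    rs <- vapply(1:50, function(sd) {
      tr <- generate_ground_truth(synth_config(n_subjects = 20, coupling = cp,
                                               seed = sd))
      s1 <- tr$session == 1
      abs(cor(tr$ability[s1], implied_entropy(tr$entropy_driver[s1]),
              method = "spearman"))
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_abs_r) > 0))
})

test_that("entropy driver is monotone decreasing in the latent spectral drive", {
  w <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(implied_entropy(w)) < 0))
})

test_that("artifact injection hits the requested trial fraction", {
  co <- generate_cohort(synth_config(n_subjects = 6, n_channels = 4,
                                     target_channel = "F3",
                                     trials_per_session = 60,
                                     artifact_rate = 0.1, seed = 21))
  peaks <- unlist(lapply(co$epochs, function(e)
    apply(matrix(abs(e$data), dim(e$data)[1L]), 1L, max)))
  frac <- mean(peaks > 100)
  n <- length(peaks)
  half_width <- 2.576 * sqrt(0.1 * 0.9 / n)  # binomial 99% bounds
  expect_gt(frac, 0.1 - half_width)
  expect_lt(frac, 0.1 + half_width)
  expect_equal(sum(peaks > 100), nrow(co$artifact_log))
})

test_that("fixtures round-trip field-for-field", {
  co <- small_cohort(seed = 5, n_subjects = 2, trials = 6)
  path <- withr::local_tempdir()
  write_fixture(co, path)
  expect_true(file.exists(file.path(path, "eeg.rds")))
  expect_true(file.exists(file.path(path, "behavior.csv")))
  back <- read_fixture(path)
  expect_identical(back$epochs[[1]]$data, co$epochs[[1]]$data)
  expect_identical(back$epochs, co$epochs)
  expect_equal(back$behavior, co$behavior)
  expect_equal(back$truth, co$truth)
})

test_that("a fixture missing a required dataset raises a format error", {
  co <- small_cohort(seed = 5, n_subjects = 2, trials = 6)
  path <- withr::local_tempdir()
  write_fixture(co, path)
  container <- readRDS(file.path(path, "eeg.rds"))
  container$groups[[2]]$fs <- NULL
  saveRDS(container, file.path(path, "eeg.rds"))
  expect_error(read_fixture(path), "missing dataset `fs`")
  expect_error(read_fixture(withr::local_tempdir()), "missing EEG container")
})
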