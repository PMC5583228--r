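test_that("average re-referencing zeroes the cross-channel mean", {
  # already zero-mean pair stays put
  arr <- array(0, c(1, 2, 10)); arr[1, 1, ] <- 5; arr[1, 2, ] <- -5
  e <- rereference_average(toy_epochs(arr))
  expect_equal(e$data, arr)
  # (10, 0) becomes (5, -5)
  arr2 <- array(0, c(1, 2, 10)); arr2[1, 1, ] <- 10
  e2 <- rereference_average(toy_epochs(arr2))
  expect_equal(e2$data[1, 1, ], rep(5, 10))
  expect_equal(e2$data[1, 2, ], rep(-5, 10))
  # random array: per-sample channel mean vanishes
  set.seed(1)
  r <- rereference_average(toy_epochs(array(rnorm(3 * 5 * 20), c(3, 5, 20))))
  expect_lt(max(abs(apply(r$data, c(1, 3), mean))), 1e-9)
  expect_error(rereference_average(toy_epochs(array(1, c(2, 1, 10)))),
               "2 channels")
})

test_that("band-pass keeps passband sinusoids and kills stopband ones", {
  fs <- 250; n <- 900; tt <- (0:(n - 1)) / fs
  arr <- array(0, c(1, 2, n))
  arr[1, 1, ] <- sin(2 * pi * 10 * tt)
  arr[1, 2, ] <- sin(2 * pi * 100 * tt)
  f <- bandpass(toy_epochs(arr, fs = fs))
  mid <- 200:700  # away from edge transients
  expect_gt(max(abs(f$data[1, 1, mid])), 0.9)
  expect_lt(max(abs(f$data[1, 2, mid])), 0.1)
  # zero in, zero out
  z <- bandpass(toy_epochs(array(0, c(1, 2, n)), fs = fs))
  expect_equal(max(abs(z$data)), 0)
  expect_error(bandpass(toy_epochs(arr, fs = fs), band = c(0.5, 130)),
               "fs/2")
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  n <- 250; fs <- 250  # epoch (-0.1, 0.9)
  const <- toy_epochs(array(7, c(1, 2, n)), fs = fs)
  b <- baseline_correct(const, c(-0.1, 0))
  expect_equal(max(abs(b$data)), 0)
  # trace whose baseline mean is 3 gets shifted down by 3
  arr <- array(0, c(1, 1, n)); arr[1, 1, ] <- c(rep(3, 25), rep(8, n - 25))
  b2 <- baseline_correct(toy_epochs(arr, fs = fs), c(-0.1, 0))
  expect_equal(b2$data[1, 1, ], arr[1, 1, ] - 3)
  set.seed(2)
  r <- baseline_correct(toy_epochs(array(rnorm(4 * 3 * n), c(4, 3, n)), fs = fs),
                        c(-0.1, 0))
  base_means <- apply(r$data[, , 1:25, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base_means)), 1e-9)
  expect_error(baseline_correct(const, c(-0.5, -0.2)), "outside the epoch")
})

test_that("artifact rejection removes exactly the over-threshold trials", {
  arr <- array(0, c(3, 2, 50))
  arr[1, 1, 10] <- 50; arr[2, 2, 20] <- 150; arr[3, 1, 30] <- 99
  res <- reject_artifacts(toy_epochs(arr), 100)
  expect_identical(res$rejected, 2L)
  expect_identical(res$epochs$trial_ids, c(1L, 3L))
  expect_equal(dim(res$epochs$data)[1], 2L)
  # nothing over threshold: nothing rejected
  res2 <- reject_artifacts(toy_epochs(arr * 0.5), 100)
  expect_length(res2$rejected, 0)
  expect_error(reject_artifacts(toy_epochs(arr), 10), "all trials rejected")
})

test_that("rejection rate matches the generator's injection rate", {
  co <- generate_cohort(synth_config(n_subjects = 6, n_channels = 4,
                                     target_channel = "F3",
                                     trials_per_session = 60,
                                     artifact_rate = 0.2, seed = 31))
  rejected <- sum(vapply(co$epochs, function(e)
    length(reject_artifacts(e, 100)$rejected), integer(1)))
  n <- nrow(co$behavior)
  frac <- rejected / n
  half_width <- 2.576 * sqrt(0.2 * 0.8 / n)
  expect_gt(frac, 0.2 - half_width)
  expect_lt(frac, 0.2 + half_width)
})

test_that("retention extraction cuts exactly fs * 3 samples at the right offset", {
  co <- small_cohort(seed = 4, n_subjects = 2, trials = 5)
  e <- co$epochs[[1]]
  r <- extract_retention(e)                    # default (0.2, 3.2) s
  expect_equal(dim(r$data)[3], 750L)
  expect_equal(r$t0, 0.2)
  # index-arithmetic oracle: (0.2 - (-0.1)) * 250 = sample 76 onward
  expect_identical(r$data, e$data[, , 76:825, drop = FALSE])
  late <- epoch_array(1, 1, e$data, e$fs, e$channels, t0 = 0.3)
  expect_error(extract_retention(late, c(0.2, 3.2)), "outside the epoch")
})

test_that("reference and baseline steps are idempotent and preserve ordering", {
  co <- small_cohort(seed = 6, n_subjects = 2, trials = 5)
  e <- co$epochs[[1]]
  r1 <- rereference_average(e)
  expect_equal(rereference_average(r1)$data, r1$data, tolerance = 1e-12)
  b1 <- baseline_correct(r1)
  expect_equal(baseline_correct(b1)$data, b1$data, tolerance = 1e-12)
  out <- preprocess(e)
  expect_identical(out$epochs$channels, e$channels)
  expect_true(all(out$epochs$trial_ids %in% e$trial_ids))
  expect_false(is.unsorted(match(out$epochs$trial_ids, e$trial_ids)))
})
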