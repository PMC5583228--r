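test_that("SRT scoring rewards fast correct and punishes fast wrong answers", {
  expect_equal(srt_score(data.frame(accuracy = 1, rt = 0.5, mt = 2)), 1.5)
  expect_equal(srt_score(data.frame(accuracy = 0, rt = 0.5, mt = 2)), -1.5)
  trials <- data.frame(accuracy = c(1, 0, 1), rt = c(1.0, 2.5, 2.9), mt = 3.0)
  expect_equal(srt_score(trials), 2.0 - 0.5 + 0.1)
  # omissions score as incorrect at the time limit: zero contribution
  expect_equal(srt_score(data.frame(accuracy = c(1, 1), rt = c(0.5, NA),
                                    mt = 2)), 1.5)
  expect_error(srt_score(data.frame()), "empty")
})

test_that("SRT is additive over trial blocks and bounded by total time", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    tr <- data.frame(accuracy = rbinom(n, 1, 0.7), rt = runif(n, 0, 3), mt = 3)
    k <- sample(n - 1, 1)
    expect_equal(srt_score(tr), srt_score(tr[1:k, ]) + srt_score(tr[(k + 1):n, ]))
    expect_lte(abs(srt_score(tr)), sum(tr$mt))
  }
})

test_that("z-scoring splits the cohort at zero with sample-sd units", {
  sc <- zscore_group(data.frame(subject = 1:3, session = 1, srt = c(1, 2, 3)))
  expect_equal(sc$z, c(-1, 0, 1))
  expect_equal(as.character(sc$group), c("low", "low", "high"))  # z = 0 is low
  set.seed(6)
  sc2 <- zscore_group(data.frame(subject = 1:20, session = 1, srt = rnorm(20, 50, 10)))
  expect_lt(abs(mean(sc2$z)), 1e-12)
  expect_lt(abs(sd(sc2$z) - 1), 1e-12)
  # grouping invariant under positive affine rescaling of SRT
  sc3 <- zscore_group(data.frame(subject = 1:20, session = 1,
                                 srt = 3.7 * sc2$srt + 12))
  expect_equal(sc3$z, sc2$z, tolerance = 1e-12)
  expect_identical(sc3$group, sc2$group)
  expect_error(zscore_group(data.frame(subject = 1:3, session = 1, srt = rep(2, 3))),
               "degenerate")
})

test_that("change rate is the symmetric percent change", {
  expect_equal(change_rate(5, 5), 0)
  expect_equal(change_rate(1, 3), 100)
  set.seed(7)
  a <- runif(1000, 0.1, 10); b <- runif(1000, 0.1, 10)
  expect_equal(change_rate(a, b), -change_rate(b, a))
  expect_error(change_rate(2, -2), "undefined")
})

test_that("repeated-measures ANOVA matches stats::aov on a balanced design", {
  set.seed(8)
  d <- expand.grid(subject = 1:4, hand = c("left", "right"), load = c(2, 4, 8))
  d$value <- rnorm(nrow(d)) + as.numeric(d$load) * 0.3
  tab <- rm_anova_2x3(d)
  fit <- summary(stats::aov(value ~ hand * load +
                              Error(factor(subject) / (hand * load)),
                            data = transform(d, hand = factor(hand),
                                             load = factor(load))))
  f_or <- c(fit[["Error: factor(subject):hand"]][[1]]["hand", "F value"],
            fit[["Error: factor(subject):load"]][[1]]["load", "F value"],
            fit[["Error: factor(subject):hand:load"]][[1]]["hand:load", "F value"])
  expect_equal(tab$F, unname(f_or), tolerance = 1e-9)
  expect_equal(tab$df_num, c(1, 2, 2))
  expect_equal(tab$df_den, c(3, 6, 6))
  expect_equal(tab$gg_epsilon[tab$effect == "hand"], 1)  # 2 levels: spherical
  expect_true(all(tab$partial_eta_sq >= 0 & tab$partial_eta_sq <= 1))
})

test_that("identical cell values give zero F, and gaps are refused", {
  d <- expand.grid(subject = 1:4, hand = c("L", "R"), load = c(2, 4, 8))
  d$value <- rep(1:4, times = 6)  # constant within subject across cells
  tab <- rm_anova_2x3(d)
  expect_equal(tab$F, c(0, 0, 0))
  expect_error(rm_anova_2x3(d[-1, ]), "incomplete design")
})

test_that("cell aggregation feeds a complete hand x load table", {
  co <- small_cohort(seed = 12, n_subjects = 4, trials = 48)
  beh1 <- co$behavior[co$behavior$session == 1, ]
  cells <- srt_cells(beh1)
  expect_equal(nrow(cells), 4 * 2 * 3)
  tab <- rm_anova_2x3(cells)
  expect_equal(nrow(tab), 3)
  expect_true(all(is.finite(tab$F)))
})

test_that("consistency report counts sign agreement between CR pairs", {
  scores <- data.frame(subject = rep(1:3, 2), session = rep(1:2, each = 3),
                       srt = c(10, 10, 10, 12, 13, 9))
  feats <- data.frame(subject = rep(1:3, 2), session = rep(1:2, each = 3),
                      channel = "FC4", sen = c(1, 1, 1, 1.1, 0.9, 0.95))
  rep <- consistency_report(scores, feats, "FC4")
  # subject 1: both up; subject 2: srt up, sen down; subject 3: both down
  expect_equal(rep$per_subject$consistent, c(TRUE, FALSE, TRUE))
  expect_equal(unname(rep$counts), c(2, 1, 2, 1))
  expect_equal(sum(rep$counts[c("consistent", "inconsistent")]), 3)
  expect_error(consistency_report(scores[-1, ], feats, "FC4"), "missing")
})

test_that("BH never rejects hypotheses that raw 0.05 testing would keep", {
  set.seed(9)
  for (i in 1:20) {
    p <- runif(30)^2
    rej <- fdr_bh(p, 0.05)$reject
    expect_true(all(p[rej] <= 0.05))
  }
})
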