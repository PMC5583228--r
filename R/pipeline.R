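#' Assemble a full-run configuration
#'
#' Collects every stage's parameters into one list: the synthetic-cohort
#' configuration (or a fixture directory to read instead), preprocessing,
#' Welch, SVM/SVR settings, and output options. Unspecified values take the
#' package defaults.
#'
#' @param synth list of [synth_config()] arguments (ignored when `input` is
#'   given).
#' @param input optional fixture directory written by [write_fixture()];
#'   when set, the cohort is read instead of simulated.
#' @param preprocess list of [preprocess_config()] arguments.
#' @param welch list of Welch arguments (`segment_s`, `overlap_frac`,
#'   `window_name`, `band`, `aggregation`).
#' @param svm list with `cost`.
#' @param svr list with `cost`, `epsilon`, `gamma`.
#' @param seed integer seed forwarded to the generator.
#' @param topomap logical: also render the scalp map PNG (default `TRUE`).
#' @return list of class `run_config`.
#' @export
run_config <- function(synth = list(), input = NULL, preprocess = list(),
                       welch = list(), svm = list(), svr = list(),
                       seed = 1, topomap = TRUE) {
  synth$seed <- seed
  structure(
    list(synth = do.call(synth_config, synth), input = input,
         preprocess = do.call(preprocess_config, preprocess),
         welch = utils::modifyList(
           list(segment_s = 1, overlap_frac = 0.5, window_name = "hamming",
                band = c(0.5, 45), aggregation = "trial_mean"), welch),
         svm = utils::modifyList(list(cost = 1), svm),
         svr = utils::modifyList(list(cost = 1, epsilon = 0.1, gamma = NULL),
                                 svr),
         seed = as.integer(seed), topomap = isTRUE(topomap)),
    class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or fixture loading), preprocessing
#' (average reference, band-pass, baseline, amplitude rejection, retention
#' extraction), per-channel spectral entropy, SRT scoring and grouping, the
#' channel fingerprint for session 1 / session 2 / merged scopes (with an
#' optional scalp map), intra- and inter-session SVM classification on the
#' best merged-scope channel, SVR prediction of SRT for the three scopes
#' (with BH adjustment across scopes), and the change-rate consistency
#' report. Every stage writes its interchange file into `out_dir`, and a run
#' manifest records the seed, package version, configuration, and per-stage
#' row counts. Re-running with an identical configuration reproduces
#' identical numeric outputs. A stage failure raises an error naming the
#' stage and leaves a `FAILED` marker next to any partial outputs.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_all <- function(cfg = run_config(), out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    if (!is.null(cfg$input)) read_fixture(cfg$input)
    else generate_cohort(cfg$synth)
  })
  .write_csv_exact(cohort$behavior, file.path(out_dir, "behavior.csv"))
  .write_csv_exact(cohort$truth, file.path(out_dir, "ground_truth.csv"))

  pre <- stage("preprocess", lapply(cohort$epochs, preprocess, cfg = cfg$preprocess))
  clean <- lapply(pre, `[[`, "epochs")
  n_rejected <- sum(vapply(pre, function(p) length(p$rejected), integer(1)))

  features <- stage("features", {
    w <- cfg$welch
    cohort_entropy(clean, segment_s = w$segment_s, overlap_frac = w$overlap_frac,
                   window_name = w$window_name, band = w$band,
                   aggregation = w$aggregation)
  })
  utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)

  # behavior restricted to retained trials, keyed by trial ids
  retained <- do.call(rbind, lapply(clean, function(e)
    data.frame(subject = e$subject, session = e$session, trial = e$trial_ids)))
  beh <- merge(cohort$behavior, retained,
               by = c("subject", "session", "trial"), sort = FALSE)
  scores <- stage("scores", score_sessions(beh))
  utils::write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)

  maps <- stage("map", {
    lapply(c(session1 = "session1", session2 = "session2", merged = "merged"),
           function(sc) fingerprint(features, scores, scope = sc))
  })
  utils::write.csv(do.call(rbind, lapply(maps, as.data.frame)),
                   file.path(out_dir, "correlation_map.csv"), row.names = FALSE)
  .write_json(lapply(maps, best_channel), file.path(out_dir, "best_channels.json"))
  if (cfg$topomap)
    stage("map", topomap(maps$merged, file.path(out_dir, "topomap_merged.png")))
  best <- best_channel(maps$merged)

  feat_of <- function(session) {
    f <- features[features$channel == best & features$session == session, ]
    s <- scores[scores$session == session, ]
    f <- f[match(s$subject, f$subject), ]
    list(x = f$sen, y = s$group, srt = s$srt, subject = s$subject)
  }
  f1 <- feat_of(1); f2 <- feat_of(2)
  cls <- stage("classify", list(
    intra_s1 = loocv_classify(f1$x, f1$y, cost = cfg$svm$cost, scheme = "intra_s1"),
    intra_s2 = loocv_classify(f2$x, f2$y, cost = cfg$svm$cost, scheme = "intra_s2"),
    inter_train2_test1 = cross_session_classify(f2$x, f2$y, f1$x, f1$y,
      cost = cfg$svm$cost, scheme = "inter_train2_test1"),
    inter_train1_test2 = cross_session_classify(f1$x, f1$y, f2$x, f2$y,
      cost = cfg$svm$cost, scheme = "inter_train1_test2")))
  .write_json(lapply(cls, function(r)
    list(scheme = r$scheme, ca = r$ca, se = r$se, sp = r$sp, auc = r$auc,
         counts = as.list(r$counts), predictions = r$predictions)),
    file.path(out_dir, "classification.json"))

  reg <- stage("predict", {
    fm <- list(x = c(f1$x, f2$x), srt = c(f1$srt, f2$srt))
    out <- list(
      session1 = loocv_svr(f1$x, f1$srt, cost = cfg$svr$cost,
        epsilon = cfg$svr$epsilon, gamma = cfg$svr$gamma, scope = "session1"),
      session2 = loocv_svr(f2$x, f2$srt, cost = cfg$svr$cost,
        epsilon = cfg$svr$epsilon, gamma = cfg$svr$gamma, scope = "session2"),
      merged = loocv_svr(fm$x, fm$srt, cost = cfg$svr$cost,
        epsilon = cfg$svr$epsilon, gamma = cfg$svr$gamma, scope = "merged"))
    qs <- fdr_bh(vapply(out, `[[`, numeric(1), "p"))$q
    for (i in seq_along(out)) out[[i]]$q <- qs[i]
    out
  })
  .write_json(lapply(reg, function(r)
    list(scope = r$scope, rmsep = r$rmsep, r = r$r, p = r$p, q = r$q,
         predictions = r$predictions)),
    file.path(out_dir, "regression.json"))

  changes <- stage("changes", consistency_report(scores, features, best))
  utils::write.csv(changes$per_subject, file.path(out_dir, "change_report.csv"),
                   row.names = FALSE)
  .write_json(c(list(channel = best), as.list(changes$counts)),
              file.path(out_dir, "change_summary.json"))

  manifest <- list(
    package = "wmentropy",
    version = as.character(utils::packageVersion("wmentropy")),
    seed = cfg$seed,
    config = .manifest_config(cfg),
    counts = list(
      subjects = length(unique(cohort$behavior$subject)),
      sessions = length(unique(cohort$behavior$session)),
      trials_in = nrow(cohort$behavior),
      trials_rejected = n_rejected,
      trials_retained = nrow(beh),
      channels = length(clean[[1L]]$channels)),
    best_channel = best)
  .write_json(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(cohort = cohort, features = features, scores = scores,
                 maps = maps, classification = cls, regression = reg,
                 changes = changes, manifest = manifest))
}

# plain-list echo of the configuration for the manifest
.manifest_config <- function(cfg) {
  list(synth = unclass(cfg$synth), input = cfg$input,
       preprocess = unclass(cfg$preprocess), welch = cfg$welch,
       svm = cfg$svm, svr = cfg$svr, topomap = cfg$topomap)
}
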