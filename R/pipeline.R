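# End-to-end training/evaluation protocol:
# preprocess -> clean -> GAN -> Mixup -> 80/20 split of the AUGMENTED set
# -> LSTM training -> prediction on the measured pairs only -> agreement
# reports. The regressor never trains on measured pairs and is never tested
# on augmented ones; the purity of the test set is enforced structurally.

#' Pipeline configuration
#'
#' @param cleaning a [cleaning_config()].
#' @param gan a [gan_config()].
#' @param rnn an [rnn_config()].
#' @param n_gan,n_mix GAN and Mixup pair counts for the augmented set.
#' @param mixup_include_measured if `TRUE` (default), Mixup parents are
#'   drawn from the GAN pool plus the measured pairs — the textbook Mixup
#'   formulation. The training set still contains no raw measured pair;
#'   measured curves enter only as halves of convex combinations. Set
#'   `FALSE` to mix the GAN pool alone.
#' @param fraction_train train share of the augmented set (default 0.8).
#' @param seed global seed, propagated to every stochastic stage.
#' @param out_dir optional directory for report CSV/JSON files.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cleaning = cleaning_config(), gan = gan_config(),
                            rnn = rnn_config(), n_gan = 1000, n_mix = 200,
                            mixup_include_measured = TRUE,
                            fraction_train = 0.8, seed = 1L, out_dir = NULL) {
  structure(list(cleaning = cleaning, gan = gan, rnn = rnn,
                 n_gan = n_gan, n_mix = n_mix,
                 mixup_include_measured = isTRUE(mixup_include_measured),
                 fraction_train = fraction_train,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Guard: a test set may contain only measured (or simulated-measured) pairs
#'
#' @param pairs list of [vf_pair()]s intended as a test set.
#' @return invisibly `TRUE`; raises a protocol-violation error otherwise.
#' @export
assert_test_purity <- function(pairs) {
  src <- vapply(pairs, function(p) p$source, character(1))
  bad <- !src %in% c("measured", "synthetic")
  if (any(bad))
    stop(errorCondition(
      sprintf("protocol violation: %d augmented pair(s) (%s) in the test set",
              sum(bad), paste(unique(src[bad]), collapse = ", ")),
      class = c("scrumforce_protocol_error", "scrumforce_config_error",
                "scrumforce_error")))
  invisible(TRUE)
}

#' Run the full train/test pipeline
#'
#' Accepts raw trials ([engagement_trial()] or `sim_trial` objects) or
#' ready-made measured pairs. Simulated trials carry their noise-free
#' ground-truth force curves, in which case agreement is additionally
#' reported against the ground truth.
#'
#' @param trials list of [engagement_trial()]s or `sim_trial`s; ignored if
#'   `pairs` is given.
#' @param cfg a [pipeline_config()].
#' @param pairs optional list of measured [vf_pair()]s, bypassing
#'   preprocessing.
#' @return list of class `scrumforce_run`: cleaned pairs, cleaning log, the
#'   trained `scrum_gan` and `force_rnn`, predictions, per-trial agreement
#'   records (vs measured, and vs ground truth when available), grouped
#'   reports by technique and shoulder, and the Bland-Altman result.
#' @export
run_end_to_end <- function(trials = NULL, cfg = pipeline_config(), pairs = NULL) {
  if (!inherits(cfg, "pipeline_config")) stop_config("cfg must be a pipeline_config")
  stage <- function(name, expr)
    withCallingHandlers(expr, scrumforce_error = function(e) {
      message(sprintf("[%s] failed: %s", name, conditionMessage(e)))
    })

  gt_forces <- NULL
  if (is.null(pairs)) {
    if (is.null(trials) || length(trials) == 0L)
      stop_data("no input: provide trials or pairs")
    is_sim <- vapply(trials, inherits, logical(1), "sim_trial")
    if (all(is_sim)) {
      gt_forces <- lapply(trials, function(s) s$ground_truth$force)
      names(gt_forces) <- vapply(trials, function(s) s$trial$trial_id, character(1))
      trials <- lapply(trials, `[[`, "trial")
    }
    pairs <- stage("preprocess", lapply(trials, build_pair, cfg = cfg$cleaning))
  }
  cl <- stage("clean", clean_trials(pairs, cfg$cleaning))
  measured <- cl$kept
  if (length(measured) < 8L)
    stop_data("only %d pairs survive cleaning; cannot train", length(measured))

  gan_cfg <- cfg$gan; gan_cfg$seed <- cfg$seed
  gan <- stage("gan", train_gan(measured, gan_cfg))
  aug <- stage("augment",
               build_augmented_dataset(measured, gan, cfg$n_gan, cfg$n_mix,
                                       seed = cfg$seed + 1L,
                                       include_measured = cfg$mixup_include_measured))
  sp <- stage("split", split_dataset(aug, cfg$fraction_train,
                                     seed = cfg$seed + 2L))

  rnn_cfg <- cfg$rnn; rnn_cfg$seed <- cfg$seed + 3L
  model <- stage("train", train_predictor(sp$train, sp$validation, rnn_cfg))

  assert_test_purity(measured)
  pred <- stage("predict", stats::predict(model, measured))

  mk_records <- function(ref_curves) {
    do.call(rbind, lapply(seq_along(measured), function(i)
      agreement(ref_curves[[i]], pred[i, ], meta = measured[[i]]$meta)))
  }
  meas_curves <- lapply(measured, `[[`, "force")
  records <- stage("evaluate", mk_records(meas_curves))
  records_gt <- NULL
  if (!is.null(gt_forces)) {
    ids <- vapply(measured, function(p) p$meta$trial_id, character(1))
    records_gt <- stage("evaluate-gt", mk_records(gt_forces[ids]))
  }

  peaks_m <- vapply(meas_curves, max, numeric(1))
  peaks_p <- apply(pred, 1L, max)
  ba <- bland_altman(peaks_m, peaks_p, group_labels = records$technique)

  out <- structure(list(
    pairs = pairs, measured = measured, cleaning_log = cl$log,
    gan = gan, augmented_n = length(aug), model = model,
    predictions = pred, records = records, records_ground_truth = records_gt,
    by_technique = grouped_report(records, "technique", meas_curves),
    by_shoulder = grouped_report(records, "shoulder", meas_curves),
    bland_altman = ba, config = cfg), class = "scrumforce_run")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(cfg$out_dir, "agreement_per_trial.csv"),
                     row.names = FALSE)
    utils::write.csv(out$by_technique, file.path(cfg$out_dir, "by_technique.csv"),
                     row.names = FALSE)
    utils::write.csv(out$by_shoulder, file.path(cfg$out_dir, "by_shoulder.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(bias = ba$bias, loa_lower = ba$loa_lower,
                              loa_upper = ba$loa_upper, n = ba$n,
                              groups = ba$groups),
                         file.path(cfg$out_dir, "bland_altman.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.scrumforce_run <- function(x, ...) {
  cat(sprintf("<scrumforce_run> %d measured pairs (%d rejected), %d augmented\n",
              length(x$measured), nrow(x$cleaning_log), x$augmented_n))
  cat(sprintf("  agreement vs measured: mean r %.3f, mean nRMSE %.1f%%, mean peak diff %.1f%%\n",
              mean(x$records$correlation), mean(x$records$nrmse_pct),
              mean(x$records$npeak_pct)))
  if (!is.null(x$records_ground_truth))
    cat(sprintf("  agreement vs ground truth: mean r %.3f, mean nRMSE %.1f%%\n",
                mean(x$records_ground_truth$correlation),
                mean(x$records_ground_truth$nrmse_pct)))
  cat(sprintf("  Bland-Altman: bias %.1f N, LoA [%.0f, %.0f] N\n",
              x$bland_altman$bias, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper))
  invisible(x)
}
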