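## End-to-end orchestration: simulate -> features -> compare -> classify ->
## regress, with a reproducibility manifest.

#' Build a pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param stages Stages to run, a subset of
#'   `c("simulate", "features", "compare", "classify", "regress")`, executed
#'   in dependency order.
#' @param seed Master seed, recorded in the manifest and driving every stage.
#' @param synthetic A [synthetic_config()] for the simulate stage.
#' @param transcripts_dir,lexicon_path,cohort_path Input locations; default to
#'   the simulate stage's outputs inside `out_dir`.
#' @param tagmap_path Optional tag-mapping JSON (default CKIP mapping).
#' @param long_pause_s Long-pause threshold in seconds.
#' @param vif_threshold VIF screening threshold.
#' @param control A [classification_control()] for the classify stage.
#' @param models,sets Classify-stage model and predictor-set lists.
#' @param resume Skip stages whose outputs already exist.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, stages = c("simulate", "features", "compare",
                                           "classify", "regress"),
                       seed = 1, synthetic = synthetic_config(seed = seed),
                       transcripts_dir = file.path(out_dir, "transcripts"),
                       lexicon_path = file.path(out_dir, "lexicon.tsv"),
                       cohort_path = file.path(out_dir, "cohort.csv"),
                       tagmap_path = NULL, long_pause_s = 2, vif_threshold = 5,
                       control = classification_control(),
                       models = c("svm", "knn", "rf"),
                       sets = c("linguistic", "biomarkers", "combined"),
                       resume = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

stage_outputs <- function(config, stage) {
  od <- config$out_dir
  switch(stage,
         simulate = c(config$cohort_path, config$lexicon_path,
                      file.path(od, "truth.csv")),
         features = file.path(od, "features.csv"),
         compare = file.path(od, "comparison.csv"),
         classify = c(file.path(od, "metrics.csv"),
                      file.path(od, "importance.csv"),
                      file.path(od, "roc_points.csv")),
         regress = c(file.path(od, "regression.csv"),
                     file.path(od, "vif_retained.txt")))
}

merge_cohort_features <- function(config) {
  fpath <- file.path(config$out_dir, "features.csv")
  if (!file.exists(config$cohort_path)) {
    stop("missing cohort table '", config$cohort_path,
         "': run the simulate stage first (or point cohort_path at your data)")
  }
  if (!file.exists(fpath)) {
    stop("missing features.csv: run the features stage first")
  }
  cohort <- read_cohort(config$cohort_path)
  feats <- read_feature_table(fpath)
  merged <- merge(as.data.frame(cohort), feats, by = "participant_id",
                  sort = TRUE)
  as_cohort_table(merged)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order and writes a manifest
#' (`manifest.json`) recording the master seed, per-stage status and MD5
#' checksums of every output, so each artifact is attributable and identical
#' seeds give identical manifests. A missing upstream artifact halts the run
#' with an error naming the stage to run first. Warnings raised inside a
#' stage are collected into the manifest so silent data loss is impossible.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  order_all <- c("simulate", "features", "compare", "classify", "regress")
  stages <- order_all[order_all %in% config$stages]
  mapping <- if (is.null(config$tagmap_path)) default_tag_mapping() else
    read_tag_mapping(config$tagmap_path)
  manifest <- list(seed = config$seed,
                   package = as.character(utils::packageVersion("speechmarker")),
                   stages = list())
  for (stage in stages) {
    outs <- stage_outputs(config, stage)
    if (config$resume && all(file.exists(outs))) {
      manifest$stages[[stage]] <- list(status = "skipped (outputs exist)",
                                       outputs = as.list(tools::md5sum(outs)))
      next
    }
    warnings_seen <- character()
    status <- "completed"
    withCallingHandlers(
      run_stage(stage, config, mapping),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    entry <- list(status = status, outputs = as.list(tools::md5sum(outs)))
    if (length(warnings_seen)) entry$warnings <- warnings_seen
    manifest$stages[[stage]] <- entry
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

run_stage <- function(stage, config, mapping) {
  od <- config$out_dir
  switch(stage,
    simulate = {
      syn <- generate_cohort(config$synthetic, seed = config$seed)
      dir.create(config$transcripts_dir, showWarnings = FALSE, recursive = TRUE)
      for (tr in syn$transcripts) {
        write_transcript(tr, file.path(config$transcripts_dir,
                                       paste0(tr$participant_id, ".json")))
      }
      write_lexicon(syn$lexicon$lexicon, config$lexicon_path)
      cohort_plain <- syn$cohort[, cohort_columns(), drop = FALSE]
      write_cohort(cohort_plain, config$cohort_path)
      truth <- planted_truth_targets(syn$config)
      utils::write.csv(truth, file.path(od, "truth.csv"), row.names = FALSE)
    },
    features = {
      if (!dir.exists(config$transcripts_dir)) {
        stop("missing transcripts at '", config$transcripts_dir,
             "': run the simulate stage first (or point transcripts_dir at your data)")
      }
      paths <- sort(list.files(config$transcripts_dir, pattern = "\\.json$",
                               full.names = TRUE))
      if (!length(paths)) stop("no transcript JSON files found")
      lex <- read_lexicon(config$lexicon_path)
      transcripts <- lapply(paths, read_transcript, mapping = mapping,
                            quiet = TRUE)
      feats <- extract_feature_table(transcripts, lex,
                                     long_pause_s = config$long_pause_s)
      write_feature_table(feats, file.path(od, "features.csv"))
    },
    compare = {
      merged <- merge_cohort_features(config)
      cmp <- compare_groups(merged)
      utils::write.csv(fmt_numeric_df(cmp), file.path(od, "comparison.csv"),
                       row.names = FALSE, quote = FALSE, na = "")
    },
    classify = {
      merged <- merge_cohort_features(config)
      report <- run_classification(merged, models = config$models,
                                   sets = config$sets,
                                   control = config$control,
                                   seed = config$seed)
      utils::write.csv(fmt_numeric_df(report$metrics),
                       file.path(od, "metrics.csv"), row.names = FALSE,
                       quote = FALSE, na = "")
      utils::write.csv(fmt_numeric_df(report$importance),
                       file.path(od, "importance.csv"), row.names = FALSE,
                       quote = FALSE, na = "")
      utils::write.csv(fmt_numeric_df(roc_points(report)),
                       file.path(od, "roc_points.csv"), row.names = FALSE,
                       quote = FALSE, na = "")
    },
    regress = {
      merged <- merge_cohort_features(config)
      rep <- run_regressions(merged, vif_threshold = config$vif_threshold,
                             seed = config$seed)
      rows <- do.call(rbind, lapply(rep$models, function(m) {
        co <- m$model$coefficients
        data.frame(outcome = m$outcome, term = co$term,
                   estimate = co$estimate, std_error = co$std_error,
                   p_value = co$p_value, r_squared = m$model$r_squared,
                   aic = m$model$aic, bic = m$model$bic, n = m$model$n)
      }))
      utils::write.csv(fmt_numeric_df(rows), file.path(od, "regression.csv"),
                       row.names = FALSE, quote = FALSE, na = "")
      writeLines(rep$retained, file.path(od, "vif_retained.txt"))
    })
  invisible(NULL)
}

## closed-form / calibrated part of the planted-truth table (fast enough for
## every pipeline run; the Monte-Carlo columns live in planted_truth())
planted_truth_targets <- function(cfg) {
  rows <- lapply(names(cfg$groups), function(g) {
    p <- cfg$groups[[g]]
    data.frame(group = g,
               quantity = c("MLU", "TTR", "LPR", "FR", "suvr_mean",
                            "hippocampus_mean", "U"),
               value = c(p$mlu_mean, p$ttr_target, p$lpr_target,
                         p$filler_rate / (1 + p$filler_rate), p$suvr_mean,
                         p$hippocampus_mean, p$utterances_per_image))
  })
  do.call(rbind, rows)
}

#' Per-repeat ROC points from a classification report
#'
#' @param report A `classification_report`.
#' @return Data frame of (set, model, repeat, FPR, TPR) step points.
#' @export
roc_points <- function(report) {
  rows <- lapply(report$runs, function(r) {
    if (is.null(r$test_scores)) return(NULL)
    ord <- order(-r$test_scores)
    lab <- r$test_labels[ord] == "early_AD"
    tpr <- cumsum(lab) / max(sum(lab), 1L)
    fpr <- cumsum(!lab) / max(sum(!lab), 1L)
    data.frame(set = r$set, model = r$model, repeat_id = r$repeat_id,
               FPR = c(0, fpr), TPR = c(0, tpr))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(set = character(), model = character(),
                                      repeat_id = integer(), FPR = numeric(),
                                      TPR = numeric())
  out
}
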