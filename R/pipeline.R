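# End-to-end orchestration: simulate/load -> preprocess -> extract ->
# select -> classify, with a serialized manifest so every run is
# reproducible from its output directory alone.

.default_config <- function() {
  list(
    seed = 1L,
    # input: either simulate = TRUE or a directory of WAVs + roster CSV
    simulate = TRUE, n_per_group = 5L, duration_s = 600,
    wav_dir = NULL, roster = NULL, hypnogram_dir = NULL,
    # preprocessing
    preprocess = TRUE, fft_ms = 32, hop_ms = 16, oversubtraction = 1,
    floor = 0.02, frac_quietest = 0.1, keep_stages = c("N2", "N3"),
    # features
    window_s = 5, frame_ms = 32, n_mfcc = 13L, lpc_order = 10L,
    calibration_offset = 0,
    # qTM
    qtm_frame_s = 1, silence_quantile = 0.15, high_quantile = 0.85,
    apnea_min_s = 20, apnea_max_s = 60,
    # selection
    alpha = 0.05, require_anova = TRUE, fdr = FALSE, top_k = NA,
    # classification
    classifier = "logistic", feature_set = "biomarker+qtm",
    task = "four_group", threshold = 15, folds = 10L,
    refit_selection = FALSE,
    save_qtm = TRUE, save_window_features = FALSE
  )
}

#' Build a run configuration
#'
#' Merges user overrides into the pipeline defaults; unknown keys are
#' rejected so typos never silently fall back to a default.
#'
#' @param ... named overrides (see [run_pipeline()] for semantics), or a
#'   single named list.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  base <- .default_config()
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("run_config: unknown key(s): ", paste(unknown, collapse = ", "))
  structure(utils::modifyList(base, over), class = "run_config")
}

#' Read a YAML or JSON run configuration file
#' @param path config file (`.yaml`/`.yml` or `.json`), flat keys.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_run_config: the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(cfg)
}

.stage_error <- function(stage, e) {
  stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)), call. = FALSE)
}

#' Run the full screening pipeline
#'
#' Executes simulate/load, preprocess, extract (+qTM), select and classify,
#' writing a deterministic artifact tree into `out_dir`: `features.csv`,
#' `qtm/<subject>.json`, `biomarker.json`, `report.json`, and
#' `manifest.json` (full config, seed and package version). Feature-set
#' choices: `"all"`, `"biomarker"`, `"biomarker+qtm"`, `"all+qtm"` (all
#' includes qTM columns already, so this equals all), `"topk"`
#' (SVM-ranked top `top_k`). Tasks: `"four_group"` or `"binary"` at
#' `threshold`.
#'
#' @param config a [run_config()] (or named list of overrides).
#' @param out_dir output directory (created if missing).
#' @param verbose log per-stage progress to stderr.
#' @return invisibly, a list with `features`, `biomarker`, `report`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, verbose = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  # ---- acquire + preprocess + extract ----
  extract_cfg <- config[c("frame_ms", "n_mfcc", "lpc_order",
                          "calibration_offset", "qtm_frame_s",
                          "silence_quantile", "high_quantile",
                          "apnea_min_s", "apnea_max_s", "fft_ms", "hop_ms",
                          "oversubtraction", "floor", "frac_quietest",
                          "keep_stages")]
  qtm_dir <- file.path(out_dir, "qtm")
  if (config$save_qtm) dir.create(qtm_dir, showWarnings = FALSE)

  acquire <- tryCatch({
    if (isTRUE(config$simulate)) {
      log_msg("stage simulate: %d/group x %gs", config$n_per_group,
              config$duration_s)
      cohort <- synth_cohort(config$n_per_group, config$duration_s,
                             config$seed)
      list(roster = cohort$roster,
           get = function(i) realize_subject(cohort, i))
    } else {
      roster <- read_roster(config$roster)
      list(roster = roster, get = function(i) {
        sid <- roster$subject_id[i]
        rec <- read_wav(file.path(config$wav_dir, paste0(sid, ".wav")), sid)
        hyp_path <- if (!is.null(config$hypnogram_dir))
          file.path(config$hypnogram_dir, paste0(sid, ".tsv")) else ""
        hyp <- if (nzchar(hyp_path) && file.exists(hyp_path))
          read_hypnogram(hyp_path) else NULL
        list(rec = rec, hyp = hyp, subject_id = sid)
      })
    }
  }, error = function(e) .stage_error("acquire", e))

  roster <- acquire$roster
  n <- nrow(roster)
  feats <- NULL
  for (i in seq_len(n)) {
    sub <- tryCatch(acquire$get(i), error = function(e) .stage_error("acquire", e))
    rec <- tryCatch({
      if (isTRUE(config$preprocess))
        preprocess_recording(sub$rec, sub$hyp, extract_cfg)
      else sub$rec
    }, error = function(e) .stage_error("preprocess", e))
    v <- tryCatch({
      vv <- extract_subject_features(rec, config$window_s, extract_cfg)
      if (config$save_qtm) {
        lev <- quantize_levels(rec, extract_cfg$qtm_frame_s,
                               extract_cfg$silence_quantile,
                               extract_cfg$high_quantile)
        lev <- mark_apnea_candidates(lev, extract_cfg$apnea_min_s,
                                     extract_cfg$apnea_max_s)
        write_qtm_json(transition_matrix(lev),
                       file.path(qtm_dir, paste0(sub$subject_id, ".json")))
      }
      vv
    }, error = function(e) .stage_error("extract", e))
    if (is.null(feats))
      feats <- matrix(NA_real_, n, length(v),
                      dimnames = list(roster$subject_id, names(v)))
    feats[i, ] <- v
    log_msg("stage extract: %s (%d/%d)", sub$subject_id, i, n)
  }
  utils::write.csv(data.frame(subject_id = rownames(feats), feats,
                              check.names = FALSE),
                   file.path(out_dir, "features.csv"), row.names = FALSE)

  # ---- select ----
  sel <- tryCatch({
    ds <- select_discriminators(feats, roster$severity_group,
                                alpha = config$alpha,
                                require_anova = config$require_anova,
                                fdr = config$fdr)
    bm <- suppressWarnings(assemble_biomarker(ds))
    jsonlite::write_json(list(biomarker = bm,
                              set_sizes = lapply(ds$sets, length)),
                         file.path(out_dir, "biomarker.json"),
                         auto_unbox = TRUE, digits = NA)
    list(ds = ds, bm = bm)
  }, error = function(e) .stage_error("select", e))
  log_msg("stage select: %d biomarker features", length(sel$bm))

  # ---- classify ----
  report <- tryCatch({
    labels <- if (config$task == "binary")
      make_binary_labels(roster, config$threshold)
    else roster$severity_group
    qtm_cols <- grep("^qtm_", colnames(feats), value = TRUE)
    subset <- switch(config$feature_set,
      "all" = , "all+qtm" = colnames(feats),
      "biomarker" = if (length(sel$bm)) sel$bm else colnames(feats),
      "biomarker+qtm" = unique(c(if (length(sel$bm)) sel$bm else
        colnames(feats), qtm_cols)),
      "topk" = {
        k <- if (is.na(config$top_k)) 50L else as.integer(config$top_k)
        svm_rank_features(feats, labels, k)$top
      },
      stop("unknown feature_set: ", config$feature_set))
    rep <- crossval_evaluate(feats, labels,
                             classifier_spec(config$classifier),
                             n_folds = config$folds, seed = config$seed,
                             feature_subset = subset,
                             refit_selection = config$refit_selection,
                             selection_alpha = config$alpha)
    out <- list(task = config$task, classifier = config$classifier,
                feature_set = config$feature_set,
                n_features = length(subset),
                accuracy = rep$accuracy, macro_auc = rep$macro_auc,
                per_class = rep$per_class,
                confusion = rep$confusion)
    jsonlite::write_json(out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor", dataframe = "rows")
    utils::write.csv(as.data.frame.matrix(rep$confusion),
                     file.path(out_dir, "confusion.csv"))
    rep
  }, error = function(e) .stage_error("classify", e))
  log_msg("stage classify: accuracy %.3f", report$accuracy)

  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("sdbscreen")),
    r_version = R.version.string,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(features = feats, biomarker = sel$bm, report = report,
                 out_dir = out_dir))
}

#' Re-run a pipeline from a saved manifest
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir output directory for the re-run.
#' @param verbose forwarded to [run_pipeline()].
#' @return as [run_pipeline()].
#' @export
rerun_manifest <- function(manifest_path, out_dir, verbose = FALSE) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  if (length(cfg$keep_stages) == 1L)
    cfg$keep_stages <- as.character(cfg$keep_stages)
  cfg <- cfg[!vapply(cfg, function(x) is.null(x) ||
                       (length(x) == 1L && is.na(x) && !is.numeric(x)),
                     logical(1))]
  run_pipeline(run_config(cfg), out_dir, verbose)
}
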