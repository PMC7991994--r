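# End-to-end orchestration: simulate -> extract -> preprocess -> evaluate,
# with a YAML-configurable run directory, input validation, manifest and
# cached-intermediate resumption.

#' Default pipeline configuration
#'
#' All analysis parameters are visible and overridable here; nested lists
#' are passed through to [cohort_spec()] and [cv_scheme()].
#'
#' @param seed Master seed for the whole run.
#' @param out_dir Run directory.
#' @param audio_dir Optional directory of existing WAV files (skips
#'   simulation); requires `metadata_csv`.
#' @param metadata_csv Metadata table for existing audio.
#' @param cohort Named list of [cohort_spec()] overrides for simulation runs.
#' @param n_pcs Number of leading principal components kept.
#' @param row_granularity `"utterance"` (default) or `"subject"`.
#' @param scheme Named list of [cv_scheme()] overrides.
#' @param thresholds Decision thresholds.
#' @param models,comparisons Grid to evaluate.
#' @param write_audio Write simulated WAVs to disk (default `FALSE`; the
#'   in-memory recordings are used either way).
#' @param resume Reuse `features.csv` from a previous run if present.
#' @return A named list (class `run_config`).
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("phonatory_run_"),
                       audio_dir = NULL, metadata_csv = NULL,
                       cohort = list(), n_pcs = 8,
                       row_granularity = c("utterance", "subject"),
                       scheme = list(), thresholds = c(0.5, 0.95),
                       models = phonatory_models(),
                       comparisons = phonatory_comparisons(),
                       write_audio = FALSE, resume = FALSE) {
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, audio_dir = audio_dir,
         metadata_csv = metadata_csv, cohort = cohort, n_pcs = n_pcs,
         row_granularity = match.arg(row_granularity), scheme = scheme,
         thresholds = thresholds, models = models, comparisons = comparisons,
         write_audio = write_audio, resume = resume),
    class = "run_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Validate an audio directory against its metadata
#'
#' Checks WAV readability and mono channel count, metadata completeness
#' (sex, age, group, vowel per file) and label vocabularies. Fatal problems
#' and non-fatal warnings are distinguished by the `level` column.
#'
#' @param audio_dir Directory containing `<subject_id>_<vowel>.wav` files.
#' @param metadata Metadata tibble or path to a CSV.
#' @return Tibble with columns `level` (`"fatal"`/`"warning"`), `item`,
#'   `message`; zero rows when everything checks out.
#' @export
validate_voice_inputs <- function(audio_dir, metadata) {
  if (is.character(metadata)) metadata <- readr::read_csv(metadata,
                                                          show_col_types = FALSE)
  probs <- list()
  note <- function(level, item, message) {
    probs[[length(probs) + 1L]] <<- tibble(level = level, item = item,
                                           message = message)
  }
  need <- c("subject_id", "vowel", "sex", "age_years", "group")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) {
    note("fatal", "metadata", paste("missing columns:",
                                    paste(miss, collapse = ", ")))
    return(bind_rows(probs))
  }
  for (i in seq_len(nrow(metadata))) {
    row <- metadata[i, ]
    item <- paste0(row$subject_id, "_", row$vowel)
    if (!row$vowel %in% c("a", "e", "i", "o", "u")) {
      note("fatal", item, paste("unknown vowel label:", row$vowel))
    }
    if (!row$sex %in% c("male", "female")) {
      note("fatal", item, paste("unknown sex label:", row$sex))
    }
    if (!row$group %in% c("C", "B", "NB")) {
      note("fatal", item, paste("unknown group label:", row$group))
    }
    if (is.na(row$age_years)) {
      note("fatal", item, "missing age (age correction impossible)")
    }
    f <- file.path(audio_dir, paste0(item, ".wav"))
    if (!file.exists(f)) {
      note("fatal", item, paste("missing file:", f))
    } else {
      wav <- tryCatch(read_wav(f), error = function(e) conditionMessage(e))
      if (is.character(wav)) note("fatal", item, wav)
      else if (length(wav$samples) < wav$sample_rate_hz * 0.5) {
        note("warning", item, "recording shorter than 0.5 s")
      }
    }
  }
  if (length(probs) == 0) {
    tibble(level = character(0), item = character(0), message = character(0))
  } else {
    bind_rows(probs)
  }
}

read_audio_dir <- function(audio_dir, metadata) {
  recs <- vector("list", nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    row <- metadata[i, ]
    f <- file.path(audio_dir, paste0(row$subject_id, "_", row$vowel, ".wav"))
    wav <- read_wav(f)
    recs[[i]] <- voice_recording(
      wav$samples, wav$sample_rate_hz, subject_id = row$subject_id,
      vowel = row$vowel, sex = row$sex, age_years = row$age_years,
      group = row$group
    )
  }
  recs
}

#' Run the full voice-analysis pipeline
#'
#' Executes simulate (unless `audio_dir` is given) -> extract -> preprocess
#' (impute apq11, age-correct, standardize, PCA, select PCs) -> evaluate,
#' writing `features.csv`, `scores.csv`, `pca_model.json`, biplot exports,
#' metrics tables, p-value matrices and a JSON run manifest into the run
#' directory. Deterministic for a fixed config.
#'
#' @param config A [run_config()].
#' @return List with the key intermediate objects and output paths,
#'   invisibly.
#' @export
run_voice_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "run.log")
  logit <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    message(line)
    cat(line, "\n", file = log_file, append = TRUE)
  }

  features_csv <- file.path(config$out_dir, "features.csv")
  if (config$resume && file.exists(features_csv)) {
    logit("resume: reading cached %s", features_csv)
    features <- readr::read_csv(features_csv, show_col_types = FALSE)
    metadata <- distinct(features[, c("subject_id", "sex", "age_years",
                                      "group")])
  } else if (!is.null(config$audio_dir)) {
    logit("extract: reading WAVs from %s", config$audio_dir)
    metadata <- readr::read_csv(config$metadata_csv, show_col_types = FALSE)
    report <- validate_voice_inputs(config$audio_dir, metadata)
    if (any(report$level == "fatal")) {
      abort(paste("input validation failed:",
                  paste(report$message[report$level == "fatal"],
                        collapse = "; ")))
    }
    recs <- read_audio_dir(config$audio_dir, metadata)
    features <- extract_cohort_features(recs)
    write_feature_csv(features, features_csv)
  } else {
    logit("simulate: generating synthetic cohort (seed %d)", config$seed)
    spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
    cohort <- generate_cohort(spec)
    metadata <- cohort$metadata
    if (config$write_audio) {
      audio_dir <- file.path(config$out_dir, "audio")
      dir.create(audio_dir, showWarnings = FALSE)
      for (rec in cohort$recordings) {
        write_wav(rec, file.path(audio_dir, paste0(rec$subject_id, "_",
                                                   rec$vowel, ".wav")))
      }
      readr::write_csv(metadata, file.path(config$out_dir, "metadata.csv"))
    }
    logit("extract: %d recordings", length(cohort$recordings))
    features <- extract_cohort_features(cohort)
    write_feature_csv(features, features_csv)
  }

  logit("preprocess: impute, age-correct, standardize, PCA")
  table <- build_feature_table(features, metadata)
  non_apq <- setdiff(phonatory_feature_names, "shimmer_apq11_pct")
  bad <- !complete.cases(table[, non_apq])
  if (any(bad)) {
    logit("dropping %d rows with undefined non-apq11 features", sum(bad))
    table <- table[!bad, ]
  }
  table <- impute_apq11(table)
  logit("imputed %d shimmer(apq11) cells", attr(table, "n_imputed") %||% 0)
  if (config$row_granularity == "subject") {
    table <- aggregate_by_subject(table)
    table$vowel <- "all"
  }
  age_model <- fit_age_correction(table)
  table <- remove_age_effects(table, age_model)
  std <- standardize_features(table)
  pca <- pca_svd(std$table)
  scores <- select_pcs(pca, config$n_pcs)
  logit("PCA: first %d PCs explain %.1f%% of the variance", config$n_pcs,
        100 * attr(scores, "cumulative_variance"))
  readr::write_csv(scores, file.path(config$out_dir, "scores.csv"))
  write_pca_json(pca, age_model, std$params,
                 file.path(config$out_dir, "pca_model.json"))
  bp <- biplot_export(pca)
  readr::write_csv(bp$scores, file.path(config$out_dir, "biplot_scores.csv"))
  readr::write_csv(bp$loadings,
                   file.path(config$out_dir, "biplot_loadings.csv"))

  logit("evaluate: %d models x %d comparisons, %d x %d-fold CV",
        length(config$models), length(config$comparisons),
        config$scheme$trials %||% 10, config$scheme$k %||% 10)
  scheme <- do.call(cv_scheme, c(config$scheme, list(seed = config$seed)))
  results <- evaluate_models(scores, config$comparisons, config$models,
                             scheme, config$thresholds)
  cfg_hash <- substr(hash(config), 1, 8)
  tables <- results_report(results, config$models, config$comparisons,
                           config$thresholds, out_dir = config$out_dir,
                           seed = config$seed, n_pcs = config$n_pcs,
                           config_hash = cfg_hash)
  pvals <- list()
  if (length(config$models) >= 2) {
    for (cmp in config$comparisons) {
      for (thr in config$thresholds) {
        pv <- compare_models(results, cmp, thr)
        pv$comparison <- cmp
        pv$threshold <- thr
        pvals[[paste(cmp, thr)]] <- pv
      }
    }
    readr::write_csv(bind_rows(pvals),
                     file.path(config$out_dir, "model_comparisons.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phonatory")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    config_hash = cfg_hash,
    n_recordings = nrow(features),
    n_rows_analysed = nrow(table),
    cumulative_variance_at_k = attr(scores, "cumulative_variance")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  logit("done: %s", config$out_dir)

  invisible(list(
    out_dir = config$out_dir, features = features, table = table,
    age_model = age_model, pca = pca, scores = scores, results = results,
    tables = tables, comparisons_tests = if (length(pvals)) bind_rows(pvals),
    manifest = manifest
  ))
}
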