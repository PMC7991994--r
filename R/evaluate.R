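# Repeated 10-fold cross-validation with training-fold upsampling at two
# decision thresholds, plus paired Bonferroni-corrected model comparisons
# and report assembly.

#' Cross-validation scheme
#'
#' @param k Number of folds (default 10).
#' @param trials Number of repetitions, each starting with a fresh random
#'   permutation of the rows (default 10).
#' @param seed Integer seed controlling permutations, upsampling and model
#'   fits.
#' @param upsample Balance training folds by minority upsampling with
#'   replacement (default `TRUE`).
#' @param group_by_subject Partition subjects instead of utterance rows, so
#'   no subject contributes rows to both a training and its test fold
#'   (default `FALSE`, matching per-utterance folding; the grouped mode
#'   avoids within-subject leakage at the cost of fidelity to that
#'   procedure).
#' @return Object of class `cv_scheme`.
#' @export
cv_scheme <- function(k = 10, trials = 10, seed = 1L, upsample = TRUE,
                      group_by_subject = FALSE) {
  if (k < 2) abort("k must be at least 2")
  if (trials < 1) abort("trials must be at least 1")
  structure(list(k = k, trials = trials, seed = as.integer(seed),
                 upsample = upsample, group_by_subject = group_by_subject),
            class = "cv_scheme")
}

# contiguous chunks of near-equal size over a permuted index
chunk_ids <- function(n, k) {
  bounds <- round(seq(0, n, length.out = k + 1))
  rep(seq_len(k), diff(bounds))
}

# one fold-assignment vector per trial; identical across models so that
# paired tests compare classifiers on the same partitions
make_partitions <- function(data, scheme) {
  n <- nrow(data)
  with_seed(scheme$seed, {
    lapply(seq_len(scheme$trials), function(trial) {
      if (scheme$group_by_subject) {
        subj <- unique(data$subject_id)
        perm <- sample(subj)
        sf <- chunk_ids(length(subj), scheme$k)
        sf[match(data$subject_id, perm)]
      } else {
        fold <- integer(n)
        fold[sample.int(n)] <- chunk_ids(n, scheme$k)
        fold
      }
    })
  })
}

#' Evaluate one classifier by repeated k-fold cross-validation
#'
#' For each trial the rows are permuted (seeded) and split into `k`
#' contiguous chunks; each chunk in turn is held out for testing while the
#' model is trained on the remaining chunks, upsampled to equal class
#' counts. Probabilities are scored once per fold and dichotomized at every
#' threshold.
#'
#' @param data Labelled dataset from [make_binary_dataset()].
#' @param model One of [phonatory_models()].
#' @param scheme A [cv_scheme()].
#' @param thresholds Decision thresholds (default `c(0.5, 0.95)`).
#' @param partitions Optional precomputed partitions (internal; used to share
#'   fold assignments across models).
#' @return A `phonatory_evaluation` tibble: one row per
#'   (threshold, trial, fold) with confusion counts and metrics.
#' @export
repeated_kfold_evaluate <- function(data, model, scheme = cv_scheme(),
                                    thresholds = c(0.5, 0.95),
                                    partitions = NULL) {
  partitions <- partitions %||% make_partitions(data, scheme)
  model_idx <- match(model, phonatory_models())
  rows <- vector("list", scheme$trials * scheme$k * length(thresholds))
  ri <- 0L
  for (trial in seq_len(scheme$trials)) {
    fold_id <- partitions[[trial]]
    for (fold in seq_len(scheme$k)) {
      test <- data[fold_id == fold, , drop = FALSE]
      train <- data[fold_id != fold, , drop = FALSE]
      if (nrow(test) == 0) next
      if (length(unique(train$.label)) < 2) {
        abort(sprintf("%s trial %d fold %d: training fold has a single class",
                      model, trial, fold))
      }
      if (scheme$upsample) {
        train <- upsample_training(
          train, seed = derive_seed(scheme$seed, trial * 1000L + fold))
      }
      fit <- fit_model(model, train,
                       seed = derive_seed(scheme$seed,
                                          model_idx * 100000L +
                                            trial * 1000L + fold))
      p <- predict(fit, test)
      for (thr in thresholds) {
        counts <- confusion_counts(test$.label, apply_threshold(p, thr))
        ri <- ri + 1L
        rows[[ri]] <- bind_cols(
          tibble(model = model, threshold = thr, trial = trial, fold = fold),
          counts, confusion_metrics(counts)
        )
      }
    }
  }
  out <- bind_rows(rows[seq_len(ri)])
  attr(out, "scheme") <- scheme
  class(out) <- c("phonatory_evaluation", class(out))
  out
}

#' Evaluate the full model x comparison grid
#'
#' Runs [repeated_kfold_evaluate()] for every requested model on every
#' requested comparison, sharing fold partitions across models within a
#' comparison so that paired tests are valid.
#'
#' @param scores Score table from [select_pcs()] (needs a `group` column).
#' @param comparisons Subset of [phonatory_comparisons()].
#' @param models Subset of [phonatory_models()].
#' @param scheme A [cv_scheme()].
#' @param thresholds Decision thresholds.
#' @param progress Print one line per (comparison, model).
#' @return A `phonatory_evaluation` tibble with a `comparison` column.
#' @export
evaluate_models <- function(scores, comparisons = phonatory_comparisons(),
                            models = phonatory_models(),
                            scheme = cv_scheme(), thresholds = c(0.5, 0.95),
                            progress = FALSE) {
  out <- list()
  for (cmp in comparisons) {
    d <- make_binary_dataset(scores, cmp)
    partitions <- make_partitions(d, scheme)
    for (m in models) {
      if (progress) message(sprintf("evaluating %s on %s", m, cmp))
      res <- repeated_kfold_evaluate(d, m, scheme, thresholds, partitions)
      res$comparison <- cmp
      out[[paste(cmp, m)]] <- res
    }
  }
  res <- bind_rows(out) |>
    select(all_of("comparison"), everything())
  attr(res, "scheme") <- scheme
  class(res) <- c("phonatory_evaluation", class(res))
  res
}

#' Aggregate fold-level metrics
#'
#' Mean of the fold-level accuracy/sensitivity/specificity per
#' (comparison, model, threshold) cell; folds whose sensitivity or
#' specificity is undefined (no positive / negative test rows) are excluded
#' from that metric's mean and counted.
#'
#' @param results A `phonatory_evaluation`.
#' @return Tibble with one row per cell.
#' @export
summarize_evaluation <- function(results) {
  grp <- intersect(c("comparison", "model", "threshold"), names(results))
  results |>
    as_tibble() |>
    group_by(across(all_of(grp))) |>
    summarise(
      n_folds = n(),
      accuracy = mean(.data$accuracy),
      sensitivity = mean(.data$sensitivity, na.rm = TRUE),
      specificity = mean(.data$specificity, na.rm = TRUE),
      n_undefined_sensitivity = sum(is.na(.data$sensitivity)),
      n_undefined_specificity = sum(is.na(.data$specificity)),
      .groups = "drop"
    )
}

#' @exportS3Method generics::tidy
tidy.phonatory_evaluation <- function(x, ...) summarize_evaluation(x)

#' @exportS3Method generics::glance
glance.phonatory_evaluation <- function(x, ...) {
  s <- summarize_evaluation(x)
  if (!"comparison" %in% names(s)) s$comparison <- "all"
  tibble(
    n_cells = nrow(s),
    n_fold_evaluations = nrow(x),
    best_accuracy = max(s$accuracy),
    best_cell = paste(s$comparison[which.max(s$accuracy)],
                      s$model[which.max(s$accuracy)],
                      s$threshold[which.max(s$accuracy)])
  )
}

#' Paired Bonferroni-corrected comparisons between classifiers
#'
#' Paired Student t tests on the fold-level metric vectors of every model
#' pair within one (comparison, threshold) cell, evaluated on identical
#' fold partitions. P values are multiplied by the number of pairs (15 for
#' six models) and capped at 1; a pair is significant when the corrected
#' value falls below `alpha`. Pairs with a zero-variance difference vector
#' are reported as `p = 1` with a degenerate flag.
#'
#' @param results A `phonatory_evaluation` (from [evaluate_models()]).
#' @param comparison,threshold The cell to test.
#' @param metric Fold-level metric to compare (default accuracy).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per model pair.
#' @export
compare_models <- function(results, comparison = NULL, threshold = 0.5,
                           metric = "accuracy", alpha = 0.05) {
  d <- as_tibble(results)
  if (!is.null(comparison) && "comparison" %in% names(d)) {
    d <- d[d$comparison == comparison, ]
  }
  d <- d[d$threshold == threshold, ]
  models <- sort(unique(d$model))
  if (length(models) < 2) abort("need at least two models to compare")
  wide <- d |>
    arrange(.data$model, .data$trial, .data$fold) |>
    select(all_of(c("model", "trial", "fold", metric))) |>
    tidyr::pivot_wider(names_from = "model", values_from = all_of(metric))
  pairs <- utils::combn(models, 2, simplify = FALSE)
  res <- map_dfr(pairs, function(pr) {
    a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
    diff <- a - b
    if (sd(diff) == 0 || all(is.na(diff))) {
      tibble(model1 = pr[1], model2 = pr[2], mean_difference = mean(diff),
             p_value = 1, degenerate = TRUE)
    } else {
      tt <- t.test(a, b, paired = TRUE)
      tibble(model1 = pr[1], model2 = pr[2], mean_difference = mean(diff),
             p_value = tt$p.value, degenerate = FALSE)
    }
  })
  res$p_adjusted <- pmin(1, res$p_value * length(pairs))
  res$significant <- res$p_adjusted < alpha
  res
}

#' Assemble the performance report tables
#'
#' Builds one wide table per decision threshold with accuracy, sensitivity
#' and specificity (in %) per model and comparison, verifying first that the
#' full model x comparison x threshold grid is present.
#'
#' @param results A `phonatory_evaluation` from [evaluate_models()].
#' @param models,comparisons,thresholds The expected grid.
#' @param out_dir Optional directory to write `metrics_threshold_*.csv` and
#'   a human-readable `metrics.txt`.
#' @param seed,n_pcs,config_hash Provenance fields embedded in the report.
#' @return List of wide tibbles keyed by threshold, invisibly when writing.
#' @export
results_report <- function(results, models = phonatory_models(),
                           comparisons = phonatory_comparisons(),
                           thresholds = c(0.5, 0.95), out_dir = NULL,
                           seed = NA_integer_, n_pcs = NA_integer_,
                           config_hash = NA_character_) {
  s <- summarize_evaluation(results)
  expected <- tidyr::crossing(comparison = comparisons, model = models,
                              threshold = thresholds)
  missing <- anti_join(expected, s,
                       by = c("comparison", "model", "threshold"))
  if (nrow(missing) > 0) {
    abort(paste("missing grid cells:",
                paste(paste(missing$comparison, missing$model,
                            missing$threshold), collapse = "; ")))
  }
  tables <- lapply(thresholds, function(thr) {
    s |>
      filter(.data$threshold == thr, .data$model %in% models,
             .data$comparison %in% comparisons) |>
      select(all_of(c("model", "comparison", "accuracy", "sensitivity",
                      "specificity"))) |>
      tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity"),
                          names_to = "metric") |>
      mutate(value = round(.data$value, 1)) |>
      tidyr::pivot_wider(names_from = "comparison", values_from = "value") |>
      arrange(match(.data$model, models))
  })
  names(tables) <- paste0("threshold_", format(100 * thresholds), "pct")
  attr(tables, "provenance") <- list(seed = seed, n_pcs = n_pcs,
                                     config_hash = config_hash)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      readr::write_csv(tables[[nm]], file.path(out_dir,
                                               paste0("metrics_", nm, ".csv")))
    }
    txt <- c(sprintf("Classification performance (%%); seed %s, %s PCs, config %s",
                     seed, n_pcs, config_hash))
    for (nm in names(tables)) {
      txt <- c(txt, "", nm,
               utils::capture.output(as.data.frame(tables[[nm]])))
    }
    writeLines(txt, file.path(out_dir, "metrics.txt"))
    return(invisible(tables))
  }
  tables
}
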