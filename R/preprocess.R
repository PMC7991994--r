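# Cohort preprocessing: feature-table assembly, the apq11 imputation rule,
# control-fitted age correction, standardization, and PCA via SVD.

#' Assemble the cohort feature table
#'
#' Joins per-utterance feature rows with the subject metadata. Row
#' granularity is one utterance (subject x vowel).
#'
#' @param features Tibble with `subject_id`, `vowel` and the 15 feature
#'   columns (per-utterance).
#' @param metadata Tibble with one row per subject (or per utterance)
#'   carrying `subject_id`, `sex`, `age_years`, `group`.
#' @return Tibble with metadata and feature columns, one row per utterance.
#' @export
build_feature_table <- function(features, metadata) {
  miss <- setdiff(phonatory_feature_names, names(features))
  if (length(miss) > 0) {
    abort(paste("missing feature columns:", paste(miss, collapse = ", ")))
  }
  meta <- distinct(metadata[, intersect(
    c("subject_id", "sex", "age_years", "group"), names(metadata))])
  orphans <- setdiff(unique(features$subject_id), meta$subject_id)
  if (length(orphans) > 0) {
    abort(paste("feature rows with no metadata subject:",
                paste(orphans, collapse = ", ")))
  }
  dup <- features |> count(.data$subject_id, .data$vowel) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste("duplicated (subject, vowel) rows:",
                paste(paste(dup$subject_id, dup$vowel), collapse = ", ")))
  }
  n_vowel <- features |> count(.data$subject_id)
  short <- n_vowel$subject_id[n_vowel$n < max(n_vowel$n)]
  if (length(short) > 0) {
    warn(paste("subjects with missing vowels:", paste(short, collapse = ", ")))
  }
  features |>
    select(-any_of(c("sex", "age_years", "group"))) |>
    left_join(meta, by = "subject_id") |>
    select(all_of(c("subject_id", "vowel", "sex", "age_years", "group")),
           all_of(phonatory_feature_names))
}

#' Impute undefined shimmer(apq11) values within subject
#'
#' Each undefined `shimmer_apq11_pct` cell is replaced by the mean of the
#' same subject's defined apq11 values across the other vowels. No other
#' feature is ever imputed.
#'
#' @param table Feature table from [build_feature_table()].
#' @return The table with apq11 imputed; number of imputed cells in
#'   attribute `n_imputed`.
#' @export
impute_apq11 <- function(table) {
  v <- table$shimmer_apq11_pct
  na_idx <- which(is.na(v))
  for (i in na_idx) {
    same <- table$subject_id == table$subject_id[i]
    others <- v[same & !is.na(v)]
    if (length(others) == 0) {
      abort(paste0("subject ", table$subject_id[i],
                   ": shimmer(apq11) undefined for every vowel, no ",
                   "imputation rule applies"))
    }
    table$shimmer_apq11_pct[i] <- mean(others)
  }
  attr(table, "n_imputed") <- length(na_idx)
  table
}

#' Fit the normal-aging correction on control subjects
#'
#' Per feature, ordinary least-squares slope of the feature against age,
#' fitted exclusively on control (group C) rows.
#'
#' @param table Feature table.
#' @param features Feature columns to fit (default all 15).
#' @return Object of class `age_correction` with a slope per feature.
#' @export
fit_age_correction <- function(table, features = phonatory_feature_names) {
  ctrl <- filter(table, .data$group == "C")
  ages <- ctrl$age_years[!is.na(ctrl$age_years)]
  if (nrow(ctrl) < 3) abort("need at least 3 control rows")
  if (length(unique(ages)) < 2) abort("control ages are degenerate (all equal)")
  fits <- map_dfr(features, function(f) {
    d <- ctrl[!is.na(ctrl[[f]]) & !is.na(ctrl$age_years), ]
    m <- lm(d[[f]] ~ d$age_years)
    tibble(feature = f, slope = unname(coef(m)[2]),
           intercept = unname(coef(m)[1]), n = nrow(d))
  })
  structure(list(slopes = fits), class = "age_correction")
}

#' @export
print.age_correction <- function(x, ...) {
  cat("<age_correction> per-feature normal-aging slopes (control-fitted)\n")
  print(x$slopes)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.age_correction <- function(x, ...) x$slopes

#' Remove normal-aging effects from all rows
#'
#' Subtracts `slope * age` from each feature of every row (all groups), using
#' the control-fitted slopes.
#'
#' @param table Feature table.
#' @param model An `age_correction` from [fit_age_correction()].
#' @return The corrected table.
#' @export
remove_age_effects <- function(table, model) {
  stopifnot(inherits(model, "age_correction"))
  for (i in seq_len(nrow(model$slopes))) {
    f <- model$slopes$feature[i]
    table[[f]] <- table[[f]] - model$slopes$slope[i] * table$age_years
  }
  table
}

#' Zero-centre and scale the feature columns
#'
#' Applies `(x - mean) / sd` per feature (sample SD, n - 1 denominator), so
#' every feature column has mean 0 and SD 1 afterwards.
#'
#' @param table Feature table.
#' @param features Feature columns to standardize.
#' @param params Optional previously fitted parameter tibble
#'   (`feature`, `mean`, `sd`) to apply instead of refitting.
#' @return List with `table` (standardized) and `params`.
#' @export
standardize_features <- function(table, features = phonatory_feature_names,
                                 params = NULL) {
  if (is.null(params)) {
    params <- map_dfr(features, function(f) {
      s <- sample_sd(table[[f]])
      if (is.na(s) || s == 0) {
        abort(paste0("feature '", f, "' has zero variance; cannot standardize"))
      }
      tibble(feature = f, mean = mean(table[[f]], na.rm = TRUE), sd = s)
    })
  }
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    table[[f]] <- (table[[f]] - params$mean[i]) / params$sd[i]
  }
  list(table = table, params = params)
}

#' Principal component analysis via singular value decomposition
#'
#' Thin SVD `X = U S V'` of the standardized feature matrix. Scores are
#' `U S` (equivalently `X V`); the explained-variance fraction of component
#' i is `s_i^2 / sum(s_j^2)`; per-component SDs are `s_i / sqrt(n - 1)` so
#' the total PC variance equals the total feature variance. The sign of each
#' loading vector is fixed by making its largest-magnitude entry positive.
#'
#' @param table Standardized feature table (the `table` element of
#'   [standardize_features()]).
#' @param features Feature columns entering the decomposition.
#' @return Object of class `phonatory_pca` with loadings, scores (with row
#'   metadata carried through), singular values and variance profile.
#' @export
pca_svd <- function(table, features = phonatory_feature_names) {
  X <- as.matrix(table[, features])
  if (anyNA(X)) abort("feature matrix contains undefined values; impute first")
  n <- nrow(X)
  sv <- svd(X)
  # sign convention: largest-|.| entry of each loading positive
  for (j in seq_len(ncol(sv$v))) {
    k <- which.max(abs(sv$v[, j]))
    if (sv$v[k, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(sv$v) <- features
  colnames(sv$v) <- paste0("PC", seq_len(ncol(sv$v)))
  meta_cols <- setdiff(names(table), features)
  explained <- sv$d^2 / sum(sv$d^2)
  structure(
    list(
      loadings = sv$v,
      singular_values = sv$d,
      sdev = sv$d / sqrt(n - 1),
      explained_variance = explained,
      cumulative_variance = cumsum(explained),
      scores = bind_cols(table[, meta_cols], as_tibble(scores)),
      features = features,
      n = n
    ),
    class = "phonatory_pca"
  )
}

#' @export
print.phonatory_pca <- function(x, ...) {
  cat(sprintf("<phonatory_pca> %d rows x %d features\n", x$n,
              length(x$features)))
  cat("cumulative explained variance (%):\n")
  print(round(100 * x$cumulative_variance, 1))
  invisible(x)
}

#' @describeIn pca_svd Tidy the PCA: `matrix = "variance"` (per-PC explained
#'   variance), `"loadings"` (long loadings) or `"scores"`.
#' @param x A `phonatory_pca`.
#' @param matrix Which component to tidy.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.phonatory_pca <- function(x, matrix = c("variance", "loadings", "scores"),
                               ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    variance = tibble(
      component = seq_along(x$singular_values),
      singular_value = x$singular_values,
      sdev = x$sdev,
      explained_variance = x$explained_variance,
      cumulative_variance = x$cumulative_variance
    ),
    loadings = as_tibble(x$loadings, rownames = "feature") |>
      tidyr::pivot_longer(-"feature", names_to = "component",
                          values_to = "loading"),
    scores = x$scores
  )
}

#' @describeIn pca_svd One-row summary: dimensions and variance captured by
#'   the first two and first eight components.
#' @exportS3Method generics::glance
glance.phonatory_pca <- function(x, ...) {
  k2 <- min(2, length(x$cumulative_variance))
  k8 <- min(8, length(x$cumulative_variance))
  tibble(
    n_rows = x$n,
    n_features = length(x$features),
    variance_pc2_pct = 100 * x$cumulative_variance[k2],
    variance_pc8_pct = 100 * x$cumulative_variance[k8]
  )
}

#' Select the leading principal components
#'
#' @param model A `phonatory_pca`.
#' @param k Number of leading components to keep (default 8).
#' @return Tibble with the row metadata and the first `k` score columns;
#'   cumulative explained variance at `k` in attribute
#'   `cumulative_variance`.
#' @export
select_pcs <- function(model, k = 8) {
  stopifnot(inherits(model, "phonatory_pca"))
  p <- length(model$singular_values)
  if (k < 1 || k > p) abort(paste0("k must lie in 1..", p))
  meta_cols <- setdiff(names(model$scores), paste0("PC", seq_len(p)))
  out <- model$scores[, c(meta_cols, paste0("PC", seq_len(k)))]
  attr(out, "cumulative_variance") <- model$cumulative_variance[k]
  out
}

#' Export biplot data (first two components)
#'
#' Numeric export sufficient to draw a PC1/PC2 biplot: per-row scores with
#' group labels, per-feature loading vectors, and the variance shares of the
#' two dimensions.
#'
#' @param model A `phonatory_pca`.
#' @return List with `scores`, `loadings` and `variance_share` (fractions
#'   for Dim1/Dim2).
#' @export
biplot_export <- function(model) {
  stopifnot(inherits(model, "phonatory_pca"))
  meta_cols <- setdiff(names(model$scores),
                       paste0("PC", seq_along(model$singular_values)))
  scores <- model$scores[, c(meta_cols, "PC1", "PC2")]
  names(scores)[names(scores) == "PC1"] <- "Dim1"
  names(scores)[names(scores) == "PC2"] <- "Dim2"
  loadings <- tibble(
    feature = rownames(model$loadings),
    Dim1 = model$loadings[, 1],
    Dim2 = model$loadings[, 2]
  )
  list(
    scores = scores,
    loadings = loadings,
    variance_share = c(Dim1 = model$explained_variance[1],
                       Dim2 = model$explained_variance[2])
  )
}

#' Average the feature table to one row per subject
#'
#' Alternative row granularity: per-subject means of each feature across
#' vowels (undefined cells ignored).
#'
#' @param table Feature table.
#' @return Tibble with one row per subject.
#' @export
aggregate_by_subject <- function(table) {
  table |>
    group_by(.data$subject_id, .data$sex, .data$age_years, .data$group) |>
    summarise(across(all_of(phonatory_feature_names),
                     ~ mean(.x, na.rm = TRUE)), .groups = "drop")
}

#' Serialize preprocessing and PCA parameters to JSON
#'
#' @param pca A `phonatory_pca`.
#' @param age_model An `age_correction`.
#' @param params Standardization parameter tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pca_json <- function(pca, age_model, params, path) {
  obj <- list(
    age_slopes = age_model$slopes,
    standardization = params,
    singular_values = pca$singular_values,
    explained_variance = pca$explained_variance,
    loadings = as.data.frame(pca$loadings)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
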