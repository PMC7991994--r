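# The six supervised classifiers evaluated on the selected principal
# components, each exposed as a fitted scorer returning positive-class
# probabilities. Hyperparameter searches are fixed: the SVM cost is tuned
# over {1e-4, 5e-4, 1e-3, 1e-2, 0.1, 1} by inner cross-validation, the
# random forest mtry over {2, 5, 8} by out-of-bag error.

#' The four group comparisons
#'
#' @return Character vector of the comparison names.
#' @export
phonatory_comparisons <- function() {
  c("C_vs_B", "C_vs_NB", "B_vs_NB", "C_vs_ALS")
}

#' The six classifier names
#'
#' @return Character vector: random forest (`rf`), naive Bayes (`nab`),
#'   logistic regression (`lr`), linear discriminant analysis (`lda`),
#'   neural network (`nn`), support vector machine (`svm`).
#' @export
phonatory_models <- function() {
  c("rf", "nab", "lr", "lda", "nn", "svm")
}

comparison_def <- function(name) {
  switch(name,
    C_vs_B = list(keep = c("C", "B"), positive = "B"),
    C_vs_NB = list(keep = c("C", "NB"), positive = "NB"),
    B_vs_NB = list(keep = c("B", "NB"), positive = "B"),
    C_vs_ALS = list(keep = c("C", "B", "NB"), positive = "ALS"),
    abort(paste0("unknown comparison '", name, "'"))
  )
}

#' Restrict a score table to one binary comparison
#'
#' Keeps the rows of the two classes and adds a `.label` factor with levels
#' `neg`/`pos`. For `C_vs_ALS` all rows are kept and both B and NB are
#' relabelled as the positive ALS class.
#'
#' @param scores Score table (from [select_pcs()]) with a `group` column.
#' @param comparison One of [phonatory_comparisons()].
#' @return The labelled dataset.
#' @export
make_binary_dataset <- function(scores, comparison) {
  def <- comparison_def(comparison)
  d <- filter(scores, .data$group %in% def$keep)
  pos <- if (def$positive == "ALS") {
    d$group %in% c("B", "NB")
  } else {
    d$group == def$positive
  }
  d$.label <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
  if (any(table(d$.label) == 0)) {
    abort(paste0(comparison, ": a class has zero rows"))
  }
  d
}

#' Upsample the minority class with replacement
#'
#' Resamples minority-class rows with replacement until the class counts are
#' equal. Meant for training folds only; test data are never resampled.
#'
#' @param data Labelled dataset with a `.label` column.
#' @param seed Optional RNG seed for a deterministic resample.
#' @return The balanced dataset.
#' @export
upsample_training <- function(data, seed = NULL) {
  tab <- table(data$.label)
  if (any(tab == 0)) abort("training data contain a single class")
  if (length(unique(tab)) == 1) return(data)
  minority <- names(tab)[which.min(tab)]
  need <- max(tab) - min(tab)
  idx <- which(data$.label == minority)
  pick <- function() sample(idx, need, replace = TRUE)
  extra <- if (is.null(seed)) pick() else with_seed(seed, pick())
  bind_rows(data, data[extra, ])
}

pc_matrix <- function(data) {
  as.matrix(data[, grep("^PC", names(data)), drop = FALSE])
}

# --- tanh multilayer perceptron (1 hidden layer), trained by full-batch
# backpropagation with a bold-driver adaptive learning rate ---------------
mlp_tanh_fit <- function(X, y01, hidden = 3, epochs = 500, lr = 0.05,
                         l2 = 1e-4) {
  n <- nrow(X); p <- ncol(X)
  W1 <- matrix(rnorm((p + 1) * hidden, 0, 0.5), p + 1, hidden)
  W2 <- matrix(rnorm(hidden + 1, 0, 0.5), hidden + 1, 1)
  Xb <- cbind(1, X)
  forward <- function(W1, W2) {
    H <- tanh(Xb %*% W1)
    Hb <- cbind(1, H)
    list(H = H, Hb = Hb, p = plogis(Hb %*% W2))
  }
  loss_of <- function(fw, W1, W2) {
    eps <- 1e-12
    -mean(y01 * log(fw$p + eps) + (1 - y01) * log(1 - fw$p + eps)) +
      l2 * (sum(W1^2) + sum(W2^2))
  }
  fw <- forward(W1, W2)
  loss <- loss_of(fw, W1, W2)
  stall <- 0
  for (e in seq_len(epochs)) {
    delta_out <- (fw$p - y01) / n                       # d loss / d logits
    g2 <- t(fw$Hb) %*% delta_out + 2 * l2 * W2
    delta_h <- (delta_out %*% t(W2[-1, , drop = FALSE])) * (1 - fw$H^2)
    g1 <- t(Xb) %*% delta_h + 2 * l2 * W1
    W1n <- W1 - lr * g1
    W2n <- W2 - lr * g2
    fwn <- forward(W1n, W2n)
    lossn <- loss_of(fwn, W1n, W2n)
    if (is.finite(lossn) && lossn <= loss) {
      if (loss - lossn < 1e-9) stall <- stall + 1 else stall <- 0
      W1 <- W1n; W2 <- W2n; fw <- fwn; loss <- lossn
      lr <- lr * 1.05
    } else {
      lr <- lr * 0.5
      stall <- stall + 1
      if (lr < 1e-8) break
    }
    if (stall >= 25) break
  }
  list(W1 = W1, W2 = W2)
}

mlp_tanh_predict <- function(fit, X) {
  H <- tanh(cbind(1, X) %*% fit$W1)
  as.numeric(plogis(cbind(1, H) %*% fit$W2))
}

svm_c_grid <- c(0.0001, 0.0005, 0.001, 0.01, 0.1, 1)

tune_svm_cost <- function(X, y, folds = 3) {
  n <- nrow(X)
  fold_id <- rep_len(seq_len(folds), n)[sample.int(n)]
  acc <- vapply(svm_c_grid, function(C) {
    correct <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      m <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = C, scale = FALSE)
      correct <- correct + sum(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / n
  }, numeric(1))
  if (all(is.na(acc))) return(1)
  best <- max(acc, na.rm = TRUE)
  # ties resolved towards the largest cost
  max(svm_c_grid[!is.na(acc) & acc >= best - 1e-12])
}

rf_mtry_grid <- function(p) unique(pmin(c(2, 5, 8), p))

#' Fit one of the six classifiers
#'
#' Fits the named model on a balanced training set whose predictors are the
#' selected principal components, returning a scorer that produces
#' positive-class probabilities. Inner hyperparameter tuning (SVM cost by
#' 3-fold cross-validation, random-forest mtry by out-of-bag error) happens
#' inside the training data only.
#'
#' @param model One of [phonatory_models()].
#' @param data Labelled training data (`.label` + `PC*` columns), typically
#'   after [upsample_training()].
#' @param seed Optional RNG seed making stochastic fits reproducible.
#' @return Object of class `phonatory_model`.
#' @export
fit_model <- function(model, data, seed = NULL) {
  model <- match.arg(model, phonatory_models())
  X <- pc_matrix(data)
  y <- data$.label
  if (length(unique(y)) < 2) abort(paste0(model, ": training fold has a single class"))
  doit <- function() {
    fit <- switch(model,
      lr = {
        d <- as.data.frame(X); d$.label <- y
        suppressWarnings(glm(.label ~ ., data = d, family = binomial("logit")))
      },
      lda = MASS::lda(X, y),
      nab = e1071::naiveBayes(as.data.frame(X), y),
      rf = {
        grid <- rf_mtry_grid(ncol(X))
        oob <- vapply(grid, function(m) {
          f <- randomForest::randomForest(X, y, ntree = 150, mtry = m)
          mean(f$err.rate[, "OOB"])
        }, numeric(1))
        best <- grid[which.min(oob)]
        randomForest::randomForest(X, y, ntree = 500, mtry = best)
      },
      svm = {
        cost <- tune_svm_cost(X, y)
        e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE,
                   probability = TRUE)
      },
      nn = mlp_tanh_fit(X, as.numeric(y == "pos"))
    )
    tuned <- switch(model,
      rf = list(mtry = fit$mtry),
      svm = list(cost = fit$cost),
      list()
    )
    structure(list(model = model, fit = fit, tuned = tuned),
              class = "phonatory_model")
  }
  if (is.null(seed)) doit() else with_seed(seed, doit())
}

#' Positive-class probabilities from a fitted classifier
#'
#' @param object A `phonatory_model`.
#' @param newdata Dataset with the `PC*` predictor columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.phonatory_model <- function(object, newdata, ...) {
  X <- pc_matrix(newdata)
  p <- switch(object$model,
    lr = {
      d <- as.data.frame(X)
      as.numeric(predict(object$fit, newdata = d, type = "response"))
    },
    lda = predict(object$fit, X)$posterior[, "pos"],
    nab = predict(object$fit, as.data.frame(X), type = "raw")[, "pos"],
    rf = predict(object$fit, X, type = "prob")[, "pos"],
    svm = {
      pr <- predict(object$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "pos"]
    },
    nn = mlp_tanh_predict(object$fit, X)
  )
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' Dichotomize probabilities at a decision threshold
#'
#' A row is classified positive iff its probability is greater than or equal
#' to the threshold.
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param threshold Decision threshold (e.g. 0.5 or 0.95).
#' @return Factor with levels `neg`/`pos`.
#' @export
apply_threshold <- function(probabilities, threshold) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    abort("probabilities must lie in [0, 1]")
  }
  factor(ifelse(probabilities >= threshold, "pos", "neg"),
         levels = c("neg", "pos"))
}

#' Confusion counts of a binary prediction
#'
#' @param truth,predicted Factors with levels `neg`/`pos`.
#' @return One-row tibble `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(truth, predicted) {
  tibble(
    tp = sum(truth == "pos" & predicted == "pos"),
    fn = sum(truth == "pos" & predicted == "neg"),
    tn = sum(truth == "neg" & predicted == "neg"),
    fp = sum(truth == "neg" & predicted == "pos")
  )
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy is `(tp + tn) / total`, sensitivity `tp / (tp + fn)`,
#' specificity `tn / (tn + fp)`, each in percent. A metric whose denominator
#' is zero (no positive or no negative test rows) is undefined (`NA`).
#'
#' @param counts One-row tibble or list with `tp`, `fn`, `tn`, `fp`.
#' @return One-row tibble `accuracy`, `sensitivity`, `specificity` (%).
#' @export
confusion_metrics <- function(counts) {
  total <- counts$tp + counts$fn + counts$tn + counts$fp
  if (total == 0) abort("empty test set")
  tibble(
    accuracy = 100 * (counts$tp + counts$tn) / total,
    sensitivity = if (counts$tp + counts$fn == 0) NA_real_ else
      100 * counts$tp / (counts$tp + counts$fn),
    specificity = if (counts$tn + counts$fp == 0) NA_real_ else
      100 * counts$tn / (counts$tn + counts$fp)
  )
}
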