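# Tile-level classification: stratified folds, the four classifiers,
# probability profiles, histology map assembly, multiclass metrics.

#' Stratified fold assignment
#'
#' Per-class round-robin assignment after a seeded shuffle, so per-class
#' counts across folds differ by at most one. A class with fewer than
#' `k` members triggers a warning and best-effort assignment.
#'
#' @param labels class labels (any type).
#' @param k number of folds (default 8).
#' @param seed integer seed.
#' @return integer vector of fold indices in `0:(k-1)`, one per label.
#' @export
stratified_folds <- function(labels, k = 8L, seed = 1L) {
  n <- length(labels)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        warning("class '", cl, "' has fewer than ", k, " members")
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- (seq_along(idx) - 1L) %% k
    }
  })
  folds
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(mean = mu, sd = sdv)
}

standardize_apply <- function(X, std) {
  sweep(sweep(as.matrix(X), 2, std$mean, "-"), 2, std$sd, "/")
}

#' Fit one of the four tile classifiers
#'
#' Kinds: `"1NN"` (1-nearest neighbor), `"linSVM"`, `"rbfSVM"` (Platt-
#' calibrated probabilities), `"ensembleTree"` (RUSBoost: boosted
#' depth-3 trees, each round trained on a class-balanced random
#' undersample). Features are standardized with training-set means/sds
#' stored on the model.
#'
#' @param X numeric matrix (no NA), samples x features.
#' @param y class labels.
#' @param kind one of `"1NN"`, `"linSVM"`, `"rbfSVM"`, `"ensembleTree"`.
#' @param hyper named list of hyperparameters; recognized:
#'   `cost_linear` (1), `cost_rbf` (10), `gamma` (1/d), `n_rounds` (100),
#'   `max_depth` (3), `learning_rate` (0.1), `seed` (1).
#' @return object of class `tile_classifier`.
#' @export
fit_tile_classifier <- function(X, y, kind = "rbfSVM", hyper = list()) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("NA values in the feature matrix")
  kinds <- c("1NN", "linSVM", "rbfSVM", "ensembleTree")
  if (!kind %in% kinds)
    stop("unknown classifier kind '", kind, "'; expected one of ",
         paste(kinds, collapse = ", "))
  y <- factor(y)
  # order class levels numerically when the labels are numeric-like, so
  # argmax ties break to the lower class id
  if (!anyNA(suppressWarnings(as.numeric(levels(y)))))
    y <- factor(y, levels = levels(y)[order(as.numeric(levels(y)))])
  std <- standardize_fit(X)
  Z <- standardize_apply(X, std)
  h <- function(name, default) if (is.null(hyper[[name]])) default else hyper[[name]]
  # SVM probability calibration draws internal CV folds; fitting under a
  # fixed RNG scope makes every fit reproducible irrespective of caller
  # RNG state
  fit <- with_seed(h("seed", 1L), switch(
    kind,
    "1NN" = list(train = Z, labels = y),
    "linSVM" = e1071::svm(Z, y, kernel = "linear", cost = h("cost_linear", 1),
                          probability = TRUE, scale = FALSE),
    "rbfSVM" = e1071::svm(Z, y, kernel = "radial", cost = h("cost_rbf", 10),
                          gamma = h("gamma", 1 / ncol(Z)),
                          probability = TRUE, scale = FALSE),
    "ensembleTree" = rusboost_fit(Z, y, n_rounds = h("n_rounds", 100L),
                                  max_depth = h("max_depth", 3L),
                                  learning_rate = h("learning_rate", 0.1),
                                  seed = h("seed", 1L))))
  structure(list(kind = kind, fit = fit, classes = levels(y), std = std),
            class = "tile_classifier")
}

# RUSBoost: SAMME-style boosting of rpart stumps; each round the
# majority classes are randomly undersampled to the minority-class count
# (sampling probability proportional to the current boosting weights).
rusboost_fit <- function(Z, y, n_rounds = 100L, max_depth = 3L,
                         learning_rate = 0.1, seed = 1L) {
  K <- nlevels(y)
  n <- nrow(Z)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  df <- data.frame(.y = y, Z)
  with_seed(seed, {
    for (rnd in seq_len(n_rounds)) {
      n_min <- min(table(y))
      sel <- unlist(lapply(levels(y), function(cl) {
        idx <- which(y == cl)
        if (length(idx) <= n_min) idx
        else idx[sample.int(length(idx), n_min, prob = w[idx] / sum(w[idx]))]
      }))
      tr <- rpart::rpart(.y ~ ., data = df[sel, , drop = FALSE],
                         method = "class",
                         control = rpart::rpart.control(
                           maxdepth = max_depth, cp = 0, minsplit = 2,
                           xval = 0))
      pred <- predict(tr, df, type = "class")
      err <- sum(w * (pred != y)) / sum(w)
      if (err >= 1 - 1 / K) next          # worse than chance: skip round
      err <- max(err, 1e-10)
      a <- learning_rate * (log((1 - err) / err) + log(K - 1))
      w <- w * exp(a * (pred != y))
      w <- w / sum(w)
      trees[[length(trees) + 1L]] <- tr
      alphas <- c(alphas, a)
      if (err < 1e-10) break
    }
  })
  list(trees = trees, alphas = alphas, classes = levels(y))
}

rusboost_scores <- function(fit, Z) {
  df <- data.frame(Z)
  scores <- matrix(0, nrow(Z), length(fit$classes),
                   dimnames = list(NULL, fit$classes))
  if (length(fit$trees) == 0) return(scores + 1 / length(fit$classes))
  for (i in seq_along(fit$trees)) {
    p <- predict(fit$trees[[i]], df, type = "class")
    scores[cbind(seq_len(nrow(Z)), as.integer(p))] <-
      scores[cbind(seq_len(nrow(Z)), as.integer(p))] + fit$alphas[i]
  }
  scores
}

#' Per-tile class probability profiles
#'
#' Returns one calibrated probability per class per sample; the
#' predicted class is the profile argmax (ties to the lower class id by
#' the model's class ordering).
#'
#' @param model `tile_classifier`.
#' @param X feature matrix with the training columns.
#' @return matrix samples x classes (rows sum to 1) with attribute
#'   `predicted` (character vector of class labels).
#' @export
predict_profiles <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$std$mean))
    stop("feature-dimension mismatch: got ", ncol(X), ", expected ",
         length(model$std$mean))
  Z <- standardize_apply(X, model$std)
  K <- length(model$classes)
  P <- switch(
    model$kind,
    "1NN" = {
      nn <- class::knn(model$fit$train, Z, model$fit$labels, k = 1)
      p <- matrix(0, nrow(Z), K, dimnames = list(NULL, model$classes))
      p[cbind(seq_len(nrow(Z)), as.integer(nn))] <- 1
      p
    },
    "linSVM" = ,
    "rbfSVM" = {
      pr <- predict(model$fit, Z, probability = TRUE)
      p <- attr(pr, "probabilities")
      p[, model$classes, drop = FALSE]
    },
    "ensembleTree" = {
      s <- rusboost_scores(model$fit, Z)
      s <- exp(s - apply(s, 1, max))
      s / rowSums(s)
    })
  P <- P / rowSums(P)
  pred <- model$classes[apply(P, 1, which.max)]
  attr(P, "predicted") <- pred
  P
}

#' @export
predict.tile_classifier <- function(object, newdata, type = c("class", "prob"),
                                    ...) {
  type <- match.arg(type)
  P <- predict_profiles(object, newdata)
  if (type == "prob") P else attr(P, "predicted")
}

#' @export
print.tile_classifier <- function(x, ...) {
  cat("Tile classifier (", x$kind, "), ", length(x$classes), " classes, ",
      length(x$std$mean), " features\n", sep = "")
  invisible(x)
}

#' Assemble a histology classification map from tile predictions
#'
#' Cell (row, col) of the map gets the predicted class of the tile at
#' that grid position; grid cells with no tile get the background
#' sentinel. The map covers rows `0..max(grid_row)` and columns
#' `0..max(grid_col)`.
#'
#' @param tile_records data.frame with `grid_row`, `grid_col` (0-based,
#'   unique per patient).
#' @param predicted_classes integer class ids, one per record.
#' @return integer matrix of class ids.
#' @export
assemble_map <- function(tile_records, predicted_classes) {
  key <- paste(tile_records$grid_row, tile_records$grid_col)
  if (anyDuplicated(key)) stop("duplicate grid coordinates")
  nr <- max(tile_records$grid_row) + 1L
  nc <- max(tile_records$grid_col) + 1L
  m <- matrix(background_sentinel(), nr, nc)
  m[cbind(tile_records$grid_row + 1L, tile_records$grid_col + 1L)] <-
    as.integer(predicted_classes)
  m
}

# Rank-statistic AUC (all positive-negative pairs; ties count 1/2).
auc_rank <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' One-vs-rest multiclass metrics
#'
#' Per-class accuracy, recall (sensitivity), precision, specificity, F1,
#' and (when profiles are supplied) one-vs-rest AUC by the rank
#' statistic, plus the aggregate accuracy and confusion matrix. A class
#' absent from `y_true` gets NA recall and is flagged.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param profiles optional probability matrix with class-named columns.
#' @return list: `confusion` (true x predicted), `accuracy`, `per_class`
#'   data.frame, `flagged` (classes absent from truth).
#' @export
multiclass_metrics <- function(y_true, y_pred, profiles = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  classes <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  yt <- factor(y_true, levels = classes)
  yp <- factor(y_pred, levels = classes)
  cm <- table(true = yt, predicted = yp)
  n <- length(yt)
  per <- data.frame(class = classes, accuracy = NA_real_, recall = NA_real_,
                    precision = NA_real_, specificity = NA_real_,
                    f1 = NA_real_, auc = NA_real_, support = as.vector(rowSums(cm)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    per$accuracy[i] <- (tp + tn) / n
    per$recall[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    per$precision[i] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    per$specificity[i] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    pr <- per$precision[i]; rc <- per$recall[i]
    per$f1[i] <- if (!is.na(pr) && !is.na(rc) && pr + rc > 0)
      2 * pr * rc / (pr + rc) else NA_real_
    if (!is.null(profiles) && classes[i] %in% colnames(profiles) &&
        any(yt == classes[i]) && any(yt != classes[i]))
      per$auc[i] <- auc_rank(profiles[, classes[i]], yt == classes[i])
  }
  list(confusion = cm, accuracy = sum(diag(cm)) / n, per_class = per,
       flagged = classes[rowSums(cm) == 0])
}

#' Stratified k-fold cross-validation of a tile classifier
#'
#' Trains on k-1 folds and tests on the held-out fold; standardization
#' (and everything else) is fit on training folds only. Pools the
#' held-out predictions into one report.
#'
#' @param X feature matrix.
#' @param y class labels.
#' @param kind classifier kind.
#' @param k folds (default 8).
#' @param seed fold seed.
#' @param hyper hyperparameters for [fit_tile_classifier()].
#' @return list: `report` ([multiclass_metrics()] of pooled held-out
#'   predictions), `fold_accuracy`, `folds`, `predicted`, `profiles`,
#'   `fold_standardization` (per-fold training means, for leakage
#'   audits).
#' @export
cv_tile_classifier <- function(X, y, kind = "rbfSVM", k = 8L, seed = 1L,
                               hyper = list()) {
  X <- as.matrix(X)
  folds <- stratified_folds(y, k, seed)
  pred <- character(length(y))
  classes <- sort(unique(as.character(y)))
  prof <- matrix(NA_real_, length(y), length(classes),
                 dimnames = list(NULL, classes))
  fold_acc <- numeric(k)
  fold_std <- vector("list", k)
  for (f in seq_len(k) - 1L) {
    tr <- folds != f; te <- folds == f
    model <- fit_tile_classifier(X[tr, , drop = FALSE], y[tr], kind, hyper)
    fold_std[[f + 1L]] <- model$std
    P <- predict_profiles(model, X[te, , drop = FALSE])
    pred[te] <- attr(P, "predicted")
    prof[te, colnames(P)] <- P
    fold_acc[f + 1L] <- mean(pred[te] == as.character(y[te]))
  }
  list(report = multiclass_metrics(y, pred, prof), fold_accuracy = fold_acc,
       folds = folds, predicted = pred, profiles = prof,
       fold_standardization = fold_std)
}
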