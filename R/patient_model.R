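# Patient-level response prediction: LOO-CV over the four classifiers,
# binary metrics with bootstrap CIs, ROC/AUC, attention maps.

#' Binary confusion counts
#'
#' @param TP,FP,TN,FN nonnegative integer counts; pCR is the positive
#'   class (an FP is an RD case called pCR, an FN a pCR case called RD).
#' @return object of class `binary_confusion`.
#' @export
binary_confusion <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "binary_confusion")
}

#' Binary classification metrics from a confusion matrix
#'
#' Exact arithmetic on the counts: accuracy = (TP+TN)/total,
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP), F1 = 2PR/(P+R). Undefined ratios (zero
#' denominators) come back NA with a flag.
#'
#' @param confusion `binary_confusion` (or a list with TP/FP/TN/FN).
#' @return list: accuracy, sensitivity, specificity, precision, f1
#'   (all proportions in [0, 1] or NA), `flags` naming any undefined
#'   ratio.
#' @export
binary_metrics <- function(confusion) {
  TP <- confusion$TP; FP <- confusion$FP
  TN <- confusion$TN; FN <- confusion$FN
  total <- TP + FP + TN + FN
  if (total <= 0) stop("empty confusion matrix")
  flags <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) { flags <<- c(flags, what); NA_real_ } else num / den
  }
  acc <- (TP + TN) / total
  sens <- ratio(TP, TP + FN, "sensitivity")
  spec <- ratio(TN, TN + FP, "specificity")
  prec <- ratio(TP, TP + FP, "precision")
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    flags <- c(flags, "f1"); NA_real_
  } else 2 * prec * sens / (prec + sens)
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       precision = prec, f1 = f1, flags = flags)
}

#' ROC curve and AUC
#'
#' AUC by the all-pairs rank statistic (ties count one half); the curve
#' walks the sorted unique score thresholds, so its trapezoidal area
#' equals the rank AUC.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or two-level labels; the positive class is
#'   `TRUE`, `"pCR"`, or the larger level.
#' @return list: `auc`, `curve` (data.frame threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else as.character(labels) == "pCR"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  auc <- auc_rank(scores, pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  list(auc = auc, curve = curve)
}

#' Leave-one-out evaluation of patient-level response prediction
#'
#' For each patient, a classifier trained on all other patients predicts
#' the two class probabilities; the call is pCR only when p(pCR) exceeds
#' one half (ties go to RD). In `nested` mode ReliefF selection is rerun
#' inside every training fold, so the held-out patient never influences
#' selection; `global` mode selects once on all patients (the
#' replication mode matching a select-then-validate ordering).
#'
#' @param X pair-feature matrix (patients x features), e.g. from
#'   [cohort_pair_features()].
#' @param outcome character vector of `"pCR"` / `"RD"`.
#' @param classifier_kind one of the four kinds of
#'   [fit_tile_classifier()].
#' @param selection_mode `"nested"` (default) or `"global"`.
#' @param n_top features selected (default 8).
#' @param k_neighbors ReliefF neighbors (default 10).
#' @param hyper classifier hyperparameters.
#' @param seed seed for ReliefF subsampling (unused by default).
#' @return object of class `loocv_result`: list(p_pCR, call, confusion
#'   (`binary_confusion`), metrics, auc, roc, selected, selection_mode).
#' @export
loocv_evaluate <- function(X, outcome, classifier_kind = "rbfSVM",
                           selection_mode = c("nested", "global"),
                           n_top = 8L, k_neighbors = 10L, hyper = list(),
                           seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  X <- as.matrix(X)
  outcome <- as.character(outcome)
  if (length(unique(outcome)) < 2 || min(table(outcome)) < 2)
    stop("need >= 2 patients per outcome class")
  n <- nrow(X)
  sel_global <- NULL
  if (selection_mode == "global") {
    w <- relieff_weights(X, outcome, k_neighbors, seed = seed)
    sel_global <- rank_and_select(w, n_top)
  }
  p_pCR <- numeric(n)
  sel_record <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    sel <- if (selection_mode == "nested") {
      w <- relieff_weights(X[tr, , drop = FALSE], outcome[tr],
                           k_neighbors, seed = seed)
      rank_and_select(w, n_top)
    } else sel_global
    sel_record[[i]] <- sel
    model <- fit_tile_classifier(X[tr, sel, drop = FALSE], outcome[tr],
                                 classifier_kind, hyper)
    P <- predict_profiles(model, X[i, sel, drop = FALSE])
    p_pCR[i] <- P[1, "pCR"]
  }
  call <- ifelse(p_pCR > 0.5, "pCR", "RD")  # ties predicted RD
  cm <- binary_confusion(TP = sum(call == "pCR" & outcome == "pCR"),
                         FP = sum(call == "pCR" & outcome == "RD"),
                         TN = sum(call == "RD" & outcome == "RD"),
                         FN = sum(call == "RD" & outcome == "pCR"))
  roc <- roc_auc(p_pCR, outcome)
  structure(list(p_pCR = p_pCR, call = call, outcome = outcome,
                 confusion = cm, metrics = binary_metrics(cm),
                 auc = roc$auc, roc = roc$curve,
                 selected = sel_record, selection_mode = selection_mode,
                 classifier_kind = classifier_kind),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  m <- x$metrics
  cat("Leave-one-out response prediction (", x$classifier_kind, ", ",
      x$selection_mode, " selection)\n", sep = "")
  cat(sprintf("  n = %d   accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              length(x$call), 100 * m$accuracy, 100 * m$sensitivity,
              100 * m$specificity))
  cat(sprintf("  precision %.3f  F1 %.3f  AUC %.3f\n",
              m$precision, m$f1, x$auc))
  invisible(x)
}

#' Bootstrap confidence intervals for binary metrics
#'
#' Patient-level bootstrap: resamples (truth, call, score) triples with
#' replacement and takes percentile intervals of each recomputed metric.
#' Resamples with a single outcome class are redrawn.
#'
#' @param outcome truth (`"pCR"` / `"RD"`).
#' @param call predicted labels.
#' @param scores p(pCR) per patient (for the AUC interval).
#' @param n_boot resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return data.frame: metric, estimate, lower, upper.
#' @export
bootstrap_metric_ci <- function(outcome, call, scores, n_boot = 1000L,
                                level = 0.95, seed = 1L) {
  n <- length(outcome)
  point <- c(unlist(binary_metrics(confusion_from_calls(outcome, call))[
    c("accuracy", "sensitivity", "specificity", "precision", "f1")]),
    auc = auc_rank(scores, outcome == "pCR"))
  draws <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(outcome[idx])) == 2) break
      }
      m <- binary_metrics(confusion_from_calls(outcome[idx], call[idx]))
      c(m$accuracy, m$sensitivity, m$specificity, m$precision, m$f1,
        auc_rank(scores[idx], outcome[idx] == "pCR"))
    }, numeric(6)))
  })
  qs <- apply(draws, 2, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2),
              na.rm = TRUE)
  data.frame(metric = c("accuracy", "sensitivity", "specificity",
                        "precision", "f1", "auc"),
             estimate = as.numeric(point), lower = qs[1, ], upper = qs[2, ],
             row.names = NULL)
}

confusion_from_calls <- function(outcome, call) {
  binary_confusion(TP = sum(call == "pCR" & outcome == "pCR"),
                   FP = sum(call == "pCR" & outcome == "RD"),
                   TN = sum(call == "RD" & outcome == "RD"),
                   FN = sum(call == "RD" & outcome == "pCR"))
}

#' Attention map over a histology classification map
#'
#' Highlights the cells of every tile cluster that serves as a node in
#' the graph of any selected feature's class pair; everything else is
#' FALSE (transparent).
#'
#' @param map integer label matrix.
#' @param selected_features character names of selected pair-feature
#'   columns (`pairA_B.feature` convention), or an n x 2 matrix of class
#'   id pairs.
#' @param connectivity cluster connectivity (default 4).
#' @return logical matrix with the map's dimensions.
#' @export
attention_map <- function(map, selected_features, connectivity = 4L) {
  if (is.character(selected_features)) {
    pr <- unique(sub("\\..*$", "", selected_features))
    pairs <- do.call(rbind, lapply(pr, function(p) {
      as.integer(strsplit(sub("^pair", "", p), "_")[[1]])
    }))
  } else pairs <- selected_features
  overlay <- matrix(FALSE, nrow(map), ncol(map))
  for (cls in unique(as.vector(pairs))) {
    for (cl in extract_clusters(map, cls, connectivity))
      overlay[cl$members] <- TRUE
  }
  overlay
}
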