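#' Confusion counts from scores and labels
#'
#' @param score Numeric decision values (positive call iff `score > threshold`).
#' @param truth Logical (or "positive"/"negative") true labels.
#' @param threshold Decision threshold (default 0 for SVM decision values).
#' @return Named list `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(score, truth, threshold = 0) {
  if (is.character(truth)) truth <- truth == "positive"
  call_pos <- score > threshold
  list(TP = sum(call_pos & truth), TN = sum(!call_pos & !truth),
       FP = sum(call_pos & !truth), FN = sum(!call_pos & truth))
}

#' Sensitivity, specificity, accuracy and Matthews correlation coefficient
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total — each reported as a
#' percentage — and MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' When any marginal of the confusion table is empty the MCC denominator is
#' zero; the MCC is then reported as `NaN` with a warning rather than clamped
#' to 0, so undefined cases stay visible.
#'
#' @param counts Named list or vector with `TP`, `TN`, `FP`, `FN`
#'   (non-negative, total > 0).
#' @return Named list `Sn`, `Sp`, `Acc` (percent), `MCC`.
#' @examples
#' compute_metrics(list(TP = 25, FN = 25, TN = 40, FP = 10))
#' @export
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  v <- as.numeric(counts[c("TP", "TN", "FP", "FN")])
  if (anyNA(v) || any(v < 0)) {
    stop("domain error: counts must be non-negative TP, TN, FP, FN",
         call. = FALSE)
  }
  TP <- v[1]; TN <- v[2]; FP <- v[3]; FN <- v[4]
  total <- TP + TN + FP + FN
  if (total == 0) stop("domain error: empty confusion table", call. = FALSE)
  denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom2 == 0) {
    warning("MCC undefined: a confusion-table marginal is empty",
            call. = FALSE)
    NaN
  } else {
    (TP * TN - FP * FN) / sqrt(denom2)
  }
  list(Sn = 100 * TP / (TP + FN), Sp = 100 * TN / (TN + FP),
       Acc = 100 * (TP + TN) / total, MCC = mcc)
}

#' ROC and precision-recall curves with their areas
#'
#' Thresholds sweep the unique scores in descending order (ties grouped, so
#' tied positive/negative pairs receive half credit, making the trapezoidal
#' AUROC identical to the normalized Mann-Whitney U statistic). The ROC
#' starts at (0, 0) and ends at (1, 1). The area under the precision-recall
#' curve uses the step-wise (precision at each recall increment) convention
#' rather than trapezoidal interpolation, which is optimistic for PR curves.
#'
#' @param score Numeric scores, larger = more positive.
#' @param truth Logical (or "positive"/"negative") true labels; both classes
#'   must be present.
#' @return List with `roc` (tibble `fpr`, `tpr`), `pr` (tibble `recall`,
#'   `precision`), `auroc`, `auprc`.
#' @export
roc_pr_curves <- function(score, truth) {
  if (is.character(truth)) truth <- truth == "positive"
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop("curve error: both classes must be present", call. = FALSE)
  }
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; t <- truth[ord]
  last <- !duplicated(s, fromLast = TRUE)  # end of each tie group
  tp <- cumsum(t)[last]
  fp <- cumsum(!t)[last]
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  auroc <- sum(diff(c(0, fpr)) * (c(0, head(tpr, -1)) + tpr) / 2)
  precision <- tp / (tp + fp)
  recall <- tpr
  auprc <- sum(diff(c(0, recall)) * precision)
  list(
    roc = tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr)),
    pr = tibble::tibble(recall = c(0, recall),
                        precision = c(precision[1L], precision)),
    auroc = auroc,
    auprc = auprc
  )
}

# Assemble an evaluation report from held-out scores.
build_report <- function(scores, scheme, seed = NA_integer_, tags = "",
                         selected = NULL, folds = NULL) {
  counts <- confusion_counts(scores$score, scores$truth)
  metrics <- compute_metrics(counts)
  curves <- roc_pr_curves(scores$score, scores$truth)
  structure(list(
    counts = counts, Sn = metrics$Sn, Sp = metrics$Sp, Acc = metrics$Acc,
    MCC = metrics$MCC, roc = curves$roc, pr = curves$pr,
    AUROC = curves$auroc, AUPRC = curves$auprc,
    scheme = scheme, seed = seed, tags = tags,
    selected_C = selected$C, selected_gamma = selected$gamma,
    folds = folds, scores = scores
  ), class = "m1a_eval")
}

#' @export
print.m1a_eval <- function(x, ...) {
  cat(sprintf("<m1a_eval> scheme: %s%s\n", x$scheme,
              if (nzchar(paste(x$tags, collapse = "")))
                paste0(" (", paste(x$tags, collapse = " -> "), ")") else ""))
  cat(sprintf("  n = %d  (TP %d, TN %d, FP %d, FN %d)\n",
              sum(unlist(x$counts)), x$counts$TP, x$counts$TN,
              x$counts$FP, x$counts$FN))
  cat(sprintf("  Sn %.2f%%  Sp %.2f%%  Acc %.2f%%  MCC %.3f\n",
              x$Sn, x$Sp, x$Acc, x$MCC))
  cat(sprintf("  AUROC %.4f  AUPRC %.4f\n", x$AUROC, x$AUPRC))
  invisible(x)
}

# Hyperparameter selection used by the resampling protocols: one grid search
# on the full dataset, reused across folds (see the methods vignette for the
# rationale and the nested alternative).
select_hyperparameters <- function(dataset, config, mask) {
  model <- grid_search_train(dataset, config, mask)
  list(C = model$selected_C, gamma = model$selected_gamma,
       cv_table = model$cv_table)
}

holdout_scores <- function(X, y, folds, C, gamma) {
  scores <- numeric(length(y))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    fit <- fit_svm(X[!hold, , drop = FALSE], y[!hold], C, gamma)
    scores[hold] <- decision_scores(fit, X[hold, , drop = FALSE])
  }
  scores
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each window is in turn singled out as the test sample while the model is
#' trained on the remaining n - 1. By default the hyperparameters (C, gamma)
#' are selected once by grid search on the full dataset and held fixed across
#' the n folds; `nested = TRUE` instead repeats the grid search inside every
#' fold (leakage-free, n times slower).
#'
#' @param dataset An `m1a_dataset` with at least 2 windows per class.
#' @param config An [svm_config()].
#' @param mask Feature mask.
#' @param nested Repeat the grid search inside each fold.
#' @return An `m1a_eval` report aggregating all n held-out scores.
#' @export
jackknife_evaluate <- function(dataset, config = svm_config(), mask = NULL,
                               nested = FALSE) {
  mask <- check_mask(mask)
  if (min(table(dataset$label)) < 2L) {
    stop("evaluation error: jackknife needs at least 2 windows per class",
         call. = FALSE)
  }
  X <- encode_windows(dataset, mask)
  y <- factor(dataset$label, levels = c("negative", "positive"))
  n <- length(y)
  if (nested) {
    scores <- vapply(seq_len(n), function(i) {
      sel <- select_hyperparameters(dataset[-i, , drop = FALSE], config, mask)
      fit <- fit_svm(X[-i, , drop = FALSE], y[-i], sel$C, sel$gamma)
      decision_scores(fit, X[i, , drop = FALSE])
    }, numeric(1))
    sel <- list(C = NA_real_, gamma = NA_real_)
  } else {
    sel <- select_hyperparameters(dataset, config, mask)
    scores <- holdout_scores(X, y, seq_len(n), sel$C, sel$gamma)
  }
  build_report(
    tibble::tibble(id = dataset$id, score = scores,
                   truth = dataset$label == "positive"),
    scheme = "jackknife", seed = config$seed, tags = dataset_tag(dataset),
    selected = sel
  )
}

#' Stratified k-fold cross-validation
#'
#' @param dataset An `m1a_dataset`; each class must have at least `k`
#'   windows.
#' @param k Number of folds (default 10).
#' @param config An [svm_config()]; hyperparameters are selected once on the
#'   full dataset, then each fold is refit with them.
#' @param mask Feature mask.
#' @param seed Seed for the fold assignment (defaults to `config$seed`).
#' @return An `m1a_eval` report; `$folds` records the fold of every window.
#' @export
kfold_evaluate <- function(dataset, k = 10L, config = svm_config(),
                           mask = NULL, seed = config$seed) {
  mask <- check_mask(mask)
  if (k < 2L) stop("evaluation error: k must be >= 2", call. = FALSE)
  if (min(table(dataset$label)) < k) {
    stop(sprintf("evaluation error: each class needs >= %d windows for %d-fold CV",
                 k, k), call. = FALSE)
  }
  X <- encode_windows(dataset, mask)
  y <- factor(dataset$label, levels = c("negative", "positive"))
  folds <- make_folds(dataset$label, k, seed)
  sel <- select_hyperparameters(dataset, config, mask)
  scores <- holdout_scores(X, y, folds, sel$C, sel$gamma)
  build_report(
    tibble::tibble(id = dataset$id, score = scores,
                   truth = dataset$label == "positive"),
    scheme = sprintf("kfold(%d)", k), seed = seed,
    tags = dataset_tag(dataset), selected = sel, folds = folds
  )
}

#' Independent-test (cross cell line / cross species) evaluation
#'
#' Trains once on one dataset and scores another, e.g. train on human, test
#' on mouse. Running it over all ordered pairs of datasets yields the
#' cross-domain accuracy matrix.
#'
#' @param train,test `m1a_dataset`s with the same window length.
#' @param config An [svm_config()].
#' @param mask Feature mask.
#' @return An `m1a_eval` report tagged `train_tag -> test_tag`.
#' @export
cross_evaluate <- function(train, test, config = svm_config(), mask = NULL) {
  if (dataset_window_length(train) != dataset_window_length(test)) {
    stop(sprintf("compatibility error: window lengths differ (%d vs %d)",
                 dataset_window_length(train), dataset_window_length(test)),
         call. = FALSE)
  }
  shared <- intersect(train$seq, test$seq)
  if (length(shared) > 0L) {
    warning(sprintf("%d sequence(s) shared between train and test sets",
                    length(shared)), call. = FALSE)
  }
  model <- grid_search_train(train, config, mask)
  pred <- stats::predict(model, test)
  build_report(
    tibble::tibble(id = test$id, score = pred$score,
                   truth = test$label == "positive"),
    scheme = "independent", seed = config$seed,
    tags = c(dataset_tag(train), dataset_tag(test)),
    selected = list(C = model$selected_C, gamma = model$selected_gamma)
  )
}

#' Feature-ablation study
#'
#' Evaluates each single feature channel (ring structure, hydrogen bond,
#' chemical functionality, nucleotide density) and the four-channel
#' combination under k-fold cross-validation, quantifying each channel's
#' contribution to site identification.
#'
#' @param dataset An `m1a_dataset`.
#' @param config An [svm_config()].
#' @param k Folds (default 10).
#' @param seed Fold-assignment seed.
#' @return Tibble with one row per mask (5 rows) and columns `mask`, `Sn`,
#'   `Sp`, `Acc`, `MCC`, `AUROC`, `AUPRC`; the full reports are attached as
#'   the `reports` attribute.
#' @export
ablation_study <- function(dataset, config = svm_config(), k = 10L,
                           seed = config$seed) {
  masks <- list(ring = "ring", hbond = "hbond",
                functionality = "functionality", density = "density",
                all = names(FEATURE_CHANNELS))
  reports <- lapply(masks, function(m) {
    kfold_evaluate(dataset, k = k, config = config, mask = m, seed = seed)
  })
  out <- tibble::tibble(
    mask = names(masks),
    Sn = vapply(reports, `[[`, numeric(1), "Sn"),
    Sp = vapply(reports, `[[`, numeric(1), "Sp"),
    Acc = vapply(reports, `[[`, numeric(1), "Acc"),
    MCC = vapply(reports, `[[`, numeric(1), "MCC"),
    AUROC = vapply(reports, `[[`, numeric(1), "AUROC"),
    AUPRC = vapply(reports, `[[`, numeric(1), "AUPRC")
  )
  attr(out, "reports") <- reports
  out
}

#' Write an evaluation report as JSON (plus optional TSV summary)
#'
#' @param report An `m1a_eval`.
#' @param path Output JSON path.
#' @param tsv_path Optional path for a one-row TSV metric summary.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, tsv_path = NULL) {
  stopifnot(inherits(report, "m1a_eval"))
  out <- list(
    scheme = report$scheme,
    tags = report$tags,
    counts = report$counts,
    metrics = list(Sn = report$Sn, Sp = report$Sp, Acc = report$Acc,
                   MCC = report$MCC, AUROC = report$AUROC,
                   AUPRC = report$AUPRC),
    auprc_convention = "stepwise",
    selected = list(C = report$selected_C, gamma = report$selected_gamma),
    roc = as.list(report$roc),
    pr = as.list(report$pr),
    folds = report$folds,
    provenance = provenance(seed = report$seed)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(tsv_path)) {
    utils::write.table(
      data.frame(scheme = report$scheme,
                 tags = paste(report$tags, collapse = "->"),
                 Sn = report$Sn, Sp = report$Sp, Acc = report$Acc,
                 MCC = report$MCC, AUROC = report$AUROC,
                 AUPRC = report$AUPRC),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Plot ROC and precision-recall curves of a report
#'
#' @param x An `m1a_eval`.
#' @param which `"roc"` or `"pr"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.m1a_eval <- function(x, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    plot(x$roc$fpr, x$roc$tpr, type = "l",
         xlab = "False positive rate (1 - Sp)",
         ylab = "True positive rate (Sn)",
         main = sprintf("ROC, AUROC = %.3f", x$AUROC), ...)
    graphics::abline(0, 1, lty = 2, col = "grey")
  } else {
    plot(x$pr$recall, x$pr$precision, type = "s", ylim = c(0, 1),
         xlab = "Recall", ylab = "Precision",
         main = sprintf("Precision-recall, AUPRC = %.3f", x$AUPRC), ...)
  }
  invisible(x)
}
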