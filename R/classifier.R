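#' RBF-SVM training configuration
#'
#' Grids default to the practitioner convention for RBF-kernel grid search:
#' `C` over 2^-5 .. 2^15 and `gamma` over 2^-15 .. 2^3, both in steps of 2^2.
#' Model selection maximizes stratified inner-CV accuracy (matching the
#' accuracy-centric reporting of this literature); AUROC can be used instead
#' via `criterion`.
#'
#' @param C_grid Ascending positive costs.
#' @param gamma_grid Ascending positive kernel widths.
#' @param inner_cv_folds Stratified folds used for selection (default 5).
#' @param seed Seed controlling the inner-CV fold assignment.
#' @param criterion `"accuracy"` (default) or `"auroc"`.
#' @return An object of class `m1a_svm_config`.
#' @export
svm_config <- function(C_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       inner_cv_folds = 5L, seed = 1L,
                       criterion = c("accuracy", "auroc")) {
  criterion <- match.arg(criterion)
  check_grid <- function(g, name) {
    if (length(g) == 0L || any(!is.finite(g)) || any(g <= 0) ||
        is.unsorted(g, strictly = TRUE)) {
      stop(sprintf("configuration error: `%s` must be nonempty, positive and strictly ascending",
                   name), call. = FALSE)
    }
  }
  check_grid(C_grid, "C_grid")
  check_grid(gamma_grid, "gamma_grid")
  if (inner_cv_folds < 2L) {
    stop("configuration error: `inner_cv_folds` must be >= 2", call. = FALSE)
  }
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid,
                 inner_cv_folds = as.integer(inner_cv_folds),
                 seed = as.integer(seed), criterion = criterion),
            class = "m1a_svm_config")
}

# Stratified fold assignment: within each class, indices are shuffled under
# the derived seed and dealt round-robin into k folds.
make_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

fit_svm <- function(X, y, C, gamma) {
  e1071::svm(x = X, y = y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE)
}

# Decision values oriented so that larger = more positive-class. libsvm signs
# decision values toward the first class it saw; the column name of the
# decision-value attribute ("positive/negative" or "negative/positive")
# records that orientation.
decision_scores <- function(fit, X) {
  if (nrow(X) == 0L) return(numeric())
  p <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  if (startsWith(colnames(dv)[1L], "negative")) -dv[, 1L] else dv[, 1L]
}

cv_score <- function(X, y, C, gamma, folds, criterion) {
  scores <- numeric(length(y))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    fit <- fit_svm(X[!hold, , drop = FALSE], y[!hold], C, gamma)
    scores[hold] <- decision_scores(fit, X[hold, , drop = FALSE])
  }
  if (criterion == "accuracy") {
    mean((scores > 0) == (y == "positive"))
  } else {
    roc_pr_curves(scores, y == "positive")$auroc
  }
}

#' Train an RBF-SVM with cross-validated grid search
#'
#' For every (C, gamma) pair the stratified inner-CV selection score is
#' computed on the encoded dataset; the winning pair (ties broken by smallest
#' C, then smallest gamma) is refit on the full dataset. Features are not
#' rescaled: every channel of the encoding already lies in \[0, 1\].
#'
#' @param dataset An `m1a_dataset` containing both classes.
#' @param config An [svm_config()].
#' @param mask Feature mask (see [encode_window()]); `NULL` = all four
#'   channels.
#' @return An object of class `m1a_model` with elements `selected_C`,
#'   `selected_gamma`, `cv_table` (per-grid-point selection scores), `mask`,
#'   `window_length` and `training_tag`.
#' @export
grid_search_train <- function(dataset, config = svm_config(), mask = NULL) {
  stopifnot(inherits(config, "m1a_svm_config"))
  mask <- check_mask(mask)
  if (length(unique(dataset$label)) < 2L) {
    stop("training error: dataset must contain both classes", call. = FALSE)
  }
  X <- encode_windows(dataset, mask)
  y <- factor(dataset$label, levels = c("negative", "positive"))
  folds <- make_folds(dataset$label, config$inner_cv_folds, config$seed)
  grid <- expand.grid(C = config$C_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$score <- vapply(seq_len(nrow(grid)), function(i) {
    cv_score(X, y, grid$C[i], grid$gamma[i], folds, config$criterion)
  }, numeric(1))
  best <- order(-grid$score, grid$C, grid$gamma)[1L]
  fit <- fit_svm(X, y, grid$C[best], grid$gamma[best])
  structure(list(
    fit = fit,
    selected_C = grid$C[best],
    selected_gamma = grid$gamma[best],
    cv_table = tibble::as_tibble(grid),
    mask = mask,
    window_length = dataset_window_length(dataset),
    training_tag = dataset_tag(dataset),
    config = config
  ), class = "m1a_model")
}

#' @export
print.m1a_model <- function(x, ...) {
  cat(sprintf(
    "<m1a_model> RBF-SVM, C = %g, gamma = %g, mask = %s, l = %d%s\n",
    x$selected_C, x$selected_gamma, paste(x$mask, collapse = "+"),
    x$window_length,
    if (nzchar(x$training_tag)) paste0(", trained on: ", x$training_tag) else ""
  ))
  invisible(x)
}

#' Score windows with a trained model
#'
#' Records are validated against the model's window length and center-base
#' convention, encoded with the model's feature mask, and scored with the
#' SVM decision function; the call is positive iff the decision value
#' exceeds 0. Decision values (not calls) feed ROC / precision-recall
#' analysis.
#'
#' @param object An `m1a_model`.
#' @param records Records tibble of query windows.
#' @param ... Unused.
#' @return Tibble with columns `id`, `score`, `call`.
#' @export
predict.m1a_model <- function(object, records, ...) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(id = character(), score = numeric(),
                          call = character()))
  }
  len <- nchar(records$seq)
  if (any(len != object$window_length)) {
    i <- which(len != object$window_length)[1L]
    stop(sprintf(
      "compatibility error: record '%s' has %d nt but the model expects %d",
      records$id[i], len[i], object$window_length
    ), call. = FALSE)
  }
  records <- validate_windows(records, object$window_length)
  X <- encode_windows(records, object$mask)
  score <- decision_scores(object$fit, X)
  tibble::tibble(id = records$id, score = unname(score),
                 call = ifelse(score > 0, "positive", "negative"))
}

MODEL_FORMAT <- "m1Apred-model"
MODEL_FORMAT_VERSION <- 1L

#' Save / load a trained model
#'
#' The file embeds a format header, the encoder descriptor (mask, window
#' length), the selected hyperparameters and the training provenance, so
#' `load_model(save_model(m))` reproduces `m`'s predictions exactly.
#'
#' @param model An `m1a_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "m1a_model"))
  saveRDS(list(format = MODEL_FORMAT, format_version = MODEL_FORMAT_VERSION,
               provenance = provenance(seed = model$config$seed),
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("load error: '%s' is not a readable model file (%s)",
                 path, conditionMessage(e)), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT)) {
    stop(sprintf("load error: '%s' is not an m1Apred model file", path),
         call. = FALSE)
  }
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    stop(sprintf("load error: model format version %s unsupported",
                 obj$format_version), call. = FALSE)
  }
  obj$model
}
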