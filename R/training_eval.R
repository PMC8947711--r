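#' Stratified k-fold split
#'
#' Partitions `1..n` into `k` disjoint folds, stratified by label: each
#' class's (shuffled) indices are dealt round-robin, so fold sizes differ
#' by at most one per class and each fold's class ratio is within one
#' trial of the global ratio. Deterministic under `seed`.
#'
#' @param n trial count.
#' @param k fold count (default 10).
#' @param labels per-trial labels, length `n`.
#' @param seed integer seed.
#' @return list of `k` integer index vectors covering `1..n` exactly once.
#' @export
kfold_split <- function(n, k = 10, labels, seed = 1L) {
  if (n < k) stop(sprintf("cannot make %d folds from %d trials", k, n))
  if (length(labels) != n) stop("labels must have length n")
  folds <- vector("list", k)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assign_to <- rep(seq_len(k), length.out = length(idx))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
      }
    }
  })
  lapply(folds, sort)
}

#' Cohen's kappa from accuracy and chance level
#'
#' `kappa = (p0 - pe) / (1 - pe)`. For a balanced two-class task the
#' chance level `pe` is 0.5, in which case `kappa = 2 * p0 - 1`.
#'
#' @param p0 observed mean accuracy (proportion in `[0, 1]`).
#' @param pe chance agreement proportion, `< 1`.
#' @return the chance-corrected agreement.
#' @export
cohen_kappa <- function(p0, pe = 0.5) {
  if (any(pe >= 1)) stop("pe must be < 1")
  (p0 - pe) / (1 - pe)
}

#' Accuracy, recall and precision from a 2 x 2 confusion matrix
#'
#' Rows are true classes, columns predicted, order (left, right).
#' Accuracy is `trace / total`; `recall_c = diag_c / rowsum_c`;
#' `precision_c = diag_c / colsum_c`. Zero denominators yield `NA`.
#'
#' @param confusion 2 x 2 matrix of nonnegative counts, total > 0.
#' @return list with `accuracy`, `recall`, `precision` (the latter two
#'   named per class).
#' @export
confusion_metrics <- function(confusion) {
  stopifnot(all(dim(confusion) == c(2, 2)), all(confusion >= 0),
            sum(confusion) > 0)
  cls <- rownames(confusion) %||% c("left", "right")
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  list(
    accuracy = sum(diag(confusion)) / sum(confusion),
    recall = stats::setNames(safe_div(diag(confusion), rowSums(confusion)), cls),
    precision = stats::setNames(safe_div(diag(confusion), colSums(confusion)), cls)
  )
}

eval_report <- function(variant, fold_accuracy, confusion, config, seed,
                        pe = 0.5) {
  met <- confusion_metrics(confusion)
  p0 <- mean(fold_accuracy)
  structure(
    list(variant = variant, fold_accuracy = fold_accuracy, accuracy = p0,
         kappa = cohen_kappa(p0, pe), confusion = confusion,
         recall = met$recall, precision = met$precision,
         pooled_accuracy = met$accuracy,
         n = sum(confusion), config = config, seed = seed),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: mean accuracy %.3f (kappa %.3f) over %d folds, n = %d\n",
              x$variant, x$accuracy, x$kappa, length(x$fold_accuracy), x$n))
  cat("  per-fold:", paste(sprintf("%.2f", x$fold_accuracy), collapse = " "), "\n")
  cat("  confusion (rows true, cols predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Cross-validated training and evaluation of a network variant
#'
#' Runs stratified k-fold cross-validation: for each fold a fresh model is
#' trained on the remaining folds (with its own inner early-stopping
#' split) and evaluated on the held-out fold. All randomness derives from
#' `config$seed`, so identical config and seed reproduce the report.
#'
#' @param spec a `network_spec`.
#' @param data list with `labels` plus the input arrays the variant needs:
#'   `eeg` (`n x 6 x 875`) and/or `cwt` (`n x 64 x 93`).
#' @param config a [train_config()].
#' @return an `eval_report` with per-fold accuracy, mean accuracy, Cohen's
#'   kappa (pe = 0.5), the pooled confusion matrix and per-class
#'   recall/precision.
#' @export
run_cv <- function(spec, data, config = train_config()) {
  labels <- data$labels
  n <- length(labels)
  if (n == 0) stop("data is empty")
  # validate shapes up front, before any training
  probe <- build_patches(build_model(spec, seed = 1L),
                         subset_inputs(data, 1L))
  lv <- intersect(c("left", "right"), unique(labels))
  if (length(lv) < 2) lv <- sort(unique(labels))
  folds <- kfold_split(n, config$folds, labels, config$seed)
  fold_acc <- numeric(length(folds))
  confusion <- matrix(0L, 2, 2, dimnames = list(true = lv, predicted = lv))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    model <- train_network(spec, subset_inputs(data, train), labels[train],
                           config, seed = derive_seed(config$seed, 100 + f))
    probs <- predict_proba(model, subset_inputs(data, test))
    pred <- model$class_levels[max.col(probs, ties.method = "first")]
    fold_acc[f] <- mean(pred == labels[test])
    confusion <- confusion + table(factor(labels[test], levels = lv),
                                   factor(pred, levels = lv))
  }
  eval_report(spec$variant, fold_acc, confusion, config, config$seed)
}
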