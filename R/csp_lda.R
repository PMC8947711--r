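#' Fit common spatial pattern (CSP) filters
#'
#' Per-trial channel covariances are normalized by their trace and averaged
#' within each class to `Ra` and `Rb`. The filters solve the generalized
#' eigenproblem `Ra w = lambda (Ra + Rb) w` (via whitening of the composite
#' covariance); the `m` eigenvectors with the largest eigenvalues and the
#' `m` with the smallest form the filter matrix, largest block first. The
#' eigenvalues lie in `[0, 1]` and the corresponding eigenvalue pairs for
#' the two classes sum to one, so the top filters maximize class-A variance
#' while the bottom filters maximize class-B variance.
#'
#' @param trials_a,trials_b numeric arrays `(n, C, T)` holding the trials
#'   of each class.
#' @param m filter pairs to keep (`2m <= C`).
#' @param reg ridge term added to the composite covariance as
#'   `reg * mean(diag)` per channel; the small default guards against
#'   numerically singular composites.
#' @return an object of class `csp_model`: `filters` (`2m x C`, rows are
#'   spatial filters), `eigenvalues` (length `2m`, class-A generalized
#'   eigenvalues), `m`, `n_channels`.
#' @export
fit_csp <- function(trials_a, trials_b, m = 1, reg = 1e-8) {
  stopifnot(length(dim(trials_a)) == 3, length(dim(trials_b)) == 3)
  C <- dim(trials_a)[2]
  if (dim(trials_b)[2] != C) stop("both classes must share the channel count")
  if (dim(trials_a)[1] < 1 || dim(trials_b)[1] < 1) stop("both classes must be nonempty")
  if (2 * m > C) stop(sprintf("m = %d filter pairs need at least %d channels", m, 2 * m))

  class_cov <- function(trials) {
    n <- dim(trials)[1]
    R <- matrix(0, C, C)
    for (i in seq_len(n)) {
      X <- trials[i, , , drop = TRUE]
      if (is.null(dim(X))) X <- matrix(X, nrow = C)
      Ci <- tcrossprod(X)
      tr <- sum(diag(Ci))
      if (tr <= 0) stop("trial with zero total variance; cannot normalize covariance")
      R <- R + Ci / tr
    }
    R / n
  }
  Ra <- class_cov(trials_a)
  Rb <- class_cov(trials_b)
  Rc <- Ra + Rb
  ec <- eigen(Rc, symmetric = TRUE)
  if (min(ec$values) <= 1e-10 * max(ec$values)) {
    # near-singular composite: retry with a small ridge
    Rc <- Rc + diag(reg * mean(diag(Rc)), C)
    ec <- eigen(Rc, symmetric = TRUE)
    if (min(ec$values) <= 1e-12 * max(ec$values)) {
      stop("composite covariance is singular; increase `reg` or supply richer data")
    }
  }
  U <- diag(1 / sqrt(ec$values), C) %*% t(ec$vectors)   # whitening: U Rc U' = I
  S <- U %*% Ra %*% t(U)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)          # eigenvalues descending
  W_all <- t(es$vectors) %*% U                           # rows: filters, lambda desc
  sel <- c(seq_len(m), C - m + seq_len(m))
  structure(
    list(filters = W_all[sel, , drop = FALSE],
         eigenvalues = pmin(pmax(es$values[sel], 0), 1),
         m = as.integer(m), n_channels = C),
    class = "csp_model"
  )
}

#' Log-variance CSP features of one trial
#'
#' `feature_j = log(var(w_j x) / sum_k var(w_k x))`. The normalization
#' makes the features invariant to global amplitude scaling of the trial;
#' variance ratios are floored at 1e-12 before the log so a filter with
#' (numerically) zero variance yields a large negative value rather than
#' `-Inf`.
#'
#' @param trial numeric matrix `C x T`.
#' @param model a `csp_model`.
#' @return numeric feature vector of length `2m`.
#' @export
csp_features <- function(trial, model) {
  if (nrow(trial) != model$n_channels) {
    stop(sprintf("trial has %d channels but the model expects %d",
                 nrow(trial), model$n_channels))
  }
  Y <- model$filters %*% trial
  v <- apply(Y, 1, stats::var)
  tot <- sum(v)
  if (tot <= 0) stop("trial has zero variance under every filter")
  log(pmax(v / tot, 1e-12))
}

#' Fisher linear discriminant
#'
#' `w` is proportional to `Sw^-1 (mu_a - mu_b)` with `Sw` the pooled
#' within-class covariance (ridge fallback if singular); the decision
#' threshold sits at the projected midpoint of the class means, so a trial
#' with positive decision score is assigned the first class level.
#'
#' @param features numeric matrix `n x d`.
#' @param labels per-row class labels (exactly two classes).
#' @param ridge ridge added to `Sw` as a fraction of its mean diagonal when
#'   plain inversion fails.
#' @return an object of class `lda_model` with `w`, `b`, `levels`.
#' @export
fit_lda <- function(features, labels, ridge = 1e-8) {
  features <- as.matrix(features)
  lv <- intersect(c("left", "right"), unique(labels))
  if (length(lv) < 2) lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2 || !all(lv %in% labels)) {
    stop("fit_lda requires observations from exactly two classes")
  }
  Xa <- features[labels == lv[1], , drop = FALSE]
  Xb <- features[labels == lv[2], , drop = FALSE]
  mu_a <- colMeans(Xa)
  mu_b <- colMeans(Xb)
  ca <- stats::cov(Xa) * (nrow(Xa) - 1)
  cb <- stats::cov(Xb) * (nrow(Xb) - 1)
  if (nrow(Xa) < 2) ca <- matrix(0, ncol(features), ncol(features))
  if (nrow(Xb) < 2) cb <- matrix(0, ncol(features), ncol(features))
  Sw <- (ca + cb) / nrow(features)   # pooled ML covariance: invariant to
                                     # duplicating the training sample

  w <- tryCatch(solve(Sw, mu_a - mu_b), error = function(e) {
    solve(Sw + diag(ridge * mean(diag(Sw)) + 1e-12, ncol(Sw)), mu_a - mu_b)
  })
  b <- -sum(w * (mu_a + mu_b)) / 2
  structure(list(w = w, b = b, levels = lv), class = "lda_model")
}

#' @rdname fit_lda
#' @param model an `lda_model`.
#' @export
predict_lda <- function(features, model) {
  features <- as.matrix(features)
  score <- as.numeric(features %*% model$w + model$b)
  model$levels[ifelse(score > 0, 1L, 2L)]
}

#' Cross-validated CSP-LDA baseline
#'
#' For each stratified fold, CSP filters and the discriminant are fitted on
#' the training folds only (no leakage) and evaluated on the held-out
#' fold. The default input is the 6-row band-stacked representation, whose
#' band-channel rows act as CSP channels.
#'
#' @param epochs a `band_stacked_epochs` or [raw_trial_set()].
#' @param m CSP filter pairs.
#' @param folds fold count.
#' @param seed integer seed for the fold split.
#' @return an `eval_report` (same contract as [run_cv()]).
#' @export
run_csp_lda_cv <- function(epochs, m = 1, folds = 10, seed = 1L) {
  dat <- epochs$data
  labels <- epochs$labels
  n <- dim(dat)[1]
  lv <- intersect(c("left", "right"), unique(labels))
  if (length(lv) < 2) lv <- sort(unique(labels))
  fold_idx <- kfold_split(n, folds, labels, seed)
  fold_acc <- numeric(length(fold_idx))
  confusion <- matrix(0L, 2, 2, dimnames = list(true = lv, predicted = lv))
  for (f in seq_along(fold_idx)) {
    test <- fold_idx[[f]]
    train <- setdiff(seq_len(n), test)
    tr_lab <- labels[train]
    csp <- fit_csp(dat[train[tr_lab == lv[1]], , , drop = FALSE],
                   dat[train[tr_lab == lv[2]], , , drop = FALSE], m = m)
    feats <- function(idx) {
      t(vapply(idx, function(i) csp_features(dat[i, , ], csp),
               numeric(2 * m)))
    }
    lda <- fit_lda(feats(train), tr_lab)
    pred <- predict_lda(feats(test), lda)
    fold_acc[f] <- mean(pred == labels[test])
    confusion <- confusion + table(factor(labels[test], levels = lv),
                                   factor(pred, levels = lv))
  }
  eval_report("csp_lda", fold_acc, confusion,
              config = list(m = m, folds = folds), seed = seed)
}
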