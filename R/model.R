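# Trainable realization of a network_spec in base-R matrix algebra.
#
# Both convolutions in this architecture reduce exactly to patch-matrix
# products: the temporal conv (kernel 1 x 8, stride 1 x 8, same padding)
# gathers 110 padded windows of 8 samples x 6 band-channels per trial, and
# the time-frequency conv (kernel 64 x 1, stride 1) takes each of the 93
# map columns whole. Forward, backward and Adam updates therefore run as
# dense matrix operations; results are bit-reproducible under a seed.

# --- patch extraction -------------------------------------------------------

# x: (n, c, w) array; width-direction conv with kernel k, stride s.
# Returns rows ordered position-fastest within trial: row = (t-1)*P + p.
patches_width <- function(x, k, s, padding) {
  d <- dim(x)
  n <- d[1]; c_in <- d[2]; w <- d[3]
  P <- if (padding == "same") ceiling(w / s) else floor((w - k) / s) + 1
  pad_left <- if (padding == "same") {
    max((P - 1) * s + k - w, 0) %/% 2
  } else 0
  M <- matrix(0, n * P, k * c_in)
  for (wi in seq_len(k)) {
    src <- (seq_len(P) - 1) * s - pad_left + wi
    ok <- which(src >= 1 & src <= w)
    if (length(ok) == 0) next
    rowidx <- rep((seq_len(n) - 1) * P, each = length(ok)) + ok
    for (ci in seq_len(c_in)) {
      vals <- t(matrix(x[, ci, src[ok]], nrow = n))
      M[rowidx, (wi - 1) * c_in + ci] <- as.vector(vals)
    }
  }
  list(mat = M, n = n, P = P)
}

# maps: (n, h, w) array; full-height column conv (kernel h x 1).
patches_column <- function(maps) {
  d <- dim(maps)
  ap <- aperm(maps, c(2, 3, 1))              # (h, w, n)
  M <- t(matrix(ap, d[2], d[3] * d[1]))      # rows: column-fastest per trial
  list(mat = M, n = d[1], P = d[3])
}

# --- model construction -----------------------------------------------------

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

branch_plan <- function(layers, in_shape, tag) {
  kinds <- vapply(layers, `[[`, "", "kind")
  if (!identical(kinds, c("conv2d", "maxpool2d", "flatten"))) {
    stop(sprintf("unsupported %s branch: expected conv2d, maxpool2d, flatten (got %s)",
                 tag, paste(kinds, collapse = ", ")))
  }
  conv <- layers[[1]]; pool <- layers[[2]]
  if (conv$kernel[1] == 1) {
    mode <- "width"
    patch_len <- conv$kernel[2] * in_shape[3]
  } else if (conv$kernel[1] == in_shape[1] && conv$kernel[2] == 1 && in_shape[3] == 1) {
    mode <- "column"
    patch_len <- conv$kernel[1]
  } else {
    stop(sprintf("unsupported %s conv geometry (kernel %s)", tag,
                 paste(conv$kernel, collapse = "x")))
  }
  shp <- branch_shapes(layers, in_shape)
  list(mode = mode, conv = conv, pool = pool, patch_len = patch_len,
       P = shp[[1]][2], P2 = shp[[2]][2], filters = conv$filters,
       flat = shp[[3]], activation = conv$activation)
}

#' Build a trainable model from a network specification
#'
#' Instantiates the layers of a `network_spec` with Glorot-uniform weights
#' drawn from a seeded stream. The resulting model's layer output shapes
#' and trainable-parameter counts equal the [propagate_shapes()] /
#' [count_parameters()] predictions exactly.
#'
#' @param spec a `network_spec` from [build_tbtf()] or
#'   [build_single_branch()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `tbtf_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  kinds <- vapply(spec$head, `[[`, "", "kind")
  if (!identical(kinds, c("dense", "dropout", "dense"))) {
    stop("unsupported head: expected dense, dropout, dense(softmax)")
  }
  if (spec$head[[3]]$activation != "softmax") {
    stop("head output layer must use softmax activation")
  }
  plans <- list()
  if (!is.null(spec$eeg_branch)) {
    plans$eeg <- branch_plan(spec$eeg_branch, spec$input_eeg, "eeg")
  }
  if (!is.null(spec$cwt_branch)) {
    plans$cwt <- branch_plan(spec$cwt_branch, spec$input_cwt, "cwt")
  }
  if (length(plans) == 0) stop("spec has no branches")
  concat <- sum(vapply(plans, `[[`, 0, "flat"))
  units1 <- spec$head[[1]]$units
  units2 <- spec$head[[3]]$units
  params <- with_seed(seed, {
    p <- list()
    for (b in names(plans)) {
      pl <- plans[[b]]
      fan_in <- pl$patch_len
      fan_out <- prod(pl$conv$kernel) * pl$filters
      p[[paste0("W_", b)]] <- glorot(pl$patch_len, pl$filters, fan_in, fan_out)
      p[[paste0("b_", b)]] <- numeric(pl$filters)
    }
    p$W_d1 <- glorot(concat, units1, concat, units1)
    p$b_d1 <- numeric(units1)
    p$W_d2 <- glorot(units1, units2, units1, units2)
    p$b_d2 <- numeric(units2)
    p
  })
  structure(list(spec = spec, variant = spec$variant, plans = plans,
                 concat = concat, dropout = spec$head[[2]]$rate,
                 head_act = spec$head[[1]]$activation,
                 params = params, class_levels = c("left", "right")),
            class = "tbtf_model")
}

#' Total trainable parameters of a built model
#' @param model a `tbtf_model`.
#' @return integer count over all weight and bias arrays.
#' @export
model_n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# --- forward / backward -----------------------------------------------------

act_fun <- function(z, act) {
  switch(act, elu = elu(z), relu = relu(z), none = z,
         stop("unsupported activation"))
}

act_grad <- function(z, a_out, act) {
  switch(act,
         elu = ifelse(z >= 0, 1, a_out + 1),
         relu = (z > 0) * 1,
         none = array(1, dim = dim(z)))
}

build_patches <- function(model, inputs) {
  pp <- list()
  for (b in names(model$plans)) {
    pl <- model$plans[[b]]
    x <- inputs[[b]]
    if (is.null(x)) stop(sprintf("variant '%s' requires the %s input", model$variant, b))
    spec_in <- if (b == "eeg") model$spec$input_eeg else model$spec$input_cwt
    d <- dim(x)
    expect <- if (pl$mode == "width") c(spec_in[3], spec_in[2]) else spec_in[1:2]
    if (!identical(as.integer(d[2:3]), as.integer(expect))) {
      stop(sprintf("%s input shape (%d, %d) does not match spec (%d, %d)",
                   b, d[2], d[3], expect[1], expect[2]))
    }
    pp[[b]] <- if (pl$mode == "width") {
      patches_width(x, pl$conv$kernel[2], pl$conv$stride[2], pl$conv$padding)
    } else {
      patches_column(x)
    }
  }
  pp
}

subset_patches <- function(pp, idx) {
  lapply(pp, function(p) {
    rows <- rep((idx - 1) * p$P, each = p$P) + seq_len(p$P)
    list(mat = p$mat[rows, , drop = FALSE], n = length(idx), P = p$P)
  })
}

branch_forward <- function(pl, params, b, pmat, n) {
  W <- params[[paste0("W_", b)]]
  bias <- params[[paste0("b_", b)]]
  Z <- pmat %*% W + matrix(bias, nrow(pmat), length(bias), byrow = TRUE)
  A <- act_fun(Z, pl$activation)
  arr <- array(A, dim = c(pl$P, n, pl$filters))
  k <- pl$pool$kernel[2]; s <- pl$pool$stride[2]
  starts <- (seq_len(pl$P2) - 1) * s
  m <- arr[starts + 1, , , drop = FALSE]
  arg <- array(1L, dim = dim(m))
  if (k > 1) {
    for (j in 2:k) {
      cand <- arr[starts + j, , , drop = FALSE]
      upd <- cand > m
      m[upd] <- cand[upd]
      arg[upd] <- j
    }
  }
  Fm <- t(matrix(aperm(m, c(1, 3, 2)), pl$P2 * pl$filters, n))
  list(Fm = Fm, Z = Z, A = A, arg = arg, n = n)
}

branch_backward <- function(pl, params, b, cache, dF, pmat) {
  n <- cache$n
  dm <- aperm(array(t(dF), dim = c(pl$P2, pl$filters, n)), c(1, 3, 2))
  dA <- array(0, dim = c(pl$P, n, pl$filters))
  k <- pl$pool$kernel[2]; s <- pl$pool$stride[2]
  starts <- (seq_len(pl$P2) - 1) * s
  for (j in seq_len(k)) {
    sel <- cache$arg == j
    if (!any(sel)) next
    tmp <- array(0, dim = dim(dm))
    tmp[sel] <- dm[sel]
    dA[starts + j, , ] <- dA[starts + j, , , drop = FALSE] + tmp
  }
  dZ <- matrix(dA, pl$P * n, pl$filters) * act_grad(cache$Z, cache$A, pl$activation)
  list(dW = crossprod(pmat, dZ), db = colSums(dZ))
}

model_forward <- function(model, pp, training = FALSE, dropout_mask = NULL) {
  caches <- list()
  Fs <- list()
  n <- pp[[1]]$n
  for (b in names(model$plans)) {
    caches[[b]] <- branch_forward(model$plans[[b]], model$params, b,
                                  pp[[b]]$mat, n)
    Fs[[b]] <- caches[[b]]$Fm
  }
  Zc <- do.call(cbind, Fs)
  Z1 <- Zc %*% model$params$W_d1 +
    matrix(model$params$b_d1, n, length(model$params$b_d1), byrow = TRUE)
  D1 <- act_fun(Z1, model$head_act)
  D1d <- if (training && model$dropout > 0) {
    if (is.null(dropout_mask)) {
      keep <- 1 - model$dropout
      dropout_mask <- (matrix(stats::runif(length(D1)), nrow(D1)) < keep) / keep
    }
    D1 * dropout_mask
  } else D1
  logits <- D1d %*% model$params$W_d2 +
    matrix(model$params$b_d2, n, length(model$params$b_d2), byrow = TRUE)
  probs <- softmax(logits)
  list(probs = probs, caches = caches, Zc = Zc, Z1 = Z1, D1 = D1, D1d = D1d,
       mask = dropout_mask, n = n)
}

model_backward <- function(model, fw, pp, y_idx) {
  n <- fw$n
  Y <- matrix(0, n, ncol(fw$probs))
  Y[cbind(seq_len(n), y_idx)] <- 1
  dlog <- (fw$probs - Y) / n
  grads <- list()
  grads$W_d2 <- crossprod(fw$D1d, dlog)
  grads$b_d2 <- colSums(dlog)
  dD1d <- tcrossprod(dlog, model$params$W_d2)
  dD1 <- if (!is.null(fw$mask)) dD1d * fw$mask else dD1d
  dZ1 <- dD1 * act_grad(fw$Z1, fw$D1, model$head_act)
  grads$W_d1 <- crossprod(fw$Zc, dZ1)
  grads$b_d1 <- colSums(dZ1)
  dZc <- tcrossprod(dZ1, model$params$W_d1)
  off <- 0
  for (b in names(model$plans)) {
    w <- model$plans[[b]]$flat
    dF <- dZc[, off + seq_len(w), drop = FALSE]
    g <- branch_backward(model$plans[[b]], model$params, b, fw$caches[[b]],
                         dF, pp[[b]]$mat)
    grads[[paste0("W_", b)]] <- g$dW
    grads[[paste0("b_", b)]] <- g$db
    off <- off + w
  }
  grads
}

cross_entropy <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

# --- training ---------------------------------------------------------------

#' Training configuration
#'
#' Adam with the conventional moment decays, categorical cross-entropy
#' loss, mini-batches, and early stopping on an inner validation split of
#' the training data.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates, in `(0, 1)`.
#' @param batch_size mini-batch size.
#' @param max_epochs upper bound on training epochs.
#' @param patience epochs without validation-loss improvement before
#'   stopping; the best-epoch weights are restored.
#' @param val_fraction fraction of the training trials held out (stratified)
#'   for early stopping; set 0 to train for exactly `max_epochs`.
#' @param folds cross-validation fold count for [run_cv()].
#' @param seed master seed; all randomness (weight init, batch order,
#'   dropout, fold assignment) derives from it.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 32, max_epochs = 100, patience = 20,
                         val_fraction = 0.1, folds = 10, seed = 1L) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            batch_size >= 1, max_epochs >= 1, folds >= 2,
            val_fraction >= 0, val_fraction < 0.5)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), val_fraction = val_fraction,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "train_config")
}

adam_step <- function(state, params, grads, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mh <- state$m[[nm]] / (1 - b1^state$t)
    vh <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(state = state, params = params)
}

#' Train a model on prepared inputs
#'
#' @param spec a `network_spec`.
#' @param inputs list with elements `eeg` (array `n x 6 x 875`) and/or
#'   `cwt` (array `n x 64 x 93`) as the variant requires.
#' @param labels per-trial class labels (`"left"`/`"right"`).
#' @param config a [train_config()].
#' @param seed seed for this training run (defaults to `config$seed`).
#' @return a fitted `tbtf_model` (best-validation-epoch weights when early
#'   stopping is active).
#' @export
train_network <- function(spec, inputs, labels, config = train_config(),
                          seed = config$seed) {
  lv <- intersect(c("left", "right"), unique(labels))
  if (length(lv) < 2) lv <- sort(unique(labels))
  if (length(lv) != 2) stop("training requires exactly two classes")
  y <- as.integer(factor(labels, levels = lv))
  n <- length(y)

  model <- build_model(spec, seed = derive_seed(seed, 1))
  model$class_levels <- lv
  pp_all <- build_patches(model, inputs)

  with_seed(derive_seed(seed, 2), {
    # stratified inner validation split for early stopping
    val_idx <- integer(0)
    if (config$val_fraction > 0 && n >= 10) {
      for (cl in 1:2) {
        cls <- which(y == cl)
        nv <- max(1, round(config$val_fraction * length(cls)))
        val_idx <- c(val_idx, sample(cls, nv))
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    pp_val <- if (length(val_idx)) subset_patches(pp_all, val_idx)

    state <- list(t = 0,
                  m = lapply(model$params, function(p) p * 0),
                  v = lapply(model$params, function(p) p * 0))
    best <- list(loss = Inf, params = model$params, wait = 0)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(tr_idx)
      nb <- ceiling(length(ord) / config$batch_size)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size,
                                                          length(ord))]
        pp_b <- subset_patches(pp_all, idx)
        fw <- model_forward(model, pp_b, training = TRUE)
        grads <- model_backward(model, fw, pp_b, y[idx])
        upd <- adam_step(state, model$params, grads, config$learning_rate,
                         config$beta1, config$beta2)
        state <- upd$state
        model$params <- upd$params
      }
      if (length(val_idx)) {
        fw <- model_forward(model, pp_val, training = FALSE)
        loss <- cross_entropy(fw$probs, y[val_idx])
        if (loss < best$loss - 1e-6) {
          best$loss <- loss
          best$params <- model$params
          best$wait <- 0
        } else {
          best$wait <- best$wait + 1
          if (best$wait >= config$patience) break
        }
      }
    }
    if (length(val_idx)) model$params <- best$params
  })
  model
}

#' Class probabilities for prepared inputs
#'
#' @param model a fitted `tbtf_model`.
#' @param inputs list with the arrays the variant requires (see
#'   [train_network()]).
#' @return numeric matrix `n x 2` of per-class probabilities (columns named
#'   by class); rows sum to one.
#' @export
predict_proba <- function(model, inputs) {
  pp <- build_patches(model, inputs)
  probs <- model_forward(model, pp, training = FALSE)$probs
  colnames(probs) <- model$class_levels
  probs
}

subset_inputs <- function(inputs, idx) {
  out <- list()
  for (nm in c("eeg", "cwt")) {
    if (!is.null(inputs[[nm]])) out[[nm]] <- inputs[[nm]][idx, , , drop = FALSE]
  }
  out
}
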