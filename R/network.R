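#' Layer specifications
#'
#' Declarative layer descriptions from which models are built, shapes
#' propagated and parameter counts derived. Shapes are `(height, width,
#' channels)`.
#'
#' @param filters number of convolution filters.
#' @param kernel,stride two-element `(h, w)` sizes.
#' @param padding `"same"` or `"valid"`.
#' @param activation one of `"elu"`, `"relu"`, `"softmax"`, `"none"`.
#' @param units dense layer width.
#' @param rate dropout probability in `[0, 1)` (probability of dropping a
#'   unit, the TensorFlow convention).
#' @return an object of class `layer_spec`.
#' @name layer_spec
NULL

layer_spec <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
conv2d_spec <- function(filters, kernel, stride, padding = "valid",
                        activation = "none") {
  stopifnot(filters >= 1, all(kernel >= 1), all(stride >= 1),
            padding %in% c("same", "valid"),
            activation %in% c("elu", "relu", "softmax", "none"))
  layer_spec("conv2d", filters = as.integer(filters), kernel = as.integer(kernel),
             stride = as.integer(stride), padding = padding, activation = activation)
}

#' @rdname layer_spec
#' @export
maxpool2d_spec <- function(kernel, stride = kernel) {
  stopifnot(all(kernel >= 1), all(stride >= 1))
  layer_spec("maxpool2d", kernel = as.integer(kernel), stride = as.integer(stride))
}

#' @rdname layer_spec
#' @export
flatten_spec <- function() layer_spec("flatten")

#' @rdname layer_spec
#' @export
dense_spec <- function(units, activation = "none") {
  stopifnot(units >= 1, activation %in% c("elu", "relu", "softmax", "none"))
  layer_spec("dense", units = as.integer(units), activation = activation)
}

#' @rdname layer_spec
#' @export
dropout_spec <- function(rate) {
  if (rate < 0 || rate >= 1) stop("dropout rate must lie in [0, 1)")
  layer_spec("dropout", rate = rate)
}

#' @rdname layer_spec
#' @export
concatenate_spec <- function() layer_spec("concatenate")

#' Two-branch temporal / time-frequency network specification
#'
#' [build_tbtf()] declares the full two-branch architecture: a temporal
#' (EEG) branch convolving the `1 x 875 x 6` band-stacked signal with 32
#' non-overlapping `1 x 8` kernels (ELU), a time-frequency (CWT) branch
#' convolving the `64 x 93 x 1` map with 32 full-height `64 x 1` kernels
#' (ReLU), each followed by `1 x 3` max-pooling and flattening; the fused
#' 2144-wide vector feeds a 128-unit ReLU layer, dropout, and a 2-unit
#' softmax output. [build_single_branch()] keeps one branch with the same
#' classification head (the ablation variants).
#'
#' @param dropout drop probability of the head dropout layer.
#' @return an object of class `network_spec` with fields `variant`,
#'   `eeg_branch`, `cwt_branch`, `head`, `input_eeg`, `input_cwt`.
#' @export
build_tbtf <- function(dropout = 0.8) {
  network_spec(
    variant = "tbtf",
    eeg_branch = eeg_branch_layers(),
    cwt_branch = cwt_branch_layers(),
    head = head_layers(dropout)
  )
}

#' @rdname build_tbtf
#' @param which `"eeg"` or `"cwt"`: which branch the single-branch variant
#'   keeps.
#' @export
build_single_branch <- function(which = c("eeg", "cwt"), dropout = 0.8) {
  if (!is.character(which) || !(which[1] %in% c("eeg", "cwt"))) {
    stop("unknown variant: `which` must be \"eeg\" or \"cwt\"")
  }
  which <- which[1]
  network_spec(
    variant = paste0(which, "_only"),
    eeg_branch = if (which == "eeg") eeg_branch_layers(),
    cwt_branch = if (which == "cwt") cwt_branch_layers(),
    head = head_layers(dropout)
  )
}

eeg_branch_layers <- function() {
  list(conv2d_spec(32, c(1, 8), c(1, 8), "same", "elu"),
       maxpool2d_spec(c(1, 3)),
       flatten_spec())
}

cwt_branch_layers <- function() {
  list(conv2d_spec(32, c(64, 1), c(1, 1), "valid", "relu"),
       maxpool2d_spec(c(1, 3)),
       flatten_spec())
}

head_layers <- function(dropout = 0.8) {
  list(dense_spec(128, "relu"),
       dropout_spec(dropout),
       dense_spec(2, "softmax"))
}

network_spec <- function(variant, eeg_branch = NULL, cwt_branch = NULL, head,
                         input_eeg = c(1, 875, 6), input_cwt = c(64, 93, 1)) {
  structure(list(variant = variant, eeg_branch = eeg_branch,
                 cwt_branch = cwt_branch, head = head,
                 input_eeg = as.integer(input_eeg),
                 input_cwt = as.integer(input_cwt)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> variant = %s\n", x$variant))
  pc <- count_parameters(x)
  print(pc$layers, row.names = FALSE)
  cat(sprintf("total trainable parameters: %d\n", pc$total))
  invisible(x)
}

#' Output shape of a single layer
#'
#' Shape arithmetic per axis: a `same`-padded convolution gives
#' `ceil(in / stride)`; a `valid` convolution or pooling layer gives
#' `floor((in - kernel) / stride) + 1`; convolution sets the channel count
#' to `filters`; `flatten` returns the total element count.
#'
#' @param layer a `layer_spec`.
#' @param in_shape integer `(h, w, c)` input shape.
#' @return the output shape `(h, w, c)`, or a single width for `flatten`.
#' @export
output_shape <- function(layer, in_shape) {
  ax <- function(n, k, s, padding) {
    out <- if (padding == "same") ceiling(n / s) else floor((n - k) / s) + 1
    if (out < 1) stop(sprintf("layer output dimension %d is nonpositive", out))
    out
  }
  switch(layer$kind,
    conv2d = {
      if (layer$padding == "valid" && any(layer$kernel > in_shape[1:2])) {
        stop("conv kernel exceeds input under valid padding")
      }
      c(ax(in_shape[1], layer$kernel[1], layer$stride[1], layer$padding),
        ax(in_shape[2], layer$kernel[2], layer$stride[2], layer$padding),
        layer$filters)
    },
    maxpool2d = {
      if (any(layer$kernel > in_shape[1:2])) stop("pool kernel exceeds input")
      c(ax(in_shape[1], layer$kernel[1], layer$stride[1], "valid"),
        ax(in_shape[2], layer$kernel[2], layer$stride[2], "valid"),
        in_shape[3])
    },
    flatten = prod(in_shape),
    dense = layer$units,
    dropout = in_shape,
    stop(sprintf("output_shape undefined for layer kind '%s'", layer$kind))
  )
}

branch_shapes <- function(layers, in_shape) {
  shapes <- vector("list", length(layers))
  cur <- in_shape
  for (i in seq_along(layers)) {
    cur <- output_shape(layers[[i]], cur)
    shapes[[i]] <- cur
  }
  shapes
}

#' Propagate shapes through a network specification
#'
#' @param spec a `network_spec`.
#' @return list with per-branch shape sequences, the flatten widths, the
#'   head input width (`concat_width`) and head shapes.
#' @export
propagate_shapes <- function(spec) {
  res <- list()
  widths <- c()
  if (!is.null(spec$eeg_branch)) {
    res$eeg <- branch_shapes(spec$eeg_branch, spec$input_eeg)
    widths <- c(widths, res$eeg[[length(res$eeg)]])
  }
  if (!is.null(spec$cwt_branch)) {
    res$cwt <- branch_shapes(spec$cwt_branch, spec$input_cwt)
    widths <- c(widths, res$cwt[[length(res$cwt)]])
  }
  res$flatten_widths <- widths
  res$concat_width <- sum(widths)
  cur <- res$concat_width
  res$head <- vector("list", length(spec$head))
  for (i in seq_along(spec$head)) {
    cur <- output_shape(spec$head[[i]], cur)
    res$head[[i]] <- cur
  }
  res
}

#' Per-layer and total trainable-parameter counts
#'
#' Convolution: `kh * kw * c_in * filters + filters`; dense:
#' `in * units + units`; pooling, flatten, concatenation and dropout carry
#' no parameters.
#'
#' @param spec a `network_spec`.
#' @return list with a `layers` data frame (`layer`, `output`, `params`)
#'   and the `total` count.
#' @export
count_parameters <- function(spec) {
  shp <- propagate_shapes(spec)
  rows <- list()
  add <- function(name, out, params) {
    rows[[length(rows) + 1]] <<- data.frame(
      layer = name, output = paste(out, collapse = " x "),
      params = as.integer(params), stringsAsFactors = FALSE)
  }
  walk_branch <- function(layers, shapes, in_shape, tag) {
    cur <- in_shape
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      p <- switch(l$kind,
        conv2d = prod(l$kernel) * cur[3] * l$filters + l$filters,
        0)
      add(paste0(tag, "_", l$kind), shapes[[i]], p)
      cur <- shapes[[i]]
    }
  }
  if (!is.null(spec$eeg_branch)) {
    walk_branch(spec$eeg_branch, shp$eeg, spec$input_eeg, "eeg")
  }
  if (!is.null(spec$cwt_branch)) {
    walk_branch(spec$cwt_branch, shp$cwt, spec$input_cwt, "cwt")
  }
  if (length(shp$flatten_widths) > 1) add("concatenate", shp$concat_width, 0)
  cur <- shp$concat_width
  for (i in seq_along(spec$head)) {
    l <- spec$head[[i]]
    p <- if (l$kind == "dense") cur * l$units + l$units else 0
    add(paste0("head_", l$kind), shp$head[[i]], p)
    cur <- shp$head[[i]]
  }
  layers <- do.call(rbind, rows)
  list(layers = layers, total = sum(layers$params))
}

#' Activation functions
#'
#' `elu(x) = x` for `x >= 0` and `a * (exp(x) - 1)` otherwise;
#' `relu(x) = max(x, 0)`; `softmax` exponentiates and normalizes each row
#' (or the vector) to sum to one, with max-subtraction for overflow safety.
#'
#' @param x numeric vector/matrix.
#' @param a positive ELU saturation scale.
#' @param y numeric vector, or matrix whose rows are score vectors.
#' @return transformed values; `softmax` returns probabilities.
#' @name activations
NULL

#' @rdname activations
#' @export
elu <- function(x, a = 1) {
  if (a <= 0) stop("elu scale a must be positive")
  ifelse(x >= 0, x, a * (exp(pmin(x, 0)) - 1))
}

#' @rdname activations
#' @export
relu <- function(x) pmax(x, 0)

#' @rdname activations
#' @export
softmax <- function(y) {
  if (is.matrix(y)) {
    z <- exp(y - apply(y, 1, max))
    z / rowSums(z)
  } else {
    z <- exp(y - max(y))
    z / sum(z)
  }
}

#' Serialize / parse a network specification
#'
#' Writes the spec as human-readable JSON so variants can be diffed;
#' parsing reconstructs an identical `network_spec`.
#'
#' @param spec a `network_spec`.
#' @param path file path; for `network_spec_json` omit to get the string.
#' @return `network_spec_read` returns the reconstructed spec.
#' @export
network_spec_write <- function(spec, path) {
  writeLines(network_spec_json(spec), path)
  invisible(path)
}

#' @rdname network_spec_write
#' @export
network_spec_json <- function(spec) {
  plain <- unclass(spec)
  for (part in c("eeg_branch", "cwt_branch", "head")) {
    if (!is.null(plain[[part]])) plain[[part]] <- lapply(plain[[part]], unclass)
  }
  jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

#' @rdname network_spec_write
#' @export
network_spec_read <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  relayer <- function(l) {
    l <- lapply(l, function(v) if (is.list(v)) unlist(v) else v)
    int_fields <- intersect(names(l), c("filters", "kernel", "stride", "units"))
    for (f in int_fields) l[[f]] <- as.integer(l[[f]])
    structure(l, class = "layer_spec")
  }
  network_spec(
    variant = raw$variant,
    eeg_branch = if (!is.null(raw$eeg_branch)) lapply(raw$eeg_branch, relayer),
    cwt_branch = if (!is.null(raw$cwt_branch)) lapply(raw$cwt_branch, relayer),
    head = lapply(raw$head, relayer),
    input_eeg = unlist(raw$input_eeg),
    input_cwt = unlist(raw$input_cwt)
  )
}
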