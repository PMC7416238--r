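## Per-view convolutional feature extractors. Each view has a fixed
## architecture: a stack of convolutions (ReLU) followed by fully connected
## layers, ending in a feature vector of width 1024 (time view), 512
## (spectral view) or 2048 (time-frequency view). The printed layer shapes
## of the source architecture are mutually inconsistent in places; declared
## output shapes are taken as authoritative and each convolution carries the
## minimal zero-padding (positive) or center-cropping (negative) per
## dimension that makes the arithmetic work — every such adjustment is
## recorded in the layer's `note`. The multiview FCM core does not depend on
## this module; it is an optional front end.

conv_layer <- function(n_in, n_out, kernel, stride, in_shape, out_shape) {
  pad <- (out_shape - 1L) * stride + kernel - in_shape
  note <- NULL
  if (any(pad != 0))
    note <- paste0("dim adjustments (",
                   paste(ifelse(pad > 0, paste0("pad ", pad),
                                paste0("crop ", -pad))[pad != 0],
                         collapse = ", "),
                   ") to reach the declared output shape")
  list(kind = "conv", n_in = n_in, n_out = n_out,
       kernel = as.integer(kernel), stride = as.integer(stride),
       in_shape = as.integer(in_shape), out_shape = as.integer(out_shape),
       pad = as.integer(pad), note = note)
}

fc_layer <- function(n_in, n_out) {
  list(kind = "fc", n_in = as.integer(n_in), n_out = as.integer(n_out))
}

#' Architecture specification of a per-view feature extractor
#'
#' Returns the layer stack for one of the three EEG views. Input geometries
#' are 23 x 256 (time), 23 x 27 (spectral) and 256 x 23 x 14
#' (time-frequency); output feature widths are 1024, 512 and 2048
#' respectively.
#'
#' @param view One of `"time"`, `"spectral"`, `"timefreq"`.
#' @return An object of class `"extractor_spec"` with fields `view`,
#'   `input_shape`, `layers` and `output_dim`. The layer chain is validated
#'   on construction; convolution layers whose declared shapes require
#'   padding or cropping carry an explanatory `note`.
#' @examples
#' extractor_spec("spectral")$output_dim
#' @export
extractor_spec <- function(view = c("time", "spectral", "timefreq")) {
  view <- match.arg(view)
  spec <- switch(view,
    time = list(
      input_shape = c(23L, 256L),
      layers = list(
        conv_layer(1L, 1L, c(1, 128), c(1, 1), c(23, 256), c(23, 129)),
        conv_layer(1L, 30L, c(1, 65), c(1, 30), c(23, 129), c(23, 6)),
        conv_layer(30L, 20L, c(4, 33), c(1, 1), c(23, 6), c(20, 33)),
        conv_layer(20L, 10L, c(8, 18), c(1, 1), c(20, 33), c(13, 16)),
        fc_layer(2080L, 102L),
        fc_layer(102L, 100L),
        fc_layer(100L, 1024L)),
      output_dim = 1024L),
    spectral = list(
      input_shape = c(23L, 27L),
      layers = list(
        conv_layer(1L, 20L, c(4, 4), c(1, 1), c(23, 27), c(20, 24)),
        conv_layer(20L, 10L, c(8, 8), c(1, 1), c(20, 24), c(13, 17)),
        fc_layer(2210L, 512L),
        fc_layer(512L, 100L),
        fc_layer(100L, 512L)),
      output_dim = 512L),
    timefreq = list(
      input_shape = c(256L, 23L, 14L),
      layers = list(
        conv_layer(1L, 1L, c(129, 1, 1), c(1, 1, 1), c(256, 23, 14),
                   c(128, 23, 24)),
        conv_layer(1L, 30L, c(65, 4, 4), c(1, 1, 1), c(128, 23, 24),
                   c(64, 24, 11)),
        conv_layer(30L, 20L, c(30, 4, 4), c(1, 1, 1), c(64, 24, 11),
                   c(32, 17, 8)),
        conv_layer(20L, 10L, c(17, 8, 1), c(1, 1, 1), c(32, 17, 8),
                   c(16, 10, 8)),
        fc_layer(12800L, 2048L),
        fc_layer(2048L, 1024L),
        fc_layer(1024L, 100L),
        fc_layer(100L, 2048L)),
      output_dim = 2048L))
  spec$view <- view
  class(spec) <- "extractor_spec"
  validate_extractor_spec(spec)
  spec
}

#' Validate an extractor layer chain
#'
#' Checks that every layer's input matches its predecessor's output: map
#' counts and spatial shapes chain through the convolutions (accounting for
#' each layer's recorded padding/cropping), the first fully connected layer
#' consumes the flattened final convolution output, and the last layer
#' produces `output_dim` features.
#'
#' @param spec An [extractor_spec()].
#' @return `TRUE` invisibly; stops with a message on any inconsistency.
#' @export
validate_extractor_spec <- function(spec) {
  shape <- spec$input_shape
  maps <- 1L
  flat <- NULL
  for (li in seq_along(spec$layers)) {
    layer <- spec$layers[[li]]
    if (layer$kind == "conv") {
      if (!is.null(flat))
        stop("convolution after a fully connected layer", call. = FALSE)
      if (layer$n_in != maps || !identical(layer$in_shape, shape))
        stop(sprintf("layer %d input does not chain", li), call. = FALSE)
      got <- (layer$in_shape + layer$pad - layer$kernel) %/% layer$stride + 1L
      if (!identical(got, layer$out_shape))
        stop(sprintf("layer %d convolution arithmetic is inconsistent", li),
             call. = FALSE)
      shape <- layer$out_shape
      maps <- layer$n_out
    } else {
      if (is.null(flat)) flat <- maps * prod(shape)
      if (layer$n_in != flat)
        stop(sprintf("layer %d expects %d inputs but receives %d",
                     li, layer$n_in, flat), call. = FALSE)
      flat <- layer$n_out
    }
  }
  if (!identical(as.integer(flat), spec$output_dim))
    stop("final layer width does not equal output_dim", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.extractor_spec <- function(x, ...) {
  cat(sprintf("Extractor spec: %s view, input %s -> %d features, %d layers\n",
              x$view, paste(x$input_shape, collapse = "x"),
              x$output_dim, length(x$layers)))
  for (l in x$layers) {
    if (l$kind == "conv")
      cat(sprintf("  conv %d@%s -> %d@%s kernel %s stride %s%s\n",
                  l$n_in, paste(l$in_shape, collapse = "x"),
                  l$n_out, paste(l$out_shape, collapse = "x"),
                  paste(l$kernel, collapse = "x"),
                  paste(l$stride, collapse = "x"),
                  if (is.null(l$note)) "" else paste0(" [", l$note, "]")))
    else cat(sprintf("  fc %d -> %d\n", l$n_in, l$n_out))
  }
  invisible(x)
}

#' Initialize extractor parameters
#'
#' He-style Gaussian weights (standard deviation `sqrt(2 / fan_in)`) and
#' zero biases for every layer, drawn reproducibly from `seed`.
#'
#' @param spec An [extractor_spec()].
#' @param seed Integer seed.
#' @return A list of per-layer parameter lists (`W`, `b`).
#' @export
init_extractor_params <- function(spec, seed = 1L) {
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  lapply(spec$layers, function(layer) {
    if (layer$kind == "conv") {
      fan_in <- layer$n_in * prod(layer$kernel)
      W <- array(stats::rnorm(layer$n_out * fan_in, sd = sqrt(2 / fan_in)),
                 c(layer$n_out, layer$n_in, layer$kernel))
      list(W = W, b = numeric(layer$n_out))
    } else {
      list(W = matrix(stats::rnorm(layer$n_out * layer$n_in,
                                   sd = sqrt(2 / layer$n_in)),
                      layer$n_out, layer$n_in),
           b = numeric(layer$n_out))
    }
  })
}

## Zero-pad (positive) or center-crop (negative) the spatial axes of a
## maps-first array.
pad_crop <- function(x, pad) {
  d <- dim(x); sp <- d[-1L]
  if (all(pad == 0L)) return(x)
  newsp <- sp + pad
  y <- array(0, c(d[1L], newsp))
  yidx <- vector("list", length(sp))
  xidx <- vector("list", length(sp))
  for (k in seq_along(sp)) {
    if (pad[k] >= 0L) {
      b <- pad[k] %/% 2L
      yidx[[k]] <- b + seq_len(sp[k]); xidx[[k]] <- seq_len(sp[k])
    } else {
      b <- (-pad[k]) %/% 2L
      yidx[[k]] <- seq_len(newsp[k]); xidx[[k]] <- b + seq_len(newsp[k])
    }
  }
  xs <- do.call(`[`, c(list(x), c(list(seq_len(d[1L])), xidx),
                       list(drop = FALSE)))
  do.call(`[<-`, c(list(y), c(list(seq_len(d[1L])), yidx), list(value = xs)))
}

## Convolution as a loop over kernel offsets, each offset contributing one
## BLAS product (n_out x n_in) %*% (n_in x prod(out_shape)).
conv_forward <- function(x, layer, par) {
  xp <- pad_crop(x, layer$pad)
  nd <- length(layer$out_shape)
  outlen <- prod(layer$out_shape)
  acc <- matrix(0, layer$n_out, outlen)
  koffs <- as.matrix(expand.grid(lapply(layer$kernel,
                                        function(k) seq_len(k) - 1L)))
  Wm <- par$W
  dim(Wm) <- c(layer$n_out, layer$n_in, prod(layer$kernel))
  spat <- vector("list", nd)
  map_idx <- seq_len(layer$n_in)
  for (r in seq_len(nrow(koffs))) {
    for (d in seq_len(nd))
      spat[[d]] <- (seq_len(layer$out_shape[d]) - 1L) * layer$stride[d] +
        koffs[r, d] + 1L
    S <- do.call(`[`, c(list(xp), c(list(map_idx), spat),
                        list(drop = FALSE)))
    dim(S) <- c(layer$n_in, outlen)
    acc <- acc + matrix(Wm[, , r], layer$n_out, layer$n_in) %*% S
  }
  acc <- pmax(acc + par$b, 0)                   # ReLU
  array(acc, c(layer$n_out, layer$out_shape))
}

forward_extractor <- function(spec, params, x) {
  if (is.matrix(x)) {
    stopifnot(identical(dim(x), as.integer(spec$input_shape)))
    h <- array(x, c(1L, dim(x)))
  } else {
    stopifnot(identical(dim(x), as.integer(spec$input_shape)))
    h <- array(x, c(1L, dim(x)))
  }
  n <- length(spec$layers)
  for (li in seq_len(n)) {
    layer <- spec$layers[[li]]
    if (layer$kind == "conv") {
      h <- conv_forward(h, layer, params[[li]])
    } else {
      v <- as.numeric(h)
      z <- drop(params[[li]]$W %*% v + params[[li]]$b)
      h <- if (li < n) pmax(z, 0) else z        # linear feature layer
    }
  }
  as.numeric(h)
}

#' Extract deep features for a batch of view inputs
#'
#' Runs the forward pass of the view's convolutional stack on each input
#' and stacks the feature vectors. Deterministic given the parameters.
#'
#' @param spec An [extractor_spec()].
#' @param params Parameters from [init_extractor_params()] or
#'   [train_extractor()]`$params`.
#' @param inputs A list of view arrays (matrix for the 2-D views, 3-D array
#'   for the time-frequency view), each of shape `spec$input_shape`; a
#'   single array is accepted.
#' @return A `K x output_dim` numeric matrix.
#' @export
extract_features <- function(spec, params, inputs) {
  if (!is.list(inputs)) inputs <- list(inputs)
  out <- t(vapply(inputs, function(x) forward_extractor(spec, params, x),
                  numeric(spec$output_dim)))
  if (!all(is.finite(out)))
    stop("extractor produced non-finite features", call. = FALSE)
  out
}

#' Train a feature-extractor readout on labelled segments
#'
#' The convolutional stack keeps its seeded random initialization (a random
#' convolutional feature map); a logistic-regression readout head on the
#' extracted features is trained by full-batch gradient descent on the
#' binary cross-entropy, giving a seeded, fully reproducible CPU training
#' loop at toy scale.
#'
#' @param spec An [extractor_spec()].
#' @param inputs List of view arrays, one per sample.
#' @param labels 0/1 labels, one per sample; both classes must be present.
#' @param epochs Gradient steps, default 200.
#' @param lr Learning rate, default 0.05.
#' @param seed Seed for the parameter initialization, default 1.
#' @return A list with `params` (the extractor parameters), `head`
#'   (readout weights and bias), `loss_trace`, and the `spec` view name.
#' @export
train_extractor <- function(spec, inputs, labels, epochs = 200L, lr = 0.05,
                            seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training requires both classes to be present", call. = FALSE)
  params <- init_extractor_params(spec, seed)
  FX <- extract_features(spec, params, inputs)
  mu <- colMeans(FX); sdv <- pmax(apply(FX, 2L, stats::sd), 1e-8)
  Z <- sweep(sweep(FX, 2L, mu), 2L, sdv, "/")
  w <- numeric(ncol(Z)); b <- 0
  n <- nrow(Z)
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    eta <- drop(Z %*% w + b)
    p <- 1 / (1 + exp(-eta))
    loss_trace[ep] <- -mean(labels * log(pmax(p, 1e-12)) +
                              (1 - labels) * log(pmax(1 - p, 1e-12)))
    g <- p - labels
    w <- w - lr * (drop(crossprod(Z, g)) / n + 1e-4 * w)
    b <- b - lr * mean(g)
  }
  list(params = params, head = list(w = w, b = b, mu = mu, sd = sdv),
       loss_trace = loss_trace, view = spec$view)
}

#' @rdname train_extractor
#' @param trained The result of `train_extractor()`.
#' @return `predict_extractor()` returns the per-sample probability of the
#'   positive class.
#' @export
predict_extractor <- function(trained, spec, inputs) {
  FX <- extract_features(spec, trained$params, inputs)
  Z <- sweep(sweep(FX, 2L, trained$head$mu), 2L, trained$head$sd, "/")
  1 / (1 + exp(-(drop(Z %*% trained$head$w) + trained$head$b)))
}
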