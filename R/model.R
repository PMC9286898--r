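#' Training configuration for the CDR image classifier
#'
#' Bundles the optimiser and geometry settings used by [cdr_cnn()].  The
#' published settings for the full-scale networks are stochastic gradient
#' descent with momentum 0.9, learning rate 1e-4, 20 epochs and mini-batches
#' of 20 images; those are the defaults for the `alexnet_like` and
#' `inception_like` architectures.  The `tiny` architecture is a desk-scale
#' network intended for small fused images (e.g. 64 x 32); its default
#' learning rate is 0.01, which suits its much smaller parameter scale.
#'
#' @param architecture one of `"tiny"`, `"alexnet_like"`, `"inception_like"`.
#' @param learning_rate positive step size; `NULL` picks the per-architecture
#'   default (0.01 for `tiny`, 1e-4 otherwise).
#' @param momentum SGD momentum coefficient.
#' @param max_epochs maximum number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param seed integer seed controlling weight initialisation and batch
#'   shuffling; fixed seed implies bit-identical training runs.
#' @param input_shape integer `(height, width)` of the input images, or `NULL`
#'   to infer from the data at fit time.
#' @return an object of class `cdr_train_config`.
#' @export
cdr_train_config <- function(architecture = c("tiny", "alexnet_like",
                                              "inception_like"),
                             learning_rate = NULL, momentum = 0.9,
                             max_epochs = 20L, batch_size = 20L, seed = 1L,
                             input_shape = NULL) {
  architecture <- match.arg(architecture)
  if (is.null(learning_rate)) {
    learning_rate <- if (architecture == "tiny") 0.01 else 1e-4
  }
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            momentum >= 0, momentum < 1)
  structure(list(architecture = architecture, learning_rate = learning_rate,
                 momentum = momentum, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 input_shape = input_shape),
            class = "cdr_train_config")
}

#' Build an untrained convolutional network
#'
#' Three architectures are available.  `tiny` is the desk-scale network used
#' throughout the test suite: two convolution blocks (3x3 conv, ReLU, 2x2 max
#' pool) followed by a dense classifier head (32 hidden units, then the
#' 2-class output).  `alexnet_like` re-expresses the five-convolution /
#' three-dense layout with ReLU activations at reduced channel widths.
#' `inception_like` is a stem convolution followed by two inception blocks
#' (parallel 1x1, 3x3, 5x5 and pooled-projection branches concatenated along
#' channels), global average pooling and a dense head.  The final layer of
#' every architecture produces 2-class softmax probabilities.
#'
#' @param architecture architecture id.
#' @param input_shape integer `(height, width)` of the input images.
#' @param channels number of input channels (fused CDR images have 1).
#' @param seed seed for weight initialisation.
#' @return an object of class `cdr_network`.
#' @export
build_network <- function(architecture = c("tiny", "alexnet_like",
                                           "inception_like"),
                          input_shape, channels = 1L, seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(length(input_shape) == 2L, all(input_shape >= 1))
  set.seed(seed)
  shape <- c(as.integer(input_shape), as.integer(channels))
  layers <- list()
  add <- function(lay) {
    layers[[length(layers) + 1L]] <<- lay
    shape <<- lay$out_shape
  }
  if (architecture == "tiny") {
    add(new_conv_layer(shape, 3L, 3L, 8L))
    add(new_relu_layer(shape))
    add(new_maxpool_layer(shape, 2L, 2L, 2L))
    add(new_conv_layer(shape, 3L, 3L, 16L))
    add(new_relu_layer(shape))
    add(new_maxpool_layer(shape, 2L, 2L, 2L))
    add(new_dense_layer(shape, 32L))
    add(new_relu_layer(shape))
    add(new_dense_layer(shape, 2L))
  } else if (architecture == "alexnet_like") {
    add(new_conv_layer(shape, 11L, 11L, 16L, stride = 4L, pad = 2L))
    add(new_relu_layer(shape))
    add(new_maxpool_layer(shape, 3L, 3L, 2L))
    add(new_conv_layer(shape, 5L, 5L, 32L, pad = 2L))
    add(new_relu_layer(shape))
    add(new_maxpool_layer(shape, 3L, 3L, 2L))
    add(new_conv_layer(shape, 3L, 3L, 48L, pad = 1L))
    add(new_relu_layer(shape))
    add(new_conv_layer(shape, 3L, 3L, 48L, pad = 1L))
    add(new_relu_layer(shape))
    add(new_conv_layer(shape, 3L, 3L, 32L, pad = 1L))
    add(new_relu_layer(shape))
    add(new_maxpool_layer(shape, 3L, 3L, 2L))
    add(new_dense_layer(shape, 128L))
    add(new_relu_layer(shape))
    add(new_dense_layer(shape, 64L))
    add(new_relu_layer(shape))
    add(new_dense_layer(shape, 2L))
  } else {
    add(new_conv_layer(shape, 7L, 7L, 16L, stride = 2L, pad = 3L))
    add(new_relu_layer(shape))
    add(new_maxpool_layer(shape, 3L, 3L, 2L, pad = 1L))
    add(new_inception_layer(shape, b1 = 8L, b3r = 8L, b3 = 16L,
                            b5r = 4L, b5 = 8L, pp = 8L))
    add(new_inception_layer(shape, b1 = 16L, b3r = 12L, b3 = 24L,
                            b5r = 4L, b5 = 8L, pp = 8L))
    add(new_gap_layer(shape))
    add(new_dense_layer(shape, 2L))
  }
  structure(list(architecture = architecture, layers = layers,
                 input_shape = c(as.integer(input_shape),
                                 as.integer(channels)),
                 n_params = count_params(layers)),
            class = "cdr_network")
}

#' @export
print.cdr_network <- function(x, ...) {
  cat("<cdr_network> architecture:", x$architecture, "\n")
  cat("  input:", paste(x$input_shape, collapse = " x "),
      " parameters:", x$n_params, "\n")
  invisible(x)
}

# coerce image input to the internal (H*W) x N matrix + shape
as_image_batch <- function(x) {
  if (inherits(x, "cdr_image_stack")) {
    return(list(x = x$x, shape = x$shape))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    return(list(x = matrix(as.numeric(x), d[1L] * d[2L], d[3L]),
                shape = d[1:2]))
  }
  if (is.matrix(x) && !is.null(attr(x, "shape"))) {
    return(list(x = x, shape = attr(x, "shape")))
  }
  stop("images must be a cdr_image_stack, an H x W x N array, ",
       "or a matrix with a 'shape' attribute")
}

as_binary_labels <- function(labels, n) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    labels <- match(labels, c("negative", "positive")) - 1L
    if (anyNA(labels)) stop("character labels must be 'positive'/'negative'")
  }
  labels <- as.integer(labels)
  if (length(labels) != n) stop("length(labels) != number of images")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(unique(labels)) < 2L) {
    stop("training data contains a single class; need both classes")
  }
  labels
}

#' Fit a convolutional CDR image classifier
#'
#' Trains a softmax convolutional network on fused compound-disease grayscale
#' images by mini-batch stochastic gradient descent with momentum, minimising
#' 2-class cross-entropy.  Training is deterministic for a fixed
#' `config$seed`.  Per-epoch loss and training accuracy are recorded.
#'
#' @param x training images: a `cdr_image_stack` (see [encode_images()]), an
#'   `H x W x N` array with values in `[0, 1]`, or an `(H*W) x N` matrix with
#'   a `shape` attribute.
#' @param labels binary vector of length N (1/"positive" = related pair).
#' @param config a [cdr_train_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `cdr_cnn` with elements `network`, `history`
#'   (per-epoch data frame), `config` and `classes`.
#' @seealso [predict.cdr_cnn()], [build_network()]
#' @export
cdr_cnn <- function(x, labels, config = cdr_train_config(), verbose = FALSE) {
  stopifnot(inherits(config, "cdr_train_config"))
  batch <- as_image_batch(x)
  n <- ncol(batch$x)
  y <- as_binary_labels(labels, n)
  if (!is.null(config$input_shape) &&
      !all(config$input_shape == batch$shape)) {
    stop("config input_shape ", paste(config$input_shape, collapse = "x"),
         " does not match image shape ", paste(batch$shape, collapse = "x"))
  }
  set.seed(config$seed)
  net <- build_network(config$architecture, batch$shape, channels = 1L,
                       seed = config$seed)
  layers <- net$layers
  velocity <- vector("list", length(layers))
  Y <- rbind(1 - y, y)               # row 1 = negative, row 2 = positive
  bs <- min(config$batch_size, n)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tot_loss <- 0
    tot_correct <- 0L
    nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      take <- ord[start:min(start + bs - 1L, n)]
      Xb <- batch$x[, take, drop = FALSE]
      Yb <- Y[, take, drop = FALSE]
      fwd <- net_forward(layers, Xb, keep_cache = TRUE)
      l <- softmax_xent(fwd$out, Yb)
      grads <- net_backward(layers, l$dlogits, fwd$caches)
      upd <- sgd_update(layers, grads, velocity,
                        config$learning_rate, config$momentum)
      layers <- upd$layers
      velocity <- upd$velocity
      tot_loss <- tot_loss + l$loss * length(take)
      tot_correct <- tot_correct +
        sum((l$probs[2L, ] > 0.5) == (Yb[2L, ] == 1))
      nb <- nb + length(take)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = tot_loss / nb, accuracy = tot_correct / nb))
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f  acc %.3f",
                      epoch, tot_loss / nb, tot_correct / nb))
    }
  }
  net$layers <- layers
  structure(list(network = net, history = history, config = config,
                 classes = c("negative", "positive")),
            class = "cdr_cnn")
}

#' Predict relationship probabilities for CDR images
#'
#' @param object a fitted [cdr_cnn()] model.
#' @param newdata images in any format accepted by [cdr_cnn()]; image shape
#'   must match the shape the model was trained on.
#' @param pairs optional data frame with `compound_id`, `disease_id` columns
#'   (one row per image) carried through to the output.
#' @param type `"response"` returns a prediction data frame (probability of
#'   the positive class and the hard label at the strict 0.5 threshold);
#'   `"prob"` returns the numeric probability vector.
#' @param ... unused.
#' @return see `type`.  A probability of exactly 0.5 is labelled negative
#'   (the positive call requires probability strictly greater than 0.5).
#' @export
predict.cdr_cnn <- function(object, newdata, pairs = NULL,
                            type = c("response", "prob"), ...) {
  type <- match.arg(type)
  batch <- as_image_batch(newdata)
  want <- object$network$input_shape[1:2]
  if (!all(batch$shape == want)) {
    stop("image shape ", paste(batch$shape, collapse = "x"),
         " does not match model input ", paste(want, collapse = "x"))
  }
  n <- ncol(batch$x)
  probs <- numeric(n)
  chunk <- 256L
  for (start in seq(1L, n, by = chunk)) {
    take <- start:min(start + chunk - 1L, n)
    out <- net_forward(object$network$layers,
                       batch$x[, take, drop = FALSE])$out
    probs[take] <- softmax_cols(out)[2L, ]
  }
  if (type == "prob") return(probs)
  res <- data.frame(probability = probs,
                    label = ifelse(probs > 0.5, "positive", "negative"),
                    stringsAsFactors = FALSE)
  if (!is.null(pairs)) {
    stopifnot(nrow(pairs) == n)
    res <- cbind(pairs[, c("compound_id", "disease_id")], res)
  }
  res
}

#' @export
print.cdr_cnn <- function(x, ...) {
  h <- x$history
  cat("<cdr_cnn> architecture:", x$config$architecture, "\n")
  cat("  input:", paste(x$network$input_shape, collapse = " x "),
      " parameters:", x$network$n_params, "\n")
  cat(sprintf("  trained %d epochs; final loss %.4f, train accuracy %.3f\n",
              nrow(h), h$loss[nrow(h)], h$accuracy[nrow(h)]))
  invisible(x)
}

#' @export
summary.cdr_cnn <- function(object, ...) {
  print(object)
  cat("  optimiser: SGD, lr =", object$config$learning_rate,
      ", momentum =", object$config$momentum,
      ", batch =", object$config$batch_size, "\n")
  invisible(object$history)
}

#' @export
plot.cdr_cnn <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "loss", ...)
  graphics::plot(h$epoch, h$accuracy, type = "b", xlab = "epoch",
                 ylab = "training accuracy", main = "accuracy", ...)
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}

#' Save / load a fitted model
#'
#' The model is serialised with `saveRDS`; a JSON sidecar records the
#' architecture, training configuration and an optional hash of the
#' normalization parameters used to encode its training images, so a
#' checkpoint can be audited without deserialising it.
#'
#' @param model a `cdr_cnn` object.
#' @param path checkpoint path (`.rds`); the sidecar is written to
#'   `<path>.json`.
#' @param norm_hash optional string identifying the normalization parameters.
#' @return `path`, invisibly.
#' @export
write_cdr_model <- function(model, path, norm_hash = NULL) {
  stopifnot(inherits(model, "cdr_cnn"))
  saveRDS(model, path)
  side <- list(architecture = model$config$architecture,
               config = unclass(model$config),
               classes = model$classes,
               n_params = model$network$n_params)
  if (!is.null(norm_hash)) side$norm_hash <- norm_hash
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_cdr_model
#' @export
read_cdr_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cdr_cnn")) stop("not a cdr_cnn checkpoint: ", path)
  model
}
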