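# Mini-batch SGD training of the network and confusion-matrix evaluation.

#' Training configuration
#'
#' Defaults follow the reference training setup: stochastic gradient
#' descent with learning rate 0.001 and (by convention) momentum 0.9, 100
#' epochs, cross-entropy loss over the softmax output. The batch size is
#' not pinned by that setup; 32 is the package default. Optional
#' augmentation applies random rotation (+/- 30 degrees) and isotropic
#' scaling (0.8-1.2) per image per epoch.
#'
#' @param learning_rate Positive SGD step size (default 0.001).
#' @param epochs Number of passes over the training set (default 100).
#' @param batch_size Mini-batch size (default 32).
#' @param momentum SGD momentum coefficient (default 0.9).
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and augmentation.
#' @param augment_rotation,augment_scaling Logical augmentation toggles
#'   (default off).
#' @return Object of class `swnet_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 100,
                         batch_size = 32, momentum = 0.9, seed = 1L,
                         augment_rotation = FALSE, augment_scaling = FALSE) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (epochs < 1) stop("`epochs` must be at least 1")
  if (batch_size < 1) stop("`batch_size` must be at least 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed),
                 augment_rotation = augment_rotation,
                 augment_scaling = augment_scaling),
            class = "swnet_train_config")
}

.one_hot <- function(labels, num_classes) {
  idx <- match(labels, .LABELS)
  if (anyNA(idx)) stop("labels must be benign/malignant")
  Y <- matrix(0, length(labels), num_classes)
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

.augment_batch <- function(xb, config) {
  d <- dim(xb)
  for (i in seq_len(d[4])) {
    img <- xb[, , , i]
    if (config$augment_rotation) {
      ang <- stats::runif(1, -30, 30)
      eb <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
      eb <- EBImage::rotate(eb, ang, output.dim = c(d[2], d[1]),
                            bg.col = "black")
      img <- aperm(EBImage::imageData(eb), c(2, 1, 3))
    }
    if (config$augment_scaling) {
      sc <- stats::runif(1, 0.8, 1.2)
      side <- max(16, round(d[1] * sc))
      eb <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
      eb <- EBImage::resize(eb, w = side, h = side)
      sm <- aperm(EBImage::imageData(eb), c(2, 1, 3))
      if (side >= d[1]) {
        off <- (side - d[1]) %/% 2
        img <- sm[off + seq_len(d[1]), off + seq_len(d[2]), , drop = FALSE]
      } else {
        pad <- array(0, dim = c(d[1], d[2], 3))
        off <- (d[1] - side) %/% 2
        pad[off + seq_len(side), off + seq_len(side), ] <- sm
        img <- pad
      }
      dim(img) <- c(d[1], d[2], 3)
    }
    xb[, , , i] <- pmin(pmax(img, 0), 1)
  }
  xb
}

#' Train a network by mini-batch SGD
#'
#' Loads and resizes the training images named by the manifest, minimizes
#' the cross-entropy loss with momentum SGD for `config$epochs` epochs, and
#' records per-epoch loss and accuracy (plus held-out metrics when
#' `validation` is given). Fully reproducible for a fixed seed on one
#' device. Training aborts with a diagnostic if the loss turns non-finite.
#'
#' @param graph A `swnet_graph`.
#' @param train_set A `swnet_manifest` (or the list returned by
#'   [generate_dataset()]); must contain both classes.
#' @param config A `swnet_train_config`.
#' @param validation Optional held-out `swnet_manifest` evaluated once per
#'   epoch.
#' @param weights Optional starting `swnet_weights` (default: fresh
#'   He-initialized weights from `config$seed`).
#' @param verbose Print one line per epoch.
#' @return A `swnet_model` with an attached `history` data frame (one row
#'   per completed epoch: epoch, loss, accuracy, and when validated,
#'   val_loss, val_accuracy).
#' @export
train <- function(graph, train_set, config = train_config(),
                  validation = NULL, weights = NULL, verbose = FALSE) {
  stopifnot(inherits(graph, "swnet_graph"),
            inherits(config, "swnet_train_config"))
  if (inherits(train_set, "list") && !is.null(train_set$manifest))
    train_set <- train_set$manifest
  if (!nrow(train_set)) stop("training set is empty")
  if (length(unique(train_set$label)) < 2)
    stop("training set must contain both classes")

  batch <- .load_batch(train_set, graph$input_size)
  x <- batch$x; labels <- batch$labels
  n <- length(labels)
  Y <- .one_hot(labels, graph$num_classes)
  val <- if (!is.null(validation)) .load_batch(validation, graph$input_size)

  old <- .hold_rng(); on.exit(.release_rng(old))
  set.seed(config$seed)
  if (is.null(weights))
    weights <- init_weights(graph, seed = config$seed + 1L)
  vel <- list()
  hist <- vector("list", config$epochs)
  augment <- config$augment_rotation || config$augment_scaling

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- x[, , , idx, drop = FALSE]
      if (augment) xb <- .augment_batch(xb, config)
      yb <- Y[idx, , drop = FALSE]
      fwd <- forward_pass(graph, weights, xb, training = TRUE, keep = TRUE)
      weights <- fwd$.weights  # batch-norm running stats advanced
      probs <- fwd$probs
      eps <- 1e-12
      loss <- -mean(rowSums(yb * log(probs + eps)))
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      ep_loss <- ep_loss + loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(probs, ties.method = "first") == max.col(yb, ties.method = "first"))
      dlogits <- (probs - yb) / nrow(yb)
      bwd <- .backward_pass(graph, weights, fwd, dlogits, training = TRUE)
      for (nm in names(bwd$param_grads)) {
        for (par in names(bwd$param_grads[[nm]])) {
          g <- bwd$param_grads[[nm]][[par]]
          key <- paste0(nm, ".", par)
          v <- if (is.null(vel[[key]])) -config$learning_rate * g
          else config$momentum * vel[[key]] - config$learning_rate * g
          vel[[key]] <- v
          tgt <- if (par %in% c("W", "b")) par
          else par # gamma / beta share names
          weights[[nm]][[tgt]] <- weights[[nm]][[tgt]] + v
        }
      }
    }
    row <- data.frame(epoch = epoch, loss = ep_loss / n,
                      accuracy = ep_correct / n)
    if (!is.null(validation)) {
      vp <- forward_pass(graph, weights, val$x, training = FALSE)$probs
      vy <- .one_hot(val$labels, graph$num_classes)
      row$val_loss <- -mean(rowSums(vy * log(vp + 1e-12)))
      row$val_accuracy <- mean(max.col(vp, ties.method = "first") == max.col(vy, ties.method = "first"))
    }
    hist[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  acc %.3f", epoch, row$loss,
                      row$accuracy))
  }
  weights <- .refresh_bn_stats(graph, weights, x, config$batch_size)
  model <- swnet_model(graph, weights)
  model$history <- do.call(rbind, hist)
  model
}

# Batch-norm recalibration: after the final SGD step, re-estimate every BN
# layer's running mean/variance from the training set itself (aggregated
# over mini-batch statistics), so inference-mode normalization matches the
# statistics of the finished network rather than a momentum-lagged average.
.refresh_bn_stats <- function(graph, weights, x, batch_size) {
  n <- dim(x)[4]
  bn_nodes <- names(graph$nodes)[.node_types(graph) == "bn"]
  acc <- stats::setNames(vector("list", length(bn_nodes)), bn_nodes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fwd <- forward_pass(graph, weights, x[, , , idx, drop = FALSE],
                        training = TRUE)
    for (nm in bn_nodes) {
      st <- get(nm, fwd$.caches)
      w <- length(idx)
      a <- acc[[nm]]
      if (is.null(a)) a <- list(w = 0, m = 0, e2 = 0)
      acc[[nm]] <- list(w = a$w + w, m = a$m + w * st$mean,
                        e2 = a$e2 + w * (st$var + st$mean^2))
    }
  }
  for (nm in bn_nodes) {
    a <- acc[[nm]]
    mu <- a$m / a$w
    weights[[nm]]$running_mean <- mu
    weights[[nm]]$running_var <- pmax(a$e2 / a$w - mu^2, 0)
  }
  weights
}

#' Evaluate a model on a labeled manifest
#'
#' Predicts the argmax-probability class for every image and tallies the
#' confusion matrix with malignant as the positive class.
#'
#' @param model A `swnet_model`.
#' @param test_set A labeled `swnet_manifest`.
#' @return A `swnet_confusion`; the predictions are attached as attribute
#'   `"predictions"`.
#' @export
evaluate <- function(model, test_set) {
  stopifnot(inherits(model, "swnet_model"))
  if (inherits(test_set, "list") && !is.null(test_set$manifest))
    test_set <- test_set$manifest
  if (!nrow(test_set)) stop("test set is empty")
  batch <- .load_batch(test_set, model$graph$input_size)
  probs <- forward_pass(model$graph, model$weights, batch$x,
                        training = FALSE)$probs
  preds <- .LABELS[max.col(probs, ties.method = "first")]
  cm <- confusion_matrix(labels = batch$labels, predictions = preds)
  attr(cm, "predictions") <- preds
  cm
}
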