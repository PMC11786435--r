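# Network execution engine: weight initialization, forward and backward
# passes over the layer DAG. Activations are H x W x C x N arrays up to the
# global average pool, and N x C matrices from there on.

#' Initialize network weights
#'
#' He (fan-in) initialization for convolution and fully-connected weights;
#' batch-norm scale 1 / shift 0 with zeroed running statistics; all biases 0.
#'
#' @param graph A `swnet_graph`.
#' @param seed Integer seed making the draw reproducible.
#' @return Named list of per-node parameter lists (class `swnet_weights`).
#' @export
init_weights <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "swnet_graph"))
  old <- .hold_rng()
  on.exit(.release_rng(old))
  set.seed(seed)
  w <- list()
  for (n in graph$nodes) {
    if (n$type == "conv") {
      fan_in <- n$kernel^2 * n$in_channels
      w[[n$name]] <- list(
        W = array(stats::rnorm(n$kernel^2 * n$in_channels * n$out_channels,
                               sd = sqrt(2 / fan_in)),
                  dim = c(n$kernel, n$kernel, n$in_channels, n$out_channels)),
        b = numeric(n$out_channels))
    } else if (n$type == "bn") {
      w[[n$name]] <- list(gamma = rep(1, n$channels),
                          beta = numeric(n$channels),
                          running_mean = numeric(n$channels),
                          running_var = rep(1, n$channels))
    } else if (n$type == "fc") {
      w[[n$name]] <- list(
        W = matrix(stats::rnorm(n$in_features * n$out_features,
                                sd = sqrt(2 / n$in_features)),
                   n$in_features, n$out_features),
        b = numeric(n$out_features))
    }
  }
  structure(w, class = "swnet_weights")
}

.hold_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.release_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

.BN_EPS <- 1e-5

.bn_forward <- function(x, p, training, momentum = 0.1, eps = .BN_EPS) {
  if (training) {
    st <- .bn_stats(x)
    mu <- st$mean; va <- st$var
  } else {
    mu <- p$running_mean; va <- p$running_var
  }
  inv <- 1 / sqrt(va + eps)
  y <- .bn_apply(x, p$gamma * inv, p$beta - p$gamma * inv * mu)
  cache <- NULL
  new_running <- NULL
  if (training) {
    cache <- list(mean = mu, var = va)
    new_running <- list(
      running_mean = (1 - momentum) * p$running_mean + momentum * mu,
      running_var = (1 - momentum) * p$running_var + momentum * va)
  }
  list(y = y, cache = cache, new_running = new_running)
}

.bn_backward <- function(x, dy, p, cache, training, eps = .BN_EPS) {
  if (!training) {
    inv <- 1 / sqrt(p$running_var + eps)
    return(list(dx = .bn_apply(dy, p$gamma * inv,
                               numeric(length(p$gamma))),
                dgamma = NULL, dbeta = NULL))
  }
  .bn_backward_train(x, dy, p$gamma, cache$mean, cache$var, eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Run a forward pass through a network
#'
#' @param graph A `swnet_graph`.
#' @param weights Matching `swnet_weights`.
#' @param x Input batch, an `H x W x 3 x N` array (values in \[0, 1\]) or a
#'   single `H x W x 3` image.
#' @param training Logical; training mode uses batch statistics in
#'   batch-norm layers and applies dropout (eval mode uses running
#'   statistics and no dropout).
#' @param keep Optional character vector of node names whose activations to
#'   retain, or `TRUE` for all (needed for backward passes).
#' @return List with `probs` (N x classes softmax output), `logits`, and
#'   `acts` (retained activations).
#' @export
forward_pass <- function(graph, weights, x, training = FALSE, keep = NULL) {
  stopifnot(inherits(graph, "swnet_graph"))
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  if (dim(x)[1] != graph$input_size || dim(x)[2] != graph$input_size)
    stop("input is ", dim(x)[1], "x", dim(x)[2], "; graph expects ",
         graph$input_size, "x", graph$input_size)
  if (dim(x)[3] != 3) stop("input must have 3 channels")
  acts <- new.env(parent = emptyenv())
  caches <- new.env(parent = emptyenv())
  keep_all <- isTRUE(keep)
  for (n in graph$nodes) {
    val <- switch(n$type,
      input = x,
      conv = .conv2d_forward(get(n$inputs, acts), weights[[n$name]]$W,
                             weights[[n$name]]$b, n$stride, n$padding),
      bn = {
        r <- .bn_forward(get(n$inputs, acts), weights[[n$name]],
                         training = training)
        if (training) assign(n$name, r$cache, caches)
        if (!is.null(r$new_running)) {
          weights[[n$name]]$running_mean <- r$new_running$running_mean
          weights[[n$name]]$running_var <- r$new_running$running_var
        }
        r$y
      },
      relu = pmax(get(n$inputs, acts), 0),
      concat = {
        ins <- lapply(n$inputs, get, envir = acts)
        dims <- dim(ins[[1]])
        chans <- vapply(ins, function(a) dim(a)[3], numeric(1))
        out <- array(0, dim = c(dims[1], dims[2], sum(chans), dims[4]))
        off <- 0
        for (a in ins) {
          ck <- dim(a)[3]
          out[, , off + seq_len(ck), ] <- a
          off <- off + ck
        }
        out
      },
      gap = {
        a <- get(n$inputs, acts)
        d <- dim(a)
        t(matrix(colMeans(matrix(a, nrow = d[1] * d[2])), d[3], d[4]))
      },
      fc = {
        a <- get(n$inputs, acts)
        sweep(a %*% weights[[n$name]]$W, 2, weights[[n$name]]$b, "+")
      },
      dropout = {
        a <- get(n$inputs, acts)
        if (training) {
          mask <- matrix(stats::runif(length(a)) >= n$p, nrow(a), ncol(a)) /
            (1 - n$p)
          assign(n$name, mask, caches)
          a * mask
        } else a
      },
      softmax = .softmax_rows(get(n$inputs, acts)))
    assign(n$name, val, acts)
  }
  keep_names <- if (keep_all) names(graph$nodes) else
    unique(c(keep, "fc3", "softmax"))
  list(probs = get("softmax", acts), logits = get("fc3", acts),
       acts = mget(intersect(keep_names, ls(acts)), acts),
       .acts_env = acts, .caches = caches, .weights = weights)
}

# Backward pass: seeds the gradient at the logits (fc3 output) and walks the
# graph in reverse topological order. Returns parameter gradients and, when
# requested, activation gradients at chosen nodes.
.backward_pass <- function(graph, weights, fwd, dlogits, training = FALSE,
                           stop_at = NULL, want_act_grads = NULL) {
  acts <- fwd$.acts_env
  caches <- fwd$.caches
  nodes <- graph$nodes
  nms <- names(nodes)
  grads <- new.env(parent = emptyenv())
  pgrads <- list()
  assign("fc3", dlogits, grads)
  stop_idx <- if (is.null(stop_at)) 1L else match(stop_at, nms)
  # walk from fc3 down; softmax node is terminal and never back-propagated
  start_idx <- match("fc3", nms)
  for (i in seq(start_idx, stop_idx)) {
    if (!is.null(stop_at) && i == stop_idx) break
    n <- nodes[[i]]
    if (!exists(n$name, grads)) next
    g <- get(n$name, grads)
    addg <- function(name, val) {
      if (exists(name, grads)) assign(name, get(name, grads) + val, grads)
      else assign(name, val, grads)
    }
    switch(n$type,
      input = NULL,
      fc = {
        a <- get(n$inputs, acts)
        pgrads[[n$name]] <- list(W = crossprod(a, g), b = colSums(g))
        addg(n$inputs, g %*% t(weights[[n$name]]$W))
      },
      dropout = {
        if (training && exists(n$name, caches))
          addg(n$inputs, g * get(n$name, caches))
        else addg(n$inputs, g)
      },
      gap = {
        a <- get(n$inputs, acts)
        d <- dim(a)
        HW <- d[1] * d[2]
        addg(n$inputs, array(rep(as.vector(t(g)) / HW, each = HW), dim = d))
      },
      bn = {
        r <- .bn_backward(get(n$inputs, acts), g, weights[[n$name]],
                          if (exists(n$name, caches)) get(n$name, caches),
                          training = training)
        if (training)
          pgrads[[n$name]] <- list(gamma = r$dgamma, beta = r$dbeta)
        addg(n$inputs, r$dx)
      },
      relu = addg(n$inputs, g * (get(n$name, acts) > 0)),
      concat = {
        off <- 0
        for (inp in n$inputs) {
          ck <- dim(get(inp, acts))[3]
          addg(inp, g[, , off + seq_len(ck), , drop = FALSE])
          off <- off + ck
        }
      },
      conv = {
        inp_idx <- match(n$inputs, nms)
        need_dx <- inp_idx >= stop_idx && nodes[[inp_idx]]$type != "input"
        r <- .conv2d_backward(get(n$inputs, acts), weights[[n$name]]$W, g,
                              n$stride, n$padding, need_dx)
        pgrads[[n$name]] <- list(W = r$dw, b = r$db)
        if (need_dx) addg(n$inputs, r$dx)
      },
      softmax = NULL)
  }
  act_grads <- NULL
  if (!is.null(want_act_grads))
    act_grads <- mget(intersect(want_act_grads, ls(grads)), grads)
  list(param_grads = pgrads, act_grads = act_grads)
}

#' Predict class probabilities for a batch of images
#'
#' @param object A `swnet_model` (graph + weights), as returned by [train()]
#'   or [swnet_model()].
#' @param x Image array `H x W x 3 x N` (or a single image).
#' @param ... Unused.
#' @return N x num_classes matrix of softmax probabilities.
#' @export
predict.swnet_model <- function(object, x, ...) {
  forward_pass(object$graph, object$weights, x, training = FALSE)$probs
}

#' Bundle a graph and weights into a model
#'
#' @param graph A `swnet_graph`.
#' @param weights Matching `swnet_weights` (default: fresh He-initialized
#'   weights with `seed`).
#' @param seed Seed for default initialization.
#' @return An object of class `swnet_model`.
#' @export
swnet_model <- function(graph, weights = NULL, seed = 1L) {
  if (is.null(weights)) weights <- init_weights(graph, seed = seed)
  structure(list(graph = graph, weights = weights), class = "swnet_model")
}

#' @export
print.swnet_model <- function(x, ...) {
  cat("SWNet model\n")
  print(x$graph)
  invisible(x)
}

#' Save / load model checkpoints
#'
#' Checkpoints are written with R's native serialization and carry a
#' structural fingerprint of the graph; loading verifies the fingerprint.
#'
#' @param model A `swnet_model`.
#' @param path File path for the checkpoint (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `swnet_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "swnet_model"))
  saveRDS(list(graph = model$graph, weights = model$weights,
               fingerprint = .graph_signature(model$graph),
               history = model$history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$fingerprint, .graph_signature(obj$graph)))
    stop("checkpoint fingerprint does not match its architecture")
  m <- swnet_model(obj$graph, obj$weights)
  m$history <- obj$history
  m
}
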