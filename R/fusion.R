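# Multi-dataset feature fusion: deep feature extraction at the pooled
# layer, concatenation across source models/datasets with provenance, and a
# softmax head on the fused representation. Dataset pooling (merging
# manifests for end-to-end training) is the second fusion mode.

#' Extract deep features for a set of images
#'
#' Runs the network in inference mode and returns the activation at a
#' spatial layer averaged over space (the global-average-pool layer by
#' default, giving the 1 x 1 x C representation that feeds the classifier
#' head — 1024-dimensional for the full-size network).
#'
#' @param model A `swnet_model`.
#' @param images A `swnet_manifest`, generator result, or `H x W x 3 x N`
#'   array.
#' @param layer Node name to read features from (default `"gap"`).
#' @return N x C numeric matrix of class `swnet_features` with attributes
#'   `source_model` and `source_dataset`; row order follows the input.
#' @export
extract_features <- function(model, images, layer = "gap") {
  stopifnot(inherits(model, "swnet_model"))
  graph <- model$graph
  if (is.null(graph$nodes[[layer]]))
    stop("unknown layer '", layer, "'; available: ",
         paste(names(graph$nodes), collapse = ", "))
  source_dataset <- "array"
  if (inherits(images, "list") && !is.null(images$manifest))
    images <- images$manifest
  if (inherits(images, "swnet_manifest")) {
    source_dataset <- paste(unique(images$source_dataset), collapse = "+")
    images <- .load_batch(images, graph$input_size)$x
  }
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1)
  fwd <- forward_pass(graph, model$weights, images, training = FALSE,
                      keep = layer)
  act <- fwd$acts[[layer]]
  feats <- if (is.matrix(act)) act else {
    d <- dim(act)
    t(matrix(colMeans(matrix(act, nrow = d[1] * d[2])), d[3], d[4]))
  }
  if (any(!is.finite(feats))) stop("non-finite features extracted")
  structure(feats, class = c("swnet_features", "matrix"),
            source_model = "swnet", source_dataset = source_dataset,
            layer = layer)
}

#' Concatenate aligned feature sets with provenance
#'
#' Joins per-image feature vectors from several sources column-wise. All
#' sets must describe the same images in the same order; the fused length
#' is the sum of the component lengths and the provenance table records
#' each component's offset and length so components can be recovered
#' exactly.
#'
#' @param sets List of `swnet_features` matrices (or plain matrices) with
#'   equal row counts.
#' @return Object of class `swnet_fused`: the fused N x sum(C) matrix with
#'   a `provenance` attribute (data frame: source_model, source_dataset,
#'   offset, length).
#' @export
fuse_concat <- function(sets) {
  if (inherits(sets, "matrix")) sets <- list(sets)
  stopifnot(length(sets) >= 1)
  n <- vapply(sets, nrow, integer(1))
  if (length(unique(n)) != 1) {
    bad <- which(n != n[1])[1]
    stop("feature sets are misaligned: set ", bad, " has ", n[bad],
         " rows, expected ", n[1])
  }
  prov <- do.call(rbind, lapply(seq_along(sets), function(i) {
    data.frame(source_model = attr(sets[[i]], "source_model") %||% "unknown",
               source_dataset = attr(sets[[i]], "source_dataset") %||%
                 paste0("set", i),
               offset = NA_integer_, length = ncol(sets[[i]]),
               stringsAsFactors = FALSE)
  }))
  prov$offset <- cumsum(c(0L, utils::head(prov$length, -1)))
  fused <- do.call(cbind, lapply(sets, unclass))
  structure(fused, class = c("swnet_fused", "matrix"), provenance = prov)
}

#' Recover one component from a fused feature set
#'
#' @param fused A `swnet_fused` matrix.
#' @param i Component index into the provenance table.
#' @return The i-th component feature matrix.
#' @export
fused_component <- function(fused, i) {
  prov <- attr(fused, "provenance")
  stopifnot(i >= 1, i <= nrow(prov))
  unclass(fused)[, prov$offset[i] + seq_len(prov$length[i]), drop = FALSE]
}

#' Merge dataset manifests into one pooled manifest
#'
#' Union of the records with source tags retained; duplicate paths across
#' sources are kept (with a warning) since they represent distinct source
#' attributions.
#'
#' @param manifests List of `swnet_manifest` objects sharing the binary
#'   label space.
#' @return Pooled `swnet_manifest`.
#' @export
merge_datasets <- function(manifests) {
  stopifnot(length(manifests) >= 1)
  for (m in manifests) {
    stopifnot(inherits(m, "swnet_manifest"))
    if (!all(m$label %in% .LABELS))
      stop("label-space mismatch: all manifests must use benign/malignant")
  }
  if (length(manifests) == 1) return(manifests[[1]])
  pooled <- do.call(rbind, lapply(manifests, as.data.frame))
  if (anyDuplicated(pooled$image_path))
    warning("duplicate image paths across sources kept with their tags",
            call. = FALSE)
  counts <- table(pooled$source_dataset)
  message("merged ", nrow(pooled), " records from ",
          paste(names(counts), counts, sep = ": ", collapse = ", "))
  df <- pooled
  rownames(df) <- NULL
  class(df) <- c("swnet_manifest", "data.frame")
  df
}

#' Train a softmax head on fused features
#'
#' Standardizes each feature dimension (training-split mean and variance)
#' and fits a ridge-regularized multinomial logistic (softmax) classifier.
#' When a test set is supplied the returned metrics are computed on it,
#' otherwise on the training data.
#'
#' @param fused N x D feature matrix (`swnet_fused` or plain).
#' @param labels Character vector of benign/malignant labels, length N.
#' @param test_fused,test_labels Optional held-out features and labels.
#' @param lambda Ridge penalty of the head (default 1e-3).
#' @return List of class `swnet_fused_classifier`: `fit` (glmnet object),
#'   `center`/`scale`, `lambda`, `metrics` (a `swnet_metrics`) and
#'   `predict`, a function mapping a feature matrix to labels.
#' @export
train_fused_classifier <- function(fused, labels, test_fused = NULL,
                                   test_labels = NULL, lambda = 1e-3) {
  X <- unclass(fused)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  if (length(unique(labels)) < 2)
    stop("labels must contain both classes")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  y <- factor(labels, levels = .LABELS)
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  pred_fun <- function(newX) {
    newXs <- scale(unclass(newX), center = ctr, scale = scl)
    p <- as.vector(stats::predict(fit, newXs, type = "response"))
    ifelse(p > 0.5, "malignant", "benign")
  }
  if (is.null(test_fused)) {
    test_fused <- X; test_labels <- labels
  }
  preds <- pred_fun(test_fused)
  cm <- confusion_matrix(labels = as.character(test_labels),
                         predictions = preds)
  structure(list(fit = fit, center = ctr, scale = scl, lambda = lambda,
                 metrics = metrics_report(cm), predict = pred_fun),
            class = "swnet_fused_classifier")
}

#' @export
print.swnet_fused_classifier <- function(x, ...) {
  cat("Fused-feature softmax head\n")
  print(x$metrics)
  invisible(x)
}
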