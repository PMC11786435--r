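# Grad-CAM saliency maps and region-mass statistics for bias auditing.

#' Grad-CAM saliency heatmap
#'
#' Computes the gradient-weighted class activation map at a chosen feature
#' layer: the gradient of the pre-softmax class score with respect to the
#' layer's feature maps is averaged over space to give one weight per
#' channel, the weighted sum of feature maps is rectified, bilinearly
#' upsampled to the input size and max-normalized to \[0, 1\]. Batch-norm
#' layers run in inference mode and dropout is disabled.
#'
#' @param model A `swnet_model`.
#' @param image A single `H x W x 3` image matching the model input size.
#' @param target_layer Name of a convolution, concatenation or batch-norm
#'   node whose feature maps to weight (default: the batch-normalized
#'   output of the last concatenation stage).
#' @param target_class Class index (1 = benign, 2 = malignant) or label;
#'   default is the model's predicted class.
#' @return Object of class `swnet_heatmap`: list with `values` (H x W map
#'   in \[0, 1\]), `raw` (unnormalized rectified map), `target_layer`,
#'   `target_class`, `all_zero` flag and the predicted probabilities.
#' @export
grad_cam <- function(model, image, target_layer = NULL, target_class = NULL) {
  stopifnot(inherits(model, "swnet_model"))
  graph <- model$graph
  if (is.null(target_layer)) {
    cands <- grep("^bnconcat", names(graph$nodes), value = TRUE)
    target_layer <- cands[length(cands)]
  }
  node <- graph$nodes[[target_layer]]
  if (is.null(node)) {
    valid <- names(graph$nodes)[.node_types(graph) %in% c("conv", "concat", "bn")]
    stop("unknown layer '", target_layer, "'; valid feature layers: ",
         paste(valid, collapse = ", "))
  }
  if (!node$type %in% c("conv", "concat", "bn"))
    stop("'", target_layer, "' is a ", node$type,
         " layer; Grad-CAM needs a spatial feature map")
  if (length(dim(image)) == 3) dim(image) <- c(dim(image), 1)

  fwd <- forward_pass(graph, model$weights, image, training = FALSE,
                      keep = TRUE)
  if (is.null(target_class))
    target_class <- which.max(fwd$probs[1, ])
  if (is.character(target_class))
    target_class <- match(target_class, .LABELS)
  stopifnot(target_class %in% seq_len(graph$num_classes))

  dlogits <- matrix(0, 1, graph$num_classes)
  dlogits[1, target_class] <- 1
  bwd <- .backward_pass(graph, model$weights, fwd, dlogits,
                        training = FALSE, stop_at = target_layer,
                        want_act_grads = target_layer)
  dact <- bwd$act_grads[[target_layer]]
  act <- fwd$acts[[target_layer]]
  d <- dim(act)
  # channel weights: spatial mean of the score gradient
  w <- colMeans(matrix(dact[, , , 1], nrow = d[1] * d[2]))
  cam <- matrix(matrix(act[, , , 1], nrow = d[1] * d[2]) %*% w, d[1], d[2])
  cam <- pmax(cam, 0)
  size <- dim(image)[1]
  if (d[1] != size) {
    eb <- EBImage::resize(EBImage::Image(t(cam)), w = size, h = size)
    cam <- t(EBImage::imageData(eb))
    cam <- pmax(cam, 0)
  }
  all_zero <- max(cam) == 0
  values <- if (all_zero) cam else cam / max(cam)
  structure(list(values = values, raw = cam, target_layer = target_layer,
                 target_class = target_class, all_zero = all_zero,
                 probs = fwd$probs[1, ]),
            class = "swnet_heatmap")
}

#' @export
print.swnet_heatmap <- function(x, ...) {
  cat(sprintf("Grad-CAM heatmap at '%s' for class %d%s\n", x$target_layer,
              x$target_class, if (x$all_zero) " (all zero)" else ""))
  invisible(x)
}

# Blue-to-red (jet-like) colormap over [0, 1].
.heat_colormap <- function(v) {
  ramp <- grDevices::colorRamp(c("#00007F", "blue", "cyan", "yellow",
                                 "red", "#7F0000"))
  rgb <- ramp(as.vector(v)) / 255
  array(rgb, dim = c(dim(v), 3))
}

#' Overlay a heatmap on an image
#'
#' Alpha-blends the color-mapped heatmap onto the image:
#' `(1 - alpha) * image + alpha * colormap(heatmap)` per pixel, so
#' `alpha = 0` returns the image and `alpha = 1` the pure color map.
#'
#' @param image `H x W x 3` array in \[0, 1\].
#' @param heatmap A `swnet_heatmap` (or bare H x W matrix) with matching
#'   spatial size.
#' @param alpha Blend weight of the heatmap (default 0.4).
#' @return Blended `H x W x 3` array in \[0, 1\].
#' @export
overlay <- function(image, heatmap, alpha = 0.4) {
  v <- if (inherits(heatmap, "swnet_heatmap")) heatmap$values else heatmap
  if (!all(dim(image)[1:2] == dim(v)))
    stop("image is ", paste(dim(image)[1:2], collapse = "x"),
         " but heatmap is ", paste(dim(v), collapse = "x"))
  stopifnot(alpha >= 0, alpha <= 1)
  cm <- .heat_colormap(v)
  out <- (1 - alpha) * image + alpha * cm
  pmin(pmax(out, 0), 1)
}

#' Fraction of saliency mass inside a region
#'
#' Sum of heatmap values inside the mask divided by the total sum; 0 for an
#' all-zero map. Applied with [vignette_mask()] this quantifies how much of
#' the model's attention falls on the vignette artifact region.
#'
#' @param heatmap A `swnet_heatmap` or H x W matrix.
#' @param mask Logical H x W matrix.
#' @return Proportion in \[0, 1\].
#' @export
saliency_mass <- function(heatmap, mask) {
  v <- if (inherits(heatmap, "swnet_heatmap")) heatmap$values else heatmap
  if (!all(dim(v) == dim(mask)))
    stop("heatmap and mask dimensions differ")
  tot <- sum(v)
  if (tot == 0) return(0)
  sum(v[mask]) / tot
}

#' Default layer set for multi-layer Grad-CAM panels
#'
#' Nine feature layers spanning the network: the stem convolution, the last
#' (fourth-branch stride-2) convolution of each stage, and the four
#' batch-normalized concatenation outputs.
#'
#' @param graph A `swnet_graph`.
#' @return Character vector of nine node names.
#' @export
gradcam_layers <- function(graph) {
  c("conv1",
    sprintf("conv_s%db4_2", 1:4),
    sprintf("bnconcat%d", 1:4))
}
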