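#' @useDynLib swnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical stage widths of the full-size network; build_swnet() scales these
# by the width multiplier.
.SWNET_STAGE_WIDTHS <- c(32L, 64L, 128L, 256L)
.SWNET_BRANCHES <- 4L
.SWNET_FC_SIZES <- c(300L, 64L)
.SWNET_DROPOUT_P <- 0.5

.node <- function(name, type, inputs = character(), ...) {
  c(list(name = name, type = type, inputs = inputs), list(...))
}

#' Build the SWNet network graph
#'
#' Constructs the directed acyclic layer graph of SWNet: a 3x3 stem
#' convolution followed by four stages. Each stage holds four parallel
#' branches of two 3x3 convolutions (stride 1 then stride 2) that all read
#' the stage input; the branch outputs are depth-concatenated and batch
#' normalized. Stage widths are 32/64/128/256 channels per branch (scaled by
#' `width_multiplier`), so the concatenated stage outputs carry 128/256/512/
#' 1024 channels while spatial resolution halves per stage. The head is
#' global average pooling, fully connected layers of 300 and 64 units with
#' dropout (p = 0.5) between them, a final fully connected classifier and a
#' terminal softmax.
#'
#' Every convolution uses a 3x3 kernel, same padding of 1 pixel and a bias
#' term, and is followed by batch normalization and a ReLU.
#'
#' @param input_size Input image side in pixels; must be divisible by 16 so
#'   the four stride-2 stages land on integer resolutions. Default 224.
#' @param num_classes Number of output classes (default 2: benign/malignant).
#' @param width_multiplier Positive scalar scaling all stage widths; branch
#'   widths become `ceiling(width_multiplier * c(32, 64, 128, 256))`. Use
#'   e.g. 1/8 for a desk-scale network with identical topology.
#' @return An object of class `swnet_graph`: a topologically ordered list of
#'   layer nodes plus graph metadata.
#' @examples
#' g <- build_swnet()
#' count_layers(g)
#' @export
build_swnet <- function(input_size = 224, num_classes = 2, width_multiplier = 1) {
  if (length(input_size) != 1 || input_size <= 0 || input_size %% 16 != 0)
    stop("`input_size` must be a positive multiple of 16, got ", input_size)
  if (length(width_multiplier) != 1 || !is.finite(width_multiplier) ||
      width_multiplier <= 0)
    stop("`width_multiplier` must be a positive scalar")
  if (num_classes < 2) stop("`num_classes` must be at least 2")

  widths <- as.integer(ceiling(width_multiplier * .SWNET_STAGE_WIDTHS))
  nodes <- list()
  add <- function(n) nodes[[n$name]] <<- n

  add(.node("input", "input", channels = 3L, size = as.integer(input_size)))

  # Stem: Conv1 brings 3 -> width[1] channels at full resolution.
  add(.node("conv1", "conv", "input", in_channels = 3L,
            out_channels = widths[1], kernel = 3L, stride = 1L, padding = 1L))
  add(.node("bn1", "bn", "conv1", channels = widths[1]))
  add(.node("relu1", "relu", "bn1"))

  stage_in <- "relu1"
  stage_in_ch <- widths[1]
  for (s in 1:4) {
    w <- widths[s]
    branch_outs <- character(.SWNET_BRANCHES)
    for (b in seq_len(.SWNET_BRANCHES)) {
      tag <- sprintf("s%db%d", s, b)
      a <- paste0("conv_", tag, "_1")
      add(.node(a, "conv", stage_in, in_channels = stage_in_ch,
                out_channels = w, kernel = 3L, stride = 1L, padding = 1L))
      add(.node(paste0("bn_", tag, "_1"), "bn", a, channels = w))
      add(.node(paste0("relu_", tag, "_1"), "relu", paste0("bn_", tag, "_1")))
      z <- paste0("conv_", tag, "_2")
      add(.node(z, "conv", paste0("relu_", tag, "_1"), in_channels = w,
                out_channels = w, kernel = 3L, stride = 2L, padding = 1L))
      add(.node(paste0("bn_", tag, "_2"), "bn", z, channels = w))
      add(.node(paste0("relu_", tag, "_2"), "relu", paste0("bn_", tag, "_2")))
      branch_outs[b] <- paste0("relu_", tag, "_2")
    }
    cc <- sprintf("concat%d", s)
    add(.node(cc, "concat", branch_outs))
    add(.node(sprintf("bnconcat%d", s), "bn", cc,
              channels = .SWNET_BRANCHES * w))
    stage_in <- sprintf("bnconcat%d", s)
    stage_in_ch <- .SWNET_BRANCHES * w
  }

  add(.node("gap", "gap", stage_in))
  add(.node("fc1", "fc", "gap", in_features = stage_in_ch,
            out_features = .SWNET_FC_SIZES[1]))
  add(.node("drop1", "dropout", "fc1", p = .SWNET_DROPOUT_P))
  add(.node("fc2", "fc", "drop1", in_features = .SWNET_FC_SIZES[1],
            out_features = .SWNET_FC_SIZES[2]))
  add(.node("drop2", "dropout", "fc2", p = .SWNET_DROPOUT_P))
  add(.node("fc3", "fc", "drop2", in_features = .SWNET_FC_SIZES[2],
            out_features = as.integer(num_classes)))
  add(.node("softmax", "softmax", "fc3"))

  structure(list(nodes = nodes,
                 input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes),
                 width_multiplier = width_multiplier,
                 widths = widths),
            class = "swnet_graph")
}

.node_types <- function(graph) {
  vapply(graph$nodes, `[[`, character(1), "type")
}

#' Count computational layers of a network graph
#'
#' Sums convolution, batch-norm, ReLU, concatenation, pooling,
#' fully-connected and dropout nodes. The input node and the terminal
#' softmax are not counted as separate layers; under this convention the
#' default SWNet graph has 113 layers (33 + 37 + 33 + 4 + 1 + 3 + 2).
#'
#' @param graph A `swnet_graph`.
#' @return Integer layer count.
#' @export
count_layers <- function(graph) {
  stopifnot(inherits(graph, "swnet_graph"))
  sum(.node_types(graph) %in%
        c("conv", "bn", "relu", "concat", "gap", "fc", "dropout"))
}

#' Tabulate node counts by layer family
#'
#' @param graph A `swnet_graph`.
#' @return Named integer vector over the layer families.
#' @export
layer_census <- function(graph) {
  stopifnot(inherits(graph, "swnet_graph"))
  types <- .node_types(graph)
  fam <- c("conv", "bn", "relu", "concat", "gap", "fc", "dropout")
  stats::setNames(vapply(fam, function(f) sum(types == f), integer(1)), fam)
}

#' Count learnable parameters per node and by layer family
#'
#' Convolution nodes contribute `kernel^2 * in_channels * out_channels`
#' weights plus `out_channels` biases; batch-norm nodes contribute a scale
#' and shift per channel; fully-connected nodes `in * out + out`. The
#' default SWNet graph totals 9,368,192 convolutional parameters.
#'
#' @param graph A `swnet_graph` (shapes are fixed at build time).
#' @return A list of class `swnet_params` with `per_node` (data frame) and
#'   `totals` (named vector: conv, bn, fc, all).
#' @export
count_parameters <- function(graph) {
  stopifnot(inherits(graph, "swnet_graph"))
  rows <- lapply(graph$nodes, function(n) {
    wc <- bc <- 0
    if (n$type == "conv") {
      if (is.null(n$in_channels))
        stop("parameter audit: unresolved input channels at node '", n$name, "'")
      wc <- n$kernel^2 * n$in_channels * n$out_channels
      bc <- n$out_channels
    } else if (n$type == "bn") {
      wc <- n$channels   # scale (gamma)
      bc <- n$channels   # shift (beta)
    } else if (n$type == "fc") {
      wc <- n$in_features * n$out_features
      bc <- n$out_features
    } else {
      return(NULL)
    }
    data.frame(name = n$name, type = n$type, weights = wc, biases = bc,
               total = wc + bc, stringsAsFactors = FALSE)
  })
  per_node <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(per_node) <- NULL
  tot <- function(tp) sum(per_node$total[per_node$type == tp])
  totals <- c(conv = tot("conv"), bn = tot("bn"), fc = tot("fc"),
              all = sum(per_node$total))
  structure(list(per_node = per_node, totals = totals), class = "swnet_params")
}

#' @export
print.swnet_params <- function(x, ...) {
  cat("Parameter audit\n")
  for (nm in names(x$totals))
    cat(sprintf("  %-5s %s\n", nm, format(x$totals[[nm]], big.mark = ",")))
  invisible(x)
}

#' Propagate activation shapes through the graph
#'
#' Symbolic shape inference: stride-1 convolutions preserve spatial size
#' (same padding), stride-2 convolutions halve it, concatenations sum
#' channels, global average pooling collapses to 1x1. For a 224x224x3 input
#' to the default graph the pooled representation is 1x1x1024.
#'
#' @param graph A `swnet_graph`.
#' @param input_shape Integer vector `c(H, W, C)`; defaults to the graph's
#'   input node.
#' @return Data frame of class `swnet_shapes` with one row per node
#'   (name, type, height, width, channels).
#' @export
forward_shapes <- function(graph, input_shape = NULL) {
  stopifnot(inherits(graph, "swnet_graph"))
  if (is.null(input_shape))
    input_shape <- c(graph$input_size, graph$input_size, 3L)
  if (length(input_shape) != 3)
    stop("`input_shape` must be c(H, W, C)")
  shapes <- list()
  for (n in graph$nodes) {
    sh <- switch(n$type,
      input = {
        if (input_shape[3] != n$channels)
          stop("input has ", input_shape[3], " channels; graph expects ",
               n$channels)
        input_shape
      },
      conv = {
        s <- shapes[[n$inputs]]
        if (s[3] != n$in_channels)
          stop("shape error at '", n$name, "': got ", s[3],
               " channels, expected ", n$in_channels)
        hw <- (s[1:2] + 2 * n$padding - n$kernel) %/% n$stride + 1
        c(hw, n$out_channels)
      },
      bn = shapes[[n$inputs]],
      relu = shapes[[n$inputs]],
      dropout = shapes[[n$inputs]],
      concat = {
        ins <- lapply(n$inputs, function(i) shapes[[i]])
        sp <- unique(lapply(ins, function(s) s[1:2]))
        if (length(sp) != 1)
          stop("shape error at '", n$name,
               "': concatenation inputs differ in spatial size")
        c(sp[[1]], sum(vapply(ins, `[[`, numeric(1), 3)))
      },
      gap = c(1, 1, shapes[[n$inputs]][3]),
      fc = {
        s <- shapes[[n$inputs]]
        if (prod(s) != n$in_features)
          stop("shape error at '", n$name, "': got ", prod(s),
               " features, expected ", n$in_features)
        c(1, 1, n$out_features)
      },
      softmax = shapes[[n$inputs]],
      stop("unknown node type: ", n$type))
    shapes[[n$name]] <- sh
  }
  out <- data.frame(
    name = names(shapes),
    type = .node_types(graph)[names(shapes)],
    height = vapply(shapes, `[[`, numeric(1), 1),
    width = vapply(shapes, `[[`, numeric(1), 2),
    channels = vapply(shapes, `[[`, numeric(1), 3),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("swnet_shapes", "data.frame")
  out
}

#' Architecture audit report
#'
#' Assembles the structural audit of a graph: node counts per layer family,
#' total layer count, per-node activation shapes and parameter counts. Used
#' by the `verify` CLI subcommand, which exits non-zero if any expected
#' count for the default build (33 convolutions, 37 batch-norms, 113 layers,
#' 9,368,192 convolutional parameters, 1024 pooled channels) mismatches.
#'
#' @param graph A `swnet_graph`.
#' @return A list of class `swnet_audit` with elements `census`, `layers`,
#'   `shapes`, `params`, and `table` (a Table-1-style per-node data frame).
#' @export
architecture_audit <- function(graph) {
  shapes <- forward_shapes(graph)
  params <- count_parameters(graph)
  pn <- params$per_node
  tab <- shapes
  tab$parameters <- pn$total[match(tab$name, pn$name)]
  tab$parameters[is.na(tab$parameters)] <- 0
  structure(list(census = layer_census(graph),
                 layers = count_layers(graph),
                 shapes = shapes, params = params, table = tab),
            class = "swnet_audit")
}

#' @export
print.swnet_audit <- function(x, ...) {
  cat("SWNet architecture audit\n")
  cat("  layers:", x$layers, "\n  census:",
      paste(names(x$census), x$census, sep = "=", collapse = " "), "\n")
  cat("  conv parameters:", format(x$params$totals[["conv"]], big.mark = ","),
      "\n")
  gap <- x$shapes[x$shapes$type == "gap", ]
  cat(sprintf("  pooled representation: %dx%dx%d\n",
              gap$height, gap$width, gap$channels))
  invisible(x)
}

#' @export
print.swnet_graph <- function(x, ...) {
  cat(sprintf(
    "SWNet graph: input %dx%dx3, widths %s, %d classes, %d layers\n",
    x$input_size, x$input_size, paste(x$widths, collapse = "/"),
    x$num_classes, count_layers(x)))
  invisible(x)
}

# Short structural signature used to fingerprint checkpoints.
.graph_signature <- function(graph) {
  paste(vapply(graph$nodes, function(n) {
    extra <- switch(n$type,
      conv = sprintf("%d>%d/s%d", n$in_channels, n$out_channels, n$stride),
      bn = as.character(n$channels),
      fc = sprintf("%d>%d", n$in_features, n$out_features),
      "")
    paste0(n$name, ":", n$type, ":", extra, "<", paste(n$inputs, collapse = "+"))
  }, character(1)), collapse = ";")
}
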