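test_that("default build reproduces the printed structural counts", {
  g <- build_swnet()
  census <- layer_census(g)
  expect_identical(unname(census["conv"]), 33L)
  expect_identical(unname(census["bn"]), 37L)
  expect_identical(unname(census["relu"]), 33L)
  expect_identical(unname(census["concat"]), 4L)
  expect_identical(unname(census["gap"]), 1L)
  expect_identical(unname(census["fc"]), 3L)
  expect_identical(unname(census["dropout"]), 2L)
  expect_identical(count_layers(g), 113L)
})

test_that("node counts are invariant to width multiplier and class count", {
  for (g in list(build_swnet(width_multiplier = 1 / 8),
                 build_swnet(num_classes = 7))) {
    expect_identical(unname(layer_census(g)["conv"]), 33L)
    expect_identical(unname(layer_census(g)["concat"]), 4L)
    expect_identical(count_layers(g), 113L)
  }
})

test_that("count_layers follows the counting convention on a hand-built graph", {
  nodes <- list(
    input = swnet:::.node("input", "input", channels = 3L, size = 16L),
    c1 = swnet:::.node("c1", "conv", "input", in_channels = 3L,
                       out_channels = 4L, kernel = 3L, stride = 1L,
                       padding = 1L),
    b1 = swnet:::.node("b1", "bn", "c1", channels = 4L))
  g <- structure(list(nodes = nodes, input_size = 16L, num_classes = 2L),
                 class = "swnet_graph")
  expect_identical(count_layers(g), 2L)
})

test_that("configuration errors are rejected", {
  expect_error(build_swnet(input_size = 225), "multiple of 16")
  expect_error(build_swnet(input_size = 100), "multiple of 16")
  expect_error(build_swnet(width_multiplier = 0), "positive")
  expect_error(build_swnet(width_multiplier = -1), "positive")
})

test_that("convolutional parameter total matches the printed value", {
  p <- count_parameters(build_swnet())
  expect_identical(unname(p$totals["conv"]), 9368192)
})

test_that("single conv 3->32 with bias follows the closed form", {
  p <- count_parameters(build_swnet())
  stem <- p$per_node[p$per_node$name == "conv1", ]
  expect_equal(stem$weights, 9 * 3 * 32)
  expect_equal(stem$biases, 32)
  expect_equal(stem$total, 896)
})

test_that("half-width network matches the hand-evaluated closed-form sum", {
  # widths 16/32/64/128: 448 + 18,560 + 110,848 + 442,880 + 1,770,496
  p <- count_parameters(build_swnet(width_multiplier = 1 / 2))
  expect_identical(unname(p$totals["conv"]), 2343232)
})

test_that("parameter audit equals brute-force tensor enumeration", {
  g <- build_swnet(input_size = 32, width_multiplier = 1 / 8)
  w <- init_weights(g, seed = 1)
  p <- count_parameters(g)
  enum <- function(types) {
    sum(vapply(names(g$nodes), function(nm) {
      if (!g$nodes[[nm]]$type %in% types) return(0)
      sum(vapply(w[[nm]][intersect(names(w[[nm]]), c("W", "b", "gamma", "beta"))],
                 length, numeric(1)))
    }, numeric(1)))
  }
  expect_equal(unname(p$totals["conv"]), enum("conv"))
  expect_equal(unname(p$totals["fc"]), enum("fc"))
  expect_equal(unname(p$totals["bn"]), enum("bn"))
})

test_that("width-scaling law: conv total equals the closed-form sum", {
  closed_form <- function(widths) {
    conv <- function(cin, cout) 9 * cin * cout + cout
    total <- conv(3, widths[1])
    stage_in <- widths[1]
    for (s in 1:4) {
      w <- widths[s]
      total <- total + 4 * (conv(stage_in, w) + conv(w, w))
      stage_in <- 4 * w
    }
    total
  }
  for (m in c(1 / 8, 1 / 4, 1)) {
    widths <- ceiling(m * c(32, 64, 128, 256))
    expect_identical(
      unname(count_parameters(build_swnet(width_multiplier = m))$totals["conv"]),
      closed_form(widths))
  }
})

test_that("shape propagation reproduces the per-stage resolutions", {
  sh <- forward_shapes(build_swnet())
  at <- function(nm) unlist(sh[sh$name == nm, c("height", "width", "channels")])
  expect_equal(unname(at("concat1")), c(112, 112, 128))
  expect_equal(unname(at("concat2")), c(56, 56, 256))
  expect_equal(unname(at("concat3")), c(28, 28, 512))
  expect_equal(unname(at("concat4")), c(14, 14, 1024))
  expect_equal(unname(at("gap")), c(1, 1, 1024))
  expect_equal(unname(at("fc1")), c(1, 1, 300))
  expect_equal(unname(at("fc3")), c(1, 1, 2))
  # every concatenation's channels equal the sum of its inputs
  g <- build_swnet()
  for (s in 1:4) {
    cc <- g$nodes[[paste0("concat", s)]]
    ch <- sum(vapply(cc$inputs, function(i) {
      unlist(sh[sh$name == i, "channels"])
    }, numeric(1)))
    expect_equal(unname(at(paste0("concat", s))["channels"]), ch)
  }
})

test_that("architecture audit bundles all printed counts", {
  a <- architecture_audit(build_swnet())
  expect_identical(a$layers, 113L)
  expect_identical(unname(a$census["conv"]), 33L)
  expect_identical(unname(a$params$totals["conv"]), 9368192)
  gap <- a$shapes[a$shapes$type == "gap", ]
  expect_equal(gap$channels, 1024)
  expect_true(all(a$table$parameters[a$table$type == "relu"] == 0))
})

test_that("softmax outputs form a probability simplex", {
  g <- build_swnet(input_size = 32, width_multiplier = 1 / 8)
  w <- init_weights(g, seed = 3)
  set.seed(9)
  x <- array(runif(32 * 32 * 3 * 5), dim = c(32, 32, 3, 5))
  p <- forward_pass(g, w, x)$probs
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
})

test_that("all-zero input with zero-initialized head gives a uniform output", {
  g <- build_swnet(input_size = 32, width_multiplier = 1 / 8)
  w <- init_weights(g, seed = 4)  # biases start at zero
  x <- array(0, dim = c(32, 32, 3, 1))
  p <- forward_pass(g, w, x)$probs
  expect_equal(as.vector(p), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("forward pass is deterministic for fixed weights and input", {
  g <- build_swnet(input_size = 32, width_multiplier = 1 / 8)
  w <- init_weights(g, seed = 5)
  set.seed(12)
  x <- array(runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  expect_identical(forward_pass(g, w, x)$probs, forward_pass(g, w, x)$probs)
})

test_that("wrong input size is a shape error", {
  g <- build_swnet(input_size = 32, width_multiplier = 1 / 8)
  w <- init_weights(g, seed = 6)
  x <- array(0, dim = c(16, 16, 3, 1))
  expect_error(forward_pass(g, w, x), "expects 32x32")
})

test_that("checkpoints round-trip and verify their fingerprint", {
  g <- build_swnet(input_size = 32, width_multiplier = 1 / 8)
  m <- swnet_model(g, seed = 8)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$weights, m$weights)
  # corrupt the graph inside the checkpoint
  obj <- readRDS(path)
  obj$graph$nodes$conv1$out_channels <- 99L
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "fingerprint")
})
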