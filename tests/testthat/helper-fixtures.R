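# Shared fixtures. Synthetic datasets and trained models are built lazily
# and cached for the session, so several test files can reuse the same
# desk-scale training runs.

.fx <- new.env(parent = emptyenv())

fixture_root <- function() {
  if (is.null(.fx$root)) {
    .fx$root <- file.path(tempdir(), "swnet-fixtures")
    dir.create(.fx$root, showWarnings = FALSE, recursive = TRUE)
  }
  .fx$root
}

# Desk-scale study conditions used throughout: 64-px images, width 1/8.
DESK_SIZE <- 64
DESK_MULT <- 1 / 8
DESK_LR <- 0.01

fixture_dataset <- function(name, spec) {
  key <- paste0("ds_", name)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generate_dataset(spec, file.path(fixture_root(), name))
  .fx[[key]]
}

desk_graph <- function() {
  if (is.null(.fx$graph))
    .fx$graph <- build_swnet(input_size = DESK_SIZE,
                             width_multiplier = DESK_MULT)
  .fx$graph
}

# 200 separable images, no confounds: the learning-property dataset.
separable_data <- function() {
  fixture_dataset("separable",
                  synthetic_spec(n_images = 200, image_size = DESK_SIZE,
                                 seed = 11))
}

# Vignette-confounded source A, anti-confounded source B, confound-free
# test set, and all-vignetted probe images for the saliency audit.
bias_data <- function(which) {
  specs <- list(
    srcA = synthetic_spec(n_images = 120, image_size = DESK_SIZE,
                          vignette_prob = c(benign = 0.1, malignant = 0.9),
                          seed = 21),
    srcB = synthetic_spec(n_images = 120, image_size = DESK_SIZE,
                          vignette_prob = c(benign = 0.9, malignant = 0.1),
                          seed = 22),
    clean_test = synthetic_spec(n_images = 60, image_size = DESK_SIZE,
                                vignette_prob = c(benign = 0, malignant = 0),
                                seed = 23),
    probe = synthetic_spec(n_images = 24, image_size = DESK_SIZE,
                           vignette_prob = c(benign = 1, malignant = 1),
                           seed = 24))
  fixture_dataset(which, specs[[which]])
}

desk_config <- function(epochs, seed = 7) {
  train_config(learning_rate = DESK_LR, epochs = epochs, batch_size = 32,
               seed = seed)
}

fixture_model <- function(name) {
  key <- paste0("m_", name)
  if (!is.null(.fx[[key]])) return(.fx[[key]])
  g <- desk_graph()
  m <- switch(name,
    learner = train(g, separable_data()$manifest, desk_config(15)),
    shuffled = {
      man <- separable_data()$manifest
      man$label <- balanced_shuffle(man$label, seed = 101)
      train(g, man, desk_config(15))
    },
    confounded = train(g, bias_data("srcA")$manifest, desk_config(12)),
    sourceB = train(g, bias_data("srcB")$manifest, desk_config(12)),
    pooled = {
      pooled <- merge_datasets(list(bias_data("srcA")$manifest,
                                    bias_data("srcB")$manifest))
      train(g, pooled, desk_config(12))
    },
    stop("unknown fixture model ", name))
  .fx[[key]] <- m
  m
}

# Mean vignette-region saliency mass of a model over the probe images,
# audited at the stage-3 concatenation output (the last stage's map is too
# coarse at desk scale to resolve the ring).
mean_vignette_mass <- function(model, layer = "bnconcat3") {
  probe <- bias_data("probe")
  x <- load_probe_images(probe$manifest)
  mask <- vignette_mask(DESK_SIZE, 0.7)
  mean(vapply(seq_len(dim(x)[4]), function(i) {
    saliency_mass(grad_cam(model, x[, , , i], target_layer = layer), mask)
  }, numeric(1)))
}

load_probe_images <- function(manifest) {
  key <- paste0("imgs_", digest_paths(manifest$image_path))
  if (is.null(.fx[[key]]))
    .fx[[key]] <- swnet:::.load_batch(manifest, DESK_SIZE)$x
  .fx[[key]]
}

digest_paths <- function(paths) {
  # cheap stable key without external digest packages
  sum(utf8ToInt(paste(basename(paths), collapse = ""))) %% 1e9
}

# Zero-information relabeling: exactly half of each true class is labeled
# malignant, so the new labels have phi = 0 with the truth. A plain
# permutation keeps ~51% agreement by chance, which a network can genuinely
# generalize from — this removes that leakage so the control is a real null.
balanced_shuffle <- function(labels, seed) {
  set.seed(seed)
  out <- labels
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    half <- sample(idx, length(idx) %/% 2)
    out[idx] <- "benign"
    out[half] <- "malignant"
  }
  out
}

# Hand-built three-layer toy network (conv -> relu -> gap -> fc) used for
# the Grad-CAM finite-difference oracle; final nodes follow the package's
# fc3/softmax naming so the generic backward seeding applies.
toy_model <- function(channels = 4, size = 8, seed = 5) {
  nodes <- list()
  add <- function(n) nodes[[n$name]] <<- n
  add(swnet:::.node("input", "input", channels = 3L, size = size))
  add(swnet:::.node("conv1", "conv", "input", in_channels = 3L,
                    out_channels = channels, kernel = 3L, stride = 1L,
                    padding = 1L))
  add(swnet:::.node("relu1", "relu", "conv1"))
  add(swnet:::.node("gap", "gap", "relu1"))
  add(swnet:::.node("fc3", "fc", "gap", in_features = channels,
                    out_features = 2L))
  add(swnet:::.node("softmax", "softmax", "fc3"))
  g <- structure(list(nodes = nodes, input_size = as.integer(size),
                      num_classes = 2L, width_multiplier = 1,
                      widths = channels),
                 class = "swnet_graph")
  swnet_model(g, init_weights(g, seed = seed))
}
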