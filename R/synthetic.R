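# Synthetic dermoscopy-like image generator. Class signal lives in lesion
# morphology (border irregularity, color variegation, size, darkness);
# dataset-level confounds (circular vignette, hair strokes) can be dialed
# per class to emulate acquisition artifacts that invite shortcut learning.

.SKIN_TONES <- rbind(
  I   = c(0.96, 0.83, 0.73),
  II  = c(0.92, 0.76, 0.65),
  III = c(0.85, 0.65, 0.52),
  IV  = c(0.72, 0.52, 0.38),
  V   = c(0.55, 0.38, 0.27),
  VI  = c(0.38, 0.26, 0.18))

#' Specify a synthetic dermoscopy dataset
#'
#' Benign lesions are rendered as fairly round, lightly pigmented blobs;
#' malignant lesions are larger, darker, with irregular (sinusoidally
#' perturbed) borders and several dark variegation patches. The per-class
#' irregularity ranges are disjoint by default, so the generative morphology
#' parameters separate the classes perfectly. Confound probabilities control
#' how often the vignette ring or hair strokes are applied per class.
#'
#' @param n_images Number of images.
#' @param image_size Square image side in pixels (default 224).
#' @param class_balance Proportion malignant (default 0.5); the malignant
#'   count is `round(class_balance * n_images)`, deterministically.
#' @param benign,malignant Per-class morphology: list with `irregularity`
#'   (range of border perturbation amplitude), `variegation` (range of dark
#'   patch counts), `diameter_frac` (lesion diameter range as a fraction of
#'   the image side) and `color` (base RGB).
#' @param vignette_prob Length-2 vector `c(benign, malignant)` of vignette
#'   probabilities.
#' @param vignette_inner_frac Untouched central radius as a fraction of the
#'   half-side (default 0.7).
#' @param hair_prob Length-2 vector `c(benign, malignant)` of hair
#'   probabilities.
#' @param hair_strokes Range of stroke counts when hair is applied.
#' @param seed Integer seed; identical spec + seed reproduce the dataset
#'   byte for byte.
#' @return Object of class `swnet_synth_spec`.
#' @export
synthetic_spec <- function(n_images = 200, image_size = 224,
                           class_balance = 0.5,
                           benign = list(irregularity = c(0.02, 0.08),
                                         variegation = c(0, 1),
                                         diameter_frac = c(0.18, 0.30),
                                         color = c(0.72, 0.52, 0.40)),
                           malignant = list(irregularity = c(0.15, 0.35),
                                            variegation = c(2, 4),
                                            diameter_frac = c(0.24, 0.40),
                                            color = c(0.38, 0.22, 0.16)),
                           vignette_prob = c(benign = 0, malignant = 0),
                           vignette_inner_frac = 0.7,
                           hair_prob = c(benign = 0, malignant = 0),
                           hair_strokes = c(4, 10),
                           seed = 1L) {
  if (n_images < 1) stop("`n_images` must be positive")
  if (image_size < 16) stop("`image_size` must be at least 16")
  probs <- c(class_balance, vignette_prob, hair_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (max(benign$diameter_frac, malignant$diameter_frac) >= 1)
    stop("lesion diameters must be smaller than the image")
  if (vignette_inner_frac <= 0 || vignette_inner_frac > 1)
    stop("`vignette_inner_frac` must lie in (0, 1]")
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 class_balance = class_balance,
                 benign = benign, malignant = malignant,
                 vignette_prob = stats::setNames(vignette_prob,
                                                 c("benign", "malignant")),
                 vignette_inner_frac = vignette_inner_frac,
                 hair_prob = stats::setNames(hair_prob,
                                             c("benign", "malignant")),
                 hair_strokes = hair_strokes,
                 seed = as.integer(seed)),
            class = "swnet_synth_spec")
}

.render_lesion <- function(size, cls, skin_rgb) {
  s <- size
  img <- array(rep(skin_rgb, each = s * s), dim = c(s, s, 3))
  img <- img + array(stats::rnorm(s * s * 3, sd = 0.015), dim = c(s, s, 3))

  R <- stats::runif(1, cls$diameter_frac[1], cls$diameter_frac[2]) * s / 2
  cx <- s / 2 + stats::runif(1, -0.08, 0.08) * s
  cy <- s / 2 + stats::runif(1, -0.08, 0.08) * s
  irr <- stats::runif(1, cls$irregularity[1], cls$irregularity[2])
  nveg <- if (cls$variegation[2] > cls$variegation[1])
    sample(cls$variegation[1]:cls$variegation[2], 1) else cls$variegation[1]

  # boundary radius r(theta) = R * (1 + irr * sum_k a_k sin(k theta + phi_k))
  ks <- 2:6
  amp <- stats::runif(length(ks)); amp <- amp / sum(amp)
  phi <- stats::runif(length(ks), 0, 2 * pi)
  yy <- matrix(seq_len(s), s, s) - cy        # row index
  xx <- matrix(seq_len(s), s, s, byrow = TRUE) - cx
  dist <- sqrt(xx^2 + yy^2)
  theta <- atan2(yy, xx)
  pert <- Reduce(`+`, lapply(seq_along(ks),
                             function(i) amp[i] * sin(ks[i] * theta + phi[i])))
  rb <- R * (1 + irr * pert)
  edge <- pmin(pmax((rb - dist) / 1.5 + 0.5, 0), 1)  # soft 1.5-px border

  col <- cls$color * stats::runif(1, 0.9, 1.1)
  for (ch in 1:3)
    img[, , ch] <- img[, , ch] * (1 - edge) + edge * col[ch]

  if (nveg > 0) {
    for (v in seq_len(nveg)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 0.55) * R
      pcx <- cx + rad * cos(ang); pcy <- cy + rad * sin(ang)
      pr <- stats::runif(1, 0.18, 0.38) * R
      pd <- sqrt((xx + cx - pcx)^2 + (yy + cy - pcy)^2)
      pe <- pmin(pmax((pr - pd) / 1.5 + 0.5, 0), 1) * edge
      dark <- col * stats::runif(1, 0.3, 0.6)
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - pe) + pe * dark[ch]
    }
  }
  list(image = pmin(pmax(img, 0), 1), irregularity = irr,
       variegation = nveg, diameter = 2 * R)
}

#' Darken an image outside a central circle (microscope vignette)
#'
#' Multiplies pixels beyond `inner_radius_fraction` of the half-side by a
#' cosine falloff that approaches black at the corners, emulating the dark
#' circular dermatoscope artifact. The central disc is untouched.
#'
#' @param image Square `H x H x 3` array.
#' @param inner_radius_fraction Radius of the untouched disc as a fraction
#'   of the half-side; must lie in (0, 1].
#' @return The vignetted image.
#' @export
add_vignette <- function(image, inner_radius_fraction = 0.7) {
  d <- dim(image)
  if (d[1] != d[2]) stop("`add_vignette` expects a square image")
  if (inner_radius_fraction <= 0 || inner_radius_fraction > 1)
    stop("`inner_radius_fraction` must lie in (0, 1]")
  s <- d[1]
  half <- (s - 1) / 2
  yy <- matrix(seq_len(s) - 1, s, s) - half
  xx <- matrix(seq_len(s) - 1, s, s, byrow = TRUE) - half
  r <- sqrt(xx^2 + yy^2) / half
  r0 <- inner_radius_fraction
  rmax <- sqrt(2)  # corner distance in half-side units
  fall <- pmin(pmax((r - r0) / (rmax - r0), 0), 1)
  factor <- 0.02 + 0.98 * 0.5 * (1 + cos(pi * fall))
  factor[r <= r0] <- 1
  image * array(rep(factor, 3), dim = d)
}

#' Mask of the vignette-affected region
#'
#' Boolean `H x H` matrix marking pixels outside the untouched central disc
#' — the region a vignette darkens. Used with [saliency_mass()] to audit how
#' much model attention falls on the artifact.
#'
#' @param size Image side in pixels.
#' @param inner_radius_fraction As in [add_vignette()].
#' @return Logical matrix.
#' @export
vignette_mask <- function(size, inner_radius_fraction = 0.7) {
  half <- (size - 1) / 2
  yy <- matrix(seq_len(size) - 1, size, size) - half
  xx <- matrix(seq_len(size) - 1, size, size, byrow = TRUE) - half
  sqrt(xx^2 + yy^2) / half > inner_radius_fraction
}

#' Draw dark hair-like strokes over an image
#'
#' Renders `n_strokes` curved dark strokes (quadratic Bezier arcs, 1-3 px
#' wide). `n_strokes = 0` returns the image unchanged.
#'
#' @param image `H x W x 3` array.
#' @param n_strokes Number of strokes (>= 0).
#' @param seed Optional integer seed for reproducible placement.
#' @return The image with strokes rendered.
#' @export
add_hair <- function(image, n_strokes, seed = NULL) {
  stopifnot(n_strokes >= 0)
  if (n_strokes == 0) return(image)
  if (!is.null(seed)) {
    old <- .hold_rng(); on.exit(.release_rng(old))
    set.seed(seed)
  }
  d <- dim(image); H <- d[1]; W <- d[2]
  for (k in seq_len(n_strokes)) {
    p0 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    ang <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 0.35, 0.8) * min(H, W)
    p2 <- p0 + len * c(sin(ang), cos(ang))
    mid <- (p0 + p2) / 2
    bend <- stats::runif(1, -0.25, 0.25) * len
    p1 <- mid + bend * c(cos(ang), -sin(ang))
    tt <- seq(0, 1, length.out = ceiling(2.5 * len))
    py <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
    px <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
    width <- sample(1:3, 1)
    shade <- stats::runif(1, 0.03, 0.15)
    offs <- seq(-(width - 1) / 2, (width - 1) / 2, by = 1)
    for (oy in offs) for (ox in offs) {
      iy <- round(py + oy); ix <- round(px + ox)
      keep <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
      if (!any(keep)) next
      idx <- cbind(iy[keep], ix[keep])
      for (ch in 1:3) {
        pl <- image[, , ch]
        pl[idx] <- shade
        image[, , ch] <- pl
      }
    }
  }
  image
}

#' Generate a labeled synthetic dermoscopy dataset
#'
#' Renders the images described by `spec`, writes them as PNG files into
#' `Benign/` and `Malignant/` subfolders of `dir` together with a
#' `metadata.csv` (filename, label, confound flags, skin tone, morphology
#' parameters), and returns the metadata plus a ready manifest.
#'
#' @param spec A `swnet_synth_spec`.
#' @param dir Output directory (created if missing).
#' @return List with `metadata` (data frame) and `manifest`
#'   (`swnet_manifest` tagged with the directory basename).
#' @export
generate_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "swnet_synth_spec"))
  for (sub in c("Benign", "Malignant"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  old <- .hold_rng(); on.exit(.release_rng(old))
  set.seed(spec$seed)

  n <- spec$n_images
  n_mal <- round(spec$class_balance * n)
  labels <- sample(rep(c("malignant", "benign"), c(n_mal, n - n_mal)))
  md <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    cls <- spec[[lab]]
    tone <- sample(nrow(.SKIN_TONES), 1)
    les <- .render_lesion(spec$image_size, cls, .SKIN_TONES[tone, ])
    img <- les$image
    has_v <- stats::runif(1) < spec$vignette_prob[[lab]]
    if (has_v) img <- add_vignette(img, spec$vignette_inner_frac)
    has_h <- stats::runif(1) < spec$hair_prob[[lab]]
    if (has_h)
      img <- add_hair(img, sample(spec$hair_strokes[1]:spec$hair_strokes[2], 1))
    sub <- if (lab == "benign") "Benign" else "Malignant"
    fn <- sprintf("synthetic_%04d.png", i)
    png::writePNG(img, file.path(dir, sub, fn))
    md[[i]] <- data.frame(
      filename = file.path(sub, fn), label = lab,
      has_vignette = has_v, has_hair = has_h,
      skin_tone = rownames(.SKIN_TONES)[tone],
      irregularity = les$irregularity, variegation = les$variegation,
      diameter = les$diameter, stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, md)
  utils::write.csv(metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  manifest <- .manifest(data.frame(
    image_path = file.path(dir, metadata$filename),
    label = metadata$label, source_dataset = basename(dir),
    split = "unassigned", stringsAsFactors = FALSE))
  list(metadata = metadata, manifest = manifest, dir = dir)
}

#' Label-artifact association (phi coefficient)
#'
#' Pearson correlation of the binary label (malignant = 1) with a binary
#' artifact flag, computed from the 2x2 contingency table. Quantifies how
#' strongly a confound is coupled to the class — the dial behind shortcut
#' learning. Degenerate margins return 0 with a warning.
#'
#' @param metadata Data frame with a `label` column and the flag column.
#' @param flag Name of the logical artifact column (default "has_vignette").
#' @return Phi coefficient in \[-1, 1\].
#' @export
confound_association <- function(metadata, flag = "has_vignette") {
  y <- metadata$label == "malignant"
  a <- as.logical(metadata[[flag]])
  if (length(unique(y)) < 2 || length(unique(a)) < 2) {
    warning("degenerate margin: phi undefined, returning 0", call. = FALSE)
    return(0)
  }
  n11 <- as.numeric(sum(y & a)); n10 <- as.numeric(sum(y & !a))
  n01 <- as.numeric(sum(!y & a)); n00 <- as.numeric(sum(!y & !a))
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

#' Threshold classifier on generative morphology parameters
#'
#' Classifies records from the generator's metadata alone (no pixels) by
#' thresholding border irregularity halfway between the class ranges. With
#' the default disjoint ranges this is exact, confirming that the labels are
#' information-bearing.
#'
#' @param metadata Generator metadata data frame.
#' @param spec The `swnet_synth_spec` that produced it.
#' @return Character vector of predicted labels.
#' @export
morphology_classifier <- function(metadata, spec) {
  thr <- (spec$benign$irregularity[2] + spec$malignant$irregularity[1]) / 2
  ifelse(metadata$irregularity > thr, "malignant", "benign")
}
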