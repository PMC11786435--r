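# Dataset manifests: folder-per-class loading, HAM10000 relabeling,
# resizing and deterministic stratified train/test splits.

.LABELS <- c("benign", "malignant")

.manifest <- function(df) {
  stopifnot(all(c("image_path", "label", "source_dataset", "split") %in%
                  names(df)))
  if (anyDuplicated(df$image_path))
    warning("manifest contains duplicated image paths", call. = FALSE)
  if (!all(df$label %in% .LABELS))
    stop("labels must be 'benign' or 'malignant'")
  rownames(df) <- NULL
  class(df) <- c("swnet_manifest", "data.frame")
  df
}

#' Load a folder-per-class image dataset
#'
#' Expects `root` to contain class-named subfolders (case-insensitive match
#' of "benign"/"malignant"; "malicious" is accepted as a synonym for
#' malignant) holding JPEG/PNG files.
#'
#' @param root Dataset directory.
#' @param source_tag Tag recorded in the `source_dataset` column.
#' @return A `swnet_manifest` data frame with columns image_path, label,
#'   source_dataset, split.
#' @export
load_folder_dataset <- function(root, source_tag = basename(root)) {
  if (!dir.exists(root)) stop("dataset root '", root, "' does not exist")
  subs <- list.dirs(root, recursive = FALSE)
  lab_of <- function(d) {
    nm <- tolower(basename(d))
    if (nm == "benign") "benign"
    else if (nm %in% c("malignant", "malicious")) "malignant"
    else NA_character_
  }
  labs <- vapply(subs, lab_of, character(1))
  subs <- subs[!is.na(labs)]; labs <- labs[!is.na(labs)]
  rows <- mapply(function(d, lab) {
    files <- list.files(d, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(files)) return(NULL)
    data.frame(image_path = files, label = lab, source_dataset = source_tag,
               split = "unassigned", stringsAsFactors = FALSE)
  }, subs, labs, SIMPLIFY = FALSE)
  df <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(df) || !nrow(df))
    stop("no benign/malignant images found under '", root, "'")
  .manifest(df)
}

#' Map a HAM10000 dx diagnosis code to a binary label
#'
#' Benign: nv (nevus), bkl (benign keratosis), df (dermatofibroma).
#' Malignant: mel (melanoma), bcc (basal cell carcinoma), ak and akiec
#' (actinic keratosis / intraepithelial carcinoma). Any other code — the
#' HAM10000 "vasc" class in particular — is rejected rather than guessed.
#'
#' @param dx_code Character vector of dx codes (case/whitespace tolerated).
#' @return Character vector of "benign"/"malignant".
#' @export
ham10000_relabel <- function(dx_code) {
  code <- tolower(trimws(dx_code))
  benign <- c("nv", "bkl", "df")
  malignant <- c("mel", "bcc", "ak", "akiec")
  bad <- setdiff(unique(code), c(benign, malignant))
  if (length(bad))
    stop("unmapped dx code(s): ", paste(bad, collapse = ", "),
         " (only nv/bkl/df and mel/bcc/ak/akiec are defined)")
  ifelse(code %in% benign, "benign", "malignant")
}

#' Read a HAM10000-style metadata table
#'
#' Accepts CSV or XLSX with columns `image_id` and `dx` and returns a data
#' frame with an added binary `label` column via [ham10000_relabel()].
#'
#' @param path Metadata file (.csv or .xlsx).
#' @return Data frame with image_id, dx, label.
#' @export
read_ham10000_metadata <- function(path) {
  ext <- tolower(tools::file_ext(path))
  md <- if (ext == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
  else if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX metadata requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path))
  } else stop("unsupported metadata format: .", ext)
  if (!all(c("image_id", "dx") %in% names(md)))
    stop("metadata must have columns 'image_id' and 'dx'")
  md$label <- ham10000_relabel(md$dx)
  md
}

#' Read an image file as an H x W x 3 array in \[0, 1\]
#'
#' @param path PNG or JPEG file.
#' @return Numeric array `H x W x 3`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG requires the 'jpeg' package")
    jpeg::readJPEG(path)
  } else stop("unsupported image format: .", ext)
  .as_rgb(img)
}

.as_rgb <- function(img) {
  if (length(dim(img)) == 2) {
    warning("non-RGB input converted to RGB", call. = FALSE)
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  } else if (dim(img)[3] == 4) {
    warning("alpha channel dropped", call. = FALSE)
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3] != 3) {
    stop("cannot interpret image with ", dim(img)[3], " channels")
  }
  img
}

#' Bilinearly resize an RGB image to a square side
#'
#' @param image `H x W x 3` array in \[0, 1\] (grayscale is promoted with a
#'   warning).
#' @param side Target side in pixels (default 224).
#' @return `side x side x 3` array in \[0, 1\].
#' @export
resize_image <- function(image, side = 224) {
  image <- .as_rgb(image)
  d <- dim(image)
  if (d[1] < 1 || d[2] < 1) stop("image must have at least one pixel")
  if (d[1] == side && d[2] == side) return(image)
  # EBImage uses x (width) as the first dimension
  eb <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(eb, w = side, h = side)
  res <- aperm(EBImage::imageData(out), c(2, 1, 3))
  pmin(pmax(res, 0), 1)
}

#' Deterministic stratified train/test split
#'
#' Assigns each record to train or test, stratified per class:
#' `round(train_fraction * n_class)` records per class go to train
#' (round-half-up), the rest to test. The same seed always yields the same
#' assignment.
#'
#' @param manifest A `swnet_manifest`.
#' @param train_fraction Proportion assigned to train (default 0.8).
#' @param seed Integer seed.
#' @return The manifest with its `split` column filled in.
#' @export
split_dataset <- function(manifest, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(manifest, "swnet_manifest"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie strictly between 0 and 1")
  counts <- table(manifest$label)
  if (any(counts < 2))
    stop("each class needs at least 2 images to stratify (got ",
         paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  old <- .hold_rng(); on.exit(.release_rng(old))
  set.seed(seed)
  split <- rep("test", nrow(manifest))
  for (lab in unique(manifest$label)) {
    idx <- which(manifest$label == lab)
    n_train <- floor(train_fraction * length(idx) + 0.5)  # round half up
    split[sample(idx, n_train)] <- "train"
  }
  manifest$split <- split
  manifest
}

#' Subset a manifest by split
#'
#' @param manifest A `swnet_manifest`.
#' @param split `"train"` or `"test"`.
#' @return The filtered manifest.
#' @export
manifest_split <- function(manifest, split) {
  .manifest(manifest[manifest$split == split, , drop = FALSE])
}

#' Persist / restore a manifest as CSV
#'
#' @param manifest A `swnet_manifest`.
#' @param path CSV file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  .manifest(utils::read.csv(path, stringsAsFactors = FALSE))
}

# Load every image of a manifest into an H x W x 3 x N array at `side`,
# skipping (with a message) files that fail to read.
.load_batch <- function(manifest, side) {
  n <- nrow(manifest)
  x <- array(0, dim = c(side, side, 3, n))
  ok <- logical(n)
  for (i in seq_len(n)) {
    img <- tryCatch(resize_image(read_image(manifest$image_path[i]), side),
                    error = function(e) NULL)
    if (is.null(img)) next
    x[, , , i] <- img
    ok[i] <- TRUE
  }
  if (!all(ok))
    message(sum(!ok), " unreadable image(s) skipped")
  list(x = x[, , , ok, drop = FALSE], labels = manifest$label[ok],
       manifest = manifest[ok, , drop = FALSE])
}
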