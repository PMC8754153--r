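# ---------------------------------------------------------------------------
# Manifests, splits, oversampling, box masks
#
# A dataset is a plain CSV manifest with one row per bounding box
# (image_path,label,x_min,y_min,x_max,y_max; box columns empty for
# nonsuspicious rows) plus the referenced PNG/JPEG images.  Boxes use
# 0-based, half-open pixel coordinates [x_min, x_max) x [y_min, y_max),
# x = column.
# ---------------------------------------------------------------------------

LABEL_LEVELS <- c("nonsuspicious", "suspicious")

parse_label <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- match(lx, LABEL_LEVELS) - 1L
  out[lx %in% c("0", "1")] <- as.integer(lx[lx %in% c("0", "1")])
  if (anyNA(out)) {
    stop("unparseable label(s): ", paste(unique(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Construct a labeled image sample
#'
#' @param image_id opaque identifier string.
#' @param image `H x W x 3` array with values in `[0,1]`.
#' @param label 0 (nonsuspicious) or 1 (suspicious).
#' @param boxes numeric matrix with columns `x_min, y_min, x_max, y_max` in
#'   0-based half-open pixel coordinates; zero rows for an unannotated
#'   sample.
#' @return an `image_sample` object. A suspicious sample without boxes is
#'   kept as classification-only (`bbox_supervised = FALSE`); a
#'   nonsuspicious sample is always supervised with an all-zero mask.
#' @export
image_sample <- function(image_id, image, label, boxes = NULL) {
  if (is.null(boxes)) boxes <- matrix(numeric(0), 0L, 4L)
  boxes <- matrix(as.numeric(boxes), ncol = 4L,
                  dimnames = list(NULL, c("x_min", "y_min", "x_max", "y_max")))
  label <- as.integer(label)
  stopifnot(label %in% c(0L, 1L), length(dim(image)) == 3L,
            dim(image)[3L] == 3L)
  if (nrow(boxes) > 0L && label == 0L) {
    stop("sample '", image_id, "': bounding boxes are only annotated on ",
         "suspicious samples", call. = FALSE)
  }
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (nrow(boxes) > 0L) {
    bad <- boxes[, 1L] < 0 | boxes[, 2L] < 0 | boxes[, 3L] > w |
      boxes[, 4L] > h | boxes[, 1L] >= boxes[, 3L] | boxes[, 2L] >= boxes[, 4L]
    if (any(bad)) {
      stop("sample '", image_id, "': box outside image bounds or degenerate",
           call. = FALSE)
    }
  }
  structure(list(image_id = image_id, image = image, label = label,
                 boxes = boxes,
                 bbox_supervised = label == 0L || nrow(boxes) > 0L),
            class = "image_sample")
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package", call. = FALSE)
    }
    aperm(EBImage::imageData(EBImage::readImage(path)), c(2L, 1L, 3L))
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Load an image manifest
#'
#' Reads a CSV manifest (columns `image_path,label,x_min,y_min,x_max,y_max`;
#' one row per box, box columns empty for box-free rows) together with the
#' referenced images. Relative image paths resolve against the manifest's
#' directory; pixel values are scaled to `[0,1]`.
#'
#' @param path manifest CSV path.
#' @return list of [image_sample()] objects, one per distinct image path,
#'   boxes aggregated. A suspicious row without boxes triggers a warning and
#'   the sample is kept as classification-only.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "label", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  df$label_int <- parse_label(df$label)
  samples <- list()
  unsupervised <- 0L
  for (pth in unique(df$image_path)) {
    rows <- df[df$image_path == pth, , drop = FALSE]
    labels <- unique(rows$label_int)
    if (length(labels) > 1L) {
      stop("image '", pth, "' appears with conflicting labels", call. = FALSE)
    }
    full <- if (grepl("^(/|[A-Za-z]:)", pth)) pth else file.path(base, pth)
    if (!file.exists(full)) stop("image file not found: ", full, call. = FALSE)
    img <- read_image_file(full)
    has_box <- !is.na(rows$x_min)
    boxes <- as.matrix(rows[has_box, c("x_min", "y_min", "x_max", "y_max")])
    h <- dim(img)[1L]; w <- dim(img)[2L]
    if (nrow(boxes) > 0L) {
      bad <- which(boxes[, 1L] < 0 | boxes[, 2L] < 0 | boxes[, 3L] > w |
                     boxes[, 4L] > h | boxes[, 1L] >= boxes[, 3L] |
                     boxes[, 2L] >= boxes[, 4L])
      if (length(bad) > 0L) {
        stop("manifest row ", rownames(rows[has_box, , drop = FALSE])[bad[1L]],
             ": box outside image bounds for '", pth, "'", call. = FALSE)
      }
    }
    s <- image_sample(pth, img, labels, boxes)
    if (s$label == 1L && nrow(boxes) == 0L) unsupervised <- unsupervised + 1L
    samples[[length(samples) + 1L]] <- s
  }
  if (unsupervised > 0L) {
    warning(unsupervised, " suspicious sample(s) without boxes kept as ",
            "classification-only (excluded from the box-supervision loss)",
            call. = FALSE)
  }
  samples
}

#' Write samples to disk as PNGs plus a manifest
#'
#' Inverse of [load_manifest()]: emits one PNG per sample and a CSV manifest
#' with one row per box.
#'
#' @param samples list of [image_sample()] objects.
#' @param dir output directory (created if missing).
#' @param manifest_name CSV file name within `dir`.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(samples, dir, manifest_name = "manifest.csv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    fname <- sprintf("img_%04d.png", i)
    png::writePNG(s$image, file.path(dir, fname))
    lab <- LABEL_LEVELS[s$label + 1L]
    if (nrow(s$boxes) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        image_path = fname, label = lab, x_min = NA_real_, y_min = NA_real_,
        x_max = NA_real_, y_max = NA_real_)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        image_path = fname, label = lab,
        x_min = s$boxes[, 1L], y_min = s$boxes[, 2L],
        x_max = s$boxes[, 3L], y_max = s$boxes[, 4L])
    }
  }
  out <- file.path(dir, manifest_name)
  utils::write.csv(do.call(rbind, rows), out, row.names = FALSE, na = "")
  invisible(out)
}

sample_labels <- function(samples) {
  vapply(samples, function(s) s$label, integer(1))
}

#' Stratified train/validation/test split
#'
#' Splits samples into three disjoint parts, stratified by label and
#' deterministic for a fixed seed.
#'
#' @param samples list of [image_sample()] objects.
#' @param fractions numeric triple summing to 1 (default `0.8, 0.1, 0.1`).
#' @param seed integer seed.
#' @return a `dataset_split` with fields `train`, `validation`, `test`.
#' @export
split_dataset <- function(samples, fractions = c(0.8, 0.1, 0.1), seed = 0L) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  labels <- sample_labels(samples)
  parts <- list(train = integer(0), validation = integer(0), test = integer(0))
  with_seed(seed, {
    for (lv in sort(unique(labels))) {
      idx <- sample(which(labels == lv))
      n <- length(idx)
      n_tr <- round(fractions[1L] * n)
      n_va <- round(fractions[2L] * n)
      n_va <- min(n_va, n - n_tr)
      parts$train <- c(parts$train, idx[seq_len(n_tr)])
      parts$validation <- c(parts$validation,
                            idx[seq_len(n_va) + n_tr])
      parts$test <- c(parts$test, idx[seq(n_tr + n_va + 1L, length.out = n - n_tr - n_va)])
    }
  })
  structure(list(train = samples[parts$train],
                 validation = samples[parts$validation],
                 test = samples[parts$test],
                 split_fractions = fractions, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>",
      "train:", length(x$train),
      " validation:", length(x$validation),
      " test:", length(x$test), "\n")
  invisible(x)
}

#' Random oversampling of the minority class
#'
#' Duplicates minority-class samples (with replacement) until both classes
#' hold equally many images; the majority class is untouched.
#'
#' @param train list of [image_sample()] objects containing both classes.
#' @param seed integer seed.
#' @return the balanced sample list (originals first, duplicates appended).
#' @export
oversample_minority <- function(train, seed = 0L) {
  labels <- sample_labels(train)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab == 0L)) {
    stop("oversampling requires both classes to be present", call. = FALSE)
  }
  if (tab[1L] == tab[2L]) return(train)
  minority <- as.integer(names(tab)[which.min(tab)])
  pool <- which(labels == minority)
  deficit <- abs(diff(as.integer(tab)))
  extra <- with_seed(seed, sample(pool, deficit, replace = TRUE))
  c(train, train[extra])
}

#' Rasterise a sample's boxes into a binary supervision mask
#'
#' The union of the boxes becomes 1 on an `H x W` grid (pixel centres decide
#' membership, so boxes scale cleanly to a grid coarser or finer than the
#' image); overlaps stay binary. A nonsuspicious sample yields the all-zero
#' mask.
#'
#' @param sample an [image_sample()].
#' @param grid integer `(H, W)` of the target grid; defaults to the image
#'   resolution.
#' @return a `supervision_mask` with fields `mask` (0/1 matrix) and
#'   `class_index`.
#' @export
boxes_to_mask <- function(sample, grid = NULL) {
  d <- dim(sample$image)
  grid <- as.integer(grid %||% d[1:2])
  mask <- matrix(0, grid[1L], grid[2L])
  if (sample$label == 1L && nrow(sample$boxes) > 0L) {
    sy <- grid[1L] / d[1L]
    sx <- grid[2L] / d[2L]
    xc <- (seq_len(grid[2L]) - 0.5)
    yc <- (seq_len(grid[1L]) - 0.5)
    for (b in seq_len(nrow(sample$boxes))) {
      bx <- sample$boxes[b, ]
      cols <- xc >= bx[1L] * sx & xc < bx[3L] * sx
      rowsv <- yc >= bx[2L] * sy & yc < bx[4L] * sy
      mask[rowsv, cols] <- 1
    }
  }
  structure(list(mask = mask, class_index = sample$label + 1L),
            class = "supervision_mask")
}

#' Write a supervision mask as a 0/255 grayscale PNG
#'
#' @param mask a `supervision_mask` from [boxes_to_mask()].
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$mask, path)
  invisible(path)
}
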