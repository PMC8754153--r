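# ---------------------------------------------------------------------------
# Evaluation: classification metrics and attention localization
#
# Classification uses the clinical convention: "suspicious" is the positive
# class, so sensitivity is the suspicious recall. The localization metrics
# quantify how much of an attention map falls where the annotators drew
# boxes; they are artifact-defined operationalisations (energy-in-box,
# thresholded IoU, pointing hit) of an otherwise visual comparison.
# ---------------------------------------------------------------------------

#' Classification metrics with "suspicious" as the positive class
#'
#' @param predictions integer vector of predicted labels (0/1).
#' @param labels integer vector of true labels (0/1).
#' @return a `classification_report` list with `accuracy`, `sensitivity`,
#'   `specificity` and the confusion counts `tp, fp, tn, fn`.
#' @export
classification_metrics <- function(predictions, labels) {
  if (length(predictions) == 0L || length(predictions) != length(labels)) {
    stop("predictions and labels must be nonempty and equal length",
         call. = FALSE)
  }
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  stopifnot(all(predictions %in% c(0L, 1L)), all(labels %in% c(0L, 1L)))
  tp <- sum(predictions == 1L & labels == 1L)
  tn <- sum(predictions == 0L & labels == 0L)
  fp <- sum(predictions == 1L & labels == 0L)
  fn <- sum(predictions == 0L & labels == 1L)
  structure(list(accuracy = (tp + tn) / length(labels),
                 sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> accuracy %.2f%%  sensitivity %.1f%%  specificity %.1f%%\n",
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Attention-localization metrics for one image
#'
#' Compares a normalised attention map with the sample's box union:
#' `energy_in_box` is the fraction of total attention mass inside the boxes,
#' `iou` the intersection-over-union of the thresholded map with the box
#' union, and `pointing_hit` whether the attention maximum lands inside a
#' box.
#'
#' @param map a normalised `attention_map` (or plain matrix in `[0,1]`) at
#'   image resolution.
#' @param sample the [image_sample()] the map explains; must have boxes.
#' @param threshold binarisation threshold on the normalised map for the IoU
#'   (default 0.5).
#' @return one-row data.frame with `energy_in_box`, `iou`, `pointing_hit`;
#'   `NULL` (with a message) when the sample has no boxes.
#' @export
attention_localization <- function(map, sample, threshold = 0.5) {
  if (nrow(sample$boxes) == 0L) {
    message("sample '", sample$image_id, "' has no boxes; skipping")
    return(NULL)
  }
  a <- if (inherits(map, "attention_map")) map$upsampled else map
  box <- boxes_to_mask(sample, dim(a))$mask
  total <- sum(a)
  energy <- if (total > 0) sum(a * box) / total else 0
  bin <- a >= threshold
  inter <- sum(bin & box == 1)
  uni <- sum(bin | box == 1)
  iou <- if (uni > 0L) inter / uni else 0
  hit <- box[which.max(a)] == 1
  data.frame(image_id = sample$image_id, energy_in_box = energy, iou = iou,
             pointing_hit = hit)
}

#' Attention-localization report over a sample set
#'
#' Computes Grad-CAM maps for the ground-truth class of every box-bearing
#' sample and aggregates the per-image metrics.
#'
#' @param model a `gain_model`.
#' @param samples list of [image_sample()] objects.
#' @param layer_id Grad-CAM target layer (default: last conv layer).
#' @param threshold IoU binarisation threshold.
#' @return a data.frame of per-image metrics with the aggregate means as
#'   attribute `"aggregate"`.
#' @export
localization_report <- function(model, samples, layer_id = NULL,
                                threshold = 0.5) {
  rows <- list()
  for (s in samples) {
    if (nrow(s$boxes) == 0L) next
    m <- gradcam(model, s$image, class_index = s$label + 1L,
                 layer_id = layer_id, target = dim(s$image)[1:2])
    rows[[length(rows) + 1L]] <- attention_localization(m, s, threshold)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), energy_in_box = numeric(0),
               iou = numeric(0), pointing_hit = logical(0))
  attr(out, "aggregate") <- data.frame(
    mean_energy_in_box = mean(out$energy_in_box),
    mean_iou = mean(out$iou),
    pointing_hit_rate = mean(out$pointing_hit))
  out
}

draw_box_outline <- function(image, boxes, color = c(1, 0, 0)) {
  d <- dim(image)
  for (b in seq_len(nrow(boxes))) {
    x0 <- max(1L, floor(boxes[b, 1L]) + 1L)
    y0 <- max(1L, floor(boxes[b, 2L]) + 1L)
    x1 <- min(d[2L], ceiling(boxes[b, 3L]))
    y1 <- min(d[1L], ceiling(boxes[b, 4L]))
    for (ch in 1:3) {
      image[y0:y1, c(x0, x1), ch] <- color[ch]
      image[c(y0, y1), x0:x1, ch] <- color[ch]
    }
  }
  image
}

#' Compare models on classification and attention localization
#'
#' Evaluates each model on the same dataset and, optionally, writes a
#' side-by-side overlay panel (columns: input, input with boxes, one
#' attention overlay per model; rows: the first `n_panel` box-bearing
#' samples).
#'
#' @param models named list of `gain_model` objects.
#' @param samples evaluation samples.
#' @param layer_ids optional named list/vector of Grad-CAM layers per model.
#' @param threshold IoU binarisation threshold.
#' @param panel_path optional PNG path for the overlay panel.
#' @param n_panel rows in the panel.
#' @return data.frame with one row per model: accuracy, sensitivity,
#'   specificity, mean energy-in-box, mean IoU, pointing-hit rate.
#' @export
compare_models <- function(models, samples, layer_ids = NULL, threshold = 0.5,
                           panel_path = NULL, n_panel = 4L) {
  stopifnot(length(models) >= 1L, !is.null(names(models)))
  labels <- sample_labels(samples)
  rows <- list()
  locs <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    layer <- if (!is.null(layer_ids)) layer_ids[[nm]] else NULL
    cls <- classification_metrics(predict_labels(m, samples), labels)
    loc <- localization_report(m, samples, layer, threshold)
    agg <- attr(loc, "aggregate")
    locs[[nm]] <- loc
    rows[[nm]] <- data.frame(model = nm, accuracy = cls$accuracy,
                             sensitivity = cls$sensitivity,
                             specificity = cls$specificity,
                             mean_energy_in_box = agg$mean_energy_in_box,
                             mean_iou = agg$mean_iou,
                             pointing_hit_rate = agg$pointing_hit_rate)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_image") <- locs
  if (!is.null(panel_path)) {
    boxed <- Filter(function(s) nrow(s$boxes) > 0L, samples)
    boxed <- boxed[seq_len(min(n_panel, length(boxed)))]
    if (length(boxed) > 0L) {
      panel_rows <- lapply(boxed, function(s) {
        cells <- list(s$image, draw_box_outline(s$image, s$boxes))
        for (nm in names(models)) {
          layer <- if (!is.null(layer_ids)) layer_ids[[nm]] else NULL
          map <- gradcam(models[[nm]], s$image, class_index = s$label + 1L,
                         layer_id = layer, target = dim(s$image)[1:2])
          cells[[length(cells) + 1L]] <- attention_overlay(s$image, map)
        }
        do.call(abind_width, cells)
      })
      png::writePNG(do.call(abind_height, panel_rows), panel_path)
    }
  }
  out
}

abind_width <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  gap <- array(1, c(d[1L], 2L, d[3L]))
  joined <- parts[[1L]]
  for (p in parts[-1L]) {
    joined2 <- array(0, c(d[1L], dim(joined)[2L] + 2L + dim(p)[2L], d[3L]))
    joined2[, seq_len(dim(joined)[2L]), ] <- joined
    joined2[, dim(joined)[2L] + 1:2, ] <- gap
    joined2[, (dim(joined)[2L] + 3L):dim(joined2)[2L], ] <- p
    joined <- joined2
  }
  joined
}

abind_height <- function(...) {
  parts <- list(...)
  w <- max(vapply(parts, function(p) dim(p)[2L], integer(1)))
  parts <- lapply(parts, function(p) {
    if (dim(p)[2L] == w) return(p)
    out <- array(1, c(dim(p)[1L], w, dim(p)[3L]))
    out[, seq_len(dim(p)[2L]), ] <- p
    out
  })
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1L], integer(1))) +
                      2L * (length(parts) - 1L), w, 3L))
  at <- 1L
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    out[at:(at + dim(p)[1L] - 1L), , ] <- p
    at <- at + dim(p)[1L]
    if (i < length(parts)) {
      out[at:(at + 1L), , ] <- 1
      at <- at + 2L
    }
  }
  out
}

#' Plot a training loss curve
#'
#' @param trace trace data.frame from [stage1_train()] or [stage2_train()].
#' @return a ggplot object (total loss per iteration, per-stream curves for
#'   stage-2 traces).
#' @export
plot_loss_curve <- function(trace) {
  if ("l_total" %in% names(trace)) {
    long <- data.frame(
      iteration = rep(trace$iteration, 3L),
      loss = c(trace$w_cl, trace$w_am, trace$w_bbox),
      stream = rep(c("zeta * L_cl", "alpha * L_am", "beta * L_bbox"),
                   each = nrow(trace)))
    ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$loss,
                                       colour = .data$stream)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "iteration", y = "weighted loss",
                    title = "Guided-attention training loss") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(trace, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "iteration", y = "cross-entropy loss",
                    title = "Stage-1 training loss") +
      ggplot2::theme_minimal()
  }
}
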