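# ---------------------------------------------------------------------------
# Grad-CAM attention maps
#
# The attention map for class c at conv layer l is the rectified
# channel-weighted sum of the layer's activation maps, with weights equal to
# the spatially averaged gradient of the pre-softmax class score with respect
# to each activation channel:
#
#   w_k = GAP( d s_c / d f_k )          (neuron importance)
#   A_c = ReLU( sum_k w_k f_k )
#
# Maps are upsampled bilinearly to the input grid and min-max normalised to
# [0,1] before any comparison with a box mask or a threshold.
# ---------------------------------------------------------------------------

#' Run a forward pass and record activations at a target layer
#'
#' The activations and scores come from the same forward pass; the returned
#' cache carries every intermediate needed to differentiate the scores with
#' respect to the recorded layer.
#'
#' @param model a `gain_model`.
#' @param image `H x W x 3` array in `[0,1]` (resized to the model input
#'   internally).
#' @param layer_id one of the model's convolutional layer ids; the default is
#'   the last convolutional layer, standard Grad-CAM practice.
#' @return a list with `activations` (`h x w x K` rectified feature stack),
#'   `scores` (pre-softmax, one per class), `layer_id`, and the forward
#'   `cache`.
#' @export
capture_activations <- function(model, image, layer_id = NULL) {
  layer_id <- layer_id %||% utils::tail(model$layer_ids, 1L)
  if (!layer_id %in% model$layer_ids) {
    stop("unknown layer_id '", layer_id, "'; valid layers: ",
         paste(model$layer_ids, collapse = ", "), call. = FALSE)
  }
  img <- prep_image(model, image)
  cache <- cnn_forward(model, img)
  acts <- switch(layer_id, conv1 = cache$f1, conv2 = cache$f2)
  list(activations = acts, scores = cache$scores, layer_id = layer_id,
       cache = cache, input = img)
}

#' Grad-CAM neuron importance weights
#'
#' Computes the spatial mean of `d s_c / d f_{l,k}` for every channel k of
#' the captured layer by explicit reverse-mode differentiation from the
#' class score through the layers above the target.
#'
#' @param model a `gain_model`.
#' @param captured result of [capture_activations()].
#' @param class_index 1-based class index of the score to differentiate
#'   (1 = nonsuspicious, 2 = suspicious).
#' @return numeric vector of length K (one weight per activation channel).
#' @export
neuron_importance <- function(model, captured, class_index) {
  cache <- captured$cache
  d2 <- dim(cache$f2)
  npix2 <- d2[1L] * d2[2L]
  # d s_c / d gap = Wh[c, ]; d gap_k / d f2 = 1/npix everywhere
  df2_chan <- model$params$Wh[class_index, ] / npix2
  if (captured$layer_id == "conv2") {
    return(df2_chan)
  }
  # continue to conv1: constant-per-channel grad at f2, through the conv2
  # ReLU, the convolution, and the average pool
  df2 <- array(rep(df2_chan, each = npix2), d2)
  dz2 <- df2 * (cache$z2 > 0)
  dpool <- conv2d_bw_input(dz2, model$params$W2)
  df1 <- avgpool2_bw(dpool, dim(cache$f1))
  d1 <- dim(cache$f1)
  colMeans(matrix(df1, d1[1L] * d1[2L], d1[3L]))
}

#' Combine activations and neuron weights into an attention map
#'
#' @param activations `h x w x K` activation stack.
#' @param weights length-K neuron importance vector.
#' @param class_index class the map explains (stored on the result).
#' @return an `attention_map` object with the rectified raw map at the conv
#'   grid resolution.
#' @export
attention_map <- function(activations, weights, class_index = NA_integer_) {
  d <- dim(activations)
  stopifnot(length(weights) == d[3L])
  raw <- matrix(matrix(activations, d[1L] * d[2L], d[3L]) %*% weights,
                d[1L], d[2L])
  raw[raw < 0] <- 0
  structure(list(raw = raw, upsampled = NULL, normalized = FALSE,
                 class_index = class_index),
            class = "attention_map")
}

#' Upsample an attention map to the image grid and normalise it
#'
#' Bilinear upsampling to `target`, then min-max normalisation to `[0,1]`.
#' An identically-zero map stays zero; a constant positive map becomes all
#' ones.
#'
#' @param map an `attention_map`.
#' @param target integer `(H, W)` of the image grid.
#' @return the map with `upsampled` filled in and `normalized = TRUE`.
#' @export
upsample_normalize <- function(map, target) {
  up <- resize_bilinear_2d(map$raw, target)
  mx <- max(up)
  if (mx <= 1e-12) {
    up[] <- 0
  } else {
    mn <- min(up)
    up <- if (mx - mn < 1e-12) array(1, dim(up)) else (up - mn) / (mx - mn)
  }
  map$upsampled <- up
  map$normalized <- TRUE
  map
}

#' Grad-CAM attention map for one image
#'
#' Convenience chain of [capture_activations()], [neuron_importance()],
#' [attention_map()] and [upsample_normalize()].
#'
#' @inheritParams capture_activations
#' @param class_index class to explain; defaults to the predicted class.
#' @param target resolution of the final map; defaults to the image size.
#' @return a normalised `attention_map`.
#' @export
gradcam <- function(model, image, class_index = NULL, layer_id = NULL,
                    target = NULL) {
  cap <- capture_activations(model, image, layer_id)
  class_index <- class_index %||% which.max(cap$scores)
  wts <- neuron_importance(model, cap, class_index)
  m <- attention_map(cap$activations, wts, class_index)
  upsample_normalize(m, target %||% dim(image)[1:2])
}

#' @export
print.attention_map <- function(x, ...) {
  cat("<attention_map> raw", paste(dim(x$raw), collapse = "x"),
      if (!is.null(x$upsampled))
        paste0(" upsampled ", paste(dim(x$upsampled), collapse = "x")),
      " normalized:", x$normalized, "\n")
  invisible(x)
}

# --- export helpers ---------------------------------------------------------

jet_colormap <- function(v) {
  # piecewise-linear blue -> cyan -> yellow -> red, v in [0,1]
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  list(r = r, g = g, b = b)
}

#' Overlay an attention map on its image
#'
#' @param image `H x W x 3` array in `[0,1]`.
#' @param map a normalised `attention_map` (or a plain `H x W` matrix in
#'   `[0,1]`).
#' @param alpha blend weight of the colourised map.
#' @return `H x W x 3` array.
#' @export
attention_overlay <- function(image, map, alpha = 0.45) {
  a <- if (inherits(map, "attention_map")) map$upsampled else map
  stopifnot(!is.null(a), all(dim(a) == dim(image)[1:2]))
  cm <- jet_colormap(a)
  out <- image
  out[, , 1] <- (1 - alpha) * image[, , 1] + alpha * cm$r
  out[, , 2] <- (1 - alpha) * image[, , 2] + alpha * cm$g
  out[, , 3] <- (1 - alpha) * image[, , 3] + alpha * cm$b
  out
}

#' Write an attention map as an 8-bit grayscale PNG
#'
#' @param map a normalised `attention_map`.
#' @param path output path.
#' @export
write_attention_png <- function(map, path) {
  stopifnot(map$normalized)
  png::writePNG(map$upsampled, path)
  invisible(path)
}
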