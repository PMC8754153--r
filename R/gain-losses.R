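# ---------------------------------------------------------------------------
# Guided-attention loss streams
#
# Three losses drive stage-2 training:
#   L_cl   -- softmax cross-entropy of the classification stream;
#   L_am   -- attention mining: the attended region is softly erased from the
#             input and the remaining evidence for the true class is pushed
#             to chance level, |0.5 - s_c(I*)|;
#   L_bbox -- mean squared error between the normalised attention map and a
#             binary box mask on the image grid.
# The total is the weighted sum  zeta*L_cl + alpha*L_am + beta*L_bbox.
# ---------------------------------------------------------------------------

#' Soft-mask parameters
#'
#' Threshold and sharpness of the sigmoid soft-threshold applied to a
#' normalised attention map. The defaults (`sigma = 0.20`, `w = 3.0`) are the
#' values under which the attention-erasing mask behaved best on the oral
#' lesion task; as `w` grows the mask approaches the hard indicator
#' `A > sigma`.
#'
#' @param sigma threshold in `[0,1]`; scalar or an `H x W` matrix.
#' @param w sharpness, `> 0`.
#' @return a `soft_mask_params` list.
#' @export
soft_mask_params <- function(sigma = 0.20, w = 3.0) {
  stopifnot(all(sigma >= 0), all(sigma <= 1), w > 0)
  structure(list(sigma = sigma, w = w), class = "soft_mask_params")
}

#' Loss-stream weights
#'
#' Weights of the combined stage-2 objective. The defaults
#' (`zeta = 0.25`, `alpha = 0.5`, `beta = 360`) were chosen so the weighted
#' classification term stays below ~2, the weighted mining term below ~0.5,
#' and the weighted box term averages ~0.5 over an iteration.
#'
#' @param zeta weight of the classification loss.
#' @param alpha weight of the attention-mining loss.
#' @param beta weight of the bounding-box loss.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(zeta = 0.25, alpha = 0.5, beta = 360) {
  stopifnot(zeta >= 0, alpha >= 0, beta >= 0)
  structure(list(zeta = zeta, alpha = alpha, beta = beta),
            class = "loss_weights")
}

#' Sigmoid soft-threshold of a normalised attention map
#'
#' `T(A) = 1 / (1 + exp(-w (A - sigma)))`, elementwise.
#'
#' @param a normalised attention values (matrix or `attention_map`).
#' @param params a [soft_mask_params()] object.
#' @return matrix of the same shape with values in `(0, 1)`.
#' @export
soft_threshold <- function(a, params = soft_mask_params()) {
  if (inherits(a, "attention_map")) {
    stopifnot(a$normalized)
    a <- a$upsampled
  }
  1 / (1 + exp(-params$w * (a - params$sigma)))
}

#' Erase the attended region from an image
#'
#' `I* = I - T(A) . I = I (1 - T(A))`, the soft-masked image fed to the
#' attention-mining stream.
#'
#' @param image `H x W x 3` array in `[0,1]`.
#' @param tmask `H x W` soft mask from [soft_threshold()].
#' @return masked image, same shape, values in `[0,1]`.
#' @export
apply_softmask <- function(image, tmask) {
  d <- dim(image)
  stopifnot(all(dim(tmask) == d[1:2]))
  image * array(rep(1 - tmask, d[3L]), d)
}

#' Attention-mining loss
#'
#' `L_am = |0.5 - sum_c s_c(I*)|` where the sum runs over the ground-truth
#' class(es) of the sample and `s_c` is the softmax probability on the masked
#' image. For a single-label binary sample this is the distance of the true
#' class's probability from chance, so a fully erased lesion scores 0.
#'
#' @param masked_probs softmax probabilities of the masked image.
#' @param truth_classes 1-based index (or indices) of the ground-truth class.
#' @return scalar in `[0, 0.5]` for a single-label sample.
#' @export
attention_mining_loss <- function(masked_probs, truth_classes) {
  if (any(masked_probs < -1e-9) || any(masked_probs > 1 + 1e-9)) {
    stop("masked scores outside [0,1]; attention mining expects softmax ",
         "probabilities", call. = FALSE)
  }
  abs(0.5 - sum(masked_probs[truth_classes]))
}

#' Bounding-box supervision loss
#'
#' `L_bbox = (1/n) sum_c mean( (A_c - H_c)^2 )` over the supervised class
#' maps, each attention map compared on the image grid with the binary mask
#' of the annotated boxes (all-zero for a nonsuspicious sample).
#'
#' @param maps a normalised `attention_map` or a list of them (one per
#'   supervised class).
#' @param masks an `H x W` 0/1 matrix, a `supervision_mask`, or a list
#'   matching `maps`.
#' @return scalar `>= 0`, zero iff every map equals its mask.
#' @export
bbox_loss <- function(maps, masks) {
  if (inherits(maps, "attention_map") || is.matrix(maps)) maps <- list(maps)
  if (!is.list(masks) || inherits(masks, "supervision_mask")) masks <- list(masks)
  stopifnot(length(maps) == length(masks))
  terms <- mapply(function(a, h) {
    av <- if (inherits(a, "attention_map")) {
      stopifnot(a$normalized)
      a$upsampled
    } else a
    hv <- if (inherits(h, "supervision_mask")) h$mask else h
    if (!all(dim(av) == dim(hv))) {
      stop("attention map and supervision mask shapes differ (",
           paste(dim(av), collapse = "x"), " vs ",
           paste(dim(hv), collapse = "x"), ")", call. = FALSE)
    }
    mean((av - hv)^2)
  }, maps, masks)
  mean(terms)
}

#' Classification loss
#'
#' Softmax cross-entropy of the pre-softmax scores against the label.
#'
#' @param scores pre-softmax class scores.
#' @param label_index 1-based true class index.
#' @return scalar `>= 0`.
#' @export
classification_loss <- function(scores, label_index) {
  p <- softmax(scores)
  -log(max(p[label_index], 1e-12))
}

#' Combine the three loss streams
#'
#' `L_total = zeta L_cl + alpha L_am + beta L_bbox`, with the weighted
#' per-stream values kept as diagnostics so their magnitudes can be
#' monitored across training.
#'
#' @param l_cl,l_am,l_bbox the per-stream losses of one iteration.
#' @param weights a [loss_weights()] object.
#' @return a `gain_loss_breakdown` list with fields `l_cl`, `l_am`,
#'   `l_bbox`, `l_total` and the weighted values `w_cl`, `w_am`, `w_bbox`.
#' @export
total_loss <- function(l_cl, l_am, l_bbox, weights = loss_weights()) {
  w_cl <- weights$zeta * l_cl
  w_am <- weights$alpha * l_am
  w_bbox <- weights$beta * l_bbox
  structure(list(l_cl = l_cl, l_am = l_am, l_bbox = l_bbox,
                 l_total = w_cl + w_am + w_bbox,
                 w_cl = w_cl, w_am = w_am, w_bbox = w_bbox,
                 weights = weights),
            class = "gain_loss_breakdown")
}

#' @export
print.gain_loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<gain_loss_breakdown> L_cl %.4g  L_am %.4g  L_bbox %.4g  L_total %.4g\n",
    x$l_cl, x$l_am, x$l_bbox, x$l_total))
  invisible(x)
}
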