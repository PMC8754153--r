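# ---------------------------------------------------------------------------
# Convolutional classifier
#
# The built-in backbone ("tiny") is a two-block CNN sized so that every
# contract in this package -- Grad-CAM, attention-guided losses, the
# two-stage training protocol -- can be exercised end to end on a laptop:
#
#   conv 3x3 (3 -> C1) -> ReLU -> avgpool 2x2
#   conv 3x3 (C1 -> C2) -> ReLU            <- Grad-CAM target layer "conv2"
#   GAP -> linear (C2 -> 2)
#
# The rectified conv outputs are the attention-map activations; because the
# target layer feeds straight into GAP + linear, the Grad-CAM neuron
# importances have the closed form W[c, k] / (h * w), which keeps the
# attention map an ordinary differentiable function of the weights.
# ---------------------------------------------------------------------------

#' Build a two-class convolutional classifier
#'
#' Constructs a classifier with a freshly initialised two-output head, the
#' head tagged so its learning-rate multiplier can differ from the body
#' during stage-1 transfer-style training.
#'
#' @param backbone backbone name. `"tiny"` is the in-repo two-block CNN;
#'   `"vgg19"` (and other ImageNet names) are recognised but unavailable
#'   because pretrained weights are not bundled with the package.
#' @param input_size integer `(H, W)` the model consumes; images are resized
#'   to this before the forward pass. Must be a multiple of 2.
#' @param channels integer vector of the two conv-block widths.
#' @param head_lr_multiplier learning-rate factor applied to the new head.
#' @param seed integer seed for the weight initialisation.
#' @return an object of class `gain_model`.
#' @export
build_classifier <- function(backbone = "tiny", input_size = c(64L, 64L),
                             channels = c(16L, 16L), head_lr_multiplier = 10,
                             seed = 0L) {
  known <- c("tiny", "vgg19", "resnet50", "inceptionresnetv2")
  if (!backbone %in% known) {
    stop("unknown backbone '", backbone, "'; valid backbones: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (backbone != "tiny") {
    stop("backbone '", backbone, "' requires pretrained weights, which are ",
         "not bundled with this package; use backbone = \"tiny\"",
         call. = FALSE)
  }
  stopifnot(length(input_size) == 2L, all(input_size %% 2L == 0L))
  c1 <- channels[1L]; c2 <- channels[2L]
  params <- with_seed(seed, {
    list(
      W1 = array(stats::rnorm(3 * 3 * 3 * c1, sd = sqrt(2 / (9 * 3))),
                 c(3L, 3L, 3L, c1)),
      b1 = numeric(c1),
      W2 = array(stats::rnorm(3 * 3 * c1 * c2, sd = sqrt(2 / (9 * c1))),
                 c(3L, 3L, c1, c2)),
      b2 = numeric(c2),
      Wh = matrix(stats::rnorm(2 * c2, sd = sqrt(1 / c2)), 2L, c2),
      bh = numeric(2L)
    )
  })
  structure(list(
    backbone = backbone,
    params = params,
    input_size = as.integer(input_size),
    channels = as.integer(channels),
    layer_ids = c("conv1", "conv2"),
    head_params = c("Wh", "bh"),
    head_lr_multiplier = head_lr_multiplier,
    n_classes = 2L
  ), class = "gain_model")
}

#' @export
print.gain_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<gain_model> backbone:", x$backbone,
      " input:", paste(x$input_size, collapse = "x"),
      " params:", np,
      " head lr x", x$head_lr_multiplier, "\n")
  invisible(x)
}

# plain numeric forward; returns every intermediate needed by Grad-CAM.
# Inputs are centred (x - 0.5) so conv features are not all-positive; the
# soft-mask erasure upstream still operates in raw [0,1] image space.
cnn_forward <- function(model, image) {
  p <- model$params
  z1 <- conv2d_fw(image - 0.5, p$W1, p$b1)
  f1 <- z1 * (z1 > 0)
  pl <- avgpool2_fw(f1)
  z2 <- conv2d_fw(pl, p$W2, p$b2)
  f2 <- z2 * (z2 > 0)
  d <- dim(f2)
  g <- colMeans(matrix(f2, d[1L] * d[2L], d[3L]))
  scores <- drop(p$Wh %*% g) + p$bh
  list(z1 = z1, f1 = f1, pool1 = pl, z2 = z2, f2 = f2, gap = g,
       scores = scores)
}

# tape forward shared by both training stages; param nodes are returned so a
# single backward pass yields all weight gradients
cnn_forward_tape <- function(pnodes, image_node) {
  f1 <- op_relu(op_conv2d(op_add_const(image_node, -0.5),
                          pnodes$W1, pnodes$b1))
  pl <- op_avgpool2(f1)
  f2 <- op_relu(op_conv2d(pl, pnodes$W2, pnodes$b2))
  scores <- op_linear(op_gap(f2), pnodes$Wh, pnodes$bh)
  list(f1 = f1, f2 = f2, scores = scores)
}

param_nodes <- function(model) {
  lapply(model$params, tn_leaf, requires = TRUE)
}

collect_grads <- function(pnodes) {
  lapply(pnodes, function(n) {
    if (is.null(n$grad)) array(0, dim(n$value) %||% length(n$value)) else n$grad
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify images with a fitted model
#'
#' @param model a `gain_model`.
#' @param samples a list of image samples (see [load_manifest()]).
#' @return integer vector of predicted labels (0 = nonsuspicious,
#'   1 = suspicious); score ties break toward nonsuspicious.
#' @export
predict_labels <- function(model, samples) {
  vapply(samples, function(s) {
    sc <- cnn_forward(model, prep_image(model, s$image))$scores
    if (sc[2L] > sc[1L]) 1L else 0L
  }, integer(1))
}

prep_image <- function(model, image) {
  resize_image(image, model$input_size)
}

# --- SGD with momentum and per-group learning-rate factors ------------------

sgd_init <- function(model) {
  list(velocity = lapply(model$params, function(p) p * 0))
}

sgd_step <- function(model, grads, state, lr, momentum = 0.9) {
  mult <- model$head_lr_multiplier
  for (nm in names(model$params)) {
    lrf <- if (nm %in% model$head_params) mult else 1
    state$velocity[[nm]] <- momentum * state$velocity[[nm]] + grads[[nm]]
    model$params[[nm]] <- model$params[[nm]] - lr * lrf * state$velocity[[nm]]
  }
  list(model = model, state = state)
}

# run `expr` under a fixed RNG state, restoring the caller's stream after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
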