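# ---------------------------------------------------------------------------
# Two-stage training protocol
#
# Stage 1 is conventional classification training: SGD with momentum, the
# freshly initialised head updated at a multiplied learning rate, the global
# rate dropped by a fixed factor on a fixed epoch period, and a stochastic
# affine augmentation drawn per iteration.  On completion the head
# multiplier is reduced for the hand-off to stage 2.
#
# Stage 2 runs the three-stream guided-attention architecture at batch size
# one.  Each iteration performs, in order: the classification forward pass
# (scores, L_cl, and the Grad-CAM map from that same pass), the soft-masked
# attention-mining pass with shared weights (L_am), and the box-supervision
# comparison (L_bbox); the single optimizer step happens only after all
# three streams, from one backward pass of the combined loss.
# ---------------------------------------------------------------------------

#' Stage-1 training configuration
#'
#' Defaults are the full-scale transfer-learning schedule: 55 epochs, batch
#' 8, learning rate 3e-4 dropping by 0.1 every 13 epochs, momentum 0.9,
#' head learning-rate factor 10 reduced to 2 afterwards, and the Table-style
#' affine augmentation policy.
#'
#' @param epochs,batch_size,learning_rate,momentum SGD schedule.
#' @param lr_drop_factor,lr_drop_period learning-rate decay: multiply by
#'   `lr_drop_factor` every `lr_drop_period` epochs.
#' @param head_lr_multiplier,final_head_lr_multiplier head learning-rate
#'   factor during stage 1 and after its completion.
#' @param augment an [augment_config()].
#' @param seed integer seed.
#' @return a `stage1_config` list.
#' @export
stage1_config <- function(epochs = 55L, batch_size = 8L,
                          learning_rate = 3e-4, momentum = 0.9,
                          lr_drop_factor = 0.1, lr_drop_period = 13L,
                          head_lr_multiplier = 10,
                          final_head_lr_multiplier = 2,
                          augment = augment_config(), seed = 0L) {
  stopifnot(learning_rate > 0, momentum >= 0, lr_drop_factor > 0,
            head_lr_multiplier >= 1, final_head_lr_multiplier >= 1,
            batch_size >= 1L, epochs >= 0L)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_period = as.integer(lr_drop_period),
                 head_lr_multiplier = head_lr_multiplier,
                 final_head_lr_multiplier = final_head_lr_multiplier,
                 augment = augment, seed = as.integer(seed)),
            class = "stage1_config")
}

#' Stage-2 (guided-attention) training configuration
#'
#' Defaults are the full-scale schedule: 5 epochs of SGD at learning rate
#' 1e-4, batch size fixed at 1 (the three-stream architecture processes one
#' image per iteration), soft-mask sigma 0.20 / sharpness 3.0, and stream
#' weights zeta 0.25 / alpha 0.5 / beta 360. Augmentation is off by default
#' in this stage.
#'
#' @param epochs,learning_rate,momentum SGD schedule (batch size is 1).
#' @param mask_params a [soft_mask_params()].
#' @param weights a [loss_weights()].
#' @param n_supervised_classes 1 (supervise the ground-truth class map only,
#'   the default) or 2 (supervise both class maps).
#' @param clip_norm global L2 gradient-norm ceiling per iteration (the box
#'   stream's large weight makes occasional spikes compound through
#'   momentum); `Inf` disables clipping.
#' @param augment an [augment_config()]; disabled by default.
#' @param seed integer seed.
#' @return a `stage2_config` list.
#' @export
stage2_config <- function(epochs = 5L, learning_rate = 1e-4, momentum = 0.9,
                          mask_params = soft_mask_params(),
                          weights = loss_weights(),
                          n_supervised_classes = 1L,
                          clip_norm = 5,
                          augment = augment_config(enabled = FALSE),
                          seed = 0L) {
  stopifnot(learning_rate > 0, epochs >= 0L,
            n_supervised_classes %in% c(1L, 2L), clip_norm > 0)
  structure(list(epochs = as.integer(epochs), batch_size = 1L,
                 learning_rate = learning_rate, momentum = momentum,
                 mask_params = mask_params, weights = weights,
                 n_supervised_classes = as.integer(n_supervised_classes),
                 clip_norm = clip_norm,
                 augment = augment, seed = as.integer(seed)),
            class = "stage2_config")
}

as_sample_list <- function(x) {
  if (inherits(x, "dataset_split")) x$train else x
}

#' Stage-1 classification training
#'
#' @param model a `gain_model` from [build_classifier()].
#' @param train a `dataset_split` (its `train` part is used, expected to be
#'   oversampled) or a plain list of [image_sample()] objects.
#' @param config a [stage1_config()].
#' @return list with the trained `model` and a per-iteration `trace`
#'   data.frame (`iteration, epoch, loss, lr`).
#' @export
stage1_train <- function(model, train, config = stage1_config()) {
  samples <- as_sample_list(train)
  if (config$epochs > 0L && length(samples) == 0L) {
    stop("stage-1 training set is empty", call. = FALSE)
  }
  state <- sgd_init(model)
  rows <- list()
  iter <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate *
        config$lr_drop_factor^((epoch - 1L) %/% config$lr_drop_period)
      ord <- sample(seq_along(samples))
      starts <- seq(1L, length(ord), by = config$batch_size)
      for (s0 in starts) {
        batch <- ord[seq(s0, min(s0 + config$batch_size - 1L, length(ord)))]
        gacc <- NULL
        lacc <- 0
        for (si in batch) {
          s <- samples[[si]]
          img <- prep_image(model, s$image)
          if (config$augment$enabled) {
            tf <- sample_transform(config$augment)
            img <- apply_transform(img, tf, config$augment$fill_rgb)
          }
          pn <- param_nodes(model)
          fw <- cnn_forward_tape(pn, tn_leaf(img))
          loss <- op_softmax_ce(fw$scores, s$label + 1L)
          tape_backward(loss)
          g <- collect_grads(pn)
          gacc <- if (is.null(gacc)) g else mapply(`+`, gacc, g, SIMPLIFY = FALSE)
          lacc <- lacc + loss$value
        }
        nb <- length(batch)
        gacc <- lapply(gacc, function(x) x / nb)
        st <- sgd_step(model, gacc, state, lr, config$momentum)
        model <- st$model
        state <- st$state
        iter <- iter + 1L
        rows[[iter]] <- data.frame(iteration = iter, epoch = epoch,
                                   loss = lacc / nb, lr = lr)
      }
    }
  })
  model$head_lr_multiplier <- config$final_head_lr_multiplier
  trace <- if (iter > 0L) do.call(rbind, rows) else
    data.frame(iteration = integer(0), epoch = integer(0),
               loss = numeric(0), lr = numeric(0))
  list(model = model, trace = trace)
}

#' One three-stream guided-attention iteration
#'
#' Runs the classification stream (scores, `L_cl`, and the attention map
#' from the same forward pass), the attention-mining stream on the
#' soft-erased image with shared weights (`L_am`), and the box-supervision
#' term (`L_bbox`), then takes exactly one optimizer step from one backward
#' pass of the weighted total. A suspicious sample without boxes contributes
#' 0 to `L_bbox`; a nonsuspicious sample is supervised against the all-zero
#' mask.
#'
#' @param model a `gain_model`.
#' @param sample an [image_sample()].
#' @param mask a `supervision_mask` at the model's input resolution
#'   (computed internally when `NULL`).
#' @param config a [stage2_config()].
#' @param state optimizer state from [sgd_init()]; when `NULL` a fresh state
#'   is used (and returned).
#' @return list with the updated `model`, optimizer `state`, the
#'   `gain_loss_breakdown`, and the normalised `attention` map matrix.
#' @export
gain_iteration <- function(model, sample, mask = NULL,
                           config = stage2_config(), state = NULL) {
  if (is.null(state)) state <- sgd_init(model)
  img <- prep_image(model, sample$image)
  if (config$augment$enabled) {
    tf <- sample_transform(config$augment)
    # boxes follow the warp so the supervision mask stays aligned
    boxes <- sample$boxes
    if (nrow(boxes) > 0L) {
      sy <- model$input_size[1L] / dim(sample$image)[1L]
      sx <- model$input_size[2L] / dim(sample$image)[2L]
      boxes[, c(1L, 3L)] <- boxes[, c(1L, 3L)] * sx
      boxes[, c(2L, 4L)] <- boxes[, c(2L, 4L)] * sy
      boxes <- transform_boxes(boxes, tf, model$input_size)
    }
    img <- apply_transform(img, tf, config$augment$fill_rgb)
    sample$image <- img
    sample$boxes <- boxes
    sample$bbox_supervised <- sample$label == 0L || nrow(boxes) > 0L
    mask <- NULL
  }
  if (is.null(mask)) mask <- boxes_to_mask(sample, model$input_size)

  g <- gain_loss_graph(model, img, sample$label, mask,
                       sample$bbox_supervised, config)
  breakdown <- total_loss(g$l_cl$value, g$l_am$value, g$l_bbox$value,
                          config$weights)
  if (!is.finite(breakdown$l_total)) {
    stop("non-finite loss in GAIN iteration: L_cl=", g$l_cl$value,
         " L_am=", g$l_am$value, " L_bbox=", g$l_bbox$value, call. = FALSE)
  }

  # deferred update: the single step happens only now, after all streams
  tape_backward(g$l_total)
  grads <- collect_grads(g$pnodes)
  cn <- config$clip_norm %||% Inf
  if (is.finite(cn)) {
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (gnorm > cn) grads <- lapply(grads, function(g) g * cn / gnorm)
  }
  st <- sgd_step(model, grads, state, config$learning_rate,
                 config$momentum)
  list(model = st$model, state = st$state, breakdown = breakdown,
       attention = g$a_norm$value)
}

# build the full three-stream loss graph on the tape; `image` is already at
# the model's input resolution.  Returned nodes share one parameter set so a
# single backward pass yields the combined-gradient of Eq.-(7)-style totals.
gain_loss_graph <- function(model, image, label, mask, bbox_supervised,
                            config) {
  cls <- label + 1L
  pn <- param_nodes(model)
  x <- tn_leaf(image)

  # stream 1: classification (and the attention map from the same pass)
  fw <- cnn_forward_tape(pn, x)
  l_cl <- op_softmax_ce(fw$scores, cls)
  d2 <- dim(fw$f2$value)
  wv <- op_row_scale(pn$Wh, cls, 1 / (d2[1L] * d2[2L]))
  a_raw <- op_relu(op_chan_wsum(fw$f2, wv))
  a_norm <- op_minmax(op_upsample_bilin(a_raw, model$input_size))

  # stream 2: attention mining on the soft-erased image, shared weights
  tmask <- op_sigmoid_shift(a_norm, config$mask_params$sigma,
                            config$mask_params$w)
  istar <- op_soft_erase(x, tmask)
  fw2 <- cnn_forward_tape(pn, istar)
  l_am <- op_abs_half(op_softmax_pick(fw2$scores, cls))

  # stream 3: box supervision of the attention map
  l_bbox <- if (!bbox_supervised) {
    tn_leaf(0)
  } else if (config$n_supervised_classes == 2L) {
    other <- 3L - cls
    wv2 <- op_row_scale(pn$Wh, other, 1 / (d2[1L] * d2[2L]))
    a2 <- op_minmax(op_upsample_bilin(
      op_relu(op_chan_wsum(fw$f2, wv2)), model$input_size))
    h_other <- matrix(0, model$input_size[1L], model$input_size[2L])
    op_wsum3(op_mse_vs(a_norm, mask$mask), op_mse_vs(a2, h_other),
             tn_leaf(0), 0.5, 0.5, 0)
  } else {
    op_mse_vs(a_norm, mask$mask)
  }

  wts <- config$weights
  l_total <- op_wsum3(l_cl, l_am, l_bbox, wts$zeta, wts$alpha, wts$beta)
  list(pnodes = pn, l_cl = l_cl, l_am = l_am, l_bbox = l_bbox,
       l_total = l_total, a_norm = a_norm)
}

#' Stage-2 guided-attention training
#'
#' Iterates [gain_iteration()] over the training samples (reshuffled each
#' epoch from the seed) for the configured number of epochs.
#'
#' @param model a `gain_model` (normally the stage-1 result).
#' @param train a `dataset_split` or list of [image_sample()] objects.
#' @param config a [stage2_config()].
#' @return list with the trained `model` and a per-iteration `trace`
#'   data.frame (`iteration, epoch, l_cl, l_am, l_bbox, l_total, w_cl,
#'   w_am, w_bbox`).
#' @export
stage2_train <- function(model, train, config = stage2_config()) {
  samples <- as_sample_list(train)
  if (config$epochs > 0L && length(samples) == 0L) {
    stop("stage-2 training set is empty", call. = FALSE)
  }
  masks <- lapply(samples, boxes_to_mask, grid = model$input_size)
  state <- sgd_init(model)
  rows <- list()
  iter <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(seq_along(samples))
      for (si in ord) {
        res <- gain_iteration(model, samples[[si]], masks[[si]], config, state)
        model <- res$model
        state <- res$state
        iter <- iter + 1L
        b <- res$breakdown
        rows[[iter]] <- data.frame(iteration = iter, epoch = epoch,
                                   l_cl = b$l_cl, l_am = b$l_am,
                                   l_bbox = b$l_bbox, l_total = b$l_total,
                                   w_cl = b$w_cl, w_am = b$w_am,
                                   w_bbox = b$w_bbox)
      }
    }
  })
  trace <- if (iter > 0L) do.call(rbind, rows) else
    data.frame(iteration = integer(0), epoch = integer(0),
               l_cl = numeric(0), l_am = numeric(0), l_bbox = numeric(0),
               l_total = numeric(0), w_cl = numeric(0), w_am = numeric(0),
               w_bbox = numeric(0))
  list(model = model, trace = trace)
}

#' Write a training trace to CSV
#'
#' @param trace a trace data.frame from [stage1_train()] or
#'   [stage2_train()].
#' @param path output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
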