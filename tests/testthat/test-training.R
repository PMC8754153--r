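small_set <- function(n = 24L, seed = 0L, rho = 0.5) {
  generate_dataset(synth_config(n_images = n, image_size = c(16L, 16L),
                                confounder_correlation = rho, seed = seed))
}

test_that("classifier construction validates backbones and seeds the head", {
  m <- build_classifier("tiny", input_size = c(16L, 16L), channels = c(3L, 3L))
  expect_s3_class(m, "gain_model")
  expect_equal(nrow(m$params$Wh), 2L)
  expect_length(cnn_forward(m, oracle_image())$scores, 2L)
  expect_error(build_classifier("alexnet"), "valid backbones")
  expect_error(build_classifier("vgg19"), "pretrained")
  a <- build_classifier(seed = 5L)
  b <- build_classifier(seed = 5L)
  expect_identical(a$params, b$params)
})

test_that("stage 1: zero epochs is a no-op and the LR schedule drops by 0.1", {
  samples <- small_set(12L)
  m <- build_classifier(input_size = c(16L, 16L), channels = c(3L, 3L))
  r0 <- stage1_train(m, samples, stage1_config(epochs = 0L))
  expect_identical(r0$model$params, m$params)
  expect_equal(nrow(r0$trace), 0L)

  cfg <- stage1_config(epochs = 14L, batch_size = 12L, learning_rate = 1e-3,
                       lr_drop_period = 13L,
                       augment = augment_config(enabled = FALSE), seed = 1L)
  r <- stage1_train(m, samples, cfg)
  lr_by_epoch <- tapply(r$trace$lr, r$trace$epoch, unique)
  expect_equal(unname(lr_by_epoch["13"]), 1e-3)
  expect_equal(unname(lr_by_epoch["14"]), 1e-4)
  # the 10 -> 2 head-multiplier hand-off happens on completion
  expect_equal(r$model$head_lr_multiplier, 2)
  expect_error(stage1_train(m, list(), cfg), "empty")
})

test_that("stage 1 descends on a separable synthetic set", {
  samples <- oversample_minority(small_set(40L, seed = 2L, rho = 1), seed = 1L)
  m <- build_classifier(input_size = c(16L, 16L), seed = 0L)
  r <- stage1_train(m, samples, stage1_config(
    epochs = 5L, learning_rate = 0.02,
    augment = augment_config(enabled = FALSE), seed = 0L))
  per_epoch <- tapply(r$trace$loss, r$trace$epoch, mean)
  expect_lt(per_epoch[[5]], per_epoch[[1]])
})

test_that("a GAIN iteration reproduces the independently chained streams", {
  m <- oracle_cnn()
  s <- Filter(function(x) x$label == 1L, generate_worked_fixture())[[1L]]
  cfg <- stage2_config(learning_rate = 1e-3)
  res <- gain_iteration(m, s, config = cfg)
  b <- res$breakdown

  # chain the public operations outside the training loop
  cap <- capture_activations(m, s$image, "conv2")
  l_cl_ref <- classification_loss(cap$scores, s$label + 1L)
  wts <- neuron_importance(m, cap, s$label + 1L)
  amap <- attention_map(cap$activations, wts)
  up <- gaincam:::resize_bilinear_2d(amap$raw, m$input_size)
  a_norm <- (up - min(up)) / (max(up) - min(up) + 1e-3)
  tm <- soft_threshold(a_norm, cfg$mask_params)
  istar <- apply_softmask(s$image, tm)
  probs <- gaincam:::softmax(naive_forward_scores(m, istar))
  l_am_ref <- attention_mining_loss(probs, s$label + 1L)
  l_bbox_ref <- bbox_loss(a_norm, boxes_to_mask(s, m$input_size)$mask)

  expect_equal(b$l_cl, l_cl_ref, tolerance = 1e-6)
  expect_equal(b$l_am, l_am_ref, tolerance = 1e-6)
  expect_equal(b$l_bbox, l_bbox_ref, tolerance = 1e-6)
  expect_equal(b$l_total, 0.25 * l_cl_ref + 0.5 * l_am_ref + 360 * l_bbox_ref,
               tolerance = 1e-6)
  expect_equal(res$attention, a_norm, tolerance = 1e-9)
})

test_that("weights update exactly once per iteration, after all streams", {
  m <- oracle_cnn()
  s <- Filter(function(x) x$label == 1L, generate_worked_fixture())[[1L]]

  # the breakdown is computed from the pre-update weights
  res <- gain_iteration(m, s, config = stage2_config(learning_rate = 1e-2))
  cap <- capture_activations(m, s$image)
  expect_equal(res$breakdown$l_cl,
               classification_loss(cap$scores, s$label + 1L),
               tolerance = 1e-12)
  # ... and the returned model differs by one optimizer step
  expect_false(identical(res$model$params, m$params))

  # a vanishing learning rate leaves the parameters untouched
  res0 <- gain_iteration(m, s, config = stage2_config(learning_rate = 1e-30))
  for (nm in names(m$params)) {
    expect_equal(res0$model$params[[nm]], m$params[[nm]], tolerance = 1e-12)
  }

  # nonsuspicious samples are supervised against the all-zero mask
  neg <- Filter(function(x) x$label == 0L, generate_worked_fixture())[[1L]]
  resn <- gain_iteration(m, neg, config = stage2_config(learning_rate = 1e-3))
  expect_gte(resn$breakdown$l_bbox, 0)
  mask <- boxes_to_mask(neg, m$input_size)
  expect_true(all(mask$mask == 0))
})

test_that("stage 2 is a no-op at zero epochs and deterministic under a seed", {
  samples <- small_set(8L, seed = 3L, rho = 1)
  m <- oracle_cnn()
  r0 <- stage2_train(m, samples, stage2_config(epochs = 0L))
  expect_identical(r0$model$params, m$params)
  expect_equal(nrow(r0$trace), 0L)

  cfg <- stage2_config(epochs = 1L, learning_rate = 1e-3, seed = 11L)
  r1 <- stage2_train(m, samples, cfg)
  r2 <- stage2_train(m, samples, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$model$params, r2$model$params)
  expect_equal(nrow(r1$trace), length(samples))
  expect_true(all(c("l_cl", "l_am", "l_bbox", "l_total",
                    "w_cl", "w_am", "w_bbox") %in% names(r1$trace)))
})

test_that("a suspicious sample without boxes contributes zero box loss", {
  m <- oracle_cnn()
  s <- make_sample(1L, boxes = matrix(c(2, 2, 8, 8), 1L))
  s$boxes <- s$boxes[0, , drop = FALSE]
  s$bbox_supervised <- FALSE
  res <- gain_iteration(m, s, config = stage2_config(learning_rate = 1e-3))
  expect_equal(res$breakdown$l_bbox, 0)
})
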