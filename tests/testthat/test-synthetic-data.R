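test_that("class counts, boxes, and confounder placement follow the config", {
  cfg <- synth_config(n_images = 10L, image_size = c(32L, 32L),
                      positive_fraction = 0.4, seed = 1L)
  samples <- generate_dataset(cfg)
  labs <- sample_labels(samples)
  expect_equal(sum(labs == 1L), 4L)
  expect_equal(sum(labs == 0L), 6L)
  for (s in samples) {
    if (s$label == 1L) expect_gte(nrow(s$boxes), 1L)
    else expect_equal(nrow(s$boxes), 0L)
  }
})

test_that("rho = 1 couples the confounder exactly to the label", {
  cfg <- synth_config(n_images = 60L, image_size = c(32L, 32L),
                      confounder_correlation = 1, seed = 2L)
  samples <- generate_dataset(cfg)
  for (s in samples) {
    expect_identical(isTRUE(s$confounder), s$label == 1L)
  }
})

test_that("rho = 0.5 decouples the confounder from the label", {
  cfg <- synth_config(n_images = 400L, image_size = c(16L, 16L),
                      confounder_correlation = 0.5, seed = 3L)
  samples <- generate_dataset(cfg)
  labs <- sample_labels(samples)
  conf <- vapply(samples, function(s) as.integer(isTRUE(s$confounder)),
                 integer(1))
  r <- cor(labs, conf)
  expect_lt(abs(r), 3 / sqrt(length(labs)))
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- synth_config(n_images = 12L, image_size = c(16L, 16L), seed = 9L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(lapply(a, `[[`, "image"), lapply(b, `[[`, "image"))
  expect_identical(lapply(a, `[[`, "boxes"), lapply(b, `[[`, "boxes"))
})

test_that("the worked fixture is byte-stable and its boxes cover the blobs", {
  fx1 <- generate_worked_fixture()
  fx2 <- generate_worked_fixture()
  expect_identical(fx1, fx2)
  expect_length(fx1, 8L)
  expect_equal(dim(fx1[[1L]]$image), c(16L, 16L, 3L))

  lesion_col <- c(0.93, 0.90, 0.70)
  for (s in Filter(function(x) x$label == 1L, fx1)) {
    box <- boxes_to_mask(s)$mask
    dist <- sqrt((s$image[, , 1] - lesion_col[1])^2 +
                   (s$image[, , 2] - lesion_col[2])^2 +
                   (s$image[, , 3] - lesion_col[3])^2)
    lesion_px <- dist < 0.15
    expect_gt(sum(lesion_px), 0)
    expect_true(all(box[lesion_px] == 1))
  }
})

test_that("the confounder occupies pixels disjoint from every lesion box", {
  cfg <- synth_config(n_images = 40L, image_size = c(32L, 32L),
                      confounder_correlation = 1, seed = 4L)
  samples <- generate_dataset(cfg)
  bar_rows <- (32L - round(0.15 * 32) + 1L):32L
  for (s in Filter(function(x) x$label == 1L, samples)) {
    mask <- boxes_to_mask(s)$mask
    expect_true(all(mask[bar_rows, ] == 0))
  }
})

test_that("classes are separable from the lesion feature alone (rho = 0)", {
  cfg <- synth_config(n_images = 120L, confounder_correlation = 0, seed = 5L)
  samples <- generate_dataset(cfg)
  feats <- t(vapply(samples, function(s) {
    lum <- (s$image[, , 1] + s$image[, , 2] + s$image[, , 3]) / 3
    keep <- apply(s$image, c(1, 2), min) < 0.85  # drop the white bar
    c(q99 = unname(stats::quantile(lum[keep], 0.99)), mean = mean(lum[keep]))
  }, numeric(2)))
  labs <- sample_labels(samples)
  fit <- suppressWarnings(
    stats::glm(labs ~ feats[, 1] + feats[, 2], family = stats::binomial()))
  acc <- mean((stats::fitted(fit) > 0.5) == (labs == 1L))
  expect_gte(acc, 0.95)
})

test_that("degenerate geometry is rejected", {
  expect_error(synth_config(lesion = list(n_blobs = c(1L, 1L),
                                          radius_frac = c(0.4, 0.5),
                                          color = c(0.8, 0.6, 0.5),
                                          color_jitter = 0.01)),
               "radius_frac")
})

test_that("the textured-patch confounder variant renders at the top edge", {
  cfg <- synth_config(n_images = 6L, image_size = c(32L, 32L),
                      confounder_correlation = 1,
                      confounder = list(type = "patch", width_frac = 0.12,
                                        color = c(0.85, 0.8, 0.55)),
                      seed = 6L)
  samples <- generate_dataset(cfg)
  pos <- Filter(function(x) x$label == 1L, samples)[[1L]]
  neg <- Filter(function(x) x$label == 0L, samples)[[1L]]
  # patch occupies the first rows of positives only (rho = 1)
  expect_gt(mean(pos$image[1:3, 8:24, 2]), mean(neg$image[1:3, 8:24, 2]))
})
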