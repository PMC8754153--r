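collapsed_config <- function() {
  augment_config(rotation = c(0, 0), scale_x = c(1, 1), scale_y = c(1, 1),
                 reflect_x = FALSE, reflect_y = FALSE,
                 shear_x = c(0, 0), shear_y = c(0, 0),
                 translate_x = c(0, 0), translate_y = c(0, 0))
}

test_that("collapsed intervals give the identity and reproduce inputs exactly", {
  tf <- sample_transform(collapsed_config())
  expect_equal(tf$rotation, 0)
  expect_false(tf$reflect_x)
  set.seed(1)
  img <- array(runif(20 * 24 * 3), c(20, 24, 3))
  expect_identical(apply_transform(img, tf), img)
})

test_that("transform sampling is deterministic and respects the ranges", {
  cfg <- augment_config()
  set.seed(11)
  a <- sample_transform(cfg)
  set.seed(11)
  b <- sample_transform(cfg)
  expect_identical(a, b)

  set.seed(2)
  rot <- replicate(1e4, sample_transform(cfg)$rotation)
  expect_true(min(rot) >= -180 && max(rot) <= 180)
  # uniform on [-180, 180]: sd = 360/sqrt(12)
  se <- 360 / sqrt(12) / sqrt(length(rot))
  expect_lt(abs(mean(rot)), 3 * se)
})

test_that("translation fills the vacated band with the configured grey", {
  img <- array(0.6, c(32, 32, 3))
  tf <- collapsed_config() |> sample_transform()
  tf$translate_x <- 5
  out <- apply_transform(img, tf)
  expect_true(all(abs(out[, 1:5, ] - 128 / 255) < 1e-12))
  expect_true(all(abs(out[, 6:32, ] - 0.6) < 1e-12))
})

test_that("a 180-degree rotation is an involution under nearest neighbour", {
  set.seed(3)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  tf <- sample_transform(collapsed_config())
  tf$rotation <- 180
  once <- apply_transform(img, tf, interpolation = "nearest")
  twice <- apply_transform(once, tf, interpolation = "nearest")
  expect_equal(twice, img, tolerance = 1e-6)
})

test_that("warped outputs stay in [0,1] for random transforms", {
  cfg <- augment_config()
  set.seed(4)
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  for (i in 1:20) {
    out <- apply_transform(img, sample_transform(cfg))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("box mapping: identity, reflection arithmetic, corner containment", {
  boxes <- matrix(c(10, 20, 30, 40), 1L,
                  dimnames = list(NULL, c("x_min", "y_min", "x_max", "y_max")))
  tf <- sample_transform(collapsed_config())
  expect_equal(unname(transform_boxes(boxes, tf, c(100L, 100L))),
               unname(boxes))

  tf$reflect_x <- TRUE
  refl <- transform_boxes(matrix(c(10, 0, 30, 10), 1L), tf, c(100L, 100L))
  expect_equal(unname(refl[1, c(1, 3)]), c(70, 90))

  # mapped corners (computed with an independent formula) lie inside the box
  set.seed(5)
  for (i in 1:25) {
    tf <- sample_transform(augment_config())
    b <- c(8, 12, 28, 40)
    h <- 64; w <- 64
    th <- tf$rotation * pi / 180
    a <- diag(c(if (tf$reflect_x) -1 else 1, if (tf$reflect_y) -1 else 1)) %*%
      matrix(c(1, tf$shear_y / w, tf$shear_x / h, 1), 2) %*%
      diag(c(tf$scale_x, tf$scale_y)) %*%
      matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    corners <- rbind(c(b[1], b[2]), c(b[3], b[2]), c(b[1], b[4]), c(b[3], b[4]))
    mapped <- t(apply(corners, 1, function(p) {
      q <- a %*% c(p[1] - 0.5 - cx, p[2] - 0.5 - cy) +
        c(tf$translate_x, tf$translate_y)
      c(q[1] + cx + 0.5, q[2] + cy + 0.5)
    }))
    out <- transform_boxes(matrix(b, 1L), tf, c(h, w))
    if (nrow(out) == 1L) {
      expect_true(all(mapped[, 1] >= out[1, 1] - 1e-9 |
                        mapped[, 1] < 0 | mapped[, 1] > w))
      expect_lte(out[1, 1], max(min(mapped[, 1]), 0) + 1e-9)
      expect_gte(out[1, 3], min(max(mapped[, 1]), w) - 1e-9)
      expect_lte(out[1, 2], max(min(mapped[, 2]), 0) + 1e-9)
      expect_gte(out[1, 4], min(max(mapped[, 2]), h) - 1e-9)
      expect_true(out[1, 3] <= w && out[1, 4] <= h &&
                    out[1, 1] >= 0 && out[1, 2] >= 0)
    }
  }
})
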