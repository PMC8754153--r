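test_that("manifest rows aggregate into one sample per image with parsed labels", {
  dir <- withr::local_tempdir()
  png::writePNG(array(0.4, c(12, 12, 3)), file.path(dir, "a.png"))
  png::writePNG(array(0.6, c(12, 12, 3)), file.path(dir, "b.png"))
  df <- data.frame(
    image_path = c("a.png", "a.png", "b.png"),
    label = c("Suspicious", "SUSPICIOUS", "nonsuspicious"),
    x_min = c(1, 5, NA), y_min = c(1, 5, NA),
    x_max = c(4, 9, NA), y_max = c(4, 9, NA))
  write.csv(df, file.path(dir, "manifest.csv"), row.names = FALSE, na = "")
  samples <- load_manifest(file.path(dir, "manifest.csv"))
  expect_length(samples, 2L)
  labs <- sample_labels(samples)
  expect_equal(sort(labs), c(0L, 1L))
  pos <- samples[[which(labs == 1L)]]
  neg <- samples[[which(labs == 0L)]]
  expect_equal(nrow(pos$boxes), 2L)
  expect_equal(nrow(neg$boxes), 0L)
  expect_true(all(pos$image >= 0 & pos$image <= 1))
})

test_that("manifest validation: missing files, bad boxes, box-free positives", {
  dir <- withr::local_tempdir()
  expect_error(load_manifest(file.path(dir, "nope.csv")), "not found")

  png::writePNG(array(0.4, c(10, 10, 3)), file.path(dir, "a.png"))
  bad <- data.frame(image_path = "a.png", label = "suspicious",
                    x_min = 4, y_min = 4, x_max = 14, y_max = 8)
  write.csv(bad, file.path(dir, "m1.csv"), row.names = FALSE, na = "")
  expect_error(load_manifest(file.path(dir, "m1.csv")), "outside image bounds")

  orphan <- data.frame(image_path = "a.png", label = "suspicious",
                       x_min = NA, y_min = NA, x_max = NA, y_max = NA)
  write.csv(orphan, file.path(dir, "m2.csv"), row.names = FALSE, na = "")
  expect_warning(s <- load_manifest(file.path(dir, "m2.csv")),
                 "classification-only")
  expect_equal(s[[1L]]$label, 1L)
  expect_false(s[[1L]]$bbox_supervised)
})

test_that("write_manifest / load_manifest round-trips the worked fixture", {
  dir <- withr::local_tempdir()
  fx <- generate_worked_fixture(dir = dir)
  back <- load_manifest(attr(fx, "manifest"))
  expect_length(back, length(fx))
  expect_equal(sample_labels(back), sample_labels(fx))
  for (i in seq_along(fx)) {
    expect_equal(unname(back[[i]]$boxes), unname(fx[[i]]$boxes))
    expect_equal(back[[i]]$image, fx[[i]]$image, tolerance = 1 / 255)
  }
})

test_that("split is stratified, conserving, and deterministic", {
  samples <- make_sample_set(60, 40)
  sp <- split_dataset(samples, c(0.8, 0.1, 0.1), seed = 7L)
  expect_length(sp$train, 80L)
  expect_length(sp$validation, 10L)
  expect_length(sp$test, 10L)
  expect_equal(sum(sample_labels(sp$train) == 0L), 48L)
  expect_equal(sum(sample_labels(sp$validation) == 0L), 6L)
  expect_equal(sum(sample_labels(sp$test) == 0L), 6L)
  expect_equal(sum(sample_labels(sp$train) == 1L), 32L)

  ids <- function(x) vapply(x, function(s) s$image_id, character(1))
  all_ids <- c(ids(sp$train), ids(sp$validation), ids(sp$test))
  expect_setequal(all_ids, ids(samples))
  expect_equal(anyDuplicated(all_ids), 0L)

  sp2 <- split_dataset(samples, c(0.8, 0.1, 0.1), seed = 7L)
  expect_identical(ids(sp2$train), ids(sp$train))

  sp3 <- split_dataset(samples, c(1, 0, 0), seed = 1L)
  expect_length(sp3$train, 100L)
  expect_error(split_dataset(samples, c(0.8, 0.1, 0.2)), "sum to 1")
})

test_that("oversampling balances with minority duplicates only", {
  samples <- make_sample_set(10, 4)
  bal <- oversample_minority(samples, seed = 3L)
  labs <- sample_labels(bal)
  expect_equal(sum(labs == 0L), 10L)
  expect_equal(sum(labs == 1L), 10L)
  ids <- vapply(bal, function(s) s$image_id, character(1))
  added <- ids[15:20]
  expect_true(all(added %in% paste0("pos", 1:4)))
  expect_identical(ids[1:14], vapply(samples, function(s) s$image_id,
                                     character(1)))

  expect_identical(oversample_minority(make_sample_set(5, 5), 1L),
                   make_sample_set(5, 5))
  # symmetry: whichever class is smaller gets duplicated
  flipped <- make_sample_set(3, 9)
  bal2 <- oversample_minority(flipped, seed = 1L)
  expect_equal(as.integer(table(sample_labels(bal2))), c(9L, 9L))
  expect_error(oversample_minority(make_sample_set(5, 0)), "both classes")
})

test_that("box rasterisation matches per-pixel membership", {
  full <- make_sample(1L, boxes = matrix(c(0, 0, 16, 16), 1L))
  expect_true(all(boxes_to_mask(full)$mask == 1))
  expect_true(all(boxes_to_mask(make_sample(0L))$mask == 0))

  two <- make_sample(1L, boxes = rbind(c(1, 1, 5, 5), c(3, 3, 7, 6)),
                     size = 8L)
  m <- boxes_to_mask(two, c(8L, 8L))
  expect_equal(m$mask, naive_box_mask(two$boxes, c(8L, 8L)))
  expect_equal(sum(m$mask), sum(naive_box_mask(two$boxes, c(8L, 8L))))
  expect_true(all(m$mask %in% c(0, 1)))

  set.seed(42)
  for (rep in 1:50) {
    nb <- sample(1:3, 1)
    boxes <- t(replicate(nb, {
      x0 <- runif(1, 0, 12); y0 <- runif(1, 0, 12)
      c(x0, y0, x0 + runif(1, 0.5, 4), y0 + runif(1, 0.5, 4))
    }))
    s <- image_sample("r", array(0.5, c(16, 16, 3)), 1L, boxes)
    expect_equal(boxes_to_mask(s, c(16L, 16L))$mask,
                 naive_box_mask(boxes, c(16L, 16L)))
  }
})
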