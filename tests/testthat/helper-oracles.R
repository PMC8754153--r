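# Shared fixtures and independent oracles.
#
# oracle_cnn(): the fixed reference network used by the differentiation
# checks -- 2 conv layers, 3 channels, 16x16 input, seed-0 weights.
oracle_cnn <- function() {
  build_classifier("tiny", input_size = c(16L, 16L), channels = c(3L, 3L),
                   seed = 0L)
}

oracle_image <- function(seed = 0L, size = 16L) {
  set.seed(seed)
  array(runif(size * size * 3), c(size, size, 3L))
}

# independent direct convolution (triple loop, zero padding), used as the
# oracle against the im2col path
naive_conv2d <- function(x, kern, bias) {
  d <- dim(x)
  ko <- dim(kern)[4L]
  out <- array(0, c(d[1L], d[2L], ko))
  for (co in seq_len(ko)) {
    for (i in seq_len(d[1L])) {
      for (j in seq_len(d[2L])) {
        acc <- bias[co]
        for (ci in seq_len(d[3L])) {
          for (di in -1:1) {
            for (dj in -1:1) {
              ii <- i + di; jj <- j + dj
              if (ii >= 1 && ii <= d[1L] && jj >= 1 && jj <= d[2L]) {
                acc <- acc + x[ii, jj, ci] * kern[di + 2L, dj + 2L, ci, co]
              }
            }
          }
        }
        out[i, j, co] <- acc
      }
    }
  }
  out
}

# independent forward pass written with naive loops (no shared code with the
# package's im2col path beyond base R)
naive_forward_scores <- function(model, image) {
  p <- model$params
  z1 <- naive_conv2d(image - 0.5, p$W1, p$b1)
  f1 <- pmax(z1, 0)
  d <- dim(f1)
  pl <- array(0, c(d[1L] / 2L, d[2L] / 2L, d[3L]))
  for (i in seq_len(dim(pl)[1L])) {
    for (j in seq_len(dim(pl)[2L])) {
      pl[i, j, ] <- (f1[2 * i - 1, 2 * j - 1, ] + f1[2 * i, 2 * j - 1, ] +
                       f1[2 * i - 1, 2 * j, ] + f1[2 * i, 2 * j, ]) / 4
    }
  }
  z2 <- naive_conv2d(pl, p$W2, p$b2)
  f2 <- pmax(z2, 0)
  gap <- apply(f2, 3, mean)
  drop(p$Wh %*% gap) + p$bh
}

# score of class `cls` as a function of the activation stack at `layer`,
# pushing the perturbed activations through the remaining layers by loops
oracle_score_from_acts <- function(model, acts, layer, cls) {
  p <- model$params
  if (layer == "conv1") {
    d <- dim(acts)
    pl <- array(0, c(d[1L] / 2L, d[2L] / 2L, d[3L]))
    for (i in seq_len(dim(pl)[1L])) {
      for (j in seq_len(dim(pl)[2L])) {
        pl[i, j, ] <- (acts[2 * i - 1, 2 * j - 1, ] + acts[2 * i, 2 * j - 1, ] +
                         acts[2 * i - 1, 2 * j, ] + acts[2 * i, 2 * j, ]) / 4
      }
    }
    f2 <- pmax(naive_conv2d(pl, p$W2, p$b2), 0)
  } else {
    f2 <- acts
  }
  gap <- apply(f2, 3, mean)
  (drop(p$Wh %*% gap) + p$bh)[cls]
}

# central-finite-difference neuron importance: GAP of d s_c / d f at `layer`
fd_neuron_importance <- function(model, image, layer, cls, eps = 1e-4) {
  cap <- capture_activations(model, image, layer)
  acts <- cap$activations
  d <- dim(acts)
  grad <- array(0, d)
  for (q in seq_len(length(acts))) {
    ap <- acts; ap[q] <- ap[q] + eps
    am <- acts; am[q] <- am[q] - eps
    grad[q] <- (oracle_score_from_acts(model, ap, layer, cls) -
                  oracle_score_from_acts(model, am, layer, cls)) / (2 * eps)
  }
  apply(grad, 3, mean)
}

# brute-force box rasterisation by per-pixel membership (pixel centres)
naive_box_mask <- function(boxes, grid) {
  mask <- matrix(0, grid[1L], grid[2L])
  for (i in seq_len(grid[1L])) {
    for (j in seq_len(grid[2L])) {
      xc <- j - 0.5; yc <- i - 0.5
      for (b in seq_len(nrow(boxes))) {
        if (xc >= boxes[b, 1L] && xc < boxes[b, 3L] &&
            yc >= boxes[b, 2L] && yc < boxes[b, 4L]) {
          mask[i, j] <- 1
        }
      }
    }
  }
  mask
}

make_sample <- function(label, boxes = NULL, size = 16L, id = "s1") {
  image_sample(id, array(0.5, c(size, size, 3L)), label, boxes)
}

# small labelled set without images on disk
make_sample_set <- function(n_neg, n_pos, size = 16L) {
  c(
    lapply(seq_len(n_neg), function(i) make_sample(0L, size = size,
                                                   id = paste0("neg", i))),
    lapply(seq_len(n_pos), function(i) {
      make_sample(1L, boxes = matrix(c(2, 2, 8, 8), 1L), size = size,
                  id = paste0("pos", i))
    })
  )
}
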