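# ---------------------------------------------------------------------------
# Numeric array primitives
#
# All tensors are plain R arrays: images are H x W x 3 in [0,1], feature
# stacks are h x w x K, kernels are k x k x Cin x Cout.  Convolutions are
# 3x3, stride 1, zero-padded ("same").  These functions carry no gradient
# bookkeeping; the tape ops below wrap them.
# ---------------------------------------------------------------------------

.gc_cache <- new.env(parent = emptyenv())

# gather-index matrix for im2col: rows ordered by output pixel (row-major in
# R's column-major sense: i fastest), columns by (ki, kj, channel) matching
# the storage order of a k x k x Cin x Cout kernel array.
im2col_idx <- function(h, w, cin, k = 3L, pad = 1L) {
  key <- paste("i2c", h, w, cin, k, pad, sep = "_")
  hit <- .gc_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L * pad
  wp <- w + 2L * pad
  oi <- rep(seq_len(h), times = w)
  oj <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, k * k * cin)
  q <- 0L
  for (c in seq_len(cin)) {
    for (dj in 0L:(k - 1L)) {
      for (di in 0L:(k - 1L)) {
        q <- q + 1L
        idx[, q] <- (oi + di) + (oj + dj - 1L) * hp + (c - 1L) * hp * wp
      }
    }
  }
  .gc_cache[[key]] <- idx
  idx
}

conv2d_fw <- function(x, kern, bias, return_cols = FALSE) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]; cin <- d[3L]
  k <- dim(kern)[1L]
  cout <- dim(kern)[4L]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, c(h + 2L * pad, w + 2L * pad, cin))
  xp[(pad + 1L):(pad + h), (pad + 1L):(pad + w), ] <- x
  idx <- im2col_idx(h, w, cin, k, pad)
  cols <- matrix(xp[idx], h * w, ncol(idx))
  y <- cols %*% matrix(kern, ncol = cout)
  y <- y + rep(bias, each = h * w)
  out <- array(y, c(h, w, cout))
  if (return_cols) list(y = out, cols = cols) else out
}

# gradient of conv2d w.r.t. its input: convolution of the output gradient
# with the spatially flipped kernel, input/output channels swapped.
conv2d_bw_input <- function(dy, kern) {
  k <- dim(kern)[1L]
  kf <- aperm(kern[k:1L, k:1L, , , drop = FALSE], c(1L, 2L, 4L, 3L))
  conv2d_fw(dy, kf, numeric(dim(kf)[4L]))
}

conv2d_bw_kernel <- function(cols, dy, kdim) {
  dym <- matrix(dy, nrow(cols), kdim[4L])
  list(dk = array(crossprod(cols, dym), kdim), db = colSums(dym))
}

avgpool2_fw <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1L], by = 2L); e1 <- o1 + 1L
  o2 <- seq(1L, d[2L], by = 2L); e2 <- o2 + 1L
  (x[o1, o2, , drop = FALSE] + x[e1, o2, , drop = FALSE] +
     x[o1, e2, , drop = FALSE] + x[e1, e2, , drop = FALSE]) / 4
}

avgpool2_bw <- function(dy, in_dim) {
  dx <- array(0, in_dim)
  d <- dim(dy)
  o1 <- seq(1L, in_dim[1L], by = 2L); e1 <- o1 + 1L
  o2 <- seq(1L, in_dim[2L], by = 2L); e2 <- o2 + 1L
  g <- dy / 4
  dx[o1, o2, ] <- g; dx[e1, o2, ] <- g
  dx[o1, e2, ] <- g; dx[e1, e2, ] <- g
  dx
}

# interpolation matrix mapping a length-n axis onto length-m, pixel-centre
# (half-pixel) convention, clamped at the borders
bilin_matrix <- function(n_out, n_in) {
  key <- paste("bl", n_out, n_in, sep = "_")
  hit <- .gc_cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  s <- pmin(pmax(s, 0), n_in - 1)
  lo <- pmin(floor(s), n_in - 2)
  fr <- s - lo
  m <- matrix(0, n_out, n_in)
  m[cbind(seq_len(n_out), lo + 1)] <- 1 - fr
  m[cbind(seq_len(n_out), lo + 2)] <- m[cbind(seq_len(n_out), lo + 2)] + fr
  .gc_cache[[key]] <- m
  m
}

resize_bilinear_2d <- function(a, target) {
  d <- dim(a)
  if (d[1L] == target[1L] && d[2L] == target[2L]) return(a)
  ry <- bilin_matrix(target[1L], d[1L])
  rx <- bilin_matrix(target[2L], d[2L])
  ry %*% a %*% t(rx)
}

#' Resize an RGB image with bilinear interpolation
#'
#' @param image numeric `H x W x 3` array with values in `[0, 1]`.
#' @param target integer vector `(H, W)` of the output size.
#' @return resized `target[1] x target[2] x 3` array.
#' @export
resize_image <- function(image, target) {
  d <- dim(image)
  if (d[1L] == target[1L] && d[2L] == target[2L]) return(image)
  out <- array(0, c(target[1L], target[2L], d[3L]))
  for (ch in seq_len(d[3L])) {
    out[, , ch] <- resize_bilinear_2d(image[, , ch], target)
  }
  out
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# ---------------------------------------------------------------------------
# Reverse-mode tape
#
# A node is an environment holding a value, its parents, and a backward
# closure mapping the node's upstream gradient to gradients for each parent.
# `tape_backward()` walks the graph once in reverse topological order, so a
# loss that is itself a function of an attention map (which already embeds
# the head-weight gradient analytically) differentiates in one pass.
# ---------------------------------------------------------------------------

tn_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$requires <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$requires, logical(1)))
  class(e) <- "gc_tnode"
  e
}

tn_leaf <- function(value, requires = FALSE) {
  e <- tn_node(value)
  e$requires <- requires
  e
}

tn_value <- function(x) if (inherits(x, "gc_tnode")) x$value else x

topo_order <- function(root) {
  out <- vector("list", 64L)
  n_out <- 0L
  stack <- list(list(node = root, i = 0L))
  token <- .gc_cache$topo_token <- (if (is.null(.gc_cache$topo_token)) 0L else .gc_cache$topo_token) + 1L
  root$.mark <- token
  while (length(stack)) {
    top <- stack[[length(stack)]]
    node <- top$node
    if (top$i < length(node$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      child <- node$parents[[top$i + 1L]]
      if (is.null(child$.mark) || child$.mark != token) {
        child$.mark <- token
        if (child$requires || length(child$parents) == 0L) {
          stack[[length(stack) + 1L]] <- list(node = child, i = 0L)
        }
      }
    } else {
      stack[[length(stack)]] <- NULL
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- node
    }
  }
  out[seq_len(n_out)]
}

tape_backward <- function(root) {
  ord <- topo_order(root)
  for (n in ord) n$grad <- NULL
  root$grad <- if (length(root$value) == 1L) 1 else array(1, dim(root$value))
  for (n in rev(ord)) {
    if (is.null(n$backfn) || is.null(n$grad) || !n$requires) next
    gs <- n$backfn(n$grad, n)
    ps <- n$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      g <- gs[[i]]
      if (is.null(g) || !p$requires) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# --- tape ops ---------------------------------------------------------------

op_conv2d <- function(x, kern, bias) {
  fw <- conv2d_fw(tn_value(x), tn_value(kern), tn_value(bias), return_cols = TRUE)
  n <- tn_node(fw$y, list(x, kern, bias), function(g, node) {
    kd <- dim(tn_value(kern))
    kb <- conv2d_bw_kernel(node$cols, g, kd)
    dx <- if (node$parents[[1L]]$requires) conv2d_bw_input(g, tn_value(kern)) else NULL
    list(dx, kb$dk, kb$db)
  })
  n$cols <- fw$cols
  n
}

op_add_const <- function(x, k) {
  tn_node(tn_value(x) + k, list(x), function(g, node) list(g))
}

op_relu <- function(x) {
  v <- tn_value(x)
  mask <- v > 0
  tn_node(v * mask, list(x), function(g, node) list(g * mask))
}

op_avgpool2 <- function(x) {
  in_dim <- dim(tn_value(x))
  tn_node(avgpool2_fw(tn_value(x)), list(x),
          function(g, node) list(avgpool2_bw(g, in_dim)))
}

op_gap <- function(x) {
  v <- tn_value(x)
  d <- dim(v)
  npix <- d[1L] * d[2L]
  tn_node(colMeans(matrix(v, npix, d[3L])), list(x), function(g, node) {
    list(array(rep(g / npix, each = npix), d))
  })
}

op_linear <- function(v, wt, bias) {
  vv <- tn_value(v)
  y <- drop(tn_value(wt) %*% vv) + tn_value(bias)
  tn_node(y, list(v, wt, bias), function(g, node) {
    list(drop(crossprod(tn_value(wt), g)), outer(g, vv), g)
  })
}

op_softmax_ce <- function(scores, label_index) {
  p <- softmax(tn_value(scores))
  n <- tn_node(-log(max(p[label_index], 1e-12)), list(scores), function(g, node) {
    d <- p
    d[label_index] <- d[label_index] - 1
    list(g * d)
  })
  n$probs <- p
  n
}

op_softmax_pick <- function(scores, class_index) {
  p <- softmax(tn_value(scores))
  tn_node(p[class_index], list(scores), function(g, node) {
    ind <- numeric(length(p))
    ind[class_index] <- 1
    list(g * p[class_index] * (ind - p))
  })
}

# row of a weight matrix scaled by a constant; the analytic Grad-CAM neuron
# importance for a GAP + linear head (d s_c / d f_k = W[c,k] / npix)
op_row_scale <- function(wt, row, scale) {
  wv <- tn_value(wt)
  tn_node(wv[row, ] * scale, list(wt), function(g, node) {
    dw <- matrix(0, nrow(wv), ncol(wv))
    dw[row, ] <- g * scale
    list(dw)
  })
}

op_chan_wsum <- function(f, wv) {
  fv <- tn_value(f)
  d <- dim(fv)
  fm <- matrix(fv, d[1L] * d[2L], d[3L])
  val <- matrix(fm %*% tn_value(wv), d[1L], d[2L])
  tn_node(val, list(f, wv), function(g, node) {
    gv <- as.vector(g)
    list(array(outer(gv, tn_value(wv)), d), drop(crossprod(fm, gv)))
  })
}

op_upsample_bilin <- function(a, target) {
  v <- tn_value(a)
  ry <- bilin_matrix(target[1L], nrow(v))
  rx <- bilin_matrix(target[2L], ncol(v))
  tn_node(ry %*% v %*% t(rx), list(a), function(g, node) {
    list(crossprod(ry, g) %*% rx)
  })
}

# min-max normalisation to [0,1]; an identically-zero map stays zero and a
# constant positive map maps to all ones.  The minimum carries gradient only
# when it is strictly positive: downstream of a ReLU the minimum is clamped
# at 0 and locally constant, which is what finite differences see.
op_minmax <- function(a, eps = 1e-3) {
  v <- tn_value(a)
  mn <- min(v)
  r <- max(v) - mn + eps
  imax <- which.max(v)
  imin <- which.min(v)
  val <- (v - mn) / r
  tn_node(val, list(a), function(g, node) {
    da <- g / r
    s2 <- sum(g * val) / r
    da[imax] <- da[imax] - s2
    if (mn > 0) da[imin] <- da[imin] - sum(g) / r + s2
    list(da)
  })
}

op_sigmoid_shift <- function(a, sigma, sharpness) {
  tv <- 1 / (1 + exp(-sharpness * (tn_value(a) - sigma)))
  tn_node(tv, list(a), function(g, node) list(g * sharpness * tv * (1 - tv)))
}

# I* = I (1 - T); the image is a constant, gradient flows to the mask only
op_soft_erase <- function(image, tmask) {
  iv <- tn_value(image)
  tv <- tn_value(tmask)
  d <- dim(iv)
  out <- iv * array(rep(1 - tv, d[3L]), d)
  tn_node(out, list(image, tmask), function(g, node) {
    ig <- iv * g
    list(NULL, -(ig[, , 1L] + ig[, , 2L] + ig[, , 3L]))
  })
}

op_mse_vs <- function(a, target) {
  v <- tn_value(a)
  diff <- v - target
  tn_node(mean(diff^2), list(a), function(g, node) {
    list(g * 2 * diff / length(diff))
  })
}

# |0.5 - p|, the chance-level attention-mining penalty
op_abs_half <- function(p) {
  v <- tn_value(p)
  tn_node(abs(0.5 - v), list(p), function(g, node) {
    list(g * (-sign(0.5 - v)))
  })
}

op_wsum3 <- function(a, b, c, wa, wb, wc) {
  tn_node(wa * tn_value(a) + wb * tn_value(b) + wc * tn_value(c),
          list(a, b, c), function(g, node) list(g * wa, g * wb, g * wc))
}
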