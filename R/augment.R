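# ---------------------------------------------------------------------------
# Stage-1 stochastic affine augmentation
#
# Each training iteration draws one affine transform -- rotation, anisotropic
# scaling, shearing, reflection, translation, composed in that order about
# the image centre -- with every parameter uniform over its configured range,
# and warps the image by inverse mapping, filling uncovered pixels with a
# constant grey.  Shear ranges are given in pixels of lateral displacement
# at the far image edge and converted to a shear coefficient at apply time,
# so the printed range means the same thing at any resolution.
# ---------------------------------------------------------------------------

#' Augmentation policy configuration
#'
#' Defaults are the stage-1 training policy: rotations over the full circle,
#' scale factors in `[0.75, 1.5]`, both reflections enabled (each applied
#' with probability 0.5), shear up to 20 px of edge displacement,
#' translations up to 5 px, and grey `[128,128,128]` fill.
#'
#' @param rotation,scale_x,scale_y,shear_x,shear_y,translate_x,translate_y
#'   numeric `(lower, upper)` sampling intervals.
#' @param reflect_x,reflect_y logical; when `TRUE` the axis is flipped with
#'   probability 0.5 per draw.
#' @param fill_rgb integer RGB triple in `[0,255]` used for uncovered pixels.
#' @param enabled master switch; when `FALSE`, [sample_transform()] always
#'   returns the identity.
#' @return an `augment_config` list.
#' @export
augment_config <- function(rotation = c(-180, 180),
                           scale_x = c(0.75, 1.5), scale_y = c(0.75, 1.5),
                           reflect_x = TRUE, reflect_y = TRUE,
                           shear_x = c(-20, 20), shear_y = c(-20, 20),
                           translate_x = c(-5, 5), translate_y = c(-5, 5),
                           fill_rgb = c(128, 128, 128), enabled = TRUE) {
  ivals <- list(rotation = rotation, scale_x = scale_x, scale_y = scale_y,
                shear_x = shear_x, shear_y = shear_y,
                translate_x = translate_x, translate_y = translate_y)
  for (nm in names(ivals)) {
    v <- ivals[[nm]]
    if (length(v) != 2L || v[1L] > v[2L]) {
      stop("augment interval '", nm, "' must be (lower <= upper)",
           call. = FALSE)
    }
  }
  stopifnot(length(fill_rgb) == 3L, all(fill_rgb >= 0), all(fill_rgb <= 255))
  structure(c(ivals, list(reflect_x = isTRUE(reflect_x),
                          reflect_y = isTRUE(reflect_y),
                          fill_rgb = fill_rgb, enabled = isTRUE(enabled))),
            class = "augment_config")
}

identity_transform <- function() {
  structure(list(rotation = 0, scale_x = 1, scale_y = 1,
                 reflect_x = FALSE, reflect_y = FALSE,
                 shear_x = 0, shear_y = 0,
                 translate_x = 0, translate_y = 0),
            class = "affine_transform")
}

#' Draw one random affine transform
#'
#' Every parameter is sampled uniformly from its interval; reflections are
#' applied with probability 0.5 when enabled. Deterministic for a fixed RNG
#' state.
#'
#' @param config an [augment_config()].
#' @return an `affine_transform` parameter list.
#' @export
sample_transform <- function(config = augment_config()) {
  if (!config$enabled) return(identity_transform())
  u <- function(iv) stats::runif(1L, iv[1L], iv[2L])
  structure(list(
    rotation = u(config$rotation),
    scale_x = u(config$scale_x),
    scale_y = u(config$scale_y),
    reflect_x = config$reflect_x && stats::runif(1L) < 0.5,
    reflect_y = config$reflect_y && stats::runif(1L) < 0.5,
    shear_x = u(config$shear_x),
    shear_y = u(config$shear_y),
    translate_x = u(config$translate_x),
    translate_y = u(config$translate_y)
  ), class = "affine_transform")
}

# forward affine pieces in centred pixel-index coordinates (x = column);
# composition order: rotate -> scale -> shear -> reflect -> translate
transform_linear <- function(tf, h, w) {
  th <- tf$rotation * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  sc <- diag(c(tf$scale_x, tf$scale_y))
  sh <- matrix(c(1, tf$shear_y / w, tf$shear_x / h, 1), 2L, 2L)
  rf <- diag(c(if (tf$reflect_x) -1 else 1, if (tf$reflect_y) -1 else 1))
  list(a = rf %*% sh %*% sc %*% rot,
       t = c(tf$translate_x, tf$translate_y))
}

#' Warp an image by an affine transform
#'
#' Inverse-mapping warp about the image centre: each output pixel samples the
#' source location that the transform maps onto it; source locations outside
#' the image are filled with `fill_rgb / 255`.
#'
#' @param image `H x W x 3` array in `[0,1]`.
#' @param transform an `affine_transform` from [sample_transform()].
#' @param fill_rgb RGB fill triple in `[0,255]`.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return warped array of the same shape, values in `[0,1]`.
#' @export
apply_transform <- function(image, transform, fill_rgb = c(128, 128, 128),
                            interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(image)
  h <- d[1L]; w <- d[2L]
  lin <- transform_linear(transform, h, w)
  ainv <- solve(lin$a)
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  qx <- rep(seq_len(w) - 1, each = h) - cx
  qy <- rep(seq_len(h) - 1, times = w) - cy
  px <- ainv[1L, 1L] * (qx - lin$t[1L]) + ainv[1L, 2L] * (qy - lin$t[2L]) + cx
  py <- ainv[2L, 1L] * (qx - lin$t[1L]) + ainv[2L, 2L] * (qy - lin$t[2L]) + cy
  fill <- fill_rgb / 255
  out <- array(0, d)
  if (interpolation == "nearest") {
    sx <- round(px); sy <- round(py)
    ok <- sx >= 0 & sx <= w - 1 & sy >= 0 & sy <= h - 1
    idx <- (sy + 1) + sx * h
    for (ch in seq_len(d[3L])) {
      plane <- image[, , ch]
      v <- rep(fill[ch], h * w)
      v[ok] <- plane[idx[ok]]
      out[, , ch] <- v
    }
  } else {
    ok <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
    x0 <- pmin(floor(px), w - 2); y0 <- pmin(floor(py), h - 2)
    x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
    fx <- px - x0; fy <- py - y0
    i00 <- (y0 + 1) + x0 * h
    for (ch in seq_len(d[3L])) {
      plane <- image[, , ch]
      v00 <- plane[i00]; v10 <- plane[i00 + h]
      v01 <- plane[i00 + 1]; v11 <- plane[i00 + h + 1]
      vb <- (1 - fy) * ((1 - fx) * v00 + fx * v10) +
        fy * ((1 - fx) * v01 + fx * v11)
      v <- rep(fill[ch], h * w)
      v[ok] <- vb[ok]
      out[, , ch] <- v
    }
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Map bounding boxes through an affine transform
#'
#' Each box's corners are mapped through the forward transform and
#' re-enclosed by their axis-aligned bounding box, clipped to the image;
#' boxes mapped fully outside are dropped.
#'
#' @param boxes numeric matrix with columns `x_min,y_min,x_max,y_max`.
#' @param transform an `affine_transform`.
#' @param size integer `(H, W)` of the image.
#' @return transformed box matrix (possibly fewer rows).
#' @export
transform_boxes <- function(boxes, transform, size) {
  if (nrow(boxes) == 0L) return(boxes)
  h <- size[1L]; w <- size[2L]
  lin <- transform_linear(transform, h, w)
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  out <- matrix(NA_real_, 0L, 4L,
                dimnames = list(NULL, c("x_min", "y_min", "x_max", "y_max")))
  for (b in seq_len(nrow(boxes))) {
    xs <- c(boxes[b, 1L], boxes[b, 3L], boxes[b, 1L], boxes[b, 3L])
    ys <- c(boxes[b, 2L], boxes[b, 2L], boxes[b, 4L], boxes[b, 4L])
    # box coords are edge coordinates: pixel-index coord = edge coord - 0.5
    px <- xs - 0.5 - cx
    py <- ys - 0.5 - cy
    mx <- lin$a[1L, 1L] * px + lin$a[1L, 2L] * py + lin$t[1L] + cx + 0.5
    my <- lin$a[2L, 1L] * px + lin$a[2L, 2L] * py + lin$t[2L] + cy + 0.5
    nb <- c(max(min(mx), 0), max(min(my), 0), min(max(mx), w), min(max(my), h))
    if (nb[1L] < nb[3L] && nb[2L] < nb[4L]) out <- rbind(out, nb)
  }
  rownames(out) <- NULL
  out
}
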