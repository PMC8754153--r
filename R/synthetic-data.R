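# ---------------------------------------------------------------------------
# Synthetic lesion-image generator
#
# Emulates the statistical structure of a clinical oral-screening set at desk
# scale: two classes with the suspicious class in the minority, lesion-like
# irregular blobs with tight bounding boxes, and -- crucially -- a
# label-correlated confounding object (a straight "tongue-depressor" bar at
# the image edge, or a textured "stained-teeth" patch) occupying pixels
# disjoint from every lesion box.  The default palette makes the confounder
# the *easy* feature (large, bright, fixed position) and the lesion the
# subtle one (a patch a shade lighter than the mucosa-toned background), so
# with confounder correlation rho = 1 a label-only classifier prefers the
# bar -- the failure mode the attention-guidance experiment then measures
# and repairs.
# ---------------------------------------------------------------------------

#' Synthetic dataset configuration
#'
#' @param n_images number of images.
#' @param image_size integer `(H, W)`; square 64 px by default.
#' @param positive_fraction fraction of suspicious images (default 0.4,
#'   mirroring a minority-positive clinical imbalance).
#' @param lesion list: `n_blobs` range, `radius_frac` range (blob radius as a
#'   fraction of the short image side), `color` RGB centre, `color_jitter`.
#' @param background list: `color` RGB, `noise_sd`.
#' @param confounder_correlation probability that a suspicious image carries
#'   the confounder and a nonsuspicious one does not; 0.5 makes the
#'   confounder label-independent, 1 makes it a perfect label proxy.
#' @param confounder list: `type` (`"bar"` or `"patch"`), `width_frac`,
#'   `color`.
#' @param seed integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_images = 200L, image_size = c(64L, 64L),
                         positive_fraction = 0.4,
                         lesion = list(n_blobs = c(1L, 2L),
                                       radius_frac = c(0.13, 0.21),
                                       color = c(0.78, 0.55, 0.52),
                                       color_jitter = 0.03),
                         background = list(color = c(0.55, 0.33, 0.35),
                                           noise_sd = 0.04),
                         confounder_correlation = 0.8,
                         confounder = list(type = "bar", width_frac = 0.15,
                                           color = c(0.98, 0.98, 0.96)),
                         seed = 0L) {
  stopifnot(n_images >= 2L, positive_fraction > 0, positive_fraction < 1,
            confounder_correlation >= 0, confounder_correlation <= 1)
  if (max(lesion$radius_frac) > 0.35) {
    stop("lesion radius_frac too large: blobs would not fit the image",
         call. = FALSE)
  }
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 positive_fraction = positive_fraction,
                 lesion = lesion, background = background,
                 confounder_correlation = confounder_correlation,
                 confounder = confounder, seed = as.integer(seed)),
            class = "synth_config")
}

# rasterise one irregular blob; returns a logical membership matrix
draw_blob <- function(h, w, cx, cy, a, b, theta, wobble_k, wobble_phi,
                      wobble_amp = 0.22) {
  xs <- rep(seq_len(w) - 1, each = h) - cx
  ys <- rep(seq_len(h) - 1, times = w) - cy
  xr <- cos(theta) * xs + sin(theta) * ys
  yr <- -sin(theta) * xs + cos(theta) * ys
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  ang <- atan2(yr / b, xr / a)
  member <- rho <= 1 + wobble_amp * sin(wobble_k * ang + wobble_phi)
  matrix(member, h, w)
}

confounder_region <- function(cfg) {
  h <- cfg$image_size[1L]; w <- cfg$image_size[2L]
  wd <- max(2L, round(cfg$confounder$width_frac * h))
  if (identical(cfg$confounder$type, "patch")) {
    list(rows = seq_len(wd), cols = seq(max(1L, round(w * 0.25)),
                                        round(w * 0.75)))
  } else {
    list(rows = (h - wd + 1L):h, cols = seq_len(w))
  }
}

paint_confounder <- function(img, cfg) {
  reg <- confounder_region(cfg)
  col <- cfg$confounder$color
  textured <- identical(cfg$confounder$type, "patch")
  for (ch in 1:3) {
    block <- matrix(col[ch], length(reg$rows), length(reg$cols))
    if (textured) {
      stripes <- 0.12 * sin(2 * pi * (seq_along(reg$cols)) / 4)
      block <- block + matrix(stripes, length(reg$rows), length(reg$cols),
                              byrow = TRUE)
    }
    img[reg$rows, reg$cols, ch] <- pmin(pmax(block, 0), 1)
  }
  img
}

synth_one_image <- function(cfg, label, with_confounder) {
  h <- cfg$image_size[1L]; w <- cfg$image_size[2L]
  bg <- cfg$background
  img <- array(rep(bg$color, each = h * w), c(h, w, 3L)) +
    array(stats::rnorm(h * w * 3L, sd = bg$noise_sd), c(h, w, 3L))
  img <- pmin(pmax(img, 0), 1)
  boxes <- matrix(numeric(0), 0L, 4L)
  if (label == 1L) {
    reg <- confounder_region(cfg)
    # keep blobs (and hence boxes) off the confounder's rows
    free_rows <- setdiff(seq_len(h), reg$rows)
    nb <- sample(seq(cfg$lesion$n_blobs[1L], cfg$lesion$n_blobs[2L]), 1L)
    rmin <- cfg$lesion$radius_frac[1L] * min(h, w)
    rmax <- cfg$lesion$radius_frac[2L] * min(h, w)
    for (i in seq_len(nb)) {
      member <- matrix(FALSE, h, w)
      for (attempt in 1:20) {
        a <- stats::runif(1L, rmin, rmax)
        b <- stats::runif(1L, rmin, rmax)
        margin <- max(a, b) * 1.25
        lo_y <- min(free_rows) - 1 + margin
        hi_y <- max(free_rows) - 1 - margin
        if (hi_y <= lo_y) next
        cx <- stats::runif(1L, margin, w - 1 - margin)
        cy <- stats::runif(1L, lo_y, hi_y)
        member <- draw_blob(h, w, cx, cy, a, b,
                            theta = stats::runif(1L, 0, pi),
                            wobble_k = sample(3:6, 1L),
                            wobble_phi = stats::runif(1L, 0, 2 * pi))
        member[reg$rows, ] <- FALSE
        if (sum(member) >= 4L) break
      }
      if (sum(member) < 4L) {
        stop("degenerate blob geometry: lesion does not fit the image",
             call. = FALSE)
      }
      col <- pmin(pmax(cfg$lesion$color +
                         stats::rnorm(3L, sd = cfg$lesion$color_jitter), 0), 1)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[member] <- col[ch]
        img[, , ch] <- plane
      }
      ridx <- which(rowSums(member) > 0)
      cidx <- which(colSums(member) > 0)
      boxes <- rbind(boxes, c(min(cidx) - 1, min(ridx) - 1, max(cidx), max(ridx)))
    }
  }
  if (with_confounder) img <- paint_confounder(img, cfg)
  list(image = img, boxes = boxes)
}

#' Generate a synthetic labeled dataset
#'
#' Deterministic for a fixed seed. Suspicious images carry lesion blobs with
#' tight boxes; the confounder co-occurs with the label according to
#' `confounder_correlation`.
#'
#' @param config a [synth_config()].
#' @param dir optional directory; when given, images and a manifest CSV are
#'   written there via [write_manifest()] and the manifest path is attached
#'   as attribute `"manifest"`.
#' @return list of [image_sample()] objects.
#' @export
generate_dataset <- function(config = synth_config(), dir = NULL) {
  n <- config$n_images
  n_pos <- round(config$positive_fraction * n)
  rho <- config$confounder_correlation
  samples <- with_seed(config$seed, {
    labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    lapply(seq_len(n), function(i) {
      lab <- labels[i]
      conf <- if (lab == 1L) stats::runif(1L) < rho else stats::runif(1L) >= rho
      one <- synth_one_image(config, lab, conf)
      s <- image_sample(sprintf("synth_%04d", i), one$image, lab, one$boxes)
      s$confounder <- conf
      s
    })
  })
  if (!is.null(dir)) {
    attr(samples, "manifest") <- write_manifest(samples, dir)
  }
  samples
}

#' Generate the small worked fixture
#'
#' Eight 16 x 16 images (3 suspicious with hand-checkable boxes, 5
#' nonsuspicious) produced under a fixed internal seed, byte-stable across
#' runs. Used by the unit tests of the I/O, attention and loss modules.
#'
#' @param dir optional directory to write the images + manifest into.
#' @return list of [image_sample()] objects.
#' @export
generate_worked_fixture <- function(dir = NULL) {
  cfg <- synth_config(n_images = 8L, image_size = c(16L, 16L),
                      positive_fraction = 0.375,
                      lesion = list(n_blobs = c(1L, 1L),
                                    radius_frac = c(0.15, 0.20),
                                    color = c(0.93, 0.90, 0.70),
                                    color_jitter = 0.02),
                      background = list(color = c(0.55, 0.33, 0.35),
                                        noise_sd = 0.02),
                      confounder_correlation = 1,
                      confounder = list(type = "bar", width_frac = 0.15,
                                        color = c(0.45, 0.30, 0.15)),
                      seed = 123L)
  generate_dataset(cfg, dir = dir)
}
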