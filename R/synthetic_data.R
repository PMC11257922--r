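# Synthetic tomato-ripeness scene generator. Emulates the statistical
# structure of outdoor smartphone captures: several fruits per image with
# class-dependent coloration (five ripeness classes separable by hue), leaf
# occluders, lighting variation, and the standard augmentations (mean blur
# 5-15, random crop 40-80 %, random rotation +-60 deg) with every output
# resized to a common square size. Fruits are rendered as shaded ellipses
# with a radial gradient and specular highlight; leaves as green elliptical
# blobs — a cheap, controllable analogue of occlusion and lighting, not
# photo-realism.

#' The five ripeness classes
#'
#' Class ids are 0-based in the fixed order unripe, half_ripe, ripe,
#' overripe, rotten. Hue ranges (fractions of the color wheel) are disjoint
#' so the generated class is recoverable from the rendered fruit hue;
#' `spot_rate` is the expected number of dark blemishes (rotten only).
#'
#' @return data.frame with columns id, name, hue_min, hue_max (mod 1),
#'   sat_min, sat_max, val_min, val_max, spot_rate.
#' @export
ripeness_classes <- function() {
  data.frame(
    id = 0:4,
    name = c("unripe", "half_ripe", "ripe", "overripe", "rotten"),
    hue_min = c(0.26, 0.09, 0.97, 0.89, 0.05),
    hue_max = c(0.34, 0.16, 1.03, 0.945, 0.085),
    sat_min = c(0.55, 0.60, 0.70, 0.55, 0.40),
    sat_max = c(0.85, 0.90, 0.95, 0.80, 0.70),
    val_min = c(0.50, 0.55, 0.50, 0.30, 0.20),
    val_max = c(0.75, 0.80, 0.75, 0.50, 0.40),
    spot_rate = c(0, 0, 0, 0, 4),
    stringsAsFactors = FALSE
  )
}

#' Scene specification
#'
#' @param image_size square image side in pixels.
#' @param n_fruits number of fruits to place (>= 1).
#' @param occlusion_prob per-fruit probability of a leaf occluder.
#' @param lighting `"sun"`, `"shade"` or `"overcast"` (value-channel
#'   multipliers 1.15 / 0.70 / 0.95).
#' @param seed RNG seed; the scene is a pure function of (spec, classes).
#' @param class_ids optional fixed class id per fruit (recycled).
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 640L, n_fruits = 6L, occlusion_prob = 0.3,
                       lighting = c("sun", "shade", "overcast"), seed = 1L,
                       class_ids = NULL) {
  lighting <- match.arg(lighting)
  stopifnot(n_fruits >= 1, occlusion_prob >= 0, occlusion_prob <= 1)
  structure(list(image_size = as.integer(image_size),
                 n_fruits = as.integer(n_fruits),
                 occlusion_prob = occlusion_prob, lighting = lighting,
                 seed = as.integer(seed), class_ids = class_ids),
            class = "scene_spec")
}

.light_mult <- c(sun = 1.15, shade = 0.70, overcast = 0.95)

.draw_ellipse <- function(img, cx, cy, a, b, h, s, v, shade = TRUE,
                          spots = 0) {
  d <- dim(img)
  x0 <- max(1L, floor(cx - a)); x1 <- min(d[2], ceiling(cx + a))
  y0 <- max(1L, floor(cy - b)); y1 <- min(d[1], ceiling(cy + b))
  if (x1 < x0 || y1 < y0) return(img)
  xs <- (x0:x1) - 0.5; ys <- (y0:y1) - 0.5
  RX <- matrix((xs - cx) / a, length(ys), length(xs), byrow = TRUE)
  RY <- matrix((ys - cy) / b, length(ys), length(xs))
  rr <- RX^2 + RY^2
  mask <- rr <= 1
  if (!any(mask)) return(img)
  vpix <- rep(v, sum(mask))
  if (shade) {
    vpix <- v * (1 - 0.45 * rr[mask])
    # specular highlight towards the upper-left light
    hl <- exp(-(((RX[mask] + 0.35)^2 + (RY[mask] + 0.35)^2)) / 0.08)
    vpix <- pmin(vpix + 0.25 * hl, 1)
  }
  rgb <- hsv_to_rgb_num(rep(h, sum(mask)), rep(s, sum(mask)), vpix)
  for (ch in 1:3) {
    plane <- img[y0:y1, x0:x1, ch]
    plane[mask] <- rgb[, ch]
    img[y0:y1, x0:x1, ch] <- plane
  }
  if (spots > 0) {
    n_sp <- stats::rpois(1, spots)
    for (k in seq_len(n_sp)) {
      ang <- stats::runif(1, 0, 2 * pi); rad <- sqrt(stats::runif(1)) * 0.7
      img <- .draw_ellipse(img, cx + rad * a * cos(ang), cy + rad * b * sin(ang),
                           a * stats::runif(1, 0.08, 0.18),
                           b * stats::runif(1, 0.08, 0.18),
                           h = 0.07, s = 0.6, v = 0.12, shade = FALSE)
    }
  }
  img
}

#' Generate a synthetic ripeness scene
#'
#' Renders `n_fruits` shaded ellipse fruits with class-dependent HSV
#' coloration on a textured foliage background, draws a leaf occluder over
#' each fruit with probability `occlusion_prob` (covering at most half the
#' fruit, so every fruit stays at least ~20 % visible), applies the lighting
#' multiplier, and returns the image with one labeled box per fruit.
#' Deterministic: the same spec yields byte-identical output.
#'
#' @param spec a [scene_spec()].
#' @param classes class table, see [ripeness_classes()].
#' @return list with `image` (\[size, size, 3\] in \[0, 1\]), `boxes`
#'   (data.frame x1, y1, x2, y2, cls; pixel coordinates, clipped) and
#'   `occluded` (logical per fruit).
#' @export
generate_scene <- function(spec, classes = ripeness_classes()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_fruits
  sz <- spec$image_size

  r_lo <- 0.055 * sz; r_hi <- 0.11 * sz
  if (2.2 * r_lo * ceiling(sqrt(n)) > sz) {
    stop("image too small to place ", n, " fruits")
  }

  # foliage-like background: dark green base plus low-frequency variation
  yy <- matrix(seq_len(sz), sz, sz); xx <- t(yy)
  tex <- 0
  for (k in 1:3) {
    fx <- stats::runif(1, 1, 4) * 2 * pi / sz
    fy <- stats::runif(1, 1, 4) * 2 * pi / sz
    ph <- stats::runif(2, 0, 2 * pi)
    tex <- tex + sin(fx * xx + ph[1]) * sin(fy * yy + ph[2]) / k
  }
  vbg <- 0.25 + 0.06 * tex + matrix(stats::runif(sz * sz, -0.02, 0.02), sz, sz)
  hbg <- 0.30 + 0.015 * tex
  bg <- hsv_to_rgb_num(as.vector(hbg), rep(0.55, sz * sz),
                       as.vector(pmin(pmax(vbg, 0), 1)))
  img <- array(bg, c(sz, sz, 3))

  cls_ids <- if (!is.null(spec$class_ids)) {
    rep(spec$class_ids, length.out = n)
  } else {
    sample(classes$id, n, replace = TRUE)
  }

  centers <- matrix(0, 0, 3)   # cx, cy, r
  boxes <- data.frame()
  occluded <- logical(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:300) {
      r <- stats::runif(1, r_lo, r_hi)
      cx <- stats::runif(1, r + 1, sz - r - 1)
      cy <- stats::runif(1, r + 1, sz - r - 1)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                0.8 * (centers[, 3] + r))) {
        placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place fruit ", i, " (image too crowded)")
    centers <- rbind(centers, c(cx, cy, r))
    a <- r; b <- r * stats::runif(1, 0.85, 1.1)
    ci <- classes[classes$id == cls_ids[i], ]
    h <- stats::runif(1, ci$hue_min, ci$hue_max) %% 1
    s <- stats::runif(1, ci$sat_min, ci$sat_max)
    v <- stats::runif(1, ci$val_min, ci$val_max)
    img <- .draw_ellipse(img, cx, cy, a, b, h, s, v, spots = ci$spot_rate)

    occluded[i] <- stats::runif(1) < spec$occlusion_prob
    if (occluded[i]) {
      # leaf blob centered near the fruit rim, covering under half the fruit
      ang <- stats::runif(1, 0, 2 * pi)
      lx <- cx + 0.9 * a * cos(ang); ly <- cy + 0.9 * b * sin(ang)
      img <- .draw_ellipse(img, lx, ly, a * stats::runif(1, 0.55, 0.75),
                           b * stats::runif(1, 0.55, 0.75),
                           h = stats::runif(1, 0.28, 0.34),
                           s = stats::runif(1, 0.5, 0.8),
                           v = stats::runif(1, 0.3, 0.45), shade = FALSE)
    }
    boxes <- rbind(boxes, data.frame(
      x1 = max(0, cx - a), y1 = max(0, cy - b),
      x2 = min(sz, cx + a), y2 = min(sz, cy + b), cls = cls_ids[i]))
  }

  img <- pmin(pmax(img * .light_mult[[spec$lighting]], 0), 1)
  list(image = img, boxes = boxes, occluded = occluded)
}

#' Recover the ripeness class from rendered hue
#'
#' Majority-hue classifier over the central region of a box: assigns the
#' class whose hue interval center is circularly closest to the median hue
#' of colorful pixels. A generator self-consistency device, not a biology
#' claim.
#'
#' @param image scene image.
#' @param box length-4 numeric (x1, y1, x2, y2) in pixels.
#' @param classes class table.
#' @return 0-based class id.
#' @export
classify_box_hue <- function(image, box, classes = ripeness_classes()) {
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  w <- (box[3] - box[1]) / 2; h <- (box[4] - box[2]) / 2
  x0 <- max(1L, floor(cx - 0.55 * w)); x1 <- min(dim(image)[2], ceiling(cx + 0.55 * w))
  y0 <- max(1L, floor(cy - 0.55 * h)); y1 <- min(dim(image)[1], ceiling(cy + 0.55 * h))
  sub <- image[y0:y1, x0:x1, , drop = FALSE]
  hsv <- rgb_to_hsv_arr(sub)
  keep <- hsv$s > 0.3
  hues <- hsv$h[keep]
  if (length(hues) == 0) hues <- as.vector(hsv$h)
  centers <- ((classes$hue_min + classes$hue_max) / 2) %% 1
  dist_circ <- function(a, b) pmin(abs(a - b), 1 - abs(a - b))
  # majority vote of per-pixel nearest class center
  votes <- vapply(hues, function(hh) which.min(dist_circ(hh, centers)), 1L)
  classes$id[which.max(tabulate(votes, nbins = nrow(classes)))]
}

# ---- augmentation -----------------------------------------------------------

#' Sample augmentation parameters
#'
#' Draws the operation parameter from its stated range: odd blur kernels in
#' {5, 7, ..., 15}, crop fraction (of the image side) in \[0.40, 0.80\],
#' rotation angle in \[-60, 60\] degrees.
#'
#' @param op_name `"mean_blur"`, `"random_crop"` or `"random_rotate"`.
#' @param n number of draws.
#' @return numeric vector of parameters.
#' @export
sample_augment_params <- function(op_name, n = 1) {
  switch(op_name,
         mean_blur = sample(seq(5L, 15L, by = 2L), n, replace = TRUE),
         random_crop = stats::runif(n, 0.40, 0.80),
         random_rotate = stats::runif(n, -60, 60),
         stop("unknown augmentation op: ", op_name))
}

#' Apply one augmentation to an image and its boxes
#'
#' Boxes are transformed with the image and clipped; boxes whose visible
#' area falls below 25 % of their original area are dropped. The output is
#' always resized to `out_size` x `out_size`.
#'
#' @param image array \[H, W, 3\].
#' @param boxes data.frame with x1, y1, x2, y2, cls (pixels).
#' @param op_name `"mean_blur"`, `"random_crop"` or `"random_rotate"`.
#' @param seed RNG seed for the parameter draw (ignored if `param` given).
#' @param param force the parameter (kernel size / crop fraction / angle).
#' @param out_size output side length.
#' @return list with `image`, `boxes` and `param`.
#' @export
augment <- function(image, boxes, op_name, seed = NULL, param = NULL,
                    out_size = 640L) {
  if (!op_name %in% c("mean_blur", "random_crop", "random_rotate")) {
    stop("unknown augmentation op: ", op_name)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (is.null(param)) param <- sample_augment_params(op_name, 1)
  d <- dim(image)
  area0 <- (boxes$x2 - boxes$x1) * (boxes$y2 - boxes$y1)

  if (op_name == "mean_blur") {
    k <- as.integer(param)
    if (k %% 2 != 1 || k < 5 || k > 15) stop("blur kernel must be odd in 5..15")
    out <- box_blur(image, k)
    bx <- boxes
  } else if (op_name == "random_crop") {
    f <- param
    if (f < 0.40 || f > 0.80) stop("crop fraction must lie in [0.40, 0.80]")
    ch <- round(f * d[1]); cw <- round(f * d[2])
    oy <- sample.int(d[1] - ch + 1L, 1L) - 1L
    ox <- sample.int(d[2] - cw + 1L, 1L) - 1L
    out <- image[oy + seq_len(ch), ox + seq_len(cw), , drop = FALSE]
    bx <- boxes
    bx$x1 <- pmin(pmax(bx$x1 - ox, 0), cw); bx$x2 <- pmin(pmax(bx$x2 - ox, 0), cw)
    bx$y1 <- pmin(pmax(bx$y1 - oy, 0), ch); bx$y2 <- pmin(pmax(bx$y2 - oy, 0), ch)
  } else {
    ang <- param
    if (ang < -60 || ang > 60) stop("rotation angle must lie in [-60, 60]")
    out <- rotate_image(image, ang, fill = c(0.08, 0.12, 0.06))
    bx <- boxes
    if (nrow(boxes)) {
      for (i in seq_len(nrow(boxes))) {
        corners <- rbind(c(boxes$x1[i], boxes$y1[i]), c(boxes$x2[i], boxes$y1[i]),
                         c(boxes$x2[i], boxes$y2[i]), c(boxes$x1[i], boxes$y2[i]))
        rot <- rotate_points(corners, ang, d[1], d[2])
        clipped <- poly_clip_rect(rot, 0, 0, d[2], d[1])
        if (poly_area(clipped) >= 0.25 * area0[i]) {
          bx$x1[i] <- min(clipped[, 1]); bx$x2[i] <- max(clipped[, 1])
          bx$y1[i] <- min(clipped[, 2]); bx$y2[i] <- max(clipped[, 2])
        } else {
          bx$x1[i] <- bx$x2[i] <- -1   # marked dropped
        }
      }
      bx <- bx[bx$x1 >= 0, , drop = FALSE]
    }
  }

  if (op_name != "random_rotate" && nrow(bx)) {
    # survival floor after crop: visible area >= 25 % of the original
    vis <- (bx$x2 - bx$x1) * (bx$y2 - bx$y1)
    bx <- bx[vis >= 0.25 * area0 & vis > 0, , drop = FALSE]
  }

  dc <- dim(out)
  sc_x <- out_size / dc[2]; sc_y <- out_size / dc[1]
  out <- resize_bilinear(out, out_size, out_size)
  if (nrow(bx)) {
    bx$x1 <- bx$x1 * sc_x; bx$x2 <- bx$x2 * sc_x
    bx$y1 <- bx$y1 * sc_y; bx$y2 <- bx$y2 * sc_y
  }
  rownames(bx) <- NULL
  list(image = out, boxes = bx, param = param)
}

# ---- dataset split ----------------------------------------------------------

#' Deterministic train/val/test split
#'
#' Shuffles `1:n_items` and splits into floor(f_train * n) training,
#' floor(f_val * n) validation and remainder test items — the rounding rule
#' that yields 2275/325/651 for 3251 items at 70/10/20.
#'
#' @param n_items number of items (>= 3).
#' @param fractions length-3 fractions summing to 1.
#' @param seed shuffle seed.
#' @return list with integer index vectors `train`, `val`, `test`
#'   (a partition of `1:n_items`).
#' @export
split_dataset <- function(n_items, fractions = c(0.70, 0.10, 0.20), seed = 1L) {
  stopifnot(n_items >= 3, length(fractions) == 3,
            abs(sum(fractions) - 1) < 1e-9)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample.int(n_items)
  n_train <- floor(fractions[1] * n_items)
  n_val <- floor(fractions[2] * n_items)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[(n_train + n_val + 1L):n_items]))
}
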