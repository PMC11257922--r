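# Image primitives for the scene generator and augmentation pipeline.
# Images are numeric arrays [H, W, 3] with values in [0, 1]; pixel (r, c)
# covers the unit square with center (c - 0.5, r - 0.5) in box coordinates
# (origin top-left, x along columns). Implemented in-package because the
# augmentation contract requires exact control of the image <-> box
# coordinate convention.

hsv_to_rgb_num <- function(h, s, v) {
  # vectorized HSV -> RGB, h in [0, 1) (wrapped), s and v in [0, 1]
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  m <- i == 0; r[m] <- v[m]; g[m] <- t[m]; b[m] <- p[m]
  m <- i == 1; r[m] <- q[m]; g[m] <- v[m]; b[m] <- p[m]
  m <- i == 2; r[m] <- p[m]; g[m] <- v[m]; b[m] <- t[m]
  m <- i == 3; r[m] <- p[m]; g[m] <- q[m]; b[m] <- v[m]
  m <- i == 4; r[m] <- t[m]; g[m] <- p[m]; b[m] <- v[m]
  m <- i >= 5; r[m] <- v[m]; g[m] <- p[m]; b[m] <- q[m]
  cbind(r, g, b)
}

rgb_to_hsv_arr <- function(image) {
  d <- dim(image)
  m <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = matrix(hsv[1, ], d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

#' Mean (box) blur of an image
#'
#' Each output pixel is the mean over the k x k window, truncated at the
#' image border (so a constant image is exactly unchanged). Implemented with
#' integral images.
#'
#' @param image array \[H, W, C\].
#' @param k odd kernel size.
#' @return blurred array of the same shape.
#' @export
box_blur <- function(image, k) {
  stopifnot(k %% 2 == 1, k >= 1)
  if (k == 1) return(image)
  d <- dim(image)
  r <- (k - 1) %/% 2
  out <- image
  for (ch in seq_len(d[3])) {
    x <- image[, , ch]
    # integral image with zero top/left border
    S <- matrix(0, d[1] + 1, d[2] + 1)
    S[-1, -1] <- apply(apply(x, 2, cumsum), 1, cumsum) |> t()
    i0 <- pmax(seq_len(d[1]) - r, 1); i1 <- pmin(seq_len(d[1]) + r, d[1])
    j0 <- pmax(seq_len(d[2]) - r, 1); j1 <- pmin(seq_len(d[2]) + r, d[2])
    sums <- S[i1 + 1, j1 + 1, drop = FALSE] - S[i0, j1 + 1, drop = FALSE] -
      S[i1 + 1, j0, drop = FALSE] + S[i0, j0, drop = FALSE]
    counts <- outer(i1 - i0 + 1, j1 - j0 + 1)
    out[, , ch] <- sums / counts
  }
  out
}

#' Bilinear resize
#'
#' @param image array \[H, W, C\].
#' @param out_h,out_w output extent.
#' @return resized array.
#' @export
resize_bilinear <- function(image, out_h, out_w) {
  d <- dim(image)
  if (out_h == d[1] && out_w == d[2]) return(image)
  # map output pixel centers to input pixel coordinates (align centers)
  ry <- (seq_len(out_h) - 0.5) * d[1] / out_h + 0.5
  rx <- (seq_len(out_w) - 0.5) * d[2] / out_w + 0.5
  ry <- pmin(pmax(ry, 1), d[1]); rx <- pmin(pmax(rx, 1), d[2])
  y0 <- pmin(floor(ry), d[1] - 1); x0 <- pmin(floor(rx), d[2] - 1)
  if (d[1] == 1) y0 <- rep(1, out_h)
  if (d[2] == 1) x0 <- rep(1, out_w)
  wy <- ry - y0; wx <- rx - x0
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) {
    x <- image[, , ch]
    a <- x[y0, x0, drop = FALSE]; b <- x[y0, pmin(x0 + 1, d[2]), drop = FALSE]
    cc <- x[pmin(y0 + 1, d[1]), x0, drop = FALSE]
    dd <- x[pmin(y0 + 1, d[1]), pmin(x0 + 1, d[2]), drop = FALSE]
    W1 <- outer(1 - wy, 1 - wx); W2 <- outer(1 - wy, wx)
    W3 <- outer(wy, 1 - wx); W4 <- outer(wy, wx)
    out[, , ch] <- a * W1 + b * W2 + cc * W3 + dd * W4
  }
  out
}

#' Rotate an image about its center
#'
#' Inverse-mapped bilinear rotation on the same canvas; pixels mapped from
#' outside the source are filled with `fill`.
#'
#' @param image array \[H, W, C\].
#' @param angle_deg counter-clockwise angle in degrees (in box coordinates,
#'   y pointing down, this appears clockwise on screen).
#' @param fill fill value (length 1 or C).
#' @return rotated array of the same shape.
#' @export
rotate_image <- function(image, angle_deg, fill = 0) {
  d <- dim(image)
  if (angle_deg == 0) return(image)
  th <- angle_deg * pi / 180
  cy <- d[1] / 2; cx <- d[2] / 2
  # output pixel centers
  yy <- rep(seq_len(d[1]) - 0.5, times = d[2]) - cy
  xx <- rep(seq_len(d[2]) - 0.5, each = d[1]) - cx
  # inverse rotation
  sx <- cos(th) * xx + sin(th) * yy + cx
  sy <- -sin(th) * xx + cos(th) * yy + cy
  px <- sx + 0.5; py <- sy + 0.5   # to pixel index space
  inside <- px >= 1 & px <= d[2] & py >= 1 & py <= d[1]
  px <- pmin(pmax(px, 1), d[2]); py <- pmin(pmax(py, 1), d[1])
  x0 <- pmin(floor(px), d[2] - 1); y0 <- pmin(floor(py), d[1] - 1)
  wx <- px - x0; wy <- py - y0
  fill <- rep(fill, length.out = d[3])
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    z <- image[, , ch]
    idx <- function(y, x) z[cbind(y, x)]
    v <- idx(y0, x0) * (1 - wy) * (1 - wx) + idx(y0, x0 + 1) * (1 - wy) * wx +
      idx(y0 + 1, x0) * wy * (1 - wx) + idx(y0 + 1, x0 + 1) * wy * wx
    v[!inside] <- fill[ch]
    out[, , ch] <- v
  }
  out
}

# rotate box-coordinate points (n x 2, origin top-left) about the image center
rotate_points <- function(pts, angle_deg, h, w) {
  th <- angle_deg * pi / 180
  cx <- w / 2; cy <- h / 2
  x <- pts[, 1] - cx; y <- pts[, 2] - cy
  cbind(cos(th) * x - sin(th) * y + cx,
        sin(th) * x + cos(th) * y + cy)
}

# Sutherland-Hodgman clip of a convex polygon against an axis-aligned rect
poly_clip_rect <- function(poly, xmin, ymin, xmax, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      a <- pts[i, ]; b <- pts[if (i == n) 1 else i + 1, ]
      ia <- inside(a); ib <- inside(b)
      if (ia) out <- rbind(out, a)
      if (xor(ia, ib)) out <- rbind(out, intersect(a, b))
    }
    out
  }
  ix <- function(a, b, x) { t <- (x - a[1]) / (b[1] - a[1]); c(x, a[2] + t * (b[2] - a[2])) }
  iy <- function(a, b, y) { t <- (y - a[2]) / (b[2] - a[2]); c(a[1] + t * (b[1] - a[1]), y) }
  poly <- clip_edge(poly, function(p) p[1] >= xmin, function(a, b) ix(a, b, xmin))
  poly <- clip_edge(poly, function(p) p[1] <= xmax, function(a, b) ix(a, b, xmax))
  poly <- clip_edge(poly, function(p) p[2] >= ymin, function(a, b) iy(a, b, ymin))
  poly <- clip_edge(poly, function(p) p[2] <= ymax, function(a, b) iy(a, b, ymax))
  poly
}

poly_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
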