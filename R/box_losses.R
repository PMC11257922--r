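# IoU-family bounding-box regression losses: IoU, GIoU, EIoU and the
# Inner-IoU / Inner-EIoU variants that compute the overlap term on
# center-shared auxiliary boxes scaled by `ratio`.
#
# All public entry points accept boxes either as corner coordinates
# c(x1, y1, x2, y2) ("xyxy") or as center/size c(cx, cy, w, h) ("cxcywh");
# conversion happens at a single point to avoid convention drift.

#' Convert boxes between corner and center/size parameterizations
#'
#' @param box numeric vector of length 4, or an n x 4 matrix (one box per row).
#' @return same shape as the input, in the other parameterization.
#' @export
box_xyxy_to_cxcywh <- function(box) {
  b <- .as_box_matrix(box)
  out <- cbind((b[, 1] + b[, 3]) / 2, (b[, 2] + b[, 4]) / 2,
               b[, 3] - b[, 1], b[, 4] - b[, 2])
  .box_like(out, box)
}

#' @rdname box_xyxy_to_cxcywh
#' @export
box_cxcywh_to_xyxy <- function(box) {
  b <- .as_box_matrix(box)
  out <- cbind(b[, 1] - b[, 3] / 2, b[, 2] - b[, 4] / 2,
               b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
  .box_like(out, box)
}

.as_box_matrix <- function(box) {
  if (is.matrix(box)) {
    stopifnot(ncol(box) == 4)
    box
  } else {
    stopifnot(length(box) == 4)
    matrix(as.numeric(box), nrow = 1)
  }
}

.box_like <- function(m, template) {
  if (is.matrix(template)) m else as.numeric(m)
}

.check_boxes <- function(a, b, format) {
  if (format == "cxcywh") {
    a <- box_cxcywh_to_xyxy(a)
    b <- box_cxcywh_to_xyxy(b)
  }
  a <- .as_box_matrix(a); b <- .as_box_matrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  if (any((a[, 3] - a[, 1]) <= 0 | (a[, 4] - a[, 2]) <= 0 |
          (b[, 3] - b[, 1]) <= 0 | (b[, 4] - b[, 2]) <= 0)) {
    warning("degenerate (zero or negative area) box; result defined via clamping")
  }
  list(a = a, b = b)
}

#' Intersection-over-union of axis-aligned boxes
#'
#' Element-wise IoU of paired boxes. Intersection is clamped at zero so
#' disjoint boxes score 0.
#'
#' @param a,b boxes (length-4 vector or n x 4 matrix, paired row-wise).
#' @param format `"xyxy"` (default) or `"cxcywh"`.
#' @return numeric vector of IoU values in \[0, 1\].
#' @export
iou <- function(a, b, format = "xyxy") {
  p <- .check_boxes(a, b, format)
  a <- p$a; b <- p$b
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  union <- pmax((a[, 3] - a[, 1]) * (a[, 4] - a[, 2]), 0) +
           pmax((b[, 3] - b[, 1]) * (b[, 4] - b[, 2]), 0) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Generalized IoU
#'
#' IoU minus the fraction of the smallest enclosing box not covered by the
#' union; ranges over (-1, 1\] and tends to -1 for far-separated boxes.
#'
#' @inheritParams iou
#' @return numeric vector of GIoU values.
#' @export
giou <- function(a, b, format = "xyxy") {
  p <- .check_boxes(a, b, format)
  a <- p$a; b <- p$b
  i <- iou(a, b)
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  union <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
           (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  enc <- cw * ch
  i - ifelse(enc > 0, (enc - union) / enc, 0)
}

#' Pairwise IoU matrix
#'
#' @param A m x 4 matrix of boxes, `B` n x 4 matrix; both xyxy.
#' @return m x n matrix of IoU values.
#' @export
iou_matrix <- function(A, B) {
  A <- .as_box_matrix(A); B <- .as_box_matrix(B)
  m <- nrow(A); n <- nrow(B)
  if (m == 0L || n == 0L) return(matrix(0, m, n))
  out <- matrix(0, m, n)
  for (j in seq_len(n)) {
    out[, j] <- iou(A, B[j, , drop = FALSE])
  }
  out
}

.inner_boxes <- function(a_c, ratio) {
  # a_c in cxcywh; auxiliary box shares the center, sides scaled by ratio
  cbind(a_c[, 1] - a_c[, 3] * ratio / 2, a_c[, 2] - a_c[, 4] * ratio / 2,
        a_c[, 1] + a_c[, 3] * ratio / 2, a_c[, 2] + a_c[, 4] * ratio / 2)
}

#' Inner-IoU: IoU of center-shared auxiliary boxes
#'
#' Both boxes are rescaled about their own centers by `ratio`; the
#' intersection of the scaled boxes (clamped at zero) is divided by
#' `ratio^2 * (area_a + area_b) - inter`. At `ratio = 1` this equals [iou()].
#'
#' @inheritParams iou
#' @param ratio auxiliary scale factor (> 0), default 0.7.
#' @return numeric vector in \[0, 1\].
#' @export
inner_iou <- function(a, b, ratio = 0.7, format = "xyxy") {
  stopifnot(ratio > 0)
  p <- .check_boxes(a, b, format)
  ac <- .as_box_matrix(box_xyxy_to_cxcywh(p$a))
  bc <- .as_box_matrix(box_xyxy_to_cxcywh(p$b))
  ai <- .inner_boxes(ac, ratio); bi <- .inner_boxes(bc, ratio)
  iw <- pmax(0, pmin(ai[, 3], bi[, 3]) - pmax(ai[, 1], bi[, 1]))
  ih <- pmax(0, pmin(ai[, 4], bi[, 4]) - pmax(ai[, 2], bi[, 2]))
  inter <- iw * ih
  union <- ac[, 3] * ac[, 4] * ratio^2 + bc[, 3] * bc[, 4] * ratio^2 - inter
  ifelse(union > 0, inter / union, 0)
}

#' EIoU loss and its three components
#'
#' `L_EIoU = L_IoU + L_dis + L_asp` with `L_IoU = 1 - IoU`, `L_dis` the
#' squared center distance normalized by the squared diagonal of the smallest
#' enclosing box, and `L_asp` the squared width and height differences
#' normalized by the squared enclosing width/height.
#'
#' @inheritParams iou
#' @return list with `l_iou`, `l_dis`, `l_asp` (numeric vectors) and their sum
#'   `loss`. All components are >= 0 and vanish exactly when the boxes coincide.
#' @export
eiou <- function(a, b, format = "xyxy") {
  p <- .check_boxes(a, b, format)
  a <- p$a; b <- p$b
  ac <- .as_box_matrix(box_xyxy_to_cxcywh(a))
  bc <- .as_box_matrix(box_xyxy_to_cxcywh(b))
  l_iou <- 1 - iou(a, b)
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  diag2 <- cw^2 + ch^2
  l_dis <- ifelse(diag2 > 0,
                  ((ac[, 1] - bc[, 1])^2 + (ac[, 2] - bc[, 2])^2) / diag2, 0)
  l_asp <- ifelse(cw > 0, (ac[, 3] - bc[, 3])^2 / cw^2, 0) +
           ifelse(ch > 0, (ac[, 4] - bc[, 4])^2 / ch^2, 0)
  list(l_iou = l_iou, l_dis = l_dis, l_asp = l_asp,
       loss = l_iou + l_dis + l_asp)
}

#' Inner-EIoU loss
#'
#' `L_Inner-EIoU = L_EIoU + IoU - IoU_inner`: the EIoU loss with its overlap
#' term effectively evaluated on the `ratio`-scaled auxiliary boxes, which
#' focuses the regression on the box center. At `ratio = 1` it equals
#' `eiou()$loss` exactly.
#'
#' @inheritParams inner_iou
#' @return numeric vector of loss values (0 iff the boxes coincide).
#' @export
inner_eiou <- function(a, b, ratio = 0.7, format = "xyxy") {
  e <- eiou(a, b, format = format)
  e$loss + iou(a, b, format = format) - inner_iou(a, b, ratio = ratio, format = format)
}

#' Resolve a box-loss function from a config name
#'
#' @param name one of `"giou"`, `"eiou"`, `"inner_eiou"`.
#' @param ratio auxiliary ratio used by `"inner_eiou"`.
#' @return function(pred, gt) -> loss vector (boxes in xyxy).
#' @export
box_loss_fn <- function(name = c("giou", "eiou", "inner_eiou"), ratio = 0.7) {
  name <- match.arg(name)
  switch(name,
    giou = function(pred, gt) 1 - giou(pred, gt),
    eiou = function(pred, gt) eiou(pred, gt)$loss,
    inner_eiou = function(pred, gt) inner_eiou(pred, gt, ratio = ratio)
  )
}

# ---- analytic gradients (w.r.t. the predicted box in cxcywh) ----------------
# Used by the head-training path; verified against finite differences in the
# test suite. Each helper returns a length-4 gradient c(d/dcx, d/dcy, d/dw, d/dh)
# for a single predicted box `p` against a fixed ground truth `g`.

.grad_corner_terms <- function(p) {
  # d(x1,y1,x2,y2)/d(cx,cy,w,h) as a 4x4 Jacobian (rows: corners)
  matrix(c(1, 0, -0.5,  0,
           0, 1,  0,  -0.5,
           1, 0,  0.5,  0,
           0, 1,  0,   0.5), nrow = 4, byrow = TRUE)
}

.iou_with_grad <- function(p, g, ratio = 1) {
  # IoU of ratio-scaled, center-shared boxes and gradient w.r.t. p (cxcywh).
  cx <- p[1]; cy <- p[2]; w <- p[3]; h <- p[4]
  a <- c(cx - w * ratio / 2, cy - h * ratio / 2, cx + w * ratio / 2, cy + h * ratio / 2)
  bc <- g
  b <- c(bc[1] - bc[3] * ratio / 2, bc[2] - bc[4] * ratio / 2,
         bc[1] + bc[3] * ratio / 2, bc[2] + bc[4] * ratio / 2)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  pos <- iw > 0 && ih > 0
  inter <- if (pos) iw * ih else 0
  union <- w * h * ratio^2 + bc[3] * bc[4] * ratio^2 - inter
  val <- if (union > 0) inter / union else 0
  # gradients of corners of the scaled box w.r.t. (cx, cy, w, h)
  J <- matrix(c(1, 0, -ratio / 2, 0,
                0, 1, 0, -ratio / 2,
                1, 0,  ratio / 2, 0,
                0, 1, 0,  ratio / 2), nrow = 4, byrow = TRUE)
  g_inter <- numeric(4)
  if (pos) {
    d_iw <- numeric(4)                       # d iw / d params
    if (a[3] < b[3]) d_iw <- d_iw + J[3, ]
    if (a[1] > b[1]) d_iw <- d_iw - J[1, ]
    d_ih <- numeric(4)
    if (a[4] < b[4]) d_ih <- d_ih + J[4, ]
    if (a[2] > b[2]) d_ih <- d_ih - J[2, ]
    g_inter <- d_iw * ih + d_ih * iw
  }
  g_union <- c(0, 0, h * ratio^2, w * ratio^2) - g_inter
  grad <- if (union > 0) (g_inter * union - inter * g_union) / union^2 else numeric(4)
  list(value = val, grad = grad)
}

#' Analytic gradient of the EIoU loss
#'
#' @param pred,gt single boxes in cxcywh (length-4 numeric).
#' @return list with `loss` and `grad` (d loss / d pred, length 4).
#' @export
eiou_grad <- function(pred, gt) {
  cx <- pred[1]; cy <- pred[2]; w <- pred[3]; h <- pred[4]
  a <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  b <- c(gt[1] - gt[3] / 2, gt[2] - gt[4] / 2, gt[1] + gt[3] / 2, gt[2] + gt[4] / 2)
  J <- .grad_corner_terms(pred)
  io <- .iou_with_grad(pred, gt, ratio = 1)

  cw <- max(a[3], b[3]) - min(a[1], b[1])
  ch <- max(a[4], b[4]) - min(a[2], b[2])
  d_cw <- numeric(4); d_ch <- numeric(4)
  if (a[3] > b[3]) d_cw <- d_cw + J[3, ]
  if (a[1] < b[1]) d_cw <- d_cw - J[1, ]
  if (a[4] > b[4]) d_ch <- d_ch + J[4, ]
  if (a[2] < b[2]) d_ch <- d_ch - J[2, ]

  diag2 <- cw^2 + ch^2
  num <- (cx - gt[1])^2 + (cy - gt[2])^2
  d_num <- c(2 * (cx - gt[1]), 2 * (cy - gt[2]), 0, 0)
  d_diag2 <- 2 * cw * d_cw + 2 * ch * d_ch
  l_dis <- num / diag2
  g_dis <- (d_num * diag2 - num * d_diag2) / diag2^2

  dw <- w - gt[3]; dh <- h - gt[4]
  l_asp <- dw^2 / cw^2 + dh^2 / ch^2
  g_asp <- (c(0, 0, 2 * dw, 0) * cw^2 - dw^2 * 2 * cw * d_cw) / cw^4 +
           (c(0, 0, 0, 2 * dh) * ch^2 - dh^2 * 2 * ch * d_ch) / ch^4

  list(loss = (1 - io$value) + l_dis + l_asp,
       grad = -io$grad + g_dis + g_asp)
}

#' Analytic gradient of the Inner-EIoU loss
#'
#' @inheritParams eiou_grad
#' @param ratio auxiliary box scale factor.
#' @return list with `loss` and `grad` (d loss / d pred, length 4, cxcywh).
#' @export
inner_eiou_grad <- function(pred, gt, ratio = 0.7) {
  e <- eiou_grad(pred, gt)
  io <- .iou_with_grad(pred, gt, ratio = 1)
  ii <- .iou_with_grad(pred, gt, ratio = ratio)
  list(loss = e$loss + io$value - ii$value,
       grad = e$grad + io$grad - ii$grad)
}

#' Analytic gradient of the GIoU loss
#'
#' @inheritParams eiou_grad
#' @return list with `loss` (`1 - GIoU`) and `grad` w.r.t. pred (cxcywh).
#' @export
giou_grad <- function(pred, gt) {
  cx <- pred[1]; cy <- pred[2]; w <- pred[3]; h <- pred[4]
  a <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  b <- c(gt[1] - gt[3] / 2, gt[2] - gt[4] / 2, gt[1] + gt[3] / 2, gt[2] + gt[4] / 2)
  J <- .grad_corner_terms(pred)
  io <- .iou_with_grad(pred, gt, ratio = 1)

  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- if (iw > 0 && ih > 0) iw * ih else 0
  union <- w * h + gt[3] * gt[4] - inter
  g_inter <- numeric(4)
  if (iw > 0 && ih > 0) {
    d_iw <- numeric(4); d_ih <- numeric(4)
    if (a[3] < b[3]) d_iw <- d_iw + J[3, ]
    if (a[1] > b[1]) d_iw <- d_iw - J[1, ]
    if (a[4] < b[4]) d_ih <- d_ih + J[4, ]
    if (a[2] > b[2]) d_ih <- d_ih - J[2, ]
    g_inter <- d_iw * ih + d_ih * iw
  }
  g_union <- c(0, 0, h, w) - g_inter

  cw <- max(a[3], b[3]) - min(a[1], b[1])
  ch <- max(a[4], b[4]) - min(a[2], b[2])
  d_cw <- numeric(4); d_ch <- numeric(4)
  if (a[3] > b[3]) d_cw <- d_cw + J[3, ]
  if (a[1] < b[1]) d_cw <- d_cw - J[1, ]
  if (a[4] > b[4]) d_ch <- d_ch + J[4, ]
  if (a[2] < b[2]) d_ch <- d_ch - J[2, ]
  enc <- cw * ch
  d_enc <- d_cw * ch + d_ch * cw
  pen <- (enc - union) / enc
  g_pen <- ((d_enc - g_union) * enc - (enc - union) * d_enc) / enc^2

  list(loss = 1 - (io$value - pen),
       grad = -(io$grad - g_pen))
}
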