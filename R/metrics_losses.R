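#' Per-pixel class-probability map
#'
#' Network output before argmax: a C x H x W array of class probabilities
#' whose per-pixel channel sum is 1.
#'
#' @param probs numeric array `(C, H, W)`, values in \[0, 1\], channel sums
#'   1 within 1e-6.
#' @param classes ordered class labels matching the channel order.
#' @return An object of class `ProbabilityMap`.
#' @export
probability_map <- function(probs, classes = 0:(dim(probs)[1] - 1)) {
  if (length(dim(probs)) != 3L) stop("probs must be a (C, H, W) array")
  if (min(probs) < -1e-9 || max(probs) > 1 + 1e-9)
    stop("probabilities must lie in [0, 1]")
  sums <- apply(probs, c(2, 3), sum)
  if (max(abs(sums - 1)) > 1e-6)
    stop("per-pixel channel sums must equal 1 (max deviation ",
         format(max(abs(sums - 1))), ")")
  structure(list(probs = probs, classes = as.integer(classes)),
            class = "ProbabilityMap")
}

#' Dice similarity coefficient between two label masks
#'
#' `DSC(A, B) = 2|A intersect B| / (|A| + |B|)` where A and B are the pixel
#' sets of class `cls` in each mask. Both regions empty returns 1 by
#' convention; exactly one empty returns 0.
#'
#' @param a,b [label_mask()]s of identical shape.
#' @param cls class label to compare.
#' @return Unitless similarity in \[0, 1\].
#' @examples
#' m <- label_mask(matrix(c(1, 1, 0, 0), 2, 2), classes = 0:1)
#' dsc(m, m, 1)
#' @export
dsc <- function(a, b, cls) {
  if (!identical(dim(a$labels), dim(b$labels)))
    stop("mask shapes differ")
  A <- a$labels == cls
  B <- b$labels == cls
  nA <- sum(A); nB <- sum(B)
  if (nA == 0 && nB == 0) return(1)
  2 * sum(A & B) / (nA + nB)
}

# Boundary pixels of a class region: region pixels with at least one
# non-region 4-neighbour, or lying on the image edge.
boundary_points <- function(labels, cls) {
  R <- labels == cls
  H <- nrow(R); W <- ncol(R)
  interior <- matrix(FALSE, H, W)
  if (H > 2 && W > 2)
    interior[2:(H - 1), 2:(W - 1)] <-
      R[2:(H - 1), 2:(W - 1)] & R[1:(H - 2), 2:(W - 1)] & R[3:H, 2:(W - 1)] &
      R[2:(H - 1), 1:(W - 2)] & R[2:(H - 1), 3:W]
  which(R & !interior, arr.ind = TRUE)
}

directed_hd <- function(A, B) {
  # max over a in A of min over b in B of Euclidean distance; points in mm
  d2 <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2
  sqrt(max(apply(d2, 1, min)))
}

#' Hausdorff distance between two class contours
#'
#' The two point sets are the boundary pixels (pixel centers, scaled by the
#' physical spacing) of class `cls` in each mask;
#' `HD(A, B) = max(h(A, B), h(B, A))` with
#' `h(A, B) = max_{a in A} min_{b in B} ||a - b||`. Reported in millimetres;
#' smaller values mean higher segmentation accuracy.
#'
#' @param a,b [label_mask()]s of identical shape and spacing.
#' @param cls class label; must be present in both masks (an absent class
#'   makes the metric undefined and raises an error, it is never reported
#'   as 0).
#' @return Distance in millimetres.
#' @export
hausdorff <- function(a, b, cls) {
  if (!identical(dim(a$labels), dim(b$labels)))
    stop("mask shapes differ")
  if (!isTRUE(all.equal(a$spacing, b$spacing)))
    stop("mask spacings differ")
  pa <- boundary_points(a$labels, cls)
  pb <- boundary_points(b$labels, cls)
  if (nrow(pa) == 0 || nrow(pb) == 0)
    stop("class ", cls, " absent in ", if (nrow(pa) == 0) "first" else "second",
         " mask: Hausdorff distance undefined")
  A <- cbind(pa[, 1] * a$spacing[1], pa[, 2] * a$spacing[2])
  B <- cbind(pb[, 1] * a$spacing[1], pb[, 2] * a$spacing[2])
  max(directed_hd(A, B), directed_hd(B, A))
}

one_hot_channel <- function(target, cls) as.numeric(target$labels == cls)

dice_terms <- function(pred, target, cls, smooth = 1e-6) {
  ci <- match(cls, pred$classes)
  if (is.na(ci)) stop("class ", cls, " not in the probability map")
  p <- as.numeric(pred$probs[ci, , ])       # (H, W) slice, column-major like labels
  g <- as.numeric(target$labels == cls)
  list(p = p, g = g,
       num = 2 * sum(p * g) + smooth,
       den = sum(p^2) + sum(g^2) + smooth)
}

#' Soft Dice loss for one class channel
#'
#' The differentiable Dice ratio `D = 2 sum(p g) / (sum(p^2) + sum(g^2))`
#' between the predicted probabilities p of class `cls` and the one-hot
#' ground truth g, with a small smoothing constant (1e-6) added to numerator
#' and denominator so the empty-empty case is defined. The training
#' objective is `1 - D`; the multiclass loss used by [train()] is the mean
#' of `1 - D` over the foreground classes.
#'
#' @param pred a [probability_map()].
#' @param target a [label_mask()] of matching shape.
#' @param cls class label.
#' @return A list with `D` (Dice ratio) and `loss` (`1 - D`).
#' @export
dice_loss <- function(pred, target, cls) {
  tm <- dice_terms(pred, target, cls)
  D <- tm$num / tm$den
  list(D = D, loss = 1 - D)
}

#' Analytic gradient of the Dice ratio
#'
#' `dD/dp_i = 2 [g_i (sum p^2 + sum g^2) - 2 p_i sum(p g)] /
#' (sum p^2 + sum g^2)^2`, evaluated with the same smoothing as
#' [dice_loss()] so it matches finite differences of the smoothed D
#' exactly. This is the quantity back-propagated during training.
#'
#' @inheritParams dice_loss
#' @return An H x W matrix of derivatives of D with respect to the class
#'   channel probabilities.
#' @export
dice_loss_grad <- function(pred, target, cls) {
  tm <- dice_terms(pred, target, cls)
  gvec <- 2 * (tm$g * tm$den - tm$p * tm$num) / tm$den^2
  matrix(gvec, nrow = dim(pred$probs)[2])
}

#' Aggregate per-image, per-class metrics
#'
#' Builds the standard report: one row per (image, class) with DSC and HD,
#' plus per-class and overall means. An undefined HD (class absent in a
#' mask) is stored as `NA` and excluded from HD means, never coerced to 0.
#'
#' @param rows data.frame with columns `image_id`, `class`, `dsc`, `hd_mm`.
#' @return An object of class `MetricReport` with `per_image` (the rows),
#'   `per_class` (means by class), `mean_dsc`, `mean_hd`, `n_images`.
#' @export
metric_report <- function(rows) {
  stopifnot(all(c("image_id", "class", "dsc", "hd_mm") %in% names(rows)))
  per_class <- do.call(rbind, lapply(split(rows, rows$class), function(d)
    data.frame(class = d$class[1], dsc = mean(d$dsc),
               hd_mm = if (all(is.na(d$hd_mm))) NA_real_
                       else mean(d$hd_mm, na.rm = TRUE),
               n_missing_hd = sum(is.na(d$hd_mm)))))
  structure(list(per_image = rows, per_class = per_class,
                 mean_dsc = mean(per_class$dsc),
                 mean_hd = if (all(is.na(per_class$hd_mm))) NA_real_
                           else mean(per_class$hd_mm, na.rm = TRUE),
                 n_images = length(unique(rows$image_id))),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf("<MetricReport: %d images, mean DSC %.4f, mean HD %s mm>\n",
              x$n_images, x$mean_dsc,
              if (is.na(x$mean_hd)) "NA" else sprintf("%.3f", x$mean_hd)))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
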