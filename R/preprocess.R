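#' Max-normalization of an intensity image
#'
#' Standardizes an image as `x' = (x - mean(x)) / (max(x) - min(x))`, with
#' mean, max and min taken over the whole image. The output has zero mean
#' and unit *range* (not unit variance). Used before feeding images to the
#' networks so that acquisition brightness/contrast differences are removed.
#'
#' @param image an [image2d()] with at least two distinct values.
#' @return The normalized [image2d()] (spacing preserved).
#' @examples
#' normalize_max(image2d(matrix(c(0, 50, 100), 1, 3)))$pixels
#' @export
normalize_max <- function(image) {
  x <- image$pixels
  rng <- max(x) - min(x)
  if (rng == 0)
    stop("degenerate input: constant image (max == min), normalization undefined")
  out <- image
  out$pixels <- (x - mean(x)) / rng
  out
}

#' Augmentation specification
#'
#' The stochastic intensity/geometry perturbations applied during training:
#' a random scale factor drawn additively about 1 from `scale_range`, a
#' shear of -5 to +5 percent slope along a uniformly random axis, and a
#' contrast gain of -5 to +5 percent about the image mean. Defaults are the
#' standard ranges for short-axis cardiac augmentation.
#'
#' @param scale_range additive fraction interval, default `c(-0.2, 0.2)`
#'   (i.e. scale factors in \[0.8, 1.2\]).
#' @param shear_range percent interval, default `c(-5, 5)`, interpreted as
#'   percent slope along a random axis.
#' @param contrast_range percent interval, default `c(-5, 5)`.
#' @param seed RNG seed.
#' @return An object of class `AugmentSpec`.
#' @export
augment_spec <- function(scale_range = c(-0.2, 0.2), shear_range = c(-5, 5),
                         contrast_range = c(-5, 5), seed = 1L) {
  for (r in list(scale_range, shear_range, contrast_range))
    if (length(r) != 2L || r[1] > r[2]) stop("each range must be c(low, high) with low <= high")
  structure(list(scale_range = scale_range, shear_range = shear_range,
                 contrast_range = contrast_range, seed = as.integer(seed)),
            class = "AugmentSpec")
}

# Inverse-map an affine transform about the image center.  A is the 2x2
# forward matrix in (row, col) coordinates; output pixel o maps to source
# s = center + A^{-1} (o - center).
affine_resample <- function(px, A, interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(px); W <- ncol(px)
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  Ai <- solve(A)
  or <- matrix(seq_len(H), H, W) - ctr[1]
  oc <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2]
  sr <- Ai[1, 1] * or + Ai[1, 2] * oc + ctr[1]
  sc <- Ai[2, 1] * or + Ai[2, 2] * oc + ctr[2]
  if (interp == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- matrix(fill, H, W)
    out[ok] <- px[cbind(ri[ok], ci[ok])]
    out
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    gv <- function(ri, ci) {
      ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
      v <- matrix(fill, H, W)
      v[ok] <- px[cbind(ri[ok], ci[ok])]
      v
    }
    gv(r0, c0) * (1 - fr) * (1 - fc) + gv(r0 + 1, c0) * fr * (1 - fc) +
      gv(r0, c0 + 1) * (1 - fr) * fc + gv(r0 + 1, c0 + 1) * fr * fc
  }
}

#' Random scale/shear/contrast augmentation of an image/mask pair
#'
#' One scale factor `s = 1 + U(scale_range)`, one shear slope
#' `U(shear_range)/100` along a random axis, and one contrast gain
#' `1 + U(contrast_range)/100` are drawn. The identical geometric transform
#' is applied to the image (bilinear interpolation) and the mask
#' (nearest-neighbour, so no interpolation-invented labels); the contrast
#' gain acts on the image only, as `x' = mean(x) + gain * (x - mean(x))`.
#' Transforms act about the image center with constant (0) padding, so the
#' output shape equals the input shape.
#'
#' @param image an [image2d()].
#' @param mask the aligned [label_mask()].
#' @param spec an [augment_spec()]; drawing uses the current RNG state
#'   (seed the caller, or see `spec$seed` used by the trainer).
#' @return A list `image`, `mask`, `params` (named draws: `scale`, `shear`,
#'   `shear_axis`, `contrast`).
#' @export
augment <- function(image, mask, spec = augment_spec()) {
  check_pair(image, mask)
  s <- 1 + runif1(spec$scale_range)
  shear <- runif1(spec$shear_range) / 100
  axis <- if (stats::runif(1) < 0.5) "row" else "col"
  gain <- 1 + runif1(spec$contrast_range) / 100
  Sh <- diag(2)
  if (axis == "row") Sh[1, 2] <- shear else Sh[2, 1] <- shear
  A <- s * Sh
  out_img <- image
  ident <- isTRUE(all.equal(A, diag(2)))
  out_img$pixels <- if (ident) image$pixels else
    affine_resample(image$pixels, A, "bilinear")
  mu <- mean(out_img$pixels)
  out_img$pixels <- mu + gain * (out_img$pixels - mu)
  out_msk <- mask
  if (!ident) {
    lb <- affine_resample(mask$labels, A, "nearest", fill = 0)
    storage.mode(lb) <- "integer"
    out_msk$labels <- lb
  }
  list(image = out_img, mask = out_msk,
       params = list(scale = s, shear = shear * 100, shear_axis = axis,
                     contrast = (gain - 1) * 100))
}

#' Crop a square region of interest
#'
#' Extracts a `size x size` window centered at `center`, zero-padding where
#' the window exceeds the image bounds. The 128-pixel default matches the
#' region-of-interest crop around the cardiac chambers used throughout the
#' package; the center defaults to the image center since no automatic
#' chamber detector is provided.
#'
#' @param image an [image2d()].
#' @param center `(row, col)` of the window center; default image center.
#' @param size window side in pixels (>= 1), default 128.
#' @return The cropped [image2d()] (spacing preserved).
#' @export
crop_roi <- function(image, center = NULL, size = 128L) {
  size <- as.integer(size)
  if (size < 1L) stop("size must be >= 1")
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  if (is.null(center)) center <- c(H %/% 2 + 1L, W %/% 2 + 1L)
  r0 <- as.integer(round(center[1])) - size %/% 2L
  c0 <- as.integer(round(center[2])) - size %/% 2L
  out <- matrix(0, size, size)
  rr <- r0 + seq_len(size) - 1L
  cc <- c0 + seq_len(size) - 1L
  rok <- which(rr >= 1L & rr <= H)
  cok <- which(cc >= 1L & cc <= W)
  if (length(rok) && length(cok))
    out[rok, cok] <- px[rr[rok], cc[cok]]
  res <- image
  res$pixels <- out
  res
}
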