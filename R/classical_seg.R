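#' Region-growing specification
#'
#' @param seeds list of `(row, col)` integer pairs (1-based), or a 2-column
#'   matrix, one seed per region to segment.
#' @param delta gray-difference growth criterion: a neighbour joins a region
#'   while `|gray - mean(region)| <= delta`. Default 25 gray levels.
#' @param connectivity 4 or 8 neighbourhood, default 4.
#' @param compare `"mean"` compares candidates against the running region
#'   mean (default); `"seed"` against the fixed seed gray value.
#' @return An object of class `RegionGrowSpec`.
#' @export
region_grow_spec <- function(seeds, delta = 25, connectivity = 4L,
                             compare = c("mean", "seed")) {
  if (is.matrix(seeds)) seeds <- lapply(seq_len(nrow(seeds)), function(i) seeds[i, ])
  if (!is.list(seeds)) seeds <- list(seeds)
  seeds <- lapply(seeds, function(s) as.integer(round(s[1:2])))
  if (delta < 0) stop("delta must be >= 0")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(seeds = seeds, delta = delta, connectivity = connectivity,
                 compare = match.arg(compare)),
            class = "RegionGrowSpec")
}

neighbour_shifts <- function(connectivity) {
  s <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    s <- c(s, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  s
}

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_logical <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
  rok <- rs >= 1L & rs <= H; cok <- cs >= 1L & cs <= W
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Seeded region growing
#'
#' Grows one region per seed by deterministic batch absorption: at each
#' iteration all unclaimed neighbour pixels whose gray value differs from
#' the current region reference (running mean, or seed value) by at most
#' `delta` are absorbed simultaneously, then the reference is updated;
#' growth stops when no neighbour qualifies. Regions are grown in seed
#' order and a pixel already claimed by an earlier region is never
#' re-assigned. The batch rule makes the result independent of any pixel
#' visiting order.
#'
#' @param image an [image2d()].
#' @param spec a [region_grow_spec()].
#' @return A [label_mask()]: pixels of region k carry label k, others 0.
#' @examples
#' img <- image2d(matrix(c(0, 0, 100, 100), 2, 2))
#' region_grow(img, region_grow_spec(list(c(1, 1)), delta = 25))$labels
#' @export
region_grow <- function(image, spec) {
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  for (s in spec$seeds)
    if (s[1] < 1L || s[1] > H || s[2] < 1L || s[2] > W)
      stop("seed (", s[1], ",", s[2], ") out of image bounds")
  shifts <- neighbour_shifts(spec$connectivity)
  claimed <- matrix(FALSE, H, W)
  labels <- matrix(0L, H, W)
  for (k in seq_along(spec$seeds)) {
    s <- spec$seeds[[k]]
    if (claimed[s[1], s[2]]) next
    region <- matrix(FALSE, H, W)
    region[s[1], s[2]] <- TRUE
    rsum <- px[s[1], s[2]]; rn <- 1L
    seed_val <- px[s[1], s[2]]
    repeat {
      ref <- if (spec$compare == "mean") rsum / rn else seed_val
      nb <- Reduce(`|`, lapply(shifts, function(d) shift_logical(region, d[1], d[2])))
      cand <- nb & !region & !claimed
      if (!any(cand)) break
      ok <- cand & abs(px - ref) <= spec$delta
      if (!any(ok)) break
      region <- region | ok
      rsum <- rsum + sum(px[ok]); rn <- rn + sum(ok)
    }
    labels[region] <- k
    claimed <- claimed | region
  }
  label_mask(labels, classes = 0:length(spec$seeds), spacing = image$spacing)
}

threshold_result <- function(threshold, curve, method) {
  structure(list(threshold = threshold, criterion_curve = curve, method = method),
            class = "ThresholdResult")
}

#' @export
print.ThresholdResult <- function(x, ...) {
  cat(sprintf("<ThresholdResult %s: T = %s>\n", x$method, format(x$threshold)))
  invisible(x)
}

check_hist <- function(hist) {
  if (hist$total <= 0) stop("empty histogram")
  if (sum(hist$counts > 0) < 2L)
    stop("degenerate histogram: fewer than two populated bins")
  invisible(TRUE)
}

#' Otsu threshold (maximum between-class variance)
#'
#' For each candidate T the foreground is the gray range `<= T` with weight
#' w0 and mean u0, the background the complement (w1, u1); the returned
#' integer T maximizes the between-class variance
#' `g(T) = w0 * w1 * (u0 - u1)^2`, ties broken by the smallest T.
#'
#' @param hist a [to_histogram()] result with at least two populated bins.
#' @return A `ThresholdResult` with the 256-entry criterion curve
#'   (`NA` where one side is empty and g is undefined).
#' @export
otsu_threshold <- function(hist) {
  check_hist(hist)
  p <- hist_probs(hist)
  g <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(g * p)
  mu <- m0[256]
  w1 <- 1 - w0
  u0 <- ifelse(w0 > 0, m0 / w0, NA_real_)
  u1 <- ifelse(w1 > 0, (mu - m0) / w1, NA_real_)
  curve <- w0 * w1 * (u0 - u1)^2
  curve[w0 == 0 | w1 == 0] <- NA_real_
  t_best <- which.max(curve) - 1L  # which.max: first (smallest) maximizer, NAs skipped
  threshold_result(t_best, curve, "otsu")
}

#' Iterative (fixed-point) threshold
#'
#' Iterates `T <- (mu1(T) + mu2(T)) / 2` where mu1 is the mean gray of the
#' pixels `<= T` and mu2 of the pixels `> T`, starting from the overall mean
#' gray (`init = "mean"`, suited when target and background areas are
#' comparable) or from the midrange of populated gray levels
#' (`init = "midrange"`, suited when they differ greatly), until two
#' consecutive T differ by less than `eps`.
#'
#' @param hist a [to_histogram()] result with at least two populated bins.
#' @param eps convergence tolerance in gray levels (default 0.5).
#' @param init initialization rule, `"mean"` or `"midrange"`.
#' @return A `ThresholdResult` with real-valued `threshold` satisfying the
#'   fixed-point equation within `eps`; `iterations` attribute records the
#'   trajectory.
#' @export
iterative_threshold <- function(hist, eps = 0.5, init = c("mean", "midrange")) {
  check_hist(hist)
  init <- match.arg(init)
  p <- hist_probs(hist)
  g <- 0:255
  pop <- which(p > 0) - 1L
  t_cur <- if (init == "mean") sum(g * p)
           else (min(pop) + max(pop)) / 2
  side_mean <- function(idx) {
    w <- sum(p[idx])
    if (w > 0) sum(g[idx] * p[idx]) / w else NA_real_
  }
  traj <- t_cur
  for (it in 1:500) {
    lo <- which(g <= t_cur); hi <- which(g > t_cur)
    mu1 <- side_mean(lo)
    mu2 <- side_mean(hi)
    # a side left empty takes the nearest populated gray level as its mean
    if (is.na(mu1)) mu1 <- min(pop[pop > t_cur])
    if (is.na(mu2)) mu2 <- max(pop[pop <= t_cur])
    t_new <- (mu1 + mu2) / 2
    traj <- c(traj, t_new)
    if (abs(t_new - t_cur) < eps) {
      # return the pre-image: |t_cur - map(t_cur)| = |t_cur - t_new| < eps,
      # so the returned value satisfies the fixed-point equation within eps
      # (the post-update iterate need not, when the class means jump at a
      # populated bin boundary)
      res <- threshold_result(t_cur, rep(NA_real_, 256), "iterative")
      attr(res, "iterations") <- traj
      return(res)
    }
    t_cur <- t_new
  }
  stop("iterative threshold did not converge within 500 iterations")
}

#' Maximum-entropy (Kapur) threshold
#'
#' The gray range `<= T` forms region S0 with cumulative probability
#' `P_T = sum_{i<=T} p_i`; the returned integer T maximizes the summed
#' Shannon entropies `H(S0) + H(S1)` of the two induced distributions
#' (natural log, `0 ln 0 = 0`). Candidates with `P_T` equal to 0 or 1 are
#' excluded (the criterion is undefined there); ties break to the
#' smallest T.
#'
#' @param hist a [to_histogram()] result with at least two populated bins.
#' @return A `ThresholdResult` with the 256-entry criterion curve.
#' @export
max_entropy_threshold <- function(hist) {
  check_hist(hist)
  p <- hist_probs(hist)
  plogp <- ifelse(p > 0, p * log(p), 0)
  PT <- cumsum(p)
  S <- cumsum(plogp)
  Stot <- S[256]
  H0 <- ifelse(PT > 0, log(PT) - S / PT, NA_real_)
  H1 <- ifelse(PT < 1, log(1 - PT) - (Stot - S) / (1 - PT), NA_real_)
  curve <- H0 + H1
  curve[PT <= 0 | PT >= 1] <- NA_real_
  t_best <- which.max(curve) - 1L
  threshold_result(t_best, curve, "max_entropy")
}

#' Apply a gray-level threshold
#'
#' Labels the bright side as foreground: label 1 where `floor(gray) > T`,
#' 0 otherwise (the atrial blood pools are brighter than myocardium on
#' short-axis MRI, so foreground = blood pool).
#'
#' @param image an [image2d()].
#' @param T gray-level threshold.
#' @return A binary [label_mask()] with classes `c(0, 1)`.
#' @export
threshold_apply <- function(image, T) {
  labels <- matrix(0L, nrow(image$pixels), ncol(image$pixels))
  labels[floor(image$pixels) > T] <- 1L
  label_mask(labels, classes = 0:1, spacing = image$spacing)
}
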