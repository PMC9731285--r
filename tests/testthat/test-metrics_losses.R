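mk <- function(m, classes = 0:2, spacing = c(1, 1))
  label_mask(m, classes = classes, spacing = spacing)

test_that("DSC reproduces its defining ratio and conventions", {
  a <- mk(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2, 4))
  b <- mk(matrix(c(1, 1, 0, 0, 1, 1, 0, 0), 2, 4))
  expect_equal(dsc(a, b, 1), 0.5)           # |A|=|B|=4, overlap 2
  expect_equal(dsc(a, a, 1), 1)
  expect_equal(dsc(a, b, 2), 1)             # both empty -> 1 by convention
  z <- mk(matrix(0L, 2, 4))
  expect_equal(dsc(a, z, 1), 0)             # exactly one empty -> 0
  expect_error(dsc(a, mk(matrix(0L, 3, 3)), 1), "shapes differ")
})

test_that("DSC matches set-counting oracle and is symmetric", {
  for (i in 1:100) {
    set.seed(i)
    H <- sample(4:16, 1); W <- sample(4:16, 1)
    a <- mk(matrix(sample(0:2, H * W, TRUE), H, W))
    b <- mk(matrix(sample(0:2, H * W, TRUE), H, W))
    for (cl in 0:2) {
      want <- dsc_oracle(as.vector(a$labels), as.vector(b$labels), cl)
      expect_identical(dsc(a, b, cl), want)
      expect_identical(dsc(a, b, cl), dsc(b, a, cl))
      expect_true(dsc(a, b, cl) >= 0 && dsc(a, b, cl) <= 1)
    }
  }
})

test_that("Hausdorff distance handles identity, 3-4-5 and spacing", {
  a <- mk(rand_blob_mask(10, 10, seed = 1), classes = 0:1)
  expect_equal(hausdorff(a, a, 1), 0)

  p1 <- matrix(0L, 6, 6); p1[1, 1] <- 1L
  p2 <- matrix(0L, 6, 6); p2[4, 5] <- 1L
  expect_equal(hausdorff(mk(p1, 0:1), mk(p2, 0:1), 1), 5)  # 3-4-5 triangle

  # physical spacing scales the distance
  expect_equal(hausdorff(mk(p1, 0:1, c(2, 2)), mk(p2, 0:1, c(2, 2)), 1), 10)

  expect_error(hausdorff(mk(p1, 0:1), mk(matrix(0L, 6, 6), 0:1), 1),
               "undefined")
  expect_error(hausdorff(mk(p1, 0:1, c(1, 1)), mk(p2, 0:1, c(1, 2)), 1),
               "spacings differ")
})

test_that("Hausdorff equals the all-pairs boundary oracle on random masks", {
  for (i in 1:50) {
    set.seed(i)
    H <- sample(8:32, 1); W <- sample(8:32, 1)
    a <- mk(rand_blob_mask(H, W), classes = 0:1)
    b <- mk(rand_blob_mask(H, W), classes = 0:1)
    got <- hausdorff(a, b, 1)
    want <- hd_oracle(a$labels, b$labels, 1L)
    expect_equal(got, want, tolerance = 1e-9)
    expect_identical(hausdorff(a, b, 1), hausdorff(b, a, 1))
    expect_equal(hausdorff(a, a, 1), 0)
    expect_equal(dsc(a, a, 1), 1)
  }
})

test_that("dilating a disjoint region never increases the directed distance", {
  dilate <- function(m) {
    H <- nrow(m); W <- ncol(m)
    out <- m
    out[-1, ] <- out[-1, ] | m[-H, ]; out[-H, ] <- out[-H, ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -W]; out[, -W] <- out[, -W] | m[, -1]
    out
  }
  bp <- function(m) {
    pts <- atriaseg:::boundary_points(m + 0L, 1L)
    cbind(pts[, 1], pts[, 2])
  }
  A <- matrix(FALSE, 20, 20); A[3:5, 3:5] <- TRUE
  B <- matrix(FALSE, 20, 20); B[14:16, 12:15] <- TRUE
  h0 <- atriaseg:::directed_hd(bp(A), bp(B))
  for (k in 1:3) {
    B <- dilate(B)
    h1 <- atriaseg:::directed_hd(bp(A), bp(B))
    expect_lte(h1, h0 + 1e-12)
    h0 <- h1
  }
})

test_that("Dice loss attains its analytic extremes", {
  g <- matrix(0L, 6, 6); g[2:4, 2:4] <- 1L
  target <- mk(g, 0:1)
  perfect <- array(0, c(2, 6, 6))
  perfect[1, , ] <- 1 - g; perfect[2, , ] <- g
  pm <- probability_map(perfect, classes = 0:1)
  res <- dice_loss(pm, target, 1)
  expect_equal(res$D, 1, tolerance = 1e-6)
  expect_equal(res$loss, 0, tolerance = 1e-6)

  allbg <- array(0, c(2, 6, 6)); allbg[1, , ] <- 1
  res0 <- dice_loss(probability_map(allbg, 0:1), target, 1)
  expect_equal(res0$D, 0, tolerance = 1e-6)
  expect_equal(res0$loss, 1, tolerance = 1e-6)
})

test_that("Dice loss matches independent summation on random inputs", {
  for (i in 1:50) {
    set.seed(i)
    H <- 5; W <- 7
    raw <- array(runif(2 * H * W), c(2, H, W))
    sums <- raw[1, , ] + raw[2, , ]
    raw[1, , ] <- raw[1, , ] / sums; raw[2, , ] <- raw[2, , ] / sums
    pm <- probability_map(raw, 0:1)
    tg <- mk(rand_blob_mask(H, W), 0:1)
    got <- dice_loss(pm, tg, 1)$D
    num <- den_p <- den_g <- 0
    for (r in 1:H) for (c in 1:W) {
      p <- raw[2, r, c]; gg <- as.numeric(tg$labels[r, c] == 1L)
      num <- num + p * gg; den_p <- den_p + p^2; den_g <- den_g + gg^2
    }
    expect_equal(got, (2 * num + 1e-6) / (den_p + den_g + 1e-6),
                 tolerance = 1e-12)
    # only the class channel matters: relabeling the background (0 -> 7)
    # leaves the class-1 loss untouched
    tg2 <- mk(ifelse(tg$labels == 1L, 1L, 7L), c(1L, 7L))
    expect_equal(dice_loss(pm, tg2, 1)$D, got, tolerance = 1e-12)
  }
})

test_that("Dice gradient is stationary at the optimum and zero on empty truth", {
  g <- matrix(0L, 5, 5); g[2:3, 2:3] <- 1L
  target <- mk(g, 0:1)
  perfect <- array(0, c(2, 5, 5))
  perfect[1, , ] <- 1 - g; perfect[2, , ] <- g
  gr <- dice_loss_grad(probability_map(perfect, 0:1), target, 1)
  expect_lt(max(abs(gr[g == 1L])), 1e-6)

  set.seed(3)
  raw <- array(runif(2 * 5 * 5), c(2, 5, 5))
  sums <- raw[1, , ] + raw[2, , ]
  raw[1, , ] <- raw[1, , ] / sums; raw[2, , ] <- raw[2, , ] / sums
  empty <- mk(matrix(0L, 5, 5), 0:1)
  gr0 <- dice_loss_grad(probability_map(raw, 0:1), empty, 1)
  # g = 0 everywhere makes sum(p g) = 0; only the 1e-6 smoothing remains
  expect_true(all(abs(gr0) < 1e-6))
})

test_that("Dice gradient matches central finite differences", {
  worst <- 0
  for (i in 1:50) {
    set.seed(i)
    H <- 4; W <- 5
    raw <- array(runif(2 * H * W, 0.05, 0.95), c(2, H, W))
    sums <- raw[1, , ] + raw[2, , ]
    raw[1, , ] <- raw[1, , ] / sums; raw[2, , ] <- raw[2, , ] / sums
    tg <- mk(rand_blob_mask(H, W), 0:1)
    pm <- probability_map(raw, 0:1)
    gr <- dice_loss_grad(pm, tg, 1)
    eps <- 1e-5
    for (j in 1:6) {
      r <- sample(H, 1); c <- sample(W, 1)
      up <- raw; up[2, r, c] <- up[2, r, c] + eps
      dn <- raw; dn[2, r, c] <- dn[2, r, c] - eps
      Dp <- dice_loss(structure(list(probs = up, classes = 0:1),
                                class = "ProbabilityMap"), tg, 1)$D
      Dm <- dice_loss(structure(list(probs = dn, classes = 0:1),
                                class = "ProbabilityMap"), tg, 1)$D
      fd <- (Dp - Dm) / (2 * eps)
      rel <- abs(fd - gr[r, c]) / max(abs(fd), abs(gr[r, c]), 1e-8)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("metric reports aggregate by class then overall", {
  rows <- data.frame(image_id = rep(c("a", "b"), each = 2),
                     class = rep(1:2, 2),
                     dsc = c(0.9, 0.8, 0.7, 0.6),
                     hd_mm = c(1, 2, 3, NA))
  rep <- metric_report(rows)
  expect_equal(rep$per_class$dsc, c(0.8, 0.7))
  expect_equal(rep$per_class$hd_mm, c(2, 2))
  expect_equal(rep$per_class$n_missing_hd, c(0L, 1L))
  expect_equal(rep$mean_dsc, 0.75)
  expect_equal(rep$n_images, 2L)
})
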