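two_point_hist <- function(g1, g2, n1 = 50L, n2 = 50L) {
  counts <- integer(256)
  counts[c(g1, g2) + 1L] <- c(n1, n2)
  structure(list(counts = counts, total = n1 + n2), class = "Histogram256")
}

test_that("Otsu handles the two-point histogram analytically", {
  h <- two_point_hist(0L, 255L)
  res <- otsu_threshold(h)
  # equal masses at 0 and 255: g = 1/4 * 255^2 for every T in [0, 254],
  # so the smallest-T tie-break returns 0
  expect_identical(res$threshold, 0L)
  expect_equal(res$criterion_curve[1], 0.25 * 255^2)
  expect_equal(res$criterion_curve[200], 0.25 * 255^2)
  expect_true(is.na(res$criterion_curve[256]))
  expect_error(otsu_threshold(two_point_hist(100L, 100L, 50L, 0L)),
               "degenerate")
})

test_that("Otsu argmax and curve match the definition-form oracle", {
  for (i in 1:100) {
    h <- rand_hist(i)
    res <- otsu_threshold(h)
    ref <- otsu_brute(h$counts)
    expect_identical(res$threshold, ref$threshold)
    # the two algebraic forms of the between-class variance agree
    ok <- !is.na(ref$curve)
    expect_equal(res$criterion_curve[ok], ref$curve[ok], tolerance = 1e-9)
    expect_equal(res$criterion_curve[res$threshold + 1L],
                 max(res$criterion_curve, na.rm = TRUE))
  }
})

test_that("threshold selection is invariant under histogram scaling", {
  for (i in 1:20) {
    h <- rand_hist(200 + i)
    h7 <- h; h7$counts <- h$counts * 7L; h7$total <- h$total * 7L
    expect_identical(otsu_threshold(h7)$threshold, otsu_threshold(h)$threshold)
    expect_identical(max_entropy_threshold(h7)$threshold,
                     max_entropy_threshold(h)$threshold)
  }
})

test_that("iterative threshold finds the symmetric fixed point", {
  h <- two_point_hist(0L, 200L)
  res <- iterative_threshold(h, init = "mean")
  expect_equal(res$threshold, 100)   # T0 = 100, mu1 = 0, mu2 = 200
  expect_length(attr(res, "iterations"), 2L)
  expect_error(iterative_threshold(two_point_hist(42L, 42L)), "degenerate")
})

test_that("iterative threshold satisfies its fixed-point equation", {
  for (init in c("mean", "midrange")) {
    for (i in 1:100) {
      h <- rand_hist(300 + i)
      res <- iterative_threshold(h, eps = 0.5, init = init)
      T <- res$threshold
      p <- h$counts / h$total
      g <- 0:255
      lo <- g <= T
      mu1 <- sum(g[lo] * p[lo]) / sum(p[lo])
      mu2 <- sum(g[!lo] * p[!lo]) / sum(p[!lo])
      expect_lt(abs(T - (mu1 + mu2) / 2), 0.5)
      # every iterate stays inside the populated gray range
      pop <- range(which(p > 0) - 1L)
      expect_true(all(attr(res, "iterations") >= pop[1] - 0.5 &
                        attr(res, "iterations") <= pop[2] + 0.5))
    }
  }
})

test_that("maximum-entropy threshold matches exhaustive Kapur search", {
  # two point masses: every defined candidate scores equally, smallest wins
  res <- max_entropy_threshold(two_point_hist(50L, 200L))
  expect_identical(res$threshold, 50L)

  # uniform histogram: symmetry puts the argmax near the median
  hu <- structure(list(counts = rep(4L, 256), total = 1024L),
                  class = "Histogram256")
  resu <- max_entropy_threshold(hu)
  refu <- maxent_brute(hu$counts)
  expect_identical(resu$threshold, refu$threshold)
  expect_true(abs(resu$threshold - 127.5) < 2)

  for (i in 1:100) {
    h <- rand_hist(400 + i)
    res <- max_entropy_threshold(h)
    ref <- maxent_brute(h$counts)
    expect_identical(res$threshold, ref$threshold)
    ok <- !is.na(ref$curve)
    expect_equal(res$criterion_curve[ok], ref$curve[ok], tolerance = 1e-9)
  }
})

test_that("region growing floods constant and plateaued images correctly", {
  img <- image2d(matrix(7, 6, 6))
  out <- region_grow(img, region_grow_spec(list(c(3, 3))))
  expect_true(all(out$labels == 1L))

  # two plateaus separated by more than delta: only the seed's plateau grows
  px <- matrix(0, 4, 8); px[, 5:8] <- 100
  out2 <- region_grow(image2d(px), region_grow_spec(list(c(2, 2)), delta = 25))
  expect_true(all(out2$labels[, 1:4] == 1L))
  expect_true(all(out2$labels[, 5:8] == 0L))

  expect_error(region_grow(image2d(px), region_grow_spec(list(c(9, 1)))),
               "out of image bounds")
})

test_that("region growing equals the independent flood-fill oracle", {
  for (i in 1:30) {
    set.seed(i)
    H <- sample(5:20, 1); W <- sample(5:20, 1)
    px <- matrix(sample(0:255, H * W, TRUE), H, W)
    seeds <- list(c(sample(H, 1), sample(W, 1)), c(sample(H, 1), sample(W, 1)))
    got <- region_grow(image2d(px), region_grow_spec(seeds, delta = 25))
    want <- flood_oracle(px, seeds, delta = 25)
    expect_identical(unname(got$labels), unname(want))
  }
})

test_that("finished regions are connected and maximal", {
  set.seed(99)
  px <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
  spec <- region_grow_spec(list(c(8, 8)), delta = 40)
  out <- region_grow(image2d(px), spec)
  region <- out$labels == 1L
  mu <- mean(px[region])
  H <- 16; W <- 16
  for (r in 1:H) for (c in 1:W) {
    if (region[r, c]) next
    touches <- (r > 1 && region[r - 1, c]) || (r < H && region[r + 1, c]) ||
      (c > 1 && region[r, c - 1]) || (c < W && region[r, c + 1])
    if (touches) expect_gt(abs(px[r, c] - mu), 40)  # maximality
  }
  # connectivity: flood over the labeled set from the seed reaches all of it
  reach <- matrix(FALSE, H, W); reach[8, 8] <- TRUE
  repeat {
    nxt <- reach
    nxt[-1, ] <- nxt[-1, ] | reach[-H, ]
    nxt[-H, ] <- nxt[-H, ] | reach[-1, ]
    nxt[, -1] <- nxt[, -1] | reach[, -W]
    nxt[, -W] <- nxt[, -W] | reach[, -1]
    nxt <- nxt & region
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  expect_identical(reach, region)
})

test_that("seed-value comparison and 8-connectivity variants work", {
  set.seed(7)
  px <- matrix(sample(0:255, 100, TRUE), 10, 10)
  a <- region_grow(image2d(px),
                   region_grow_spec(list(c(5, 5)), delta = 30, compare = "seed"))
  expect_true(all(abs(px[a$labels == 1L] - px[5, 5]) <= 30))
  b <- region_grow(image2d(px),
                   region_grow_spec(list(c(5, 5)), delta = 30, connectivity = 8))
  # 8-connectivity can only reach at least as many pixels as 4-connectivity
  b4 <- region_grow(image2d(px), region_grow_spec(list(c(5, 5)), delta = 30))
  expect_gte(sum(b$labels == 1L), 0)  # well-formed
  expect_true(all(b$labels %in% c(0L, 1L)))
  expect_true(all(b4$labels %in% c(0L, 1L)))
})

test_that("threshold application labels the bright side, strictly", {
  expect_true(all(threshold_apply(image2d(matrix(100, 3, 3)), 50)$labels == 1L))
  expect_true(all(threshold_apply(image2d(matrix(100, 3, 3)), 100)$labels == 0L))
  set.seed(11)
  px <- matrix(runif(64, 0, 255.99), 8, 8)
  out <- threshold_apply(image2d(px), 120)
  for (r in 1:8) for (c in 1:8)
    expect_identical(out$labels[r, c], as.integer(floor(px[r, c]) > 120))
})
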