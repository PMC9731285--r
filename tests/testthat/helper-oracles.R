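# Independent oracles and fixture generators. Everything here is written
# directly from the defining formulas (sums over explicit loops), not by
# calling package internals, so tests compare two genuinely separate
# computations.

rand_hist <- function(seed) {
  set.seed(seed)
  counts <- integer(256)
  k <- sample(2:40, 1)
  bins <- sample(0:255, k)
  counts[bins + 1L] <- sample(1:500, k, replace = TRUE)
  structure(list(counts = counts, total = sum(counts)), class = "Histogram256")
}

# Otsu criterion evaluated from the definition form of the between-class
# variance, g(T) = w0 (u0 - u)^2 + w1 (u1 - u)^2, by explicit summation.
otsu_brute <- function(counts) {
  total <- sum(counts)
  g <- 0:255
  p <- counts / total
  u <- sum(g * p)
  crit <- rep(NA_real_, 256)
  for (T in 0:255) {
    lo <- which(g <= T)
    w0 <- sum(p[lo]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    u0 <- sum(g[lo] * p[lo]) / w0
    u1 <- sum(g[-lo] * p[-lo]) / w1
    crit[T + 1L] <- w0 * (u0 - u)^2 + w1 * (u1 - u)^2
  }
  list(threshold = which.max(crit) - 1L, curve = crit)
}

# Kapur criterion H(S0) + H(S1) by explicit summation with 0 ln 0 = 0.
maxent_brute <- function(counts) {
  p <- counts / sum(counts)
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  crit <- rep(NA_real_, 256)
  for (T in 0:255) {
    PT <- sum(p[seq_len(T + 1L)])
    if (PT <= 0 || PT >= 1) next
    crit[T + 1L] <- ent(p[seq_len(T + 1L)] / PT) +
      ent(p[(T + 2L):256] / (1 - PT))
  }
  list(threshold = which.max(crit) - 1L, curve = crit)
}

# Batch-absorption flood fill written with explicit worklist scans: each
# round collects every unclaimed neighbour of the region, keeps those within
# delta of the current region mean, absorbs them all, and recomputes.
flood_oracle <- function(px, seeds, delta = 25, connectivity = 4L) {
  H <- nrow(px); W <- ncol(px)
  labels <- matrix(0L, H, W)
  nb <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    nb <- c(nb, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  for (k in seq_along(seeds)) {
    s <- seeds[[k]]
    if (labels[s[1], s[2]] != 0L) next
    region <- matrix(FALSE, H, W)
    region[s[1], s[2]] <- TRUE
    repeat {
      mu <- mean(px[region])
      cand <- list()
      for (r in seq_len(H)) for (c in seq_len(W)) {
        if (!region[r, c]) next
        for (d in nb) {
          rr <- r + d[1]; cc <- c + d[2]
          if (rr < 1 || rr > H || cc < 1 || cc > W) next
          if (region[rr, cc] || labels[rr, cc] != 0L) next
          cand[[length(cand) + 1L]] <- c(rr, cc)
        }
      }
      grew <- FALSE
      for (p in cand) {
        if (abs(px[p[1], p[2]] - mu) <= delta && !region[p[1], p[2]]) {
          region[p[1], p[2]] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    labels[region] <- k
  }
  labels
}

dsc_oracle <- function(a, b, cls) {
  nA <- 0L; nB <- 0L; nAB <- 0L
  for (i in seq_along(a)) {
    inA <- a[i] == cls; inB <- b[i] == cls
    nA <- nA + inA; nB <- nB + inB; nAB <- nAB + (inA && inB)
  }
  if (nA + nB == 0) return(1)
  2 * nAB / (nA + nB)
}

# Boundary pixels by explicit neighbour checks; directed distances by a full
# double loop over all boundary-point pairs.
hd_oracle <- function(la, lb, cls, spacing = c(1, 1)) {
  bnd <- function(m) {
    H <- nrow(m); W <- ncol(m)
    pts <- NULL
    for (r in seq_len(H)) for (c in seq_len(W)) {
      if (m[r, c] != cls) next
      edge <- r == 1 || r == H || c == 1 || c == W
      if (!edge) {
        edge <- m[r - 1, c] != cls || m[r + 1, c] != cls ||
          m[r, c - 1] != cls || m[r, c + 1] != cls
      }
      if (edge) pts <- rbind(pts, c(r * spacing[1], c * spacing[2]))
    }
    pts
  }
  A <- bnd(la); B <- bnd(lb)
  dir_h <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        d <- sqrt((P[i, 1] - Q[j, 1])^2 + (P[i, 2] - Q[j, 2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(dir_h(A, B), dir_h(B, A))
}

# A random mask with one or two solid random rectangles of the class, so the
# class is guaranteed present.
rand_blob_mask <- function(H, W, cls = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0L, H, W)
  for (i in seq_len(sample(1:2, 1))) {
    r0 <- sample(1:(H - 2), 1); c0 <- sample(1:(W - 2), 1)
    r1 <- min(H, r0 + sample(1:6, 1)); c1 <- min(W, c0 + sample(1:6, 1))
    m[r0:r1, c0:c1] <- cls
  }
  m
}

## ---- closed-form parameter counts (layer inventory) -----------------------

n_conv <- function(K, Cin, Cout) K * K * Cin * Cout + Cout
n_bn <- function(C, norm) if (norm == "batch") 2 * C else 0
n_convT <- function(Cin, Cout) 4 * Cin * Cout + Cout

n_block <- function(Cin, Cout, spec) {
  n <- n_conv(3, Cin, Cout) + n_bn(Cout, spec$norm) +
    n_conv(3, Cout, Cout) + n_bn(Cout, spec$norm)
  if (spec$block == "residual" && Cin != Cout) n <- n + n_conv(1, Cin, Cout)
  n
}

n_u_module <- function(C, spec) {
  d <- spec$inner_depth; w <- spec$inner_widen
  n <- 0
  for (l in seq_len(d)) {
    Cin <- if (l == 1) C else C * w^(l - 2)
    n <- n + n_block(Cin, C * w^(l - 1), spec)
  }
  n <- n + n_block(C * w^(d - 1), C * w^d, spec)
  for (l in seq_len(d)) {
    Cl <- C * w^(l - 1)
    n <- n + n_convT(C * w^l, Cl) + n_block(2 * Cl, Cl, spec)
  }
  n
}

n_uunet <- function(spec) {
  Fb <- spec$base_filters; L <- spec$outer_depth
  n <- n_conv(3, spec$in_channels, Fb) + n_bn(Fb, spec$norm)
  for (i in seq_len(L)) {
    Ci <- Fb * 2^(i - 1)
    if (i > 1) n <- n + n_conv(1, Ci / 2, Ci)       # down transition
    n <- n + 2 * n_u_module(Ci, spec)               # encoder + decoder
    if (i > 1) n <- n + n_convT(Ci, Ci / 2)         # outer up path
  }
  n + n_conv(1, Fb, spec$n_classes)
}

n_deconvnet <- function(spec) {
  Fb <- spec$base_filters
  ch <- Fb * c(1, 2, 4, 4, 4)
  n <- 0
  for (s in 1:5) {
    Cin <- if (s == 1) spec$in_channels else ch[s - 1]
    n <- n + n_conv(3, Cin, ch[s]) + n_bn(ch[s], spec$norm)
    if (s <= 2) n <- n + n_conv(3, ch[s], ch[s]) + n_bn(ch[s], spec$norm)
  }
  for (s in 5:1) {
    Cd <- if (s == 1) Fb else ch[s - 1]
    n <- n + n_convT(ch[s], Cd) + n_conv(3, Cd, Cd) + n_bn(Cd, spec$norm)
  }
  n + n_conv(1, Fb, spec$n_classes)
}

# Zero every F-path parameter of a standalone residual block so only the
# identity path remains.
zero_f_path <- function(blk) {
  for (nm in ls(blk$params)) {
    if (grepl("\\.c[12]\\.", nm) || grepl("\\.n[12]\\.", nm))
      blk$params[[nm]] <- blk$params[[nm]] * 0
  }
  invisible(blk)
}

tiny_phantom_manifest <- function(n, size, dir, seed, ...) {
  make_dataset(n, phantom_spec(size = c(size, size), ...), seed = seed,
               out_dir = dir)
}
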