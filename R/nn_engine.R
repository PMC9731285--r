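# Minimal reverse-mode autodiff over (H, W, C, N) arrays.
#
# A forward pass optionally records nodes on a tape (training); without a
# tape every op returns a plain array (inference). Nodes are environments
# holding the value, the accumulated gradient, their parents and a backward
# closure; creation order is a topological order, so backpropagation is a
# single reverse sweep.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

tape_active <- function() !is.null(.ag$tape)

ag_start_tape <- function() {
  .ag$tape <- new.env(parent = emptyenv())
  .ag$tape$nodes <- list()
  invisible(.ag$tape)
}

ag_stop_tape <- function() {
  t <- .ag$tape
  .ag$tape <- NULL
  invisible(t)
}

is_node <- function(x) is.environment(x)

nval <- function(x) if (is_node(x)) x$val else x

ag_node <- function(val, parents = list(), backfn = NULL, pname = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  n$pname <- pname
  t <- .ag$tape
  t$nodes[[length(t$nodes) + 1L]] <- n
  n
}

acc_grad <- function(node, g) {
  if (!is_node(node)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backward sweep from a scalar loss node; returns named list of gradients
# for parameter nodes (those with a pname).
ag_backward <- function(loss, tape) {
  loss$grad <- 1
  grads <- list()
  for (i in rev(seq_along(tape$nodes))) {
    n <- tape$nodes[[i]]
    if (is.null(n$grad)) next
    if (!is.null(n$pname)) grads[[n$pname]] <- n$grad
    if (is.null(n$backfn)) next
    pg <- n$backfn(n$grad)
    for (j in seq_along(n$parents)) acc_grad(n$parents[[j]], pg[[j]])
  }
  grads
}

## ---- ops ------------------------------------------------------------------

op_conv2d <- function(x, w, b, K, pad) {
  y <- cpp_conv2d_fw(nval(x), nval(w), nval(b), K, pad)
  if (!tape_active()) return(y)
  xa <- nval(x); wa <- nval(w)
  ag_node(y, list(x, w, b), function(gy) {
    bw <- cpp_conv2d_bw(xa, wa, gy, K, pad)
    list(bw$dx, bw$dw, bw$db)
  })
}

op_convT2 <- function(x, w, b) {
  y <- cpp_convT2_fw(nval(x), nval(w), nval(b))
  if (!tape_active()) return(y)
  xa <- nval(x); wa <- nval(w)
  ag_node(y, list(x, w, b), function(gy) {
    bw <- cpp_convT2_bw(xa, wa, gy)
    list(bw$dx, bw$dw, bw$db)
  })
}

op_maxpool2 <- function(x) {
  fw <- cpp_maxpool2_fw(nval(x))
  if (!tape_active()) return(fw$y)
  d <- dim(nval(x))
  ag_node(fw$y, list(x), function(gy) {
    list(cpp_maxpool2_bw(gy, fw$idx, d[1], d[2]))
  })
}

op_relu <- function(x) {
  y <- cpp_relu_fw(nval(x))
  if (!tape_active()) return(y)
  ag_node(y, list(x), function(gy) list(cpp_relu_bw(gy, y)))
}

op_add <- function(x, y) {
  v <- nval(x) + nval(y)
  if (!tape_active()) return(v)
  ag_node(v, list(x, y), function(gy) list(gy, gy))
}

op_concat <- function(x, y) {
  xa <- nval(x); ya <- nval(y)
  dx <- dim(xa); dy <- dim(ya)
  out <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
  out[, , seq_len(dx[3]), ] <- xa
  out[, , dx[3] + seq_len(dy[3]), ] <- ya
  if (!tape_active()) return(out)
  ag_node(out, list(x, y), function(gy) {
    list(gy[, , seq_len(dx[3]), , drop = FALSE],
         gy[, , dx[3] + seq_len(dy[3]), , drop = FALSE])
  })
}

# Batch normalization over (H, W, N) per channel. `state` carries running
# mean/var for inference; biased variance, momentum 0.1. All broadcasting
# is done by the channel-affine kernel.
op_bnorm <- function(x, gamma, beta, state, nm, training,
                     momentum = 0.1, eps = 1e-5) {
  xa <- nval(x)
  d <- dim(xa)
  M <- d[1] * d[2] * d[4]
  if (is.null(state[[nm]]))
    state[[nm]] <- list(mean = rep(0, d[3]), var = rep(1, d[3]))
  if (training) {
    mu <- cpp_ch_sum(xa) / M
    vr <- pmax(cpp_ch_dot(xa, xa) / M - mu^2, 0)
    st <- state[[nm]]
    state[[nm]] <- list(mean = (1 - momentum) * st$mean + momentum * mu,
                        var = (1 - momentum) * st$var + momentum * vr)
  } else {
    st <- state[[nm]]
    mu <- st$mean; vr <- st$var
  }
  ivar <- 1 / sqrt(vr + eps)
  ga <- nval(gamma)
  y <- cpp_ch_affine(xa, ga * ivar, nval(beta) - ga * mu * ivar)
  if (!tape_active()) return(y)
  ag_node(y, list(x, gamma, beta), function(gy) {
    xhat <- cpp_ch_affine(xa, ivar, -mu * ivar)
    dgamma <- cpp_ch_dot(gy, xhat)
    dbeta <- cpp_ch_sum(gy)
    dxhat <- cpp_ch_affine(gy, ga, numeric(d[3]))
    if (training) {
      s1 <- cpp_ch_sum(dxhat)
      s2 <- cpp_ch_dot(dxhat, xhat)
      dx <- cpp_bn_bw(dxhat, xhat, s1, s2, ivar, M)
    } else {
      dx <- cpp_ch_affine(dxhat, ivar, numeric(d[3]))
    }
    list(dx, dgamma, dbeta)
  })
}

# replicate an (H, W, 1, N) slice along the channel axis
bc_rep <- function(m, C) m[, , rep(1L, C), , drop = FALSE]

softmax_channels <- function(z) {
  d <- dim(z)
  m <- z[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) m <- pmax(m, z[, , c, , drop = FALSE])
  e <- exp(z - bc_rep(m, d[3]))
  s <- e[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) s <- s + e[, , c, , drop = FALSE]
  e / bc_rep(s, d[3])
}

# Softmax over channels followed by the multiclass soft Dice loss
# (mean of 1 - D over foreground channel indices), sums taken over the whole
# batch. Returns a scalar node; gradient composes the analytic Dice
# derivative with the softmax Jacobian.
op_softmax_dice <- function(logits, onehot, fg_idx, smooth = 1e-6) {
  z <- nval(logits)
  d <- dim(z)
  p <- softmax_channels(z)
  Ds <- numeric(length(fg_idx))
  nums <- dens <- numeric(length(fg_idx))
  for (k in seq_along(fg_idx)) {
    ci <- fg_idx[k]
    pc <- p[, , ci, ]
    gc <- onehot[, , ci, ]
    nums[k] <- 2 * sum(pc * gc) + smooth
    dens[k] <- sum(pc * pc) + sum(gc * gc) + smooth
    Ds[k] <- nums[k] / dens[k]
  }
  loss <- mean(1 - Ds)
  if (!tape_active()) return(structure(loss, probs = p, dice = Ds))
  node <- ag_node(loss, list(logits), function(gy) {
    dLdp <- array(0, d)
    for (k in seq_along(fg_idx)) {
      ci <- fg_idx[k]
      pc <- p[, , ci, ]
      gc <- onehot[, , ci, ]
      dDdp <- 2 * (gc * dens[k] - pc * nums[k]) / dens[k]^2
      dLdp[, , ci, ] <- -dDdp / length(fg_idx)
    }
    inner <- p * dLdp
    s <- inner[, , 1, , drop = FALSE]
    for (c in seq_len(d[3])[-1]) s <- s + inner[, , c, , drop = FALSE]
    dz <- p * (dLdp - bc_rep(s, d[3]))
    list(gy * dz)
  })
  node$probs <- p
  node$dice <- Ds
  node
}

## ---- parameters -----------------------------------------------------------

# He init (gain 2) for convolutions feeding a rectifier; plain fan-in
# scaling (gain 1) for linear layers (projections, transposed convolutions,
# the classification head) so activation variance is preserved through
# paths that have no normalization.
fan_init <- function(dims, fan_in, gain) {
  array(stats::rnorm(prod(dims), 0, sqrt(gain / fan_in)), dims)
}

# Parameter provider bound to a model's parameter environment. In "init"
# mode missing parameters are created (seeded RNG assumed active); in run
# mode parameters are wrapped as tape nodes (cached per pass) so gradients
# can be collected by name.
make_provider <- function(params, mode = c("run", "init")) {
  mode <- match.arg(mode)
  cache <- new.env(parent = emptyenv())
  function(name, dims, init = c("he", "linear", "zeros", "ones", "small"),
           fan_in = NULL) {
    init <- match.arg(init)
    if (is.null(params[[name]])) {
      if (mode != "init") stop("unknown parameter: ", name)
      params[[name]] <- switch(init,
        he = fan_init(dims, fan_in %||% dims[1], 2),
        linear = fan_init(dims, fan_in %||% dims[1], 1),
        zeros = array(0, dims),
        ones = array(1, dims),
        small = array(0.1, dims))
    }
    if (!tape_active()) return(params[[name]])
    if (is.null(cache[[name]]))
      cache[[name]] <- ag_node(params[[name]], pname = name)
    cache[[name]]
  }
}

param_count <- function(params)
  sum(vapply(ls(params), function(n) length(params[[n]]), numeric(1)))

## ---- Adam -----------------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

adam_step <- function(params, grads, st, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- (st$t %||% 0) + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(st[[nm]])) st[[nm]] <- list(m = 0 * g, v = 0 * g)
    s <- st[[nm]]
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    st[[nm]] <- s
    mhat <- s$m / (1 - beta1^st$t)
    vhat <- s$v / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}
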