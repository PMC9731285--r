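#' Declarative network specification
#'
#' Describes a segmentation network so that builders can construct it: the
#' nested residual U-network has `outer_depth` outer levels, each an
#' encoder/decoder pair that is itself a small U of `inner_depth` levels
#' built from residual (or plain) convolution blocks. Channel width doubles
#' per outer level from `base_filters`; within a module it is constant by
#' default, or doubles per inner level when `inner_widen = 2`.
#' Input spatial size must be divisible by `2^(outer_depth + inner_depth)`.
#'
#' @param in_channels input channels (1 for grayscale MRI).
#' @param n_classes output classes (3: background, LA, RA).
#' @param base_filters channel width of the first outer level, default 16.
#' @param outer_depth number of outer-U levels, default 3.
#' @param inner_depth number of levels inside each U module, default 2.
#' @param inner_widen channel multiplier per inner level within a U module
#'   (1 = constant width, the default, keeps the model CPU-trainable;
#'   2 doubles toward the inner bottleneck).
#' @param block `"residual"` (default) or `"plain"` convolution blocks.
#' @param norm `"batch"` (default) or `"none"`.
#' @return An object of class `ModelSpec`.
#' @export
model_spec <- function(in_channels = 1L, n_classes = 3L, base_filters = 16L,
                       outer_depth = 3L, inner_depth = 2L, inner_widen = 1L,
                       block = c("residual", "plain"),
                       norm = c("batch", "none")) {
  spec <- structure(list(in_channels = as.integer(in_channels),
                         n_classes = as.integer(n_classes),
                         base_filters = as.integer(base_filters),
                         outer_depth = as.integer(outer_depth),
                         inner_depth = as.integer(inner_depth),
                         inner_widen = as.integer(inner_widen),
                         block = match.arg(block), norm = match.arg(norm)),
                    class = "ModelSpec")
  if (spec$outer_depth < 1L || spec$inner_depth < 1L || spec$base_filters < 1L)
    stop("outer_depth, inner_depth and base_filters must all be >= 1")
  if (!spec$inner_widen %in% c(1L, 2L)) stop("inner_widen must be 1 or 2")
  spec
}

size_multiple <- function(spec, arch = "uunet") {
  if (arch == "deconvnet") 32L else 2L^(spec$outer_depth + spec$inner_depth)
}

check_divisible <- function(H, W, m) {
  if (H %% m != 0 || W %% m != 0)
    stop("input spatial size ", H, "x", W,
         " must be divisible by ", m)
}

## ---- architecture forwards ------------------------------------------------

conv_layer <- function(x, nm, Cin, Cout, K, P, pad = (K - 1L) %/% 2L,
                       init = "he") {
  w <- P(paste0(nm, ".w"), c(K * K * Cin, Cout), init, fan_in = K * K * Cin)
  b <- P(paste0(nm, ".b"), Cout, "zeros")
  op_conv2d(x, w, b, K, pad)
}

norm_relu <- function(x, nm, C, P, spec, training, state,
                      gamma_init = "ones") {
  if (spec$norm == "batch") {
    g <- P(paste0(nm, ".g"), C, gamma_init)
    be <- P(paste0(nm, ".be"), C, "zeros")
    x <- op_bnorm(x, g, be, state, nm, training)
  }
  op_relu(x)
}

convT_layer <- function(x, nm, Cin, Cout, P) {
  w <- P(paste0(nm, ".w"), c(Cin, 4L * Cout), "linear", fan_in = Cin)
  b <- P(paste0(nm, ".b"), Cout, "zeros")
  op_convT2(x, w, b)
}

# F path of a block: two 3x3 convolutions, each followed by normalization
# and rectification. The second normalization's gain starts small (0.1) so
# a fresh residual block is near the identity map: activation variance
# stays bounded with depth and the softmax head starts unsaturated. A gain
# of exactly zero would instead be a dead branch: the rectifier that
# follows it gates gradients at 0, so the gain could never move.
block_f_path <- function(x, nm, Cin, Cout, P, spec, training, state) {
  f <- conv_layer(x, paste0(nm, ".c1"), Cin, Cout, 3L, P)
  f <- norm_relu(f, paste0(nm, ".n1"), Cout, P, spec, training, state)
  f <- conv_layer(f, paste0(nm, ".c2"), Cout, Cout, 3L, P)
  norm_relu(f, paste0(nm, ".n2"), Cout, P, spec, training, state,
            gamma_init = if (spec$block == "residual") "small" else "ones")
}

# Residual block H(X) = F(X) + X; the identity path is a 1x1 convolution
# when the channel counts differ. A "plain" block is the F path alone.
block_fwd <- function(x, nm, Cin, Cout, P, spec, training, state) {
  f <- block_f_path(x, nm, Cin, Cout, P, spec, training, state)
  if (spec$block == "plain") return(f)
  idp <- if (Cin == Cout) x
         else conv_layer(x, paste0(nm, ".proj"), Cin, Cout, 1L, P,
                         init = "linear")
  op_add(f, idp)
}

# One U module: inner_depth levels of blocks with 2x2 max pooling, a
# bottleneck, and a mirrored transposed-convolution up path whose skips are
# joined by concatenation. A decoder-kind module additionally receives
# per-scale feature maps (`adds`) joined by element-wise addition; an
# encoder-kind module exposes its per-scale features (and bottleneck) for
# exactly that purpose in the matching decoder.
u_module_fwd <- function(kind, x, nm, C, P, spec, training, state, adds = NULL) {
  d <- spec$inner_depth
  wd <- spec$inner_widen
  dims <- dim(nval(x))
  check_divisible(dims[1], dims[2], 2L^d)
  feats <- vector("list", d + 1L)
  cur <- x
  for (l in seq_len(d)) {
    Cin <- if (l == 1L) C else C * wd^(l - 2L)
    Cout <- C * wd^(l - 1L)
    cur <- block_fwd(cur, sprintf("%s.d%d", nm, l), Cin, Cout,
                     P, spec, training, state)
    if (!is.null(adds)) cur <- op_add(cur, adds[[l]])
    feats[[l]] <- cur
    cur <- op_maxpool2(cur)
  }
  cur <- block_fwd(cur, paste0(nm, ".bott"), C * wd^(d - 1L), C * wd^d,
                   P, spec, training, state)
  if (!is.null(adds)) cur <- op_add(cur, adds[[d + 1L]])
  feats[[d + 1L]] <- cur
  for (l in rev(seq_len(d))) {
    Cl <- C * wd^(l - 1L)                      # width at this inner scale
    cur <- convT_layer(cur, sprintf("%s.u%d.up", nm, l),
                       C * wd^l, Cl, P)
    cur <- op_concat(cur, feats[[l]])          # 2*Cl channels after the skip
    cur <- block_fwd(cur, sprintf("%s.u%d", nm, l), 2L * Cl, Cl,
                     P, spec, training, state)
  }
  list(out = cur, feats = feats)
}

uunet_fwd <- function(x, P, spec, training, state) {
  dims <- dim(nval(x))
  check_divisible(dims[1], dims[2], size_multiple(spec))
  Fb <- spec$base_filters
  L <- spec$outer_depth
  cur <- conv_layer(x, "stem.c", spec$in_channels, Fb, 3L, P)
  cur <- norm_relu(cur, "stem.n", Fb, P, spec, training, state)
  encs <- vector("list", L)
  for (i in seq_len(L)) {
    Ci <- Fb * 2L^(i - 1L)
    if (i > 1L) {
      cur <- op_maxpool2(cur)
      cur <- conv_layer(cur, sprintf("down%d", i), Ci %/% 2L, Ci, 1L, P,
                        init = "linear")
    }
    encs[[i]] <- u_module_fwd("encoder", cur, sprintf("enc%d", i), Ci,
                              P, spec, training, state)
    cur <- encs[[i]]$out
  }
  up <- NULL
  for (i in rev(seq_len(L))) {
    Ci <- Fb * 2L^(i - 1L)
    inp <- if (i == L) encs[[L]]$out else op_add(up, encs[[i]]$out)
    dm <- u_module_fwd("decoder", inp, sprintf("dec%d", i), Ci,
                       P, spec, training, state, adds = encs[[i]]$feats)
    if (i > 1L)
      up <- convT_layer(dm$out, sprintf("up%d", i), Ci, Ci %/% 2L, P)
  }
  conv_layer(dm$out, "head", Fb, spec$n_classes, 1L, P, init = "linear")
}

deconvnet_channels <- function(Fb) Fb * c(1L, 2L, 4L, 4L, 4L)

deconvnet_fwd <- function(x, P, spec, training, state) {
  dims <- dim(nval(x))
  check_divisible(dims[1], dims[2], 32L)
  Fb <- spec$base_filters
  ch <- deconvnet_channels(Fb)
  cur <- x
  for (s in 1:5) {
    Cin <- if (s == 1L) spec$in_channels else ch[s - 1L]
    cur <- conv_layer(cur, sprintf("e%d.c1", s), Cin, ch[s], 3L, P)
    cur <- norm_relu(cur, sprintf("e%d.n1", s), ch[s], P, spec, training, state)
    if (s <= 2L) {  # overlapping stages: a second successive convolution
      cur <- conv_layer(cur, sprintf("e%d.c2", s), ch[s], ch[s], 3L, P)
      cur <- norm_relu(cur, sprintf("e%d.n2", s), ch[s], P, spec, training, state)
    }
    cur <- op_maxpool2(cur)
  }
  for (s in 5:1) {
    Cd <- if (s == 1L) Fb else ch[s - 1L]
    cur <- convT_layer(cur, sprintf("d%d.up", s), ch[s], Cd, P)
    cur <- conv_layer(cur, sprintf("d%d.c", s), Cd, Cd, 3L, P)
    cur <- norm_relu(cur, sprintf("d%d.n", s), Cd, P, spec, training, state)
  }
  conv_layer(cur, "head", Fb, spec$n_classes, 1L, P, init = "linear")
}

forward_logits <- function(model, x, training = FALSE, mode = "run") {
  P <- make_provider(model$params, mode)
  fwd <- switch(model$arch, uunet = uunet_fwd, deconvnet = deconvnet_fwd,
                stop("unknown architecture: ", model$arch))
  fwd(x, P, model$spec, training, model$state)
}

new_seg_model <- function(spec, arch, seed) {
  params <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  model <- structure(list(spec = spec, arch = arch, params = params,
                          state = state, seed = as.integer(seed)),
                     class = "SegModel")
  s <- size_multiple(spec, arch)
  dummy <- array(0, c(s, s, spec$in_channels, 1L))
  with_seed(seed, forward_logits(model, dummy, training = FALSE, mode = "init"))
  # reset batch-norm state touched by the shape-probing pass
  rm(list = ls(state), envir = state)
  model$parameter_count <- param_count(params)
  model
}

#' Build the nested residual U-network
#'
#' Outer U of `outer_depth` levels; each level holds one encoder U module
#' (down path) and one decoder U module (up path). The encoder's per-scale
#' intermediate features are passed to the matching decoder by element-wise
#' addition, its output also feeds the decoder path through the outer skip,
#' and inner skips are joined by concatenation — creating multiple distinct
#' computation paths from input to output. A final 1x1 convolution maps to
#' `n_classes`; per-pixel probabilities are obtained by a softmax at
#' prediction time.
#'
#' @param spec a [model_spec()].
#' @param seed RNG seed for parameter initialization (He-normal); two
#'   builds from the same spec and seed have identical parameter vectors.
#' @return A `SegModel` (opaque parameter store plus its spec and
#'   `parameter_count`).
#' @export
build_uunet <- function(spec = model_spec(), seed = 17L)
  new_seg_model(spec, "uunet", seed)

#' Build the deconvolution-network baseline
#'
#' A VGG-like encoder of five 3x3-convolution stages (stride 1, zero
#' padding 1, the first two stages with two successive convolutions) each
#' followed by 2x2 max pooling, mirrored by a transposed-convolution
#' decoder, with the final fully-connected layers replaced by a 1x1
#' classification convolution. Input spatial size must be divisible by 32.
#'
#' @inheritParams build_uunet
#' @return A `SegModel`.
#' @export
build_deconvnet <- function(spec = model_spec(), seed = 17L)
  new_seg_model(spec, "deconvnet", seed)

#' @export
print.SegModel <- function(x, ...) {
  cat(sprintf("<SegModel %s: base %d, outer %d, inner %d, %s blocks, %d parameters>\n",
              x$arch, x$spec$base_filters, x$spec$outer_depth,
              x$spec$inner_depth, x$spec$block, x$parameter_count))
  invisible(x)
}

#' Build a standalone residual block
#'
#' Mainly a testing and inspection surface: returns the block as an object
#' whose `forward` runs H(X) = F(X) + X on an `(H, W, Cin, N)` array, with
#' `f_path` and `identity_path` exposing the two summands separately.
#'
#' @param channels_in,channels_out channel counts (>= 1).
#' @param spec a [model_spec()] (controls block type and normalization).
#' @param seed RNG seed for initialization.
#' @return A list with `forward(x, training = FALSE)`, `f_path(x)`,
#'   `identity_path(x)`, `params` (environment), `parameter_count`.
#' @export
build_residual_block <- function(channels_in, channels_out,
                                 spec = model_spec(), seed = 17L) {
  params <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  run <- function(x, what = "block", training = FALSE, mode = "run") {
    P <- make_provider(params, mode)
    switch(what,
      block = block_fwd(x, "blk", channels_in, channels_out,
                        P, spec, training, state),
      f = block_f_path(x, "blk", channels_in, channels_out,
                       P, spec, training, state),
      id = if (channels_in == channels_out) x
           else conv_layer(x, "blk.proj", channels_in, channels_out, 1L, P))
  }
  dummy <- array(0, c(4, 4, channels_in, 1))
  with_seed(seed, run(dummy, mode = "init"))
  rm(list = ls(state), envir = state)
  list(forward = function(x, training = FALSE) run(x, "block", training),
       f_path = function(x) run(x, "f"),
       identity_path = function(x) run(x, "id"),
       params = params, parameter_count = param_count(params))
}

#' Build a standalone U module (encoder or decoder kind)
#'
#' One inner-U sampling module as used at each outer level: `inner_depth`
#' levels of blocks with 2x2 max pooling, concatenation skips, and a
#' mirrored transposed-convolution up path. The encoder kind exposes its
#' per-scale intermediate features (`feats`, smallest last); the decoder
#' kind accepts a matching list of `adds` joined by element-wise addition.
#'
#' @param kind `"encoder"` or `"decoder"`.
#' @param channels input/output channel count of the module.
#' @param spec a [model_spec()].
#' @param seed RNG seed.
#' @return A list with `forward(x, adds = NULL, training = FALSE)` returning
#'   `list(out, feats)`, plus `params` and `parameter_count`.
#' @export
build_u_module <- function(kind = c("encoder", "decoder"), channels,
                           spec = model_spec(), seed = 17L) {
  kind <- match.arg(kind)
  params <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  run <- function(x, adds = NULL, training = FALSE, mode = "run") {
    P <- make_provider(params, mode)
    u_module_fwd(kind, x, "mod", channels, P, spec, training, state, adds)
  }
  s <- 2L^spec$inner_depth
  dummy <- array(0, c(s, s, channels, 1))
  # addition links are parameter-free, so a null-`adds` pass creates
  # every parameter for either kind
  with_seed(seed, run(dummy, mode = "init"))
  rm(list = ls(state), envir = state)
  list(forward = function(x, adds = NULL, training = FALSE)
         run(x, adds, training),
       kind = kind, params = params, parameter_count = param_count(params))
}

#' Segment an image with a trained model
#'
#' Runs a deterministic forward pass (batch-norm in inference mode, no
#' stochastic layers) and takes the per-pixel argmax over the class
#' probabilities; exact ties resolve to the lowest class index. The image
#' should be max-normalized ([normalize_max()]) like the training inputs,
#' and its spatial size must satisfy the model's divisibility rule.
#'
#' @param model a `SegModel`.
#' @param image an [image2d()].
#' @return A list with `mask` ([label_mask()]) and `prob`
#'   ([probability_map()]).
#' @export
predict_mask <- function(model, image) {
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  check_divisible(H, W, size_multiple(model$spec, model$arch))
  x <- array(px, c(H, W, 1L, 1L))
  logits <- forward_logits(model, x, training = FALSE)
  p4 <- softmax_channels(logits)
  C <- dim(p4)[3]
  idx <- apply(p4[, , , 1], c(1, 2), which.max)  # ties -> first (lowest class)
  classes <- 0:(C - 1L)
  mask <- label_mask(idx - 1L, classes = classes, spacing = image$spacing)
  prob <- probability_map(aperm(p4[, , , 1], c(3, 1, 2)), classes = classes)
  list(mask = mask, prob = prob)
}
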