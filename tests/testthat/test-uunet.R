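test_that("a residual block with a zeroed F path is the identity", {
  blk <- build_residual_block(8, 8, model_spec(), seed = 1)
  zero_f_path(blk)
  set.seed(2)
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  expect_identical(blk$forward(x), x)
})

test_that("residual blocks satisfy the H = F + identity decomposition", {
  blk <- build_residual_block(16, 32, model_spec(), seed = 3)
  set.seed(4)
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16, 1))
  h <- blk$forward(x)
  expect_equal(dim(h), c(8L, 8L, 32L, 1L))        # shape contract
  f <- blk$f_path(x)
  idp <- blk$identity_path(x)
  expect_lt(max(abs(h - idp - f)), 1e-5)
})

test_that("block and module parameter counts match the layer inventory", {
  for (spec in list(model_spec(),
                    model_spec(inner_widen = 2L),
                    model_spec(base_filters = 8L, norm = "none"),
                    model_spec(block = "plain"))) {
    blk <- build_residual_block(4, 12, spec)
    expect_equal(blk$parameter_count, n_block(4, 12, spec))
    for (kind in c("encoder", "decoder")) {
      um <- build_u_module(kind, 8, spec)
      expect_equal(um$parameter_count, n_u_module(8, spec))
    }
  }
})

test_that("encoder modules expose per-scale features, decoders accept adds", {
  spec <- model_spec(inner_widen = 2L)
  enc <- build_u_module("encoder", 16, spec)
  x <- array(rnorm(64 * 64 * 16), c(64, 64, 16, 1))
  out <- enc$forward(x)
  expect_equal(dim(out$out), c(64L, 64L, 16L, 1L))
  # bottleneck feature: channels 16 * 2^inner_depth at 1/4 spatial scale
  expect_equal(dim(out$feats[[3]]), c(16L, 16L, 64L, 1L))

  dec <- build_u_module("decoder", 16, spec)
  xa <- array(rnorm(16 * 16 * 16), c(16, 16, 16, 1))
  plain <- dec$forward(xa)
  zeros <- lapply(dec$forward(xa)$feats, function(f) array(0, dim(f)))
  with_adds <- dec$forward(xa, adds = zeros)
  expect_equal(with_adds$out, plain$out)  # additive identity
})

test_that("UU-NET preserves shape and emits per-pixel probabilities", {
  grid <- list(list(model_spec(base_filters = 4L, outer_depth = 1L,
                               inner_depth = 1L), 16L),
               list(model_spec(base_filters = 4L, outer_depth = 2L,
                               inner_depth = 1L), 24L),
               list(model_spec(base_filters = 4L, outer_depth = 1L,
                               inner_depth = 2L, inner_widen = 2L), 32L),
               list(model_spec(base_filters = 8L), 32L))
  for (g in grid) {
    m <- build_uunet(g[[1]], seed = 5)
    ph <- make_phantom(phantom_spec(size = c(g[[2]], g[[2]]), seed = 1))
    pred <- predict_mask(m, normalize_max(ph$image))
    expect_equal(dim(pred$mask$labels), dim(ph$image$pixels))
    sums <- apply(pred$prob$probs, c(2, 3), sum)
    expect_lt(max(abs(sums - 1)), 1e-6)
  }
  expect_error(predict_mask(build_uunet(model_spec(), seed = 1),
                            image2d(matrix(0:1, 10, 10))), "divisible")
})

test_that("whole-model parameter counts match closed form, and scale as predicted", {
  for (spec in list(model_spec(),
                    model_spec(base_filters = 8L),
                    model_spec(inner_widen = 2L, outer_depth = 2L))) {
    expect_equal(build_uunet(spec, seed = 1)$parameter_count, n_uunet(spec))
    expect_equal(build_deconvnet(spec, seed = 1)$parameter_count,
                 n_deconvnet(spec))
  }
  r_obs <- build_uunet(model_spec(base_filters = 16L), 1)$parameter_count /
    build_uunet(model_spec(base_filters = 8L), 1)$parameter_count
  r_pred <- n_uunet(model_spec(base_filters = 16L)) /
    n_uunet(model_spec(base_filters = 8L))
  expect_equal(r_obs, r_pred)
})

test_that("deconvnet handles its stated input geometries", {
  spec <- model_spec(base_filters = 4L)
  m <- build_deconvnet(spec, seed = 2)
  p224 <- predict_mask(m, image2d(matrix(rnorm(224 * 224), 224, 224)))
  expect_equal(dim(p224$mask$labels), c(224L, 224L))
  expect_equal(dim(p224$prob$probs)[1], 3L)
  p128 <- predict_mask(m, image2d(matrix(rnorm(128 * 128), 128, 128)))
  expect_equal(dim(p128$mask$labels), c(128L, 128L))
  expect_error(predict_mask(m, image2d(matrix(0:1, 48, 48))), "divisible")
})

test_that("model building is deterministic under seed", {
  a <- build_uunet(model_spec(base_filters = 4L), seed = 17)
  b <- build_uunet(model_spec(base_filters = 4L), seed = 17)
  for (nm in ls(a$params)) expect_identical(a$params[[nm]], b$params[[nm]])
  c <- build_uunet(model_spec(base_filters = 4L), seed = 18)
  expect_false(identical(a$params[["head.w"]], c$params[["head.w"]]))
})

test_that("prediction is deterministic and ties resolve to the lowest class", {
  spec <- model_spec(base_filters = 4L, outer_depth = 1L, inner_depth = 1L)
  m <- build_uunet(spec, seed = 6)
  img <- image2d(matrix(runif(16 * 16, 0, 255), 16, 16))
  p1 <- predict_mask(m, normalize_max(img))
  p2 <- predict_mask(m, normalize_max(img))
  expect_identical(p1$mask$labels, p2$mask$labels)
  expect_identical(p1$prob$probs, p2$prob$probs)
  # zero the head: all logits equal, every pixel ties across classes -> 0
  m$params[["head.w"]] <- m$params[["head.w"]] * 0
  m$params[["head.b"]] <- m$params[["head.b"]] * 0
  tied <- predict_mask(m, normalize_max(img))
  expect_true(all(tied$mask$labels == 0L))
})

test_that("gradients reach the deepest encoder block after one step", {
  # at initialization the residual branches are gated shut (zero-init
  # norm gain), so the F-path convolutions only receive gradient once the
  # first update moves the gain off zero
  ag <- asNamespace("atriaseg")
  spec <- model_spec(base_filters = 4L)
  m <- build_uunet(spec, seed = 7)
  ph <- make_phantom(phantom_spec(size = c(32, 32), seed = 2))
  xy <- ag$item_xy(list(image = ph$image, mask = ph$mask), 3L)
  ost <- ag$adam_state()
  for (step in 1:2) {
    tape <- ag$ag_start_tape()
    loss <- ag$op_softmax_dice(ag$forward_logits(m, xy$x, training = TRUE),
                               xy$y, c(2L, 3L))
    grads <- ag$ag_backward(loss, tape)
    ag$ag_stop_tape()
    expect_true(all(is.finite(unlist(grads))))
    ag$adam_step(m$params, grads, ost, lr = 2e-3)
  }
  deep <- grads[["enc3.bott.c1.w"]]
  expect_false(is.null(deep))
  expect_gt(sqrt(sum(deep^2)), 0)
})

test_that("the network can overfit a handful of phantoms", {
  # capacity probe on the minimal fixture: two ringed pools, no noise, no
  # bias, no confounder vessel and no vein openings. The full phantom's
  # ring openings put the label boundary inside a flat-intensity region,
  # which caps even memorization around DSC 0.98; the probe here asks
  # whether the architecture can fit the atrial geometry itself.
  dir <- withr::local_tempdir()
  man <- make_dataset(4, phantom_spec(size = c(64, 64), noise_sigma = 0,
                                      bias_amplitude = 0, vein_width = 0,
                                      confounder = NA),
                      seed = 7, out_dir = dir)
  res <- train(train_config(manifest = man,
                            optimizer = list(steps = 200L), seed = 11))
  items <- atriaseg:::load_items(man)
  expect_gte(atriaseg:::mean_fg_dsc(res$model, items), 0.99)
})
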