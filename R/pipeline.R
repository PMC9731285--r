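#' Training configuration
#'
#' @param model a [model_spec()].
#' @param arch `"uunet"` or `"deconvnet"`.
#' @param manifest training-set manifest: a `data.frame` with columns
#'   `id`, `image`, `mask` (as written by [make_dataset()]) or the path of
#'   such a CSV.
#' @param val_manifest optional held-out manifest for validation scoring
#'   and best-checkpoint selection.
#' @param optimizer list with `learning_rate` (>= 0, default 2e-3),
#'   `steps` (>= 1) and `batch_size` (>= 1); the optimizer is
#'   adaptive-moment (Adam).
#' @param loss `"dice"`: mean soft Dice loss over the foreground classes.
#' @param augment optional [augment_spec()]; `NULL` disables augmentation.
#' @param eval_every validation cadence in steps.
#' @param seed master RNG seed (initialization, data order, augmentation).
#' @param out_dir optional directory for the training-log CSV.
#' @return An object of class `TrainConfig`.
#' @export
train_config <- function(model = model_spec(), arch = c("uunet", "deconvnet"),
                         manifest, val_manifest = NULL,
                         optimizer = list(learning_rate = 2e-3, steps = 300L,
                                          batch_size = 4L),
                         loss = "dice", augment = NULL, eval_every = 25L,
                         seed = 17L, out_dir = NULL) {
  arch <- match.arg(arch)
  opt <- utils::modifyList(list(learning_rate = 2e-3, steps = 300L,
                                batch_size = 4L), optimizer)
  if (opt$learning_rate < 0) stop("learning_rate must be >= 0")
  if (opt$batch_size < 1L) stop("batch_size must be >= 1")
  if (opt$steps < 1L) stop("steps must be >= 1")
  structure(list(model = model, arch = arch, manifest = manifest,
                 val_manifest = val_manifest, optimizer = opt, loss = loss,
                 augment = augment, eval_every = as.integer(eval_every),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "TrainConfig")
}

load_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "image", "mask") %in% names(manifest)))
  manifest
}

load_items <- function(manifest) {
  manifest <- load_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i)
    list(id = manifest$id[i],
         image = read_image(manifest$image[i]),
         mask = read_mask(manifest$mask[i], classes = 0:2)))
}

#' Assign dataset items to cross-validation folds
#'
#' Deterministic under `seed`; fold sizes differ by at most one and every
#' item lands in exactly one fold.
#'
#' @param manifest a manifest `data.frame` or CSV path (or anything with
#'   `nrow`).
#' @param k number of folds (2 <= k <= n).
#' @param seed RNG seed.
#' @return Integer vector of fold ids (1..k), one per manifest row.
#' @export
split_dataset <- function(manifest, k, seed = 1L) {
  n <- if (is.numeric(manifest) && length(manifest) == 1L) as.integer(manifest)
       else nrow(load_manifest(manifest))
  k <- as.integer(k)
  if (k > n) stop("k = ", k, " folds exceed n = ", n, " items")
  if (k < 2L) stop("k must be >= 2")
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  folds <- integer(n)
  folds[with_seed(seed, sample.int(n))] <- rep(seq_len(k), times = sizes)
  folds
}

item_xy <- function(item, n_classes) {
  px <- normalize_max(item$image)$pixels
  H <- nrow(px); W <- ncol(px)
  y <- array(0, c(H, W, n_classes, 1L))
  for (c in seq_len(n_classes))
    y[, , c, 1] <- as.numeric(item$mask$labels == (c - 1L))
  list(x = array(px, c(H, W, 1L, 1L)), y = y)
}

mean_fg_dsc <- function(model, items) {
  vals <- vapply(items, function(it) {
    pm <- predict_mask(model, normalize_max(it$image))$mask
    a <- label_mask((pm$labels > 0L) + 0L, classes = 0:1, spacing = pm$spacing)
    b <- label_mask((it$mask$labels > 0L) + 0L, classes = 0:1,
                    spacing = it$mask$spacing)
    dsc(a, b, 1L)
  }, numeric(1))
  mean(vals)
}

snapshot_env <- function(e) as.list(e, all.names = TRUE)
restore_env <- function(e, snap) {
  rm(list = ls(e, all.names = TRUE), envir = e)
  for (nm in names(snap)) e[[nm]] <- snap[[nm]]
}

#' Train a segmentation network
#'
#' Minimizes the mean foreground soft Dice loss by Adam over minibatches
#' drawn with replacement from the training manifest. Fully seeded: data
#' order, augmentation draws and parameter initialization all derive from
#' `config$seed`, so two runs with the same configuration produce identical
#' training logs (single-threaded). If a validation manifest is given, the
#' parameters with the best validation mean foreground DSC are restored at
#' the end.
#'
#' @param config a [train_config()].
#' @return A list with `model` (the trained `SegModel`), `log` (data.frame
#'   `step`, `loss`, `val_dsc`) and `best_val_dsc`. The log is also written
#'   to `train_log.csv` under `config$out_dir` when set.
#' @export
train <- function(config) {
  items <- load_items(config$manifest)
  val_items <- if (!is.null(config$val_manifest)) load_items(config$val_manifest)
  spec <- config$model
  model <- new_seg_model(spec, config$arch, config$seed)
  opt <- config$optimizer
  ost <- adam_state()
  xy <- lapply(items, item_xy, n_classes = spec$n_classes)
  n <- length(items)
  B <- min(opt$batch_size, n)
  steps <- opt$steps
  log_step <- integer(0); log_loss <- numeric(0); log_val <- numeric(0)
  best <- list(dsc = -Inf, params = NULL, state = NULL)
  fg_idx <- seq_len(spec$n_classes)[-1]  # channels of the foreground classes
  with_seed(config$seed + 1L, {
    for (step in seq_len(steps)) {
      idx <- sample.int(n, B, replace = n < B)
      bx <- by <- NULL
      for (j in seq_along(idx)) {
        it <- items[[idx[j]]]
        if (!is.null(config$augment)) {
          aug <- augment(it$image, it$mask, config$augment)
          pair <- item_xy(list(image = aug$image, mask = aug$mask),
                          spec$n_classes)
        } else pair <- xy[[idx[j]]]
        if (is.null(bx)) {
          d <- dim(pair$x)
          bx <- array(0, c(d[1], d[2], 1L, B))
          by <- array(0, c(d[1], d[2], spec$n_classes, B))
        }
        bx[, , 1, j] <- pair$x[, , 1, 1]
        by[, , , j] <- pair$y[, , , 1]
      }
      tape <- ag_start_tape()
      loss_node <- tryCatch({
        logits <- forward_logits(model, bx, training = TRUE)
        op_softmax_dice(logits, by, fg_idx)
      }, finally = NULL)
      grads <- ag_backward(loss_node, tape)
      ag_stop_tape()
      loss <- loss_node$val
      if (!is.finite(loss))
        stop("training aborted: non-finite loss at step ", step)
      adam_step(model$params, grads, ost, lr = opt$learning_rate)
      val_dsc <- NA_real_
      if (!is.null(val_items) &&
          (step %% config$eval_every == 0L || step == steps)) {
        val_dsc <- mean_fg_dsc(model, val_items)
        if (val_dsc > best$dsc)
          best <- list(dsc = val_dsc, params = snapshot_env(model$params),
                       state = snapshot_env(model$state))
      }
      log_step <- c(log_step, step)
      log_loss <- c(log_loss, loss)
      log_val <- c(log_val, val_dsc)
    }
  })
  if (!is.null(val_items) && is.finite(best$dsc)) {
    restore_env(model$params, best$params)
    restore_env(model$state, best$state)
  }
  log <- data.frame(step = log_step, loss = log_loss, val_dsc = log_val)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(log, file.path(config$out_dir, "train_log.csv"),
                     row.names = FALSE)
  }
  list(model = model,
       log = log,
       best_val_dsc = if (is.null(val_items)) NA_real_ else best$dsc)
}

#' Evaluate a model on a held-out manifest
#'
#' Predicts every image (after [normalize_max()]), scores per-image,
#' per-class DSC and Hausdorff distance, and aggregates them. A class
#' absent from a prediction makes HD undefined: it is recorded as `NA`
#' (flagged, excluded from means) and the DSC is 0.
#'
#' @param model a trained `SegModel`.
#' @param manifest manifest `data.frame`/CSV path, or a list of items as
#'   produced by `atriaseg:::load_items`.
#' @param classes foreground classes to score, default `c(1, 2)`.
#' @return A [metric_report()] with additional fields `mean_fg_dsc` (mean
#'   over images of the binary any-atrium DSC) and `per_image_fg`.
#' @export
evaluate_run <- function(model, manifest, classes = c(1L, 2L)) {
  items <- if (is.list(manifest) && !is.data.frame(manifest) &&
               !is.null(manifest[[1]]$image)) manifest else load_items(manifest)
  rows <- list()
  fg_rows <- list()
  for (it in items) {
    pred <- predict_mask(model, normalize_max(it$image))$mask
    for (cl in classes) {
      d <- dsc(pred, it$mask, cl)
      h <- tryCatch(hausdorff(pred, it$mask, cl), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(image_id = it$id, class = cl, dsc = d, hd_mm = h)
    }
    pfg <- label_mask((pred$labels > 0L) + 0L, classes = 0:1,
                      spacing = pred$spacing)
    tfg <- label_mask((it$mask$labels > 0L) + 0L, classes = 0:1,
                      spacing = it$mask$spacing)
    fg_rows[[length(fg_rows) + 1L]] <-
      data.frame(image_id = it$id, dsc = dsc(pfg, tfg, 1L),
                 hd_mm = tryCatch(hausdorff(pfg, tfg, 1L),
                                  error = function(e) NA_real_))
  }
  rep <- metric_report(do.call(rbind, rows))
  rep$per_image_fg <- do.call(rbind, fg_rows)
  rep$mean_fg_dsc <- mean(rep$per_image_fg$dsc)
  rep
}

classical_predict <- function(method, image, truth) {
  if (method == "region_grow") {
    seeds <- lapply(c(1L, 2L), function(cl) {
      w <- which(truth$labels == cl, arr.ind = TRUE)
      if (nrow(w) == 0) return(NULL)
      round(colMeans(w))
    })
    seeds <- Filter(Negate(is.null), seeds)
    if (length(seeds) == 0) return(NULL)
    rg <- region_grow(image, region_grow_spec(seeds, delta = 25))
    label_mask((rg$labels > 0L) + 0L, classes = 0:1, spacing = image$spacing)
  } else {
    hist <- to_histogram(image)
    t_res <- switch(method,
                    otsu = otsu_threshold(hist),
                    iterative = iterative_threshold(hist),
                    max_entropy = max_entropy_threshold(hist),
                    stop("unknown classical method: ", method))
    threshold_apply(image, t_res$threshold)
  }
}

#' Compare segmentation methods on a common held-out set
#'
#' Produces one row per method with the held-out mean foreground
#' (any-atrium) DSC in percent and mean foreground Hausdorff distance in
#' millimetres. Classical methods operate on the raw gray-level images
#' (thresholds from each image's own histogram; region-growing seeds at the
#' true per-class centroids with the standard gray-difference criterion of
#' 25); learned methods run on max-normalized inputs. The pseudo-method
#' `"truth"` scores the ground truth against itself.
#'
#' @param manifest held-out manifest (`data.frame`/CSV path) or item list.
#' @param methods subset of `c("region_grow", "otsu", "iterative",
#'   "max_entropy", "deconvnet", "uunet", "truth")`.
#' @param models named list supplying a trained `SegModel` for each
#'   requested learned method; a missing model skips the row with a
#'   warning.
#' @return data.frame with columns `method`, `dsc_pct`, `hd_mm`, `n_images`.
#' @export
compare_methods <- function(manifest,
                            methods = c("region_grow", "otsu", "iterative",
                                        "max_entropy"),
                            models = list()) {
  items <- if (is.list(manifest) && !is.data.frame(manifest) &&
               !is.null(manifest[[1]]$image)) manifest else load_items(manifest)
  out <- list()
  for (m in methods) {
    if (m %in% c("uunet", "deconvnet")) {
      if (is.null(models[[m]])) {
        warning("no trained model supplied for ", m, "; row skipped")
        next
      }
      rep <- evaluate_run(models[[m]], items)
      dvals <- rep$per_image_fg$dsc
      hvals <- rep$per_image_fg$hd_mm
    } else {
      dvals <- hvals <- numeric(0)
      for (it in items) {
        pred <- if (m == "truth")
          label_mask((it$mask$labels > 0L) + 0L, classes = 0:1,
                     spacing = it$mask$spacing)
        else classical_predict(m, it$image, it$mask)
        if (is.null(pred)) next
        tfg <- label_mask((it$mask$labels > 0L) + 0L, classes = 0:1,
                          spacing = it$mask$spacing)
        dvals <- c(dvals, dsc(pred, tfg, 1L))
        hvals <- c(hvals, tryCatch(hausdorff(pred, tfg, 1L),
                                   error = function(e) NA_real_))
      }
    }
    out[[m]] <- data.frame(method = m,
                           dsc_pct = 100 * mean(dvals),
                           hd_mm = if (all(is.na(hvals))) NA_real_
                                   else mean(hvals, na.rm = TRUE),
                           n_images = length(dvals))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
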