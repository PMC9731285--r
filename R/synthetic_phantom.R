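#' Specification of a synthetic short-axis phantom
#'
#' Describes a paired intensity image and label mask that emulates a cropped
#' short-axis cardiac MRI slice: two elliptical atrial blood pools (bright),
#' each wrapped by a 2-pixel myocardial ring at intermediate gray, on a dark
#' background, plus a confounder blob at blood-like intensity outside the
#' atria (an aortic-root-like vessel) so that pure gray-level thresholding
#' over-segments — neighbouring tissue of similar gray level is picked up,
#' the classical failure mode on real short-axis images. Each pool is also
#' connected to the outside through a blood-intensity "vein" channel that
#' breaks the myocardial ring (the LA channel runs to the confounder vessel,
#' the RA channel laterally outward), the way real atria open into the
#' pulmonary veins and venae cavae; a region grower that escapes through
#' the opening floods the neighbouring vessel. Additive Gaussian noise and
#' an optional smooth multiplicative bias field model acquisition
#' imperfections.
#'
#' Ellipse tuples are `(center_row, center_col, semi_axis_a, semi_axis_b,
#' rotation_deg)` in pixel units, 1-based pixel-center coordinates. Defaults
#' scale with `size` so the same relative geometry is produced at any
#' resolution; at the default 128 x 128 the pools are roughly 30 pixels
#' across, matching a region-of-interest crop around the atria.
#'
#' @param size integer length-2 `(H, W)`, default `c(128, 128)`.
#' @param la_ellipse,ra_ellipse,confounder ellipse tuples as above;
#'   `confounder = NULL` disables the distractor blob.
#' @param intensities named numeric vector of mean gray per region on the
#'   0-255 scale: `background`, `myocardium` (the rings), `la`, `ra`,
#'   `confounder`.
#' @param noise_sigma additive Gaussian standard deviation in gray levels.
#' @param bias_amplitude peak-to-peak amplitude of the smooth multiplicative
#'   bias field, as a fraction in \[0, 0.5\] (0 = no bias).
#' @param vein_width width of the blood-intensity vein channels in pixels;
#'   0 disables them (closed rings).
#' @param spacing physical pixel size `(row_mm, col_mm)` in millimetres.
#' @param seed RNG seed making the phantom a pure function of the spec.
#' @return An object of class `PhantomSpec`.
#' @examples
#' ph <- make_phantom(phantom_spec(size = c(64, 64), noise_sigma = 0))
#' table(ph$mask$labels)
#' @export
phantom_spec <- function(size = c(128, 128),
                         la_ellipse = NULL, ra_ellipse = NULL,
                         confounder = NULL,
                         intensities = c(background = 50, myocardium = 100,
                                         la = 200, ra = 200, confounder = 195),
                         noise_sigma = 10, bias_amplitude = 0.15,
                         vein_width = NULL,
                         spacing = c(1, 1), seed = 1L) {
  size <- as.integer(rep(size, length.out = 2))
  s <- min(size)
  la_ellipse <- la_ellipse %||%
    c(0.50 * size[1], 0.34 * size[2], 0.140 * s, 0.110 * s, 20)
  ra_ellipse <- ra_ellipse %||%
    c(0.50 * size[1], 0.69 * size[2], 0.125 * s, 0.094 * s, -15)
  if (is.null(confounder))
    confounder <- c(0.22 * size[1], 0.45 * size[2], 0.095 * s, 0.075 * s, 10)
  else if (length(confounder) == 1 && is.na(confounder)) confounder <- NULL
  vein_width <- vein_width %||% max(2, round(0.05 * s))
  spec <- structure(list(size = size, la_ellipse = la_ellipse,
                         ra_ellipse = ra_ellipse, confounder = confounder,
                         intensities = intensities,
                         noise_sigma = noise_sigma,
                         bias_amplitude = bias_amplitude,
                         vein_width = vein_width,
                         spacing = as.numeric(spacing),
                         seed = as.integer(seed)),
                    class = "PhantomSpec")
  validate_phantom_spec(spec)
  spec
}

ellipse_inside <- function(e, H, W, margin = 2) {
  ext <- max(e[3], e[4]) + margin
  e[1] - ext >= 0.5 && e[1] + ext <= H + 0.5 &&
    e[2] - ext >= 0.5 && e[2] + ext <= W + 0.5
}

validate_phantom_spec <- function(spec) {
  H <- spec$size[1]; W <- spec$size[2]
  if (H < 8 || W < 8) stop("phantom size too small")
  for (nm in c("la_ellipse", "ra_ellipse")) {
    e <- spec[[nm]]
    if (e[3] <= 0 || e[4] <= 0) stop(nm, ": semi-axes must be positive")
    if (!ellipse_inside(e, H, W)) stop(nm, " (with its ring) exceeds the image")
  }
  if (!is.null(spec$confounder) && !ellipse_inside(spec$confounder, H, W, 0))
    stop("confounder ellipse exceeds the image")
  la <- rasterize_ellipse(spec$la_ellipse, H, W)
  ra <- rasterize_ellipse(spec$ra_ellipse, H, W)
  if (any(la & ra)) stop("LA and RA ellipses overlap")
  iv <- spec$intensities
  if (any(iv < 0 | iv > 255)) stop("region means must lie in [0, 255]")
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (spec$bias_amplitude < 0 || spec$bias_amplitude > 0.5)
    stop("bias_amplitude must lie in [0, 0.5]")
  invisible(spec)
}

# A pixel belongs to the ellipse iff its center satisfies the rotated
# ellipse inequality (u/a)^2 + (v/b)^2 <= 1.
rasterize_ellipse <- function(e, H, W) {
  th <- e[5] * pi / 180
  r <- matrix(seq_len(H), H, W) - e[1]
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE) - e[2]
  u <- r * cos(th) + c_ * sin(th)
  v <- -r * sin(th) + c_ * cos(th)
  (u / e[3])^2 + (v / e[4])^2 <= 1
}

ellipse_ring <- function(e, H, W, width = 2) {
  outer_e <- e; outer_e[3] <- e[3] + width; outer_e[4] <- e[4] + width
  rasterize_ellipse(outer_e, H, W) & !rasterize_ellipse(e, H, W)
}

# Rasterize a straight channel of width `w` from point p0 toward p1,
# spanning projections [0, len] along the unit direction.
rasterize_channel <- function(p0, p1, w, len, H, W) {
  dvec <- p1 - p0
  nl <- sqrt(sum(dvec^2))
  if (nl == 0) return(matrix(FALSE, H, W))
  u <- dvec / nl
  r <- matrix(seq_len(H), H, W) - p0[1]
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE) - p0[2]
  along <- r * u[1] + c_ * u[2]
  across <- -r * u[2] + c_ * u[1]
  along >= 0 & along <= len & abs(across) <= w / 2
}

# The two vein channels: LA pool -> confounder vessel; RA pool -> laterally
# outward past its ring.
vein_masks <- function(spec, H, W) {
  if (is.null(spec$vein_width) || spec$vein_width <= 0)
    return(matrix(FALSE, H, W))
  la <- spec$la_ellipse; ra <- spec$ra_ellipse
  out <- matrix(FALSE, H, W)
  if (!is.null(spec$confounder)) {
    ctr <- spec$confounder[1:2]
    out <- out | rasterize_channel(la[1:2], ctr, spec$vein_width,
                                   sqrt(sum((ctr - la[1:2])^2)), H, W)
  }
  ra_target <- c(ra[1], min(W, ra[2] + ra[3] + 6 + 0.1 * W))
  out | rasterize_channel(ra[1:2], ra_target, spec$vein_width,
                          ra[3] + 6 + 0.1 * W, H, W)
}

# Smooth multiplicative bias field with peak-to-peak amplitude `amp`:
# a separable half-sine surface, brightest at the image center.
bias_field <- function(H, W, amp) {
  if (amp <= 0) return(matrix(1, H, W))
  g <- outer(sin(pi * (seq_len(H) - 0.5) / H),
             sin(pi * (seq_len(W) - 0.5) / W))
  1 - amp / 2 + amp * g
}

#' Generate one phantom image/mask pair
#'
#' Construction order: region means are painted (rings over background,
#' blood pools over rings), the smooth bias field multiplies the image, the
#' seeded Gaussian noise is added, and the result is clipped to \[0, 255\].
#' Identical `spec` (including its `seed`) yields bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `image` ([image2d()]), `mask`
#'   ([label_mask()] with labels 1 = LA, 2 = RA) and `clean` (the noiseless,
#'   unbiased Image2D, useful for noise-model checks).
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  H <- spec$size[1]; W <- spec$size[2]
  iv <- spec$intensities
  la <- rasterize_ellipse(spec$la_ellipse, H, W)
  ra <- rasterize_ellipse(spec$ra_ellipse, H, W)
  img <- matrix(iv[["background"]], H, W)
  img[ellipse_ring(spec$la_ellipse, H, W)] <- iv[["myocardium"]]
  img[ellipse_ring(spec$ra_ellipse, H, W)] <- iv[["myocardium"]]
  if (!is.null(spec$confounder))
    img[rasterize_ellipse(spec$confounder, H, W)] <- iv[["confounder"]]
  img[vein_masks(spec, H, W)] <- iv[["la"]]  # channels at blood intensity
  img[la] <- iv[["la"]]
  img[ra] <- iv[["ra"]]
  clean <- img
  img <- img * bias_field(H, W, spec$bias_amplitude)
  if (spec$noise_sigma > 0)
    img <- img + with_seed(spec$seed,
                           matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W))
  img <- pmin(pmax(img, 0), 255)
  labels <- matrix(0L, H, W)
  labels[la] <- 1L
  labels[ra] <- 2L
  list(image = image2d(img, spacing = spec$spacing, source_id = "phantom"),
       mask = label_mask(labels, classes = 0:2, spacing = spec$spacing),
       clean = image2d(clean, spacing = spec$spacing, source_id = "phantom-clean"))
}

default_jitter <- function() {
  list(center_px = 0.04,    # +/- fraction of min(size), additive on centers
       axes_rel = 0.15,     # +/- relative on semi-axes
       rot_deg = 10,        # +/- degrees
       intensity = 8,       # +/- gray levels on region means
       noise_rel = 0.25,    # +/- relative on noise_sigma
       bias_rel = 0.4)      # +/- relative on bias_amplitude
}

jitter_ellipse <- function(e, s, jit) {
  c(e[1] + stats::runif(1, -1, 1) * jit$center_px * s,
    e[2] + stats::runif(1, -1, 1) * jit$center_px * s,
    e[3] * (1 + stats::runif(1, -1, 1) * jit$axes_rel),
    e[4] * (1 + stats::runif(1, -1, 1) * jit$axes_rel),
    e[5] + stats::runif(1, -1, 1) * jit$rot_deg)
}

jitter_spec <- function(base, jit) {
  s <- min(base$size)
  iv <- base$intensities +
    stats::runif(length(base$intensities), -1, 1) * jit$intensity
  sp <- base
  sp$la_ellipse <- jitter_ellipse(base$la_ellipse, s, jit)
  sp$ra_ellipse <- jitter_ellipse(base$ra_ellipse, s, jit)
  if (!is.null(base$confounder))
    sp$confounder <- jitter_ellipse(base$confounder, s, jit)
  sp$intensities <- pmin(pmax(iv, 0), 255)
  sp$noise_sigma <- base$noise_sigma * (1 + stats::runif(1, -1, 1) * jit$noise_rel)
  sp$bias_amplitude <- min(0.5, max(0, base$bias_amplitude *
                                      (1 + stats::runif(1, -1, 1) * jit$bias_rel)))
  sp
}

flatten_spec <- function(spec) {
  e <- function(x, p) stats::setNames(as.list(x), paste0(p, c("cr", "cc", "a", "b", "rot")))
  conf <- spec$confounder %||% rep(NA_real_, 5)
  c(list(H = spec$size[1], W = spec$size[2]),
    e(spec$la_ellipse, "la_"), e(spec$ra_ellipse, "ra_"), e(conf, "conf_"),
    as.list(stats::setNames(as.numeric(spec$intensities),
                            paste0("int_", names(spec$intensities)))),
    list(noise_sigma = spec$noise_sigma, bias_amplitude = spec$bias_amplitude,
         vein_width = spec$vein_width %||% 0, seed = spec$seed))
}

#' Generate a phantom dataset with jittered geometry
#'
#' Draws `n` specs whose ellipse parameters, intensities, noise and bias are
#' perturbed uniformly within the jitter ranges, writes each image/mask pair
#' as PNG, and returns (and writes) a CSV manifest holding the file paths and
#' every spec field. The whole operation is a pure function of
#' `(base_spec, jitter, seed)`.
#'
#' @param n number of phantoms (>= 1).
#' @param base_spec a [phantom_spec()] giving the nominal geometry.
#' @param jitter named list of per-field ranges; see `atriaseg:::default_jitter`.
#' @param seed RNG seed; phantom i uses derived seed `seed * 1000L + i`.
#' @param out_dir output directory, created if missing.
#' @return The manifest `data.frame` (also written to
#'   `file.path(out_dir, "manifest.csv")`), with columns `id`, `image`,
#'   `mask` and the flattened spec fields.
#' @export
make_dataset <- function(n, base_spec = phantom_spec(), jitter = default_jitter(),
                         seed = 1L, out_dir) {
  stopifnot(n >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jit <- utils::modifyList(default_jitter(), jitter %||% list())
  rows <- vector("list", n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      sp <- NULL
      for (try in 1:100) {
        cand <- jitter_spec(base_spec, jit)
        cand$seed <- as.integer(seed * 1000L + i)
        ok <- tryCatch({ validate_phantom_spec(cand); TRUE },
                       error = function(e) FALSE)
        if (ok) { sp <- cand; break }
      }
      if (is.null(sp))
        stop("could not draw a valid jittered spec after 100 attempts (item ", i, ")")
      ph <- make_phantom(sp)
      img_path <- file.path(out_dir, sprintf("phantom_%03d.png", i))
      msk_path <- file.path(out_dir, sprintf("phantom_%03d_mask.png", i))
      qimg <- ph$image
      qimg$pixels <- round(qimg$pixels)
      write_image(qimg, img_path)
      write_mask(ph$mask, msk_path)
      rows[[i]] <- c(list(id = sprintf("phantom_%03d", i),
                          image = img_path, mask = msk_path),
                     flatten_spec(sp))
    }
  })
  manifest <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
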