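#' Single-channel 2-D intensity image
#'
#' The unit every algorithm in the package consumes: an H x W real-valued
#' intensity grid with a physical pixel size in millimetres. The spacing
#' carries the mm units in which Hausdorff distances are reported.
#'
#' @param pixels numeric matrix (H x W) of finite intensities.
#' @param spacing numeric length-2 vector `(row_mm, col_mm)`, strictly
#'   positive physical pixel size in millimetres.
#' @param source_id free-text provenance tag.
#' @return An object of class `Image2D` with fields `pixels`, `spacing`,
#'   `source_id`.
#' @examples
#' img <- image2d(matrix(0:99, 10, 10))
#' dim(img$pixels)
#' @export
image2d <- function(pixels, spacing = c(1, 1), source_id = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("Image2D requires H >= 1 and W >= 1")
  if (!all(is.finite(pixels)))
    stop("Image2D intensities must be finite (no NaN/Inf)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two strictly positive values (row_mm, col_mm)")
  structure(list(pixels = pixels, spacing = spacing,
                 source_id = as.character(source_id)[1]),
            class = "Image2D")
}

#' @export
print.Image2D <- function(x, ...) {
  cat(sprintf("<Image2D %d x %d, spacing %.3g x %.3g mm, range [%.4g, %.4g]%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels),
              if (nzchar(x$source_id)) paste0(", ", x$source_id) else ""))
  invisible(x)
}

#' Integer label mask aligned to an image
#'
#' Houses manual and predicted segmentations. The default class coding is
#' 0 = background, 1 = left atrium (LA), 2 = right atrium (RA).
#'
#' @param labels integer matrix (H x W); every value must be a member of
#'   `classes`.
#' @param classes ordered integer label vocabulary.
#' @param spacing physical pixel size `(row_mm, col_mm)` in millimetres.
#' @return An object of class `LabelMask`.
#' @examples
#' m <- label_mask(matrix(0L, 4, 4))
#' table(m$labels)
#' @export
label_mask <- function(labels, classes = 0:2, spacing = c(1, 1)) {
  labels <- as.matrix(labels)
  if (any(labels != round(labels))) stop("labels must be integers")
  storage.mode(labels) <- "integer"
  classes <- as.integer(classes)
  if (!all(labels %in% classes))
    stop("every label must be a member of `classes`; found: ",
         paste(setdiff(unique(as.vector(labels)), classes), collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("spacing must be two strictly positive values")
  structure(list(labels = labels, classes = classes, spacing = spacing),
            class = "LabelMask")
}

#' @export
print.LabelMask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$classes))
  cat(sprintf("<LabelMask %d x %d, classes {%s}, counts %s>\n",
              nrow(x$labels), ncol(x$labels),
              paste(x$classes, collapse = ","),
              paste(as.integer(tab), collapse = "/")))
  invisible(x)
}

check_pair <- function(image, mask) {
  if (!identical(dim(image$pixels), dim(mask$labels)))
    stop("image and mask shapes differ")
  if (!isTRUE(all.equal(image$spacing, mask$spacing)))
    stop("image and mask spacing differ")
  invisible(TRUE)
}

#' 256-bin gray-level histogram
#'
#' The substrate of the three threshold-selection methods: counts of floored
#' gray values 0..255 plus a probability view p_i = counts_i / total.
#'
#' @param image an [image2d()] with intensities in \[0, 255\].
#' @return An object of class `Histogram256` with fields `counts`
#'   (256 integers, bin g holds the number of pixels with floored value g)
#'   and `total` (= H*W).
#' @examples
#' h <- to_histogram(image2d(matrix(c(0, 0, 255, 255), 2, 2)))
#' h$counts[c(1, 256)]
#' @export
to_histogram <- function(image) {
  x <- if (inherits(image, "Image2D")) image$pixels else as.matrix(image)
  if (min(x) < 0 || max(x) > 255)
    stop("intensities outside [0, 255]; rescale before building a histogram")
  g <- floor(x)
  counts <- tabulate(as.integer(g) + 1L, nbins = 256L)
  structure(list(counts = counts, total = sum(counts)), class = "Histogram256")
}

#' @export
print.Histogram256 <- function(x, ...) {
  nz <- which(x$counts > 0L)
  cat(sprintf("<Histogram256: %d pixels over %d populated bins [%d, %d]>\n",
              x$total, length(nz), min(nz) - 1L, max(nz) - 1L))
  invisible(x)
}

hist_probs <- function(hist) hist$counts / hist$total

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
is_png_path <- function(path) grepl("\\.png$", path, ignore.case = TRUE)

collapse_singleton <- function(arr, path) {
  d <- dim(arr)
  if (is.null(d) || length(d) == 2L) return(as.matrix(arr))
  if (length(d) == 3L) {
    s <- which(d == 1L)
    if (length(s) == 0L)
      stop("multi-slice volume without a singleton axis: ", path)
    message("collapsing singleton axis ", s[1], " of ", path)
    return(matrix(arr, nrow = d[-s[1]][1], ncol = d[-s[1]][2]))
  }
  stop("unsupported dimensionality (", length(d), "-d) in ", path)
}

read_png_gray <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    rgb <- img[, , seq_len(min(ch, 3L)), drop = FALSE]
    if (max(abs(sweep(rgb, c(1, 2), rgb[, , 1]))) > 0)
      stop("PNG is not grayscale: ", path)
    img <- rgb[, , 1]
  }
  px <- round(img * (2^depth - 1))
  matrix(px, nrow(px), ncol(px))  # drop readPNG attributes
}

#' Read a grayscale image from PNG or NIfTI
#'
#' Integer intensities are preserved losslessly. NIfTI `pixdim` fields
#' populate the spacing; PNG carries no physical spacing, so it defaults to
#' 1.0 mm isotropic. A 3-D NIfTI volume is accepted only if one axis is a
#' singleton (it is collapsed with a message).
#'
#' @param path file path ending in `.png`, `.nii` or `.nii.gz`.
#' @param spacing optional spacing override `(row_mm, col_mm)`.
#' @return An [image2d()].
#' @export
read_image <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("cannot read image, no such file: ", path)
  if (is_png_path(path)) {
    px <- read_png_gray(path)
    sp <- if (is.null(spacing)) c(1, 1) else spacing
  } else if (is_nifti_path(path)) {
    nii <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(nii)
    px <- collapse_singleton(nii[drop = FALSE], path)
    px <- matrix(as.numeric(px), nrow(px), ncol(px))  # drop NIfTI attributes
    sp <- if (is.null(spacing)) pd[1:2] else spacing
    if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1)
  } else stop("unsupported image format (want .png/.nii/.nii.gz): ", path)
  image2d(px, spacing = sp, source_id = basename(path))
}

#' Write an image to PNG or NIfTI
#'
#' PNG output is 8-bit (intensities must be integers in \[0, 255\]); NIfTI
#' stores 16-bit integers losslessly (or doubles for non-integer data) and
#' records the spacing in `pixdim`.
#'
#' @param image an [image2d()].
#' @param path destination ending in `.png`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- image$pixels
  if (is_png_path(path)) {
    if (min(px) < 0 || max(px) > 255 || any(px != round(px)))
      stop("PNG output requires integer intensities in [0, 255]; ",
           "use NIfTI for wider or real-valued data")
    png::writePNG(px / 255, path)
  } else if (is_nifti_path(path)) {
    integral <- all(px == round(px))
    dt <- if (integral && min(px) >= 0 && max(px) <= 65535) "uint16" else "double"
    nii <- RNifti::asNifti(structure(px, pixdim = image$spacing))
    RNifti::writeNifti(nii, path, datatype = dt)
  } else stop("unsupported image format (want .png/.nii/.nii.gz): ", path)
  invisible(path)
}

#' Write a label mask (PNG or NIfTI)
#'
#' Labels are stored at their raw integer values (8-bit PNG or uint8 NIfTI),
#' so `read_mask(write_mask(m))` reproduces the labels exactly.
#'
#' @param mask a [label_mask()]; labels must fit in 8 bits.
#' @param path destination ending in `.png`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  lb <- mask$labels
  if (min(lb) < 0 || max(lb) > 255) stop("labels must fit in 8 bits")
  if (is_png_path(path)) {
    png::writePNG(lb / 255, path)
  } else if (is_nifti_path(path)) {
    nii <- RNifti::asNifti(structure(lb, pixdim = mask$spacing))
    RNifti::writeNifti(nii, path, datatype = "uint8")
  } else stop("unsupported mask format (want .png/.nii/.nii.gz): ", path)
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param path file path.
#' @param classes label vocabulary of the returned mask; defaults to the
#'   values present in the file.
#' @param spacing optional spacing override.
#' @return A [label_mask()].
#' @export
read_mask <- function(path, classes = NULL, spacing = NULL) {
  img <- read_image(path, spacing = spacing)
  lb <- round(img$pixels)
  if (is.null(classes)) classes <- sort(unique(as.integer(lb)))
  label_mask(lb, classes = classes, spacing = img$spacing)
}
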