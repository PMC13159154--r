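# Image containers and pre-analytical processing: Z-projection, tile
# stitching, rolling-ball background subtraction, Gaussian smoothing.
# Intensities are kept on a normalized [0, 1] scale internally; `bit_depth`
# records the acquisition depth used for TIFF quantization and PSNR.

#' Chip image container
#'
#' A single-channel 2D grayscale image of one organ-chip gel channel,
#' together with its acquisition metadata. Pixels are stored as a numeric
#' matrix (rows = y, columns = x, origin top-left, 0-based pixel-centered
#' coordinates in all reported centroids) on a normalized `[0, 1]` intensity
#' scale.
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param channel One of `"BF"` (bright-field), `"DAPI"` (Hoechst, all
#'   nuclei) or `"TRITC"` (EthD-2/PI, dead cells).
#' @param chip_id Chip identifier string.
#' @param day Integer day of culture.
#' @param pixel_size_um Physical pixel size in micrometres.
#' @param bit_depth Acquisition bit depth, 8 or 16.
#' @return An object of class `chip_image`.
#' @export
chip_image <- function(pixels, channel = c("BF", "DAPI", "TRITC"),
                       chip_id = "chip", day = 0L, pixel_size_um = 3,
                       bit_depth = 16L) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stopf("image dimensions must be positive")
  if (anyNA(pixels) || any(pixels < 0))
    stopf("intensities must be non-negative and finite")
  if (!bit_depth %in% c(8L, 16L)) stopf("`bit_depth` must be 8 or 16")
  structure(
    list(pixels = pixels, channel = channel, chip_id = as.character(chip_id),
         day = as.integer(day), pixel_size_um = pixel_size_um,
         bit_depth = as.integer(bit_depth)),
    class = "chip_image")
}

#' @export
print.chip_image <- function(x, ...) {
  cat(sprintf("<chip_image> %s | chip %s day %d | %d x %d px | %d-bit | %.2f um/px\n",
              x$channel, x$chip_id, x$day, ncol(x$pixels), nrow(x$pixels),
              x$bit_depth, x$pixel_size_um))
  invisible(x)
}

as_pixels <- function(img) {
  if (inherits(img, "chip_image")) img$pixels
  else if (is.matrix(img)) img
  else stopf("expected a chip_image or a numeric matrix")
}

# Rebuild a chip_image carrying over metadata from a template.
rewrap <- function(pixels, template, channel = NULL) {
  if (inherits(template, "chip_image")) {
    chip_image(pixels, channel %||% template$channel, template$chip_id,
               template$day, template$pixel_size_um, template$bit_depth)
  } else pixels
}

#' Z-stack container
#'
#' An ordered list of same-shape 2D slices spanning the gel channel height.
#'
#' @param slices List of numeric matrices, all with identical dimensions.
#' @param step_um Axial step size between slices, micrometres.
#' @param channel Optional channel tag forwarded to projections.
#' @return An object of class `z_stack`.
#' @export
z_stack <- function(slices, step_um = 14, channel = "BF") {
  if (!is.list(slices) || length(slices) < 1L)
    stopf("a z_stack needs at least one slice")
  d <- dim(slices[[1]])
  ok <- vapply(slices, function(s) is.matrix(s) && identical(dim(s), d), logical(1))
  if (!all(ok)) stopf("all slices must be matrices with identical dimensions")
  structure(list(slices = slices, step_um = step_um, channel = channel),
            class = "z_stack")
}

#' Project a Z-stack to a single 2D image
#'
#' Maximum-intensity projection by default (each output pixel is the maximum
#' over slices at that position); mean projection is available as an option.
#'
#' @param stack A [z_stack()].
#' @param method `"max"` (default) or `"mean"`.
#' @param ... Metadata passed to [chip_image()] (`chip_id`, `day`, ...).
#' @return A [chip_image()].
#' @export
max_project <- function(stack, method = c("max", "mean"), ...) {
  method <- match.arg(method)
  if (!inherits(stack, "z_stack")) stopf("`stack` must be a z_stack")
  px <- if (method == "max") {
    Reduce(pmax, stack$slices)
  } else {
    Reduce(`+`, stack$slices) / length(stack$slices)
  }
  chip_image(px, channel = stack$channel, ...)
}

#' Stitch a row of overlapping fields of view
#'
#' Tiles are assumed to be a left-to-right strip of equal-shape fields of
#' view (chips are imaged as a horizontal row of overlapping fields). The
#' overlap region is blended with a linear ramp, which is exact on constant
#' input and reconstructs a source image exactly when the tiles are
#' overlapping crops of it.
#'
#' @param tiles List of [chip_image()]s or matrices, left to right.
#' @param overlap_fraction Fraction of tile width shared between neighbours,
#'   in `[0, 0.5)`.
#' @return A stitched image of the same class as the first tile.
#' @export
stitch_tiles <- function(tiles, overlap_fraction = 0.1) {
  if (length(tiles) < 1L) stopf("no tiles to stitch")
  if (overlap_fraction < 0 || overlap_fraction >= 0.5)
    stopf("`overlap_fraction` must be in [0, 0.5)")
  mats <- lapply(tiles, as_pixels)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stopf("tiles must share identical dimensions")
  n <- length(mats)
  w <- d[2]
  ov <- round(overlap_fraction * w)
  out_w <- n * w - (n - 1L) * ov
  acc <- matrix(0, d[1], out_w)
  wsum <- matrix(0, d[1], out_w)
  for (i in seq_len(n)) {
    x0 <- (i - 1L) * (w - ov)  # 0-based offset
    wt <- rep(1, w)
    if (ov > 0) {
      ramp <- seq_len(ov) / (ov + 1)
      if (i > 1L) wt[seq_len(ov)] <- ramp
      if (i < n) wt[w - ov + seq_len(ov)] <- rev(ramp)
    }
    cols <- x0 + seq_len(w)
    acc[, cols] <- acc[, cols] + sweep(mats[[i]], 2, wt, `*`)
    wsum[, cols] <- wsum[, cols] + matrix(wt, d[1], w, byrow = TRUE)
  }
  rewrap(acc / wsum, tiles[[1]])
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as a grayscale morphological opening with a disc
#' structuring element of the given radius and subtracts it, clipping at
#' zero. A constant image maps to zero; features smaller than the disc are
#' preserved.
#'
#' @param img A [chip_image()] or matrix.
#' @param radius_px Disc radius in pixels (> 0).
#' @return Image of the input class with background removed.
#' @export
subtract_background <- function(img, radius_px = 50) {
  if (!is_scalar_number(radius_px) || radius_px <= 0)
    stopf("`radius_px` must be a positive number")
  px <- as_pixels(img)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  bg <- EBImage::opening(px, brush)
  rewrap(pmax(px - bg, 0), img)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 1D convolution along rows then columns with reflective padding.
convolve_sep <- function(px, k) {
  r <- (length(k) - 1L) / 2L
  h <- nrow(px); w <- ncol(px)
  ridx <- c(rev(seq_len(min(r, h))), seq_len(h), h + 1L - seq_len(min(r, h)))
  if (r > h) stopf("smoothing kernel larger than image")
  pad <- px[ridx, , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(k)) out <- out + k[j] * pad[(j - 1L) + seq_len(h), , drop = FALSE]
  if (r > w) stopf("smoothing kernel larger than image")
  cidx <- c(rev(seq_len(min(r, w))), seq_len(w), w + 1L - seq_len(min(r, w)))
  pad <- out[, cidx, drop = FALSE]
  out2 <- matrix(0, h, w)
  for (j in seq_along(k)) out2 <- out2 + k[j] * pad[, (j - 1L) + seq_len(w), drop = FALSE]
  out2
}

#' Gaussian smoothing
#'
#' Separable Gaussian convolution with reflective boundary handling; the
#' kernel is truncated at 3.5 sigma and normalized, so total intensity of
#' interior content is conserved. `sigma_px = 0` is the identity.
#'
#' @param img A [chip_image()] or matrix.
#' @param sigma_px Gaussian standard deviation in pixels (>= 0).
#' @return Smoothed image of the input class.
#' @export
gaussian_smooth <- function(img, sigma_px = 1) {
  if (!is_scalar_number(sigma_px) || sigma_px < 0)
    stopf("`sigma_px` must be a non-negative number")
  if (sigma_px == 0) return(img)
  px <- as_pixels(img)
  rewrap(convolve_sep(px, gaussian_kernel_1d(sigma_px)), img)
}

#' Read and write single-channel TIFF images
#'
#' Thin wrappers over the tiff package that quantize to the declared bit
#' depth, making write/read round trips byte-stable.
#'
#' @param img A [chip_image()].
#' @param path Output file path.
#' @return `write_chip_tiff` returns `path` invisibly; `read_chip_tiff`
#'   returns a [chip_image()].
#' @export
write_chip_tiff <- function(img, path) {
  stopifnot(inherits(img, "chip_image"))
  px <- clamp01(img$pixels)
  tiff::writeTIFF(px, path, bits.per.sample = img$bit_depth,
                  compression = "none")
  invisible(path)
}

#' @rdname write_chip_tiff
#' @param channel,chip_id,day,pixel_size_um,bit_depth Metadata for the
#'   returned [chip_image()] (TIFF files carry pixels only).
#' @export
read_chip_tiff <- function(path, channel = "BF", chip_id = "chip", day = 0L,
                           pixel_size_um = 3, bit_depth = 16L) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  chip_image(px, channel, chip_id, day, pixel_size_um, bit_depth)
}

# Quantize to the uniform grid representable at `bits` (used by the
# simulator so in-memory images equal their TIFF round trip).
quantize <- function(px, bits) {
  mx <- 2^bits - 1
  round(clamp01(px) * mx) / mx
}
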