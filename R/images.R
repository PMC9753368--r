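#' @useDynLib phenopaint, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Read an RGB image from a PNG file
#'
#' Returns an H x W x 3 numeric array with values in [0, 1]. Grayscale and
#' RGBA files are promoted/truncated to three channels.
#'
#' @param path path to a PNG file.
#' @return numeric array of dimension height x width x 3.
#' @export
read_rgb <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] >= 4L) a <- a[, , 1:3, drop = FALSE]
  a[, , 1:3, drop = FALSE]
}

#' Read a binary mask from a PNG file
#'
#' Any pixel with mean intensity above 0.5 is foreground.
#'
#' @param path path to a PNG file.
#' @return integer matrix of 0/1 values.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  m <- matrix(0L, nrow(a), ncol(a))
  m[a > 0.5] <- 1L
  m
}

#' Write an RGB image (values in [0, 1]) to a PNG file
#' @param rgb H x W x 3 array in [0, 1].
#' @param path output path.
#' @export
write_rgb <- function(rgb, path) {
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}

#' Write a binary mask to a PNG file
#' @param mask 0/1 matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

# Luma grayscale conversion (ITU-R BT.601 weights), H x W matrix in [0, 1].
as_gray <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Bounding box of the foreground; list(r0, r1, c0, c1, h, w) or NULL if empty.
mask_bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  list(r0 = r0, r1 = r1, c0 = c0, c1 = c1, h = r1 - r0 + 1L, w = c1 - c0 + 1L)
}

# Square resize; bilinear for intensities, nearest ("none") keeps masks binary.
resize_rgb <- function(rgb, side) {
  if (nrow(rgb) == side && ncol(rgb) == side) return(rgb)
  out <- EBImage::resize(rgb, w = side, h = side, filter = "bilinear")
  array(pmin(pmax(out, 0), 1), dim = c(side, side, 3L))
}

resize_mask <- function(mask, side) {
  if (nrow(mask) == side && ncol(mask) == side) return(mask)
  out <- EBImage::resize(mask, w = side, h = side, filter = "none")
  m <- matrix(0L, side, side)
  m[out > 0.5] <- 1L
  m
}

# Foreground recovered from a rendered/generated image: any pixel that is
# not (near) black. Used where a generated image has no companion mask.
mask_from_rgb <- function(rgb, threshold = 10 / 255) {
  v <- pmax(rgb[, , 1], pmax(rgb[, , 2], rgb[, , 3]))
  m <- matrix(0L, nrow(v), ncol(v))
  m[v > threshold] <- 1L
  m
}

# Largest 8-connected foreground component. Generated images carry isolated
# background speckles that would otherwise pin the bounding box to the full
# canvas; a single-plant image has one true component.
largest_component <- function(mask) {
  if (sum(mask) == 0L) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  m <- matrix(0L, nrow(mask), ncol(mask))
  m[lab == keep] <- 1L
  m
}
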