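#' Phenotypic trait schema
#'
#' The full panel holds 18 traits in a fixed order: six intensity texture
#' statistics over the foreground (M, SE, S, MU3, U, E), silhouette
#' morphology (TPA, H, W, TBR, CBA, THR, PAR, FDIC, P) and colour areas
#' (GPA, YPA, YTR). The \code{"no-yellow"} variant drops YPA and YTR for
#' crops with essentially no yellow tissue (e.g. rice and maize seedlings),
#' leaving 16 active traits for conditioning.
#'
#' @param variant \code{"full"} (18 active traits) or \code{"no-yellow"} (16).
#' @return an object of class \code{trait_schema} with elements
#'   \code{ordered_names} (all 18 trait names, fixed order) and \code{active}
#'   (the subset used as the GAN condition vector).
#' @export
trait_schema <- function(variant = c("full", "no-yellow")) {
  variant <- match.arg(variant)
  ordered <- c("M", "SE", "S", "MU3", "U", "E", "TPA", "H", "W", "TBR",
               "CBA", "THR", "PAR", "FDIC", "P", "GPA", "YPA", "YTR")
  active <- if (variant == "full") ordered else setdiff(ordered, c("YPA", "YTR"))
  structure(list(variant = variant, ordered_names = ordered, active = active),
            class = "trait_schema")
}

#' @export
print.trait_schema <- function(x, ...) {
  cat("Trait schema (", x$variant, "): ", length(x$active),
      " active of ", length(x$ordered_names), " traits\n", sep = "")
  cat(" ", paste(x$active, collapse = " "), "\n")
  invisible(x)
}

#' Intensity histogram texture statistics
#'
#' Computes the six first-order texture statistics of an intensity sample
#' from its normalized histogram p(z): mean \eqn{M = \sum z_i p(z_i)},
#' standard deviation SE, smoothness \eqn{S = 1 - 1/(1 + \sigma^2)}, third
#' central moment MU3, uniformity \eqn{U = \sum p(z_i)^2} and Shannon
#' entropy \eqn{E = -\sum p \log_2 p} (bits).
#'
#' Histogram bin centres are \eqn{i/(n_{bins}-1)}; intensities quantized
#' from 8-bit images are therefore represented exactly at the default 256
#' bins.
#'
#' @param values numeric vector of intensities in [0, 1] (foreground pixels).
#' @param n_bins number of histogram bins (>= 2); default 256.
#' @return named list with M, SE, S, MU3, U, E.
#' @export
histogram_stats <- function(values, n_bins = 256L) {
  if (length(values) == 0L) stop("empty foreground")
  if (anyNA(values) || min(values) < 0 || max(values) > 1)
    stop("intensities must lie in [0, 1]")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  bin <- as.integer(round(values * (n_bins - 1)))
  cnt <- tabulate(bin + 1L, nbins = n_bins)
  p <- cnt / length(values)
  z <- (seq_len(n_bins) - 1) / (n_bins - 1)
  M <- sum(z * p)
  v <- sum((z - M)^2 * p)
  pos <- p > 0
  list(M = M,
       SE = sqrt(v),
       S = 1 - 1 / (1 + v),
       MU3 = sum((z - M)^3 * p),
       U = sum(p^2),
       E = -sum(p[pos] * log2(p[pos])))
}

# Inclusive point-in-convex-polygon pixel count of the filled hull of the
# foreground pixel centres. Degenerate (collinear) foregrounds fall back to
# the bounding-box pixel set, which for a line is the line itself.
hull_pixel_area <- function(mask, bb) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (bb$h == 1L || bb$w == 1L) return(as.numeric(bb$h) * bb$w)
  hull <- grDevices::chull(idx[, 2], idx[, 1])  # (x = col, y = row)
  hx <- idx[hull, 2]; hy <- idx[hull, 1]
  nh <- length(hull)
  if (nh < 3L) return(as.numeric(bb$h) * bb$w)
  grid <- expand.grid(y = bb$r0:bb$r1, x = bb$c0:bb$c1)
  inside <- rep(TRUE, nrow(grid))
  # chull returns vertices clockwise in (x, y); every interior point lies on
  # the same side (cross product <= 0) of every directed edge.
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (grid$y - hy[i]) - (hy[j] - hy[i]) * (grid$x - hx[i])
    inside <- inside & (cr <= 1e-9)
    if (!any(inside)) break
  }
  sum(inside)
}

#' Silhouette morphology traits
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return named list with TPA (foreground pixel count), H and W (bounding
#'   rectangle height/width in pixels), CBA = H*W, TBR = TPA/CBA, THR =
#'   TPA / filled-convex-hull pixel count, P (count of foreground pixels with
#'   at least one 4-neighbour in the background; the image border counts as
#'   background) and PAR = P/TPA.
#' @export
morphology_traits <- function(mask) {
  bb <- mask_bbox(mask)
  if (is.null(bb)) stop("empty foreground")
  TPA <- sum(mask > 0)
  H <- bb$h; W <- bb$w
  CBA <- as.numeric(H) * W
  pad <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) + 0L
  core <- pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  nb <- pad[1:nrow(mask), 2:(ncol(mask) + 1L)] +
        pad[3:(nrow(mask) + 2L), 2:(ncol(mask) + 1L)] +
        pad[2:(nrow(mask) + 1L), 1:ncol(mask)] +
        pad[2:(nrow(mask) + 1L), 3:(ncol(mask) + 2L)]
  P <- sum(core == 1L & nb < 4L)
  hull_area <- hull_pixel_area(mask, bb)
  list(TPA = TPA, H = H, W = W, CBA = CBA, TBR = TPA / CBA,
       THR = TPA / hull_area, P = P, PAR = P / TPA)
}

#' Box-counting fractal dimension of a silhouette
#'
#' The mask is cropped to its bounding box, padded to the next power-of-two
#' square, and occupied boxes N(s) are counted for box sizes
#' s = 1, 2, 4, ..., side/2. The returned dimension is the least-squares
#' slope of log N(s) against log(1/s). A one-pixel bounding box returns 0
#' (the fit is degenerate).
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return the fractal dimension (a filled patch approaches 2, a thin line 1).
#' @export
fractal_dimension <- function(mask) {
  bb <- mask_bbox(mask)
  if (is.null(bb)) stop("empty foreground")
  crop <- (mask[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE] > 0) + 0L
  side <- 2^ceiling(log2(max(bb$h, bb$w)))
  if (side < 2L) return(0)
  sq <- matrix(0L, side, side)
  sq[seq_len(bb$h), seq_len(bb$w)] <- crop
  sizes <- 2^(0:(log2(side) - 1))
  counts <- vapply(sizes, function(s) {
    nb <- side / s
    # occupancy of each s x s block via a two-step fold
    rowfold <- rowsum(sq, rep(seq_len(nb), each = s))
    colfold <- t(rowsum(t(rowfold), rep(seq_len(nb), each = s)))
    sum(colfold > 0)
  }, numeric(1))
  x <- log(1 / sizes)
  y <- log(counts)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Green and yellow projected areas
#'
#' Foreground pixels are classified by HSV hue: green for hue in [60, 180)
#' degrees, yellow for hue in [20, 60) degrees, in both cases requiring
#' saturation and value at or above configurable floors so that dark or
#' achromatic pixels count as neither. YTR = TPA / max(YPA, 1).
#'
#' @param rgb H x W x 3 array in [0, 1].
#' @param mask 0/1 matrix of the same height/width.
#' @param sat_floor,val_floor minimum saturation/value for a pixel to carry
#'   colour; default 0.15.
#' @return named list with GPA, YPA, YTR.
#' @export
color_traits <- function(rgb, mask, sat_floor = 0.15, val_floor = 0.15) {
  if (nrow(rgb) != nrow(mask) || ncol(rgb) != ncol(mask))
    stop("rgb and mask dimensions differ")
  fg <- which(mask > 0)
  if (length(fg) == 0L) stop("empty foreground")
  r <- rgb[, , 1][fg]; g <- rgb[, , 2][fg]; b <- rgb[, , 3][fg]
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  hue <- hsv[1, ] * 360
  ok <- hsv[2, ] >= sat_floor & hsv[3, ] >= val_floor
  GPA <- sum(ok & hue >= 60 & hue < 180)
  YPA <- sum(ok & hue >= 20 & hue < 60)
  list(GPA = GPA, YPA = YPA, YTR = length(fg) / max(YPA, 1))
}

#' Extract the full phenotypic trait vector of one image
#'
#' Texture statistics are computed over the gray-converted foreground
#' intensities only (the black background would otherwise dominate every
#' histogram moment); morphology and fractal dimension over the mask; colour
#' areas over the masked RGB values.
#'
#' @param rgb H x W x 3 array in [0, 1].
#' @param mask 0/1 matrix of the same height/width, nonempty.
#' @param schema a \code{\link{trait_schema}}; the returned vector carries
#'   all 18 ordered traits, the schema records which are active.
#' @param n_bins histogram bins for the texture statistics.
#' @return named numeric vector over \code{schema$ordered_names}.
#' @export
extract_traits <- function(rgb, mask, schema = trait_schema("full"),
                           n_bins = 256L) {
  if (nrow(rgb) != nrow(mask) || ncol(rgb) != ncol(mask))
    stop("rgb and mask dimensions differ")
  gray <- as_gray(rgb)
  tex <- histogram_stats(gray[mask > 0], n_bins = n_bins)
  mor <- morphology_traits(mask)
  col <- color_traits(rgb, mask)
  all <- c(tex, mor, FDIC = fractal_dimension(mask), col)
  out <- unlist(all)[schema$ordered_names]
  names(out) <- schema$ordered_names
  out
}

#' Trait table of a set of images
#'
#' @param rgbs list of RGB arrays.
#' @param masks list of matching masks.
#' @param schema a \code{\link{trait_schema}}.
#' @param ids optional image identifiers (defaults to names or sequence).
#' @return data.frame with column \code{image_id} followed by the 18 traits.
#' @export
trait_table <- function(rgbs, masks, schema = trait_schema("full"), ids = NULL) {
  stopifnot(length(rgbs) == length(masks))
  if (is.null(ids)) ids <- names(rgbs)
  if (is.null(ids)) ids <- sprintf("img%04d", seq_along(rgbs))
  rows <- t(vapply(seq_along(rgbs),
                   function(i) extract_traits(rgbs[[i]], masks[[i]], schema),
                   numeric(length(schema$ordered_names))))
  out <- data.frame(image_id = ids, rows, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
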