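# Seeded procedural generator of plant-like silhouettes: a vertical stem with
# alternating side branches (two recursion levels), drawn with hard un-
# anti-aliased strokes so that areas, perimeters and bounding boxes are
# integer-exact and the mask is exactly the set of non-black pixels.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parameters of one synthetic plant
#'
#' @param canvas square canvas side in pixels (>= 32).
#' @param n_branches number of first-order side branches (>= 0).
#' @param branch_angle_spread maximal branch angle from the vertical, degrees.
#' @param stem_height_frac stem height as a fraction of the canvas side.
#' @param stroke_width stroke width in pixels (>= 1).
#' @param leaf_length_frac first-order branch length as a fraction of the
#'   stem height.
#' @param yellow_fraction probability that a segment is drawn yellow.
#' @param hue_jitter per-segment hue jitter in degrees.
#' @param seed RNG seed making the rendering deterministic.
#' @return a \code{plant_params} list.
#' @export
plant_params <- function(canvas = 64L, n_branches = 5L,
                         branch_angle_spread = 45, stem_height_frac = 0.8,
                         stroke_width = 1L, leaf_length_frac = 0.35,
                         yellow_fraction = 0.2, hue_jitter = 10, seed = 1L) {
  p <- list(canvas = as.integer(canvas), n_branches = as.integer(n_branches),
            branch_angle_spread = branch_angle_spread,
            stem_height_frac = stem_height_frac,
            stroke_width = as.integer(stroke_width),
            leaf_length_frac = leaf_length_frac,
            yellow_fraction = yellow_fraction, hue_jitter = hue_jitter,
            seed = as.integer(seed))
  if (p$canvas < 32L) stop("canvas must be >= 32")
  if (p$stroke_width < 1L) stop("stroke_width must be >= 1")
  if (p$n_branches < 0L) stop("n_branches must be >= 0")
  for (f in c("stem_height_frac", "leaf_length_frac", "yellow_fraction"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  structure(p, class = "plant_params")
}

# Stamp a stroke_width square at integer steps along a segment.
stroke_pixels <- function(x0, y0, x1, y1, w, side) {
  len <- max(abs(x1 - x0), abs(y1 - y0), 1)
  t <- seq(0, 1, length.out = ceiling(len) * 2 + 1)
  cx <- round(x0 + t * (x1 - x0))
  cy <- round(y0 + t * (y1 - y0))
  half0 <- floor((w - 1) / 2)
  half1 <- w - 1 - half0
  px <- integer(0); py <- integer(0)
  for (dx in -half0:half1) for (dy in -half0:half1) {
    px <- c(px, cx + dx); py <- c(py, cy + dy)
  }
  keep <- px >= 1 & px <= side & py >= 1 & py <= side
  cbind(row = py[keep], col = px[keep])
}

segment_color <- function(yellow_fraction, hue_jitter) {
  yellow <- stats::runif(1) < yellow_fraction
  hue <- if (yellow) 40 + stats::runif(1, -1, 1) * hue_jitter
         else 115 + stats::runif(1, -1, 1) * hue_jitter
  hue <- min(max(hue, 21), 179)
  s <- stats::runif(1, 0.55, 0.95)
  v <- stats::runif(1, 0.55, 0.95)
  grDevices::col2rgb(grDevices::hsv(hue / 360, s, v))[, 1] / 255
}

#' Render one synthetic plant silhouette
#'
#' Draws a vertical stem with \code{n_branches} alternating side branches and
#' one level of sub-branches on a black background. Segments are coloured
#' green or (with probability \code{yellow_fraction}) yellow, with per-segment
#' hue/brightness jitter so intensity texture statistics vary across plants.
#' The mask equals the set of non-black pixels exactly.
#'
#' @param params a \code{\link{plant_params}} object.
#' @return list with elements \code{rgb} (canvas x canvas x 3 array in [0, 1])
#'   and \code{mask} (0/1 matrix).
#' @export
render_plant <- function(params) {
  stopifnot(inherits(params, "plant_params"))
  S <- params$canvas
  with_seed(params$seed, {
    rgb <- array(0, dim = c(S, S, 3L))
    paint <- function(pix, colr) {
      if (nrow(pix) == 0L) return(invisible())
      for (ch in 1:3) {
        pl <- rgb[, , ch]
        pl[pix] <- colr[ch]
        rgb[, , ch] <<- pl
      }
    }
    w <- params$stroke_width
    stem_h <- max(2L, as.integer(round(params$stem_height_frac * S)))
    cx <- as.integer(round(S / 2))
    half0 <- floor((w - 1) / 2); half1 <- w - 1 - half0
    stem_cols <- (cx - half0):(cx + half1)
    stem_rows <- (S - stem_h + 1L):S
    paint(as.matrix(expand.grid(row = stem_rows, col = stem_cols)),
          segment_color(params$yellow_fraction, params$hue_jitter))
    draw_branch <- function(x, y, ang, len, depth) {
      x1 <- x + sin(ang) * len
      y1 <- y - cos(ang) * len
      paint(stroke_pixels(x, y, x1, y1, w, S),
            segment_color(params$yellow_fraction, params$hue_jitter))
      if (depth < 2L) {
        for (frac in c(0.55, 1)) {
          xa <- x + frac * (x1 - x); ya <- y + frac * (y1 - y)
          sub_ang <- ang + sample(c(-1, 1), 1) *
            stats::runif(1, 0.3, 1) * params$branch_angle_spread * pi / 180
          draw_branch(xa, ya, sub_ang, len * stats::runif(1, 0.4, 0.6),
                      depth + 1L)
        }
      }
    }
    if (params$n_branches > 0L) {
      heights <- seq(0.15, 0.95, length.out = params$n_branches)
      for (i in seq_len(params$n_branches)) {
        y <- S - heights[i] * (stem_h - 1)
        side_sign <- if (i %% 2L == 0L) 1 else -1
        ang <- side_sign * stats::runif(1, 0.35, 1) *
          params$branch_angle_spread * pi / 180
        # allometric: branch length scales with the stem, so overall plant
        # size (and with it H, W, TPA) tracks stem_height_frac
        len <- params$leaf_length_frac * stem_h * stats::runif(1, 0.7, 1)
        draw_branch(cx, y, ang, len, 1L)
      }
    }
    mask <- mask_from_rgb(rgb, threshold = 0)
    # a branch can exit the canvas and a sub-branch re-enter it, leaving a
    # detached fragment; a plant is one connected object, so keep the main
    # component only
    mask <- largest_component(mask)
    for (ch in 1:3) {
      pl <- rgb[, , ch]
      pl[mask == 0L] <- 0
      rgb[, , ch] <- pl
    }
    list(rgb = rgb, mask = mask)
  })
}

default_param_ranges <- function() {
  list(n_branches = c(2, 9), branch_angle_spread = c(20, 70),
       stem_height_frac = c(0.45, 0.95), stroke_width = c(1, 3),
       leaf_length_frac = c(0.2, 0.5), yellow_fraction = c(0, 0.5),
       hue_jitter = c(5, 15))
}

#' Generate a synthetic plant dataset
#'
#' Samples \code{\link{plant_params}} uniformly from \code{param_ranges}
#' under a master seed and renders \code{n} plants. Masks are guaranteed
#' nonempty (the stem is always drawn). With the default ranges all 18
#' traits vary across a dataset of moderate size.
#'
#' @param n number of plants (>= 2).
#' @param seed master seed; rendering is fully reproducible.
#' @param canvas canvas side in pixels.
#' @param param_ranges named list of c(lo, hi) ranges; defaults cover a broad
#'   morphological range (2-9 branches, stems 45-95\% of the canvas, strokes
#'   1-3 px, up to half the segments yellow).
#' @param dir optional directory; when given, images and masks are written as
#'   PNGs together with a \code{params.json} provenance file.
#' @return invisible list of records, each with \code{image_id}, \code{rgb},
#'   \code{mask} and \code{params}.
#' @export
synth_dataset <- function(n, seed = 1L, canvas = 64L, param_ranges = NULL,
                          dir = NULL) {
  if (n < 2L) stop("n must be >= 2")
  rg <- default_param_ranges()
  if (!is.null(param_ranges)) rg[names(param_ranges)] <- param_ranges
  recs <- with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max, n)
    lapply(seq_len(n), function(i) {
      u <- function(f) stats::runif(1, rg[[f]][1], rg[[f]][2])
      pp <- plant_params(
        canvas = canvas,
        n_branches = as.integer(round(u("n_branches"))),
        branch_angle_spread = u("branch_angle_spread"),
        stem_height_frac = u("stem_height_frac"),
        stroke_width = as.integer(round(u("stroke_width"))),
        leaf_length_frac = u("leaf_length_frac"),
        yellow_fraction = u("yellow_fraction"),
        hue_jitter = u("hue_jitter"),
        seed = sub_seeds[i])
      img <- render_plant(pp)
      list(image_id = sprintf("plant%05d", i), rgb = img$rgb,
           mask = img$mask, params = pp)
    })
  })
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (r in recs) {
      write_rgb(r$rgb, file.path(dir, "images", paste0(r$image_id, ".png")))
      write_mask(r$mask, file.path(dir, "masks", paste0(r$image_id, ".png")))
    }
    prov <- lapply(recs, function(r) c(list(image_id = r$image_id),
                                       unclass(r$params)))
    jsonlite::write_json(prov, file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(recs)
}
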