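#' Centre a cropped foreground on a square black canvas
#'
#' The mask's bounding-box content is copied bit-identically onto an M x M
#' black canvas with its top-left corner at (floor((M-h)/2), floor((M-w)/2)).
#'
#' @param rgb H x W x 3 array in [0, 1].
#' @param mask 0/1 matrix of the same height/width, nonempty.
#' @param M canvas side in pixels; must be >= both bounding-box sides.
#' @return list with the centred \code{rgb} and \code{mask}.
#' @export
center_on_canvas <- function(rgb, mask, M) {
  bb <- mask_bbox(mask)
  if (is.null(bb)) stop("empty foreground")
  if (bb$h > M) stop("bounding-box height ", bb$h, " exceeds canvas ", M)
  if (bb$w > M) stop("bounding-box width ", bb$w, " exceeds canvas ", M)
  r_off <- floor((M - bb$h) / 2)
  c_off <- floor((M - bb$w) / 2)
  out_rgb <- array(0, dim = c(M, M, 3L))
  out_mask <- matrix(0L, M, M)
  rows <- (r_off + 1L):(r_off + bb$h)
  cols <- (c_off + 1L):(c_off + bb$w)
  out_rgb[rows, cols, ] <- rgb[bb$r0:bb$r1, bb$c0:bb$c1, , drop = FALSE]
  out_mask[rows, cols] <- (mask[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE] > 0) + 0L
  list(rgb = out_rgb, mask = out_mask)
}

#' Fit a per-trait min-max normalizer
#'
#' @param traits numeric matrix or data.frame (rows = samples, cols = traits).
#' @return a \code{trait_normalizer} with per-trait \code{min} and \code{max}.
#' @export
fit_normalizer <- function(traits) {
  m <- as.matrix(traits)
  structure(list(names = colnames(m),
                 min = apply(m, 2, min),
                 max = apply(m, 2, max)),
            class = "trait_normalizer")
}

#' Min-max normalize traits to [0, 1]
#'
#' Each trait maps to (t - min) / (max - min), clamped to [0, 1] so unseen
#' test-time extremes stay inside the trained condition domain; a trait that
#' was constant on the training set (max == min) maps to 0.
#'
#' @param traits numeric vector, matrix or data.frame over the fitted traits.
#' @param state a \code{\link{fit_normalizer}} result.
#' @return matrix of the same rows with values in [0, 1].
#' @export
normalize_traits <- function(traits, state) {
  m <- if (is.null(dim(traits))) matrix(traits, nrow = 1,
                                        dimnames = list(NULL, names(traits)))
       else as.matrix(traits)
  if (!is.null(state$names)) {
    if (!all(state$names %in% colnames(m)))
      stop("missing trait columns: ",
           paste(setdiff(state$names, colnames(m)), collapse = ", "))
    m <- m[, state$names, drop = FALSE]
  }
  rng <- state$max - state$min
  out <- sweep(m, 2, state$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Invert min-max normalization
#'
#' Right inverse of \code{\link{normalize_traits}} on in-range values.
#'
#' @param z matrix/vector of normalized values in [0, 1].
#' @param state a \code{\link{fit_normalizer}} result.
#' @return matrix on the original trait scales.
#' @export
denormalize_traits <- function(z, state) {
  m <- if (is.null(dim(z))) matrix(z, nrow = 1) else as.matrix(z)
  out <- sweep(sweep(m, 2, state$max - state$min, "*"), 2, state$min, "+")
  colnames(out) <- state$names
  out
}

#' Build a training/testing dataset manifest
#'
#' Implements the preprocessing pipeline: the dataset-wide canvas side M is
#' the maximum bounding-box side over all masks; every image is centred on an
#' M x M black canvas and resized to \code{target_resolution} (bilinear for
#' RGB, nearest for masks so they stay binary); traits are extracted from the
#' resized image/mask so that trait scales match what the GAN sees; records
#' are split into train/test by a seeded shuffle; the min-max normalizer is
#' fitted on the training split only.
#'
#' @param records list of records with \code{image_id}, \code{rgb},
#'   \code{mask} (e.g. from \code{\link{synth_dataset}} or
#'   \code{\link{read_image_dir}}).
#' @param schema a \code{\link{trait_schema}}.
#' @param target_resolution model-facing square resolution (e.g. 256, or 64
#'   for desk-scale work).
#' @param test_fraction fraction of records assigned to the test split.
#' @param seed seed controlling the split.
#' @return a \code{dataset_manifest}: records (with resized rgb/mask, traits,
#'   split label), canvas_M, target_resolution, schema, normalizer, seed.
#' @export
build_dataset <- function(records, schema = trait_schema("full"),
                          target_resolution = 64L, test_fraction = 0.1,
                          seed = 1L) {
  if (length(records) < 2L) stop("need at least 2 images")
  empty <- vapply(records, function(r) sum(r$mask > 0) == 0L, logical(1))
  if (any(empty))
    stop("empty masks for: ",
         paste(vapply(records[empty], `[[`, "", "image_id"), collapse = ", "))
  bbs <- lapply(records, function(r) mask_bbox(r$mask))
  canvas_M <- max(vapply(bbs, function(b) max(b$h, b$w), integer(1)))
  recs <- lapply(records, function(r) {
    cen <- center_on_canvas(r$rgb, r$mask, canvas_M)
    rgb <- resize_rgb(cen$rgb, target_resolution)
    mask <- resize_mask(cen$mask, target_resolution)
    if (sum(mask) == 0L)  # guard against nearest-resize wiping a thin mask
      mask <- center_fallback(target_resolution)
    list(image_id = r$image_id, rgb = rgb, mask = mask,
         traits = extract_traits(rgb, mask, schema))
  })
  n <- length(recs)
  n_test <- round(test_fraction * n)
  ord <- with_seed(seed, sample.int(n))
  test_idx <- sort(ord[seq_len(n_test)])
  for (i in seq_len(n))
    recs[[i]]$split <- if (i %in% test_idx) "test" else "train"
  train_traits <- do.call(rbind, lapply(recs[setdiff(seq_len(n), test_idx)],
                                        `[[`, "traits"))
  structure(list(records = recs, canvas_M = canvas_M,
                 target_resolution = as.integer(target_resolution),
                 schema = schema, normalizer = fit_normalizer(train_traits),
                 seed = as.integer(seed)),
            class = "dataset_manifest")
}

# Nearest resize of a 1-px structure can in principle drop every foreground
# pixel; mark the centre pixel so downstream code never sees an empty mask.
center_fallback <- function(side) {
  m <- matrix(0L, side, side)
  m[ceiling(side / 2), ceiling(side / 2)] <- 1L
  m
}

#' @export
print.dataset_manifest <- function(x, ...) {
  sp <- manifest_split(x)
  cat("Dataset manifest: ", length(x$records), " records (",
      length(sp$train), " train / ", length(sp$test), " test)\n", sep = "")
  cat("  canvas M = ", x$canvas_M, ", resolution = ", x$target_resolution,
      ", schema = ", x$schema$variant, "\n", sep = "")
  invisible(x)
}

# Indices of the two splits.
manifest_split <- function(manifest) {
  lab <- vapply(manifest$records, `[[`, "", "split")
  list(train = which(lab == "train"), test = which(lab == "test"))
}

# n x 18 trait matrix of selected records.
manifest_traits <- function(manifest, idx = seq_along(manifest$records)) {
  do.call(rbind, lapply(manifest$records[idx], `[[`, "traits"))
}

#' Read an images/masks directory pair into records
#'
#' @param image_dir directory of RGB PNGs.
#' @param mask_dir directory of mask PNGs with matching file names.
#' @return list of records usable by \code{\link{build_dataset}}.
#' @export
read_image_dir <- function(image_dir, mask_dir) {
  files <- sort(list.files(image_dir, pattern = "\\.png$"))
  if (length(files) == 0L) stop("no PNG images in ", image_dir)
  lapply(files, function(f) {
    mp <- file.path(mask_dir, f)
    if (!file.exists(mp)) stop("no mask for ", f)
    list(image_id = sub("\\.png$", "", f),
         rgb = read_rgb(file.path(image_dir, f)), mask = read_mask(mp))
  })
}

#' Write a manifest to a directory
#'
#' Layout: \code{images/*.png}, \code{masks/*.png}, \code{traits.csv} (columns
#' image_id, split, then the 18 traits) and \code{meta.json} (canvas M,
#' resolution, schema, normalizer state, seed).
#'
#' @param manifest a \code{\link{build_dataset}} result.
#' @param dir output directory.
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (r in manifest$records) {
    write_rgb(r$rgb, file.path(dir, "images", paste0(r$image_id, ".png")))
    write_mask(r$mask, file.path(dir, "masks", paste0(r$image_id, ".png")))
  }
  tr <- manifest_traits(manifest)
  df <- data.frame(image_id = vapply(manifest$records, `[[`, "", "image_id"),
                   split = vapply(manifest$records, `[[`, "", "split"),
                   tr, check.names = FALSE)
  utils::write.csv(df, file.path(dir, "traits.csv"), row.names = FALSE)
  meta <- list(canvas_M = manifest$canvas_M,
               target_resolution = manifest$target_resolution,
               schema_variant = manifest$schema$variant,
               normalizer = list(names = manifest$normalizer$names,
                                 min = as.numeric(manifest$normalizer$min),
                                 max = as.numeric(manifest$normalizer$max)),
               seed = manifest$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a manifest written by \code{\link{write_manifest}}
#' @param dir manifest directory.
#' @return a \code{dataset_manifest}.
#' @export
read_manifest <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  df <- utils::read.csv(file.path(dir, "traits.csv"), check.names = FALSE)
  schema <- trait_schema(meta$schema_variant)
  recs <- lapply(seq_len(nrow(df)), function(i) {
    id <- df$image_id[i]
    tr <- as.numeric(df[i, schema$ordered_names])
    names(tr) <- schema$ordered_names
    list(image_id = id,
         rgb = read_rgb(file.path(dir, "images", paste0(id, ".png"))),
         mask = read_mask(file.path(dir, "masks", paste0(id, ".png"))),
         traits = tr, split = df$split[i])
  })
  norm <- structure(list(names = meta$normalizer$names,
                         min = stats::setNames(meta$normalizer$min, meta$normalizer$names),
                         max = stats::setNames(meta$normalizer$max, meta$normalizer$names)),
                    class = "trait_normalizer")
  structure(list(records = recs, canvas_M = meta$canvas_M,
                 target_resolution = meta$target_resolution,
                 schema = schema, normalizer = norm, seed = meta$seed),
            class = "dataset_manifest")
}
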