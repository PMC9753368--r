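#' Global structural similarity of two images
#'
#' The single-window (global statistics) form:
#' \deqn{SSIM(x,y) = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#'   {(\mu_x^2+\mu_y^2+c_1)(\sigma_x^2+\sigma_y^2+c_2)}}
#' with \eqn{c_1 = (k_1 L)^2}, \eqn{c_2 = (k_2 L)^2} and moments taken over
#' all pixels (population denominators, so \code{ssim(x, x)} is exactly 1).
#' Colour inputs are averaged to gray first. An optional sliding-window mode
#' (\code{window > 0}) averages the same statistic over square windows.
#'
#' @param x,y numeric matrices (grayscale) or H x W x 3 arrays of equal
#'   dimensions, on the scale given by \code{L}.
#' @param L dynamic range of the pixel values (255 for 8-bit).
#' @param k1,k2 stabilisation constants.
#' @param window 0 for the global form (default); otherwise the square
#'   window side for a mean-of-windows SSIM.
#' @return scalar similarity in [-1, 1].
#' @export
ssim <- function(x, y, L = 255, k1 = 0.01, k2 = 0.03, window = 0L) {
  if (length(dim(x)) == 3L) x <- as_gray(x)
  if (length(dim(y)) == 3L) y <- as_gray(y)
  if (!all(dim(x) == dim(y))) stop("image dimensions differ")
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  stat <- function(xs, ys) {
    n <- length(xs)
    mx <- mean(xs); my <- mean(ys)
    vx <- sum((xs - mx)^2) / n
    vy <- sum((ys - my)^2) / n
    cxy <- sum((xs - mx) * (ys - my)) / n
    ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  if (window <= 0L) return(stat(as.numeric(x), as.numeric(y)))
  w <- as.integer(window)
  vals <- c()
  for (i in seq(1L, nrow(x) - w + 1L, by = w))
    for (j in seq(1L, ncol(x) - w + 1L, by = w))
      vals <- c(vals, stat(x[i:(i + w - 1L), j:(j + w - 1L)],
                           y[i:(i + w - 1L), j:(j + w - 1L)]))
  mean(vals)
}

#' Feature-space Gaussian statistics of an image set
#'
#' Applies a feature extractor to every image and returns the sample mean
#' vector and covariance matrix used by the Fréchet distance. The default
#' \code{"pixel"} extractor is deterministic: grayscale, area-averaged to an
#' 8 x 8 grid and flattened to 64 features on the 0-255 scale. A custom
#' extractor (e.g. a pretrained deep embedding) can be supplied as a
#' function image -> numeric vector; distances are only comparable within
#' one extractor.
#'
#' @param images list of H x W x 3 arrays in [0, 1] (at least 2).
#' @param extractor \code{"pixel"} or a function.
#' @return a \code{feature_stats} list with \code{mu}, \code{sigma}, \code{n}.
#' @export
embed <- function(images, extractor = "pixel") {
  if (length(images) < 2L) stop("need at least 2 images")
  fn <- if (is.function(extractor)) extractor else switch(
    extractor,
    pixel = function(img) {
      g <- as_gray(img) * 255
      side <- nrow(g)
      if (side %% 8L != 0L) stop("pixel extractor needs a side divisible by 8")
      f <- side %/% 8L
      p <- rowsum(g, rep(seq_len(8L), each = f))
      p <- t(rowsum(t(p), rep(seq_len(8L), each = f))) / f^2
      as.numeric(p)
    },
    stop("unknown extractor '", extractor, "'"))
  feats <- t(vapply(images, fn, numeric(length(fn(images[[1]])))))
  structure(list(mu = colMeans(feats), sigma = stats::cov(feats),
                 n = nrow(feats)),
            class = "feature_stats")
}

# Symmetric PSD matrix square root; eigenvalues clipped at zero.
sqrtm_psd <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Fréchet distance between two feature-space Gaussians
#'
#' \deqn{d^2 = |\mu_a - \mu_b|^2 + tr(\Sigma_a + \Sigma_b
#'   - 2(\Sigma_a \Sigma_b)^{1/2})}
#' The matrix square root is computed through symmetric eigendecompositions
#' of \eqn{\Sigma_a^{1/2}\Sigma_b\Sigma_a^{1/2}}, with negative eigenvalues
#' clipped at zero, so the result is real and nonnegative up to roundoff.
#'
#' @param a,b \code{feature_stats} from \code{\link{embed}} (same dimension).
#' @return scalar distance (>= 0).
#' @export
fid <- function(a, b) {
  if (length(a$mu) != length(b$mu)) stop("feature dimensions differ")
  Sa <- (a$sigma + t(a$sigma)) / 2
  Sb <- (b$sigma + t(b$sigma)) / 2
  ra <- sqrtm_psd(Sa)
  cross <- sqrtm_psd(ra %*% Sb %*% ra)
  d2 <- sum((a$mu - b$mu)^2) + sum(diag(Sa)) + sum(diag(Sb)) -
    2 * sum(diag(cross))
  max(d2, 0)
}

#' Per-trait Pearson correlation between real and virtual trait matrices
#'
#' \deqn{r = \frac{\sum(x-\bar x)(y-\bar y)}
#'   {\sqrt{\sum(x-\bar x)^2 \sum(y-\bar y)^2}}}
#' computed column by column. Columns with zero variance on either side give
#' NA (reported as missing and excluded from the mean/sd).
#'
#' @param real,virtual n x T numeric matrices of the same shape, n >= 3.
#' @return list with \code{r} (named per-trait vector), \code{mean},
#'   \code{sd}.
#' @export
trait_correlation <- function(real, virtual) {
  real <- as.matrix(real); virtual <- as.matrix(virtual)
  if (!all(dim(real) == dim(virtual))) stop("trait matrix shapes differ")
  if (nrow(real) < 3L) stop("need at least 3 samples")
  r <- vapply(seq_len(ncol(real)), function(j) {
    x <- virtual[, j]; y <- real[, j]
    dx <- x - mean(x); dy <- y - mean(y)
    den <- sqrt(sum(dx^2) * sum(dy^2))
    if (den == 0) return(NA_real_)
    sum(dx * dy) / den
  }, numeric(1))
  names(r) <- colnames(real)
  list(r = r, mean = mean(r, na.rm = TRUE), sd = stats::sd(r[!is.na(r)]))
}

#' Cosine similarity of two trait vectors
#'
#' \deqn{\cos\theta = \frac{\sum_i x_i y_i}
#'   {\sqrt{\sum_i x_i^2}\sqrt{\sum_i y_i^2}}}
#'
#' @param x,y numeric vectors of equal length with nonzero norms.
#' @return scalar in [-1, 1].
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vector lengths differ")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero vector")
  sum(x * y) / (nx * ny)
}

#' Compare a real and a virtual image set
#'
#' Core of the evaluation report: pairwise SSIM (record i against record i),
#' Fréchet distance between the two sets in feature space, traits
#' re-extracted from the virtual images (foreground recovered as non-black
#' pixels) compared by per-trait Pearson correlation, and per-record cosine
#' similarity of min-max normalized trait vectors (raw traits span several
#' orders of magnitude and would make the cosine trivially close to 1).
#'
#' @param real,virtual lists of H x W x 3 arrays in [0, 1], equal length.
#' @param real_traits n x 18 matrix of the real records' traits.
#' @param schema a \code{\link{trait_schema}}.
#' @param normalizer the dataset normalizer (for the cosine computation).
#' @param extractor feature extractor for the Fréchet distance.
#' @return an \code{eval_report}.
#' @export
evaluate_images <- function(real, virtual, real_traits, schema, normalizer,
                            extractor = "pixel") {
  n <- length(real)
  stopifnot(length(virtual) == n, nrow(real_traits) == n)
  ssim_vals <- vapply(seq_len(n), function(i)
    ssim(as_gray(real[[i]]) * 255, as_gray(virtual[[i]]) * 255), numeric(1))
  fid_val <- fid(embed(real, extractor), embed(virtual, extractor))

  virt_traits <- matrix(NA_real_, n, length(schema$ordered_names),
                        dimnames = list(NULL, schema$ordered_names))
  for (i in seq_len(n)) {
    m <- largest_component(mask_from_rgb(virtual[[i]]))
    if (sum(m) > 0L)
      virt_traits[i, ] <- extract_traits(virtual[[i]], m, schema)
  }
  ok <- stats::complete.cases(virt_traits)
  active <- schema$active
  corr <- trait_correlation(real_traits[ok, active, drop = FALSE],
                            virt_traits[ok, active, drop = FALSE])
  rn <- normalize_traits(real_traits[, , drop = FALSE], normalizer)[, active, drop = FALSE]
  vn <- normalize_traits(virt_traits[ok, , drop = FALSE], normalizer)[, active, drop = FALSE]
  cosv <- vapply(seq_len(sum(ok)), function(i) {
    xi <- vn[i, ]; yi <- rn[which(ok)[i], ]
    if (sum(xi^2) == 0 || sum(yi^2) == 0) return(NA_real_)
    cosine_similarity(xi, yi)
  }, numeric(1))
  structure(list(n = n, n_valid = sum(ok),
                 ssim_mean = mean(ssim_vals), ssim_sd = stats::sd(ssim_vals),
                 fid = fid_val,
                 corr_per_trait = corr$r, corr_mean = corr$mean,
                 corr_sd = corr$sd,
                 cosine_mean = mean(cosv, na.rm = TRUE),
                 cosine_sd = stats::sd(cosv[!is.na(cosv)]),
                 virtual_traits = virt_traits),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation over ", x$n, " image pairs (", x$n_valid,
      " with nonempty virtual foreground)\n", sep = "")
  cat(sprintf("  SSIM  %.4f +/- %.4f\n", x$ssim_mean, x$ssim_sd))
  cat(sprintf("  FID   %.4f (pixel-feature space)\n", x$fid))
  cat(sprintf("  trait correlation  mean %.4f +/- %.4f\n",
              x$corr_mean, x$corr_sd))
  cat(sprintf("  cosine similarity  mean %.4f +/- %.4f\n",
              x$cosine_mean, x$cosine_sd))
  invisible(x)
}

#' Evaluate a trained checkpoint on the test split
#'
#' Generates one virtual image per test record from its real traits and
#' compares the two sets with \code{\link{evaluate_images}}.
#'
#' @param checkpoint a \code{gan_checkpoint}.
#' @param manifest the dataset manifest holding the test split.
#' @param seed noise seed for generation.
#' @param extractor feature extractor for the Fréchet distance.
#' @return an \code{eval_report}.
#' @export
evaluate <- function(checkpoint, manifest, seed = 1L, extractor = "pixel") {
  sp <- manifest_split(manifest)
  if (length(sp$test) == 0L) stop("empty test split")
  recs <- manifest$records[sp$test]
  traits <- manifest_traits(manifest, sp$test)
  tab <- as.data.frame(traits)[, checkpoint$schema$active, drop = FALSE]
  virtual <- gan_generate(checkpoint, tab, seed = seed)
  real <- lapply(recs, `[[`, "rgb")
  evaluate_images(real, virtual, traits, manifest$schema,
                  manifest$normalizer, extractor = extractor)
}
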