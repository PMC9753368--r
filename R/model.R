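#' Preset configurations
#'
#' \code{"desk"} is a single-stage 64 x 64 configuration (small channel
#' widths, 8-dimensional noise, 60 epochs, batch 16) that trains on one CPU
#' in minutes; \code{"paper"} is the full three-stage 64/128/256 tree with
#' 100-dimensional noise and 600 epochs, sized for GPU-scale datasets.
#'
#' @param name \code{"desk"} or \code{"paper"}.
#' @param cond_dim number of active traits (16 or 18).
#' @param seed seed used for both weight init and training.
#' @return list with elements \code{gen} (a \code{\link{gan_config}}) and
#'   \code{train} (a \code{\link{train_config}}).
#' @export
gan_preset <- function(name = c("desk", "paper"), cond_dim = 18L, seed = 1L) {
  name <- match.arg(name)
  if (name == "desk") {
    list(gen = gan_config(n_stages = 1L, base_resolution = 64L, z_dim = 8L,
                          cond_dim = cond_dim, base_channels = 8L,
                          disc_channels = 8L, seed = seed),
         train = train_config(batch_size = 16L, epochs = 60L, seed = seed))
  } else {
    list(gen = gan_config(n_stages = 3L, base_resolution = 64L, z_dim = 100L,
                          cond_dim = cond_dim, base_channels = 32L,
                          disc_channels = 32L, seed = seed),
         train = train_config(batch_size = 16L, epochs = 600L, seed = seed))
  }
}

#' Fit a trait-to-image model
#'
#' High-level fitting interface: trains the trait-conditioned multi-stage
#' GAN on a dataset manifest and returns a fitted-model object with the
#' usual methods (\code{print}, \code{summary}, \code{predict}, \code{plot},
#' \code{simulate}).
#'
#' @param manifest a \code{\link{build_dataset}} result.
#' @param preset \code{"desk"} or \code{"paper"}; individual settings below
#'   override the preset.
#' @param stages,epochs,batch_size,z_dim,base_channels,disc_channels,lr,w_mis
#'   optional overrides of the preset configuration.
#' @param seed master seed (weights, shuffles, noise).
#' @param verbose print per-epoch progress.
#' @return an object of class \code{phenopaint} wrapping the trained
#'   checkpoint.
#' @examples
#' \donttest{
#' recs <- synth_dataset(40, seed = 1)
#' man <- build_dataset(recs, target_resolution = 64, test_fraction = 0.2)
#' fit <- phenopaint(man, epochs = 2, verbose = FALSE)
#' imgs <- predict(fit, newdata = test_traits(man))
#' }
#' @export
phenopaint <- function(manifest, preset = "desk", stages = NULL,
                       epochs = NULL, batch_size = NULL, z_dim = NULL,
                       base_channels = NULL, disc_channels = NULL,
                       lr = NULL, w_mis = NULL, seed = 1L, verbose = FALSE) {
  cond_dim <- length(manifest$schema$active)
  pr <- gan_preset(preset, cond_dim = cond_dim, seed = seed)
  g <- pr$gen; tr <- pr$train
  if (!is.null(stages)) g$n_stages <- as.integer(stages)
  if (!is.null(z_dim)) g$z_dim <- as.integer(z_dim)
  if (!is.null(base_channels)) g$base_channels <- as.integer(base_channels)
  if (!is.null(disc_channels)) g$disc_channels <- as.integer(disc_channels)
  g$base_resolution <- manifest$target_resolution %/% 2L^(g$n_stages - 1L)
  if (!is.null(epochs)) tr$epochs <- as.integer(epochs)
  if (!is.null(batch_size)) tr$batch_size <- as.integer(batch_size)
  if (!is.null(lr)) tr$lr <- lr
  if (!is.null(w_mis)) tr$w_mis <- w_mis
  ck <- gan_train(manifest, g, tr, verbose = verbose)
  structure(list(checkpoint = ck, manifest = manifest,
                 call = match.call()),
            class = "phenopaint")
}

#' Trait table of a manifest's test split
#'
#' Convenience accessor: the active-trait columns of the test records, ready
#' to feed to \code{predict} or \code{\link{gan_generate}}.
#'
#' @param manifest a \code{\link{build_dataset}} result.
#' @return data.frame of raw (unnormalized) active traits.
#' @export
test_traits <- function(manifest) {
  sp <- manifest_split(manifest)
  as.data.frame(manifest_traits(manifest, sp$test))[,
    manifest$schema$active, drop = FALSE]
}

#' @export
print.phenopaint <- function(x, ...) {
  cat("Trait-to-image GAN fit\n")
  print(x$checkpoint)
  invisible(x)
}

#' @export
summary.phenopaint <- function(object, ...) {
  ck <- object$checkpoint
  el <- ck$epoch_log
  cat("Trait-to-image GAN fit\n")
  cat("  stages: ", ck$config$n_stages, " (final side ",
      stage_side(ck$config, ck$config$n_stages), ")\n", sep = "")
  cat("  condition: ", ck$config$cond_dim, " traits (",
      ck$schema$variant, " schema), z_dim ", ck$config$z_dim, "\n", sep = "")
  cat("  training: ", ck$train_config$epochs, " epochs, batch ",
      ck$train_config$batch_size, ", lr ", ck$train_config$lr, "\n", sep = "")
  if (nrow(el) > 0) {
    cat(sprintf("  loss: D %.4f -> %.4f, G %.4f -> %.4f\n",
                el$d_loss[1], el$d_loss[nrow(el)],
                el$g_loss[1], el$g_loss[nrow(el)]))
    cat(sprintf("  monitor SSIM: %.4f -> %.4f\n",
                el$monitor_ssim[1], el$monitor_ssim[nrow(el)]))
  }
  invisible(object)
}

#' Generate images from new trait vectors
#'
#' @param object a fitted \code{\link{phenopaint}} model.
#' @param newdata data.frame of raw traits (columns = active schema traits);
#'   defaults to the manifest's test split.
#' @param seed noise seed.
#' @param ... unused.
#' @return list of H x W x 3 arrays in [0, 1].
#' @export
predict.phenopaint <- function(object, newdata = NULL, seed = 1L, ...) {
  if (is.null(newdata)) newdata <- test_traits(object$manifest)
  gan_generate(object$checkpoint, newdata, seed = seed)
}

#' Plot training diagnostics
#'
#' Left: per-epoch generator/discriminator loss; right: monitor-set SSIM.
#'
#' @param x a fitted \code{\link{phenopaint}} model.
#' @param ... passed to \code{matplot}.
#' @export
plot.phenopaint <- function(x, ...) {
  el <- x$checkpoint$epoch_log
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(el$epoch, cbind(el$d_loss, el$g_loss), type = "l",
                    lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("D", "G"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  graphics::plot(el$epoch, el$monitor_ssim, type = "l", xlab = "epoch",
                 ylab = "monitor SSIM")
  invisible(x)
}

#' Simulate images from the fitted model
#'
#' Draws \code{nsim} images for each supplied trait row (fresh noise per
#' draw), illustrating the many-images-per-trait-vector ambiguity the noise
#' input models.
#'
#' @param object a fitted \code{\link{phenopaint}} model.
#' @param nsim draws per trait row.
#' @param seed noise seed.
#' @param traits data.frame of raw traits; defaults to the first test record.
#' @param ... unused.
#' @return list of length nsim; each element a list of images.
#' @export
simulate.phenopaint <- function(object, nsim = 1, seed = 1L, traits = NULL,
                                ...) {
  if (is.null(traits)) traits <- test_traits(object$manifest)[1, , drop = FALSE]
  lapply(seq_len(nsim), function(s)
    gan_generate(object$checkpoint, traits, seed = seed + s - 1L))
}
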