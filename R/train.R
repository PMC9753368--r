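#' Training configuration
#'
#' Defaults follow the Adam settings used for this model family:
#' lr = 2e-4, beta_1 = 0.5, beta_2 = 0.999, epsilon = 1e-8.
#'
#' @param lr learning rate (> 0).
#' @param beta1,beta2 Adam moment decays in [0, 1).
#' @param epsilon Adam epsilon.
#' @param batch_size minibatch size.
#' @param epochs number of epochs.
#' @param w_mis weight of the mismatched-pair conditional discriminator term
#'   (0 disables it).
#' @param snapshot_every write a checkpoint every this many epochs (0 = only
#'   at the end); only used when an output directory is given.
#' @param seed master training seed (noise draws, shuffles).
#' @return a \code{train_config} list.
#' @export
train_config <- function(lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 16L, epochs = 60L,
                         w_mis = 1, snapshot_every = 0L, seed = 1L) {
  if (lr <= 0) stop("lr must be > 0")
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    stop("beta1 and beta2 must lie in [0, 1)")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), w_mis = w_mis,
                 snapshot_every = as.integer(snapshot_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Exact area-average downscale of an (H, W, C, N) array by an integer factor.
downscale_area <- function(a, f) {
  if (f == 1L) return(a)
  d <- dim(a)
  x <- rowsum(matrix(a, d[1], prod(d[-1])), rep(seq_len(d[1] %/% f), each = f))
  x <- aperm(array(x, c(d[1] %/% f, d[2], d[3], d[4])), c(2, 1, 3, 4))
  x <- rowsum(matrix(x, d[2], prod(d[c(1, 3, 4)]) %/% f),
              rep(seq_len(d[2] %/% f), each = f))
  x <- aperm(array(x, c(d[2] %/% f, d[1] %/% f, d[3], d[4])), c(2, 1, 3, 4))
  x / f^2
}

# Stack records' rgb arrays into an (H, W, 3, N) array in [0, 1].
stack_images <- function(records) {
  H <- nrow(records[[1]]$rgb)
  arr <- array(0, dim = c(H, H, 3L, length(records)))
  for (i in seq_along(records)) arr[, , , i] <- records[[i]]$rgb
  arr
}

# Slice an (H, W, 3, N) array into the [-1, 1] spatial matrix layout.
batch_layout <- function(arr, idx) {
  images_to_layout(arr[, , , idx, drop = FALSE])
}

#' Train the trait-conditioned GAN
#'
#' Alternates one discriminator step over all stages and one generator step
#' per minibatch. Real images at each stage resolution are obtained by exact
#' area-average downscaling of the stored records. The discriminator sees
#' real images with matched and (weight \code{w_mis}) mismatched conditions
#' plus generated images; the generator is scored by the updated
#' discriminators. Fully reproducible for a fixed seed on one device.
#'
#' A small monitor set (the first few test records, or train records when no
#' test split exists) is tracked once per epoch: its mean structural
#' similarity between generated and real images is logged.
#'
#' @param manifest a \code{\link{build_dataset}} result with a nonempty
#'   train split.
#' @param gen_config a \code{\link{gan_config}}; its final-stage side must
#'   equal the manifest resolution and its cond_dim the number of active
#'   traits.
#' @param tr_config a \code{\link{train_config}}.
#' @param out_dir optional directory for periodic checkpoints and the loss
#'   log CSV.
#' @param verbose print per-epoch progress.
#' @return a \code{gan_checkpoint}: trained parameters, configs, schema,
#'   normalizer state, per-batch \code{loss_log} and per-epoch
#'   \code{epoch_log}.
#' @export
gan_train <- function(manifest, gen_config, tr_config = train_config(),
                      out_dir = NULL, verbose = FALSE) {
  sp <- manifest_split(manifest)
  if (length(sp$train) == 0L) stop("empty train split")
  config <- gen_config
  final_side <- stage_side(config, config$n_stages)
  if (final_side != manifest$target_resolution)
    stop("final stage side ", final_side, " != manifest resolution ",
         manifest$target_resolution)
  active <- manifest$schema$active
  if (config$cond_dim != length(active))
    stop("cond_dim ", config$cond_dim, " != number of active traits ",
         length(active))

  cond_all <- normalize_traits(manifest_traits(manifest, sp$train),
                               manifest$normalizer)[, active, drop = FALSE]
  full <- stack_images(manifest$records[sp$train])
  reals <- lapply(seq_len(config$n_stages), function(k)
    downscale_area(full, final_side %/% stage_side(config, k)))

  monitor_idx <- if (length(sp$test) > 0L) sp$test[seq_len(min(8L, length(sp$test)))]
                 else sp$train[seq_len(min(8L, length(sp$train)))]
  monitor_real <- stack_images(manifest$records[monitor_idx])
  monitor_cond <- normalize_traits(manifest_traits(manifest, monitor_idx),
                                   manifest$normalizer)[, active, drop = FALSE]

  model <- gan_init(config)
  opt_g <- adam_new(); opt_d <- adam_new()
  g_names <- param_names(model, "g")
  d_names <- param_names(model, "d")

  n_train <- length(sp$train)
  B <- tr_config$batch_size
  n_batches <- ceiling(n_train / B)
  loss_log <- data.frame(epoch = integer(0), batch = integer(0),
                         d_loss = numeric(0), g_loss = numeric(0))
  epoch_log <- data.frame(epoch = integer(0), d_loss = numeric(0),
                          g_loss = numeric(0), monitor_ssim = numeric(0))

  set.seed(tr_config$seed)
  monitor_z <- if (config$z_dim > 0L)
    matrix(stats::rnorm(length(monitor_idx) * config$z_dim),
           ncol = config$z_dim) else NULL

  for (epoch in seq_len(tr_config$epochs)) {
    perm <- sample.int(n_train)
    ep_d <- ep_g <- 0
    for (b in seq_len(n_batches)) {
      idx <- perm[((b - 1L) * B + 1L):min(b * B, n_train)]
      nb <- length(idx)
      cb <- cond_all[idx, , drop = FALSE]
      cmis <- cb[c(seq_len(nb)[-1], 1L), , drop = FALSE]
      z <- if (config$z_dim > 0L)
        matrix(stats::rnorm(nb * config$z_dim), ncol = config$z_dim) else NULL

      # generator forward (training mode)
      tp_g <- tape_new(model$pe, train = TRUE)
      gb <- g_build(tp_g, z, cb, config)

      # ---- discriminator step over all stages ----
      d_grads <- new.env(parent = emptyenv())
      d_loss <- 0
      for (k in seq_len(config$n_stages)) {
        tp_d <- tape_new(model$pe, train = TRUE)
        xr <- t_input(tp_d, batch_layout(reals[[k]], idx),
                      H = stage_side(config, k), W = stage_side(config, k),
                      N = nb)
        cid <- t_input(tp_d, cb)
        cmid <- t_input(tp_d, cmis)
        dr <- d_build(tp_d, xr, cid, k, config)
        mis_id <- d_build_cond_head(tp_d, dr$trunk, cmid, k)
        xf <- t_input(tp_d, node_out(tp_g, gb$imgs[k]),
                      H = stage_side(config, k), W = stage_side(config, k),
                      N = nb)
        dfk <- d_build(tp_d, xf, cid, k, config)

        t_ru <- bce_logits(node_out(tp_d, dr$uncond), 1)
        t_rc <- bce_logits(node_out(tp_d, dr$cond), 1)
        t_fu <- bce_logits(node_out(tp_d, dfk$uncond), 0)
        t_fc <- bce_logits(node_out(tp_d, dfk$cond), 0)
        t_mc <- bce_logits(node_out(tp_d, mis_id), 0)
        d_loss <- d_loss + t_ru$loss + t_rc$loss + t_fu$loss + t_fc$loss +
          tr_config$w_mis * t_mc$loss
        seeds <- list()
        seeds[[as.character(dr$uncond)]] <- t_ru$grad
        seeds[[as.character(dr$cond)]] <- t_rc$grad
        seeds[[as.character(dfk$uncond)]] <- t_fu$grad
        seeds[[as.character(dfk$cond)]] <- t_fc$grad
        if (tr_config$w_mis > 0)
          seeds[[as.character(mis_id)]] <- tr_config$w_mis * t_mc$grad
        backward(tp_d, seeds, d_grads)
      }
      adam_step(model$pe, d_grads, opt_d, d_names, lr = tr_config$lr,
                beta1 = tr_config$beta1, beta2 = tr_config$beta2,
                eps = tr_config$epsilon)

      # ---- generator step (discriminators fixed, re-scored after update) --
      g_seeds <- list()
      g_loss <- 0
      for (k in seq_len(config$n_stages)) {
        db <- d_build(tp_g, gb$imgs[k], gb$c_id, k, config)
        t_u <- bce_logits(node_out(tp_g, db$uncond), 1)
        t_c <- bce_logits(node_out(tp_g, db$cond), 1)
        g_loss <- g_loss + t_u$loss + t_c$loss
        g_seeds[[as.character(db$uncond)]] <- t_u$grad
        g_seeds[[as.character(db$cond)]] <- t_c$grad
      }
      g_grads <- backward(tp_g, g_seeds)
      adam_step(model$pe, g_grads, opt_g, g_names, lr = tr_config$lr,
                beta1 = tr_config$beta1, beta2 = tr_config$beta2,
                eps = tr_config$epsilon)

      if (!is.finite(d_loss) || !is.finite(g_loss))
        stop("non-finite loss at epoch ", epoch, ", batch ", b,
             " (d = ", d_loss, ", g = ", g_loss, ")")
      loss_log <- rbind(loss_log,
                        data.frame(epoch = epoch, batch = b,
                                   d_loss = d_loss, g_loss = g_loss))
      ep_d <- ep_d + d_loss; ep_g <- ep_g + g_loss
    }

    ms <- monitor_ssim(model, monitor_z, monitor_cond, monitor_real, config)
    epoch_log <- rbind(epoch_log,
                       data.frame(epoch = epoch, d_loss = ep_d / n_batches,
                                  g_loss = ep_g / n_batches,
                                  monitor_ssim = ms))
    if (verbose)
      message(sprintf("epoch %3d  D %.4f  G %.4f  ssim %.4f",
                      epoch, ep_d / n_batches, ep_g / n_batches, ms))
    if (!is.null(out_dir) && tr_config$snapshot_every > 0L &&
        epoch %% tr_config$snapshot_every == 0L) {
      ck <- make_checkpoint(model, manifest, tr_config, loss_log, epoch_log)
      save_checkpoint(ck, file.path(out_dir, sprintf("epoch%04d.rds", epoch)))
    }
  }

  ck <- make_checkpoint(model, manifest, tr_config, loss_log, epoch_log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(ck, file.path(out_dir, "checkpoint.rds"))
    utils::write.csv(loss_log, file.path(out_dir, "loss_log.csv"),
                     row.names = FALSE)
    utils::write.csv(epoch_log, file.path(out_dir, "epoch_log.csv"),
                     row.names = FALSE)
  }
  ck
}

make_checkpoint <- function(model, manifest, tr_config, loss_log, epoch_log) {
  structure(list(params = as.list(model$pe), config = model$config,
                 schema = manifest$schema, normalizer = manifest$normalizer,
                 train_config = tr_config, loss_log = loss_log,
                 epoch_log = epoch_log),
            class = "gan_checkpoint")
}

checkpoint_model <- function(checkpoint) {
  structure(list(pe = list2env(checkpoint$params, parent = emptyenv()),
                 config = checkpoint$config),
            class = "gan_model")
}

#' @export
print.gan_checkpoint <- function(x, ...) {
  cat("GAN checkpoint: ", x$config$n_stages, " stage(s), final side ",
      stage_side(x$config, x$config$n_stages), ", cond_dim ",
      x$config$cond_dim, "\n", sep = "")
  if (nrow(x$epoch_log) > 0) {
    last <- x$epoch_log[nrow(x$epoch_log), ]
    cat(sprintf("  %d epochs trained; final D %.4f, G %.4f, monitor SSIM %.4f\n",
                last$epoch, last$d_loss, last$g_loss, last$monitor_ssim))
  }
  invisible(x)
}

#' Save / load a checkpoint archive
#'
#' The archive is self-contained: weights, generator config, trait schema
#' and normalizer state, so generation needs no other files.
#'
#' @param checkpoint a \code{gan_checkpoint}.
#' @param path file path (.rds).
#' @export
save_checkpoint <- function(checkpoint, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# Mean global SSIM of the monitor set under the current weights (eval mode).
monitor_ssim <- function(model, z, cond, real_arr, config) {
  gen <- generator_forward(model, z, cond, train = FALSE)
  imgs <- gen$images[[config$n_stages]]
  vals <- vapply(seq_len(dim(real_arr)[4]), function(i) {
    g <- (imgs[, , , i] + 1) / 2
    ssim(as_gray(g) * 255, as_gray(real_arr[, , , i]) * 255)
  }, numeric(1))
  mean(vals)
}

#' Generate images from a table of raw traits
#'
#' Each row is normalized with the checkpoint's stored min-max state, paired
#' with seeded noise, and mapped through the generator in evaluation mode.
#' Final-stage images are quantized to 8 bits.
#'
#' @param checkpoint a \code{gan_checkpoint} (or \code{\link{gan_train}}
#'   result).
#' @param traits data.frame or matrix whose columns are exactly the
#'   checkpoint schema's active traits (any order; extra or missing columns
#'   are an error).
#' @param seed seed for the noise draws.
#' @param out_dir optional directory to write PNGs into.
#' @return list of H x W x 3 arrays in [0, 1], one per row, at the final
#'   stage resolution.
#' @export
gan_generate <- function(checkpoint, traits, seed = 1L, out_dir = NULL) {
  model <- checkpoint_model(checkpoint)
  config <- checkpoint$config
  active <- checkpoint$schema$active
  tm <- as.matrix(as.data.frame(traits)[, , drop = FALSE])
  missing_cols <- setdiff(active, colnames(tm))
  extra <- setdiff(colnames(tm), active)
  if (length(missing_cols) > 0)
    stop("missing trait columns: ", paste(missing_cols, collapse = ", "))
  if (length(extra) > 0)
    stop("unexpected trait columns: ", paste(extra, collapse = ", "))
  norm_state <- checkpoint$normalizer
  sub <- structure(list(names = active,
                        min = norm_state$min[active],
                        max = norm_state$max[active]),
                   class = "trait_normalizer")
  cond <- normalize_traits(tm[, active, drop = FALSE], sub)
  n <- nrow(cond)
  z <- with_seed(seed, if (config$z_dim > 0L)
    matrix(stats::rnorm(n * config$z_dim), ncol = config$z_dim) else NULL)
  side <- stage_side(config, config$n_stages)
  out <- vector("list", n)
  for (start in seq(1L, n, by = 32L)) {
    idx <- start:min(start + 31L, n)
    gen <- generator_forward(model,
                             if (is.null(z)) NULL else z[idx, , drop = FALSE],
                             cond[idx, , drop = FALSE], train = FALSE)
    imgs <- gen$images[[config$n_stages]]
    for (j in seq_along(idx))
      out[[idx[j]]] <- round(pmin(pmax((imgs[, , , j] + 1) / 2, 0), 1) * 255) / 255
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ids <- rownames(tm)
    if (is.null(ids) || identical(ids, as.character(seq_len(n))))
      ids <- sprintf("gen%05d", seq_len(n))
    for (i in seq_len(n))
      write_rgb(out[[i]], file.path(out_dir, paste0(ids[i], ".png")))
  }
  out
}
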