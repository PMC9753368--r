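desk_small <- function(seed = 11L) {
  recs <- synth_dataset(32, seed = 201)
  man <- build_dataset(recs, target_resolution = 64, test_fraction = 0.125,
                       seed = 202)
  cfg <- gan_config(n_stages = 1L, base_resolution = 64L, z_dim = 4L,
                    cond_dim = 18L, base_channels = 4L, disc_channels = 4L,
                    seed = seed)
  list(man = man, cfg = cfg)
}

test_that("a short training run produces finite logs of the expected length", {
  d <- desk_small()
  tc <- train_config(batch_size = 16L, epochs = 2L, seed = 31L)
  ck <- gan_train(d$man, d$cfg, tc)
  n_train <- sum(vapply(d$man$records, `[[`, "", "split") == "train")
  expect_s3_class(ck, "gan_checkpoint")
  expect_identical(nrow(ck$loss_log), 2L * as.integer(ceiling(n_train / 16)))
  expect_true(all(is.finite(ck$loss_log$d_loss)))
  expect_true(all(is.finite(ck$loss_log$g_loss)))
  expect_identical(nrow(ck$epoch_log), 2L)
})

test_that("training is bit-reproducible under a fixed seed", {
  d <- desk_small()
  tc <- train_config(batch_size = 16L, epochs = 2L, seed = 77L)
  ck1 <- gan_train(d$man, d$cfg, tc)
  ck2 <- gan_train(d$man, d$cfg, tc)
  expect_identical(ck1$loss_log, ck2$loss_log)
  expect_identical(ck1$params, ck2$params)
})

test_that("generator and discriminator updates do not touch each other's weights", {
  pp <- asNamespace("phenopaint")
  d <- desk_small()
  cfg <- d$cfg
  model <- gan_init(cfg)
  set.seed(8)
  cb <- matrix(runif(4 * 18), 4)
  z <- matrix(rnorm(4 * cfg$z_dim), 4)
  real <- matrix(runif(64 * 64 * 4 * 3) * 2 - 1, 64 * 64 * 4, 3)

  snap <- function(who) {
    nms <- pp$param_names(model, who)
    stats::setNames(lapply(nms, function(n) model$pe[[n]]), nms)
  }

  # one discriminator-only update
  g_before <- snap("g")
  tp <- pp$tape_new(model$pe, train = TRUE)
  xr <- pp$t_input(tp, real, H = 64, W = 64, N = 4)
  cid <- pp$t_input(tp, cb)
  dr <- pp$d_build(tp, xr, cid, 1, cfg)
  lu <- pp$bce_logits(pp$node_out(tp, dr$uncond), 1)
  seeds <- list(); seeds[[as.character(dr$uncond)]] <- lu$grad
  grads <- pp$backward(tp, seeds)
  pp$adam_step(model$pe, grads, pp$adam_new(), pp$param_names(model, "d"))
  expect_identical(snap("g"), g_before)
  d_after <- snap("d")

  # one generator-only update driven through the discriminator
  tp <- pp$tape_new(model$pe, train = TRUE)
  gb <- pp$g_build(tp, z, cb, cfg)
  db <- pp$d_build(tp, gb$imgs[1], gb$c_id, 1, cfg)
  lu <- pp$bce_logits(pp$node_out(tp, db$uncond), 1)
  seeds <- list(); seeds[[as.character(db$uncond)]] <- lu$grad
  grads <- pp$backward(tp, seeds)
  pp$adam_step(model$pe, grads, pp$adam_new(), pp$param_names(model, "g"))
  expect_identical(snap("d"), d_after)
})

test_that("a single-image dataset is memorized: SSIM rises from first to last epoch", {
  r <- render_plant(plant_params(seed = 15, n_branches = 4))
  recs <- list(list(image_id = "a", rgb = r$rgb, mask = r$mask),
               list(image_id = "b", rgb = r$rgb, mask = r$mask))
  man <- build_dataset(recs, target_resolution = 64, test_fraction = 0.5,
                       seed = 1)
  cfg <- gan_config(n_stages = 1L, base_resolution = 64L, z_dim = 0L,
                    cond_dim = 18L, base_channels = 8L, disc_channels = 8L,
                    seed = 5L)
  tc <- train_config(batch_size = 1L, epochs = 200L, seed = 9L)
  ck <- gan_train(man, cfg, tc)
  expect_gt(ck$epoch_log$monitor_ssim[200], ck$epoch_log$monitor_ssim[1])
})

test_that("generation is seeded, sized by the checkpoint, and checks its columns", {
  d <- desk_small()
  tc <- train_config(batch_size = 16L, epochs = 1L, seed = 13L)
  ck <- gan_train(d$man, d$cfg, tc)
  tab <- test_traits(d$man)[rep(1, 5), ]
  imgs <- gan_generate(ck, tab, seed = 21)
  expect_length(imgs, 5L)
  expect_identical(dim(imgs[[1]]), c(64L, 64L, 3L))
  expect_identical(gan_generate(ck, tab[1, ], seed = 21)[[1]], imgs[[1]])

  expect_error(gan_generate(ck, tab[, -3], seed = 1), "missing trait")
  bad <- cbind(tab, junk = 1)
  expect_error(gan_generate(ck, bad, seed = 1), "unexpected trait")

  ser <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, ser)
  ck2 <- load_checkpoint(ser)
  expect_identical(gan_generate(ck2, tab, seed = 21), imgs)
})
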