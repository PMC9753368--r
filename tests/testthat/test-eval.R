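test_that("structural similarity obeys identity, symmetry and its zero-variance closed form", {
  set.seed(14)
  x <- matrix(runif(32 * 32, 0, 255), 32)
  y <- matrix(runif(32 * 32, 0, 255), 32)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)

  black <- matrix(0, 16, 16)
  white <- matrix(255, 16, 16)
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  expect_equal(ssim(black, white), c1 * c2 / ((255^2 + c1) * c2),
               tolerance = 1e-12)

  expect_error(ssim(x, matrix(0, 16, 16)), "dimensions")
  # windowed variant also satisfies identity
  expect_equal(ssim(x, x, window = 8L), 1, tolerance = 1e-12)
})

test_that("the Fréchet distance matches 1-D closed forms and is symmetric and nonnegative", {
  fs <- function(mu, sigma) structure(list(mu = mu, sigma = sigma, n = 10L),
                                      class = "feature_stats")
  a <- fs(0, matrix(1)); b <- fs(2, matrix(1))
  expect_equal(fid(a, a), 0, tolerance = 1e-8)
  expect_equal(fid(a, b), 4, tolerance = 1e-8)

  set.seed(15)
  d <- rnorm(5)
  S <- crossprod(matrix(rnorm(25), 5))
  expect_equal(fid(fs(d, S), fs(rep(0, 5), S)), sum(d^2), tolerance = 1e-8)

  S2 <- crossprod(matrix(rnorm(25), 5))
  expect_equal(fid(fs(d, S), fs(rep(0, 5), S2)),
               fid(fs(rep(0, 5), S2), fs(d, S)), tolerance = 1e-8)
  expect_gte(fid(fs(d, S), fs(rep(0, 5), S2)), 0)

  # diagonal case: sum of per-dimension (mu Delta)^2 + (sd difference)^2
  s1 <- c(1, 4, 9); s2 <- c(4, 1, 1)
  expect_equal(fid(fs(c(1, 2, 3), diag(s1)), fs(c(0, 0, 0), diag(s2))),
               sum(c(1, 2, 3)^2) + sum((sqrt(s1) - sqrt(s2))^2),
               tolerance = 1e-8)
  expect_error(fid(a, fs(rep(0, 2), diag(2))), "dimensions")
})

test_that("the pixel embedding yields 64 features and zero distance on duplicated sets", {
  set.seed(16)
  imgs <- lapply(1:5, function(i) array(runif(256 * 256 * 3),
                                        dim = c(256, 256, 3)))
  st <- embed(imgs)
  expect_length(st$mu, 64L)
  expect_identical(dim(st$sigma), c(64L, 64L))
  expect_equal(fid(st, embed(imgs)), 0, tolerance = 1e-8)

  dup <- rep(imgs[1], 4)
  expect_true(all(abs(embed(dup)$sigma) < 1e-12))
  expect_error(embed(imgs[1]), "at least 2")

  # set statistics ignore ordering
  expect_equal(fid(embed(imgs), embed(rev(imgs))), 0, tolerance = 1e-8)
})

test_that("per-trait correlation matches hand and library computations", {
  set.seed(17)
  real <- matrix(rnorm(150), 50, 3)
  expect_equal(unname(trait_correlation(real, real)$r), rep(1, 3))
  centered <- sweep(real, 2, colMeans(real))
  expect_equal(unname(trait_correlation(real, -centered)$r), rep(-1, 3))

  # 4-point example, frozen from brute-force evaluation of the formula
  tc <- trait_correlation(matrix(c(1, 2, 3, 4)), matrix(c(2, 4, 5, 9)))
  expect_equal(unname(tc$r), 0.9647638, tolerance = 1e-4)

  # independent oracle: stats::cor on a random 50 x 18 pair
  a <- matrix(rnorm(900), 50, 18)
  b <- a + matrix(rnorm(900, sd = 0.5), 50, 18)
  expect_equal(unname(trait_correlation(a, b)$r),
               unname(diag(stats::cor(b, a))), tolerance = 1e-10)

  const <- cbind(a[, 1], rep(2, 50))
  expect_true(is.na(trait_correlation(const, const + 0)$r[2]))
  expect_error(trait_correlation(a, b[, 1:3]), "shapes")
})

test_that("cosine similarity matches its closed forms", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2),
               tolerance = 1e-9)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(1:3, 1:4), "lengths")
})

test_that("feeding the real images back as virtual gives the perfect report", {
  sp <- phenopaint:::manifest_split(tiny_manifest)
  idx <- c(sp$train, sp$test)[1:20]
  real <- lapply(tiny_manifest$records[idx], `[[`, "rgb")
  traits <- phenopaint:::manifest_traits(tiny_manifest, idx)
  rep <- evaluate_images(real, real, traits, tiny_manifest$schema,
                         tiny_manifest$normalizer)
  expect_equal(rep$ssim_mean, 1, tolerance = 1e-9)
  expect_equal(rep$fid, 0, tolerance = 1e-6)
  r <- rep$corr_per_trait
  expect_true(all(abs(r[!is.na(r)] - 1) < 1e-9))
  expect_equal(rep$cosine_mean, 1, tolerance = 1e-9)
})

test_that("a smoke evaluation of a barely trained model is finite everywhere", {
  cfg <- gan_config(n_stages = 1L, base_resolution = 64L, z_dim = 4L,
                    cond_dim = 18L, base_channels = 4L, disc_channels = 4L,
                    seed = 23L)
  ck <- gan_train(tiny_manifest, cfg,
                  train_config(batch_size = 16L, epochs = 1L, seed = 24L))
  rep <- evaluate(ck, tiny_manifest, seed = 25)
  expect_true(is.finite(rep$ssim_mean))
  expect_true(is.finite(rep$fid))
  expect_true(is.finite(rep$cosine_mean))
  expect_identical(rep$n, length(phenopaint:::manifest_split(tiny_manifest)$test))
})
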