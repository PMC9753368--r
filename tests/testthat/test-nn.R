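pp <- asNamespace("phenopaint")

test_that("the two convolution kernels agree with each other and with a brute-force loop", {
  brute_conv <- function(X, Wm, b, H, W, N, k, s, p) {
    Cin <- ncol(X); Cout <- ncol(Wm)
    Ho <- (H + 2 * p - k) %/% s + 1; Wo <- (W + 2 * p - k) %/% s + 1
    Y <- matrix(0, Ho * Wo * N, Cout)
    Xa <- array(X, c(H, W, N, Cin))
    for (n in 1:N) for (wo in 1:Wo) for (ho in 1:Ho) for (co in 1:Cout) {
      acc <- b[co]
      for (ci in 1:Cin) for (kw in 1:k) for (kh in 1:k) {
        hi <- (ho - 1) * s - p + kh; wi <- (wo - 1) * s - p + kw
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          acc <- acc + Xa[hi, wi, n, ci] *
            Wm[(kh - 1) + k * (kw - 1) + k * k * (ci - 1) + 1, co]
      }
      Y[(ho - 1) + Ho * (wo - 1) + Ho * Wo * (n - 1) + 1, co] <- acc
    }
    Y
  }
  set.seed(2)
  for (cse in list(c(5, 7, 2, 3, 2, 3, 1, 1), c(8, 8, 2, 2, 3, 4, 2, 1))) {
    H <- cse[1]; W <- cse[2]; N <- cse[3]; Cin <- cse[4]; Cout <- cse[5]
    k <- cse[6]; s <- cse[7]; p <- cse[8]
    X <- matrix(rnorm(H * W * N * Cin), H * W * N, Cin)
    Wm <- matrix(rnorm(k * k * Cin * Cout), k * k * Cin, Cout)
    b <- rnorm(Cout)
    ref <- brute_conv(X, Wm, b, H, W, N, k, s, p)
    r1 <- pp$conv2d_fwd(X, Wm, b, H, W, N, k, s, p)
    y2 <- pp$conv2d_fwd_direct(X, Wm, b, H, W, N, k, s, p)
    expect_equal(r1$Y, ref, tolerance = 1e-12)
    expect_equal(y2, ref, tolerance = 1e-12)
    dY <- matrix(rnorm(length(ref)), nrow(ref))
    b1 <- pp$conv2d_bwd(r1$P, Wm, dY, H, W, N, Cin, k, s, p)
    b2 <- pp$conv2d_bwd_direct(X, Wm, dY, H, W, N, k, s, p)
    expect_equal(b1$dX, b2$dX, tolerance = 1e-12)
    expect_equal(b1$dW, b2$dW, tolerance = 1e-12)
    expect_equal(as.numeric(b1$db), as.numeric(b2$db), tolerance = 1e-12)
  }
})

test_that("tape gradients match central finite differences through generator and discriminator", {
  set.seed(1)
  cfg <- gan_config(n_stages = 1, base_resolution = 8, z_dim = 3,
                    cond_dim = 2, base_channels = 4, disc_channels = 4,
                    seed = 7)
  model <- gan_init(cfg)
  z <- matrix(rnorm(2 * 3), 2)
  cv <- matrix(runif(4), 2)
  loss_fn <- function() {
    tp <- pp$tape_new(model$pe, train = TRUE)
    gb <- pp$g_build(tp, z, cv, cfg)
    db <- pp$d_build(tp, gb$imgs[1], gb$c_id, 1, cfg)
    lu <- pp$bce_logits(pp$node_out(tp, db$uncond), 1)
    lc <- pp$bce_logits(pp$node_out(tp, db$cond), 1)
    seeds <- list()
    seeds[[as.character(db$uncond)]] <- lu$grad
    seeds[[as.character(db$cond)]] <- lc$grad
    list(loss = lu$loss + lc$loss, grads = pp$backward(tp, seeds))
  }
  base <- loss_fn()
  for (nm in c("g1_fc_W", "g1_fcbn_g", "g1_u1_c_W", "g1_u1_bn_B", "g1_img_W",
               "d1_c1_W", "d1_cj_W", "d1_cjbn_g", "d1_ul_W", "d1_cl_b")) {
    pv <- model$pe[[nm]]
    i <- sample(length(pv), 1)
    eps <- 1e-5
    model$pe[[nm]][i] <- pv[i] + eps; lp <- loss_fn()$loss
    model$pe[[nm]][i] <- pv[i] - eps; lm <- loss_fn()$loss
    model$pe[[nm]][i] <- pv[i]
    num <- (lp - lm) / (2 * eps)
    ana <- base$grads[[nm]][i]
    expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
  }
})

test_that("binary cross-entropy with logits matches closed forms and stays finite", {
  r <- pp$bce_logits(matrix(0, 4, 1), 1)
  expect_equal(r$loss, log(2), tolerance = 1e-12)
  expect_equal(pp$bce_logits(matrix(0, 4, 1), 0)$loss, log(2),
               tolerance = 1e-12)
  # near-perfect confident logits: loss essentially zero, gradients finite
  big <- pp$bce_logits(matrix(50, 3, 1), 1)
  expect_lt(big$loss, 1e-5)
  expect_true(all(is.finite(big$grad)))
  expect_true(is.finite(pp$bce_logits(matrix(-500, 2, 1), 0)$loss))
})

test_that("one Adam step at t = 1 reduces to a signed step of size lr", {
  pe <- new.env(); pe$w <- c(1, -2)
  st <- pp$adam_new()
  g <- new.env(); g$w <- c(0.3, -0.7)
  pp$adam_step(pe, g, st, "w", lr = 0.01, beta1 = 0.5, beta2 = 0.999,
               eps = 1e-8)
  # m/bc1 = grad, sqrt(v/bc2) = |grad| at the first step
  expect_equal(pe$w, c(1, -2) - 0.01 * sign(c(0.3, -0.7)), tolerance = 1e-6)
})

test_that("layout round trip between image arrays and spatial matrices is lossless", {
  set.seed(3)
  a <- array(runif(8 * 8 * 3 * 4), dim = c(8, 8, 3, 4))
  X <- pp$images_to_layout(a)
  expect_identical(dim(X), c(8L * 8L * 4L, 3L))
  back <- pp$layout_to_images(X, 8, 8, 4)
  expect_equal(back, a, tolerance = 1e-12)
})
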