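# Minimal reverse-mode tape for the GAN networks.
#
# Feature maps live in a (H*W*N) x C matrix layout (rows: h fastest, then w,
# then batch index n; columns: channels), so convolution reduces to
# im2col + one BLAS matmul (src/conv_ops.cpp), batch normalization to
# column-wise moments, and channel concatenation to cbind. Parameters are
# kept in an environment so batchnorm running statistics and Adam updates
# mutate in place.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

.pp_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .pp_cache, inherits = FALSE))
    assign(key, builder(), envir = .pp_cache)
  get(key, envir = .pp_cache, inherits = FALSE)
}

# ---- parameter initialisation -------------------------------------------

init_dense <- function(pe, name, n_in, n_out, std = 0.02) {
  pe[[paste0(name, "_W")]] <- matrix(stats::rnorm(n_in * n_out, 0, std), n_in, n_out)
  pe[[paste0(name, "_b")]] <- numeric(n_out)
}

init_conv <- function(pe, name, c_in, c_out, k, std = 0.02) {
  pe[[paste0(name, "_W")]] <- matrix(stats::rnorm(k * k * c_in * c_out, 0, std),
                                     k * k * c_in, c_out)
  pe[[paste0(name, "_b")]] <- numeric(c_out)
}

init_bn <- function(pe, name, c) {
  pe[[paste0(name, "_g")]] <- rep(1, c)
  # small random shift: with an exactly constant input batch the normalized
  # activations are zero and the output equals beta, so beta = 0 would leave
  # every ReLU unit dead and block all upstream gradients
  pe[[paste0(name, "_B")]] <- stats::rnorm(c, 0, 0.02)
  pe[[paste0(name, "_rm")]] <- numeric(c)
  pe[[paste0(name, "_rv")]] <- rep(1, c)
}

# ---- tape ----------------------------------------------------------------

tape_new <- function(pe, train = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$pe <- pe
  tp$train <- train
  tp$nodes <- list()
  tp
}

node_add <- function(tp, node) {
  tp$nodes[[length(tp$nodes) + 1L]] <- node
  length(tp$nodes)
}

# force id before touching tp$nodes: the id argument is often a nested t_*
# call that itself appends nodes to the tape
node_out <- function(tp, id) { force(id); tp$nodes[[id]]$out }
node_meta <- function(tp, id) { force(id); tp$nodes[[id]]$meta }

# meta: list(H, W, N) spatial geometry; for dense nodes H = W = NULL, N rows.
t_input <- function(tp, X, H = NULL, W = NULL, N = NULL) {
  if (is.null(N)) N <- nrow(X)
  node_add(tp, list(op = "input", out = X, meta = list(H = H, W = W, N = N)))
}

t_dense <- function(tp, x, name) {
  X <- node_out(tp, x)
  W <- tp$pe[[paste0(name, "_W")]]
  b <- tp$pe[[paste0(name, "_b")]]
  Y <- X %*% W
  Y <- sweep(Y, 2, b, "+")
  node_add(tp, list(op = "dense", ins = x, name = name, out = Y,
                    meta = node_meta(tp, x)))
}

t_conv <- function(tp, x, name, k, s = 1L, p = (k - 1L) %/% 2L) {
  X <- node_out(tp, x)
  m <- node_meta(tp, x)
  W <- tp$pe[[paste0(name, "_W")]]
  b <- tp$pe[[paste0(name, "_b")]]
  Ho <- (m$H + 2L * p - k) %/% s + 1L
  Wo <- (m$W + 2L * p - k) %/% s + 1L
  # the im2col route materializes a (Ho*Wo*N) x (k^2*Cin) patch matrix;
  # above ~4 MB the direct accumulation kernel is faster
  direct <- as.numeric(Ho) * Wo * m$N * k * k * ncol(X) * 8 > 4e6
  if (direct) {
    Y <- conv2d_fwd_direct(X, W, b, m$H, m$W, m$N, k, s, p)
    cache <- list(direct = TRUE, Cin = ncol(X))
  } else {
    r <- conv2d_fwd(X, W, b, m$H, m$W, m$N, k, s, p)
    Y <- r$Y
    cache <- list(direct = FALSE, P = r$P, Cin = ncol(X))
  }
  node_add(tp, list(op = "conv", ins = x, name = name, k = k, s = s, p = p,
                    out = Y, cache = cache,
                    meta = list(H = Ho, W = Wo, N = m$N)))
}

t_bn <- function(tp, x, name) {
  X <- node_out(tp, x)
  g <- tp$pe[[paste0(name, "_g")]]
  B <- tp$pe[[paste0(name, "_B")]]
  if (tp$train) {
    mu <- colMeans(X)
    va <- colMeans(X * X) - mu^2
    va[va < 0] <- 0
    tp$pe[[paste0(name, "_rm")]] <- (1 - BN_MOMENTUM) * tp$pe[[paste0(name, "_rm")]] + BN_MOMENTUM * mu
    tp$pe[[paste0(name, "_rv")]] <- (1 - BN_MOMENTUM) * tp$pe[[paste0(name, "_rv")]] + BN_MOMENTUM * va
  } else {
    mu <- tp$pe[[paste0(name, "_rm")]]
    va <- tp$pe[[paste0(name, "_rv")]]
  }
  invstd <- 1 / sqrt(va + BN_EPS)
  r <- bn_fwd_cpp(X, g, B, mu, invstd)
  node_add(tp, list(op = "bn", ins = x, name = name, out = r$Y,
                    cache = list(xhat = r$xhat, invstd = invstd),
                    meta = node_meta(tp, x)))
}

t_relu <- function(tp, x) {
  node_add(tp, list(op = "relu", ins = x, out = relu_fwd(node_out(tp, x)),
                    meta = node_meta(tp, x)))
}

t_lrelu <- function(tp, x, alpha = 0.2) {
  node_add(tp, list(op = "lrelu", ins = x,
                    out = lrelu_fwd(node_out(tp, x), alpha),
                    cache = list(alpha = alpha), meta = node_meta(tp, x)))
}

t_tanh <- function(tp, x) {
  Y <- tanh(node_out(tp, x))
  node_add(tp, list(op = "tanh", ins = x, out = Y, cache = list(y = Y),
                    meta = node_meta(tp, x)))
}

up2_index <- function(H, W, N) {
  cache_get(sprintf("up2_%d_%d_%d", H, W, N), function() {
    # output row (ho, wo, n) gathers input row (ho %/% 2, wo %/% 2, n)
    ho <- rep(seq_len(2 * H), times = 2 * W * N)
    wo <- rep(rep(seq_len(2 * W), each = 2 * H), times = N)
    n <- rep(seq_len(N), each = 4 * H * W)
    hi <- (ho + 1L) %/% 2L
    wi <- (wo + 1L) %/% 2L
    hi + H * (wi - 1L) + H * W * (n - 1L)
  })
}

t_up2 <- function(tp, x) {
  m <- node_meta(tp, x)
  idx <- up2_index(m$H, m$W, m$N)
  X <- node_out(tp, x)
  node_add(tp, list(op = "up2", ins = x, out = X[idx, , drop = FALSE],
                    cache = list(idx = idx, n_in = nrow(X)),
                    meta = list(H = 2L * m$H, W = 2L * m$W, N = m$N)))
}

t_add <- function(tp, x1, x2) {
  node_add(tp, list(op = "add", ins = c(x1, x2),
                    out = node_out(tp, x1) + node_out(tp, x2),
                    meta = node_meta(tp, x1)))
}

t_concat <- function(tp, x1, x2) {
  X1 <- node_out(tp, x1); X2 <- node_out(tp, x2)
  node_add(tp, list(op = "concat", ins = c(x1, x2), out = cbind(X1, X2),
                    cache = list(n1 = ncol(X1)), meta = node_meta(tp, x1)))
}

# Spatially replicate a per-sample vector (N x T) over an H x W grid.
t_tile <- function(tp, x, H, W) {
  X <- node_out(tp, x)
  N <- nrow(X)
  idx <- rep(seq_len(N), each = H * W)
  node_add(tp, list(op = "tile", ins = x, out = X[idx, , drop = FALSE],
                    cache = list(idx = idx, n_in = N),
                    meta = list(H = H, W = W, N = N)))
}

# N x (H*W*C) dense activations (columns ordered h, w, c) -> spatial layout.
t_reshape_spatial <- function(tp, x, H, W, C) {
  X <- node_out(tp, x)
  N <- nrow(X)
  a <- array(t(X), dim = c(H, W, C, N))
  Y <- matrix(aperm(a, c(1, 2, 4, 3)), H * W * N, C)
  node_add(tp, list(op = "reshape", ins = x, out = Y,
                    cache = list(C = C, Nn = N),
                    meta = list(H = H, W = W, N = N)))
}

backward <- function(tp, seeds, grads = NULL) {
  if (is.null(grads)) grads <- new.env(parent = emptyenv())
  n <- length(tp$nodes)
  pend <- vector("list", n)
  for (id in names(seeds)) pend[[as.integer(id)]] <- seeds[[id]]
  acc_param <- function(name, g) {
    if (is.null(grads[[name]])) grads[[name]] <- g
    else grads[[name]] <- grads[[name]] + g
  }
  acc_pend <- function(id, g) {
    if (is.null(pend[[id]])) pend[[id]] <<- g else pend[[id]] <<- pend[[id]] + g
  }
  for (i in rev(seq_len(n))) {
    dY <- pend[[i]]
    if (is.null(dY)) next
    nd <- tp$nodes[[i]]
    switch(nd$op,
      input = NULL,
      dense = {
        X <- node_out(tp, nd$ins)
        W <- tp$pe[[paste0(nd$name, "_W")]]
        acc_param(paste0(nd$name, "_W"), crossprod(X, dY))
        acc_param(paste0(nd$name, "_b"), colSums(dY))
        acc_pend(nd$ins, tcrossprod(dY, W))
      },
      conv = {
        m <- node_meta(tp, nd$ins)
        r <- if (nd$cache$direct)
          conv2d_bwd_direct(node_out(tp, nd$ins),
                            tp$pe[[paste0(nd$name, "_W")]],
                            dY, m$H, m$W, m$N, nd$k, nd$s, nd$p)
        else
          conv2d_bwd(nd$cache$P, tp$pe[[paste0(nd$name, "_W")]],
                     dY, m$H, m$W, m$N, nd$cache$Cin, nd$k, nd$s, nd$p)
        acc_param(paste0(nd$name, "_W"), r$dW)
        acc_param(paste0(nd$name, "_b"), as.numeric(r$db))
        acc_pend(nd$ins, r$dX)
      },
      bn = {
        g <- tp$pe[[paste0(nd$name, "_g")]]
        invstd <- nd$cache$invstd
        if (tp$train) {
          r <- bn_bwd_cpp(nd$cache$xhat, dY, g, invstd)
          acc_param(paste0(nd$name, "_g"), as.numeric(r$dg))
          acc_param(paste0(nd$name, "_B"), as.numeric(r$dB))
          acc_pend(nd$ins, r$dX)
        } else {
          acc_param(paste0(nd$name, "_g"), colSums(dY * nd$cache$xhat))
          acc_param(paste0(nd$name, "_B"), colSums(dY))
          acc_pend(nd$ins, sweep(dY, 2, g * invstd, "*"))
        }
      },
      relu = acc_pend(nd$ins, relu_bwd(nd$out, dY)),
      lrelu = acc_pend(nd$ins, lrelu_bwd(nd$out, dY, nd$cache$alpha)),
      tanh = acc_pend(nd$ins, dY * (1 - nd$cache$y^2)),
      up2 = acc_pend(nd$ins, rowsum(dY, nd$cache$idx,
                                    reorder = TRUE)),
      add = { acc_pend(nd$ins[1], dY); acc_pend(nd$ins[2], dY) },
      concat = {
        n1 <- nd$cache$n1
        acc_pend(nd$ins[1], dY[, seq_len(n1), drop = FALSE])
        acc_pend(nd$ins[2], dY[, -seq_len(n1), drop = FALSE])
      },
      tile = acc_pend(nd$ins, rowsum(dY, nd$cache$idx, reorder = TRUE)),
      reshape = {
        m <- nd$meta
        a <- array(dY, dim = c(m$H, m$W, m$N, nd$cache$C))
        a <- aperm(a, c(1, 2, 4, 3))  # -> H, W, C, N
        acc_pend(nd$ins, t(matrix(a, m$H * m$W * nd$cache$C, m$N)))
      },
      stop("unknown op ", nd$op))
  }
  grads
}

# ---- losses --------------------------------------------------------------

# Numerically stable binary cross-entropy with logits; returns the mean loss
# and the gradient wrt the logits (already divided by the sample count).
bce_logits <- function(logits, target) {
  x <- as.numeric(logits)
  loss <- mean(pmax(x, 0) - x * target + log1p(exp(-abs(x))))
  grad <- matrix((1 / (1 + exp(-x)) - target) / length(x), length(x), 1)
  list(loss = loss, grad = grad)
}

# ---- Adam ----------------------------------------------------------------

adam_new <- function() {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- list()
  st$v <- list()
  st
}

adam_step <- function(pe, grads, st, names, lr = 2e-4, beta1 = 0.5,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- st$m[[nm]]; v <- st$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    st$m[[nm]] <- m; st$v[[nm]] <- v
    pe[[nm]] <- pe[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  invisible(NULL)
}

# Convert a batch of images (H x W x 3 x N array, values in [0, 1]) to the
# spatial matrix layout scaled to [-1, 1], and back.
images_to_layout <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3]) * 2 - 1
}

layout_to_images <- function(X, H, W, N) {
  a <- array(X, dim = c(H, W, N, 3L))
  (aperm(a, c(1, 2, 4, 3)) + 1) / 2
}
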