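#' Configuration of the trait-conditioned multi-stage GAN
#'
#' The generator follows a tree of up to three stages. Stage 1 maps the
#' concatenated noise and condition vector through a fully connected block
#' (linear + batchnorm) to a 4 x 4 feature map, then through upsampling
#' blocks (nearest upsample + 3x3 conv + batchnorm + ReLU) to the base
#' resolution, emitting a tanh image and the hidden feature map h1. Each
#' later stage spatially replicates the condition vector, concatenates it
#' with the previous hidden features along the channel dimension, and applies
#' a joint block (conv + batchnorm), two residual blocks, one upsampling
#' block and a tanh image head, doubling the side per stage (64/128/256 at
#' defaults). Each stage has its own discriminator with an unconditional
#' real-vs-fake head and a conditional trait-match head.
#'
#' @param n_stages number of generator/discriminator stages (1-3).
#' @param base_resolution stage-1 output side in pixels (default 64).
#' @param z_dim noise vector length; 0 gives a deterministic trait-to-image
#'   mapping, the default 100 models the many-images-per-trait ambiguity.
#' @param cond_dim length of the condition vector (16 or 18 active traits).
#' @param base_channels generator channel width unit; stage 1 starts at
#'   8 * base_channels at 4 x 4 and halves per upsampling block.
#' @param disc_channels discriminator channel width unit.
#' @param seed seed for weight initialisation.
#' @return a \code{gan_config} list.
#' @export
gan_config <- function(n_stages = 3L, base_resolution = 64L, z_dim = 100L,
                       cond_dim = 18L, base_channels = 32L,
                       disc_channels = 32L, seed = 1L) {
  if (!n_stages %in% 1:3) stop("n_stages must be 1, 2 or 3")
  if (log2(base_resolution) %% 1 != 0 || base_resolution < 8)
    stop("base_resolution must be a power of two >= 8")
  structure(list(n_stages = as.integer(n_stages),
                 base_resolution = as.integer(base_resolution),
                 z_dim = as.integer(z_dim), cond_dim = as.integer(cond_dim),
                 base_channels = as.integer(base_channels),
                 disc_channels = as.integer(disc_channels),
                 seed = as.integer(seed)),
            class = "gan_config")
}

# Generator channel schedule: stage-1 blocks halve from 8*gf; each later
# stage halves its input hidden width once more (floor 4 channels).
gen_channels <- function(config) {
  gf <- config$base_channels
  n_up <- as.integer(log2(config$base_resolution)) - 2L
  ch <- pmax(8L * gf %/% 2L^(0:n_up), 4L)
  list(n_up = n_up, fc = ch[1], up = ch[-1], h1 = ch[length(ch)])
}

stage_side <- function(config, k) config$base_resolution * 2L^(k - 1L)

#' Initialise GAN weights
#'
#' @param config a \code{\link{gan_config}}.
#' @return a \code{gan_model} holding the parameter environment and config.
#' @export
gan_init <- function(config) {
  pe <- new.env(parent = emptyenv())
  gc_ <- gen_channels(config)
  with_seed(config$seed, {
    # stage 1 generator
    init_dense(pe, "g1_fc", config$z_dim + config$cond_dim, 16L * gc_$fc)
    init_bn(pe, "g1_fcbn", 16L * gc_$fc)
    c_in <- gc_$fc
    for (i in seq_len(gc_$n_up)) {
      init_conv(pe, paste0("g1_u", i, "_c"), c_in, gc_$up[i], 3L)
      init_bn(pe, paste0("g1_u", i, "_bn"), gc_$up[i])
      c_in <- gc_$up[i]
    }
    init_conv(pe, "g1_img", c_in, 3L, 3L)
    # later stages
    h_ch <- c_in
    for (k in 2:3) {
      if (k > config$n_stages) break
      pre <- paste0("g", k, "_")
      init_conv(pe, paste0(pre, "joint_c"), h_ch + config$cond_dim, h_ch, 3L)
      init_bn(pe, paste0(pre, "joint_bn"), h_ch)
      for (r in 1:2) {
        init_conv(pe, paste0(pre, "r", r, "_c1"), h_ch, h_ch, 3L)
        init_bn(pe, paste0(pre, "r", r, "_bn1"), h_ch)
        init_conv(pe, paste0(pre, "r", r, "_c2"), h_ch, h_ch, 3L)
        init_bn(pe, paste0(pre, "r", r, "_bn2"), h_ch)
      }
      up_ch <- max(h_ch %/% 2L, 4L)
      init_conv(pe, paste0(pre, "u_c"), h_ch, up_ch, 3L)
      init_bn(pe, paste0(pre, "u_bn"), up_ch)
      init_conv(pe, paste0(pre, "img"), up_ch, 3L, 3L)
      h_ch <- up_ch
    }
    # discriminators
    df <- config$disc_channels
    for (k in seq_len(config$n_stages)) {
      pre <- paste0("d", k, "_")
      side <- stage_side(config, k)
      n_down <- as.integer(log2(side)) - 2L
      c_in <- 3L
      for (i in seq_len(n_down)) {
        c_out <- min(df * 2L^(i - 1L), 8L * df)
        init_conv(pe, paste0(pre, "c", i), c_in, c_out, 4L)
        if (i > 1L) init_bn(pe, paste0(pre, "bn", i), c_out)
        c_in <- c_out
      }
      init_conv(pe, paste0(pre, "ul"), c_in, 1L, 4L)
      init_conv(pe, paste0(pre, "cj"), c_in + config$cond_dim, c_in, 3L)
      init_bn(pe, paste0(pre, "cjbn"), c_in)
      init_conv(pe, paste0(pre, "cl"), c_in, 1L, 4L)
    }
  })
  structure(list(pe = pe, config = config), class = "gan_model")
}

# Parameter-name predicates used to route Adam updates.
param_names <- function(model, who = c("g", "d")) {
  who <- match.arg(who)
  nms <- ls(model$pe)
  nms <- nms[!grepl("_(rm|rv)$", nms)]  # running stats are not trainable
  nms[startsWith(nms, who)]
}

check_condition <- function(c, config) {
  if (ncol(c) != config$cond_dim)
    stop("condition has ", ncol(c), " columns, config expects ",
         config$cond_dim)
  if (anyNA(c) || min(c) < -1e-9 || max(c) > 1 + 1e-9)
    stop("condition values must lie in [0, 1]")
}

# Build the generator graph on a tape; returns node ids of the condition
# input, per-stage images and hidden feature maps.
g_build <- function(tp, z, c, config) {
  gc_ <- gen_channels(config)
  N <- nrow(c)
  zc <- if (config$z_dim > 0L) cbind(z, c) else c
  in_id <- t_input(tp, zc)
  c_id <- t_input(tp, c)
  x <- t_relu(tp, t_bn(tp, t_dense(tp, in_id, "g1_fc"), "g1_fcbn"))
  x <- t_reshape_spatial(tp, x, 4L, 4L, gc_$fc)
  for (i in seq_len(gc_$n_up)) {
    x <- t_up2(tp, x)
    x <- t_relu(tp, t_bn(tp, t_conv(tp, x, paste0("g1_u", i, "_c"), 3L),
                         paste0("g1_u", i, "_bn")))
  }
  h <- x
  imgs <- c(t_tanh(tp, t_conv(tp, h, "g1_img", 3L)))
  hs <- c(h)
  for (k in seq_len(config$n_stages)[-1]) {
    pre <- paste0("g", k, "_")
    m <- node_meta(tp, h)
    ctile <- t_tile(tp, c_id, m$H, m$W)
    x <- t_concat(tp, h, ctile)
    x <- t_relu(tp, t_bn(tp, t_conv(tp, x, paste0(pre, "joint_c"), 3L),
                         paste0(pre, "joint_bn")))
    for (r in 1:2) {
      y <- t_relu(tp, t_bn(tp, t_conv(tp, x, paste0(pre, "r", r, "_c1"), 3L),
                           paste0(pre, "r", r, "_bn1")))
      y <- t_bn(tp, t_conv(tp, y, paste0(pre, "r", r, "_c2"), 3L),
                paste0(pre, "r", r, "_bn2"))
      x <- t_relu(tp, t_add(tp, x, y))
    }
    x <- t_up2(tp, x)
    h <- t_relu(tp, t_bn(tp, t_conv(tp, x, paste0(pre, "u_c"), 3L),
                         paste0(pre, "u_bn")))
    imgs <- c(imgs, t_tanh(tp, t_conv(tp, h, paste0(pre, "img"), 3L)))
    hs <- c(hs, h)
  }
  list(c_id = c_id, imgs = imgs, hs = hs, N = N)
}

#' Generator forward pass
#'
#' @param model a \code{\link{gan_init}} result.
#' @param z N x z_dim standard-normal noise matrix (ignored when z_dim = 0).
#' @param c N x cond_dim condition matrix with values in [0, 1].
#' @param train logical; TRUE uses batch statistics in batchnorm (training),
#'   FALSE the running averages (generation).
#' @return list with \code{images} (per stage, H x W x 3 x N arrays with
#'   values in [-1, 1]) and \code{hidden} (per-stage feature matrices).
#' @export
generator_forward <- function(model, z, c, train = FALSE) {
  config <- model$config
  if (is.null(dim(c))) c <- matrix(c, nrow = 1)
  check_condition(c, config)
  if (config$z_dim > 0L) {
    if (is.null(dim(z))) z <- matrix(z, nrow = 1)
    stopifnot(ncol(z) == config$z_dim, nrow(z) == nrow(c))
  }
  tp <- tape_new(model$pe, train = train)
  gb <- g_build(tp, z, c, config)
  images <- lapply(seq_along(gb$imgs), function(k) {
    side <- stage_side(config, k)
    a <- array(node_out(tp, gb$imgs[k]), dim = c(side, side, gb$N, 3L))
    aperm(a, c(1, 2, 4, 3))
  })
  hidden <- lapply(gb$hs, function(id) node_out(tp, id))
  list(images = images, hidden = hidden)
}

# Discriminator graph for stage k on an image node; returns logit node ids.
d_build <- function(tp, img_id, c_id, k, config) {
  pre <- paste0("d", k, "_")
  side <- stage_side(config, k)
  n_down <- as.integer(log2(side)) - 2L
  x <- img_id
  for (i in seq_len(n_down)) {
    x <- t_conv(tp, x, paste0(pre, "c", i), 4L, s = 2L, p = 1L)
    if (i > 1L) x <- t_bn(tp, x, paste0(pre, "bn", i))
    x <- t_lrelu(tp, x)
  }
  uncond <- t_conv(tp, x, paste0(pre, "ul"), 4L, s = 4L, p = 0L)
  ctile <- t_tile(tp, c_id, 4L, 4L)
  y <- t_concat(tp, x, ctile)
  y <- t_lrelu(tp, t_bn(tp, t_conv(tp, y, paste0(pre, "cj"), 3L),
                        paste0(pre, "cjbn")))
  cond <- t_conv(tp, y, paste0(pre, "cl"), 4L, s = 4L, p = 0L)
  list(uncond = uncond, cond = cond, trunk = x)
}

# Conditional head only, reusing an already computed trunk node.
d_build_cond_head <- function(tp, trunk_id, c_id, k) {
  pre <- paste0("d", k, "_")
  ctile <- t_tile(tp, c_id, 4L, 4L)
  y <- t_concat(tp, trunk_id, ctile)
  y <- t_lrelu(tp, t_bn(tp, t_conv(tp, y, paste0(pre, "cj"), 3L),
                        paste0(pre, "cjbn")))
  t_conv(tp, y, paste0(pre, "cl"), 4L, s = 4L, p = 0L)
}

#' Discriminator forward pass
#'
#' @param model a \code{\link{gan_init}} result.
#' @param images H x W x 3 x N array with values in [-1, 1]; the side must
#'   match the stage resolution.
#' @param c N x cond_dim condition matrix.
#' @param stage stage index (1-based).
#' @param train logical; batch vs running batchnorm statistics.
#' @return list with \code{uncond_logit} and \code{cond_logit}, length-N
#'   numeric vectors.
#' @export
discriminator_forward <- function(model, images, c, stage = 1L, train = FALSE) {
  config <- model$config
  side <- stage_side(config, stage)
  d <- dim(images)
  if (d[1] != side || d[2] != side)
    stop("image side ", d[1], " does not match stage ", stage,
         " resolution ", side)
  if (is.null(dim(c))) c <- matrix(c, nrow = 1)
  check_condition(c, config)
  tp <- tape_new(model$pe, train = train)
  X <- matrix(aperm(images, c(1, 2, 4, 3)), side * side * d[4], 3L)
  img_id <- t_input(tp, X, H = side, W = side, N = d[4])
  c_id <- t_input(tp, c)
  db <- d_build(tp, img_id, c_id, stage, config)
  list(uncond_logit = as.numeric(node_out(tp, db$uncond)),
       cond_logit = as.numeric(node_out(tp, db$cond)))
}

#' Per-stage discriminator loss
#'
#' Binary cross-entropy over logits: real images score 1 and fakes 0 on the
#' unconditional head; (real, matched traits) score 1 while (fake, traits)
#' and optionally (real, mismatched traits) score 0 on the conditional head.
#'
#' @param real_uncond,real_cond logits of real images (matched condition).
#' @param fake_uncond,fake_cond logits of generated images.
#' @param mis_cond logits of real images with mismatched conditions, or NULL.
#' @param w_mis weight of the mismatched term.
#' @return scalar loss (mean over the batch, summed over terms).
#' @export
discriminator_loss <- function(real_uncond, real_cond, fake_uncond, fake_cond,
                               mis_cond = NULL, w_mis = 1) {
  l <- bce_logits(real_uncond, 1)$loss + bce_logits(real_cond, 1)$loss +
       bce_logits(fake_uncond, 0)$loss + bce_logits(fake_cond, 0)$loss
  if (!is.null(mis_cond) && w_mis > 0)
    l <- l + w_mis * bce_logits(mis_cond, 0)$loss
  l
}

#' Per-stage generator loss
#'
#' @param fake_uncond,fake_cond discriminator logits of generated images.
#' @return scalar loss: the generator drives both heads towards 1.
#' @export
generator_loss <- function(fake_uncond, fake_cond) {
  bce_logits(fake_uncond, 1)$loss + bce_logits(fake_cond, 1)$loss
}
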