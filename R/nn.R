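# Minimal CNN engine: explicit forward/backward passes for the two network
# topologies used here (U-Net generator, VGG-style discriminator) plus Adam.
# Convolutions run through the compiled im2col/GEMM kernels (src/conv_ops.cpp);
# tensors are plain R arrays in (H, W, C, B) layout. No autodiff framework is
# available in the supported dependency set, so gradients are hand-derived and
# validated against finite differences in the test suite.

conv_w_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

lrelu_fwd <- function(z, slope) lrelu_fwd_cpp(z, slope)

lrelu_bwd <- function(z, dy, slope) lrelu_bwd_cpp(z, dy, slope)

avgpool2_fwd <- function(x) {
  d <- dim(x)
  o <- seq(1L, d[1], by = 2L); oc <- seq(1L, d[2], by = 2L)
  (x[o, oc, , , drop = FALSE] + x[o + 1L, oc, , , drop = FALSE] +
     x[o, oc + 1L, , , drop = FALSE] + x[o + 1L, oc + 1L, , , drop = FALSE]) / 4
}

avgpool2_bwd <- function(dy) {
  d <- dim(dy)
  dy[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
     drop = FALSE] / 4
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  o <- seq(1L, d[1], by = 2L); oc <- seq(1L, d[2], by = 2L)
  dy[o, oc, , , drop = FALSE] + dy[o + 1L, oc, , , drop = FALSE] +
    dy[o, oc + 1L, , , drop = FALSE] + dy[o + 1L, oc + 1L, , , drop = FALSE]
}

chan_cat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Generator (U-Net) architecture specification
#'
#' Encoder of `depth` convolutional blocks with 2x average-pool downsampling
#' between them, a bottleneck block, and a symmetric decoder with skip
#' connections. Every block is two 3x3 convolutions, each followed by a leaky
#' ReLU; the second convolution changes the channel count (doubling on the
#' way down, halving on the way up). Upsampling is resize-convolution
#' (nearest-neighbour 2x followed by a 3x3 convolution). A final 1x1 linear
#' convolution projects back to one channel; input and output shapes match.
#'
#' @param depth number of down/up levels (>= 1).
#' @param base_channels channels of the first encoder block.
#' @param leaky_slope negative slope of the leaky ReLU, in (0, 1).
#' @return a `generator_spec`.
#' @export
generator_spec <- function(depth = 4L, base_channels = 32L, leaky_slope = 0.2) {
  if (depth < 1 || base_channels < 1) stop("invalid generator spec", call. = FALSE)
  if (leaky_slope <= 0 || leaky_slope >= 1)
    stop("leaky_slope must be in (0,1)", call. = FALSE)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 leaky_slope = leaky_slope),
            class = "generator_spec")
}

#' Discriminator (VGG-style) architecture specification
#'
#' `n_blocks` convolutional blocks (two 3x3 conv + leaky ReLU layers each,
#' channels doubling per block) with 2x average pooling after each block,
#' global average pooling, and a dense head with sigmoid output, so scores
#' lie in \[0, 1\].
#'
#' @param n_blocks number of conv blocks (>= 1).
#' @param base_channels channels of the first block.
#' @param leaky_slope negative slope of the leaky ReLU.
#' @return a `discriminator_spec`.
#' @export
discriminator_spec <- function(n_blocks = 3L, base_channels = 32L,
                               leaky_slope = 0.2) {
  if (n_blocks < 1 || base_channels < 1)
    stop("invalid discriminator spec", call. = FALSE)
  structure(list(n_blocks = as.integer(n_blocks),
                 base_channels = as.integer(base_channels),
                 leaky_slope = leaky_slope),
            class = "discriminator_spec")
}

gen_init <- function(spec, seed = 1L) {
  with_seed(seed, {
    c0 <- spec$base_channels; d <- spec$depth
    P <- list()
    ch <- 1L
    for (i in 0:(d - 1L)) {
      out <- c0 * 2L^i
      P[[sprintf("enc%d_w1", i)]] <- conv_w_init(3L, ch, ch)
      P[[sprintf("enc%d_b1", i)]] <- numeric(ch)
      P[[sprintf("enc%d_w2", i)]] <- conv_w_init(3L, ch, out)
      P[[sprintf("enc%d_b2", i)]] <- numeric(out)
      ch <- out
    }
    P$bott_w1 <- conv_w_init(3L, ch, ch); P$bott_b1 <- numeric(ch)
    P$bott_w2 <- conv_w_init(3L, ch, 2L * ch); P$bott_b2 <- numeric(2L * ch)
    ch <- 2L * ch
    for (i in (d - 1L):0) {
      sk <- c0 * 2L^i
      P[[sprintf("up%d_w", i)]] <- conv_w_init(3L, ch, sk)
      P[[sprintf("up%d_b", i)]] <- numeric(sk)
      cc <- 2L * sk
      P[[sprintf("dec%d_w1", i)]] <- conv_w_init(3L, cc, cc)
      P[[sprintf("dec%d_b1", i)]] <- numeric(cc)
      P[[sprintf("dec%d_w2", i)]] <- conv_w_init(3L, cc, sk)
      P[[sprintf("dec%d_b2", i)]] <- numeric(sk)
      ch <- sk
    }
    P$final_w <- conv_w_init(1L, c0, 1L)
    P$final_b <- numeric(1L)
    P
  })
}

block_fwd <- function(a, w1, b1, w2, b2, slope) {
  z1 <- conv2d_fwd(a, w1, b1)
  a1 <- lrelu_fwd(z1, slope)
  z2 <- conv2d_fwd(a1, w2, b2)
  a2 <- lrelu_fwd(z2, slope)
  list(a2 = a2, cache = list(a = a, z1 = z1, a1 = a1, z2 = z2))
}

block_bwd <- function(cache, w1, w2, da2, slope, need_dx = TRUE) {
  dz2 <- lrelu_bwd(cache$z2, da2, slope)
  g2 <- conv2d_bwd(cache$a1, w2, dz2, TRUE)
  dz1 <- lrelu_bwd(cache$z1, g2$dx, slope)
  g1 <- conv2d_bwd(cache$a, w1, dz1, need_dx)
  list(dx = if (need_dx) g1$dx else NULL,
       dw1 = g1$dw, db1 = g1$db, dw2 = g2$dw, db2 = g2$db)
}

gen_forward <- function(P, spec, x, keep_cache = FALSE) {
  d <- spec$depth; s <- spec$leaky_slope
  cache <- if (keep_cache) list() else NULL
  skips <- vector("list", d)
  a <- x
  for (i in 0:(d - 1L)) {
    bl <- block_fwd(a, P[[sprintf("enc%d_w1", i)]], P[[sprintf("enc%d_b1", i)]],
                    P[[sprintf("enc%d_w2", i)]], P[[sprintf("enc%d_b2", i)]], s)
    if (keep_cache) cache[[sprintf("enc%d", i)]] <- bl$cache
    skips[[i + 1L]] <- bl$a2
    a <- avgpool2_fwd(bl$a2)
  }
  bl <- block_fwd(a, P$bott_w1, P$bott_b1, P$bott_w2, P$bott_b2, s)
  if (keep_cache) cache$bott <- bl$cache
  a <- bl$a2
  for (i in (d - 1L):0) {
    u <- upsample2_fwd(a)
    zu <- conv2d_fwd(u, P[[sprintf("up%d_w", i)]], P[[sprintf("up%d_b", i)]])
    au <- lrelu_fwd(zu, s)
    cc <- chan_cat(au, skips[[i + 1L]])
    bl <- block_fwd(cc, P[[sprintf("dec%d_w1", i)]], P[[sprintf("dec%d_b1", i)]],
                    P[[sprintf("dec%d_w2", i)]], P[[sprintf("dec%d_b2", i)]], s)
    if (keep_cache) {
      cache[[sprintf("up%d", i)]] <- list(u = u, zu = zu, n_up = dim(au)[3])
      cache[[sprintf("dec%d", i)]] <- bl$cache
    }
    a <- bl$a2
  }
  y <- conv2d_fwd(a, P$final_w, P$final_b)
  if (keep_cache) cache$final_in <- a
  list(y = y, cache = cache)
}

gen_backward <- function(P, spec, cache, dy) {
  d <- spec$depth; s <- spec$leaky_slope
  G <- list()
  gf <- conv2d_bwd(cache$final_in, P$final_w, dy, TRUE)
  G$final_w <- gf$dw; G$final_b <- gf$db
  da <- gf$dx
  dskips <- vector("list", d)
  for (i in 0:(d - 1L)) {
    bb <- block_bwd(cache[[sprintf("dec%d", i)]],
                    P[[sprintf("dec%d_w1", i)]], P[[sprintf("dec%d_w2", i)]],
                    da, s)
    G[[sprintf("dec%d_w1", i)]] <- bb$dw1; G[[sprintf("dec%d_b1", i)]] <- bb$db1
    G[[sprintf("dec%d_w2", i)]] <- bb$dw2; G[[sprintf("dec%d_b2", i)]] <- bb$db2
    n_up <- cache[[sprintf("up%d", i)]]$n_up
    dau <- bb$dx[, , seq_len(n_up), , drop = FALSE]
    dskips[[i + 1L]] <- bb$dx[, , n_up + seq_len(dim(bb$dx)[3] - n_up), ,
                              drop = FALSE]
    dzu <- lrelu_bwd(cache[[sprintf("up%d", i)]]$zu, dau, s)
    gu <- conv2d_bwd(cache[[sprintf("up%d", i)]]$u,
                     P[[sprintf("up%d_w", i)]], dzu, TRUE)
    G[[sprintf("up%d_w", i)]] <- gu$dw; G[[sprintf("up%d_b", i)]] <- gu$db
    da <- upsample2_bwd(gu$dx)
  }
  bb <- block_bwd(cache$bott, P$bott_w1, P$bott_w2, da, s)
  G$bott_w1 <- bb$dw1; G$bott_b1 <- bb$db1
  G$bott_w2 <- bb$dw2; G$bott_b2 <- bb$db2
  da <- bb$dx
  for (i in (d - 1L):0) {
    da_full <- avgpool2_bwd(da) + dskips[[i + 1L]]
    bb <- block_bwd(cache[[sprintf("enc%d", i)]],
                    P[[sprintf("enc%d_w1", i)]], P[[sprintf("enc%d_w2", i)]],
                    da_full, s, need_dx = (i > 0L))
    G[[sprintf("enc%d_w1", i)]] <- bb$dw1; G[[sprintf("enc%d_b1", i)]] <- bb$db1
    G[[sprintf("enc%d_w2", i)]] <- bb$dw2; G[[sprintf("enc%d_b2", i)]] <- bb$db2
    da <- bb$dx
  }
  G
}

disc_init <- function(spec, seed = 1L) {
  with_seed(seed, {
    c0 <- spec$base_channels
    P <- list()
    ch <- 1L
    for (j in seq_len(spec$n_blocks)) {
      out <- c0 * 2L^(j - 1L)
      P[[sprintf("blk%d_w1", j)]] <- conv_w_init(3L, ch, out)
      P[[sprintf("blk%d_b1", j)]] <- numeric(out)
      P[[sprintf("blk%d_w2", j)]] <- conv_w_init(3L, out, out)
      P[[sprintf("blk%d_b2", j)]] <- numeric(out)
      ch <- out
    }
    P$head_w <- stats::rnorm(ch, sd = sqrt(1 / ch))
    P$head_b <- 0
    P
  })
}

disc_forward <- function(P, spec, x, keep_cache = FALSE) {
  s <- spec$leaky_slope
  cache <- if (keep_cache) list() else NULL
  a <- x
  for (j in seq_len(spec$n_blocks)) {
    z1 <- conv2d_fwd(a, P[[sprintf("blk%d_w1", j)]], P[[sprintf("blk%d_b1", j)]])
    a1 <- lrelu_fwd(z1, s)
    z2 <- conv2d_fwd(a1, P[[sprintf("blk%d_w2", j)]], P[[sprintf("blk%d_b2", j)]])
    a2 <- lrelu_fwd(z2, s)
    if (keep_cache) cache[[sprintf("blk%d", j)]] <-
      list(a = a, z1 = z1, a1 = a1, z2 = z2)
    a <- avgpool2_fwd(a2)
  }
  d <- dim(a)
  gap <- apply(a, c(3, 4), mean)                       # (C, B)
  if (is.null(dim(gap))) gap <- matrix(gap, nrow = d[3])
  logit <- as.vector(crossprod(gap, P$head_w)) + P$head_b
  score <- 1 / (1 + exp(-logit))
  if (keep_cache) {
    cache$gap <- gap; cache$score <- score; cache$pool_dim <- d
  }
  list(score = score, cache = cache)
}

disc_backward <- function(P, spec, cache, dscore, need_dx = FALSE) {
  s <- spec$leaky_slope
  sc <- cache$score
  dlogit <- dscore * sc * (1 - sc)
  G <- list()
  G$head_w <- as.vector(cache$gap %*% dlogit)
  G$head_b <- sum(dlogit)
  dgap <- outer(P$head_w, dlogit)                       # (C, B)
  d <- cache$pool_dim
  da <- array(rep(dgap, each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  for (j in spec$n_blocks:1) {
    cc <- cache[[sprintf("blk%d", j)]]
    da2 <- avgpool2_bwd(da)
    dz2 <- lrelu_bwd(cc$z2, da2, s)
    g2 <- conv2d_bwd(cc$a1, P[[sprintf("blk%d_w2", j)]], dz2, TRUE)
    dz1 <- lrelu_bwd(cc$z1, g2$dx, s)
    g1 <- conv2d_bwd(cc$a, P[[sprintf("blk%d_w1", j)]], dz1,
                     need_dx || j > 1L)
    G[[sprintf("blk%d_w1", j)]] <- g1$dw; G[[sprintf("blk%d_b1", j)]] <- g1$db
    G[[sprintf("blk%d_w2", j)]] <- g2$dw; G[[sprintf("blk%d_b2", j)]] <- g2$db
    da <- g1$dx
  }
  list(grads = G, dx = if (need_dx) da else NULL)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Build a generator network
#'
#' Initializes U-Net weights (He initialization, deterministic under `seed`)
#' and returns a callable generator object. The network accepts any input
#' whose sides are multiples of 2^depth; other sizes are reflect-padded
#' internally and cropped on output.
#'
#' @param spec a [generator_spec()].
#' @param seed integer weight-initialization seed.
#' @return a `sem_generator`; apply it to a matrix or (H, W, 1, B) array with
#'   [generator_apply()].
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  structure(list(spec = spec, params = gen_init(spec, seed), seed = seed),
            class = "sem_generator")
}

#' Number of trainable parameters of a network object
#' @param net a `sem_generator` or `sem_discriminator`.
#' @return integer parameter count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

reflect_pad_to <- function(m, mult) {
  nr <- nrow(m); nc <- ncol(m)
  tr <- (mult - nr %% mult) %% mult
  tc <- (mult - nc %% mult) %% mult
  if (tr > 0) m <- rbind(m, m[nr - seq_len(tr), , drop = FALSE])
  if (tc > 0) m <- cbind(m, m[, nc - seq_len(tc), drop = FALSE])
  m
}

#' Run the generator on a patch or batch
#'
#' @param gen a `sem_generator`.
#' @param x numeric matrix (single patch) or (H, W, 1, B) array.
#' @return same type as the input.
#' @export
generator_apply <- function(gen, x) {
  single <- is.matrix(x)
  if (single) {
    nr0 <- nrow(x); nc0 <- ncol(x)
    xp <- reflect_pad_to(x, 2L^gen$spec$depth)
    x <- array(xp, c(nrow(xp), ncol(xp), 1L, 1L))
  }
  y <- gen_forward(gen$params, gen$spec, x)$y
  if (single) return(matrix(y[, , 1L, 1L], dim(y)[1], dim(y)[2])[1:nr0, 1:nc0])
  y
}

#' Build a discriminator network
#'
#' @param spec a [discriminator_spec()].
#' @param seed integer weight-initialization seed.
#' @return a `sem_discriminator`; score patches with [discriminator_apply()].
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = 1L) {
  structure(list(spec = spec, params = disc_init(spec, seed), seed = seed),
            class = "sem_discriminator")
}

#' Score a patch (or batch) with the discriminator
#'
#' @param disc a `sem_discriminator`.
#' @param x numeric matrix or (H, W, 1, B) array.
#' @return score(s) in \[0, 1\].
#' @export
discriminator_apply <- function(disc, x) {
  if (is.matrix(x)) {
    xp <- reflect_pad_to(x, 2L^disc$spec$n_blocks)
    x <- array(xp, c(nrow(xp), ncol(xp), 1L, 1L))
  }
  disc_forward(disc$params, disc$spec, x)$score
}
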