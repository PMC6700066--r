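# Composite GAN objective and training schedule.
#
# Generator loss:  L1{G(x), z} + alpha * TV{G(x)} + beta * (1 - D(G(x)))^2
#   L1 = mean absolute pixel difference over the M x N patch,
#   TV = anisotropic total variation (sum of absolute vertical and horizontal
#        neighbour differences, boundary terms omitted),
#   adversarial term = least-squares penalty on the discriminator score.
# Discriminator loss:  D(G(x))^2 + (1 - D(z))^2.
#
# alpha and beta are calibrated so that at the working point the
# adversarial, L1 and TV terms contribute 84%, 14% and 2% of the generator
# total. The generator updates every iteration; the discriminator only every
# `d_update_period`-th iteration (default 4) to avoid overfitting it.

#' Mean absolute (L1) loss between two patches
#'
#' `(1/(M N)) * sum |z_ij - g_ij|`; non-negative and symmetric.
#'
#' @param output,target numeric matrices/arrays of identical shape.
#' @return scalar loss.
#' @export
l1_loss <- function(output, target) {
  if (!all(dim(output) == dim(target)))
    stop("shape mismatch between output and target", call. = FALSE)
  mean(abs(target - output))
}

#' Anisotropic total-variation loss
#'
#' Sum over valid pixels of |v\[i+1,j\] - v\[i,j\]| + |v\[i,j+1\] - v\[i,j\]|;
#' terms that would index outside the grid are omitted. Penalizes noise while
#' preserving edges; note this is a raw sum, not a per-pixel mean.
#'
#' @param image numeric matrix (at least 2 x 2).
#' @return scalar loss.
#' @export
tv_loss <- function(image) {
  m <- if (is_sem_image(image)) image$pixels else image
  nr <- nrow(m); nc <- ncol(m)
  sum(abs(m[-1, , drop = FALSE] - m[-nr, , drop = FALSE])) +
    sum(abs(m[, -1, drop = FALSE] - m[, -nc, drop = FALSE]))
}

#' Loss weights of the composite generator objective
#' @param alpha TV weight (>= 0).
#' @param beta adversarial weight (>= 0).
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(alpha, beta) {
  if (alpha < 0 || beta < 0) stop("loss weights must be non-negative", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "loss_weights")
}

#' Composite generator loss
#'
#' `L1 + alpha * TV + beta * (1 - d_score_on_fake)^2`.
#'
#' @param g_out generator output patch.
#' @param target ground-truth patch.
#' @param d_score_on_fake discriminator score of `g_out`, in \[0, 1\].
#' @param weights a [loss_weights()].
#' @return scalar loss.
#' @export
generator_loss <- function(g_out, target, d_score_on_fake, weights) {
  if (d_score_on_fake < 0 || d_score_on_fake > 1)
    stop("discriminator score must be in [0,1]", call. = FALSE)
  l1_loss(g_out, target) + weights$alpha * tv_loss(g_out) +
    weights$beta * (1 - d_score_on_fake)^2
}

#' Least-squares discriminator loss
#'
#' `d_score_on_fake^2 + (1 - d_score_on_real)^2`: zero for perfect
#' discrimination, 2 when maximally confused.
#'
#' @param d_score_on_fake,d_score_on_real scores in \[0, 1\].
#' @return scalar loss.
#' @export
discriminator_loss <- function(d_score_on_fake, d_score_on_real) {
  if (any(c(d_score_on_fake, d_score_on_real) < 0) ||
      any(c(d_score_on_fake, d_score_on_real) > 1))
    stop("discriminator scores must be in [0,1]", call. = FALSE)
  d_score_on_fake^2 + (1 - d_score_on_real)^2
}

#' Calibrate loss weights to the 84/14/2 composition
#'
#' Given raw magnitudes of the three generator loss terms at the working
#' point, returns (alpha, beta) such that, with the L1 term at fixed weight 1,
#' the weighted adversarial, L1 and TV terms make up 84%, 14% and 2% of the
#' total generator loss.
#'
#' @param raw_l1,raw_tv,raw_adv raw (unweighted) term magnitudes, all > 0.
#' @return a [loss_weights()].
#' @examples
#' calibrate_loss_weights(1, 1, 1)  # alpha = 1/7, beta = 6
#' @export
calibrate_loss_weights <- function(raw_l1, raw_tv, raw_adv) {
  if (raw_l1 <= 0 || raw_tv <= 0 || raw_adv <= 0)
    stop("cannot calibrate: all raw loss terms must be > 0", call. = FALSE)
  total <- raw_l1 / 0.14
  loss_weights(alpha = 0.02 * total / raw_tv,
               beta = 0.84 * total / raw_adv)
}

#' Training configuration
#'
#' @param iterations number of generator updates (>= 1).
#' @param d_update_period discriminator update period: the discriminator is
#'   updated when `iteration %% d_update_period == 0` (default 4).
#' @param batch_size patches per update.
#' @param learning_rate Adam step size.
#' @param seed master seed for initialization, data order and augmentation.
#' @param weights a [loss_weights()], or `"auto"` to calibrate the 84/14/2
#'   composition on a warm-up batch.
#' @param augment apply random dihedral augmentation per sample (default TRUE).
#' @param lr_decay_at iterations at which the learning rate is multiplied by
#'   `lr_decay`; empty for a constant rate.
#' @param lr_decay step-decay factor.
#' @return a `train_config`.
#' @export
train_config <- function(iterations = 2000L, d_update_period = 4L,
                         batch_size = 8L, learning_rate = 1e-4,
                         seed = 1L, weights = "auto", augment = TRUE,
                         lr_decay_at = integer(), lr_decay = 0.3) {
  if (iterations < 1 || d_update_period < 1)
    stop("iterations and d_update_period must be >= 1", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 d_update_period = as.integer(d_update_period),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed), weights = weights,
                 augment = isTRUE(augment),
                 lr_decay_at = as.integer(lr_decay_at),
                 lr_decay = lr_decay),
            class = "train_config")
}

# stack a list of matrices into an (H, W, 1, B) array
stack_patches <- function(mats) {
  d <- dim(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(d[1], d[2], 1L, length(mats)))
}

# gradient of the batch-mean L1 w.r.t. the generator output
l1_grad <- function(y, z) sign(y - z) / (dim(y)[1] * dim(y)[2] * dim(y)[4])

# gradient of the batch-mean anisotropic TV w.r.t. a (H,W,1,B) array
tv_grad <- function(y) {
  g <- y * 0
  nr <- dim(y)[1]; nc <- dim(y)[2]
  sv <- sign(y[-1, , , , drop = FALSE] - y[-nr, , , , drop = FALSE])
  g[-1, , , ] <- g[-1, , , , drop = FALSE] + sv
  g[-nr, , , ] <- g[-nr, , , , drop = FALSE] - sv
  sh <- sign(y[, -1, , , drop = FALSE] - y[, -nc, , , drop = FALSE])
  g[, -1, , ] <- g[, -1, , , drop = FALSE] + sh
  g[, -nc, , ] <- g[, -nc, , , drop = FALSE] - sh
  g / dim(y)[4]
}

batch_tv <- function(y) {
  mean(vapply(seq_len(dim(y)[4]),
              function(b) tv_loss(matrix(y[, , 1, b], dim(y)[1], dim(y)[2])),
              numeric(1)))
}

#' Train the super-resolution GAN
#'
#' The generator is updated every iteration on the composite loss; the
#' discriminator is updated on its least-squares loss only when
#' `iteration %% d_update_period == 0`. Fully seeded: weight initialization,
#' batch order and augmentation all derive from `config$seed`, so two runs
#' with identical inputs are bit-identical. Training aborts with a diagnostic
#' if any loss becomes non-finite.
#'
#' @param dataset a non-empty `patch_dataset` of normalized pairs.
#' @param g_spec a [generator_spec()].
#' @param d_spec a [discriminator_spec()].
#' @param config a [train_config()].
#' @param val_dataset optional held-out `patch_dataset`; validation L1 of the
#'   trained generator and of the identity mapping are reported.
#' @param verbose print progress every 100 iterations.
#' @return list with `generator` (a `sem_generator`), `discriminator`,
#'   `history` (data.frame: per-iteration loss terms and their shares of the
#'   generator total), `weights`, and validation summaries when requested.
#' @export
train_gan <- function(dataset, g_spec = generator_spec(2L, 8L),
                      d_spec = discriminator_spec(2L, 8L),
                      config = train_config(), val_dataset = NULL,
                      verbose = FALSE) {
  n <- length(dataset$pairs)
  if (n == 0L) stop("dataset is empty", call. = FALSE)
  gp <- gen_init(g_spec, config$seed)
  dp <- disc_init(d_spec, config$seed + 1L)
  g_state <- adam_init(gp)
  d_state <- adam_init(dp)

  # resolve loss weights, calibrating on a warm-up batch if requested
  weights <- config$weights
  if (identical(weights, "auto")) {
    idx <- with_seed(config$seed + 2L,
                     sample.int(n, min(config$batch_size, n)))
    xb <- stack_patches(lapply(dataset$pairs[idx], `[[`, "x"))
    zb <- stack_patches(lapply(dataset$pairs[idx], `[[`, "z"))
    y <- gen_forward(gp, g_spec, xb)$y
    s <- disc_forward(dp, d_spec, y)$score
    raw_adv <- mean((1 - s)^2)
    weights <- calibrate_loss_weights(l1_loss(y, zb),
                                      max(batch_tv(y), 1e-12),
                                      max(raw_adv, 1e-12))
  }

  hist_rows <- vector("list", config$iterations)
  rng <- with_seed(config$seed + 3L,
                   matrix(sample.int(n, config$iterations * config$batch_size,
                                     replace = TRUE),
                          nrow = config$iterations))
  aug_idx <- with_seed(config$seed + 4L,
                       matrix(sample.int(8L, config$iterations * config$batch_size,
                                         replace = TRUE) - 1L,
                              nrow = config$iterations))
  d_loss_last <- NA_real_
  lr <- config$learning_rate
  for (it in seq_len(config$iterations)) {
    if (it %in% config$lr_decay_at) lr <- lr * config$lr_decay
    idx <- rng[it, ]
    xs <- lapply(dataset$pairs[idx], `[[`, "x")
    zs <- lapply(dataset$pairs[idx], `[[`, "z")
    if (config$augment) {
      for (b in seq_along(idx)) {
        xs[[b]] <- dihedral_apply(xs[[b]], aug_idx[it, b])
        zs[[b]] <- dihedral_apply(zs[[b]], aug_idx[it, b])
      }
    }
    xb <- stack_patches(xs); zb <- stack_patches(zs)

    fw <- gen_forward(gp, g_spec, xb, keep_cache = TRUE)
    y <- fw$y
    dfw <- disc_forward(dp, d_spec, y, keep_cache = TRUE)
    s_fake <- dfw$score

    term_l1 <- l1_loss(y, zb)
    term_tv <- batch_tv(y)
    term_adv <- mean((1 - s_fake)^2)
    g_total <- term_l1 + weights$alpha * term_tv + weights$beta * term_adv
    if (!is.finite(g_total))
      stop(sprintf("non-finite generator loss at iteration %d (L1=%g TV=%g adv=%g)",
                   it, term_l1, term_tv, term_adv), call. = FALSE)

    B <- dim(y)[4]
    dy <- l1_grad(y, zb) + weights$alpha * tv_grad(y)
    if (weights$beta > 0) {
      dsc <- -2 * weights$beta * (1 - s_fake) / B
      dy <- dy + disc_backward(dp, d_spec, dfw$cache, dsc, need_dx = TRUE)$dx
    }
    gg <- gen_backward(gp, g_spec, fw$cache, dy)
    up <- adam_step(gp, gg, g_state, lr)
    gp <- up$params; g_state <- up$state

    if (it %% config$d_update_period == 0L) {
      dfw_fake <- disc_forward(dp, d_spec, y, keep_cache = TRUE)
      dfw_real <- disc_forward(dp, d_spec, zb, keep_cache = TRUE)
      d_loss_last <- mean(dfw_fake$score^2) + mean((1 - dfw_real$score)^2)
      if (!is.finite(d_loss_last))
        stop(sprintf("non-finite discriminator loss at iteration %d", it),
             call. = FALSE)
      gdf <- disc_backward(dp, d_spec, dfw_fake$cache,
                           2 * dfw_fake$score / B)$grads
      gdr <- disc_backward(dp, d_spec, dfw_real$cache,
                           -2 * (1 - dfw_real$score) / B)$grads
      gd <- gdf
      for (nm in names(gd)) gd[[nm]] <- gd[[nm]] + gdr[[nm]]
      upd <- adam_step(dp, gd, d_state, lr)
      dp <- upd$params; d_state <- upd$state
    }

    w_l1 <- term_l1; w_tv <- weights$alpha * term_tv
    w_adv <- weights$beta * term_adv
    hist_rows[[it]] <- data.frame(
      iteration = it, l1 = term_l1, tv = term_tv, adv = term_adv,
      g_total = g_total,
      share_l1 = w_l1 / g_total, share_tv = w_tv / g_total,
      share_adv = w_adv / g_total,
      d_loss = if (it %% config$d_update_period == 0L) d_loss_last else NA_real_,
      d_updated = it %% config$d_update_period == 0L)
    if (verbose && it %% 100L == 0L)
      message(sprintf("iter %d: L1 %.4f TV %.1f adv %.4f", it, term_l1,
                      term_tv, term_adv))
  }

  gen <- structure(list(spec = g_spec, params = gp, seed = config$seed),
                   class = "sem_generator")
  disc <- structure(list(spec = d_spec, params = dp, seed = config$seed + 1L),
                    class = "sem_discriminator")
  out <- list(generator = gen, discriminator = disc,
              history = do.call(rbind, hist_rows), weights = weights)
  if (!is.null(val_dataset) && length(val_dataset$pairs) > 0L) {
    xb <- stack_patches(lapply(val_dataset$pairs, `[[`, "x"))
    zb <- stack_patches(lapply(val_dataset$pairs, `[[`, "z"))
    y <- gen_forward(gp, g_spec, xb)$y
    out$val_l1 <- l1_loss(y, zb)
    out$val_l1_identity <- l1_loss(xb, zb)
  }
  out
}

# cosine-ramp feathering weight for tiled blending
feather_weight <- function(size, overlap) {
  w <- rep(1, size)
  if (overlap > 0) {
    ramp <- (1 - cos(pi * seq_len(overlap) / (overlap + 1))) / 2
    w[seq_len(overlap)] <- ramp
    w[size - seq_len(overlap) + 1L] <- ramp
  }
  w
}

#' Super-resolve a full image with a trained generator
#'
#' Normalizes the input with its own mean/std, Lanczos-upsamples by `factor`
#' (default 2, the training magnification ratio), runs tiled inference with
#' feathered overlap blending, denormalizes, and halves the pixel pitch.
#' Images no larger than one tile are processed in a single pass.
#' Deterministic: two runs are bit-identical.
#'
#' @param generator a trained `sem_generator`.
#' @param image low-resolution `sem_image`.
#' @param factor upsampling (magnification) ratio.
#' @param tile tile side in output pixels (default 128).
#' @param overlap tile overlap in pixels (default 16).
#' @return the super-resolved `sem_image`.
#' @export
infer_image <- function(generator, image, factor = 2L, tile = 128L,
                        overlap = 16L) {
  assert_sem_image(image)
  nrm <- normalize_image(image$pixels)
  up <- lanczos_upsample(nrm$image, factor)
  nr <- nrow(up); nc <- ncol(up)

  if (nr <= tile && nc <= tile) {
    out <- generator_apply(generator, up)
  } else {
    step <- tile - overlap
    r0s <- unique(pmin(seq(1L, nr, by = step), max(nr - tile + 1L, 1L)))
    c0s <- unique(pmin(seq(1L, nc, by = step), max(nc - tile + 1L, 1L)))
    acc <- matrix(0, nr, nc); wacc <- matrix(0, nr, nc)
    for (r0 in r0s) for (c0 in c0s) {
      r1 <- min(r0 + tile - 1L, nr); c1 <- min(c0 + tile - 1L, nc)
      patch <- up[r0:r1, c0:c1, drop = FALSE]
      y <- generator_apply(generator, patch)
      wr <- feather_weight(nrow(patch), overlap)
      wc <- feather_weight(ncol(patch), overlap)
      wmat <- outer(wr, wc)
      acc[r0:r1, c0:c1] <- acc[r0:r1, c0:c1] + y * wmat
      wacc[r0:r1, c0:c1] <- wacc[r0:r1, c0:c1] + wmat
    }
    out <- acc / pmax(wacc, 1e-12)
  }
  px <- denormalize_image(out, nrm$stats)
  sem_image(pmax(px, 0), image$pixel_size_nm / factor,
            meta = c(image$meta[setdiff(names(image$meta), "source")],
                     list(source = "infer_image", tile = tile,
                          overlap = overlap, factor = factor)))
}

#' Save / load a trained generator as JSON
#'
#' Text-format checkpoint: architecture manifest plus flattened weights.
#'
#' @param generator a `sem_generator`.
#' @param path output JSON path.
#' @return `path` invisibly; `read_generator` returns the `sem_generator`.
#' @export
write_generator <- function(generator, path) {
  obj <- list(spec = unclass(generator$spec),
              params = lapply(generator$params, function(p)
                list(dim = if (is.null(dim(p))) length(p) else dim(p),
                     data = as.vector(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generator
#' @export
read_generator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- generator_spec(obj$spec$depth, obj$spec$base_channels,
                         obj$spec$leaky_slope)
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) > 1L) array(p$data, dim = p$dim) else as.numeric(p$data)
  })
  structure(list(spec = spec, params = params, seed = NA_integer_),
            class = "sem_generator")
}
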