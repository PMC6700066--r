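test_that("loss formulas match naive references on random patches", {
  set.seed(10)
  for (k in 1:100) {
    a <- matrix(rnorm(6 * 5), 6, 5)
    b <- matrix(rnorm(6 * 5), 6, 5)
    expect_equal(l1_loss(a, b), naive_l1(a, b), tolerance = 1e-9)
    expect_equal(tv_loss(a), naive_tv(a), tolerance = 1e-9)
    d_fake <- runif(1); d_real <- runif(1)
    al <- runif(1); be <- runif(1)
    expect_equal(generator_loss(a, b, d_fake, loss_weights(al, be)),
                 naive_generator_loss(a, b, d_fake, al, be), tolerance = 1e-9)
    expect_equal(discriminator_loss(d_fake, d_real),
                 naive_discriminator_loss(d_fake, d_real), tolerance = 1e-12)
  }
})

test_that("hand-computed loss examples", {
  expect_equal(l1_loss(matrix(c(0, 4, 2, 6), 2, 2), matrix(0, 2, 2)), 3.0)
  expect_equal(l1_loss(matrix(5, 3, 3), matrix(2, 3, 3)), 3)
  expect_equal(l1_loss(matrix(1, 2, 2), matrix(1, 2, 2)), 0)
  expect_error(l1_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")

  expect_equal(tv_loss(matrix(7, 4, 4)), 0)
  # single vertical step of height h between two columns of a 4x4 image
  h <- 1.3
  step <- cbind(matrix(0, 4, 2), matrix(h, 4, 2))
  expect_equal(tv_loss(step), 4 * h)
  # anisotropic sum is symmetric under transposition of the pattern
  expect_equal(tv_loss(t(step)), tv_loss(step))

  # flat output equal to target, perfect score: every term vanishes
  flat <- matrix(2, 3, 3)
  expect_equal(generator_loss(flat, flat, 1, loss_weights(0.7, 0.3)), 0)
  # non-flat output equal to target, alpha 0, d = 0: only (1 - 0)^2 remains
  z <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(generator_loss(z, z, 0, loss_weights(0, 1)), 1.0)
  # alpha = 0.5, beta = 2 with L1 = 0.3, TV = 0.4, d = 0.5 -> 0.3 + 0.2 + 0.5
  g <- matrix(c(0, 0, 0.2, 0.2), 2, 2)        # TV = 0.4
  expect_equal(tv_loss(g), 0.4)
  expect_equal(generator_loss(g, g - 0.3, 0.5, loss_weights(0.5, 2)), 1.0)

  expect_equal(discriminator_loss(0, 1), 0)
  expect_equal(discriminator_loss(1, 0), 2)
  expect_equal(discriminator_loss(0.5, 0.5), 0.5)
  expect_error(discriminator_loss(1.2, 0), "0,1")
  expect_error(loss_weights(-1, 0), "non-negative")
})

test_that("calibrate_loss_weights hits the 84/14/2 composition", {
  w <- calibrate_loss_weights(1, 1, 1)
  expect_equal(w$alpha, 1 / 7, tolerance = 1e-12)
  expect_equal(w$beta, 6, tolerance = 1e-12)

  w2 <- calibrate_loss_weights(2, 4, 0.5)
  expect_equal(w2$alpha, 0.02 * (2 / 0.14) / 4, tolerance = 1e-12)
  expect_equal(w2$beta, 24, tolerance = 1e-12)

  # shares check: with these weights the composition is exactly 84/14/2
  raw <- c(l1 = 0.37, tv = 12.3, adv = 0.81)
  w3 <- calibrate_loss_weights(raw["l1"], raw["tv"], raw["adv"])
  total <- raw["l1"] + w3$alpha * raw["tv"] + w3$beta * raw["adv"]
  expect_equal(unname(raw["l1"] / total), 0.14, tolerance = 1e-9)
  expect_equal(unname(w3$alpha * raw["tv"] / total), 0.02, tolerance = 1e-9)
  expect_equal(unname(w3$beta * raw["adv"] / total), 0.84, tolerance = 1e-9)

  expect_error(calibrate_loss_weights(1, 1, 0), "calibrate")
})

test_that("generator: shape contract, determinism, finite outputs", {
  spec <- generator_spec(2, 4)
  gen <- build_generator(spec, seed = 5)
  x <- matrix(rnorm(64 * 64), 64, 64)
  y <- generator_apply(gen, x)
  expect_equal(dim(y), c(64L, 64L))
  # non-multiple-of-2^depth sides are padded internally and cropped back
  x2 <- matrix(rnorm(50 * 46), 50, 46)
  expect_equal(dim(generator_apply(gen, x2)), c(50L, 46L))

  expect_identical(n_parameters(build_generator(spec, seed = 1)),
                   n_parameters(build_generator(spec, seed = 2)))
  expect_identical(generator_apply(gen, x), generator_apply(gen, x))

  set.seed(6)
  for (k in 1:20) {
    xi <- matrix(rnorm(32 * 32, sd = sample(c(0.1, 1, 10), 1)), 32, 32)
    expect_true(all(is.finite(generator_apply(gen, xi))))
  }
})

test_that("discriminator: sigmoid range, determinism, robustness", {
  disc <- build_discriminator(discriminator_spec(2, 4), seed = 7)
  set.seed(8)
  for (k in 1:20) {
    x <- matrix(rnorm(32 * 32), 32, 32)
    s <- discriminator_apply(disc, x)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_identical(discriminator_apply(disc, x), s)
    expect_true(is.finite(discriminator_apply(disc, x * 100)))
  }
})

test_that("network gradients match finite differences", {
  spec <- generator_spec(1, 2)
  P <- semsr:::gen_init(spec, 3)
  set.seed(9)
  xx <- array(rnorm(16), c(4, 4, 1, 1))
  zz <- array(rnorm(16), c(4, 4, 1, 1))
  loss_fn <- function(P) sum((semsr:::gen_forward(P, spec, xx)$y - zz)^2) / 2
  fw <- semsr:::gen_forward(P, spec, xx, keep_cache = TRUE)
  G <- semsr:::gen_backward(P, spec, fw$cache, fw$y - zz)
  eps <- 1e-6
  for (nm in names(P)) {
    for (q in sample(length(P[[nm]]), min(2, length(P[[nm]])))) {
      Pp <- P; Pp[[nm]][q] <- Pp[[nm]][q] + eps
      Pm <- P; Pm[[nm]][q] <- Pm[[nm]][q] - eps
      num <- (loss_fn(Pp) - loss_fn(Pm)) / (2 * eps)
      expect_equal(G[[nm]][q], num, tolerance = 1e-4)
    }
  }

  dspec <- discriminator_spec(1, 2)
  DP <- semsr:::disc_init(dspec, 4)
  dloss <- function(DP, x) sum((1 - semsr:::disc_forward(DP, dspec, x)$score)^2)
  dfw <- semsr:::disc_forward(DP, dspec, xx, keep_cache = TRUE)
  bb <- semsr:::disc_backward(DP, dspec, dfw$cache, -2 * (1 - dfw$score),
                              need_dx = TRUE)
  for (nm in names(DP)) {
    for (q in sample(length(DP[[nm]]), min(2, length(DP[[nm]])))) {
      Pp <- DP; Pp[[nm]][q] <- Pp[[nm]][q] + eps
      Pm <- DP; Pm[[nm]][q] <- Pm[[nm]][q] - eps
      num <- (dloss(Pp, xx) - dloss(Pm, xx)) / (2 * eps)
      expect_equal(bb$grads[[nm]][q], num, tolerance = 1e-4)
    }
  }
  # input gradient (used by the adversarial term)
  for (q in c(1, 7, 16)) {
    xp <- xx; xp[q] <- xp[q] + eps
    xm <- xx; xm[q] <- xm[q] - eps
    num <- (dloss(DP, xp) - dloss(DP, xm)) / (2 * eps)
    expect_equal(bb$dx[q], num, tolerance = 1e-4)
  }
})

test_that("training schedule, share bookkeeping and determinism", {
  set.seed(11)
  mk <- function(n) lapply(seq_len(n), function(i) {
    z <- semsr:::gaussian_blur(matrix(rnorm(256), 16, 16), 0.5)
    x <- semsr:::gaussian_blur(z, 1)
    list(x = (x - mean(x)) / sd(x), z = (z - mean(z)) / sd(z),
         row0 = 1, col0 = 1)
  })
  ds <- patch_dataset(mk(24))
  cfg <- train_config(iterations = 9, d_update_period = 4, batch_size = 4,
                      seed = 2)
  res <- train_gan(ds, generator_spec(1, 4), discriminator_spec(1, 4), cfg)
  expect_equal(nrow(res$history), 9L)
  expect_equal(sum(res$history$d_updated), 9L %/% 4L)
  shares <- with(res$history, share_l1 + share_tv + share_adv)
  expect_true(all(abs(shares - 1) < 1e-6))

  # iterations = 1 edge cases
  h1 <- train_gan(ds, generator_spec(1, 4), discriminator_spec(1, 4),
                  train_config(iterations = 1, d_update_period = 4,
                               batch_size = 4, seed = 2))$history
  expect_equal(nrow(h1), 1L)
  expect_equal(sum(h1$d_updated), 0L)
  h2 <- train_gan(ds, generator_spec(1, 4), discriminator_spec(1, 4),
                  train_config(iterations = 1, d_update_period = 1,
                               batch_size = 4, seed = 2))$history
  expect_equal(sum(h2$d_updated), 1L)

  # determinism: identical seed + config twice -> identical weights
  res2 <- train_gan(ds, generator_spec(1, 4), discriminator_spec(1, 4), cfg)
  expect_identical(res$generator$params, res2$generator$params)

  expect_error(train_gan(patch_dataset(list()), generator_spec(1, 4),
                         discriminator_spec(1, 4), cfg), "empty")
})

test_that("pure-L1 training beats the identity baseline on blurred pairs", {
  set.seed(12)
  mk <- function(n, seed0) lapply(seq_len(n), function(i) {
    set.seed(seed0 + i)
    z <- semsr:::gaussian_blur(matrix(rnorm(32 * 32), 32, 32), 0.7)
    x <- semsr:::gaussian_blur(z, 1.8)
    list(x = (x - mean(x)) / sd(x), z = (z - mean(z)) / sd(z),
         row0 = 1, col0 = 1)
  })
  train <- patch_dataset(mk(200, 1000))
  val <- patch_dataset(mk(24, 9000))
  res <- train_gan(train, generator_spec(2, 8), discriminator_spec(1, 4),
                   train_config(iterations = 400, batch_size = 8,
                                learning_rate = 1e-3, seed = 3,
                                weights = loss_weights(0, 0)),
                   val_dataset = val)
  expect_lt(res$val_l1, res$val_l1_identity)
})

test_that("tiled inference matches whole-image inference and is deterministic", {
  gen <- build_generator(generator_spec(2, 4), seed = 13)
  img <- textured_image(128, seed = 14, pitch = 14.2)
  whole <- infer_image(gen, img, tile = 512)
  tiled <- infer_image(gen, img, tile = 96, overlap = 16)
  expect_equal(dim(whole$pixels), c(256L, 256L))
  expect_equal(whole$pixel_size_nm, 7.1)
  dr <- diff(range(whole$pixels))
  expect_lt(mean(abs(whole$pixels - tiled$pixels)), 0.01 * dr)
  expect_identical(infer_image(gen, img, tile = 96, overlap = 16)$pixels,
                   tiled$pixels)
})

test_that("generator checkpoints round-trip through JSON", {
  gen <- build_generator(generator_spec(1, 3), seed = 15)
  path <- tempfile(fileext = ".json")
  write_generator(gen, path)
  gen2 <- read_generator(path)
  x <- matrix(rnorm(16 * 16), 16, 16)
  expect_equal(generator_apply(gen2, x), generator_apply(gen, x),
               tolerance = 1e-12)
})
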