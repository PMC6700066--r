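test_that("lanczos upsample: identity, DC preservation, round trip", {
  img <- textured_image(64, seed = 2)
  expect_identical(lanczos_upsample(img, 1), img)

  const <- sem_image(matrix(0.7, 32, 32), 10)
  up <- lanczos_upsample(const, 2)
  expect_equal(dim(up$pixels), c(64L, 64L))
  expect_equal(up$pixel_size_nm, 5)
  expect_lt(max(abs(up$pixels - 0.7)), 1e-6)

  # band-limited image: upsample 2x then decimate 2x recovers the original
  bl <- sem_image(semsr:::gaussian_blur(matrix(runif(64 * 64), 64, 64), 2), 10)
  up2 <- lanczos_upsample(bl, 2)
  dec <- up2$pixels[seq(1, 128, by = 2), seq(1, 128, by = 2)]
  expect_lt(mean(abs(dec - bl$pixels)), 0.01 * diff(range(bl$pixels)))

  expect_error(lanczos_upsample(img, 0), "factor")
})

test_that("estimate_affine recovers identity, known shift and known rotation", {
  fixed <- textured_image(160, seed = 5)

  est0 <- estimate_affine(fixed, fixed)
  expect_lt(sqrt(sum(est0$shift_px^2)), 0.1)
  expect_lt(abs(est0$rotation_deg), 0.05)

  # moving(i) = fixed(i + t) with t = (5, -3): recovered pull-shift is -t
  t_true <- c(5, -3)
  Ash <- semsr:::similarity_affine(0, 1, t_true, c(0, 0))
  moving <- sem_image(affine_apply(fixed$pixels, Ash), 7.1)
  est <- estimate_affine(moving, fixed)
  expect_lt(sqrt(sum((est$shift_px + t_true)^2)), 0.5)

  # known 2 degree rotation about the center
  Arot <- semsr:::similarity_affine(2, 1, c(0, 0), (dim(fixed$pixels) - 1) / 2)
  moving_r <- sem_image(affine_apply(fixed$pixels, Arot), 7.1)
  est_r <- estimate_affine(moving_r, fixed)
  expect_lt(abs(est_r$rotation_deg + 2), 0.2)
  # applying the estimated transform must align the pair
  expect_gt(est_r$correlation, 0.98)
})

test_that("estimate_affine rejects flat images", {
  flat <- sem_image(matrix(1, 64, 64), 7.1)
  expect_error(estimate_affine(flat, flat), "degenerate")
})

test_that("warp_apply: zero field identity, uniform shift on a ramp, inversion", {
  ramp <- matrix(rep(seq(0, 63), each = 64), 64, 64)  # value = column index
  zf <- displacement_field(matrix(0, 64, 64), matrix(0, 64, 64))
  expect_equal(warp_apply(ramp, zf), ramp)

  # dx = 1 on a horizontal ramp shifts values by one step in the interior
  uf <- displacement_field(matrix(0, 64, 64), matrix(1, 64, 64))
  w <- warp_apply(ramp, uf)
  expect_equal(w[, 1:63], ramp[, 1:63] + 1)

  img <- textured_image(96, seed = 8)
  f <- random_smooth_field(c(96, 96), 2, 32, seed = 4)
  neg <- displacement_field(-f$dy, -f$dx)
  back <- warp_apply(warp_apply(img$pixels, f), neg)
  interior <- 9:88
  err <- mean(abs(back[interior, interior] - img$pixels[interior, interior]))
  expect_lt(err, 0.02 * diff(range(img$pixels)))

  expect_error(warp_apply(matrix(0, 3, 3), zf), "shape")
})

test_that("sub-pixel translations are recovered within 0.25 px", {
  img <- textured_image(128, seed = 13)
  set.seed(77)
  for (k in 1:5) {
    t_true <- runif(2, 0.25, 0.75)
    f <- displacement_field(matrix(t_true[1], 128, 128),
                            matrix(t_true[2], 128, 128))
    moving <- warp_apply(img$pixels, f)
    s <- semsr:::xcorr_shift(img$pixels, moving, 8)
    expect_lt(sqrt(sum((s + t_true)^2)), 0.25)
  }
})

test_that("pyramid elastic registration recovers a known smooth warp", {
  img <- textured_image(128, seed = 21)
  expect_lt(sqrt(mean(unlist(
    pyramid_elastic_register(img, img, levels = 2, min_block_px = 16)[c("dy", "dx")]
  )^2)), 0.1)

  f_true <- random_smooth_field(c(128, 128), 2, 64, seed = 31)
  moving <- sem_image(warp_apply(img$pixels, f_true), 7.1)
  f_hat <- pyramid_elastic_register(moving, img, levels = 3, min_block_px = 16)
  # moving(i) = img(i + f_true(i)); the pull field back to img is ~ -f_true
  interior <- 13:116
  epe <- sqrt((f_hat$dy + f_true$dy)^2 + (f_hat$dx + f_true$dx)^2)
  expect_lt(sqrt(mean(epe[interior, interior]^2)), 0.5)
})

test_that("registration never decreases correlation", {
  set.seed(55)
  for (k in 1:10) {
    img <- textured_image(96, seed = 100 + k)
    f_true <- random_smooth_field(c(96, 96), runif(1, 0.5, 3), 48,
                                  seed = 200 + k)
    moving <- warp_apply(img$pixels, f_true)
    c0 <- zncc(img$pixels, moving)
    f_hat <- pyramid_elastic_register(moving, img$pixels, levels = 2,
                                      min_block_px = 16)
    c1 <- zncc(img$pixels, warp_apply(moving, f_hat))
    expect_gte(c1, c0 - 1e-12)
  }
})

test_that("register_pair aligns a simulated degraded pair", {
  field <- generate_particle_field(12, fov_nm = 908.8, near_pair_fraction = 0.5,
                                   pair_radius_range_nm = c(20, 45), seed = 3)
  high <- render_highres(field, 7.1)
  low <- degrade(high, degradation_config(psf_sigma_nm = 8,
                                          downsample_factor = 2, seed = 4))
  rp <- register_pair(low, high, levels = 2, min_block_px = 16)
  expect_gte(rp$correlation["elastic"], rp$correlation["before"] - 1e-12)
  expect_gt(rp$correlation["elastic"], 0.8)
})
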