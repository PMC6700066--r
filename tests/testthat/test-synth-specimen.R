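test_that("particle field generation respects counts, bounds and determinism", {
  f0 <- generate_particle_field(0, seed = 1)
  expect_equal(nrow(f0$particles), 0L)

  f <- generate_particle_field(40, fov_nm = 2000, near_pair_fraction = 0.5,
                               seed = 42)
  p <- f$particles
  expect_equal(nrow(p), 40L)
  expect_true(all(p$radius_nm >= 2.5 & p$radius_nm <= 75))
  expect_true(all(p$x_nm >= 0 & p$x_nm <= 2000))
  expect_true(all(p$y_nm >= 0 & p$y_nm <= 2000))
  # disks fully inside the field of view
  expect_true(all(p$x_nm - p$radius_nm >= 0 & p$x_nm + p$radius_nm <= 2000))

  f2 <- generate_particle_field(40, fov_nm = 2000, near_pair_fraction = 0.5,
                                seed = 42)
  expect_identical(f$particles, f2$particles)
  f3 <- generate_particle_field(40, fov_nm = 2000, near_pair_fraction = 0.5,
                                seed = 43)
  expect_false(identical(f$particles, f3$particles))
})

test_that("planted pairs have the requested gap range", {
  f <- generate_particle_field(30, fov_nm = 3000, near_pair_fraction = 1,
                               gap_range_nm = c(5, 40), seed = 7)
  segs <- pair_gap_segments(f)
  expect_equal(nrow(segs), 15L)
  expect_true(all(segs$gap_nm >= 5 - 1e-9 & segs$gap_nm <= 40 + 1e-9))
})

test_that("invalid field arguments error", {
  expect_error(generate_particle_field(5, fov_nm = -10), "positive")
  expect_error(generate_particle_field(5, radius_range_nm = c(100, 800),
                                       fov_nm = 500), "radius range")
})

test_that("rendering: empty field, symmetry, area proportionality", {
  empty <- generate_particle_field(0, fov_nm = 355, seed = 1)
  img <- render_highres(empty, 7.1, texture_amp = 0.02)
  expect_s3_class(img, "sem_image")
  expect_lte(max(img$pixels), 0.2 + 0.02 + 1e-12)

  # single centered particle: 180-degree rotational symmetry
  f1 <- structure(list(
    particles = data.frame(x_nm = 224, y_nm = 224, radius_nm = 50,
                           pair_id = NA_integer_),
    fov_nm = c(455.1, 455.1), seed = 1), class = "particle_field")
  im <- render_highres(f1, 7.1, texture_amp = 0)$pixels
  # pixel center grid is 0..63 * 7.1 nm; particle sits at index 224/7.1
  rot <- im[rev(seq_len(nrow(im))), rev(seq_len(ncol(im)))]
  ctr <- 224 / 7.1  # = 31.549..., not a grid point; compare via interpolation
  expect_lt(mean(abs(im - rot)), 0.02)

  # integrated foreground intensity tracks total particle area
  area_int <- function(radii) {
    parts <- data.frame(x_nm = seq(200, by = 400,
                                   length.out = length(radii)),
                        y_nm = rep(200, length(radii)),
                        radius_nm = radii, pair_id = NA_integer_)
    f <- structure(list(particles = parts,
                        fov_nm = c(400 * length(radii), 400), seed = 1),
                   class = "particle_field")
    im <- render_highres(f, 4, background_level = 0, texture_amp = 0)
    sum(im$pixels) * 16  # nm^2 per pixel
  }
  a1 <- area_int(40)
  a2 <- area_int(c(40, 40))
  a4 <- area_int(c(40, 40, 40, 40))
  expect_equal(a2 / a1, 2, tolerance = 0.02)
  expect_equal(a4 / a1, 4, tolerance = 0.02)
  expect_equal(a1, pi * 40^2, tolerance = 0.05)
})

test_that("degrade: identity config reproduces the input", {
  img <- textured_image(64, seed = 3)
  out <- degrade(img, degradation_config(psf_sigma_nm = 0, downsample_factor = 1,
                                         noise_poisson_scale = 0,
                                         noise_gaussian_sigma = 0,
                                         autocontrast = FALSE))
  expect_equal(out$pixels, img$pixels)
  expect_equal(out$pixel_size_nm, img$pixel_size_nm)
})

test_that("degrade halves dimensions and doubles pitch at factor 2", {
  img <- sem_image(matrix(runif(256 * 256), 256, 256), 7.1)
  out <- degrade(img, degradation_config(downsample_factor = 2, seed = 1))
  expect_equal(dim(out$pixels), c(128L, 128L))
  expect_equal(out$pixel_size_nm, 14.2)
  # dimensional bookkeeping: physical extent conserved
  expect_equal(nrow(out$pixels) * out$pixel_size_nm,
               nrow(img$pixels) * img$pixel_size_nm)
})

test_that("degrade crops to a multiple of the factor and records it", {
  img <- sem_image(matrix(runif(65 * 67), 65, 67), 7.1)
  out <- degrade(img, degradation_config(downsample_factor = 2,
                                         noise_poisson_scale = 0,
                                         noise_gaussian_sigma = 0,
                                         autocontrast = FALSE))
  expect_equal(dim(out$pixels), c(32L, 33L))
  expect_equal(out$meta$crop_px, c(1, 1))
})

test_that("decimation of a super-Nyquist sinusoid aliases to |f - 2 f_Nyq|", {
  # 0.050 cycles/nm sampled at 14.2 nm -> folds to 1/14.2 - 0.05 = 0.02042
  n <- 256; ps <- 7.1
  xs <- (0:(n - 1)) * ps
  img <- sem_image(0.5 + 0.4 * outer(rep(1, n), sin(2 * pi * 0.050 * xs)), ps)
  lo <- degrade(img, degradation_config(psf_sigma_nm = 0, downsample_factor = 2,
                                        noise_poisson_scale = 0,
                                        noise_gaussian_sigma = 0,
                                        autocontrast = FALSE))
  sp <- power_spectrum(lo)
  m <- sp$magnitude
  m[abs(sp$fy) < 1e-12, abs(sp$fx) < 1e-12] <- 0  # remove DC
  pk <- which(m == max(m), arr.ind = TRUE)[1, ]
  f_alias <- 2 * (1 / (2 * 14.2)) - 0.050
  bin <- 1 / (ncol(lo$pixels) * 14.2)
  expect_lt(abs(abs(sp$fx[pk[2]]) - f_alias), bin + 1e-12)
})

test_that("degradation is deterministic under its seed", {
  img <- textured_image(64, seed = 5)
  cfg <- degradation_config(psf_sigma_nm = 5, downsample_factor = 2,
                            seed = 99)
  expect_identical(degrade(img, cfg)$pixels, degrade(img, cfg)$pixels)
})

test_that("damage warp: identity at zero, bounded displacement, decreasing correlation", {
  img <- textured_image(96, seed = 11)
  expect_identical(apply_damage_warp(img, 0, 32, seed = 1)$pixels, img$pixels)

  f <- random_smooth_field(c(96, 96), magnitude_px = 3.5, smoothness_px = 24,
                           seed = 2)
  expect_lte(max(sqrt(f$dy^2 + f$dx^2)), 3.5 + 1e-9)
  expect_identical(random_smooth_field(c(96, 96), 3.5, 24, seed = 2), f)

  cors <- vapply(c(0, 1, 2, 4, 8), function(m)
    zncc(img$pixels, apply_damage_warp(img, m, 24, seed = 3)$pixels),
    numeric(1))
  expect_true(all(diff(cors) <= 1e-9))
})
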