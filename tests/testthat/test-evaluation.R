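test_that("extract_profile: constant image, geometry, row agreement", {
  const <- sem_image(matrix(0.4, 32, 32), 7.1)
  pr <- extract_profile(const, c(0, 35.5), c(200, 35.5))
  expect_true(all(abs(pr$intensities - 0.4) < 1e-12))
  expect_equal(max(pr$positions_nm), 200)
  expect_true(all(diff(pr$positions_nm) > 0))

  set.seed(21)
  img <- sem_image(matrix(runif(32 * 32), 32, 32), 7.1)
  # axis-aligned profile at integer steps equals direct row slicing:
  # y = 5 px -> image row 6; samples every 7.1 nm hit integer columns
  pr2 <- extract_profile(img, c(0, 5 * 7.1), c(31 * 7.1, 5 * 7.1),
                         step_nm = 7.1)
  expect_equal(pr2$intensities, img$pixels[6, ], tolerance = 1e-6)

  expect_error(extract_profile(img, c(-5, 0), c(10, 10)), "outside")
})

test_that("measure_gap reproduces the worked three-sample example", {
  pr <- make_line_profile(c(0, 7.1, 14.2), c(1.0, 0.5, 1.0))
  g <- measure_gap(pr)
  expect_true(g$exists)
  expect_equal(g$width_nm, 8.52, tolerance = 1e-9)
  # symmetric valley: crossings equidistant from the center
  expect_equal(g$valley_pos_nm, 7.1)
})

test_that("measure_gap basic rules", {
  # valley at 0.9 of peak: no gap under the 60% rule
  pr <- make_line_profile(seq(0, 20, by = 5), c(0.2, 1.0, 0.9, 1.0, 0.2))
  expect_false(measure_gap(pr)$exists)
  # monotone profile: no two flanking peaks
  mono <- make_line_profile(seq(0, 20, by = 5), c(1, 2, 3, 4, 5))
  m <- measure_gap(mono)
  expect_false(m$exists)
  expect_match(m$reason, "peaks")
})

test_that("gap width is invariant to intensity scaling and reversal", {
  set.seed(22)
  for (k in 1:25) {
    pr <- random_two_peak_profile(3000 + k)
    g <- measure_gap(pr)
    sc <- make_line_profile(pr$positions_nm, pr$intensities * 7.3)
    gs <- measure_gap(sc)
    expect_equal(gs$exists, g$exists)
    rv <- make_line_profile(pr$positions_nm, rev(pr$intensities))
    gr <- measure_gap(rv)
    expect_equal(gr$exists, g$exists)
    if (g$exists && is.finite(g$width_nm)) {
      expect_equal(gs$width_nm, g$width_nm, tolerance = 1e-9)
      expect_equal(gr$width_nm, g$width_nm, tolerance = 1e-6)
    }
  }
})

test_that("measure_gap agrees with the dense-scan oracle", {
  # full 1000-profile sweep lives in the acceptance suite; spot-check here
  for (k in 1:50) {
    pr <- random_two_peak_profile(100 + k)
    g <- measure_gap(pr)
    o <- oracle_measure_gap(pr$positions_nm, pr$intensities)
    expect_equal(g$exists, o$exists, info = paste("profile", k))
    if (g$exists && o$exists)
      expect_equal(g$width_nm, o$width, tolerance = 1e-3)
  }
})

test_that("gaussian_fit_histogram is moment-based and guards degenerate input", {
  expect_equal(gaussian_fit_histogram(c(10, 12, 14))$mu, 12)
  set.seed(23)
  draws <- rnorm(10000, 20, 3)
  fit <- gaussian_fit_histogram(draws, n_bins = 30)
  expect_equal(fit$mu, 20, tolerance = 0.1)
  expect_equal(fit$sigma, 3, tolerance = 0.1)
  # bin count does not change the fit
  fit2 <- gaussian_fit_histogram(draws, n_bins = 7)
  expect_identical(c(fit$mu, fit$sigma), c(fit2$mu, fit2$sigma))
  expect_error(gaussian_fit_histogram(rep(5, 10)), "degenerate")
})

test_that("gap_study partitions counts and behaves under blur", {
  field <- generate_particle_field(16, fov_nm = 1420, near_pair_fraction = 1,
                                   gap_range_nm = c(5, 40),
                                   pair_radius_range_nm = c(20, 45), seed = 31)
  gt <- render_highres(field, 7.1)
  blur <- gt
  blur$pixels <- semsr:::gaussian_blur(gt$pixels, 10 / 7.1)
  segs <- pair_gap_segments(field)
  st <- gap_study(list(input = blur, output = gt, ground_truth = gt), segs)

  pc <- st$per_class
  expect_equal(pc$n_resolved + pc$n_unresolved, rep(nrow(segs), 3))
  # output == ground truth: identical stats, zero width difference
  expect_equal(pc$mean_abs_diff_nm[pc$class == "output"], 0)
  expect_equal(pc$undetected_fraction[pc$class == "output"],
               pc$undetected_fraction[pc$class == "ground_truth"])
  # blurred input cannot resolve more gaps than the ground truth
  expect_gte(pc$undetected_fraction[pc$class == "input"],
             pc$undetected_fraction[pc$class == "ground_truth"])

  expect_error(gap_study(list(input = gt, output = gt, ground_truth = gt),
                         segs[0, ]), "non-empty")
})

test_that("undetected fraction is monotone in blur width", {
  field <- generate_particle_field(24, fov_nm = 2130, near_pair_fraction = 1,
                                   gap_range_nm = c(5, 40),
                                   pair_radius_range_nm = c(20, 45), seed = 33)
  gt <- render_highres(field, 7.1)
  segs <- pair_gap_segments(field)
  fr <- vapply(c(0, 5, 10, 20), function(s) {
    b <- gt
    if (s > 0) b$pixels <- semsr:::gaussian_blur(gt$pixels, s / 7.1)
    st <- gap_study(list(input = b, output = b, ground_truth = gt), segs)
    st$per_class$undetected_fraction[st$per_class$class == "input"]
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("power spectrum: DC, sinusoid peaks, Parseval", {
  const <- sem_image(matrix(3, 16, 16), 7.1)
  sp <- power_spectrum(const)
  dc <- which(sp$magnitude == max(sp$magnitude), arr.ind = TRUE)[1, ]
  expect_equal(abs(sp$fy[dc[1]]), 0)
  expect_equal(abs(sp$fx[dc[2]]), 0)
  expect_equal(sum(sp$magnitude > 1e-6), 1L)

  n <- 64
  k <- 5  # cycles per image along x
  img <- sem_image(1 + 0.5 * outer(rep(1, n), sin(2 * pi * k * (0:(n - 1)) / n)),
                   7.1)
  sp2 <- power_spectrum(img)
  m <- sp2$magnitude
  m[abs(sp2$fy) < 1e-12, abs(sp2$fx) < 1e-12] <- 0
  ord <- order(m, decreasing = TRUE)[1:2]
  peak_fx <- sp2$fx[((ord - 1) %/% n) + 1]
  expect_equal(sort(peak_fx), sort(c(-1, 1) * k / (n * 7.1)), tolerance = 1e-9)

  set.seed(24)
  r <- sem_image(matrix(runif(32 * 32), 32, 32), 5)
  spr <- power_spectrum(r)
  expect_equal(sum(spr$magnitude^2) / (32 * 32), sum(r$pixels^2),
               tolerance = 1e-6)
})

test_that("radial average: white-noise flatness and upsampling depression", {
  # isotropic white noise: flat radial profile (averaged over seeds)
  acc <- NULL
  for (s in 1:50) {
    set.seed(400 + s)
    img <- sem_image(matrix(runif(64 * 64), 64, 64), 7.1)
    rs <- radial_average(power_spectrum(img), n_bins = 12)
    acc <- if (is.null(acc)) rs$magnitude else acc + rs$magnitude
  }
  acc <- acc / 50
  mid <- acc[2:11]  # drop DC-contaminated first bin and sparse last bin
  expect_lt((max(mid) - min(mid)) / mean(mid), 0.1)

  # Lanczos-upsampled decimated image loses energy above the coarse Nyquist
  field <- generate_particle_field(14, fov_nm = 908.8, near_pair_fraction = 0.5,
                                   pair_radius_range_nm = c(20, 45), seed = 41)
  gt <- render_highres(field, 7.1)
  lo <- degrade(gt, degradation_config(psf_sigma_nm = 8, downsample_factor = 2,
                                       noise_poisson_scale = 0,
                                       noise_gaussian_sigma = 0,
                                       autocontrast = FALSE))
  up <- lanczos_upsample(lo, 2)
  nn <- min(nrow(up$pixels), nrow(gt$pixels))
  up$pixels <- up$pixels[1:nn, 1:nn]; gt$pixels <- gt$pixels[1:nn, 1:nn]
  rs_gt <- radial_average(power_spectrum(gt), 32)
  rs_up <- radial_average(power_spectrum(up), 32)
  hi <- rs_gt$frequency > 1 / (2 * 14.2)
  expect_true(mean(rs_up$magnitude[hi] < rs_gt$magnitude[hi], na.rm = TRUE) > 0.9)

  expect_error(radial_average(power_spectrum(gt), 1), "n_bins")
})

test_that("spectrum_study averages spectra per class", {
  img <- textured_image(32, seed = 26)
  one <- spectrum_study(list(a = img), n_bins = 8)$a
  direct <- radial_average(power_spectrum(img), 8)
  expect_equal(one$magnitude, direct$magnitude)
  rep3 <- spectrum_study(list(a = list(img, img, img)), n_bins = 8)$a
  expect_equal(rep3$magnitude, one$magnitude)
  expect_error(spectrum_study(list(a = list(img, textured_image(16, seed = 1)))),
               "mismatched")
})
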