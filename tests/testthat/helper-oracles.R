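# Independent reference implementations used to validate the fast paths.
# These deliberately use naive double loops / dense scans, not the package's
# own algorithms.

naive_l1 <- function(output, target) {
  s <- 0
  for (i in seq_len(nrow(output)))
    for (j in seq_len(ncol(output)))
      s <- s + abs(target[i, j] - output[i, j])
  s / (nrow(output) * ncol(output))
}

naive_tv <- function(m) {
  s <- 0
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i < nr) s <- s + abs(m[i + 1, j] - m[i, j])
    if (j < nc) s <- s + abs(m[i, j + 1] - m[i, j])
  }
  s
}

naive_generator_loss <- function(g_out, target, d_fake, alpha, beta)
  naive_l1(g_out, target) + alpha * naive_tv(g_out) + beta * (1 - d_fake)^2

naive_discriminator_loss <- function(d_fake, d_real) d_fake^2 + (1 - d_real)^2

# dense-scan gap oracle: linear interpolation of the profile at `res` nm,
# thresholds located by scanning, not by closed-form interpolation. The
# valley is sought strictly between the first and last profile samples
# (profile endpoints are the particle centers, not valley candidates) —
# the same convention the measurement defines.
oracle_measure_gap <- function(positions, intensities, exist_frac = 0.6,
                               width_frac = 0.8, res = 1e-4) {
  xs <- seq(min(positions), max(positions), by = res)
  vs <- stats::approx(positions, intensities, xout = xs)$y
  n_s <- length(positions)
  interior <- which(xs >= positions[2] & xs <= positions[n_s - 1L])
  vi <- interior[which.min(vs[interior])]
  if (vi <= 1L || vi >= length(vs))
    return(list(exists = FALSE, width = NA_real_))
  valley <- vs[vi]
  pl <- max(vs[1:(vi - 1L)]); pr <- max(vs[(vi + 1L):length(vs)])
  if (pl <= valley || pr <= valley)
    return(list(exists = FALSE, width = NA_real_))
  ref <- min(pl, pr)
  if (!(valley < exist_frac * ref))
    return(list(exists = FALSE, width = NA_real_))
  thr <- width_frac * ref
  l <- max(which(vs[1:(vi - 1L)] >= thr))
  r <- vi + min(which(vs[(vi + 1L):length(vs)] >= thr))
  list(exists = TRUE, width = xs[r] - xs[l])
}

# random two-peak profile: two Gaussian bumps on a low base; spans the range
# of shapes measure_gap must handle, including shallow (non-existent) valleys
random_two_peak_profile <- function(seed) {
  set.seed(seed)
  span <- 40
  pos <- seq(0, span, by = 1.25)
  h1 <- runif(1, 0.6, 1.2); h2 <- runif(1, 0.6, 1.2)
  w1 <- runif(1, 3, 8); w2 <- runif(1, 3, 8)
  c1 <- runif(1, 6, 14); c2 <- runif(1, 26, 34)
  base <- runif(1, 0.05, 0.55)
  v <- base + h1 * exp(-(pos - c1)^2 / (2 * w1^2)) +
    h2 * exp(-(pos - c2)^2 / (2 * w2^2))
  structure(list(positions_nm = pos, intensities = v), class = "line_profile")
}

# textured test image for registration studies: smoothed noise, fixed seed
textured_image <- function(n = 160, seed = 1, pitch = 7.1) {
  set.seed(seed)
  m <- semsr:::gaussian_blur(matrix(runif(n * n), n, n), 2)
  sem_image(m, pitch)
}

make_line_profile <- function(positions, intensities)
  structure(list(positions_nm = positions, intensities = intensities),
            class = "line_profile")
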