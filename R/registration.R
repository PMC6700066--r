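# Co-registration of low/high-resolution SEM pairs.
#
# Pipeline: Lanczos-upsample the low-resolution image onto the high-resolution
# pixel grid; correct rotation/scale/translation with a correlation-driven
# affine; then refine locally with a pyramid elastic scheme that splits the
# images into iteratively smaller blocks, estimates each block's translation
# by cross-correlation with parabolic sub-pixel refinement, and interpolates
# the block shifts into a dense smooth displacement field.
#
# Displacement/affine convention: transforms map FIXED-image coordinates to
# sampling positions in the MOVING image (pull/backward warping), so warping
# never leaves holes.

#' Displacement field constructor
#'
#' @param dy,dx numeric matrices of per-pixel displacements (pixels), same
#'   shape as the fixed image; `dy` is the row (vertical) component.
#' @return a `displacement_field`.
#' @export
displacement_field <- function(dy, dx) {
  if (!all(dim(dy) == dim(dx))) stop("dy and dx must have the same shape", call. = FALSE)
  if (!all(is.finite(dy)) || !all(is.finite(dx)))
    stop("displacements must be finite", call. = FALSE)
  structure(list(dy = dy, dx = dx), class = "displacement_field")
}

#' Affine transform constructor (2 x 3, pull convention)
#'
#' Maps fixed-image pixel coordinates (row, col) to sampling positions in the
#' moving image: `(y', x') = A[,1:2] %*% (y, x) + A[,3]`.
#'
#' @param m 2 x 3 numeric matrix.
#' @return an `affine_transform`.
#' @export
affine_transform <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 3L))) stop("affine matrix must be 2 x 3", call. = FALSE)
  if (abs(det(m[, 1:2])) <= 1e-6) stop("linear part is singular", call. = FALSE)
  structure(list(matrix = m), class = "affine_transform")
}

identity_affine <- function() affine_transform(cbind(diag(2), c(0, 0)))

# bilinear sampling at 0-based fractional coordinates, edge-clamped
bilinear_sample <- function(m, yq, xq) {
  nr <- nrow(m); nc <- ncol(m)
  yq <- pmin(pmax(yq, 0), nr - 1)
  xq <- pmin(pmax(xq, 0), nc - 1)
  y0 <- pmin(floor(yq), nr - 2); x0 <- pmin(floor(xq), nc - 2)
  y0 <- pmax(y0, 0); x0 <- pmax(x0, 0)
  fy <- yq - y0; fx <- xq - x0
  i00 <- y0 + 1 + x0 * nr
  v00 <- m[i00];        v10 <- m[i00 + 1]
  v01 <- m[i00 + nr];   v11 <- m[i00 + nr + 1]
  v00 * (1 - fy) * (1 - fx) + v10 * fy * (1 - fx) +
    v01 * (1 - fy) * fx + v11 * fy * fx
}

#' Warp an image by a displacement field
#'
#' Pull warping: output pixel (i, j) takes the bilinear sample of the input at
#' (i + dy\[i,j\], j + dx\[i,j\]); out-of-bounds samples clamp to the edge.
#'
#' @param image a `sem_image` (or numeric matrix).
#' @param field a `displacement_field` of the same shape.
#' @return warped image of the same type and shape.
#' @export
warp_apply <- function(image, field) {
  m <- if (is_sem_image(image)) image$pixels else image
  if (!all(dim(m) == dim(field$dy)))
    stop("image and field shapes differ", call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  base_y <- matrix(seq_len(nr) - 1, nr, nc)
  base_x <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  out <- matrix(bilinear_sample(m, base_y + field$dy, base_x + field$dx), nr, nc)
  if (is_sem_image(image)) {
    image$pixels <- pmax(out, 0)
    image
  } else out
}

#' Lanczos upsampling
#'
#' Separable windowed-sinc (Lanczos, order `a`) interpolation. Output pixel j
#' samples input coordinate j / factor, so decimation phase (pixel (0,0)) is
#' preserved and `upsample(decimate(x))` realigns with `x`. Kernel weights are
#' renormalized per output sample, so constants are reproduced exactly.
#'
#' @param image a `sem_image` or numeric matrix.
#' @param factor integer upsampling factor (>= 1).
#' @param a Lanczos order (default 3).
#' @return upsampled image; for `sem_image` input, `pixel_size_nm` is divided
#'   by `factor`.
#' @export
lanczos_upsample <- function(image, factor, a = 3L) {
  if (factor < 1 || factor != round(factor))
    stop("factor must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  m <- if (is_sem_image(image)) image$pixels else image
  if (factor == 1L) return(image)

  weights_1d <- function(n_in) {
    n_out <- n_in * factor
    W <- matrix(0, n_out, n_in)
    for (j in seq_len(n_out)) {
      x <- (j - 1) / factor               # input coordinate, 0-based
      k0 <- floor(x) - a + 1L
      ks <- k0:(floor(x) + a)
      t <- x - ks
      w <- ifelse(t == 0, 1,
                  a * sin(pi * t) * sin(pi * t / a) / (pi^2 * t^2))
      w[abs(t) >= a] <- 0
      ks_cl <- pmin(pmax(ks, 0L), n_in - 1L)   # edge clamp
      for (q in seq_along(ks)) W[j, ks_cl[q] + 1L] <- W[j, ks_cl[q] + 1L] + w[q]
      W[j, ] <- W[j, ] / sum(W[j, ])
    }
    W
  }
  Wr <- weights_1d(nrow(m))
  Wc <- if (ncol(m) == nrow(m)) Wr else weights_1d(ncol(m))
  out <- Wr %*% m %*% t(Wc)
  if (is_sem_image(image)) {
    img <- image
    img$pixels <- pmax(out, 0)
    img$pixel_size_nm <- image$pixel_size_nm / factor
    img$meta$upsampled_by <- factor
    img
  } else out
}

# cross-correlation shift estimate with parabolic sub-pixel refinement.
# Returns (dy, dx) such that fixed(i, j) ~ moving(i + dy, j + dx).
# Zero-mean, zero-padded FFT correlation; peak searched within +/- max_shift.
# A second pass on the first-pass-resampled moving image removes most of the
# parabolic fit's sub-pixel bias.
xcorr_shift <- function(fixed, moving, max_shift, refine = TRUE) {
  s1 <- xcorr_shift_once(fixed, moving, max_shift)
  if (!refine) return(s1)
  nr <- nrow(moving); nc <- ncol(moving)
  base_y <- matrix(seq_len(nr) - 1, nr, nc)
  base_x <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  warped <- matrix(bilinear_sample(moving, base_y + s1[1], base_x + s1[2]),
                   nr, nc)
  s2 <- xcorr_shift_once(fixed, warped, max(2L, ceiling(abs(s1) %% 1 + 1)))
  s1 + s2
}

xcorr_shift_once <- function(fixed, moving, max_shift) {
  nr <- nrow(fixed); nc <- ncol(fixed)
  max_shift <- min(max_shift, nr - 1L, nc - 1L)
  P <- nr + max_shift; Q <- nc + max_shift
  A <- matrix(0, P, Q); B <- matrix(0, P, Q)
  A[1:nr, 1:nc] <- fixed - mean(fixed)
  B[1:nr, 1:nc] <- moving - mean(moving)
  CC <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE))
  sh <- (-max_shift):max_shift
  idx <- function(s, n) ((s %% n) + 1L)
  grid <- CC[idx(sh, P), idx(sh, Q)]
  pk <- which(grid == max(grid), arr.ind = TRUE)[1, ]
  dy <- sh[pk[1]]; dx <- sh[pk[2]]
  sub <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) return(0)                 # not a proper peak
    max(min(0.5 * (cm - cp) / den, 0.5), -0.5)
  }
  ddy <- ddx <- 0
  if (pk[1] > 1 && pk[1] < nrow(grid))
    ddy <- sub(grid[pk[1] - 1, pk[2]], grid[pk[1], pk[2]], grid[pk[1] + 1, pk[2]])
  if (pk[2] > 1 && pk[2] < ncol(grid))
    ddx <- sub(grid[pk[1], pk[2] - 1], grid[pk[1], pk[2]], grid[pk[1], pk[2] + 1])
  c(dy + ddy, dx + ddx)
}

#' Apply an affine transform to an image (pull warping)
#'
#' @param image `sem_image` or matrix (the moving image).
#' @param transform an `affine_transform` mapping output (fixed) coordinates
#'   to input sampling positions.
#' @param out_shape output (rows, cols); default the input shape.
#' @return resampled image.
#' @export
affine_apply <- function(image, transform, out_shape = NULL) {
  m <- if (is_sem_image(image)) image$pixels else image
  if (is.null(out_shape)) out_shape <- dim(m)
  A <- transform$matrix
  nr <- out_shape[1]; nc <- out_shape[2]
  base_y <- matrix(seq_len(nr) - 1, nr, nc)
  base_x <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  yq <- A[1, 1] * base_y + A[1, 2] * base_x + A[1, 3]
  xq <- A[2, 1] * base_y + A[2, 2] * base_x + A[2, 3]
  out <- matrix(bilinear_sample(m, yq, xq), nr, nc)
  if (is_sem_image(image)) {
    image$pixels <- pmax(out, 0)
    image
  } else out
}

# rotation (deg) + isotropic scale about the image center, plus translation t
# applied in fixed coordinates before the similarity: pull transform
# x_m = s R (x_f + t - c) + c
similarity_affine <- function(rot_deg, scale, t, center) {
  th <- rot_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  L <- scale * R
  offset <- as.vector(L %*% (t - center)) + center
  affine_transform(cbind(L, offset))
}

#' Estimate the affine (similarity) transform aligning two images
#'
#' Coarse grid search over rotation and isotropic scale with FFT
#' cross-correlation for translation, followed by a local fine search.
#' Maximizes zero-normalized cross-correlation; the identity is returned if no
#' candidate improves on it, so the post-alignment correlation never drops.
#'
#' @param moving,fixed `sem_image`s on the same pixel grid (upsample first).
#' @param rot_range_deg rotation search interval (degrees).
#' @param scale_range isotropic scale search interval.
#' @param max_shift_px translation search radius (pixels).
#' @return list with `transform` (an `affine_transform`, pull convention:
#'   fixed coords -> moving coords), `correlation`, and the estimated
#'   `rotation_deg`, `scale`, `shift_px`.
#' @export
estimate_affine <- function(moving, fixed,
                            rot_range_deg = c(-5, 5),
                            scale_range = c(0.96, 1.04),
                            max_shift_px = NULL) {
  mf <- if (is_sem_image(fixed)) fixed$pixels else fixed
  mm <- if (is_sem_image(moving)) moving$pixels else moving
  if (stats::sd(mf) == 0 || stats::sd(mm) == 0)
    stop("degenerate input: zero-variance image", call. = FALSE)
  if (is.null(max_shift_px)) max_shift_px <- round(min(dim(mf)) / 4)
  center <- (dim(mf) - 1) / 2

  crop_margin <- max(2L, round(min(dim(mf)) * 0.1))
  interior <- function(x) {
    x[(crop_margin + 1):(nrow(x) - crop_margin),
      (crop_margin + 1):(ncol(x) - crop_margin)]
  }
  score_of <- function(rot, sc) {
    A0 <- similarity_affine(rot, sc, c(0, 0), center)
    w <- affine_apply(mm, A0, dim(mf))
    t_hat <- xcorr_shift(mf, w, max_shift_px)
    A <- similarity_affine(rot, sc, t_hat, center)
    w2 <- affine_apply(mm, A, dim(mf))
    list(score = zncc(interior(mf), interior(w2)), transform = A,
         rot = rot, scale = sc, shift = t_hat)
  }
  search <- function(rots, scales, best) {
    for (rot in rots) for (sc in scales) {
      cand <- score_of(rot, sc)
      if (cand$score > best$score) best <- cand
    }
    best
  }
  best <- list(score = -Inf)
  best <- search(seq(rot_range_deg[1], rot_range_deg[2], by = 1),
                 seq(scale_range[1], scale_range[2], by = 0.02), best)
  best <- search(best$rot + seq(-0.5, 0.5, by = 0.1),
                 best$scale + seq(-0.01, 0.01, by = 0.005), best)
  best <- search(best$rot + seq(-0.08, 0.08, by = 0.02),
                 best$scale + seq(-0.004, 0.004, by = 0.002), best)

  id_score <- zncc(interior(mf), interior(mm))
  if (best$score < id_score)
    best <- list(score = id_score, transform = identity_affine(),
                 rot = 0, scale = 1, shift = c(0, 0))
  list(transform = best$transform, correlation = best$score,
       rotation_deg = best$rot, scale = best$scale, shift_px = best$shift)
}

# Catmull-Rom interpolation of a coarse value grid (samples at `centers`,
# 0-based pixel coordinates) onto 0..n-1; separable, edge-clamped.
interp_grid_bicubic <- function(V, centers_y, centers_x, out_shape) {
  cr_weights <- function(centers, n_out) {
    ng <- length(centers)
    if (ng == 1L) return(matrix(1, n_out, 1))
    sp <- centers[2] - centers[1]
    g <- ((seq_len(n_out) - 1) - centers[1]) / sp    # grid coordinate
    g <- pmin(pmax(g, 0), ng - 1)
    i1 <- pmin(floor(g), ng - 2); t <- g - i1
    W <- matrix(0, n_out, ng)
    k <- cbind(i1 - 1, i1, i1 + 1, i1 + 2)
    w <- cbind(-0.5 * t^3 + t^2 - 0.5 * t,
               1.5 * t^3 - 2.5 * t^2 + 1,
               -1.5 * t^3 + 2 * t^2 + 0.5 * t,
               0.5 * t^3 - 0.5 * t^2)
    for (q in 1:4) {
      kc <- pmin(pmax(k[, q], 0), ng - 1) + 1
      W[cbind(seq_len(n_out), kc)] <- W[cbind(seq_len(n_out), kc)] + w[, q]
    }
    W
  }
  Wy <- cr_weights(centers_y, out_shape[1])
  Wx <- cr_weights(centers_x, out_shape[2])
  Wy %*% V %*% t(Wx)
}

#' Pyramid elastic registration
#'
#' Coarse-to-fine block matching: at level k the field of view is split into
#' 2^k x 2^k blocks; each block's residual translation (moving warped by the
#' current field vs fixed) is estimated by cross-correlation with parabolic
#' sub-pixel refinement; block shifts are interpolated (Catmull-Rom bicubic)
#' to a dense displacement field and composed across levels. A level whose
#' update would lower the moving/fixed correlation is rolled back, so the
#' final correlation never falls below the starting (e.g. affine-only) one.
#' Zero-variance blocks inherit the field interpolated from their neighbours.
#'
#' @param moving,fixed `sem_image`s (or matrices) of identical shape.
#' @param levels number of pyramid levels (>= 1).
#' @param min_block_px stop refining when blocks would get smaller than this.
#' @param max_shift_px per-block search radius at level 1; halved per level.
#' @return a `displacement_field` mapping fixed coords to moving coords.
#' @export
pyramid_elastic_register <- function(moving, fixed, levels = 3L,
                                     min_block_px = 24L, max_shift_px = NULL) {
  mf <- if (is_sem_image(fixed)) fixed$pixels else fixed
  mm <- if (is_sem_image(moving)) moving$pixels else moving
  if (!all(dim(mf) == dim(mm))) stop("images must have the same shape", call. = FALSE)
  if (levels < 1) stop("levels must be >= 1", call. = FALSE)
  nr <- nrow(mf); nc <- ncol(mf)
  if (is.null(max_shift_px)) max_shift_px <- max(4, round(min(nr, nc) / 8))

  field <- displacement_field(matrix(0, nr, nc), matrix(0, nr, nc))
  best_corr <- zncc(mf, mm)

  for (k in seq_len(levels)) {
    nb <- 2L^k
    bh <- nr %/% nb; bw <- nc %/% nb
    if (min(bh, bw) < min_block_px) break
    warped <- warp_apply(mm, field)
    Vy <- matrix(NA_real_, nb, nb); Vx <- matrix(NA_real_, nb, nb)
    ms <- max(2L, round(max_shift_px / 2^(k - 1)))
    for (bi in seq_len(nb)) for (bj in seq_len(nb)) {
      ri <- ((bi - 1) * bh + 1):(bi * bh)
      rj <- ((bj - 1) * bw + 1):(bj * bw)
      fb <- mf[ri, rj]; wb <- warped[ri, rj]
      if (stats::sd(fb) < 1e-10 || stats::sd(wb) < 1e-10) next
      s <- xcorr_shift(fb, wb, ms)
      Vy[bi, bj] <- s[1]; Vx[bi, bj] <- s[2]
    }
    # flat blocks inherit the mean of their estimated neighbours
    if (anyNA(Vy)) {
      fill <- function(V) {
        if (all(is.na(V))) return(matrix(0, nb, nb))
        while (anyNA(V)) {
          for (bi in seq_len(nb)) for (bj in seq_len(nb)) {
            if (!is.na(V[bi, bj])) next
            ni <- max(1, bi - 1):min(nb, bi + 1)
            nj <- max(1, bj - 1):min(nb, bj + 1)
            nh <- V[ni, nj]
            if (any(!is.na(nh))) V[bi, bj] <- mean(nh, na.rm = TRUE)
          }
        }
        V
      }
      Vy <- fill(Vy); Vx <- fill(Vx)
    }
    cy <- (seq_len(nb) - 0.5) * bh - 0.5
    cx <- (seq_len(nb) - 0.5) * bw - 0.5
    ry <- interp_grid_bicubic(Vy, cy, cx, c(nr, nc))
    rx <- interp_grid_bicubic(Vx, cy, cx, c(nr, nc))
    cand <- displacement_field(field$dy + ry, field$dx + rx)
    cand_corr <- zncc(mf, warp_apply(mm, cand))
    if (cand_corr >= best_corr) {
      field <- cand
      best_corr <- cand_corr
    }
  }
  field
}

#' Register a low/high-resolution pair end to end
#'
#' Upsamples the low-resolution image by `factor` (Lanczos), then aligns the
#' high-resolution image to it with the affine and elastic stages (the
#' high-resolution acquisition is the moving image by default, so the network
#' input keeps the coarse acquisition's geometry).
#'
#' @param low,high the coarse and fine `sem_image`s.
#' @param factor pitch ratio between low and high (default 2).
#' @param levels,min_block_px elastic-stage controls.
#' @param elastic run the elastic refinement stage (default TRUE).
#' @return list with `x` (upsampled low), `z` (aligned high), `transform`,
#'   `field`, `correlation` (before/affine/elastic).
#' @export
register_pair <- function(low, high, factor = 2L, levels = 3L,
                          min_block_px = 24L, elastic = TRUE) {
  x <- lanczos_upsample(low, factor)
  if (!all(dim(x$pixels) == dim(high$pixels))) {
    nr <- min(nrow(x$pixels), nrow(high$pixels))
    nc <- min(ncol(x$pixels), ncol(high$pixels))
    x$pixels <- x$pixels[1:nr, 1:nc, drop = FALSE]
    high$pixels <- high$pixels[1:nr, 1:nc, drop = FALSE]
  }
  corr0 <- zncc(x, high)
  est <- estimate_affine(moving = high, fixed = x)
  z <- affine_apply(high, est$transform, dim(x$pixels))
  corr_aff <- zncc(x, z)
  field <- NULL; corr_el <- corr_aff
  if (elastic) {
    field <- pyramid_elastic_register(z, x, levels = levels,
                                      min_block_px = min_block_px)
    z <- warp_apply(z, field)
    corr_el <- zncc(x, z)
  }
  list(x = x, z = z, transform = est$transform, field = field,
       correlation = c(before = corr0, affine = corr_aff, elastic = corr_el))
}
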