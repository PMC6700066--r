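# Synthetic gold-on-carbon specimen and SEM acquisition forward model.
#
# The simulator emulates the resolution test target used to benchmark SEM
# systems: gold nanoparticles with diameters 5-150 nm immobilized on a darker
# carbon substrate. A fraction of particles is planted as near-pairs with a
# controlled edge-to-edge gap so that gap-resolvability statistics have known
# ground truth. The low-magnification acquisition is modelled as an aliased
# version of the high-magnification one: beam-PSF blur, plain decimation
# (no anti-alias pre-filter), per-pixel detector noise, and an optional
# automatic brightness/contrast stretch.

#' Generate a random nanoparticle field
#'
#' Particle radii are drawn uniformly from `radius_range_nm` (default
#' 2.5-75 nm, i.e. diameters 5-150 nm). A fraction `near_pair_fraction` of the
#' particles is placed as pairs whose edge-to-edge gap is drawn uniformly from
#' `gap_range_nm`; these planted pairs are the measurable gaps used by the
#' evaluation module. Remaining particles are placed independently with
#' overlap rejection. Fully deterministic under `seed`.
#'
#' @param n_particles number of particles (>= 0).
#' @param radius_range_nm radius interval in nm; must lie inside
#'   (0, min(fov)/2).
#' @param fov_nm field of view (width, height) in nm; a single number is
#'   recycled to a square field.
#' @param near_pair_fraction fraction of particles placed as gap pairs.
#' @param gap_range_nm edge-to-edge gap interval for planted pairs (nm).
#' @param pair_radius_range_nm radius interval for pair members; defaults to
#'   `radius_range_nm` clamped so both disks plus the gap fit in the field.
#' @param seed integer seed.
#' @return a `particle_field`: list with `particles` (data.frame `x_nm`,
#'   `y_nm`, `radius_nm`, `pair_id`), `fov_nm`, `seed`.
#' @export
generate_particle_field <- function(n_particles,
                                    radius_range_nm = c(2.5, 75),
                                    fov_nm = c(1420, 1420),
                                    near_pair_fraction = 0.5,
                                    gap_range_nm = c(5, 40),
                                    pair_radius_range_nm = NULL,
                                    seed = 1L) {
  if (length(fov_nm) == 1L) fov_nm <- c(fov_nm, fov_nm)
  if (any(fov_nm <= 0)) stop("field of view must be positive", call. = FALSE)
  if (n_particles < 0) stop("n_particles must be >= 0", call. = FALSE)
  if (any(radius_range_nm <= 0) || diff(radius_range_nm) < 0 ||
      radius_range_nm[2] >= min(fov_nm) / 2)
    stop("radius range must lie inside (0, fov/2)", call. = FALSE)
  if (near_pair_fraction < 0 || near_pair_fraction > 1)
    stop("near_pair_fraction must be in [0, 1]", call. = FALSE)
  if (is.null(pair_radius_range_nm)) {
    pair_radius_range_nm <- c(radius_range_nm[1],
                              min(radius_range_nm[2], min(fov_nm) / 8))
    pair_radius_range_nm[2] <- max(pair_radius_range_nm)
  }

  empty <- data.frame(x_nm = numeric(), y_nm = numeric(),
                      radius_nm = numeric(), pair_id = integer())
  field <- structure(list(particles = empty, fov_nm = fov_nm,
                          seed = as.integer(seed)),
                     class = "particle_field")
  if (n_particles == 0L) return(field)

  n_pairs <- floor(n_particles * near_pair_fraction / 2)
  n_single <- n_particles - 2L * n_pairs

  with_seed(seed, {
    rows <- vector("list", n_pairs + n_single)
    placed <- matrix(numeric(0), ncol = 3)  # x, y, r of accepted particles

    ok_overlap <- function(x, y, r) {
      if (nrow(placed) == 0L) return(TRUE)
      d <- sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2)
      all(d >= placed[, 3] + r + 2)  # keep >= 2 nm clearance
    }

    pid <- 0L
    for (p in seq_len(n_pairs)) {
      pid <- pid + 1L
      for (try in 1:200) {
        r1 <- stats::runif(1, pair_radius_range_nm[1], pair_radius_range_nm[2])
        r2 <- stats::runif(1, pair_radius_range_nm[1], pair_radius_range_nm[2])
        gap <- stats::runif(1, gap_range_nm[1], gap_range_nm[2])
        theta <- stats::runif(1, 0, 2 * pi)
        half <- (r1 + r2 + gap) / 2
        inset <- half + max(r1, r2)
        if (2 * inset >= min(fov_nm)) next
        mx <- stats::runif(1, inset, fov_nm[1] - inset)
        my <- stats::runif(1, inset, fov_nm[2] - inset)
        ux <- cos(theta); uy <- sin(theta)
        x1 <- mx - half * ux; y1 <- my - half * uy
        x2 <- mx + half * ux; y2 <- my + half * uy
        if (ok_overlap(x1, y1, r1) && ok_overlap(x2, y2, r2)) {
          placed <- rbind(placed, c(x1, y1, r1), c(x2, y2, r2))
          rows[[p]] <- data.frame(x_nm = c(x1, x2), y_nm = c(y1, y2),
                                  radius_nm = c(r1, r2),
                                  pair_id = c(pid, pid))
          break
        }
      }
    }
    for (s in seq_len(n_single)) {
      for (try in 1:200) {
        r <- stats::runif(1, radius_range_nm[1], radius_range_nm[2])
        x <- stats::runif(1, r, fov_nm[1] - r)
        y <- stats::runif(1, r, fov_nm[2] - r)
        if (ok_overlap(x, y, r) || try == 200L) {
          placed <- rbind(placed, c(x, y, r))
          rows[[n_pairs + s]] <- data.frame(x_nm = x, y_nm = y, radius_nm = r,
                                            pair_id = NA_integer_)
          break
        }
      }
    }
    field$particles <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(field$particles) <- NULL
  })
  field
}

#' @export
print.particle_field <- function(x, ...) {
  np <- nrow(x$particles)
  cat(sprintf("<particle_field> %d particles (%d planted pairs) in %g x %g nm\n",
              np, length(unique(stats::na.omit(x$particles$pair_id))),
              x$fov_nm[1], x$fov_nm[2]))
  invisible(x)
}

#' Planted gap segments of a particle field
#'
#' One segment per planted pair, running through the two particle centers.
#' These are the line profiles along which gap resolvability is measured.
#'
#' @param field a `particle_field`.
#' @return data.frame with columns `pair_id, x1_nm, y1_nm, x2_nm, y2_nm,
#'   gap_nm` (`gap_nm` = true edge-to-edge distance).
#' @export
pair_gap_segments <- function(field) {
  p <- field$particles
  ids <- sort(unique(stats::na.omit(p$pair_id)))
  out <- lapply(ids, function(id) {
    q <- p[!is.na(p$pair_id) & p$pair_id == id, ]
    if (nrow(q) != 2L) return(NULL)
    d <- sqrt(diff(q$x_nm)^2 + diff(q$y_nm)^2)
    data.frame(pair_id = id,
               x1_nm = q$x_nm[1], y1_nm = q$y_nm[1],
               x2_nm = q$x_nm[2], y2_nm = q$y_nm[2],
               gap_nm = d - sum(q$radius_nm))
  })
  do.call(rbind, out)
}

#' Render the high-resolution ground-truth image of a particle field
#'
#' Anti-aliased rendering of bright disks on a darker, gently textured
#' background. Disk edges use a linear coverage ramp of width
#' `edge_softness_nm`, so integrated foreground intensity is proportional to
#' particle area. The image extent is the largest integer pixel grid fitting
#' the field of view; any cropped remainder is recorded in `meta$crop_nm`.
#'
#' @param field a `particle_field`.
#' @param pixel_size_nm pixel pitch of the rendering (nm), e.g. 7.1.
#' @param background_level background intensity (fraction of dynamic range).
#' @param particle_level intensity of the gold particles.
#' @param edge_softness_nm width of the linear edge ramp (default one pixel).
#' @param texture_amp peak amplitude of the smooth background texture.
#' @return a `sem_image` at `pixel_size_nm`.
#' @export
render_highres <- function(field, pixel_size_nm,
                           background_level = 0.2,
                           particle_level = 1.0,
                           edge_softness_nm = pixel_size_nm,
                           texture_amp = 0.02) {
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0", call. = FALSE)
  nc <- max(1L, floor(field$fov_nm[1] / pixel_size_nm))
  nr <- max(1L, floor(field$fov_nm[2] / pixel_size_nm))
  crop <- c(field$fov_nm[1] - nc * pixel_size_nm,
            field$fov_nm[2] - nr * pixel_size_nm)

  # smooth low-frequency background texture, seeded from the field
  bg <- matrix(background_level, nr, nc)
  if (texture_amp > 0) {
    xs <- (seq_len(nc) - 1) * pixel_size_nm
    ys <- (seq_len(nr) - 1) * pixel_size_nm
    tex <- with_seed(field$seed + 7L, {
      t <- matrix(0, nr, nc)
      for (k in 1:4) {
        wl <- stats::runif(1, 150, 500)        # nm
        th <- stats::runif(1, 0, pi)
        ph <- stats::runif(1, 0, 2 * pi)
        fx <- cos(th) / wl; fy <- sin(th) / wl
        t <- t + outer(ys, xs, function(y, x) sin(2 * pi * (fx * x + fy * y) + ph))
      }
      t / max(abs(t)) * texture_amp
    })
    bg <- bg + tex
  }

  cov <- matrix(0, nr, nc)
  s <- max(edge_softness_nm, 1e-9)
  p <- field$particles
  for (i in seq_len(NROW(p))) {
    r <- p$radius_nm[i]
    # bounding box in pixel indices (0-based centers at index * pitch)
    j0 <- max(0L, floor((p$x_nm[i] - r - s) / pixel_size_nm))
    j1 <- min(nc - 1L, ceiling((p$x_nm[i] + r + s) / pixel_size_nm))
    i0 <- max(0L, floor((p$y_nm[i] - r - s) / pixel_size_nm))
    i1 <- min(nr - 1L, ceiling((p$y_nm[i] + r + s) / pixel_size_nm))
    if (j1 < j0 || i1 < i0) next
    jj <- j0:j1; ii <- i0:i1
    dx <- jj * pixel_size_nm - p$x_nm[i]
    dy <- ii * pixel_size_nm - p$y_nm[i]
    d <- sqrt(outer(dy^2, dx^2, "+"))
    c_loc <- pmin(pmax(0.5 + (r - d) / s, 0), 1)
    idx_r <- ii + 1L; idx_c <- jj + 1L
    cov[idx_r, idx_c] <- pmax(cov[idx_r, idx_c], c_loc)
  }
  px <- bg * (1 - cov) + particle_level * cov
  sem_image(pmax(px, 0), pixel_size_nm,
            meta = list(source = "render_highres", crop_nm = crop,
                        background_level = background_level,
                        particle_level = particle_level,
                        edge_softness_nm = edge_softness_nm,
                        texture_amp = texture_amp, seed = field$seed))
}

#' Degradation (low-magnification acquisition) configuration
#'
#' @param psf_sigma_nm Gaussian beam-PSF sigma in nm (>= 0).
#' @param downsample_factor integer decimation factor (>= 1).
#' @param noise_poisson_scale scale of signal-dependent (shot-like) noise;
#'   the per-pixel standard deviation is `sqrt(intensity * scale)`.
#' @param noise_gaussian_sigma additive read-noise sigma.
#' @param autocontrast apply a percentile min/max brightness/contrast stretch
#'   (emulating the microscope's automatic adjustment).
#' @param autocontrast_percentiles lower/upper percentiles of the stretch.
#' @param seed integer noise seed.
#' @return a `degradation_config` list.
#' @export
degradation_config <- function(psf_sigma_nm = 10,
                               downsample_factor = 2L,
                               noise_poisson_scale = 0.001,
                               noise_gaussian_sigma = 0.01,
                               autocontrast = TRUE,
                               autocontrast_percentiles = c(0.5, 99.5),
                               seed = 1L) {
  if (psf_sigma_nm < 0 || noise_poisson_scale < 0 || noise_gaussian_sigma < 0)
    stop("degradation parameters must be non-negative", call. = FALSE)
  if (downsample_factor < 1) stop("downsample_factor must be >= 1", call. = FALSE)
  structure(list(psf_sigma_nm = psf_sigma_nm,
                 downsample_factor = as.integer(downsample_factor),
                 noise_poisson_scale = noise_poisson_scale,
                 noise_gaussian_sigma = noise_gaussian_sigma,
                 autocontrast = isTRUE(autocontrast),
                 autocontrast_percentiles = autocontrast_percentiles,
                 seed = as.integer(seed)),
            class = "degradation_config")
}

# separable Gaussian blur with edge-replicate padding; sigma in pixels
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma_px))
  w <- stats::dnorm(-r:r, sd = sigma_px)
  w <- w / sum(w)
  blur_axis <- function(x, along_rows) {
    if (!along_rows) return(t(blur_axis(t(x), TRUE)))
    n <- nrow(x)
    pad <- rbind(x[rep(1L, r), , drop = FALSE], x, x[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (t in seq_along(w)) out <- out + w[t] * pad[(t - 1) + seq_len(n), , drop = FALSE]
    out
  }
  blur_axis(blur_axis(m, TRUE), FALSE)
}

#' Simulate the low-magnification acquisition of a high-resolution image
#'
#' Applies, in order: Gaussian beam-PSF blur of width `psf_sigma_nm`; plain
#' decimation by `downsample_factor` keeping pixel (0,0) phase — deliberately
#' aliasing, with no anti-alias pre-filter beyond the PSF; signal-dependent
#' shot-like noise plus additive Gaussian noise (noise accrues per acquired
#' pixel, hence after decimation); and an optional percentile
#' brightness/contrast stretch. Output pixel pitch is
#' `input pitch * downsample_factor`. If the factor does not divide the image
#' dimensions the image is cropped to the largest multiple and the crop is
#' recorded in `meta$crop_px`.
#'
#' @param high a `sem_image` (the high-resolution acquisition).
#' @param config a `degradation_config`.
#' @return a `sem_image` at the coarser pitch.
#' @export
degrade <- function(high, config) {
  assert_sem_image(high)
  if (!inherits(config, "degradation_config"))
    stop("`config` must be a degradation_config", call. = FALSE)
  k <- config$downsample_factor
  px <- high$pixels
  crop <- c(nrow(px) %% k, ncol(px) %% k)
  if (any(crop > 0))
    px <- px[seq_len(nrow(px) - crop[1]), seq_len(ncol(px) - crop[2]), drop = FALSE]

  px <- gaussian_blur(px, config$psf_sigma_nm / high$pixel_size_nm)
  px <- px[seq(1L, nrow(px), by = k), seq(1L, ncol(px), by = k), drop = FALSE]

  if (config$noise_poisson_scale > 0 || config$noise_gaussian_sigma > 0) {
    px <- with_seed(config$seed, {
      n <- length(px)
      sd_shot <- sqrt(pmax(px, 0) * config$noise_poisson_scale)
      px + sd_shot * stats::rnorm(n) + config$noise_gaussian_sigma * stats::rnorm(n)
    })
  }
  if (config$autocontrast) {
    q <- stats::quantile(px, config$autocontrast_percentiles / 100,
                         names = FALSE)
    if (q[2] > q[1]) px <- (px - q[1]) / (q[2] - q[1])
  }
  sem_image(pmax(px, 0), high$pixel_size_nm * k,
            meta = c(high$meta[setdiff(names(high$meta), "source")],
                     list(source = "degrade", crop_px = crop,
                          degradation = unclass(config))))
}

#' Smooth random displacement field
#'
#' Sum of four low-frequency sinusoidal displacement components with random
#' orientations and phases per axis, rescaled so the maximum displacement
#' magnitude equals `magnitude_px`. Used to emulate beam-damage deformation.
#'
#' @param shape (rows, cols) of the field.
#' @param magnitude_px maximum displacement magnitude in pixels.
#' @param smoothness_px shortest deformation wavelength in pixels.
#' @param seed integer seed.
#' @return list with matrices `dy`, `dx` (class `displacement_field`).
#' @export
random_smooth_field <- function(shape, magnitude_px, smoothness_px, seed = 1L) {
  if (magnitude_px < 0) stop("magnitude must be >= 0", call. = FALSE)
  if (smoothness_px <= 0) stop("smoothness must be > 0", call. = FALSE)
  nr <- shape[1]; nc <- shape[2]
  ii <- seq_len(nr) - 1; jj <- seq_len(nc) - 1
  with_seed(seed, {
    comp <- function() {
      m <- matrix(0, nr, nc)
      for (k in 1:4) {
        wl <- stats::runif(1, smoothness_px, 4 * smoothness_px)
        th <- stats::runif(1, 0, pi)
        ph <- stats::runif(1, 0, 2 * pi)
        fy <- sin(th) / wl; fx <- cos(th) / wl
        m <- m + outer(ii, jj, function(y, x) sin(2 * pi * (fy * y + fx * x) + ph))
      }
      m
    }
    dy <- comp(); dx <- comp()
    mag <- sqrt(dy^2 + dx^2)
    mmax <- max(mag)
    if (mmax > 0) {
      dy <- dy / mmax * magnitude_px
      dx <- dx / mmax * magnitude_px
    }
    displacement_field(dy, dx)
  })
}

#' Apply a beam-damage deformation to an image
#'
#' Warps the image by a smooth random displacement field with maximum
#' displacement `magnitude_px`; deterministic under `seed`. Emulates the
#' structural deformation of soft specimens (e.g. hydrogels) between the two
#' acquisitions of a training pair, which breaks sub-pixel co-registration.
#'
#' @param image a `sem_image`.
#' @param magnitude_px maximum displacement, pixels (>= 0).
#' @param smoothness_px shortest deformation wavelength, pixels (> 0).
#' @param seed integer seed.
#' @return the warped `sem_image`.
#' @export
apply_damage_warp <- function(image, magnitude_px, smoothness_px = 32, seed = 1L) {
  assert_sem_image(image)
  if (magnitude_px == 0) return(image)
  f <- random_smooth_field(dim(image$pixels), magnitude_px, smoothness_px, seed)
  out <- warp_apply(image, f)
  out$meta$damage <- list(magnitude_px = magnitude_px,
                          smoothness_px = smoothness_px, seed = seed)
  out
}
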