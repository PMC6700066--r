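# Resolution quantification.
#
# Gap resolvability: along a line profile crossing two adjacent particles, a
# gap exists if the valley between the flanking peaks falls below 60% of the
# peak reference intensity; its width is the distance between the two
# sub-sample crossings of 80% of that reference, located by linear
# interpolation. "Peak reference" defaults to the smaller of the two flanking
# peaks (policy "min-peak"), which guarantees both 80% crossings exist; the
# alternative readings are available behind `peak_policy`.
#
# Spectral analysis: magnitude of the centered 2D DFT with physical frequency
# axes (cycles/nm), averaged over annuli of constant spatial frequency.

#' Extract an intensity profile along a line segment
#'
#' Bilinear sampling along the segment from `p1` to `p2` (each `c(x_nm,
#' y_nm)`) at spacing `step_nm`; positions are measured from `p1`.
#'
#' @param image a `sem_image`.
#' @param p1,p2 endpoints in nm, `c(x_nm, y_nm)`; must lie inside the image.
#' @param step_nm sample spacing (default half the pixel pitch).
#' @return a `line_profile`: list with `positions_nm`, `intensities`.
#' @export
extract_profile <- function(image, p1, p2, step_nm = image$pixel_size_nm / 2) {
  assert_sem_image(image)
  if (step_nm <= 0) stop("step_nm must be > 0", call. = FALSE)
  ps <- image$pixel_size_nm
  ext_x <- (ncol(image$pixels) - 1) * ps
  ext_y <- (nrow(image$pixels) - 1) * ps
  for (p in list(p1, p2))
    if (p[1] < 0 || p[1] > ext_x || p[2] < 0 || p[2] > ext_y)
      stop("profile endpoint outside the image", call. = FALSE)
  len <- sqrt(sum((p2 - p1)^2))
  pos <- seq(0, len, by = step_nm)
  if (len - pos[length(pos)] > 1e-9 * max(1, len)) pos <- c(pos, len)
  tt <- if (len > 0) pos / len else pos * 0
  xs <- p1[1] + tt * (p2[1] - p1[1])
  ys <- p1[2] + tt * (p2[2] - p1[2])
  vals <- bilinear_sample(image$pixels, ys / ps, xs / ps)
  structure(list(positions_nm = pos, intensities = as.vector(vals)),
            class = "line_profile")
}

#' Measure gap existence and width on a line profile
#'
#' The valley is the interior global minimum; the flanking peaks are the
#' maxima on either side of it. A gap exists iff the valley intensity is
#' below `exist_frac` (default 0.6) of the peak reference; the width is the
#' distance between the two crossings of `width_frac` (default 0.8) of the
#' reference, found by linear interpolation between adjacent samples. The
#' result is invariant to uniform intensity scaling and profile reversal.
#'
#' @param profile a `line_profile` (>= 3 samples).
#' @param exist_frac existence threshold as a fraction of the peak reference.
#' @param width_frac width threshold as a fraction of the peak reference.
#' @param peak_policy `"min-peak"` (default; reference = smaller flanking
#'   peak, both crossings guaranteed), `"max-peak"`, or `"per-side"` (each
#'   crossing uses its own side's peak; existence uses the smaller peak).
#' @return a `gap_measurement`: list with `exists`, `width_nm` (NA when not
#'   measurable), `min_over_peak`, `valley_pos_nm`, `reason`.
#' @export
measure_gap <- function(profile, exist_frac = 0.6, width_frac = 0.8,
                        peak_policy = c("min-peak", "max-peak", "per-side")) {
  peak_policy <- match.arg(peak_policy)
  v <- profile$intensities
  x <- profile$positions_nm
  n <- length(v)
  no_gap <- function(reason) {
    structure(list(exists = FALSE, width_nm = NA_real_,
                   min_over_peak = NA_real_, valley_pos_nm = NA_real_,
                   reason = reason), class = "gap_measurement")
  }
  if (n < 3L) return(no_gap("profile too short"))
  vi <- which.min(v[2:(n - 1L)]) + 1L
  valley <- v[vi]
  peak_l <- max(v[1:(vi - 1L)])
  peak_r <- max(v[(vi + 1L):n])
  if (peak_l <= valley || peak_r <= valley)
    return(no_gap("fewer than two flanking peaks"))
  ref <- switch(peak_policy,
                "min-peak" = min(peak_l, peak_r),
                "max-peak" = max(peak_l, peak_r),
                "per-side" = min(peak_l, peak_r))
  mop <- valley / ref
  exists <- mop < exist_frac
  if (!exists)
    return(structure(list(exists = FALSE, width_nm = NA_real_,
                          min_over_peak = mop, valley_pos_nm = x[vi],
                          reason = "valley above existence threshold"),
                     class = "gap_measurement"))
  thr_l <- width_frac * if (peak_policy == "per-side") peak_l else ref
  thr_r <- width_frac * if (peak_policy == "per-side") peak_r else ref
  cross_left <- function(thr) {
    for (i in (vi - 1L):1) {
      if (v[i] >= thr) {
        # crossing between sample i (>= thr) and i+1 (< thr)
        f <- (v[i] - thr) / (v[i] - v[i + 1L])
        return(x[i] + f * (x[i + 1L] - x[i]))
      }
    }
    NA_real_
  }
  cross_right <- function(thr) {
    for (i in (vi + 1L):n) {
      if (v[i] >= thr) {
        f <- (v[i] - thr) / (v[i] - v[i - 1L])
        return(x[i] - f * (x[i] - x[i - 1L]))
      }
    }
    NA_real_
  }
  xl <- cross_left(thr_l)
  xr <- cross_right(thr_r)
  if (is.na(xl) || is.na(xr))
    return(structure(list(exists = TRUE, width_nm = NA_real_,
                          min_over_peak = mop, valley_pos_nm = x[vi],
                          reason = "width threshold not crossed on one side"),
                     class = "gap_measurement"))
  structure(list(exists = TRUE, width_nm = xr - xl, min_over_peak = mop,
                 valley_pos_nm = x[vi], reason = NA_character_),
            class = "gap_measurement")
}

#' Moment-based Gaussian fit of a width sample
#'
#' Maximum-likelihood-style normal fit using the sample mean and sample
#' standard deviation; bin count affects only the returned plotting
#' histogram, never the fit.
#'
#' @param widths numeric vector with >= 3 distinct values.
#' @param n_bins histogram bin count for plotting.
#' @return list with `mu`, `sigma`, `histogram` (breaks, counts).
#' @export
gaussian_fit_histogram <- function(widths, n_bins = 15L) {
  widths <- widths[is.finite(widths)]
  if (length(unique(widths)) < 3L || stats::sd(widths) == 0)
    stop("degenerate input: need >= 3 distinct finite values", call. = FALSE)
  h <- graphics::hist(widths, breaks = n_bins, plot = FALSE)
  list(mu = mean(widths), sigma = stats::sd(widths),
       histogram = list(breaks = h$breaks, counts = h$counts))
}

#' Gap-resolvability study over an image triple
#'
#' Measures every gap segment in the input, output and ground-truth images,
#' then summarizes per class: undetected-gap fraction, mean absolute width
#' difference vs ground truth (over gaps resolved in both that class and the
#' ground truth), and a Gaussian fit of the resolved-width histogram.
#'
#' @param images named list with `input`, `output`, `ground_truth`
#'   (`sem_image`s on a common, co-registered pixel grid).
#' @param gap_segments data.frame with columns `x1_nm, y1_nm, x2_nm, y2_nm`
#'   (e.g. from [pair_gap_segments()]), selected on the ground-truth image.
#' @param exist_frac,width_frac,peak_policy see [measure_gap()].
#' @param n_bins histogram bins for the Gaussian fit summaries.
#' @return a `gap_study_result`: list with `n_gaps`, `per_class` (data.frame:
#'   class, n_resolved, n_unresolved, undetected_fraction, mean_abs_diff_nm,
#'   mu, sigma) and `measurements` (long data.frame, one row per segment and
#'   class).
#' @export
gap_study <- function(images, gap_segments, exist_frac = 0.6,
                      width_frac = 0.8, peak_policy = "min-peak",
                      n_bins = 15L) {
  stopifnot(all(c("input", "output", "ground_truth") %in% names(images)))
  if (NROW(gap_segments) == 0L)
    stop("gap_segments must be non-empty", call. = FALSE)
  classes <- c("input", "output", "ground_truth")
  meas <- list()
  for (cl in classes) {
    img <- images[[cl]]
    assert_sem_image(img)
    for (g in seq_len(NROW(gap_segments))) {
      seg <- gap_segments[g, ]
      pr <- extract_profile(img, c(seg$x1_nm, seg$y1_nm),
                            c(seg$x2_nm, seg$y2_nm))
      m <- measure_gap(pr, exist_frac, width_frac, peak_policy)
      meas[[length(meas) + 1L]] <-
        data.frame(segment = g, class = cl, exists = m$exists,
                   width_nm = if (is.null(m$width_nm)) NA_real_ else m$width_nm,
                   min_over_peak = m$min_over_peak)
    }
  }
  meas <- do.call(rbind, meas)
  gt <- meas[meas$class == "ground_truth", ]
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    mc <- meas[meas$class == cl, ]
    resolved <- mc$exists & is.finite(mc$width_nm)
    both <- resolved & gt$exists & is.finite(gt$width_nm)
    mad_nm <- if (any(both))
      mean(abs(mc$width_nm[both] - gt$width_nm[both])) else NA_real_
    fit <- tryCatch(gaussian_fit_histogram(mc$width_nm[resolved], n_bins),
                    error = function(e) list(mu = NA_real_, sigma = NA_real_))
    data.frame(class = cl,
               n_resolved = sum(mc$exists),
               n_unresolved = sum(!mc$exists),
               undetected_fraction = mean(!mc$exists),
               mean_abs_diff_nm = mad_nm,
               mu = fit$mu, sigma = fit$sigma)
  }))
  structure(list(n_gaps = NROW(gap_segments), per_class = per_class,
                 measurements = meas),
            class = "gap_study_result")
}

#' @export
print.gap_study_result <- function(x, ...) {
  cat(sprintf("<gap_study_result> %d gaps\n", x$n_gaps))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((floor(nr / 2) + 1L):nr, 1L:floor(nr / 2)),
    c((floor(nc / 2) + 1L):nc, 1L:floor(nc / 2))]
}

#' Centered 2D power spectrum with physical frequency axes
#'
#' Magnitude of the centered 2D discrete Fourier transform; frequency axes in
#' cycles/nm derived from the pixel pitch.
#'
#' @param image a `sem_image` (at least 8 x 8).
#' @param log_scale return log10(1 + magnitude) for display.
#' @return a `power_spectrum`: list with `magnitude` (centered), `fy`, `fx`
#'   (cycles/nm), `pixel_size_nm`.
#' @export
power_spectrum <- function(image, log_scale = FALSE) {
  assert_sem_image(image)
  m <- image$pixels
  if (nrow(m) < 8L || ncol(m) < 8L) stop("image must be >= 8x8", call. = FALSE)
  mag <- Mod(stats::fft(m))
  mag <- fftshift2(mag)
  if (log_scale) mag <- log10(1 + mag)
  nr <- nrow(m); nc <- ncol(m)
  fy <- (seq_len(nr) - 1L - floor(nr / 2)) / (nr * image$pixel_size_nm)
  fx <- (seq_len(nc) - 1L - floor(nc / 2)) / (nc * image$pixel_size_nm)
  structure(list(magnitude = mag, fy = fy, fx = fx,
                 pixel_size_nm = image$pixel_size_nm),
            class = "power_spectrum")
}

#' Radially-averaged spectrum
#'
#' Mean spectral magnitude over annular bins of physical spatial frequency,
#' with uniform bin edges from 0 to the image Nyquist (1 / (2 pixel pitch)).
#'
#' @param spectrum a `power_spectrum` (centered).
#' @param n_bins number of annular bins (>= 2).
#' @return a `radial_spectrum`: data.frame with `frequency` (bin centers,
#'   cycles/nm) and `magnitude` (mean per annulus).
#' @export
radial_average <- function(spectrum, n_bins = 64L) {
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  r <- sqrt(outer(spectrum$fy^2, spectrum$fx^2, "+"))
  nyq <- 1 / (2 * spectrum$pixel_size_nm)
  edges <- seq(0, nyq, length.out = n_bins + 1L)
  bin <- findInterval(r, edges, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= n_bins
  mags <- tapply(spectrum$magnitude[keep], bin[keep], mean)
  out <- data.frame(frequency = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
                    magnitude = NA_real_)
  out$magnitude[as.integer(names(mags))] <- as.vector(mags)
  structure(out, class = c("radial_spectrum", "data.frame"))
}

#' Radially-averaged spectra per image class
#'
#' Averages the centered 2D magnitude spectra across the images of each class
#' (input / output / ground truth) before radial averaging, mirroring the
#' spatial-frequency comparison of averaged fields of view.
#'
#' @param images named list of classes, each a list of `sem_image`s of
#'   identical shape and pitch (a bare `sem_image` is accepted too).
#' @param n_bins annular bin count.
#' @return named list of `radial_spectrum` per class.
#' @export
spectrum_study <- function(images, n_bins = 64L) {
  lapply(images, function(cls) {
    if (is_sem_image(cls)) cls <- list(cls)
    if (length(cls) < 1L) stop("each class needs >= 1 image", call. = FALSE)
    specs <- lapply(cls, power_spectrum)
    shp <- dim(specs[[1]]$magnitude)
    for (s in specs)
      if (!all(dim(s$magnitude) == shp))
        stop("mismatched image shapes within a class", call. = FALSE)
    avg <- Reduce(`+`, lapply(specs, `[[`, "magnitude")) / length(specs)
    s <- specs[[1]]
    s$magnitude <- avg
    radial_average(s, n_bins)
  })
}
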