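#' SEM image container
#'
#' A minimal S3 container for a single-channel micrograph: a numeric matrix of
#' finite, non-negative intensities plus the physical pixel pitch in
#' nanometres and a free-form provenance record. All pipeline stages consume
#' and produce `SEMImage` objects so that physical units travel with the
#' pixels.
#'
#' Coordinate convention (used everywhere in this package): row-major,
#' 0-based indices, origin at the top-left pixel, pixel centers at integer
#' coordinates; physical position in nm = index * pixel_size_nm.
#'
#' @param pixels numeric matrix (M rows x N columns) of finite, non-negative
#'   intensities.
#' @param pixel_size_nm physical size of one pixel, in nm; must be > 0.
#' @param meta named list of provenance information (free form).
#' @return An object of class `sem_image`.
#' @export
sem_image <- function(pixels, pixel_size_nm, meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image intensities must be finite", call. = FALSE)
  if (any(pixels < 0))
    stop("image intensities must be non-negative", call. = FALSE)
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number", call. = FALSE)
  structure(list(pixels = pixels,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 meta = meta),
            class = "sem_image")
}

#' @export
print.sem_image <- function(x, ...) {
  cat(sprintf("<sem_image> %d x %d px @ %.4g nm/px  [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              min(x$pixels), max(x$pixels)))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.sem_image <- function(x) dim(x$pixels)

is_sem_image <- function(x) inherits(x, "sem_image")

assert_sem_image <- function(x, arg = deparse(substitute(x))) {
  if (!is_sem_image(x)) stop(sprintf("`%s` must be a sem_image", arg), call. = FALSE)
  invisible(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations are
#' bit-reproducible without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Zero-normalized cross-correlation of two images or matrices
#'
#' Pearson correlation of the flattened pixel vectors; the similarity metric
#' used throughout registration and patch filtering. Returns 0 when either
#' input has zero variance (a flat patch carries no alignment information).
#'
#' @param a,b numeric matrices or `sem_image` objects of equal size.
#' @return correlation in \[-1, 1\].
#' @export
zncc <- function(a, b) {
  if (is_sem_image(a)) a <- a$pixels
  if (is_sem_image(b)) b <- b$pixels
  if (!all(dim(a) == dim(b))) stop("images must have the same shape", call. = FALSE)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(as.vector(a), as.vector(b))
}

#' Electron-exposure ratio between two pixel pitches
#'
#' At fixed field of view and equal dwell time per pixel, the number of
#' electrons delivered to the specimen scales with the number of scanned
#' pixels, i.e. with the inverse square of the pixel pitch. Imaging at
#' 7.1 nm/px instead of 14.2 nm/px therefore costs a four-fold electron dose;
#' equivalently, super-resolving the coarse scan gives a four-fold dose (and
#' acquisition-time) reduction.
#'
#' @param fine_pitch_nm pixel pitch of the high-resolution scan (nm).
#' @param coarse_pitch_nm pixel pitch of the low-resolution scan (nm).
#' @param dwell_ratio dwell time ratio fine/coarse (default 1, equal dwell).
#' @return the dose ratio fine/coarse (> 1 when the fine scan costs more).
#' @examples
#' electron_dose_ratio(7.1, 14.2)  # 4
#' @export
electron_dose_ratio <- function(fine_pitch_nm, coarse_pitch_nm, dwell_ratio = 1) {
  if (fine_pitch_nm <= 0 || coarse_pitch_nm <= 0 || dwell_ratio <= 0)
    stop("pitches and dwell ratio must be positive", call. = FALSE)
  (coarse_pitch_nm / fine_pitch_nm)^2 * dwell_ratio
}
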