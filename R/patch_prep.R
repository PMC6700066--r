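# Training-patch preparation: per-image mean/std normalization (applied to
# the whole source image, not per patch, so local contrast differences
# survive), non-overlapping or strided tiling into P x P patch pairs,
# correlation-based rejection of damage-corrupted pairs, and lossless
# dihedral (rotate/flip) augmentation.

#' Normalize an image to zero mean and unit standard deviation
#'
#' Emulates the normalization applied to every acquisition to cancel the
#' microscope's automatic brightness/contrast fluctuations. The statistics are
#' returned so the transform can be inverted after inference.
#'
#' @param image `sem_image` or numeric matrix with at least 2 distinct values.
#' @return list with `image` (normalized matrix, or `sem_image` whose pixels
#'   are the normalized values offset is NOT clamped) and `stats`
#'   (`mean`, `sd`).
#' @export
normalize_image <- function(image) {
  m <- if (is_sem_image(image)) image$pixels else image
  mu <- mean(m); sdv <- stats::sd(m)
  if (!is.finite(sdv) || sdv == 0)
    stop("degenerate input: constant image cannot be normalized", call. = FALSE)
  list(image = (m - mu) / sdv, stats = list(mean = mu, sd = sdv))
}

#' Invert [normalize_image()]
#' @param m normalized matrix.
#' @param stats the `stats` element returned by [normalize_image()].
#' @return matrix on the original intensity scale.
#' @export
denormalize_image <- function(m, stats) m * stats$sd + stats$mean

#' Tile a registered pair into patch pairs
#'
#' Patches are placed at offsets \{0, stride, 2 stride, ...\} and must lie
#' wholly inside the image, giving
#' (floor((M - size)/stride) + 1) * (floor((N - size)/stride) + 1) patches.
#' Offsets are recorded so every patch maps back to its source block exactly.
#'
#' @param x,z numeric matrices of identical shape (normalized input and
#'   ground truth).
#' @param size patch side (pixels).
#' @param stride step between patch origins (>= 1); `stride = size` gives
#'   non-overlapping tiles.
#' @return a `patch_dataset`: list of `patch_pair`s (`x`, `z`, `row0`, `col0`,
#'   both 1-based origins) plus provenance.
#' @export
tile_patches <- function(x, z, size, stride = size) {
  if (!all(dim(x) == dim(z))) stop("x and z must have the same shape", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  if (size > nrow(x) || size > ncol(x)) {
    warning("patch size exceeds image; returning empty dataset")
    return(patch_dataset(list()))
  }
  r0 <- seq(1L, nrow(x) - size + 1L, by = stride)
  c0 <- seq(1L, ncol(x) - size + 1L, by = stride)
  pairs <- vector("list", length(r0) * length(c0))
  n <- 0L
  for (i in r0) for (j in c0) {
    n <- n + 1L
    pairs[[n]] <- list(x = x[i:(i + size - 1L), j:(j + size - 1L)],
                       z = z[i:(i + size - 1L), j:(j + size - 1L)],
                       row0 = i, col0 = j)
  }
  patch_dataset(pairs, size = size, stride = stride)
}

#' Patch dataset constructor
#' @param pairs list of patch pairs (`x`, `z`, `row0`, `col0`).
#' @param ... provenance fields stored alongside.
#' @return a `patch_dataset`.
#' @export
patch_dataset <- function(pairs, ...) {
  structure(list(pairs = pairs, provenance = list(...)),
            class = "patch_dataset")
}

#' @export
length.patch_dataset <- function(x) length(x$pairs)

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d patch pairs\n", length(x$pairs)))
  invisible(x)
}

#' Concatenate patch datasets
#' @param ... `patch_dataset` objects.
#' @return combined `patch_dataset`.
#' @export
concat_patches <- function(...) {
  ds <- list(...)
  patch_dataset(do.call(c, lapply(ds, function(d) d$pairs)))
}

#' Remove damage-corrupted patch pairs by correlation
#'
#' A pair is kept iff the zero-normalized correlation of its x and z patches
#' is at least `threshold`. Beam damage between the two acquisitions destroys
#' local similarity, so corrupted pairs fall below an experimentally chosen
#' threshold and are dropped from training. A flat patch has correlation 0
#' by convention and is removed at any positive threshold.
#'
#' @param dataset a `patch_dataset`.
#' @param threshold correlation threshold in \[-1, 1\] (default 0.5).
#' @return list with `kept` and `removed` (`patch_dataset`s) and
#'   `correlations` (numeric, one per input pair).
#' @export
filter_by_correlation <- function(dataset, threshold = 0.5) {
  cors <- vapply(dataset$pairs, function(p) zncc(p$x, p$z), numeric(1))
  keep <- cors >= threshold
  list(kept = patch_dataset(dataset$pairs[keep],
                            filter_threshold = threshold),
       removed = patch_dataset(dataset$pairs[!keep],
                               filter_threshold = threshold),
       correlations = cors)
}

#' Apply one of the 8 dihedral transforms to a matrix
#'
#' Index 0-3: counter-clockwise rotations by 0/90/180/270 degrees;
#' index 4-7: the same rotations after a horizontal flip. These are the
#' lossless symmetries of the square, so x/z alignment is preserved exactly.
#'
#' @param m square numeric matrix.
#' @param index transform index in 0..7.
#' @return transformed matrix.
#' @export
dihedral_apply <- function(m, index) {
  if (nrow(m) != ncol(m) && index %% 2 == 1)
    stop("90-degree rotation requires a square patch", call. = FALSE)
  index <- as.integer(index) %% 8L
  if (index >= 4L) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  r <- index %% 4L
  rot90 <- function(x) t(x)[rev(seq_len(ncol(x))), , drop = FALSE]
  for (i in seq_len(r)) m <- rot90(m)
  m
}

#' Randomly rotate/flip a patch pair
#'
#' Draws one of the 8 dihedral transforms under `seed` and applies it
#' identically to x and z.
#'
#' @param pair a patch pair (`x`, `z`).
#' @param seed integer seed.
#' @return the augmented pair; the chosen transform index is attached as
#'   `dihedral`.
#' @export
augment_patch <- function(pair, seed = 1L) {
  idx <- with_seed(seed, sample.int(8L, 1L) - 1L)
  pair$x <- dihedral_apply(pair$x, idx)
  pair$z <- dihedral_apply(pair$z, idx)
  pair$dihedral <- idx
  pair
}

#' Build a training dataset from registered image pairs
#'
#' Normalizes each source pair (per image, not per patch), tiles, and filters
#' by correlation.
#'
#' @param pairs list of lists with elements `x` and `z` (`sem_image`s or
#'   matrices on a common grid).
#' @param size,stride tiling controls.
#' @param threshold correlation filter threshold.
#' @return list with `dataset` (kept pairs), `removed`, `n_total`.
#' @export
build_patch_dataset <- function(pairs, size = 128L, stride = size,
                                threshold = 0.5) {
  all_pairs <- list()
  for (p in pairs) {
    xm <- normalize_image(p$x)$image
    zm <- normalize_image(p$z)$image
    ds <- tile_patches(xm, zm, size = size, stride = stride)
    all_pairs <- c(all_pairs, ds$pairs)
  }
  res <- filter_by_correlation(patch_dataset(all_pairs), threshold)
  list(dataset = res$kept, removed = res$removed, n_total = length(all_pairs))
}
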