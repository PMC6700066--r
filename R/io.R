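# Image and geometry I/O.
#
# No TIFF reader/writer is available in the supported dependency set, so
# images are stored as grayscale PNG (8-bit, the depth the `png` codec
# supports — also the native depth of most SEM exports) or plain-text PGM
# (P2, 16-bit), each with a JSON sidecar (<file>.json) carrying
# pixel_size_nm, the intensity scaling used for quantization, and provenance.

#' Write an SEM image to disk
#'
#' Writes grayscale PNG (`.png`, 8-bit) or plain-text PGM (`.pgm`, 16-bit),
#' chosen by file extension, plus a JSON sidecar `<path>.json` with the pixel
#' size and the linear intensity scaling so the float image can be recovered.
#'
#' @param image a `sem_image`.
#' @param path output path ending in `.png` or `.pgm`.
#' @param range intensity range mapped to the quantization range; default the
#'   image's own \[min, max\] (recorded in the sidecar).
#' @return `path`, invisibly.
#' @export
write_sem_image <- function(image, path, range = NULL) {
  assert_sem_image(image)
  px <- image$pixels
  if (is.null(range)) range <- range(px)
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) hi <- lo + 1
  ext <- tolower(tools::file_ext(path))
  depth <- if (ext == "png") 255L else 65535L
  q <- round((pmin(pmax(px, lo), hi) - lo) / (hi - lo) * depth)
  if (ext == "png") {
    png::writePNG(q / depth, target = path)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(q), nrow(q)),
                 as.character(depth)), con)
    # one image row per line; readers tolerate arbitrary whitespace
    writeLines(apply(q, 1L, paste, collapse = " "), con)
  } else stop("unsupported image extension: ", ext, call. = FALSE)
  sidecar <- list(pixel_size_nm = image$pixel_size_nm,
                  intensity_offset = lo, intensity_scale = hi - lo,
                  depth = depth, meta = image$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an SEM image written by [write_sem_image()]
#'
#' @param path path to a `.png` or `.pgm` file with its JSON sidecar.
#' @return a `sem_image` with intensities restored to their original scale.
#' @export
read_sem_image <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing sidecar ", side_path, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    q <- png::readPNG(path)
    if (length(dim(q)) == 3L) q <- q[, , 1L]
  } else if (ext == "pgm") {
    txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
    if (txt[1] != "P2") stop("only plain (P2) PGM is supported", call. = FALSE)
    nc <- as.integer(txt[2]); nr <- as.integer(txt[3])
    maxv <- as.numeric(txt[4])
    q <- matrix(as.numeric(txt[-(1:4)]), nrow = nr, ncol = nc, byrow = TRUE)
    q <- q / maxv
  } else stop("unsupported image extension: ", ext, call. = FALSE)
  px <- q * side$intensity_scale + side$intensity_offset
  meta <- side$meta
  if (is.null(meta)) meta <- list()
  sem_image(px, side$pixel_size_nm, meta = as.list(meta))
}

#' Write particle geometry as CSV
#'
#' Columns `x_nm, y_nm, radius_nm`; pair membership (when present) is kept in
#' a `pair_id` column so planted gaps can be re-identified.
#'
#' @param field a `particle_field`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_particle_field <- function(field, path) {
  utils::write.csv(field$particles, path, row.names = FALSE)
  invisible(path)
}

#' Read particle geometry CSV written by [write_particle_field()]
#' @param path CSV path.
#' @param fov_nm field of view (width, height) in nm.
#' @param seed seed recorded in the restored object (default NA).
#' @return a `particle_field`.
#' @export
read_particle_field <- function(path, fov_nm, seed = NA_integer_) {
  particles <- utils::read.csv(path)
  structure(list(particles = particles, fov_nm = fov_nm, seed = seed),
            class = "particle_field")
}
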