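# Core image preparation: 6x6 tiling, central segments, inversion --------

#' Construct a core image
#'
#' A TMA core raster held as an `height x width x 3` integer array of
#' 8-bit RGB values (0-255).
#'
#' @param core_id Core identifier.
#' @param pixels Numeric array, `h x w x 3`, values in 0..255.
#' @return Object of class `core_image`.
#' @export
core_image <- function(core_id, pixels) {
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L) {
    stop("pixels must be a non-empty h x w x 3 RGB array", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0 | pixels > 255)) {
    stop("pixel values must be in 0..255", call. = FALSE)
  }
  structure(list(core_id = as.character(core_id),
                 pixels = pixels), class = "core_image")
}

#' Split a core image into a 6x6 grid of tiles
#'
#' The raster is padded on its right and bottom edges with white
#' (stain-background-like) pixels up to the next multiple of six, then
#' cut into 36 equal tiles indexed row-major 0-35: tile `k` covers grid
#' row `k %/% 6` and column `k %% 6`.
#'
#' @param image A `core_image`.
#' @return List of 36 pixel arrays, element `k + 1` being segment `k`.
#' @export
tile_core <- function(image) {
  stopifnot(inherits(image, "core_image"))
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  H <- 6L * ceiling(h / 6); W <- 6L * ceiling(w / 6)
  if (H != h || W != w) {
    padded <- array(255, dim = c(H, W, 3L))
    padded[seq_len(h), seq_len(w), ] <- px
    px <- padded
  }
  th <- H %/% 6L; tw <- W %/% 6L
  tiles <- vector("list", 36L)
  for (k in 0:35) {
    r <- k %/% 6L; cc <- k %% 6L
    tiles[[k + 1L]] <- px[r * th + seq_len(th), cc * tw + seq_len(tw), ,
                          drop = FALSE]
  }
  names(tiles) <- paste0("s", 0:35)
  tiles
}

#' Indices of the central 16 segments
#'
#' Outer segments of a TMA core often contain only a handful of cells;
#' restricting scoring to the inner 4x4 block (grid rows and columns
#' 1-4 of the 6x6 grid, zero-based) discards them. Returns the 16
#' row-major segment indices of that block.
#'
#' @return Sorted integer vector of length 16.
#' @export
central_segment_indices <- function() {
  as.integer(sort(outer(1:4 * 6L, 1:4, `+`)))
}

#' Invert tile colours
#'
#' Per-channel 8-bit complement (`v -> 255 - v`), the display transform
#' applied before showing tiles to players. An involution; no stain
#' deconvolution is attempted.
#'
#' @param tile Pixel array with values in 0..255.
#' @return Array of the same shape.
#' @export
invert_colors <- function(tile) {
  if (anyNA(tile) || any(tile < 0 | tile > 255)) {
    stop("pixel values must be in 0..255", call. = FALSE)
  }
  255 - tile
}

# Plain-text PPM I/O ------------------------------------------------------
# ASCII PPM (P3) keeps fixtures text-only; no binary image libraries are
# assumed to be present.

#' Read and write ASCII PPM (P3) rasters
#'
#' Minimal plain-text raster interchange used for tiles and fixtures.
#'
#' @param path File path.
#' @param pixels `h x w x 3` array of 0..255 values.
#' @return `read_ppm` returns the pixel array; `write_ppm` returns
#'   `path` invisibly.
#' @name ppm
NULL

#' @rdname ppm
#' @export
read_ppm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P3") stop("not an ASCII PPM (P3) file", call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxv <- as.integer(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != 3L * w * h) stop("truncated PPM data", call. = FALSE)
  if (maxv != 255L) vals <- vals * 255 / maxv
  # PPM is row-major, channel-interleaved
  px <- array(0, dim = c(h, w, 3L))
  m <- matrix(vals, nrow = 3L)
  for (ch in 1:3) px[, , ch] <- matrix(m[ch, ], nrow = h, byrow = TRUE)
  px
}

#' @rdname ppm
#' @export
write_ppm <- function(pixels, path) {
  d <- dim(pixels)
  stopifnot(length(d) == 3L, d[3] == 3L)
  h <- d[1]; w <- d[2]
  vals <- integer(3L * w * h)
  for (ch in 1:3) {
    vals[seq(ch, by = 3L, length.out = w * h)] <-
      as.integer(round(t(pixels[, , ch])))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' Write all 36 tiles of a core as PPM files
#'
#' Files are named `<core_id>_s<index>.ppm` in `dir`.
#'
#' @param image A `core_image`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_tiles <- function(image, dir) {
  stopifnot(inherits(image, "core_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tiles <- tile_core(image)
  paths <- file.path(dir, sprintf("%s_s%d.ppm", image$core_id, 0:35))
  for (k in seq_along(tiles)) write_ppm(tiles[[k]], paths[k])
  invisible(paths)
}
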