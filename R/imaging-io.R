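#' Read an RGB image
#'
#' Reads a PNG, JPEG or TIFF file into the package's image representation:
#' an integer array of dimension \code{c(height, width, 3)} with channel
#' values in 0--255. Grayscale images are replicated across the three
#' channels; an alpha channel is dropped; higher bit depths are rescaled
#' to 0--255.
#'
#' @param path path to a PNG, JPEG or TIFF file.
#' @return integer array \code{height x width x 3}, values in 0--255.
#' @examples
#' f <- tempfile(fileext = ".png")
#' writeRgbImage(solidImage(4, 6, c(255, 210, 60)), f)
#' img <- readRgbImage(f)
#' dim(img)
#' @export
readRgbImage <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  readers <- list(
    png  = function(p) png::readPNG(p),
    jpg  = function(p) jpeg::readJPEG(p),
    jpeg = function(p) jpeg::readJPEG(p),
    tif  = function(p) tiff::readTIFF(p),
    tiff = function(p) tiff::readTIFF(p)
  )
  order <- unique(c(ext, "png", "jpeg", "tiff"))
  order <- order[order %in% names(readers)]
  raw <- NULL
  for (fmt in order) {
    raw <- tryCatch(readers[[fmt]](path), error = function(e) NULL,
                    warning = function(w) NULL)
    if (!is.null(raw)) break
  }
  if (is.null(raw))
    stop("cannot decode image file: ", path)
  if (is.matrix(raw)) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (length(dim(raw)) != 3L)
    stop("cannot decode image file: ", path)
  if (dim(raw)[3] >= 4L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 2L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(raw)[3] == 1L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  img <- array(as.integer(floor(raw * 255 + 0.5)), dim = dim(raw))
  storage.mode(img) <- "integer"
  img
}

#' Write an RGB image as 8-bit PNG
#'
#' @param img integer array \code{height x width x 3}, values 0--255.
#' @param path output path (PNG).
#' @return invisibly, \code{path}.
#' @export
writeRgbImage <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  ok <- tryCatch({
    png::writePNG(img / 255, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path))
    stop("cannot write image to: ", path)
  invisible(path)
}

#' Build a solid-color image
#'
#' Convenience constructor for a uniform image, mainly for examples and
#' tests.
#'
#' @param height,width dimensions in pixels.
#' @param rgb numeric(3), channel values in 0--255.
#' @return integer array \code{height x width x 3}.
#' @export
solidImage <- function(height, width, rgb) {
  stopifnot(length(rgb) == 3L, all(rgb >= 0), all(rgb <= 255))
  img <- array(0L, dim = c(height, width, 3L))
  for (k in 1:3) img[, , k] <- as.integer(round(rgb[k]))
  img
}

#' Convert an RGB image to 8-bit gray
#'
#' Rec.601 luminance, \code{gray = 0.299 R + 0.587 G + 0.114 B}, rounded
#' half up and clamped to 0--255.
#'
#' @param img integer array \code{height x width x 3}, values 0--255.
#' @return integer matrix \code{height x width} of gray values.
#' @examples
#' toGray(solidImage(1, 1, c(100, 200, 50)))[1, 1]  # 153
#' @export
toGray <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  d <- dim(img)
  g <- 0.299 * img[, , 1, drop = TRUE] + 0.587 * img[, , 2, drop = TRUE] +
       0.114 * img[, , 3, drop = TRUE]
  g <- floor(g + 0.5)
  g[g < 0] <- 0
  g[g > 255] <- 255
  matrix(as.integer(g), nrow = d[1], ncol = d[2])
}

#' Write a result overlay
#'
#' Writes a PNG in which grain pixels are tinted green and accepted germ
#' pixels tinted red (50/50 blend with the pure color), over the original
#' image.
#'
#' @param img integer array \code{height x width x 3}.
#' @param grainMask logical matrix, grain foreground.
#' @param germMask logical matrix, accepted germ pixels.
#' @param path output PNG path.
#' @return invisibly, \code{path}.
#' @export
writeOverlay <- function(img, grainMask, germMask, path) {
  d <- dim(img)
  stopifnot(identical(dim(grainMask), d[1:2]),
            identical(dim(germMask), d[1:2]))
  out <- img
  tint <- function(mask, color) {
    for (k in 1:3) {
      ch <- out[, , k]
      ch[mask] <- as.integer(floor(0.5 * ch[mask] + 0.5 * color[k] + 0.5))
      out[, , k] <<- ch
    }
  }
  tint(grainMask & !germMask, c(0, 255, 0))
  tint(germMask, c(255, 0, 0))
  writeRgbImage(out, path)
}
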