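#' Read a slide image from PNG or TIFF
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return A numeric `height x width x 3` array on the 0--255 scale.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), c(dim(img), 3))
  }
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write a slide image to PNG or TIFF
#'
#' @param image A `height x width x 3` array on the 0--255 scale.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, `path`.
#' @export
write_slide_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3)
  x <- clamp(image, 0, 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

# run code with a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
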