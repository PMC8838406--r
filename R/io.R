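## Image I/O. Fundus datasets ship as PNG/TIFF (and STARE as PPM); everything
## is represented internally as a plain numeric matrix (grayscale, [0,1]) or
## an h x w x 3 array (color, [0,1]), indexed [row, column].

#' Read an image file
#'
#' Reads PNG, TIFF or PNM (PGM/PPM, ASCII or binary) into a numeric matrix
#' (grayscale) or an `h x w x 3` array (color) with values in `[0, 1]`.
#' An alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.pgm` or `.ppm` file.
#' @return Numeric matrix or 3-channel array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    pgm  = ,
    ppm  = ,
    pnm  = read_pnm(path),
    stop("unsupported image format: .", ext,
         " (supported: png, tif/tiff, pgm/ppm)", call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE]
    else img <- img[, , 1L]
  }
  img
}

#' Write an image file
#'
#' Writes a grayscale matrix or 3-channel array (values in `[0, 1]`) as PNG
#' or TIFF, chosen by file extension. Binary masks are written as 0/1 PNG.
#'
#' @param img Numeric matrix or `h x w x 3` array in `[0, 1]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path),
    stop("unsupported output format: .", ext, call. = FALSE)
  )
  invisible(path)
}

# Minimal PNM reader (P2/P5 grayscale, P3/P6 color); no installed R package
# reads this format. Handles '#' comments and maxval scaling; 16-bit big-endian
# for maxval > 255 per the format definition.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- local({
    buf <- character(0)
    function() {
      while (length(buf) == 0L) {
        line <- readLines(con, n = 1L, warn = FALSE)
        if (length(line) == 0L) stop("truncated PNM header", call. = FALSE)
        line <- sub("#.*$", "", line)
        buf <<- strsplit(trimws(line), "[[:space:]]+")[[1]]
        buf <<- buf[nzchar(buf)]
      }
      t <- buf[1L]; buf <<- buf[-1L]; t
    }
  })
  magic <- tok()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic: ", magic, call. = FALSE)
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    scan(con, what = integer(), n = n, quiet = TRUE, comment.char = "#")
  } else {
    if (maxval > 255L) as.integer(readBin(con, "integer", n = n, size = 2L,
                                          signed = FALSE, endian = "big"))
    else as.integer(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  }
  if (length(vals) != n) stop("truncated PNM payload", call. = FALSE)
  x <- vals / maxval
  if (nch == 1L) {
    matrix(x, nrow = h, ncol = w, byrow = TRUE)
  } else {
    arr <- array(0, dim = c(h, w, 3L))
    for (c in 1:3) arr[, , c] <- matrix(x[seq(c, n, by = 3L)], h, w, byrow = TRUE)
    arr
  }
}
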