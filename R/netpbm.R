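#' Read a Netpbm image (PGM/PPM, ASCII or binary)
#'
#' Frame storage for this package uses the Netpbm family: `P2`/`P5`
#' greyscale (PGM) and `P3`/`P6` colour (PPM), 8-bit, which are lossless
#' and need no external decoder. Greyscale images are returned as an
#' integer matrix (rows = image rows, top to bottom); colour images as an
#' `height x width x 3` integer array with channels R, G, B.
#'
#' @param path path to a `.pgm`/`.ppm`/`.pnm` file.
#' @return integer matrix (grey) or 3-d integer array (colour), values
#'   in `0..maxval` (maxval must be <= 255).
#' @seealso [write_pnm()]
#' @export
read_pnm <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 2L) stop("not a Netpbm file: ", path)
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("unsupported image format (expected PGM/PPM magic P2/P3/P5/P6): ",
         path)
  }
  # tokenizer over the header: whitespace-separated, '#' starts a comment
  pos <- 3L
  next_token <- function() {
    repeat {
      while (pos <= length(raw) && raw[pos] %in% as.raw(c(32L, 9L, 10L, 13L)))
        pos <<- pos + 1L
      if (pos <= length(raw) && raw[pos] == as.raw(35L)) {  # '#'
        while (pos <= length(raw) && raw[pos] != as.raw(10L)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= length(raw) && !(raw[pos] %in% as.raw(c(32L, 9L, 10L, 13L))))
      pos <<- pos + 1L
    if (start > length(raw)) stop("truncated Netpbm header: ", path)
    rawToChar(raw[start:(pos - 1L)])
  }
  width  <- as.integer(next_token())
  height <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(width) || is.na(height) || width < 1L || height < 1L)
    stop("invalid Netpbm dimensions in ", path)
  if (is.na(maxval) || maxval < 1L || maxval > 255L)
    stop("only 8-bit Netpbm images are supported (maxval <= 255): ", path)
  nchan <- if (magic %in% c("P3", "P6")) 3L else 1L
  nval <- width * height * nchan

  if (magic %in% c("P5", "P6")) {
    pos <- pos + 1L  # single whitespace byte after maxval
    if (length(raw) - pos + 1L < nval) stop("truncated pixel data in ", path)
    vals <- as.integer(raw[pos:(pos + nval - 1L)])
  } else {
    body <- rawToChar(raw[pos:length(raw)])
    vals <- suppressWarnings(as.integer(scan(text = body, what = integer(),
                                             comment.char = "#",
                                             quiet = TRUE, n = nval)))
    if (length(vals) < nval || anyNA(vals))
      stop("truncated or invalid ASCII pixel data in ", path)
  }
  if (nchan == 1L) {
    # file order is row-major; R matrices are column-major
    matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  } else {
    arr <- array(0L, dim = c(height, width, 3L))
    for (ch in 1:3) {
      arr[, , ch] <- matrix(vals[seq(ch, nval, by = 3L)],
                            nrow = height, ncol = width, byrow = TRUE)
    }
    arr
  }
}

#' Write a Netpbm image (binary PGM/PPM)
#'
#' @param img integer/numeric matrix (greyscale) or `height x width x 3`
#'   array (colour); values are rounded and clamped to `0..255`.
#' @param path output path; by convention `.pgm` for grey, `.ppm` for
#'   colour.
#' @param ascii write the ASCII (`P2`/`P3`) variant instead of binary.
#' @return `path`, invisibly.
#' @export
write_pnm <- function(img, path, ascii = FALSE) {
  is_color <- length(dim(img)) == 3L
  if (is_color && dim(img)[3] != 3L) stop("colour image must have 3 channels")
  if (!is_color && length(dim(img)) != 2L) stop("image must be a matrix or h x w x 3 array")
  h <- dim(img)[1]; w <- dim(img)[2]
  v <- pmin(pmax(round(img), 0), 255)
  # interleave channels in row-major order
  if (is_color) {
    flat <- integer(h * w * 3L)
    for (ch in 1:3) flat[seq(ch, length(flat), by = 3L)] <- as.integer(t(v[, , ch]))
  } else {
    flat <- as.integer(t(v))
  }
  magic <- if (is_color) (if (ascii) "P3" else "P6") else (if (ascii) "P2" else "P5")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(magic, paste(w, h), "255"), con, sep = "\n")
  if (ascii) {
    writeLines(paste(flat, collapse = "\n"), con, sep = "\n")
  } else {
    writeBin(as.raw(flat), con)
  }
  invisible(path)
}
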