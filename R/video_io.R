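#' Frame sequences
#'
#' A `frame_sequence` is an ordered list of frames plus acquisition
#' metadata. Frames are either greyscale matrices or `h x w x 3` RGB
#' arrays (8-bit scale, values 0..255); all frames must share one set of
#' dimensions. Frame indices are 1-based and contiguous. `fps` defaults
#' to 24.96 frames/s, the overhead-camera rate the package is calibrated
#' around; `pixel_scale` (mm per pixel) is optional and all kinematics
#' stay in pixel units when it is absent.
#'
#' @param frames list of matrices or `h x w x 3` arrays.
#' @param fps frames per second, `> 0`.
#' @param pixel_scale optional mm per pixel.
#' @return an object of class `frame_sequence`: a list with elements
#'   `frames`, `fps`, `pixel_scale`.
#' @export
frame_sequence <- function(frames, fps = 24.96, pixel_scale = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("frames must be a non-empty list of images")
  dims <- lapply(frames, function(f) dim(f)[1:2])
  d0 <- dims[[1]]
  if (is.null(d0)) stop("frames must be matrices or 3-d arrays")
  same <- vapply(dims, function(d) isTRUE(all(d == d0)), logical(1))
  if (!all(same)) stop("all frames must share identical dimensions")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number")
  if (!is.null(pixel_scale) &&
      (!is.numeric(pixel_scale) || pixel_scale <= 0))
    stop("pixel_scale must be a positive number or NULL")
  structure(list(frames = frames, fps = fps, pixel_scale = pixel_scale),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  kind <- if (length(d) == 3L) "RGB" else "grey"
  cat(sprintf("<frame_sequence> %d %s frames, %d x %d px, %.4g fps%s\n",
              length(x$frames), kind, d[2], d[1], x$fps,
              if (is.null(x$pixel_scale)) ""
              else sprintf(", %.4g mm/px", x$pixel_scale)))
  invisible(x)
}

#' Read a frame directory into a frame sequence
#'
#' Reads all Netpbm images (`.pgm`, `.ppm`, `.pnm`) in a directory, in
#' lexicographic filename order, as the frames of one video. Compressed
#' video containers are not supported in this build (no decoder
#' dependency); export your video to numbered frames first, e.g.
#' `ffmpeg -i in.mp4 frames/f%05d.pgm`.
#'
#' @param path directory containing the frames.
#' @param fps frames per second of the recording. Required: frame
#'   directories carry no rate metadata.
#' @param pixel_scale optional mm per pixel.
#' @return a [frame_sequence()].
#' @export
read_frames <- function(path, fps = NULL, pixel_scale = NULL) {
  if (!dir.exists(path)) {
    if (file.exists(path))
      stop("compressed video containers are not supported; ",
           "decode to a directory of PGM/PPM frames first: ", path)
    stop("cannot read path: ", path)
  }
  files <- list.files(path, pattern = "\\.(pgm|ppm|pnm)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- sort(files, method = "radix")
  if (length(files) == 0L) stop("no PGM/PPM frames found in ", path)
  if (is.null(fps))
    stop("fps must be given when reading a frame directory")
  frames <- lapply(files, read_pnm)
  frame_sequence(frames, fps = fps, pixel_scale = pixel_scale)
}

#' Write a frame sequence to a directory of Netpbm images
#'
#' Lossless round-trip companion of [read_frames()]: grey frames are
#' written as binary PGM, RGB frames as binary PPM, with zero-padded
#' numeric filenames so lexicographic order is temporal order.
#'
#' @param fs a [frame_sequence()].
#' @param path output directory (created if needed).
#' @param prefix filename prefix.
#' @return character vector of file paths, invisibly.
#' @export
write_frames <- function(fs, path, prefix = "frame") {
  stopifnot(inherits(fs, "frame_sequence"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- length(fs$frames)
  ext <- if (length(dim(fs$frames[[1]])) == 3L) "ppm" else "pgm"
  files <- file.path(path, sprintf("%s_%06d.%s", prefix, seq_len(n), ext))
  for (i in seq_len(n)) write_pnm(fs$frames[[i]], files[i])
  invisible(files)
}

#' Colour-deconvolution greyscale conversion
#'
#' Converts an RGB frame to a contrast-enhanced grey image through
#' optical-density unmixing. Each 8-bit intensity is turned into an
#' optical density `OD_c = -log10(max(I_c, 1)/255)` (zeros are clamped to
#' 1 so OD stays finite); the OD vector of every pixel is then unmixed
#' against a 3x3 stain matrix whose rows are the characteristic OD unit
#' vectors of the dyes/illumination, and one unmixed channel is kept.
#' With the identity stain matrix (the default) the unmixed channels are
#' simply the per-channel optical densities, i.e. a log-scale contrast
#' enhancement of dark objects.
#'
#' @param frame `h x w x 3` RGB array, or a grey matrix (treated as a
#'   single channel; the stain matrix is then ignored).
#' @param stain_matrix 3x3 numeric matrix, rows = stain OD vectors. Must
#'   be non-singular.
#' @param channel which unmixed channel to keep, 1..3.
#' @param rescale linearly rescale the result to `[0, 255]`. For a video,
#'   pass a common `range` instead of per-frame rescaling so frames stay
#'   comparable over time (see [gray_frames()]).
#' @param range optional `c(min, max)` of unmixed values used for the
#'   rescale; defaults to the frame's own range.
#' @return numeric matrix of grey values (the `GrayFrame`): non-negative,
#'   finite, in `[0, 255]` when `rescale = TRUE`, raw unmixed optical
#'   densities otherwise.
#' @examples
#' px <- array(c(25, 255, 255), dim = c(1, 1, 3))
#' deconvolve_to_gray(px, rescale = FALSE)  # -log10(25/255) ~ 1.0086
#' @export
deconvolve_to_gray <- function(frame, stain_matrix = diag(3), channel = 1L,
                               rescale = TRUE, range = NULL) {
  d <- dim(frame)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("frame must be an RGB array or a grey matrix")
  if (!is.matrix(stain_matrix) || !all(dim(stain_matrix) == c(3L, 3L)))
    stop("stain_matrix must be 3x3")
  if (any(rowSums(abs(stain_matrix)) == 0)) stop("stain_matrix has a zero row")
  if (!(channel %in% 1:3)) stop("channel must be 1, 2 or 3")

  if (length(d) == 2L) {
    od <- -log10(pmax(frame, 1) / 255)
    out <- od
  } else {
    inv <- tryCatch(solve(stain_matrix),
                    error = function(e) stop("singular stain matrix"))
    n <- d[1] * d[2]
    odm <- matrix(0, n, 3L)
    for (ch in 1:3) odm[, ch] <- -log10(pmax(as.vector(frame[, , ch]), 1) / 255)
    # od = conc %*% M  =>  conc = od %*% M^-1
    conc <- odm %*% inv
    out <- matrix(conc[, channel], d[1], d[2])
  }
  if (rescale) {
    r <- if (is.null(range)) base::range(out) else range
    if (diff(r) <= 0) out[] <- 0 else out <- (out - r[1]) / diff(r) * 255
    out <- pmin(pmax(out, 0), 255)
  }
  out
}

#' Convert a whole video to greyscale with a video-global rescale
#'
#' Applies [deconvolve_to_gray()] to every frame, then rescales all
#' frames with the single global min/max of the unmixed values. A global
#' (not per-frame) rescale preserves temporal comparability, which the
#' median-projection background subtraction relies on.
#'
#' @inheritParams deconvolve_to_gray
#' @param fs a [frame_sequence()].
#' @return list of grey matrices in `[0, 255]`, one per frame.
#' @export
gray_frames <- function(fs, stain_matrix = diag(3), channel = 1L) {
  stopifnot(inherits(fs, "frame_sequence"))
  raw <- lapply(fs$frames, deconvolve_to_gray, stain_matrix = stain_matrix,
                channel = channel, rescale = FALSE)
  r <- base::range(vapply(raw, base::range, numeric(2)))
  lapply(raw, function(g) {
    if (diff(r) <= 0) { g[] <- 0; g }
    else pmin(pmax((g - r[1]) / diff(r) * 255, 0), 255)
  })
}
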