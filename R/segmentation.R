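#' Median time-projection background model
#'
#' The static background of an overhead tank video is estimated as the
#' per-pixel median over time: as long as each pixel is covered by a fish
#' in fewer than half of the frames used, moving fish vanish completely
#' from the projection. For an even number of frames the lower median
#' (the n/2-th order statistic) is used, so background values remain
#' actual observed grey levels.
#'
#' @param frames list of grey matrices (e.g. from [gray_frames()]), all
#'   the same size. Subsampling the video (every k-th frame) is fine and
#'   much faster; `n_frames_used` records how many went in.
#' @return object of class `background_model`: list with `values` (the
#'   median image) and `n_frames_used`.
#' @export
median_projection <- function(frames) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("need at least one frame")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) isTRUE(all(dim(f) == d)), logical(1))))
    stop("frames must share identical dimensions")
  n <- length(frames)
  k <- (n + 1L) %/% 2L  # lower median for even n
  if (n == 1L) {
    med <- frames[[1]] + 0  # drop integer storage
  } else {
    # one two-key radix order over all pixels at once (pixel id, value):
    # the k-th entry of each pixel's block is its lower median
    npix <- length(frames[[1]])
    v <- as.numeric(unlist(frames, use.names = FALSE))
    pix <- rep.int(seq_len(npix), n)
    o <- order(pix, v, method = "radix")
    med <- v[o[(seq_len(npix) - 1L) * n + k]]
    med <- matrix(med, d[1], d[2])
  }
  structure(list(values = med, n_frames_used = n), class = "background_model")
}

#' Background subtraction
#'
#' Absolute per-pixel difference between a grey frame and the background
#' model. The absolute value makes the result insensitive to whether fish
#' are darker or lighter than the tank floor.
#'
#' @param frame grey matrix.
#' @param bg a [median_projection()] result (or a plain matrix).
#' @return grey difference matrix, same dimensions.
#' @export
subtract_background <- function(frame, bg) {
  bgv <- if (inherits(bg, "background_model")) bg$values else bg
  if (!isTRUE(all(dim(frame) == dim(bgv))))
    stop("frame and background dimensions differ")
  abs(frame - bgv)
}

#' 256-bin grey histogram
#'
#' Bins grey values into the 256 integer bins `0..255` (values are
#' clamped, then floored), the histogram the intermodes threshold
#' operates on.
#'
#' @param img numeric matrix with values on the 0..255 scale.
#' @return integer vector of length 256; element `i` counts bin `i - 1`.
#' @export
gray_histogram <- function(img) {
  v <- pmin(pmax(floor(img), 0), 255)
  tabulate(as.integer(v) + 1L, nbins = 256L)
}

#' Intermodes automatic threshold
#'
#' Iteratively smooths a 256-bin histogram with a 3-bin moving mean
#' (zero-padded at the ends) until exactly two local maxima remain, then
#' returns the rounded midpoint of the two modes. This is the classic
#' intermodes rule for bimodal images. Histograms that never become
#' bimodal -- unimodal or flat inputs, or ones whose modes merge past two
#' straight to one -- raise an error after 10,000 smoothing passes.
#'
#' Foreground is conventionally taken as pixels strictly above the
#' returned level.
#'
#' @param histogram 256 non-negative counts (see [gray_histogram()]).
#' @param max_iter smoothing-iteration cap.
#' @return integer threshold level in 0..255.
#' @examples
#' h <- integer(256); h[11] <- 40; h[21] <- 60
#' intermodes_threshold(h)  # modes 10 and 20 -> 15
#' @export
intermodes_threshold <- function(histogram, max_iter = 10000L) {
  if (length(histogram) != 256L) stop("histogram must have 256 bins")
  if (any(histogram < 0)) stop("histogram counts must be non-negative")
  if (sum(histogram) <= 0) stop("empty histogram")
  h <- as.numeric(histogram)
  peaks <- function(h) {
    left <- c(0, h[-256L]); right <- c(h[-1L], 0)
    which(h > left & h > right)
  }
  iter <- 0L
  repeat {
    p <- peaks(h)
    if (length(p) == 2L) {
      return(as.integer(round((sum(p) - 2L) / 2)))  # bins are 0-based
    }
    if (length(p) < 2L || iter >= max_iter)
      stop("histogram is not bimodal: intermodes threshold undefined")
    h <- (c(0, h[-256L]) + h + c(h[-1L], 0)) / 3
    iter <- iter + 1L
  }
}

# Majority (median) filter on a binary mask via box sums: a pixel becomes
# foreground when foreground pixels are a strict majority of its
# (2r+1) x (2r+1) window, windows clipped at the image border.
#' Binary median filter
#'
#' Median filtering of a binary mask with a square structuring window of
#' radius `radius`; equivalent to a strict-majority vote over the window.
#' Used to knock isolated noise pixels out of thresholded masks.
#'
#' @param mask logical matrix.
#' @param radius window radius in pixels (window side `2 * radius + 1`);
#'   `0` returns the mask unchanged.
#' @return logical matrix.
#' @export
median_filter_mask <- function(mask, radius = 2L) {
  stopifnot(is.matrix(mask))
  radius <- as.integer(radius)
  if (radius <= 0L) return(mask)
  ones <- box_sum(mask * 1, radius)
  # per-pixel window size, clipped at the borders
  h <- nrow(mask); w <- ncol(mask)
  wr <- pmin(seq_len(h) + radius, h) - pmax(seq_len(h) - radius, 1L) + 1L
  wc <- pmin(seq_len(w) + radius, w) - pmax(seq_len(w) - radius, 1L) + 1L
  2 * ones > outer(wr, wc)
}

# vectorised column-wise cumulative sum
col_cumsum <- function(m) {
  y <- cumsum(m)
  if (ncol(m) > 1L) {
    off <- c(0, y[nrow(m) * seq_len(ncol(m) - 1L)])
    y <- y - rep(off, each = nrow(m))
  }
  dim(y) <- dim(m)
  y
}

# clipped box sum via 2-d cumulative sums
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  cs <- t(col_cumsum(t(col_cumsum(m))))  # cs[i, j] = sum m[1:i, 1:j]
  P <- matrix(0, h + 1L, w + 1L); P[-1L, -1L] <- cs
  i1 <- pmax(seq_len(h) - r, 1L); i2 <- pmin(seq_len(h) + r, h)
  j1 <- pmax(seq_len(w) - r, 1L); j2 <- pmin(seq_len(w) + r, w)
  P[i2 + 1L, j2 + 1L] - P[i1, j2 + 1L] - P[i2 + 1L, j1] + P[i1, j1]
}

#' Label 8-connected components of a binary mask
#'
#' @param mask logical matrix.
#' @return integer matrix of the same size: 0 for background, 1..k
#'   component labels. Labels are ordered by the smallest linear
#'   (column-major) pixel index in each component.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  inset <- match(seq_len(h * w), idx)  # linear index -> vertex id or NA
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rn <- r + off[1]; cn <- c + off[2]
    ok <- rn >= 1L & rn <= h & cn >= 1L & cn <= w
    nb <- inset[(cn[ok] - 1L) * h + rn[ok]]
    has <- !is.na(nb)
    from <- which(ok)[has]
    edges <- c(edges, rbind(from, nb[has]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  # relabel so component ids follow first occurrence in scan order
  lab[idx] <- match(memb, unique(memb))
  lab
}

#' Segment one background-subtracted frame into fish detections
#'
#' Full per-frame segmentation: intermodes threshold of the
#' difference-image histogram, median filtering of the mask, 8-connected
#' component labelling, and a size gate that drops components outside
#' `[min_area, max_area]` (specks of noise, merged reflections). Each
#' surviving component becomes a `detection` with its pixel set, area and
#' unweighted centroid.
#'
#' @param diff background-subtracted grey matrix (see
#'   [subtract_background()]).
#' @param median_radius radius of the binary median filter, px.
#' @param min_area,max_area inclusive component-area bounds, px.
#' @param frame_index frame number recorded in each detection (1-based).
#' @return list of `detection` objects, sorted by label; each is a list
#'   with `frame`, `label`, `centroid` (x, y), `area`, `pixels` (n x 2
#'   matrix of x, y). Coordinates are 1-based, x = column, y = row.
#' @export
segment_frame <- function(diff, median_radius = 2L, min_area = 100L,
                          max_area = 50000L, frame_index = NA_integer_) {
  if (min_area > max_area) stop("min_area must be <= max_area")
  thr <- intermodes_threshold(gray_histogram(diff))
  mask <- diff > thr
  mask <- median_filter_mask(mask, median_radius)
  lab <- label_components(mask)
  k <- max(lab)
  dets <- list()
  if (k > 0L) {
    h <- nrow(lab)
    idx <- which(lab > 0L)
    labs <- lab[idx]
    xs <- ((idx - 1L) %/% h) + 1L
    ys <- ((idx - 1L) %% h) + 1L
    for (l in seq_len(k)) {
      sel <- labs == l
      a <- sum(sel)
      if (a < min_area || a > max_area) next
      px <- cbind(x = xs[sel], y = ys[sel])
      dets[[length(dets) + 1L]] <- structure(
        list(frame = frame_index, label = l,
             centroid = c(x = mean(px[, 1]), y = mean(px[, 2])),
             area = a, pixels = px),
        class = "detection")
    }
  }
  dets
}

#' Detections as a data frame
#'
#' @param dets list of `detection` objects (possibly from several frames).
#' @return data.frame with columns frame, label, x, y, area.
#' @export
detections_to_df <- function(dets) {
  if (length(dets) == 0L)
    return(data.frame(frame = integer(), label = integer(),
                      x = numeric(), y = numeric(), area = integer()))
  data.frame(
    frame = vapply(dets, function(d) as.integer(d$frame), integer(1)),
    label = vapply(dets, function(d) d$label, integer(1)),
    x = vapply(dets, function(d) d$centroid[["x"]], numeric(1)),
    y = vapply(dets, function(d) d$centroid[["y"]], numeric(1)),
    area = vapply(dets, function(d) as.integer(d$area), integer(1)))
}
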