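#' Gated assignment of detections to track heads
#'
#' One linking step of the tracker: solves the minimum-total-cost
#' one-to-one pairing between current track head positions and the
#' detections of the next frame, with Euclidean centroid separation as
#' the cost ([solve_assignment()]). After solving, any pair further
#' apart than `max_link_distance` is dissolved: its track and detection
#' are returned as unmatched instead (gating prevents absurd links when
#' a fish disappears).
#'
#' @param track_heads numeric matrix (or list) of track head centroids,
#'   one `(x, y)` row per active track.
#' @param detections numeric matrix (or list) of detection centroids.
#' @param max_link_distance gate radius in pixels, `> 0`.
#' @return object of class `assignment`: list with `pairs` (integer
#'   matrix, columns `track`, `detection`), `unmatched_tracks`,
#'   `unmatched_detections` (integer vectors), and `total_cost` (sum of
#'   the surviving pair distances, px).
#' @export
assign_detections <- function(track_heads, detections,
                              max_link_distance = 150) {
  if (max_link_distance <= 0) stop("max_link_distance must be positive")
  th <- as_xy_matrix(track_heads)
  dt <- as_xy_matrix(detections)
  nt <- nrow(th); nd <- nrow(dt)
  empty <- function(pairs, ut, ud, cost)
    structure(list(pairs = pairs, unmatched_tracks = ut,
                   unmatched_detections = ud, total_cost = cost),
              class = "assignment")
  pairs0 <- matrix(integer(0), 0L, 2L,
                   dimnames = list(NULL, c("track", "detection")))
  if (nt == 0L || nd == 0L)
    return(empty(pairs0, seq_len(nt), seq_len(nd), 0))
  cost <- sqrt(outer(th[, 1], dt[, 1], "-")^2 + outer(th[, 2], dt[, 2], "-")^2)
  sol <- solve_assignment(cost)
  d <- cost[sol$pairs]
  keep <- d <= max_link_distance
  pairs <- sol$pairs[keep, , drop = FALSE]
  colnames(pairs) <- c("track", "detection")
  empty(pairs,
        setdiff(seq_len(nt), pairs[, 1]),
        setdiff(seq_len(nd), pairs[, 2]),
        sum(d[keep]))
}

as_xy_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (length(x) == 0L) return(matrix(numeric(0), 0L, 2L))
    x <- do.call(rbind, lapply(x, function(p) as.numeric(p)[1:2]))
  }
  if (is.null(x)) return(matrix(numeric(0), 0L, 2L))
  x <- as.matrix(x)
  if (nrow(x) > 0L && ncol(x) != 2L) stop("centroids must be (x, y) pairs")
  x
}

#' Build fish tracks across frames
#'
#' Frame-by-frame Munkres linking with immediate termination: matched
#' tracks are extended by their detection, unmatched detections start new
#' tracks (ids in creation order), and a track that misses a single
#' frame is closed -- there is no gap closing and no motion model, so
#' track frame indices are strictly consecutive.
#'
#' @param detections_by_frame list (one element per frame, in temporal
#'   order) of detection lists as produced by [segment_frame()].
#' @param max_link_distance linking gate in pixels.
#' @return list of `fish_track` objects: each has `track_id`,
#'   `detections` (time-ordered list), `start_frame`, `end_frame`.
#' @export
build_tracks <- function(detections_by_frame, max_link_distance = 150) {
  finished <- list()
  active <- list()  # each: list(track_id, detections)
  next_id <- 1L
  for (f in seq_along(detections_by_frame)) {
    dets <- detections_by_frame[[f]]
    heads <- lapply(active, function(tr)
      tr$detections[[length(tr$detections)]]$centroid)
    cents <- lapply(dets, function(d) d$centroid)
    a <- assign_detections(heads, cents, max_link_distance)
    new_active <- list()
    if (nrow(a$pairs) > 0L) {
      for (i in seq_len(nrow(a$pairs))) {
        tr <- active[[a$pairs[i, 1]]]
        d <- dets[[a$pairs[i, 2]]]
        if (is.na(d$frame)) d$frame <- f
        tr$detections[[length(tr$detections) + 1L]] <- d
        new_active[[length(new_active) + 1L]] <- tr
      }
    }
    for (ti in a$unmatched_tracks)
      finished[[length(finished) + 1L]] <- active[[ti]]
    for (di in a$unmatched_detections) {
      d <- dets[[di]]
      if (is.na(d$frame)) d$frame <- f
      new_active[[length(new_active) + 1L]] <-
        list(track_id = next_id, detections = list(d))
      next_id <- next_id + 1L
    }
    active <- new_active
  }
  finished <- c(finished, active)
  finished <- finished[order(vapply(finished, function(tr) tr$track_id,
                                    integer(1)))]
  lapply(finished, function(tr) {
    frames <- vapply(tr$detections, function(d) as.integer(d$frame), integer(1))
    structure(list(track_id = tr$track_id, detections = tr$detections,
                   start_frame = frames[1L],
                   end_frame = frames[length(frames)]),
              class = "fish_track")
  })
}

#' @export
print.fish_track <- function(x, ...) {
  cat(sprintf("<fish_track %d> frames %d..%d (%d detections)\n",
              x$track_id, x$start_frame, x$end_frame, length(x$detections)))
  invisible(x)
}

#' Track length in frames
#' @param track a `fish_track`.
#' @return integer number of frames spanned.
#' @export
track_length <- function(track) length(track$detections)

#' Track centroids as a matrix
#' @param track a `fish_track`.
#' @return numeric matrix with columns x, y, one row per frame.
#' @export
track_centroids <- function(track) {
  do.call(rbind, lapply(track$detections, function(d) d$centroid))
}

#' Drop short (spurious) tracks
#'
#' Tracks shorter than `min_frames` are discarded as false tracks; the
#' conventional cutoff is 50 frames (about 2 s at 24.96 fps). Order is
#' preserved.
#'
#' @param tracks list of `fish_track` objects.
#' @param min_frames minimum track length in frames, `>= 1`.
#' @return filtered list of tracks.
#' @export
filter_short_tracks <- function(tracks, min_frames = 50L) {
  if (min_frames < 1L) stop("min_frames must be >= 1")
  tracks[vapply(tracks, track_length, integer(1)) >= min_frames]
}

#' Instantaneous frame-to-frame speeds of a track
#'
#' Speed at each step is the Euclidean distance between consecutive
#' centroids, in pixels/frame; each value is attributed to the later
#' frame of its step. If `pixel_scale` (mm/px) is known, speeds convert
#' to mm/s as `speed * fps * pixel_scale` (see [speeds_mm_per_s()]).
#'
#' @param track a `fish_track` of length >= 2.
#' @param fps frames per second.
#' @param pixel_scale optional mm per pixel.
#' @return object of class `speed_series`: list with `track_id`,
#'   `speeds` (px/frame, length = track length - 1), `frames` (the later
#'   frame of each step), `fps`, `pixel_scale`.
#' @export
instantaneous_speeds <- function(track, fps = 24.96, pixel_scale = NULL) {
  if (track_length(track) < 2L)
    stop("track must span at least 2 frames to have speeds")
  xy <- track_centroids(track)
  dxy <- diff(xy)
  sp <- sqrt(rowSums(dxy^2))
  frames <- vapply(track$detections, function(d) as.integer(d$frame),
                   integer(1))[-1L]
  structure(list(track_id = track$track_id, speeds = as.numeric(sp),
                 frames = frames, fps = fps, pixel_scale = pixel_scale),
            class = "speed_series")
}

#' Convert a speed series to mm/s
#' @param ss a `speed_series` whose `pixel_scale` is set.
#' @return numeric vector of speeds in mm/s.
#' @export
speeds_mm_per_s <- function(ss) {
  if (is.null(ss$pixel_scale))
    stop("speed series has no pixel_scale; speeds are in px/frame only")
  ss$speeds * ss$fps * ss$pixel_scale
}

#' Tracks as a data frame
#' @param tracks list of `fish_track` objects.
#' @return data.frame with columns track_id, frame, x, y, area.
#' @export
tracks_to_df <- function(tracks) {
  if (length(tracks) == 0L)
    return(data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric(), area = integer()))
  do.call(rbind, lapply(tracks, function(tr) {
    df <- detections_to_df(tr$detections)
    cbind(track_id = tr$track_id, df[, c("frame", "x", "y", "area")])
  }))
}
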