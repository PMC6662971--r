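#' Full swim-behaviour quantification pipeline
#'
#' Runs the whole chain on a video: colour-deconvolution greyscale
#' conversion with a video-global rescale, median time-projection
#' background subtraction, intermodes-threshold segmentation with median
#' filtering and a size gate, Munkres centroid linking into tracks,
#' exclusion of tracks shorter than `min_track_frames`, per-frame
#' backbone spline curvature, and per-fish summaries (mean instantaneous
#' velocity and range of movement over the `n_active` most-active
#' frames).
#'
#' Frames whose difference histogram never becomes bimodal (nothing
#' moving) contribute zero detections rather than aborting the run;
#' detections whose skeleton is too small for a spline get `NA`
#' curvature for that frame.
#'
#' @param fs a [frame_sequence()].
#' @param stain_matrix,channel greyscale conversion, see
#'   [deconvolve_to_gray()].
#' @param background_frames how many evenly spaced frames to feed the
#'   median projection (the full video works but is slower).
#' @param median_radius,min_area,max_area segmentation parameters, see
#'   [segment_frame()].
#' @param max_link_distance tracker gate, px.
#' @param min_track_frames minimum track length kept.
#' @param n_active number of most-active frames per fish summary.
#' @param smoothing spline smoothing (df), `NULL` for the default.
#' @param curvature_samples curvature samples per frame.
#' @return object of class `swim_analysis`: list with `tracks`,
#'   `speeds` (per track), `curvatures` (per track data.frame of frame /
#'   backbone_length / frame_curvature / min / max local curvature),
#'   `summaries` (one-row-per-fish data.frame), `background`,
#'   `n_frames`, and the parameter set used.
#' @export
track_swim_video <- function(fs, stain_matrix = diag(3), channel = 1L,
                             background_frames = 50L, median_radius = 2L,
                             min_area = 100L, max_area = 50000L,
                             max_link_distance = 150,
                             min_track_frames = 50L, n_active = 100L,
                             smoothing = NULL, curvature_samples = 100L) {
  stopifnot(inherits(fs, "frame_sequence"))
  n <- length(fs$frames)
  gray <- gray_frames(fs, stain_matrix = stain_matrix, channel = channel)
  sub <- unique(round(seq(1L, n, length.out = min(background_frames, n))))
  bg <- median_projection(gray[sub])
  dets_by_frame <- vector("list", n)
  n_failed <- 0L
  for (f in seq_len(n)) {
    dets_by_frame[[f]] <- tryCatch(
      segment_frame(subtract_background(gray[[f]], bg),
                    median_radius = median_radius, min_area = min_area,
                    max_area = max_area, frame_index = f),
      error = function(e) { n_failed <<- n_failed + 1L; list() })
  }
  if (n_failed > 0L)
    warning(n_failed, " frame(s) had no bimodal histogram; ",
            "treated as empty")
  tracks <- filter_short_tracks(build_tracks(dets_by_frame,
                                             max_link_distance),
                                min_track_frames)
  speeds <- lapply(tracks, instantaneous_speeds, fps = fs$fps,
                   pixel_scale = fs$pixel_scale)
  curvatures <- lapply(tracks, track_curvatures, smoothing = smoothing,
                       M = curvature_samples)
  summaries <- mapply(function(tr, sp, cv) {
    s <- summarize_fish(tr, sp, cv, n_active = n_active)
    data.frame(fish_id = s$fish_id, mean_velocity = s$mean_velocity,
               range_of_movement = s$range_of_movement,
               n_frames_used = s$n_frames_used,
               short_series = s$short_series)
  }, tracks, speeds, curvatures, SIMPLIFY = FALSE)
  summaries <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame(fish_id = integer(), mean_velocity = numeric(),
               range_of_movement = numeric(), n_frames_used = integer(),
               short_series = logical())
  structure(list(tracks = tracks, speeds = speeds,
                 curvatures = curvatures, summaries = summaries,
                 background = bg, n_frames = n,
                 params = list(median_radius = median_radius,
                               min_area = min_area, max_area = max_area,
                               max_link_distance = max_link_distance,
                               min_track_frames = min_track_frames,
                               n_active = n_active)),
            class = "swim_analysis")
}

#' Per-frame backbone curvature of one track
#'
#' Skeletonises every detection of a track, fits the backbone spline and
#' samples its signed curvature, carrying head/tail orientation forward
#' from frame to frame so the curvature sign stays continuous.
#' Detections whose skeleton is too small yield `NA` for that frame.
#'
#' @param track a `fish_track`.
#' @param smoothing spline smoothing (df) passed to [fit_spline()].
#' @param M curvature samples per frame.
#' @return data.frame with columns `track_id`, `frame`,
#'   `backbone_length`, `curvature` (the per-frame mean signed
#'   curvature), `min_curvature`, `max_curvature`.
#' @export
track_curvatures <- function(track, smoothing = NULL, M = 100L) {
  stopifnot(inherits(track, "fish_track"))
  prev <- NULL
  rows <- lapply(track$detections, function(d) {
    res <- tryCatch({
      bb <- extract_backbone(d$pixels)
      sp <- fit_spline(bb, smoothing = smoothing)
      prof <- curvature_profile(sp, M = M, previous = prev)
      prev <<- prof
      inner <- prof$s >= 0.05 & prof$s <= 0.95
      c(sp$backbone_length, prof$frame_curvature,
        min(prof$samples[inner]), max(prof$samples[inner]))
    }, error = function(e) rep(NA_real_, 4L))
    data.frame(track_id = track$track_id, frame = as.integer(d$frame),
               backbone_length = res[1], curvature = res[2],
               min_curvature = res[3], max_curvature = res[4])
  })
  do.call(rbind, rows)
}

#' @export
print.swim_analysis <- function(x, ...) {
  cat(sprintf("<swim_analysis> %d frames, %d track(s) kept\n",
              x$n_frames, length(x$tracks)))
  if (nrow(x$summaries)) {
    cat("per-fish summaries (most-active frames):\n")
    print(x$summaries, row.names = FALSE)
  }
  invisible(x)
}
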