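#' Configuration of a synthetic swimming-fish video
#'
#' Describes an overhead-view tank recording to be simulated: dark
#' elongated fish bodies undulating (oscillating body curvature) while
#' translating over a static textured background. Defaults emulate the
#' recording conditions the pipeline is calibrated around -- 1920 x 1080
#' at 24.96 frames/s with 2 fish per movie -- with fish geometry sized
#' for an adult zebrafish seen from above at that resolution. For
#' desk-scale tests use the 3x reduced geometry, e.g.
#' `swim_config(frame_size = c(640, 360), body_length = 60,
#' body_width = 12, speed = 5, curvature_amplitude = 0.015)` (curvature
#' has units 1/px and therefore scales up as resolution scales down).
#'
#' @param n_fish number of fish.
#' @param frame_size `c(width, height)` in pixels.
#' @param fps frames per second.
#' @param n_frames number of frames.
#' @param body_length fish midline length, px.
#' @param body_width fish body width, px.
#' @param speed programmed centroid displacement per frame, px.
#' @param heading_sd SD of the per-frame heading random walk, radians
#'   (0 for straight-line swimming).
#' @param curvature_amplitude amplitude A of the sinusoidal body
#'   curvature, 1/px; per-frame programmed curvature is
#'   `A * sin(2 * pi * beat_freq * t + phase)`.
#' @param beat_freq tail-beat frequency, Hz.
#' @param background_level base background grey level (0..255).
#' @param texture_sd SD of the static background texture, grey levels.
#' @param contrast how much darker the fish are than the background,
#'   grey levels.
#' @param pixel_noise_sd SD of per-frame sensor noise, grey levels.
#' @param seed RNG seed; simulation and rendering are deterministic
#'   given the config.
#' @param init_positions optional `n_fish x 2` matrix of initial (x, y)
#'   centroids (must be pairwise >= 2 * body_length apart); `NULL` for
#'   random placement under the same constraint.
#' @param init_headings optional initial headings, radians.
#' @return a list of class `swim_config`.
#' @export
swim_config <- function(n_fish = 2L, frame_size = c(1920L, 1080L),
                        fps = 24.96, n_frames = 500L,
                        body_length = 180, body_width = 36, speed = 15,
                        heading_sd = 0.05, curvature_amplitude = 0.005,
                        beat_freq = 2, background_level = 160,
                        texture_sd = 8, contrast = 60, pixel_noise_sd = 3,
                        seed = 1L, init_positions = NULL,
                        init_headings = NULL) {
  stopifnot(n_fish >= 1L, length(frame_size) == 2L, all(frame_size > 0),
            fps > 0, n_frames >= 1L, body_length > 0, body_width > 0,
            speed >= 0, heading_sd >= 0, curvature_amplitude >= 0,
            beat_freq >= 0, background_level > 0, texture_sd >= 0,
            contrast >= 0, pixel_noise_sd >= 0)
  if (!is.null(init_positions)) {
    init_positions <- as.matrix(init_positions)
    stopifnot(nrow(init_positions) == n_fish, ncol(init_positions) == 2L)
  }
  structure(list(n_fish = as.integer(n_fish),
                 frame_size = as.integer(frame_size), fps = fps,
                 n_frames = as.integer(n_frames),
                 body_length = body_length, body_width = body_width,
                 speed = speed, heading_sd = heading_sd,
                 curvature_amplitude = curvature_amplitude,
                 beat_freq = beat_freq,
                 background_level = background_level,
                 texture_sd = texture_sd, contrast = contrast,
                 pixel_noise_sd = pixel_noise_sd, seed = as.integer(seed),
                 init_positions = init_positions,
                 init_headings = init_headings),
            class = "swim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate fish trajectories with exact ground truth
#'
#' Deterministic (given the config seed) simulation of fish centroids,
#' headings and body curvature. Each fish advances `speed` pixels per
#' frame along a heading that performs a Gaussian random walk, reflects
#' off the tank walls, and carries a midline that is a circular-arc
#' segment of length `body_length` whose signed curvature oscillates as
#' `A * sin(2 * pi * f * t + phase)` with a random per-fish phase.
#'
#' @param config a [swim_config()].
#' @return object of class `ground_truth`: data.frame with columns
#'   `fish`, `frame` (1-based), `x`, `y`, `heading`, `speed`,
#'   `curvature`; the config is attached as attribute `config`.
#' @export
simulate_swim <- function(config) {
  stopifnot(inherits(config, "swim_config"))
  W <- config$frame_size[1]; H <- config$frame_size[2]
  margin <- config$body_length / 2 + config$body_width
  if (2 * margin >= W || 2 * margin >= H)
    stop("frame too small for the configured fish size")
  with_seed(config$seed, {
    pos <- config$init_positions
    if (is.null(pos)) {
      pos <- matrix(NA_real_, config$n_fish, 2L)
      for (i in seq_len(config$n_fish)) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          p <- c(stats::runif(1, margin, W - margin),
                 stats::runif(1, margin, H - margin))
          if (i == 1L || all(sqrt(rowSums(sweep(pos[seq_len(i - 1L), ,
                                                    drop = FALSE], 2L, p)^2)) >=
                             2 * config$body_length)) {
            pos[i, ] <- p; placed <- TRUE; break
          }
        }
        if (!placed)
          stop("could not place fish with the required separation")
      }
    } else {
      d <- as.matrix(stats::dist(pos))
      if (any(d[upper.tri(d)] < 2 * config$body_length))
        stop("init_positions closer than 2 * body_length")
    }
    heading <- if (is.null(config$init_headings))
      stats::runif(config$n_fish, 0, 2 * pi) else config$init_headings
    phase <- stats::runif(config$n_fish, 0, 2 * pi)
    n <- config$n_frames
    out <- vector("list", config$n_fish)
    for (i in seq_len(config$n_fish)) {
      xs <- numeric(n); ys <- numeric(n); hs <- numeric(n)
      p <- pos[i, ]; h <- heading[i]
      for (f in seq_len(n)) {
        xs[f] <- p[1]; ys[f] <- p[2]; hs[f] <- h
        if (config$heading_sd > 0) h <- h + stats::rnorm(1, 0, config$heading_sd)
        p <- p + config$speed * c(cos(h), sin(h))
        # reflect off walls (keep the whole body inside the frame)
        if (p[1] < margin)     { p[1] <- 2 * margin - p[1];        h <- pi - h }
        if (p[1] > W - margin) { p[1] <- 2 * (W - margin) - p[1];  h <- pi - h }
        if (p[2] < margin)     { p[2] <- 2 * margin - p[2];        h <- -h }
        if (p[2] > H - margin) { p[2] <- 2 * (H - margin) - p[2];  h <- -h }
      }
      t <- (seq_len(n) - 1L) / config$fps
      out[[i]] <- data.frame(
        fish = i, frame = seq_len(n), x = xs, y = ys, heading = hs,
        speed = config$speed,
        curvature = config$curvature_amplitude *
          sin(2 * pi * config$beat_freq * t + phase[i]))
    }
    truth <- do.call(rbind, out)
    attr(truth, "config") <- config
    class(truth) <- c("ground_truth", "data.frame")
    truth
  })
}

# midline of a constant-curvature arc of length L centred on its own
# centroid, so body bending does not displace the rendered blob centroid
arc_midline <- function(cx, cy, heading, L, kappa, step = 0.5) {
  s <- seq(-L / 2, L / 2, by = step)
  if (abs(kappa) < 1e-9) {
    x <- s * cos(heading); y <- s * sin(heading)
  } else {
    x <- (sin(heading + kappa * s) - sin(heading)) / kappa
    y <- -(cos(heading + kappa * s) - cos(heading)) / kappa
  }
  cbind(x = x - mean(x) + cx, y = y - mean(y) + cy)
}

#' Render a simulated swim as video frames
#'
#' Draws each fish as a filled capsule (constant-width band with round
#' caps) along its circular-arc midline, darker than the background by
#' the configured contrast. The background is a fixed seeded texture;
#' independent Gaussian pixel noise is added to every frame. Rendering
#' is deterministic given the config. Frames are greyscale 8-bit
#' matrices; written to disk (binary PGM plus a ground-truth CSV) when
#' `out` is given, which round-trips losslessly through [read_frames()].
#'
#' @param truth a [simulate_swim()] result.
#' @param config the matching [swim_config()]; defaults to the config
#'   stored in `truth`.
#' @param out optional output directory for PGM frames and
#'   `ground_truth.csv`.
#' @return a [frame_sequence()] of greyscale frames.
#' @export
render_video <- function(truth, config = attr(truth, "config"), out = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "swim_config"))
  W <- config$frame_size[1]; H <- config$frame_size[2]
  r <- config$body_width / 2
  dd <- expand.grid(dy = seq(-ceiling(r), ceiling(r)),
                    dx = seq(-ceiling(r), ceiling(r)))
  dd <- dd[dd$dx^2 + dd$dy^2 <= r^2, ]
  fish_level <- config$background_level - config$contrast
  frames <- with_seed(config$seed + 1L, {
    texture <- matrix(config$background_level +
                        stats::rnorm(H * W, 0, config$texture_sd), H, W)
    lapply(seq_len(config$n_frames), function(f) {
      img <- texture
      sub <- truth[truth$frame == f, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        mid <- arc_midline(sub$x[i], sub$y[i], sub$heading[i],
                           config$body_length, sub$curvature[i])
        rows <- outer(round(mid[, 2]), dd$dy, `+`)
        cols <- outer(round(mid[, 1]), dd$dx, `+`)
        ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
        img[cbind(rows[ok], cols[ok])] <- fish_level
      }
      if (config$pixel_noise_sd > 0)
        img <- img + stats::rnorm(H * W, 0, config$pixel_noise_sd)
      m <- pmin(pmax(round(img), 0), 255)
      storage.mode(m) <- "integer"
      m
    })
  })
  fs <- frame_sequence(frames, fps = config$fps)
  if (!is.null(out)) {
    write_frames(fs, out)
    utils::write.csv(
      truth[, c("fish", "frame", "x", "y", "speed", "curvature")],
      file.path(out, "ground_truth.csv"), row.names = FALSE)
  }
  fs
}
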