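# Shared fixtures and independent oracles, built in code at test time.

# reduced desk-scale synthetic world: 640 x 360, 3x-scaled-down fish
desk_config <- function(n_frames = 60, seed = 11, heading_sd = 0,
                        curvature_amplitude = 0.015, speed = 5,
                        n_fish = 2, pixel_noise_sd = 3, contrast = 60,
                        init_positions = rbind(c(160, 90), c(160, 270)),
                        init_headings = c(0, 0), ...) {
  swim_config(n_fish = n_fish, frame_size = c(640, 360),
              n_frames = n_frames, body_length = 60, body_width = 12,
              speed = speed, heading_sd = heading_sd,
              curvature_amplitude = curvature_amplitude,
              contrast = contrast, pixel_noise_sd = pixel_noise_sd,
              seed = seed,
              init_positions = init_positions[seq_len(n_fish), , drop = FALSE],
              init_headings = init_headings[seq_len(n_fish)], ...)
}

# brute-force minimum assignment cost over all permutations
# (permutation tables cached per size; up to 7! = 5040)
.perm_cache <- new.env(parent = emptyenv())
all_perms <- function(k) {
  key <- as.character(k)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  .perm_cache[[key]] <- do.call(rbind, perms(seq_len(k)))
  .perm_cache[[key]]
}
brute_force_assignment_cost <- function(C) {
  n <- nrow(C); m <- ncol(C)
  if (n > m) { C <- t(C); tmp <- n; n <- m; m <- tmp }
  P <- all_perms(m)
  costs <- apply(P[, seq_len(n), drop = FALSE], 1L, function(p)
    sum(C[cbind(seq_len(n), p)]))
  min(costs)
}

# recursive flood fill component labelling (8-connectivity) for tiny masks
flood_fill_labels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  fill <- function(i, j) {
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > h || p[2] < 1 || p[2] > w) next
      if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <<- cur
      for (di in -1:1) for (dj in -1:1)
        if (di != 0 || dj != 0)
          stack[[length(stack) + 1L]] <- c(p[1] + di, p[2] + dj)
    }
  }
  for (j in seq_len(w)) for (i in seq_len(h))
    if (mask[i, j] && lab[i, j] == 0L) { cur <- cur + 1L; fill(i, j) }
  lab
}

# build a detection-list sequence from per-frame centroid matrices
detections_from_centroids <- function(centroids_by_frame) {
  lapply(seq_along(centroids_by_frame), function(f) {
    cm <- centroids_by_frame[[f]]
    if (is.null(cm) || nrow(cm) == 0L) return(list())
    lapply(seq_len(nrow(cm)), function(i)
      structure(list(frame = f, label = i,
                     centroid = c(x = unname(cm[i, 1]), y = unname(cm[i, 2])),
                     area = 1L, pixels = cm[i, , drop = FALSE]),
                class = "detection"))
  })
}

# filled rectangle pixel set
rect_pixels <- function(x0, x1, y0, y1) {
  as.matrix(expand.grid(x = x0:x1, y = y0:y1))
}
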