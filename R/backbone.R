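#' Skeletonise a detection and order its midline
#'
#' Thins the pixel set of a detection to a 1-px skeleton (Zhang-Suen
#' morphological thinning) and orders it into a backbone: when the
#' skeleton branches, the backbone is the longest endpoint-to-endpoint
#' geodesic through the skeleton's 8-adjacency graph (orthogonal steps
#' weight 1, diagonal steps sqrt(2)); side branches are dropped.
#'
#' @param mask_pixels `n x 2` matrix of (x, y) pixel coordinates of one
#'   detection (n >= 20), or a `detection` object.
#' @return object of class `backbone`: list with `points` (ordered
#'   `m x 2` matrix of (x, y), consecutive points 8-adjacent) and
#'   `n_endpoints_found` (number of degree-1 skeleton pixels).
#' @export
extract_backbone <- function(mask_pixels) {
  if (inherits(mask_pixels, "detection")) mask_pixels <- mask_pixels$pixels
  px <- as.matrix(mask_pixels)
  if (nrow(px) < 20L) stop("object too small to skeletonise (< 20 pixels)")
  x0 <- min(px[, 1]); y0 <- min(px[, 2])
  w <- max(px[, 1]) - x0 + 1L; h <- max(px[, 2]) - y0 + 1L
  # 1-px zero border so thinning never touches the crop edge
  m <- matrix(0L, h + 2L, w + 2L)
  m[cbind(px[, 2] - y0 + 2L, px[, 1] - x0 + 2L)] <- 1L
  sk <- thin_mask(m)
  idx <- which(sk == 1L)
  if (length(idx) < 5L) stop("skeleton too small (< 5 points)")
  r <- ((idx - 1L) %% nrow(sk)) + 1L
  c <- ((idx - 1L) %/% nrow(sk)) + 1L
  # 8-adjacency graph, weighted by step length
  keymap <- match(seq_len(length(sk)), idx)
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (off in list(c(1L, 0L, 1), c(0L, 1L, 1),
                   c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))) {
    rn <- r + off[1]; cn <- c + off[2]
    ok <- rn >= 1L & rn <= nrow(sk) & cn >= 1L & cn <= ncol(sk)
    nb <- keymap[(cn[ok] - 1L) * nrow(sk) + rn[ok]]
    has <- !is.na(nb)
    ef <- c(ef, which(ok)[has]); et <- c(et, nb[has])
    ew <- c(ew, rep(off[3], sum(has)))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(ef))
    g <- igraph::add_edges(g, rbind(ef, et), weight = ew)
  path <- igraph::get_diameter(g, weights = igraph::E(g)$weight)
  vp <- as.integer(path)
  if (length(vp) < 5L) stop("skeleton path too short (< 5 points)")
  pts <- cbind(x = c[vp] + x0 - 2L, y = r[vp] + y0 - 2L)
  n_end <- sum(igraph::degree(g) == 1L)
  structure(list(points = pts, n_endpoints_found = n_end),
            class = "backbone")
}

# Zhang-Suen thinning of a 0/1 matrix (assumed zero-padded at border).
thin_mask <- function(m) {
  shift <- function(mm, dr, dc) {
    out <- matrix(0L, nrow(mm), ncol(mm))
    rs <- seq_len(nrow(mm)) + dr
    cs <- seq_len(ncol(mm)) + dc
    okr <- rs >= 1L & rs <= nrow(mm)
    okc <- cs >= 1L & cs <= ncol(mm)
    out[okr, okc] <- mm[rs[okr], cs[okc]]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # clockwise neighbours starting at north
      P2 <- shift(m, -1L,  0L); P3 <- shift(m, -1L,  1L)
      P4 <- shift(m,  0L,  1L); P5 <- shift(m,  1L,  1L)
      P6 <- shift(m,  1L,  0L); P7 <- shift(m,  1L, -1L)
      P8 <- shift(m,  0L, -1L); P9 <- shift(m, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
           (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
           (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
           (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      if (sub == 1L) {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) return(m)
  }
}

#' Fit a smooth spline curve to a backbone
#'
#' Cubic B-spline regression curves are fitted independently to the x
#' and y backbone coordinates against normalised cumulative chord
#' length `s` in `[0, 1]`. Smoothness is controlled by the size of the
#' spline basis (`smoothing` = number of basis functions, with evenly
#' spaced interior knots): the default of roughly one basis function per
#' 10 backbone pixels (clamped to `[5, 12]`) flattens 1-px skeleton
#' staircase noise while following genuine body bends. Unpenalised
#' regression splines are used rather than penalised smoothing splines
#' because the latter's natural boundary conditions force the second
#' derivative -- hence the curvature -- to zero at the snout and tail
#' tip. Backbone length is the arc length of the fitted curve,
#' integrated numerically on a 1001-point grid.
#'
#' @param backbone a [extract_backbone()] result, or an `n x 2` matrix of
#'   ordered (x, y) points (n >= 5).
#' @param smoothing basis size for each component spline (>= 4); larger
#'   follows the points more closely. `NULL` for the
#'   point-count-proportional default.
#' @return object of class `spline_model`; evaluate it with
#'   [predict.spline_model()]. Contains `n_points`, `smoothing` (basis
#'   size actually used), `backbone_length` (px) and the fitted
#'   `head`/`tail` end coordinates.
#' @export
fit_spline <- function(backbone, smoothing = NULL) {
  pts <- if (inherits(backbone, "backbone")) backbone$points else as.matrix(backbone)
  if (nrow(pts) < 5L) stop("need at least 5 backbone points")
  step <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, step > 0)  # drop exact duplicates
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n < 5L) stop("degenerate backbone (all points coincident)")
  chord <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- chord[n]
  if (total <= 0) stop("degenerate backbone (zero length)")
  s <- chord / total
  df <- if (is.null(smoothing)) max(5, min(12, ceiling(n / 10))) else smoothing
  df <- as.integer(max(4L, min(df, n)))
  # full clamped knot vector: cubic, evenly spaced interior knots
  inner <- if (df > 4L) seq(0, 1, length.out = df - 2L)[-c(1L, df - 2L)]
           else numeric(0)
  knots <- c(rep(0, 4L), inner, rep(1, 4L))
  basis <- splines::splineDesign(knots, s, ord = 4L)
  qrb <- qr(basis)
  coef_x <- qr.coef(qrb, pts[, 1])
  coef_y <- qr.coef(qrb, pts[, 2])
  if (anyNA(coef_x) || anyNA(coef_y))
    stop("degenerate backbone: spline basis is rank deficient")
  obj <- structure(list(knots = knots, coef_x = coef_x, coef_y = coef_y,
                        n_points = n, smoothing = df),
                   class = "spline_model")
  sg <- seq(0, 1, length.out = 1001L)
  d1 <- predict(obj, sg, deriv = 1L)
  sp <- sqrt(d1$x^2 + d1$y^2)
  obj$backbone_length <- sum((sp[-1L] + sp[-length(sp)]) / 2) *
    (sg[2L] - sg[1L])
  ends <- predict(obj, c(0, 1))
  obj$head <- c(x = ends$x[1], y = ends$y[1])
  obj$tail <- c(x = ends$x[2], y = ends$y[2])
  obj
}

#' Evaluate a fitted backbone spline
#'
#' @param object a [fit_spline()] result.
#' @param s arc-length positions in `[0, 1]`.
#' @param deriv derivative order 0, 1 or 2 (with respect to `s`).
#' @param ... unused.
#' @return list with components `s`, `x`, `y`.
#' @export
predict.spline_model <- function(object, s, deriv = 0L, ...) {
  design <- splines::splineDesign(object$knots, s, ord = 4L,
                                  derivs = rep(as.integer(deriv), length(s)))
  list(s = s, x = as.numeric(design %*% object$coef_x),
       y = as.numeric(design %*% object$coef_y))
}

#' Signed curvature profile of a fitted backbone
#'
#' Samples the signed curvature
#' `kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)`
#' (parameterisation-invariant, units 1/px) at `M` evenly spaced
#' positions along the fitted spline. The sign of kappa depends on the
#' traversal direction, which a skeleton does not define; orientation is
#' therefore made continuous over time: if a `previous` profile is
#' supplied, the current backbone is traversed so that its head end is
#' the end nearer the previous head end (first frame: arbitrary `+1`).
#' The per-frame scalar `frame_curvature` is the mean of the signed
#' samples with the outer 5% at each end excluded, where spline end
#' effects dominate.
#'
#' @param spline a [fit_spline()] result.
#' @param M number of curvature samples.
#' @param previous the previous frame's `curvature_profile` of the same
#'   fish, or `NULL`.
#' @param trim fraction of arc length excluded at each end from
#'   `frame_curvature`.
#' @return object of class `curvature_profile`: list with `samples`
#'   (signed kappa at `s`), `s`, `frame_curvature`, `orientation_sign`
#'   (+1/-1 relative to the spline's stored direction), and the oriented
#'   `head`/`tail` coordinates.
#' @export
curvature_profile <- function(spline, M = 100L, previous = NULL,
                              trim = 0.05) {
  stopifnot(inherits(spline, "spline_model"))
  s <- seq(0, 1, length.out = M)
  d1 <- predict(spline, s, deriv = 1L)
  d2 <- predict(spline, s, deriv = 2L)
  x1 <- d1$x; y1 <- d1$y
  x2 <- d2$x; y2 <- d2$y
  denom <- (x1^2 + y1^2)^1.5
  if (any(!is.finite(denom)) || any(denom == 0))
    stop("degenerate spline: undefined tangent")
  kappa <- (x1 * y2 - y1 * x2) / denom
  if (any(!is.finite(kappa))) stop("non-finite curvature")
  head <- spline$head; tail <- spline$tail
  sign <- 1
  if (!is.null(previous)) {
    ph <- previous$head
    if (sum((head - ph)^2) > sum((tail - ph)^2)) {
      sign <- -1
      kappa <- -rev(kappa)
      tmp <- head; head <- tail; tail <- tmp
    }
  }
  inner <- s >= trim & s <= 1 - trim
  structure(list(samples = kappa, s = s,
                 frame_curvature = mean(kappa[inner]),
                 orientation_sign = sign, head = head, tail = tail),
            class = "curvature_profile")
}

#' Range of movement from per-frame curvatures
#'
#' A fish's range of movement is the maximum minus the minimum of its
#' per-frame body-curvature scalars -- the full amplitude of body
#' bending over the frames considered. Always `>= 0`; 0 iff the series
#' is constant; invariant to reordering.
#'
#' @param frame_curvatures numeric vector of per-frame curvature
#'   scalars (1/px), length >= 1. `NA`s are dropped.
#' @return `max - min` of the values.
#' @export
range_of_movement <- function(frame_curvatures) {
  v <- frame_curvatures[!is.na(frame_curvatures)]
  if (length(v) == 0L) stop("no curvature values")
  if (any(!is.finite(v))) stop("non-finite curvature values")
  max(v) - min(v)
}
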