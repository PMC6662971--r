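#' Select a fish's most-active frames
#'
#' Picks the `n` frames with the highest activity value (by convention
#' the instantaneous speed, attributed to the later frame of each step).
#' Ties are broken in favour of the earlier frame. If fewer than `n`
#' frames are available, all are returned and the result carries
#' `attr(, "short_series") = TRUE`.
#'
#' @param activity numeric vector of per-frame activity values.
#' @param n number of frames to select (default 100).
#' @param frames frame indices corresponding to `activity`.
#' @return integer vector of selected frame indices, sorted increasing,
#'   with attribute `short_series`.
#' @export
select_active_frames <- function(activity, n = 100L,
                                 frames = seq_along(activity)) {
  if (n < 1L) stop("n must be >= 1")
  if (length(activity) == 0L) stop("empty activity series")
  if (length(frames) != length(activity))
    stop("frames and activity lengths differ")
  short <- length(activity) < n
  if (short) {
    warning("fewer than ", n, " frames available; using all ",
            length(activity))
    sel <- frames
  } else {
    o <- order(-activity, frames)[seq_len(n)]
    sel <- frames[o]
  }
  structure(sort(as.integer(sel)), short_series = short)
}

#' Per-fish kinematic summary over the most-active frames
#'
#' Restricts a track's speed and curvature series to the fish's
#' `n_active` most-active frames and summarises them: `mean_velocity` is
#' the mean instantaneous speed there and `range_of_movement` the
#' max - min of the per-frame curvature scalars there. One such summary
#' per fish is the unit of downstream group comparisons.
#'
#' @param track a `fish_track` (should already have passed
#'   [filter_short_tracks()]).
#' @param speeds the track's [instantaneous_speeds()].
#' @param curvatures per-frame curvature scalars: either a numeric
#'   vector named by frame index, or a data.frame with columns `frame`
#'   and `curvature`.
#' @param n_active number of most-active frames to use (default 100).
#' @return object of class `fish_summary`: list with `fish_id`,
#'   `mean_velocity` (px/frame, or mm/s if the speed series is
#'   calibrated), `range_of_movement`, `n_frames_used`, `short_series`.
#' @export
summarize_fish <- function(track, speeds, curvatures, n_active = 100L) {
  stopifnot(inherits(track, "fish_track"))
  if (is.data.frame(curvatures)) {
    curv <- curvatures$curvature
    cframes <- as.integer(curvatures$frame)
  } else {
    curv <- as.numeric(curvatures)
    cframes <- if (!is.null(names(curvatures)))
      as.integer(names(curvatures)) else seq_along(curvatures)
  }
  sel <- suppressWarnings(
    select_active_frames(speeds$speeds, n = n_active, frames = speeds$frames))
  vsel <- speeds$speeds[match(sel, speeds$frames)]
  csel <- curv[match(sel, cframes)]
  csel <- csel[!is.na(csel)]
  if (length(csel) == 0L)
    stop("no curvature values on the selected active frames")
  mv <- mean(vsel)
  if (!is.null(speeds$pixel_scale))
    mv <- mv * speeds$fps * speeds$pixel_scale
  structure(list(fish_id = track$track_id,
                 mean_velocity = mv,
                 range_of_movement = range_of_movement(csel),
                 n_frames_used = length(sel),
                 short_series = isTRUE(attr(sel, "short_series"))),
            class = "fish_summary")
}

#' Fixed-effects two-way ANOVA for balanced designs
#'
#' Two-way analysis of variance with interaction for per-fish summary
#' values crossed by two factors (e.g. genotype x sex, or genotype x
#' session). Only balanced designs (equal cell counts) are accepted, so
#' type I and type II sums of squares coincide and the decomposition is
#' unambiguous. With one observation per cell the interaction is
#' inestimable and is dropped, which is noted in the result.
#'
#' @param data data.frame with the response and the two factors.
#' @param response,factor_a,factor_b column names.
#' @return object of class `anova_table`: data.frame with columns
#'   `term`, `df`, `sum_sq`, `mean_sq`, `statistic`, `p.value` (residual
#'   row included), with attribute `note` when the interaction was
#'   dropped.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  for (col in c(response, factor_a, factor_b))
    if (!col %in% names(data)) stop("column not found: ", col)
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("each factor needs at least 2 levels")
  if (anyNA(y) || anyNA(A) || anyNA(B)) stop("missing values in design")
  cells <- table(A, B)
  if (any(cells == 0L)) stop("empty design cell")
  if (length(unique(as.vector(cells))) != 1L)
    stop("unbalanced design: two_way_anova requires equal cell counts")
  per_cell <- cells[1L]
  note <- NULL
  if (per_cell == 1L) {
    note <- "single observation per cell: interaction dropped"
    fit <- stats::lm(y ~ A + B)
  } else {
    fit <- stats::lm(y ~ A * B)
  }
  an <- stats::anova(fit)
  terms <- rownames(an)
  terms[terms == "A"] <- factor_a
  terms[terms == "B"] <- factor_b
  terms[terms == "A:B"] <- paste0(factor_a, ":", factor_b)
  terms[terms == "Residuals"] <- "residual"
  out <- data.frame(term = terms, df = an$Df, sum_sq = an$`Sum Sq`,
                    mean_sq = an$`Mean Sq`, statistic = an$`F value`,
                    p.value = an$`Pr(>F)`, row.names = NULL)
  structure(out, class = c("anova_table", "data.frame"), note = note)
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons, clipped to `[0, 1]`.
#' Monotone in both `p` and `m`.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param m number of comparisons (default: `length(p_values)`).
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p_values, m = length(p_values)) {
  if (m < 1L) stop("m must be >= 1")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must be in [0, 1]")
  pmin(pmax(1 - (1 - p_values)^m, 0), 1)
}

#' Fish body mass index
#'
#' `BMI = weight / length^2`, in g/cm^2.
#'
#' @param weight weight in grams, `> 0`.
#' @param length length in cm, `> 0`.
#' @return BMI in g/cm^2. Vectorised.
#' @export
bmi <- function(weight, length) {
  check_positive(weight, "weight"); check_positive(length, "length")
  weight / length^2
}

#' Fulton's condition factor K
#'
#' `K = 100 * weight / length^3` (dimensionless for weight in g, length
#' in cm); invariant under isometric growth.
#'
#' @inheritParams bmi
#' @return K. Vectorised.
#' @export
fulton_k <- function(weight, length) {
  check_positive(weight, "weight"); check_positive(length, "length")
  100 * weight / length^3
}

check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(what, " must be positive and finite")
}

#' Add morphometric indices to a weight/length table
#'
#' @param records data.frame with columns `weight_g` and `length_cm`
#'   (other columns such as fish_id, sex, genotype pass through).
#' @return the data.frame with `bmi` and `fulton_k` columns appended.
#' @export
morphometrics <- function(records) {
  if (!all(c("weight_g", "length_cm") %in% names(records)))
    stop("records must have weight_g and length_cm columns")
  records$bmi <- bmi(records$weight_g, records$length_cm)
  records$fulton_k <- fulton_k(records$weight_g, records$length_cm)
  records
}

#' Chi-square test of Mendelian segregation
#'
#' Goodness-of-fit chi-square (no continuity correction) of observed
#' genotype-class counts against expected Mendelian ratios, e.g.
#' `c(1, 15)` for the double-homozygote class out of a double
#' heterozygote incross. `df = classes - 1`; the p-value is the upper
#' tail of the chi-square distribution.
#'
#' @param observed non-negative integer counts per genotype class.
#' @param expected_ratio positive expected weights, same length.
#' @return list of class `mendelian_chi2` with `statistic`, `df`,
#'   `p.value`, `observed`, `expected`.
#' @examples
#' mendelian_chi2(c(7, 131), c(1, 15))  # P = 0.567
#' @export
mendelian_chi2 <- function(observed, expected_ratio) {
  if (length(observed) != length(expected_ratio) || length(observed) < 2L)
    stop("observed and expected_ratio must have equal length >= 2")
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed must be non-negative integers")
  if (any(expected_ratio <= 0)) stop("expected ratios must be positive")
  total <- sum(observed)
  if (total <= 0) stop("total observed count must be positive")
  expected <- total * expected_ratio / sum(expected_ratio)
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = observed, expected = expected),
            class = "mendelian_chi2")
}

#' @export
print.mendelian_chi2 <- function(x, ...) {
  cat(sprintf("Mendelian segregation chi-square: X2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  cat("observed:", paste(x$observed, collapse = ", "),
      " expected:", paste(signif(x$expected, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Genotype class percentage at printed precision
#'
#' @param k class count, `0 <= k <= n`.
#' @param n total genotyped, `> 0`.
#' @param digits decimal places to round to (0 for whole percent).
#' @return `100 * k / n`, rounded.
#' @export
genotype_percent <- function(k, n, digits = 0L) {
  if (n <= 0) stop("n must be positive")
  if (any(k < 0) || any(k > n)) stop("k must be between 0 and n")
  round(100 * k / n, digits)
}
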