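test_that("most-active frame selection is a top-n by activity", {
  act <- rep(0, 200); act[50:149] <- 10
  sel <- select_active_frames(act, n = 100)
  expect_equal(as.integer(sel), 50:149)
  expect_false(attr(sel, "short_series"))
  # fewer frames than requested: all returned, flagged
  expect_warning(s2 <- select_active_frames(rep(1, 80), n = 100), "fewer")
  expect_length(s2, 80L)
  expect_true(attr(s2, "short_series"))
  # random activities against a full sort oracle
  set.seed(31)
  a <- runif(500)
  sel3 <- select_active_frames(a, n = 100)
  oracle <- sort(order(a, decreasing = TRUE)[1:100])
  expect_equal(as.integer(sel3), oracle)
  # ties break toward the earlier frame
  tie <- c(5, 5, 5, 1)
  expect_equal(as.integer(select_active_frames(tie, n = 2)), c(1L, 2L))
  expect_error(select_active_frames(numeric(0)), "empty")
})

test_that("per-fish summaries restrict to the active frames", {
  n <- 120
  trk <- build_tracks(detections_from_centroids(
    lapply(seq_len(n), function(f) cbind(x = 5 * f, y = 0))), 150)[[1]]
  sp <- instantaneous_speeds(trk, fps = 24.96)
  curv <- data.frame(frame = seq_len(n), curvature = 0.1)
  s <- summarize_fish(trk, sp, curv, n_active = 100)
  expect_equal(s$mean_velocity, 5)
  expect_equal(s$range_of_movement, 0)
  expect_equal(s$n_frames_used, 100L)
  # track with exactly 100 speed steps: all used, not flagged short
  trk2 <- build_tracks(detections_from_centroids(
    lapply(1:101, function(f) cbind(x = 2 * f, y = 0))), 150)[[1]]
  sp2 <- instantaneous_speeds(trk2, fps = 24.96)
  s2 <- summarize_fish(trk2, sp2,
                       data.frame(frame = 1:101, curvature = runif(101)),
                       n_active = 100)
  expect_equal(s2$n_frames_used, 100L)
  expect_false(s2$short_series)
  # disjoint curvature frames error
  expect_error(summarize_fish(trk, sp,
                              data.frame(frame = 500:600, curvature = 0)),
               "no curvature")
})

test_that("two-way ANOVA matches an independent cell-means decomposition", {
  # balanced 2 x 3 with integer values; oracle computed from cell means
  df <- expand.grid(a = c("wt", "mut"), b = c("s1", "s2", "s3"),
                    rep = 1:4, stringsAsFactors = FALSE)
  set.seed(12)
  df$y <- as.numeric(sample(1:20, nrow(df), replace = TRUE))
  tab <- two_way_anova(df, "y", "a", "b")
  grand <- mean(df$y)
  am <- tapply(df$y, df$a, mean); bm <- tapply(df$y, df$b, mean)
  cm <- tapply(df$y, list(df$a, df$b), mean)
  n_a <- 12; n_b <- 8; n_cell <- 4
  ss_a <- n_a * sum((am - grand)^2)
  ss_b <- n_b * sum((bm - grand)^2)
  ss_cells <- n_cell * sum((cm - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((df$y - cm[cbind(df$a, df$b)])^2)
  get <- function(term) tab$sum_sq[tab$term == term]
  expect_equal(get("a"), ss_a, tolerance = 1e-10)
  expect_equal(get("b"), ss_b, tolerance = 1e-10)
  expect_equal(get("a:b"), ss_ab, tolerance = 1e-10)
  expect_equal(get("residual"), ss_res, tolerance = 1e-10)
  expect_equal(tab$df, c(1L, 2L, 2L, 18L))
  expect_equal(sum(tab$df), nrow(df) - 1L)
  # F and p from the decomposition
  expect_equal(tab$statistic[1], (ss_a / 1) / (ss_res / 18),
               tolerance = 1e-10)
  expect_equal(tab$p.value[1],
               pf((ss_a / 1) / (ss_res / 18), 1, 18, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("ANOVA edge cases: null effects, one obs per cell, imbalance", {
  # equal cell means, nonzero residual variance -> F = 0
  df <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:2)
  df$y <- c(1, 1, 1, 1, 3, 3, 3, 3)  # every cell holds {1, 3}
  tab <- two_way_anova(df, "y", "a", "b")
  eff <- tab[tab$term != "residual", ]
  expect_true(all(abs(eff$statistic) < 1e-10))
  expect_true(all(eff$p.value > 0.99))
  # single observation per cell: interaction dropped with a note
  df1 <- expand.grid(a = c("x", "y"), b = c("u", "v"))
  df1$y <- c(1, 2, 3, 5)
  tab1 <- two_way_anova(df1, "y", "a", "b")
  expect_false("a:b" %in% tab1$term)
  expect_match(attr(tab1, "note"), "interaction dropped")
  # unbalanced designs are refused
  df2 <- rbind(df, df[1, ])
  expect_error(two_way_anova(df2, "y", "a", "b"), "unbalanced")
  expect_error(two_way_anova(df[df$a == "x", ], "y", "a", "b"), "2 levels")
})

test_that("a genuine additive effect is detected at n = 6 per cell", {
  set.seed(77)
  hits <- 0L
  for (rep in 1:10) {
    df <- expand.grid(geno = c("het", "hom"), sex = c("m", "f"), i = 1:6)
    df$y <- rnorm(nrow(df), 10, 1) + ifelse(df$geno == "hom", -2, 0)
    tab <- two_way_anova(df, "y", "geno", "sex")
    if (tab$p.value[tab$term == "geno"] < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("Sidak adjustment is exact and monotone", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.01, 3), 1 - 0.99^3)
  expect_equal(sidak_adjust(0.01, 3), 0.029701)
  expect_equal(sidak_adjust(1, 7), 1)
  expect_equal(sidak_adjust(0, 5), 0)
  p <- seq(0, 1, by = 0.1)
  expect_true(all(diff(sidak_adjust(p, 4)) >= 0))
  expect_true(all(sidak_adjust(p, 5) >= sidak_adjust(p, 2)))
  expect_error(sidak_adjust(1.2, 2), "\\[0, 1\\]")
})

test_that("BMI and Fulton's K follow their defining formulas", {
  expect_equal(bmi(0.5, 3), 0.5 / 9)
  expect_equal(bmi(1, 1), 1)
  expect_equal(fulton_k(0.5, 3), 100 * 0.5 / 27)
  expect_equal(fulton_k(1, 10), 0.1)
  set.seed(2)
  w <- runif(20, 0.1, 2); l <- runif(20, 1, 6)
  expect_equal(bmi(w, 2 * l), bmi(w, l) / 4)          # BMI ~ length^-2
  expect_equal(fulton_k(8 * w, 2 * l), fulton_k(w, l)) # isometric invariance
  expect_error(bmi(0, 3), "positive")
  expect_error(fulton_k(1, -2), "positive")
  rec <- morphometrics(data.frame(fish_id = 1:2, weight_g = c(0.5, 1),
                                  length_cm = c(3, 10)))
  expect_equal(rec$bmi, c(0.5 / 9, 0.01))
  expect_equal(rec$fulton_k, c(100 * 0.5 / 27, 0.1))
})

test_that("Mendelian chi-square reproduces the segregation worked examples", {
  a <- mendelian_chi2(c(7, 131), c(1, 15))
  expect_equal(a$statistic, 0.327, tolerance = 0.002)
  expect_equal(a$df, 1L)
  expect_lte(abs(a$p.value - 0.567), 0.001)
  b <- mendelian_chi2(c(0, 104), c(1, 15))
  expect_equal(round(b$p.value, 3), 0.008)
  expect_equal(b$statistic, 6.933, tolerance = 1e-3)
  # exactly proportional counts
  c0 <- mendelian_chi2(c(10, 150), c(1, 15))
  expect_equal(c0$statistic, 0)
  expect_equal(c0$p.value, 1)
  expect_error(mendelian_chi2(c(-1, 5), c(1, 1)), "non-negative")
  expect_error(mendelian_chi2(c(1, 5), c(0, 1)), "positive")
})

test_that("chi-square p decreases as counts move away from expectation", {
  total <- 160
  ps <- vapply(0:10, function(k)
    mendelian_chi2(c(k, total - k), c(1, 15))$p.value, numeric(1))
  # expectation is 10: p increases to k = 10
  expect_true(all(diff(ps) > 0))
  ps2 <- vapply(10:40, function(k)
    mendelian_chi2(c(k, total - k), c(1, 15))$p.value, numeric(1))
  expect_true(all(diff(ps2) < 0))
})

test_that("genotype percentages round at the printed precision", {
  expect_equal(genotype_percent(28, 107), 26)
  expect_equal(genotype_percent(9, 39), 23)
  expect_equal(genotype_percent(22, 533, digits = 1), 4.1)
  expect_equal(genotype_percent(0, 41), 0)
  expect_error(genotype_percent(5, 0), "positive")
  expect_error(genotype_percent(6, 5), "between")
})
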