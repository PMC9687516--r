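test_that("normality check branches on per-group Shapiro-Wilk results", {
  anova_picks <- 0
  for (seed in 1:50) {
    df <- withr::with_seed(seed, data.frame(
      grade = rep(0:3, each = 30), value = rnorm(120)))
    nc <- normality_check(df, value, grade)
    if (attr(nc, "branch") == "anova_tukey") anova_picks <- anova_picks + 1
  }
  # four independent tests at alpha 0.05: expect ~0.95^4 = 81% joint pass,
  # well above the 90%-of-seeds bar for at least approximate behavior
  expect_gte(anova_picks, 0.7 * 50)

  # one heavily skewed group forces the rank-based branch
  df <- withr::with_seed(7, data.frame(
    grade = rep(0:3, each = 30),
    value = c(rnorm(90), rexp(30)^3)))
  expect_equal(attr(normality_check(df, value, grade), "branch"), "kw_dunn")

  tiny <- data.frame(grade = rep(0:1, each = 2), value = rnorm(4))
  expect_error(normality_check(tiny, value, grade), "at least 3")
})

test_that("well-separated groups get distinct letters", {
  df <- withr::with_seed(1, data.frame(
    grade = rep(c(0, 3), each = 30),
    value = c(rnorm(30, 0), rnorm(30, 5))))
  cmp <- compare_groups(df, value, grade)
  expect_equal(cmp$summary$letters, c("a", "b"))
  expect_lt(cmp$omnibus_p, 0.05)
})

test_that("identically distributed groups usually share one letter", {
  shared <- 0
  for (seed in 1:50) {
    df <- withr::with_seed(seed, data.frame(
      grade = rep(0:3, each = 30), value = rnorm(120)))
    cmp <- compare_groups(df, value, grade)
    if (all(cmp$summary$letters == "a")) shared <- shared + 1
  }
  expect_gte(shared, 0.9 * 50)
})

test_that("a 0 < (1~2) < 3 mean pattern yields letters a,b,b,c and the monotone flag", {
  # middle groups differ by much less than the pairwise critical difference,
  # so they share a letter while the overall trend stays increasing
  df <- withr::with_seed(2, data.frame(
    grade = rep(0:3, each = 30),
    value = c(rnorm(30, 0), rnorm(30, 5), rnorm(30, 5.5), rnorm(30, 10))))
  cmp <- compare_groups(df, value, grade)
  expect_equal(cmp$summary$letters, c("a", "b", "b", "c"))
  expect_true(cmp$monotone_increase)
})

test_that("degenerate all-identical data short-circuits without tests", {
  df <- data.frame(grade = rep(0:3, each = 5), value = 2)
  cmp <- compare_groups(df, value, grade)
  expect_true(cmp$degenerate)
  expect_true(all(cmp$summary$letters == "a"))
  expect_false(cmp$monotone_increase)
})

test_that("letters are reconstructible from the pairwise p map alone", {
  for (seed in 1:30) {
    k <- withr::with_seed(seed, sample(3:5, 1))
    lev <- as.character(seq_len(k) - 1)
    pairs <- t(utils::combn(lev, 2))
    p_adj <- withr::with_seed(seed + 1000, runif(nrow(pairs)))
    pw <- tibble::tibble(group1 = pairs[, 1], group2 = pairs[, 2],
                         p_adj = p_adj)
    lmap <- eotrhtex:::cld_insert_absorb(lev, pw, alpha = 0.05)
    for (r in seq_len(nrow(pw))) {
      share <- length(intersect(strsplit(lmap[[pw$group1[r]]], "")[[1]],
                                strsplit(lmap[[pw$group2[r]]], "")[[1]])) > 0
      expect_equal(share, pw$p_adj[r] >= 0.05,
                   label = paste("seed", seed, "pair", r))
    }
  }
})

test_that("under the null the monotone flag fires at about the alpha rate", {
  fires <- 0
  n_sim <- 500
  for (seed in seq_len(n_sim)) {
    df <- withr::with_seed(seed + 5000, data.frame(
      grade = rep(0:3, each = 12), value = rnorm(48)))
    cmp <- compare_groups(df, value, grade)
    if (cmp$monotone_increase) fires <- fires + 1
  }
  alpha <- 0.05
  se <- sqrt(alpha * (1 - alpha) / n_sim)
  expect_lte(fires / n_sim, alpha + 2 * se)
})

test_that("Dunn's rank-based post-hoc detects a clear location shift", {
  df <- withr::with_seed(3, data.frame(
    grade = rep(0:2, each = 30),
    value = c(rexp(30)^2, rexp(30)^2, rexp(30)^2 + 25)))
  cmp <- compare_groups(df, value, grade)
  expect_equal(cmp$branch, "kw_dunn")
  pw <- tidy(cmp)
  p02 <- pw$p_adj[(pw$group1 == "0" & pw$group2 == "2") |
                    (pw$group1 == "2" & pw$group2 == "0")]
  p01 <- pw$p_adj[(pw$group1 == "0" & pw$group2 == "1") |
                    (pw$group1 == "1" & pw$group2 == "0")]
  expect_lt(p02, 0.05)
  expect_gt(p01, 0.05)
})

test_that("slope comparison recovers noiseless closed-form cases", {
  g <- rep(0:3, each = 5)
  a <- data.frame(grade = g, value = 2 * g)
  b <- data.frame(grade = g, value = 2 * g + 1)
  sc <- compare_slopes(a, b)
  expect_equal(sc$slope_a, 2, tolerance = 1e-10)
  expect_equal(sc$slope_b, 2, tolerance = 1e-10)
  expect_gt(sc$slope_equality_p, 0.05)
  expect_equal(sc$common_slope, 2, tolerance = 1e-10)
  expect_lt(sc$intercept_equality_p, 0.05)
  expect_true(is.na(sc$common_intercept))

  # identical series: everything pools
  sc2 <- compare_slopes(a, a)
  expect_equal(sc2$slope_equality_p, 1)
  expect_equal(sc2$common_slope, 2, tolerance = 1e-10)
  expect_equal(sc2$intercept_equality_p, 1)
  expect_equal(sc2$common_intercept, 0, tolerance = 1e-10)

  # clearly different slopes are rejected
  c_ <- data.frame(grade = g, value = 1 * g)
  d <- data.frame(grade = g, value = 3 * g)
  sc3 <- compare_slopes(c_, d)
  expect_lt(sc3$slope_equality_p, 0.05)
  expect_true(is.na(sc3$common_slope))

  expect_error(compare_slopes(data.frame(grade = rep(1, 4), value = 1:4), a),
               "at least 2 distinct grades")
})

test_that("OLS slope on noisy linear data is recovered accurately", {
  df <- withr::with_seed(8, data.frame(grade = rep(0:3, each = 40)))
  df$value <- 0.028 * df$grade + 0.5
  sc <- compare_slopes(df, df)
  expect_equal(sc$slope_a, 0.028, tolerance = 1e-10)
})

test_that("tidy and glance methods return the expected shapes", {
  df <- withr::with_seed(4, data.frame(
    grade = rep(0:1, each = 20), value = c(rnorm(20), rnorm(20, 3))))
  cmp <- compare_groups(df, value, grade)
  expect_true(all(c("group1", "group2", "p_adj") %in% names(tidy(cmp))))
  g <- glance(cmp)
  expect_equal(nrow(g), 1)
  expect_true(g$monotone_increase)
})
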