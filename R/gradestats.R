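#' Per-group normality check and test-branch decision
#'
#' Applies a Shapiro-Wilk test to each group independently. The parametric
#' branch (one-way ANOVA with Tukey's HSD) is taken only when every group
#' passes at `alpha`; otherwise the rank-based branch (Kruskal-Wallis with
#' Dunn's post-hoc tests) is used.
#'
#' @param data Data frame with at least the value and group columns.
#' @param value,group Column names (tidy-eval) holding the measure values
#'   and group labels.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per group (`group`, `n`, `shapiro_p`,
#'   `normal`) and attribute `branch` (`"anova_tukey"` or `"kw_dunn"`).
#' @export
normality_check <- function(data, value, group, alpha = 0.05) {
  df <- dplyr::tibble(value = dplyr::pull(data, {{ value }}),
                      group = dplyr::pull(data, {{ group }}))
  out <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  if (any(out$n < 3)) {
    stop("each group needs at least 3 observations for the Shapiro-Wilk ",
         "test; smallest group has ", min(out$n))
  }
  out$shapiro_p <- vapply(out$group, function(g) {
    x <- df$value[df$group == g]
    if (sd(x) == 0) return(0) # degenerate sample: treat as non-Gaussian
    shapiro.test(x)$p.value
  }, numeric(1))
  out$normal <- out$shapiro_p >= alpha
  attr(out, "branch") <- if (all(out$normal)) "anova_tukey" else "kw_dunn"
  out
}

# Dunn's rank-based pairwise z-tests after Kruskal-Wallis, with tie
# correction; p-values Bonferroni-adjusted over all pairs
dunn_pairwise <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- sort(unique(groups))
  mean_rank <- vapply(lev, function(g) mean(r[groups == g]), numeric(1))
  n_g <- vapply(lev, function(g) sum(groups == g), numeric(1))
  pairs <- utils::combn(seq_along(lev), 2)
  k <- ncol(pairs)
  res <- vector("list", k)
  for (p in seq_len(k)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[i] + 1 / n_g[j]))
    z <- (mean_rank[i] - mean_rank[j]) / se
    res[[p]] <- tibble::tibble(group1 = lev[i], group2 = lev[j],
                               statistic = z,
                               p_adj = min(1, 2 * pnorm(-abs(z)) * k))
  }
  dplyr::bind_rows(res)
}

# Insert-and-absorb compact letter display. `pairwise` has columns group1,
# group2, p_adj; two groups share a letter iff their adjusted p >= alpha.
cld_insert_absorb <- function(levels, pairwise, alpha = 0.05) {
  cols <- list(levels)
  sig <- pairwise[!is.na(pairwise$p_adj) & pairwise$p_adj < alpha, ,
                  drop = FALSE]
  absorb <- function(cols) {
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a != b && keep[b] && all(cols[[a]] %in% cols[[b]]) &&
            (length(cols[[a]]) < length(cols[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    cols[keep]
  }
  for (p in seq_len(nrow(sig))) {
    g1 <- sig$group1[p]; g2 <- sig$group2[p]
    new_cols <- list()
    for (col in cols) {
      if (g1 %in% col && g2 %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, g1)),
                      list(setdiff(col, g2)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    cols <- absorb(new_cols)
  }
  # stable ordering: by the first (lowest) group each column contains
  ord <- order(vapply(cols, function(col) min(match(col, levels)),
                      numeric(1)))
  cols <- cols[ord]
  letters_map <- stats::setNames(vector("list", length(levels)), levels)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) {
      letters_map[[as.character(g)]] <-
        c(letters_map[[as.character(g)]], letters[ci])
    }
  }
  vapply(letters_map, function(l) paste(sort(l), collapse = ""), character(1))
}

#' Compare a measure between ordered groups
#'
#' Branches on per-group normality ([normality_check()]): one-way ANOVA with
#' Tukey's HSD for Gaussian data, Kruskal-Wallis with Bonferroni-adjusted
#' Dunn tests otherwise. Groups are labelled with a compact letter display
#' (two groups share a letter iff not significantly different). The
#' `monotone_increase` flag marks the grade-related-increase pattern: group
#' means non-decreasing in group order and a significant difference between
#' the lowest and highest group.
#'
#' @inheritParams normality_check
#' @return A `grade_comparison` object: list with `branch`, `omnibus_p`,
#'   `summary` (group, n, mean, sd, letters), `pairwise` (group1, group2,
#'   p_adj), `monotone_increase`, `degenerate`, `alpha`.
#' @export
compare_groups <- function(data, value, group, alpha = 0.05) {
  df <- dplyr::tibble(value = dplyr::pull(data, {{ value }}),
                      group = dplyr::pull(data, {{ group }}))
  df <- df[is.finite(df$value), ]
  lev <- sort(unique(df$group))
  if (length(lev) < 2) stop("need at least 2 groups to compare")
  summary_tbl <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$group)
  if (sd(df$value) == 0) {
    summary_tbl$letters <- "a"
    out <- list(branch = NA_character_, omnibus_p = NA_real_,
                summary = summary_tbl,
                pairwise = tibble::tibble(group1 = character(),
                                          group2 = character(),
                                          p_adj = numeric()),
                monotone_increase = FALSE, degenerate = TRUE, alpha = alpha)
    return(structure(out, class = "grade_comparison"))
  }
  branch <- attr(normality_check(df, value, group, alpha), "branch")
  gf <- factor(df$group, levels = lev)
  if (branch == "anova_tukey") {
    fit <- aov(value ~ gf, data = df)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$gf
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- tibble::tibble(
      group1 = vapply(nm, `[`, character(1), 2),
      group2 = vapply(nm, `[`, character(1), 1),
      p_adj = tk[, "p adj"])
  } else {
    omnibus_p <- kruskal.test(df$value, gf)$p.value
    pairwise <- dunn_pairwise(df$value, as.character(df$group))
  }
  pairwise$group1 <- as.character(pairwise$group1)
  pairwise$group2 <- as.character(pairwise$group2)
  letters_map <- cld_insert_absorb(as.character(lev), pairwise, alpha)
  summary_tbl$letters <- unname(letters_map[as.character(summary_tbl$group)])
  extreme <- pairwise[
    (pairwise$group1 == as.character(lev[1]) &
       pairwise$group2 == as.character(lev[length(lev)])) |
    (pairwise$group2 == as.character(lev[1]) &
       pairwise$group1 == as.character(lev[length(lev)])), ]
  monotone <- all(diff(summary_tbl$mean) >= 0) &&
    nrow(extreme) > 0 && extreme$p_adj[1] < alpha
  out <- list(branch = branch, omnibus_p = omnibus_p, summary = summary_tbl,
              pairwise = pairwise, monotone_increase = monotone,
              degenerate = FALSE, alpha = alpha)
  structure(out, class = "grade_comparison")
}

#' @export
print.grade_comparison <- function(x, ...) {
  cat("Grade comparison (", if (is.na(x$branch)) "degenerate" else x$branch,
      "), omnibus p = ", format.pval(x$omnibus_p, digits = 3), "\n", sep = "")
  print(x$summary)
  if (x$monotone_increase) cat("Monotone increase across groups: yes\n")
  invisible(x)
}

#' @export
tidy.grade_comparison <- function(x, ...) x$pairwise

#' @export
glance.grade_comparison <- function(x, ...) {
  tibble::tibble(branch = x$branch, omnibus_p = x$omnibus_p,
                 n_groups = nrow(x$summary),
                 monotone_increase = x$monotone_increase,
                 degenerate = x$degenerate)
}

# F-test comparing nested linear models, robust to zero residual variance:
# an extra sum of squares below tol counts as "no difference" (p = 1)
nested_f_test <- function(fit_small, fit_big, tol = 1e-10) {
  rss_small <- sum(residuals(fit_small)^2)
  rss_big <- sum(residuals(fit_big)^2)
  df_extra <- fit_small$df.residual - fit_big$df.residual
  ss_extra <- rss_small - rss_big
  scale <- mean(fitted(fit_big)^2) + 1
  if (ss_extra < tol * scale) return(1)
  if (rss_big < tol * scale) return(0)
  f <- (ss_extra / df_extra) / (rss_big / fit_big$df.residual)
  stats::pf(f, df_extra, fit_big$df.residual, lower.tail = FALSE)
}

#' Regression-based similarity of two measure-versus-grade series
#'
#' Fits ordinary least squares of value on (numeric) grade separately for
#' the two series, then tests slope equality via the interaction term of the
#' pooled model. When the slopes do not differ (`p > alpha`), a common slope
#' is estimated from the additive model and the intercepts are compared;
#' when those do not differ either, a common intercept is reported. This is
#' the sequential similarity logic used for comparing an entropy measure's
#' grade trend against each GLCM feature's.
#'
#' @param series_a,series_b Data frames with numeric columns `grade` and
#'   `value`, each spanning at least two distinct grades.
#' @param alpha Significance level for the sequential tests.
#' @return A `slope_comparison` object with slopes, intercepts, the
#'   equality p-values, and common slope/intercept where pooled.
#' @export
compare_slopes <- function(series_a, series_b, alpha = 0.05) {
  for (s in list(series_a, series_b)) {
    if (!all(c("grade", "value") %in% names(s))) {
      stop("each series needs columns 'grade' and 'value'")
    }
    if (length(unique(s$grade)) < 2) {
      stop("each series must span at least 2 distinct grades")
    }
  }
  fa <- lm(value ~ grade, data = series_a)
  fb <- lm(value ~ grade, data = series_b)
  pooled <- dplyr::bind_rows(
    dplyr::mutate(series_a[c("grade", "value")], series = "A"),
    dplyr::mutate(series_b[c("grade", "value")], series = "B"))
  fit_add <- lm(value ~ grade + series, data = pooled)
  fit_int <- lm(value ~ grade * series, data = pooled)
  slope_p <- nested_f_test(fit_add, fit_int)
  out <- list(slope_a = unname(coef(fa)["grade"]),
              slope_b = unname(coef(fb)["grade"]),
              intercept_a = unname(coef(fa)["(Intercept)"]),
              intercept_b = unname(coef(fb)["(Intercept)"]),
              slope_equality_p = slope_p,
              common_slope = NA_real_,
              intercept_equality_p = NA_real_,
              common_intercept = NA_real_,
              alpha = alpha)
  if (slope_p > alpha) {
    out$common_slope <- unname(coef(fit_add)["grade"])
    fit_pool <- lm(value ~ grade, data = pooled)
    out$intercept_equality_p <- nested_f_test(fit_pool, fit_add)
    if (out$intercept_equality_p > alpha) {
      out$common_intercept <- unname(coef(fit_pool)["(Intercept)"])
    }
  }
  structure(out, class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat("Slopes: A =", signif(x$slope_a, 4), ", B =", signif(x$slope_b, 4),
      "; equality p =", format.pval(x$slope_equality_p, digits = 3), "\n")
  if (!is.na(x$common_slope)) {
    cat("Common slope:", signif(x$common_slope, 4),
        "; intercept equality p =",
        format.pval(x$intercept_equality_p, digits = 3), "\n")
  }
  invisible(x)
}

#' @export
tidy.slope_comparison <- function(x, ...) {
  tibble::tibble(term = c("slope_a", "slope_b", "intercept_a", "intercept_b",
                          "common_slope", "common_intercept"),
                 estimate = c(x$slope_a, x$slope_b, x$intercept_a,
                              x$intercept_b, x$common_slope,
                              x$common_intercept))
}

#' @export
glance.slope_comparison <- function(x, ...) {
  tibble::tibble(slope_equality_p = x$slope_equality_p,
                 intercept_equality_p = x$intercept_equality_p,
                 slopes_pooled = !is.na(x$common_slope),
                 intercepts_pooled = !is.na(x$common_intercept))
}
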