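test_that("threshold statistics use the sample SD", {
  expect_equal(compute_threshold(c(0, 2), threshold_rule("mean")), 1)
  expect_equal(compute_threshold(c(0, 2), threshold_rule("mean_plus_sd")),
               1 + sqrt(2))
  expect_equal(compute_threshold(c(0, 2), threshold_rule("mean_plus_2sd")),
               1 + 2 * sqrt(2))
  expect_error(compute_threshold(numeric(0)), "empty reference")
})

test_that("classification is strict-above with ties to the negative class", {
  cm <- classify_by_threshold(c(10, 11), c(1, 2), 5)
  expect_equal(cm, c(TP = 2L, FP = 0L, FN = 0L, TN = 2L))
  # all values equal to the threshold: nothing is called positive
  cm2 <- classify_by_threshold(rep(3, 4), rep(3, 6), 3)
  expect_equal(cm2, c(TP = 0L, FP = 0L, FN = 4L, TN = 6L))
  # positive_below mirrors the rule
  cm3 <- classify_by_threshold(c(1, 2), c(10, 11), 5,
                               direction = "positive_below")
  expect_equal(cm3, c(TP = 2L, FP = 0L, FN = 0L, TN = 2L))
})

test_that("accuracy ratios follow the standard formulae with NA when undefined", {
  m <- accuracy_metrics(c(TP = 4, FP = 2, FN = 4, TN = 35))
  v <- setNames(m$value, m$metric)
  expect_equal(v[["Se"]], 0.5)
  expect_equal(v[["Sp"]], 35 / 37)
  expect_equal(v[["PPV"]], 4 / 6)
  expect_equal(v[["NPV"]], 35 / 39)
  und <- accuracy_metrics(c(TP = 0, FP = 0, FN = 8, TN = 37))
  expect_true(is.na(und$value[und$metric == "PPV"]))
  expect_equal(und$value_2dp[und$metric == "NPV"], 0.82)
})

test_that("half-up rounding matches diagnostic table conventions", {
  expect_equal(eotrhtex:::round_half_up(0.125, 2), 0.13)
  expect_equal(eotrhtex:::round_half_up(0.665, 2), 0.67)
  m <- accuracy_metrics(c(TP = 1, FP = 0, FN = 7, TN = 37))
  expect_equal(m$value_2dp[m$metric == "Se"], 0.13) # 1/8 = 0.125
})

test_that("metrics are symmetric under class-label and direction swap", {
  pos <- c(2, 7, 9); neg <- c(1, 3, 4, 8)
  thr <- 5
  cm <- classify_by_threshold(pos, neg, thr)
  cm_sw <- classify_by_threshold(neg, pos, thr, direction = "positive_below")
  # swapping classes and direction exchanges TP<->TN and FP<->FN... except
  # ties: none of the values equal the threshold here
  expect_equal(cm[["TP"]], cm_sw[["TN"]])
  expect_equal(cm[["FP"]], cm_sw[["FN"]])
  m <- accuracy_metrics(cm); m_sw <- accuracy_metrics(cm_sw)
  expect_equal(m$value[m$metric == "Se"], m_sw$value[m_sw$metric == "Sp"])
  expect_equal(m$value[m$metric == "PPV"], m_sw$value[m_sw$metric == "NPV"])
})

test_that("detect_grades reports three rules with monotone TP/FP counts", {
  feats <- fake_features(list(
    "0" = withr::with_seed(1, rnorm(37, 0.80, 0.02)),
    "3" = withr::with_seed(2, rnorm(8, 0.86, 0.03))))
  rep_ <- detect_grades(feats, "DistEn2D", "normalize")
  expect_equal(sort(unique(rep_$rule)),
               c("mean", "mean_plus_2sd", "mean_plus_sd"))
  wide <- unique(rep_[c("rule", "TP", "FP")])
  wide <- wide[match(c("mean", "mean_plus_sd", "mean_plus_2sd"),
                     wide$rule), ]
  expect_true(all(diff(wide$TP) <= 0))
  expect_true(all(diff(wide$FP) <= 0))
  expect_error(detect_grades(feats[feats$grade == 0, ], "DistEn2D",
                             "normalize"),
               "both grade 0 and grade 3")
})

test_that("perfect separation gives Se = Sp = 1 at the mean threshold", {
  feats <- fake_features(list("0" = rep(c(0.1, 0.12), 10),
                              "3" = rep(c(0.9, 0.92), 4)))
  rep_ <- detect_grades(feats, "DistEn2D", "normalize",
                        rules = list(threshold_rule("mean")))
  v <- setNames(rep_$value, rep_$metric)
  expect_equal(v[["Se"]], 1)
  expect_equal(v[["Sp"]], 1)
})

test_that("the detection table renders undefined ratios as a dash", {
  feats <- fake_features(list("0" = rep(c(0.1, 0.12), 10),
                              "3" = c(0.11, 0.12, 0.13, 0.11)))
  rep_ <- detect_grades(feats, "DistEn2D", "normalize")
  tab <- format_detection_table(rep_)
  expect_true(any(tab$shown == "-") || all(is.finite(rep_$value)))
})
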