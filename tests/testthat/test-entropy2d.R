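test_that("sliding window enumeration has the right count, order and content", {
  img <- matrix(1:9, 3, 3, byrow = TRUE)
  W <- roi_windows(img, 2, 2)
  expect_equal(nrow(W), 4) # (3-2+1)^2
  # row-major scan order, row-major flattening
  expect_equal(W[1, ], c(1, 2, 4, 5))
  expect_equal(W[2, ], c(2, 3, 5, 6))
  expect_equal(W[3, ], c(4, 5, 7, 8))
  expect_equal(W[4, ], c(5, 6, 8, 9))
  expect_equal(nrow(roi_windows(img, 3, 3)), 1)
  expect_error(roi_windows(matrix(0, 2, 2), 3, 3), "larger than image")
})

test_that("block downsampling respects the pixel budget via local means", {
  img <- matrix(1, 100, 100)
  out <- downsample_budget(img, 64 * 64)
  expect_equal(dim(out), c(50, 50))
  expect_equal(attr(out, "downsample_factor"), 2)
  expect_true(all(out == 1))
  # within budget: unchanged
  small <- matrix(rnorm(16), 4, 4)
  expect_identical(downsample_budget(small, 4096), small)
  # block means are exact
  img2 <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(as.vector(downsample_budget(img2, 1)), 2.5)
})

test_that("a constant image yields zero for all five entropies", {
  img <- matrix(7, 8, 8)
  suppressWarnings(res <- entropy_suite(img))
  expect_equal(res$measure, c("SampEn2D", "FuzzEn2D", "PermEn2D",
                              "DispEn2D", "DistEn2D"))
  expect_equal(res$value, rep(0, 5))
})

test_that("SampEn2D and FuzzEn2D on small fixtures match brute-force enumeration", {
  cb <- checkerboard(4, 1, 2)
  p1 <- entropy_params(m = 1, r_coeff = 0.2, nf = 2)
  expect_equal(samp_en_2d(cb, p1)$value, oracle_sampen2d(cb, 1, 0.2),
               tolerance = 1e-12)
  expect_equal(fuzz_en_2d(cb, p1)$value, oracle_fuzzen2d(cb, 1, 0.2, 2),
               tolerance = 1e-12)
  # a non-trivial asymmetric fixture at m = 2
  img <- matrix(c(0, 1, 2, 0, 2,
                  1, 0, 1, 2, 0,
                  2, 2, 0, 1, 1,
                  0, 1, 2, 2, 0,
                  1, 0, 0, 1, 2), 5, 5, byrow = TRUE)
  p2 <- entropy_params(m = 2)
  expect_equal(samp_en_2d(img, p2)$value, oracle_sampen2d(img, 2, 0.2),
               tolerance = 1e-12)
  expect_equal(fuzz_en_2d(img, p2)$value, oracle_fuzzen2d(img, 2, 0.2, 2),
               tolerance = 1e-12)
})

test_that("FuzzEn2D is always finite with similarities in (0, 1]", {
  img <- noise_image(10, seed = 3)
  v <- fuzz_en_2d(img)$value
  expect_true(is.finite(v))
})

test_that("PermEn2D identifies ordinal pattern structure", {
  # strictly increasing row-major gradient: one pattern, entropy 0
  grad <- matrix(1:20, 4, 5, byrow = TRUE)
  expect_equal(perm_en_2d(grad)$value, 0)
  # checkerboard on a 4x5 grid: exactly two patterns, 6 windows each -> ln 2
  cb <- matrix(ifelse((row(matrix(0, 4, 5)) +
                         col(matrix(0, 4, 5))) %% 2 == 0, 1, 2), 4, 5)
  expect_equal(perm_en_2d(cb)$value, log(2), tolerance = 1e-12)
  expect_equal(perm_en_2d(cb)$value, oracle_permen2d(cb), tolerance = 1e-12)
})

test_that("DispEn2D matches direct pattern tallies and its entropy bounds", {
  stripes <- matrix(rep(c(0, 10), length.out = 4), 4, 4) # alternating rows
  expect_equal(disp_en_2d(stripes)$value, oracle_dispen2d(stripes),
               tolerance = 1e-12)
  img <- noise_image(32, seed = 9)
  v <- disp_en_2d(img, entropy_params(c = 6))$value
  expect_gte(v, 0)
  expect_lte(v, log(6^4))
})

test_that("DistEn2D reaches 1 when distances fill all bins equally", {
  strip <- matrix(c(0, 1, 2, 3), 1, 4)
  # m=1 windows; pairwise distances {1,1,1,2,2,3}: 3 in each half of [0,3]
  v <- dist_en_2d(strip, entropy_params(m = 1, M = 2))$value
  expect_equal(v, 1, tolerance = 1e-12)
  cb <- checkerboard(4, 1, 2)
  expect_equal(dist_en_2d(cb, entropy_params(m = 2, M = 8))$value,
               oracle_disten2d(cb, 2, 8), tolerance = 1e-12)
})

test_that("normalized DistEn2D lies in [0, 1] for arbitrary images", {
  for (seed in 1:10) {
    img <- random_small_matrix(seed)
    v <- dist_en_2d(img, entropy_params(m = 1, M = 16))$value
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("all five measures match the brute-force oracles on random small matrices", {
  p <- entropy_params(m = 2, M = 32)
  n_match <- 0
  for (seed in 1:40) {
    img <- random_small_matrix(seed + 100)
    expect_equal(samp_en_2d(img, p)$value, oracle_sampen2d(img),
                 tolerance = 1e-9, label = paste("SampEn2D seed", seed))
    expect_equal(fuzz_en_2d(img, p)$value, oracle_fuzzen2d(img),
                 tolerance = 1e-9, label = paste("FuzzEn2D seed", seed))
    expect_equal(perm_en_2d(img, p)$value, oracle_permen2d(img),
                 tolerance = 1e-9, label = paste("PermEn2D seed", seed))
    expect_equal(disp_en_2d(img, p)$value, oracle_dispen2d(img),
                 tolerance = 1e-9, label = paste("DispEn2D seed", seed))
    expect_equal(dist_en_2d(img, p)$value, oracle_disten2d(img, 2, 32),
                 tolerance = 1e-9, label = paste("DistEn2D seed", seed))
    n_match <- n_match + 1
  }
  expect_equal(n_match, 40)
})

test_that("all measures are shift invariant", {
  img <- noise_image(12, seed = 5)
  shifted <- img + 123.4
  p <- entropy_params()
  expect_identical(perm_en_2d(img, p)$value, perm_en_2d(shifted, p)$value)
  expect_equal(samp_en_2d(img, p)$value, samp_en_2d(shifted, p)$value,
               tolerance = 1e-9)
  expect_equal(fuzz_en_2d(img, p)$value, fuzz_en_2d(shifted, p)$value,
               tolerance = 1e-9)
  expect_equal(disp_en_2d(img, p)$value, disp_en_2d(shifted, p)$value,
               tolerance = 1e-9)
  expect_equal(dist_en_2d(img, p)$value, dist_en_2d(shifted, p)$value,
               tolerance = 1e-9)
})

test_that("measures with data-adaptive scaling are scale invariant", {
  img <- noise_image(12, seed = 6)
  scaled <- img * 5.3
  p <- entropy_params()
  expect_identical(perm_en_2d(img, p)$value, perm_en_2d(scaled, p)$value)
  expect_equal(samp_en_2d(img, p)$value, samp_en_2d(scaled, p)$value,
               tolerance = 1e-9)
  expect_equal(disp_en_2d(img, p)$value, disp_en_2d(scaled, p)$value,
               tolerance = 1e-9)
  expect_equal(dist_en_2d(img, p)$value, dist_en_2d(scaled, p)$value,
               tolerance = 1e-9)
  # the exponential similarity exp(-d^nf / r) is scale-free only for nf = 1
  p1 <- entropy_params(nf = 1)
  expect_equal(fuzz_en_2d(img, p1)$value, fuzz_en_2d(scaled, p1)$value,
               tolerance = 1e-9)
})

test_that("i.i.d. noise scores at least as high as periodic texture on average", {
  # a wide tolerance keeps SampEn2D defined on pure noise, where matches at
  # the (m+1) window size are otherwise vanishingly rare
  p <- entropy_params(r_coeff = 1)
  vals <- function(img) {
    suppressWarnings(r <- entropy_suite(img, p))
    setNames(r$value, r$measure)
  }
  noise_mat <- sapply(1:20, function(s) vals(noise_image(32, seed = s)))
  cb32 <- checkerboard(32, 0, 255)
  periodic <- vals(cb32)
  for (m in rownames(noise_mat)) {
    expect_gte(mean(noise_mat[m, ], na.rm = TRUE), periodic[[m]])
  }
})

test_that("entropy_suite returns the five measures in fixed order and keeps NA markers", {
  img <- noise_image(8, seed = 2)
  res <- entropy_suite(img)
  expect_equal(res$measure, c("SampEn2D", "FuzzEn2D", "PermEn2D",
                              "DispEn2D", "DistEn2D"))
  expect_equal(nrow(res), 5)
})

test_that("the printed window-count prefactor variant is available but off by default", {
  img <- noise_image(8, seed = 7)
  p0 <- entropy_params()
  p1 <- entropy_params(count_prefactor = TRUE)
  n_windows <- (8 - 2 + 1)^2
  expect_equal(perm_en_2d(img, p1)$value,
               perm_en_2d(img, p0)$value / n_windows, tolerance = 1e-12)
  expect_equal(disp_en_2d(img, p1)$value,
               disp_en_2d(img, p0)$value / n_windows, tolerance = 1e-12)
})
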