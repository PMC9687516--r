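#' Parameters for the two-dimensional entropy measures
#'
#' All free parameters of the five texture entropies, with the canonical
#' defaults of the originating method papers. Tolerances are data-adaptive:
#' `r = r_coeff * SD(img)` (population SD), the dispersion class mapping uses
#' the image's own mean/SD through the normal CDF, and the distribution
#' entropy bins span `[0, max pairwise distance]`, so all measures are
#' invariant to adding a constant to the image.
#'
#' @param m Window side for sample/fuzzy/distribution entropies (>= 1);
#'   sample and fuzzy entropy compare `m x m` against `(m+1) x (m+1)` windows.
#' @param r_coeff Tolerance coefficient; the similarity tolerance is
#'   `r_coeff` times the population SD of the matrix.
#' @param nf Fuzzy exponent of the exponential similarity
#'   `exp(-d^nf / r)`.
#' @param dm,dn Sub-matrix dimensions (rows, cols) for permutation and
#'   dispersion entropies (>= 2).
#' @param c Number of dispersion classes (>= 2).
#' @param M Number of empirical-PDF histogram bins for distribution
#'   entropy (>= 2).
#' @param normalize Named logical flags: `perm` divides PermEn2D by
#'   `log((dm*dn)!)`, `disp` divides DispEn2D by `log(c^(dm*dn))`, `dist`
#'   (default `TRUE`) divides DistEn2D by `log2(M)` so it lies in `[0, 1]`.
#' @param count_prefactor If `TRUE`, multiply PermEn2D/DispEn2D by the
#'   reciprocal of the window count, reproducing a printed formula variant;
#'   the default `FALSE` is the conventional, image-size-independent Shannon
#'   form.
#' @param pixel_budget Maximum number of pixels entering the quadratic
#'   pairwise scans (default `64 * 64`). Larger images are block-downsampled
#'   by local means first (see [downsample_budget()]).
#' @return An `entropy_params` object.
#' @export
entropy_params <- function(m = 2L, r_coeff = 0.2, nf = 2, dm = 2L, dn = 2L,
                           c = 6L, M = 512L,
                           normalize = c(perm = FALSE, disp = FALSE,
                                         dist = TRUE),
                           count_prefactor = FALSE,
                           pixel_budget = 64L * 64L) {
  stopifnot(m >= 1, r_coeff > 0, nf > 0, dm >= 2, dn >= 2, c >= 2, M >= 2,
            pixel_budget >= 4)
  norm <- c(perm = FALSE, disp = FALSE, dist = TRUE)
  norm[names(normalize)] <- normalize
  structure(list(m = as.integer(m), r_coeff = r_coeff, nf = nf,
                 dm = as.integer(dm), dn = as.integer(dn), c = as.integer(c),
                 M = as.integer(M), normalize = norm,
                 count_prefactor = isTRUE(count_prefactor),
                 pixel_budget = as.integer(pixel_budget)),
            class = "entropy_params")
}

#' Enumerate sliding windows of a matrix
#'
#' Returns all contiguous `a x b` sub-matrices in row-major scan order
#' (left-to-right, top-to-bottom), each flattened row-major into one row of
#' the result. The count is `(rows - a + 1) * (cols - b + 1)`.
#'
#' @param img Numeric matrix.
#' @param a,b Window rows and columns.
#' @return A numeric matrix with one flattened window per row and attribute
#'   `window_dim = c(a, b)`.
#' @export
roi_windows <- function(img, a, b) {
  stopifnot(is.matrix(img))
  nr <- nrow(img) - a + 1L
  nc <- ncol(img) - b + 1L
  if (nr < 1 || nc < 1) {
    stop("window (", a, "x", b, ") larger than image (",
         nrow(img), "x", ncol(img), ")")
  }
  W <- matrix(0, nr * nc, a * b)
  k <- 0L
  for (dr in 0:(a - 1L)) {
    for (dc in 0:(b - 1L)) {
      k <- k + 1L
      sub <- img[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
      W[, (dr * b) + dc + 1L] <- as.vector(t(sub))
    }
  }
  structure(W, window_dim = c(a, b))
}

#' Block-downsample an image to a pixel budget
#'
#' The quadratic pairwise scans of sample, fuzzy and distribution entropy
#' cost O(P^2) in the number of windows; to keep that cost bounded and
#' deterministic, images larger than `budget` pixels are reduced by local
#' block means with the smallest integer factor that fits. Images within the
#' budget are returned unchanged.
#'
#' @param img Numeric matrix.
#' @param budget Maximum pixel count.
#' @return The (possibly reduced) matrix, with attribute
#'   `downsample_factor` when reduction occurred.
#' @export
downsample_budget <- function(img, budget = 64L * 64L) {
  if (length(img) <= budget) return(img)
  f <- 2L
  while (ceiling(nrow(img) / f) * ceiling(ncol(img) / f) > budget) {
    f <- f + 1L
  }
  ri <- (seq_len(nrow(img)) - 1L) %/% f
  ci <- (seq_len(ncol(img)) - 1L) %/% f
  # mean over each f x f block (partial blocks at the edges use what exists)
  sums <- rowsum(t(rowsum(img, ri)), ci)
  cnts <- rowsum(t(rowsum(matrix(1, nrow(img), ncol(img)), ri)), ci)
  out <- t(sums / cnts)
  structure(matrix(as.numeric(out), nrow(out), ncol(out)),
            downsample_factor = f)
}

# windows restricted to top-left positions where both the m- and the
# (m+1)-window fit, as a K x P matrix for the C++ kernels
paired_windows <- function(img, m) {
  if (nrow(img) < m + 1 || ncol(img) < m + 1) {
    stop("image (", nrow(img), "x", ncol(img),
         ") too small for (m+1)-windows with m = ", m)
  }
  cropped <- img[seq_len(nrow(img) - 1L), seq_len(ncol(img) - 1L),
                 drop = FALSE]
  list(Wm = t(unclass(roi_windows(cropped, m, m))),
       Wm1 = t(unclass(roi_windows(img, m + 1L, m + 1L))))
}

entropy_result <- function(measure, value, note = NA_character_) {
  tibble::tibble(measure = measure, value = value, note = note)
}

#' Two-dimensional sample entropy (SampEn2D)
#'
#' The negative natural logarithm of the conditional probability that window
#' patterns similar at size `m x m` remain similar at size `(m+1) x (m+1)`.
#' Similarity is a Chebyshev distance within tolerance
#' `r = r_coeff * SD(img)`; self-matches are excluded; both window sizes are
#' taken over the positions where the larger window fits. Low values indicate
#' regular or periodic texture, high values irregular texture. When no
#' matching pairs exist at either size the measure is undefined and `NA` is
#' returned with a `note`.
#'
#' @param img Real-valued matrix.
#' @param params An [entropy_params()].
#' @return One-row tibble with columns `measure`, `value`, `note`.
#' @export
samp_en_2d <- function(img, params = entropy_params()) {
  img <- downsample_budget(img, params$pixel_budget)
  r <- params$r_coeff * sd_pop(img)
  W <- paired_windows(img, params$m)
  A <- chebyshev_pairs_within(W$Wm, r)
  B <- chebyshev_pairs_within(W$Wm1, r)
  if (A == 0 || B == 0) {
    return(entropy_result("SampEn2D", NA_real_,
                          "undefined: no matching window pairs"))
  }
  entropy_result("SampEn2D", -log(B / A))
}

#' Two-dimensional fuzzy entropy (FuzzEn2D)
#'
#' Like SampEn2D but with a continuous degree of similarity: windows are
#' mean-subtracted and each ordered pair contributes
#' `exp(-d^nf / r)` with `d` their Chebyshev distance. The value is
#' `-log(phi_{m+1} / phi_m)` where `phi` is the mean similarity. Because the
#' exponential never reaches zero the measure is always finite; a constant
#' image yields exactly 0.
#'
#' @inheritParams samp_en_2d
#' @return One-row tibble with columns `measure`, `value`, `note`.
#' @export
fuzz_en_2d <- function(img, params = entropy_params()) {
  img <- downsample_budget(img, params$pixel_budget)
  r <- params$r_coeff * sd_pop(img)
  if (r == 0) {
    return(entropy_result("FuzzEn2D", 0,
                          "degenerate: constant image, all similarities 1"))
  }
  W <- paired_windows(img, params$m)
  center <- function(M) M - rep(colMeans(M), each = nrow(M))
  phi_m <- fuzzy_similarity_mean(center(W$Wm), r, params$nf)
  phi_m1 <- fuzzy_similarity_mean(center(W$Wm1), r, params$nf)
  value <- -log(phi_m1 / phi_m)
  if (!is.finite(value)) {
    return(entropy_result("FuzzEn2D", NA_real_,
                          "undefined: fewer than two windows"))
  }
  entropy_result("FuzzEn2D", value)
}

# ordinal pattern ids for the rows of a window matrix; ties broken by
# position order (order() is stable)
ordinal_pattern_ids <- function(W) {
  apply(W, 1L, function(w) paste(order(w), collapse = ","))
}

shannon <- function(counts, base = exp(1)) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Two-dimensional permutation entropy (PermEn2D)
#'
#' Shannon entropy of the distribution of ordinal (rank-order) patterns of
#' `dm x dn` sliding sub-matrices. Each window is flattened row-major and its
#' pattern is the permutation sorting its values ascending, ties broken by
#' position. Regular images where pixels always appear in the same order give
#' 0; highly disordered images approach `log((dm*dn)!)`.
#'
#' @inheritParams samp_en_2d
#' @return One-row tibble with columns `measure`, `value`, `note`.
#' @export
perm_en_2d <- function(img, params = entropy_params()) {
  img <- downsample_budget(img, params$pixel_budget)
  W <- roi_windows(img, params$dm, params$dn)
  tab <- table(ordinal_pattern_ids(W))
  h <- shannon(as.numeric(tab))
  if (params$count_prefactor) h <- h / nrow(W)
  if (params$normalize[["perm"]]) h <- h / log(factorial(params$dm * params$dn))
  entropy_result("PermEn2D", h)
}

#' Two-dimensional dispersion entropy (DispEn2D)
#'
#' Pixels are mapped through the normal CDF (with the image's own mean and
#' SD) to `v in (0,1)` and assigned to one of `c` classes by
#' `z = round(c * v + 0.5)` clipped to `[1, c]`. The measure is the Shannon
#' entropy of the class-pattern distribution of `dm x dn` sliding windows.
#' A constant image has a single class and yields 0 with a warning.
#'
#' @inheritParams samp_en_2d
#' @return One-row tibble with columns `measure`, `value`, `note`.
#' @export
disp_en_2d <- function(img, params = entropy_params()) {
  img <- downsample_budget(img, params$pixel_budget)
  s <- sd_pop(img)
  if (s == 0) {
    warning("constant image: dispersion entropy is 0 (single class)")
    return(entropy_result("DispEn2D", 0, "degenerate: constant image"))
  }
  v <- pnorm(img, mean = mean(img), sd = s)
  z <- pmin(pmax(floor(params$c * v + 0.5 + 0.5), 1), params$c)
  z <- matrix(z, nrow(img), ncol(img))
  W <- roi_windows(z, params$dm, params$dn)
  tab <- table(apply(W, 1L, paste, collapse = ","))
  h <- shannon(as.numeric(tab))
  if (params$count_prefactor) h <- h / nrow(W)
  if (params$normalize[["disp"]]) {
    h <- h / (params$dm * params$dn * log(params$c))
  }
  entropy_result("DispEn2D", h)
}

#' Two-dimensional distribution entropy (DistEn2D)
#'
#' Estimates the empirical probability density of the Chebyshev distances
#' between all unordered pairs of `m x m` sliding windows, using `M`
#' equal-width histogram bins spanning `[0, max distance]`, and returns its
#' Shannon entropy in bits, by default normalized by `log2(M)` so the value
#' lies in `[0, 1]`. Designed for small images: every window pair contributes
#' regardless of any tolerance. A constant image concentrates all mass in one
#' bin and yields 0.
#'
#' @inheritParams samp_en_2d
#' @return One-row tibble with columns `measure`, `value`, `note`.
#' @export
dist_en_2d <- function(img, params = entropy_params()) {
  img <- downsample_budget(img, params$pixel_budget)
  W <- t(unclass(roi_windows(img, params$m, params$m)))
  if (ncol(W) < 2) stop("need at least two windows for DistEn2D")
  hist <- chebyshev_distance_hist(W, params$M)
  h <- shannon(hist$counts, base = 2)
  if (params$normalize[["dist"]]) h <- h / log2(params$M)
  entropy_result("DistEn2D", h)
}

#' Compute all five two-dimensional entropies
#'
#' Runs SampEn2D, FuzzEn2D, PermEn2D, DispEn2D and DistEn2D with shared
#' parameters, in that fixed order. An undefined SampEn2D (no matching
#' pairs) is reported as `NA` with a note rather than aborting the suite.
#'
#' @inheritParams samp_en_2d
#' @return Tibble with five rows (`measure`, `value`, `note`).
#' @export
entropy_suite <- function(img, params = entropy_params()) {
  dplyr::bind_rows(
    samp_en_2d(img, params),
    fuzz_en_2d(img, params),
    perm_en_2d(img, params),
    disp_en_2d(img, params),
    dist_en_2d(img, params)
  )
}
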