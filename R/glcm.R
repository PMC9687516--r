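#' Parameters for gray-level co-occurrence matrix features
#'
#' @param n_levels Number of gray levels after min-max quantization (>= 2).
#' @param distance Pixel offset distance (>= 1).
#' @param directions Subset of `c(0, 45, 90, 135)` degrees.
#' @param symmetric Count each pair in both orders (default `TRUE`).
#' @param averaging `"average_features"` computes the six features per
#'   direction and averages them (default); `"average_matrices"` pools the
#'   co-occurrence counts over directions first.
#' @return A `glcm_params` object.
#' @export
glcm_params <- function(n_levels = 32L, distance = 1L,
                        directions = c(0, 45, 90, 135), symmetric = TRUE,
                        averaging = c("average_features",
                                      "average_matrices")) {
  averaging <- match.arg(averaging)
  stopifnot(n_levels >= 2, distance >= 1, length(directions) >= 1,
            all(directions %in% c(0, 45, 90, 135)))
  structure(list(n_levels = as.integer(n_levels),
                 distance = as.integer(distance),
                 directions = directions, symmetric = isTRUE(symmetric),
                 averaging = averaging),
            class = "glcm_params")
}

#' Quantize an image to discrete gray levels
#'
#' Equal-width binning between the matrix minimum and maximum into levels
#' `1..n_levels`; a constant image maps entirely to level 1. Because binning
#' is min-max based, every downstream GLCM feature is invariant to adding a
#' constant to the raw image.
#'
#' @param img Real-valued matrix.
#' @param n_levels Number of levels (>= 2).
#' @return Integer matrix with values in `1..n_levels`.
#' @export
quantize_levels <- function(img, n_levels = 32L) {
  stopifnot(is.matrix(img), n_levels >= 2)
  rng <- range(img)
  if (rng[1] == rng[2]) {
    return(matrix(1L, nrow(img), ncol(img)))
  }
  q <- floor((img - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1
  matrix(as.integer(pmin(q, n_levels)), nrow(img), ncol(img))
}

# (row, col) offset for one direction at a given distance, raster convention
direction_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported GLCM direction: ", angle))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring quantized level pairs at the given pixel offset(s),
#' optionally symmetrized, and normalizes each matrix to sum 1.
#'
#' @param q Integer level matrix from [quantize_levels()].
#' @param params A [glcm_params()].
#' @return A list of probability matrices, one per direction, or a single
#'   pooled matrix in a one-element list when
#'   `averaging == "average_matrices"`.
#' @export
cooccurrence <- function(q, params = glcm_params()) {
  stopifnot(is.matrix(q))
  L <- max(params$n_levels, max(q))
  d <- params$distance
  mats <- lapply(params$directions, function(angle) {
    off <- direction_offset(angle, d)
    nr <- nrow(q); nc <- ncol(q)
    rs <- seq_len(nr)[(seq_len(nr) + off[1]) >= 1 &
                      (seq_len(nr) + off[1]) <= nr]
    cs <- seq_len(nc)[(seq_len(nc) + off[2]) >= 1 &
                      (seq_len(nc) + off[2]) <= nc]
    if (length(rs) == 0 || length(cs) == 0) {
      stop("image (", nr, "x", nc, ") smaller than GLCM offset at ",
           angle, " degrees, distance ", d)
    }
    i <- as.vector(q[rs, cs, drop = FALSE])
    j <- as.vector(q[rs + off[1], cs + off[2], drop = FALSE])
    C <- matrix(tabulate((j - 1L) * L + i, nbins = L * L), L, L)
    if (params$symmetric) C <- C + t(C)
    C
  })
  if (params$averaging == "average_matrices") {
    pooled <- Reduce(`+`, mats)
    mats <- list(pooled)
  }
  lapply(mats, function(C) C / sum(C))
}

#' The six GLCM texture features
#'
#' Computes, from a normalized co-occurrence probability matrix `p(i, j)`
#' with difference marginal `p_diff(k) = sum over |i-j| = k`:
#' contrast `sum (i-j)^2 p(i,j)`; cluster prominence
#' `sum (i + j - mu_x - mu_y)^4 p(i,j)`; difference average
#' `sum k p_diff(k)`; difference entropy
#' `-sum p_diff(k) log2 p_diff(k)`; difference variance
#' `sum (k - difference average)^2 p_diff(k)`; and inverse variance
#' `sum over i != j of p(i,j) / (i-j)^2`.
#'
#' @param P Normalized co-occurrence probability matrix.
#' @return Tibble with columns `measure`, `value` (six rows).
#' @export
glcm_features <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-8) {
    stop("co-occurrence matrix is not normalized (sum = ", sum(P), ")")
  }
  L <- nrow(P)
  i <- row(P); j <- col(P)
  mu_x <- sum(i * P)
  mu_y <- sum(j * P)
  k <- abs(i - j)
  p_diff <- vapply(0:(L - 1), function(kk) sum(P[k == kk]), numeric(1))
  contrast <- sum((i - j)^2 * P)
  cluster_prominence <- sum((i + j - mu_x - mu_y)^4 * P)
  diff_avg <- sum((0:(L - 1)) * p_diff)
  pd <- p_diff[p_diff > 0]
  diff_entropy <- -sum(pd * log2(pd))
  diff_var <- sum(((0:(L - 1)) - diff_avg)^2 * p_diff)
  off <- i != j
  inverse_variance <- sum(P[off] / (i[off] - j[off])^2)
  tibble::tibble(
    measure = c("ClusterProminence", "Contrast", "DifferenceAverage",
                "DifferenceEntropy", "DifferenceVariance", "InverseVariance"),
    value = c(cluster_prominence, contrast, diff_avg, diff_entropy,
              diff_var, inverse_variance))
}

#' Compute the six GLCM features of an image
#'
#' Quantizes the image, builds the co-occurrence matrices over the configured
#' directions, and returns the six features, either averaged over
#' per-direction features or computed from the pooled matrix depending on
#' `params$averaging`.
#'
#' @param img Real-valued matrix.
#' @param params A [glcm_params()].
#' @return Tibble with columns `measure`, `value`, `note` (six rows).
#' @export
glcm_suite <- function(img, params = glcm_params()) {
  q <- quantize_levels(img, params$n_levels)
  mats <- cooccurrence(q, params)
  feats <- lapply(mats, glcm_features)
  out <- feats[[1]]
  if (length(feats) > 1) {
    out$value <- Reduce(`+`, lapply(feats, `[[`, "value")) / length(feats)
  }
  out$note <- NA_character_
  out
}
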