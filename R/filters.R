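#' Normalize filter: zero mean, unit variance
#'
#' Linearly rescales the pixel set so that it has zero mean and unit
#' (population) variance, which increases image contrast without changing
#' its spatial structure. A constant input has no variance to rescale; it is
#' returned as an all-zero matrix with a warning.
#'
#' @param img Numeric intensity matrix.
#' @return Real-valued matrix of the same shape.
#' @export
filter_normalize <- function(img) {
  stopifnot(is.matrix(img), length(img) > 0)
  s <- sd_pop(img)
  if (s == 0) {
    warning("constant image: normalize filter returns all zeros")
    return(matrix(0, nrow(img), ncol(img)))
  }
  (img - mean(img)) / s
}

# pad a matrix by replicating its edge rows/columns k times on each side
pad_replicate <- function(img, k) {
  ri <- c(rep(1L, k), seq_len(nrow(img)), rep(nrow(img), k))
  ci <- c(rep(1L, k), seq_len(ncol(img)), rep(ncol(img), k))
  img[ri, ci, drop = FALSE]
}

#' Median filter
#'
#' Replaces each pixel by the median of its square `(2 * radius + 1)^2`
#' neighborhood, the classic non-linear noise-reduction step for radiographs.
#' Borders are handled by edge replication so that no artificial intensities
#' enter at the ROI boundary.
#'
#' @param img Numeric intensity matrix.
#' @param radius Neighborhood radius in pixels (>= 1); radius 1 is the
#'   standard 3x3 window.
#' @return Matrix of the same shape.
#' @export
filter_median <- function(img, radius = 1L) {
  stopifnot(is.matrix(img))
  if (!is.numeric(radius) || length(radius) != 1 || radius < 1) {
    stop("median filter radius must be an integer >= 1")
  }
  radius <- as.integer(radius)
  p <- pad_replicate(img, radius)
  nr <- nrow(img); nc <- ncol(img)
  side <- 2L * radius + 1L
  # stack the side^2 shifted copies, then take the row-wise median
  nb <- matrix(0, nr * nc, side * side)
  k <- 0L
  for (dr in 0:(side - 1L)) {
    for (dc in 0:(side - 1L)) {
      k <- k + 1L
      nb[, k] <- as.vector(p[dr + seq_len(nr), dc + seq_len(nc)])
    }
  }
  matrix(apply(nb, 1L, median), nr, nc)
}

#' Laplacian sharpening filter
#'
#' Convolves the image with the 4-neighbor Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` and subtracts the weighted response from the
#' input (`out = img - weight * Laplacian(img)`), which amplifies regions of
#' rapid intensity change and highlights edges. Borders are edge-replicated.
#'
#' @param img Numeric intensity matrix.
#' @param weight Positive sharpening weight (default 1).
#' @return Real-valued matrix of the same shape.
#' @export
filter_laplacian_sharpen <- function(img, weight = 1) {
  stopifnot(is.matrix(img))
  if (!is.numeric(weight) || length(weight) != 1 || weight <= 0) {
    stop("laplacian sharpening weight must be > 0")
  }
  p <- pad_replicate(img, 1L)
  nr <- nrow(img); nc <- ncol(img)
  up    <- p[seq_len(nr),     1L + seq_len(nc)]
  down  <- p[2L + seq_len(nr), 1L + seq_len(nc)]
  left  <- p[1L + seq_len(nr), seq_len(nc)]
  right <- p[1L + seq_len(nr), 2L + seq_len(nc)]
  lap <- up + down + left + right - 4 * img
  img - weight * lap
}

#' Specify a preprocessing filter
#'
#' @param name One of `"normalize"`, `"median"`, `"laplacian_sharpen"`.
#' @param median_radius Radius for the median filter (used only when
#'   `name == "median"`).
#' @param laplacian_weight Weight for the sharpening filter (used only when
#'   `name == "laplacian_sharpen"`).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(name = c("normalize", "median", "laplacian_sharpen"),
                        median_radius = 1L, laplacian_weight = 1) {
  name <- match.arg(name)
  spec <- list(name = name)
  if (name == "median") spec$median_radius <- as.integer(median_radius)
  if (name == "laplacian_sharpen") spec$laplacian_weight <- laplacian_weight
  structure(spec, class = "filter_spec")
}

#' The three default preprocessing filters
#'
#' Normalize, median (radius 1) and Laplacian sharpening (weight 1), in the
#' fixed order used throughout the pipeline.
#'
#' @return A named list of `filter_spec` objects.
#' @export
default_filters <- function() {
  list(normalize = filter_spec("normalize"),
       median = filter_spec("median"),
       laplacian_sharpen = filter_spec("laplacian_sharpen"))
}

#' Apply a filter specification to an image
#'
#' @param img Numeric intensity matrix.
#' @param spec A [filter_spec()].
#' @return Filtered matrix with attribute `filter` recording the filter name.
#' @export
apply_filter <- function(img, spec) {
  if (!inherits(spec, "filter_spec")) stop("spec must be a filter_spec")
  out <- switch(spec$name,
    normalize = filter_normalize(img),
    median = filter_median(img, spec$median_radius),
    laplacian_sharpen = filter_laplacian_sharpen(img, spec$laplacian_weight),
    stop("unknown filter: ", spec$name))
  attr(out, "filter") <- spec$name
  out
}
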