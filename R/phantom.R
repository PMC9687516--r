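#' Specify a synthetic graded tooth phantom
#'
#' Describes one synthetic incisor ROI emulating the radiographic structure
#' the texture analysis assumes: a high-intensity, roughly tooth-shaped
#' region on a darker background, overlaid with an alternating mosaic of
#' low-radiopacity (resorption-like) dark lesions and high-radiopacity
#' (hypercementosis-like) bright blobs concentrated in the apical third,
#' plus additive Gaussian noise. Lesion counts and noise grow with the EOTRH
#' grade so that image irregularity increases monotonically from grade 0
#' (0 dark / 0 bright lesions, noise SD 4) to grade 3 (9 / 6, noise SD 12).
#'
#' @param grade EOTRH grade, integer 0-3.
#' @param width,height Image size in pixels (default 96 x 160).
#' @param seed RNG seed for this phantom.
#' @param n_resorption Number of dark lesions; default scales with grade as
#'   0/2/5/9.
#' @param n_hypercementosis Number of bright apical blobs; default 0/1/3/6.
#' @param lesion_radius_range Min and max lesion radius in pixels.
#' @param lesion_contrast Named vector `c(dark = -0.45, bright = 0.45)`,
#'   lesion amplitude as a fraction of the tooth base intensity.
#' @param base_tooth_intensity Tooth intensity on the 0-255 scale.
#' @param background_intensity Background intensity on the 0-255 scale.
#' @param noise_sd Additive Gaussian noise SD in gray levels; default
#'   4/6/8/12 by grade.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grade, width = 96L, height = 160L, seed = 1L,
                         n_resorption = c(0L, 2L, 5L, 9L)[grade + 1L],
                         n_hypercementosis = c(0L, 1L, 3L, 6L)[grade + 1L],
                         lesion_radius_range = c(3, 10),
                         lesion_contrast = c(dark = -0.45, bright = 0.45),
                         base_tooth_intensity = 180,
                         background_intensity = 60,
                         noise_sd = c(4, 6, 8, 12)[grade + 1L]) {
  stopifnot(grade %in% 0:3, width >= 8, height >= 8,
            n_resorption >= 0, n_hypercementosis >= 0,
            length(lesion_radius_range) == 2,
            lesion_radius_range[1] <= lesion_radius_range[2],
            base_tooth_intensity >= 0, base_tooth_intensity <= 255,
            background_intensity >= 0, background_intensity <= 255,
            noise_sd >= 0)
  if (max(lesion_radius_range) >= min(width, height) / 2) {
    stop("lesion radii must be smaller than half the image size")
  }
  structure(list(grade = as.integer(grade), width = as.integer(width),
                 height = as.integer(height), seed = as.integer(seed),
                 n_resorption = as.integer(n_resorption),
                 n_hypercementosis = as.integer(n_hypercementosis),
                 lesion_radius_range = lesion_radius_range,
                 lesion_contrast = lesion_contrast,
                 base_tooth_intensity = base_tooth_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd),
            class = "phantom_spec")
}

# Gaussian intensity bump added in place; sigma = radius / 2 so the nominal
# radius is about the 2-sigma extent of the soft lesion margin
add_blob <- function(img, cy, cx, radius, amplitude) {
  y <- row(img); x <- col(img)
  img + amplitude * exp(-((y - cy)^2 + (x - cx)^2) / (2 * (radius / 2)^2))
}

#' Generate one synthetic tooth phantom
#'
#' Deterministic for a fixed spec (including seed). The tooth is an
#' axis-aligned superellipse mask at the base intensity; dark lesions are
#' placed uniformly at random inside the mask; bright blobs are restricted to
#' the apical (bottom) third of the mask; both have soft Gaussian profiles.
#' Gaussian noise is added and the result clipped to `[0, 255]`.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `pixels` (height x width numeric matrix),
#'   `grade`, `mask` (logical tooth mask), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- spec$width; h <- spec$height
  with_seed(spec$seed, {
    y <- row(matrix(0, h, w)); x <- col(matrix(0, h, w))
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    ay <- 0.44 * h; ax <- 0.36 * w
    mask <- (abs((x - cx) / ax)^4 + abs((y - cy) / ay)^4) <= 1
    if (!any(mask)) stop("phantom spec produces an empty tooth mask")
    img <- matrix(spec$background_intensity, h, w)
    img[mask] <- spec$base_tooth_intensity
    in_mask <- which(mask)
    mask_rows <- ((in_mask - 1) %% h) + 1
    apical_cut <- quantile(mask_rows, 2 / 3)
    apical <- in_mask[mask_rows >= apical_cut]
    place <- function(img, n, candidates, amplitude_frac) {
      if (n == 0) return(img)
      if (length(candidates) == 0) {
        stop("phantom mask too small to place lesions")
      }
      centers <- sample(candidates, n, replace = TRUE)
      radii <- runif(n, spec$lesion_radius_range[1],
                     spec$lesion_radius_range[2])
      amp <- amplitude_frac * spec$base_tooth_intensity
      for (k in seq_len(n)) {
        ry <- ((centers[k] - 1) %% h) + 1
        rx <- ((centers[k] - 1) %/% h) + 1
        img <- add_blob(img, ry, rx, radii[k], amp)
      }
      img
    }
    img <- place(img, spec$n_resorption, in_mask,
                 spec$lesion_contrast[["dark"]])
    img <- place(img, spec$n_hypercementosis, apical,
                 spec$lesion_contrast[["bright"]])
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
    }
    img <- pmin(pmax(img, 0), 255)
    list(pixels = matrix(img, h, w), grade = spec$grade, mask = mask,
         spec = spec)
  })
}

#' Generate a graded phantom cohort with manifest
#'
#' Writes one 8-bit grayscale PNG per phantom plus a manifest CSV consumable
#' by [read_manifest()]. The default group sizes (37/94/20/8 for grades
#' 0-3, 159 teeth in total) mirror a realistic clinical EOTRH cohort in which
#' most teeth are mildly affected and severe disease is rare. Horse IDs are
#' assigned two teeth per horse (Triadan 101 and 201). Per-image seeds are
#' derived deterministically from `base_seed`, so regeneration with the same
#' seed is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param group_sizes Named integer vector, grade -> count.
#' @param base_seed Integer master seed.
#' @param width,height Phantom size in pixels.
#' @param ... Further arguments passed to [phantom_spec()] (applied to every
#'   phantom).
#' @return The manifest tibble, invisibly; the manifest CSV is written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
generate_cohort <- function(dir, group_sizes = c("0" = 37L, "1" = 94L,
                                                 "2" = 20L, "3" = 8L),
                            base_seed = 1L, width = 96L, height = 160L,
                            ...) {
  stopifnot(all(as.integer(names(group_sizes)) %in% 0:3),
            all(group_sizes >= 1))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grades <- rep(as.integer(names(group_sizes)), group_sizes)
  n <- length(grades)
  seeds <- (abs(as.integer(base_seed)) %% 20000L) * 100000L + seq_len(n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phantom_spec(grade = grades[i], width = width, height = height,
                         seed = seeds[i], ...)
    ph <- generate_phantom(spec)
    fname <- sprintf("phantom_g%d_%03d.png", grades[i], i)
    png::writePNG(ph$pixels / 255, file.path(dir, fname))
    records[[i]] <- tibble::tibble(
      horse_id = sprintf("H%03d", (i - 1L) %/% 2L + 1L),
      tooth = if (i %% 2L == 1L) 101L else 201L,
      grade = grades[i],
      image = fname,
      x0 = 0L, y0 = 0L, x1 = as.integer(width), y1 = as.integer(height))
  }
  manifest <- dplyr::bind_rows(records)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
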