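#' Texture features of one ROI under one filter
#'
#' Applies the filter, then computes the five entropy measures and/or the
#' six GLCM features of the filtered ROI.
#'
#' @param roi Numeric intensity matrix.
#' @param spec A [filter_spec()].
#' @param entropy An [entropy_params()] or `NULL` to skip entropies.
#' @param glcm A [glcm_params()] or `NULL` to skip GLCM features.
#' @return Tibble with columns `filter`, `measure`, `value`, `note`.
#' @export
roi_features <- function(roi, spec, entropy = entropy_params(),
                         glcm = glcm_params()) {
  filtered <- apply_filter(roi, spec)
  parts <- list()
  if (!is.null(entropy)) parts$entropy <- entropy_suite(filtered, entropy)
  if (!is.null(glcm)) parts$glcm <- glcm_suite(filtered, glcm)
  out <- dplyr::bind_rows(parts)
  out$filter <- spec$name
  out[c("filter", "measure", "value", "note")]
}

#' Extract the full feature table for a cohort
#'
#' For every ROI in the manifest and every filter, computes the enabled
#' texture families: 5 entropies x 3 filters = 15 entropy rows and 6 GLCM
#' features x 3 filters = 18 GLCM rows per ROI with the defaults. ROIs that
#' fail to process are skipped with a warning; the number skipped is
#' recorded in the `n_failed` attribute.
#'
#' @param manifest Manifest tibble ([read_manifest()]) or path to a
#'   manifest CSV.
#' @param image_dir Directory image paths are relative to (defaults to the
#'   manifest's own directory when `manifest` is a path, else `"."`).
#' @param filters List of [filter_spec()]s (default [default_filters()]).
#' @param entropy An [entropy_params()] or `NULL` to disable entropies.
#' @param glcm A [glcm_params()] or `NULL` to disable GLCM features.
#' @return Long-format tibble with columns `horse_id`, `tooth`, `grade`,
#'   `filter`, `measure`, `value`, `note`.
#' @export
extract_features <- function(manifest, image_dir = NULL,
                             filters = default_filters(),
                             entropy = entropy_params(),
                             glcm = glcm_params()) {
  if (is.character(manifest)) {
    if (is.null(image_dir)) image_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(image_dir)) image_dir <- "."
  if (nrow(manifest) == 0) {
    warning("empty manifest: returning empty feature table")
    return(tibble::tibble(horse_id = character(), tooth = integer(),
                          grade = integer(), filter = character(),
                          measure = character(), value = numeric(),
                          note = character()))
  }
  n_failed <- 0L
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    rows[[i]] <- tryCatch({
      img <- load_radiograph(file.path(image_dir, rec$image))
      roi <- extract_roi(img, rec$x0, rec$y0, rec$x1, rec$y1)
      feats <- purrr::map_dfr(filters, function(spec) {
        suppressWarnings(roi_features(roi, spec, entropy, glcm))
      })
      dplyr::bind_cols(
        tibble::tibble(horse_id = rec$horse_id, tooth = rec$tooth,
                       grade = rec$grade),
        feats)
    }, error = function(e) {
      warning("skipping ROI for horse ", rec$horse_id, " tooth ", rec$tooth,
              ": ", conditionMessage(e), call. = FALSE)
      n_failed <<- n_failed + 1L
      NULL
    })
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_failed") <- n_failed
  out
}

#' Grade-wise statistics for every filter-measure combination
#'
#' Runs [compare_groups()] per (filter, measure) pair, and
#' [compare_slopes()] between the configured entropy measure and each GLCM
#' feature under the same filter.
#'
#' @param features Feature tibble from [extract_features()].
#' @param alpha Significance level.
#' @param regression_measure Entropy measure whose grade trend is compared
#'   against the GLCM features (default `"DistEn2D"`).
#' @param regression_filter Filter under which the regression comparison is
#'   made (default `"normalize"`).
#' @return List with `comparisons` (tibble: one row per filter-measure with
#'   branch, omnibus p, monotone flag and the `grade_comparison` object in a
#'   list-column) and `regressions` (tibble: one row per GLCM feature with
#'   slopes and equality tests).
#' @export
run_stats <- function(features, alpha = 0.05,
                      regression_measure = "DistEn2D",
                      regression_filter = "normalize") {
  combos <- features |>
    dplyr::distinct(.data$filter, .data$measure)
  comparisons <- purrr::pmap_dfr(combos, function(filter, measure) {
    sub <- features[features$filter == filter &
                      features$measure == measure &
                      is.finite(features$value), ]
    if (length(unique(sub$grade)) < 2) {
      warning("skipping ", filter, "/", measure,
              ": fewer than 2 grades with data")
      return(NULL)
    }
    cmp <- tryCatch(compare_groups(sub, value, grade, alpha),
                    error = function(e) {
                      warning("skipping ", filter, "/", measure, ": ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(cmp)) return(NULL)
    dplyr::bind_cols(tibble::tibble(filter = filter, measure = measure),
                     glance(cmp),
                     tibble::tibble(comparison = list(cmp)))
  })
  glcm_measures <- c("ClusterProminence", "Contrast", "DifferenceAverage",
                     "DifferenceEntropy", "DifferenceVariance",
                     "InverseVariance")
  present <- intersect(glcm_measures, unique(features$measure))
  ent <- features[features$measure == regression_measure &
                    features$filter == regression_filter &
                    is.finite(features$value), ]
  regressions <- NULL
  if (nrow(ent) > 0 && length(unique(ent$grade)) >= 2 &&
      length(present) > 0) {
    regressions <- purrr::map_dfr(present, function(gm) {
      gsub_ <- features[features$measure == gm &
                          features$filter == regression_filter &
                          is.finite(features$value), ]
      if (length(unique(gsub_$grade)) < 2) return(NULL)
      sc <- compare_slopes(ent[c("grade", "value")],
                           gsub_[c("grade", "value")], alpha)
      dplyr::bind_cols(
        tibble::tibble(entropy_measure = regression_measure,
                       glcm_measure = gm, filter = regression_filter),
        glance(sc),
        tibble::tibble(slope_entropy = sc$slope_a, slope_glcm = sc$slope_b,
                       common_slope = sc$common_slope,
                       comparison = list(sc)))
    })
  }
  list(comparisons = comparisons, regressions = regressions)
}

#' Run the full phantom-to-report pipeline
#'
#' Generates (or reads) a cohort, extracts the feature table, computes the
#' grade-wise statistics and the grade 0 vs 3 detection report for the
#' selected measure. This is the programmatic equivalent of the command-line
#' `all` subcommand.
#'
#' @param dir Working directory for generated images and outputs.
#' @param group_sizes Cohort group sizes (grade -> count).
#' @param seed Master seed for phantom generation.
#' @param filters,entropy,glcm Pipeline parameter objects.
#' @param detect_measure,detect_filter Measure/filter used for detection.
#' @param alpha Significance level.
#' @return List with `manifest`, `features`, `stats`, `detection`.
#' @export
run_pipeline <- function(dir, group_sizes = c("0" = 37L, "1" = 94L,
                                              "2" = 20L, "3" = 8L),
                         seed = 1L, filters = default_filters(),
                         entropy = entropy_params(), glcm = glcm_params(),
                         detect_measure = "DistEn2D",
                         detect_filter = "normalize", alpha = 0.05) {
  manifest <- generate_cohort(dir, group_sizes, base_seed = seed)
  features <- extract_features(manifest, image_dir = dir, filters = filters,
                               entropy = entropy, glcm = glcm)
  stats <- run_stats(features, alpha = alpha,
                     regression_measure = detect_measure,
                     regression_filter = detect_filter)
  detection <- detect_grades(features, detect_measure, detect_filter)
  list(manifest = manifest, features = features, stats = stats,
       detection = detection)
}

#' Write a feature table to CSV
#'
#' Values are written at full precision; undefined measurements are the
#' literal token `NA` with the reason kept in the `note` column, so the file
#' round-trips losslessly through [read_feature_table()].
#'
#' @param features Feature tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(features, path, na = "NA")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Feature tibble.
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    horse_id = readr::col_character(),
                    tooth = readr::col_integer(),
                    grade = readr::col_integer(),
                    filter = readr::col_character(),
                    measure = readr::col_character(),
                    value = readr::col_double(),
                    note = readr::col_character()))
}
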