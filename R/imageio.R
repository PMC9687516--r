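#' Load a radiograph as a grayscale intensity matrix
#'
#' Reads an 8- or 16-bit PNG or JPEG and returns the pixel intensities on
#' their native integer scale (0..255 for 8-bit, 0..65535 for 16-bit). Color
#' images are collapsed to a single channel with the Rec. 601 luminance
#' weights (0.299 R + 0.587 G + 0.114 B); any alpha channel is dropped.
#' No rescaling is applied at load time: the preprocessing filters and texture
#' measures define their own scaling downstream.
#'
#' @param path Path to a PNG or JPEG file.
#' @return A numeric matrix (rows x cols) with attributes `bit_depth` and
#'   `source_path`.
#' @export
load_radiograph <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read radiograph: file does not exist: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch({
    if (ext == "png") {
      png::readPNG(path)
    } else if (ext %in% c("jpg", "jpeg")) {
      jpeg::readJPEG(path)
    } else {
      # sniff the magic bytes for extension-less files
      magic <- readBin(path, "raw", n = 8)
      if (length(magic) >= 8 &&
          identical(magic[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47,
                                         0x0d, 0x0a, 0x1a, 0x0a)))) {
        png::readPNG(path)
      } else if (length(magic) >= 2 &&
                 identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
        jpeg::readJPEG(path)
      } else {
        stop("not a PNG or JPEG file")
      }
    }
  }, error = function(e) {
    stop("cannot read radiograph '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (length(arr) == 0) stop("zero-size image: ", path)
  # readPNG/readJPEG return values in [0,1]; 16-bit PNGs come through at
  # 1/65535 granularity. Recover the native integer scale.
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  scaled8 <- arr * 255
  bit_depth <- if (ext == "png" || ext == "") {
    if (max(abs(scaled8 - round(scaled8))) > 1e-6) 16L else 8L
  } else 8L
  img <- arr * (2^bit_depth - 1)
  img <- matrix(as.numeric(img), nrow(arr), ncol(arr))
  structure(img, bit_depth = bit_depth, source_path = path)
}

#' Read a region-of-interest manifest
#'
#' The manifest is a UTF-8 CSV with a mandatory header and the columns
#' `horse_id`, `tooth`, `grade`, `image`, `x0`, `y0`, `x1`, `y1`. Each row
#' describes one rectangular tooth ROI: Triadan tooth number (101 or 201),
#' EOTRH grade 0-3, and pixel coordinates in the 0-based, half-open
#' convention (`x` = column, `y` = row, the rectangle is
#' `[x0, x1) x [y0, y1)`).
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with one row per ROI.
#' @export
read_manifest <- function(path) {
  required <- c("horse_id", "tooth", "grade", "image",
                "x0", "y0", "x1", "y1")
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          horse_id = readr::col_character(),
                          tooth = readr::col_integer(),
                          grade = readr::col_integer(),
                          image = readr::col_character(),
                          .default = readr::col_integer()))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[required]
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!row$grade %in% 0:3) {
      stop("manifest row ", i, ": grade must be in 0..3, got ", row$grade)
    }
    if (!row$tooth %in% c(101L, 201L)) {
      stop("manifest row ", i, ": tooth must be 101 or 201, got ", row$tooth)
    }
    if (is.na(row$x0) || is.na(row$y0) || is.na(row$x1) || is.na(row$y1) ||
        row$x1 <= row$x0 || row$y1 <= row$y0) {
      stop("manifest row ", i, ": invalid ROI rectangle (need x1 > x0, y1 > y0)")
    }
  }
  df
}

#' Write a region-of-interest manifest
#'
#' Inverse of [read_manifest()]: writes the tibble as CSV so that a
#' read-back reproduces all records exactly.
#'
#' @param manifest Tibble as returned by [read_manifest()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' Extract a rectangular ROI from an image matrix
#'
#' Coordinates are 0-based and half-open: the returned matrix has
#' `y1 - y0` rows and `x1 - x0` columns. The pixels are copied.
#'
#' @param img Numeric intensity matrix.
#' @param x0,y0,x1,y1 Integer pixel coordinates (`x` = column, `y` = row).
#' @return Numeric matrix of shape `(y1 - y0) x (x1 - x0)`.
#' @export
extract_roi <- function(img, x0, y0, x1, y1) {
  stopifnot(is.matrix(img))
  if (x1 <= x0 || y1 <= y0) {
    stop("invalid ROI rectangle: need x1 > x0 and y1 > y0")
  }
  if (x0 < 0 || y0 < 0 || x1 > ncol(img) || y1 > nrow(img)) {
    stop("ROI rectangle (", x0, ",", y0, ",", x1, ",", y1,
         ") lies outside the ", nrow(img), "x", ncol(img), " image")
  }
  out <- img[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  matrix(as.numeric(out), nrow(out), ncol(out))
}
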