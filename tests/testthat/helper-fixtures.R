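# Small deterministic images used across tests.

checkerboard <- function(n = 4, lo = 1, hi = 2) {
  matrix(ifelse((row(diag(n)) + col(diag(n))) %% 2 == 0, lo, hi), n, n)
}

noise_image <- function(n = 32, seed = 1, lo = 0, hi = 255) {
  withr::with_seed(seed, matrix(runif(n * n, lo, hi), n, n))
}

random_small_matrix <- function(seed, max_side = 6, values = 0:2) {
  withr::with_seed(seed, {
    nr <- sample(3:max_side, 1)
    nc <- sample(3:max_side, 1)
    matrix(sample(values, nr * nc, replace = TRUE), nr, nc)
  })
}

# feature table with one value per (grade, replicate) for a single
# filter/measure combination
fake_features <- function(values_by_grade, measure = "DistEn2D",
                          filter = "normalize") {
  rows <- lapply(names(values_by_grade), function(g) {
    v <- values_by_grade[[g]]
    tibble::tibble(
      horse_id = sprintf("H%s_%02d", g, seq_along(v)),
      tooth = 101L, grade = as.integer(g), filter = filter,
      measure = measure, value = v, note = NA_character_)
  })
  dplyr::bind_rows(rows)
}
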