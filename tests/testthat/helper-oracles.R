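# Brute-force reference implementations of the five 2-D entropies, written
# as direct loops over explicit sub-matrices. They share no code with the
# package kernels and exist solely as independent oracles for equivalence
# tests on small matrices.

oracle_submatrices <- function(img, a, b) {
  out <- list()
  for (y in seq_len(nrow(img) - a + 1)) {
    for (x in seq_len(ncol(img) - b + 1)) {
      out[[length(out) + 1]] <- img[y:(y + a - 1), x:(x + b - 1),
                                    drop = FALSE]
    }
  }
  out
}

oracle_sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

oracle_cheby <- function(A, B) max(abs(A - B))

oracle_sampen2d <- function(img, m = 2, r_coeff = 0.2) {
  r <- r_coeff * oracle_sd_pop(img)
  H <- nrow(img); W <- ncol(img)
  if (H < m + 1 || W < m + 1) stop("too small")
  wm <- list(); wm1 <- list()
  for (y in seq_len(H - m)) {
    for (x in seq_len(W - m)) {
      wm[[length(wm) + 1]] <- img[y:(y + m - 1), x:(x + m - 1), drop = FALSE]
      wm1[[length(wm1) + 1]] <- img[y:(y + m), x:(x + m), drop = FALSE]
    }
  }
  count_pairs <- function(ws) {
    cnt <- 0
    for (i in seq_along(ws)) {
      for (j in seq_along(ws)) {
        if (i != j && oracle_cheby(ws[[i]], ws[[j]]) <= r) cnt <- cnt + 1
      }
    }
    cnt
  }
  A <- count_pairs(wm); B <- count_pairs(wm1)
  if (A == 0 || B == 0) return(NA_real_)
  -log(B / A)
}

oracle_fuzzen2d <- function(img, m = 2, r_coeff = 0.2, nf = 2) {
  r <- r_coeff * oracle_sd_pop(img)
  if (r == 0) return(0)
  H <- nrow(img); W <- ncol(img)
  wm <- list(); wm1 <- list()
  for (y in seq_len(H - m)) {
    for (x in seq_len(W - m)) {
      s1 <- img[y:(y + m - 1), x:(x + m - 1), drop = FALSE]
      s2 <- img[y:(y + m), x:(x + m), drop = FALSE]
      wm[[length(wm) + 1]] <- s1 - mean(s1)
      wm1[[length(wm1) + 1]] <- s2 - mean(s2)
    }
  }
  phi <- function(ws) {
    if (length(ws) < 2) return(NA_real_) # no pairs to compare
    sims <- c()
    for (i in seq_along(ws)) {
      for (j in seq_along(ws)) {
        if (i != j) {
          d <- oracle_cheby(ws[[i]], ws[[j]])
          sims <- c(sims, exp(-(d^nf) / r))
        }
      }
    }
    mean(sims)
  }
  -log(phi(wm1) / phi(wm))
}

oracle_permen2d <- function(img, dm = 2, dn = 2) {
  pats <- c()
  for (s in oracle_submatrices(img, dm, dn)) {
    v <- as.vector(t(s)) # row-major flattening
    pats <- c(pats, paste(order(v), collapse = "-"))
  }
  p <- table(pats) / length(pats)
  -sum(p * log(p))
}

oracle_dispen2d <- function(img, dm = 2, dn = 2, c_classes = 6) {
  s <- oracle_sd_pop(img)
  if (s == 0) return(0)
  v <- pnorm(img, mean(img), s)
  z <- floor(c_classes * v + 0.5 + 0.5) # round half-up of c*v + 0.5
  z[z < 1] <- 1
  z[z > c_classes] <- c_classes
  z <- matrix(z, nrow(img), ncol(img))
  pats <- c()
  for (sub in oracle_submatrices(z, dm, dn)) {
    pats <- c(pats, paste(as.vector(t(sub)), collapse = "-"))
  }
  p <- table(pats) / length(pats)
  -sum(p * log(p))
}

oracle_disten2d <- function(img, m = 2, M = 512, normalize = TRUE) {
  ws <- oracle_submatrices(img, m, m)
  d <- c()
  for (i in seq_along(ws)) {
    for (j in seq_along(ws)) {
      if (i < j) d <- c(d, oracle_cheby(ws[[i]], ws[[j]]))
    }
  }
  if (max(d) == 0) return(0)
  bins <- pmin(M, floor(d / max(d) * M) + 1)
  p <- tabulate(bins, nbins = M) / length(d)
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  if (normalize) h / log2(M) else h
}

# Naive double-loop GLCM reference: counts level pairs at one offset.
oracle_glcm <- function(q, dy, dx, symmetric = TRUE) {
  L <- max(q)
  C <- matrix(0, L, L)
  for (y in seq_len(nrow(q))) {
    for (x in seq_len(ncol(q))) {
      y2 <- y + dy; x2 <- x + dx
      if (y2 >= 1 && y2 <= nrow(q) && x2 >= 1 && x2 <= ncol(q)) {
        C[q[y, x], q[y2, x2]] <- C[q[y, x], q[y2, x2]] + 1
      }
    }
  }
  if (symmetric) C <- C + t(C)
  C / sum(C)
}

oracle_glcm_features <- function(P) {
  L <- nrow(P)
  mu_x <- 0; mu_y <- 0
  for (i in 1:L) for (j in 1:L) {
    mu_x <- mu_x + i * P[i, j]; mu_y <- mu_y + j * P[i, j]
  }
  contrast <- 0; cp <- 0; iv <- 0
  pd <- numeric(L)
  for (i in 1:L) {
    for (j in 1:L) {
      contrast <- contrast + (i - j)^2 * P[i, j]
      cp <- cp + (i + j - mu_x - mu_y)^4 * P[i, j]
      pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
      if (i != j) iv <- iv + P[i, j] / (i - j)^2
    }
  }
  k <- 0:(L - 1)
  da <- sum(k * pd)
  de <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  dv <- sum((k - da)^2 * pd)
  c(ClusterProminence = cp, Contrast = contrast, DifferenceAverage = da,
    DifferenceEntropy = de, DifferenceVariance = dv, InverseVariance = iv)
}
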