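# Shared fixtures, all generated in code.

# Sierpinski carpet after `iter` subdivisions (side 3^iter).
sierpinski_carpet <- function(iter) {
  m <- matrix(TRUE, 1L, 1L)
  for (i in seq_len(iter)) {
    n <- nrow(m)
    blk <- matrix(FALSE, 3L * n, 3L * n)
    for (r in 0:2) for (cc in 0:2) if (!(r == 1 && cc == 1))
      blk[(r * n + 1):(r * n + n), (cc * n + 1):(cc * n + n)] <- m
    m <- blk
  }
  m
}

# Period-2 checkerboard with value 1 where (row + col) is even.
checkerboard <- function(n) {
  outer(seq_len(n), seq_len(n), function(i, j) as.numeric((i + j) %% 2 == 0))
}

# Dice overlap of two logical masks.
dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Brute-force local window mean with symmetric (edge-duplicating) mirror
# boundary (oracle for the adaptive threshold), O(n^2 w^2) - tiny inputs.
brute_local_mean <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- i + di; jj <- j + dj
      if (ii < 1L) ii <- 1L - ii            # ..., 2, 1 | 1, 2, ...
      if (ii > n) ii <- 2L * n + 1L - ii
      if (jj < 1L) jj <- 1L - jj
      if (jj > m) jj <- 2L * m + 1L - jj
      s <- s + x[ii, jj]
    }
    out[i, j] <- s / w^2
  }
  out
}

# Exhaustive Otsu threshold search over `levels` histogram bins
# (independent oracle for otsu_threshold).
brute_otsu <- function(x, levels = 256L) {
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  idx <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(idx, nbins = levels)
  mids <- (br[-1L] + br[-(levels + 1L)]) / 2
  best <- -Inf; bk <- 0L
  for (k in seq_len(levels - 1L)) {
    w0 <- sum(cnt[1:k]); w1 <- sum(cnt) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(cnt[1:k] * mids[1:k]) / w0
    m1 <- sum(cnt[(k + 1L):levels] * mids[(k + 1L):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; bk <- k }
  }
  br[bk + 1L]
}

# ICC(2,1) from first principles on a small table: explicit two-way
# ANOVA sums of squares (oracle for icc_two_way).
brute_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  msr <- k * sum((rowMeans(m) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - gm)^2) / (k - 1)
  sse <- sum((m - gm)^2) - k * sum((rowMeans(m) - gm)^2) -
    n * sum((colMeans(m) - gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Average-rank Spearman correlation computed by hand (oracle).
brute_spearman <- function(x, y) {
  rk <- function(v) {
    sv <- sort(v); r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sv == v[i]))
    r
  }
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small default cohort used by several association tests.
test_cohort <- function(n = 1500, seed = 77, ...) {
  transform_variables(generate_cohort(cohort_config(n_subjects = n,
                                                    rng_seed = seed, ...)))
}
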