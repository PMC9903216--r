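# Internal numerical helpers shared across modules.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("rng_seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Pad a matrix by `h` pixels on every side with mirror (symmetric) boundary.
# h must be < dim; for larger pads the reflection is applied recursively.
pad_reflect <- function(x, h) {
  if (h == 0L) return(x)
  n <- nrow(x); m <- ncol(x)
  while (h >= n || h >= m) {
    k <- min(n, m) - 1L
    x <- pad_reflect(x, k)
    h <- h - k
    n <- nrow(x); m <- ncol(x)
  }
  ri <- c(h:1, 1:n, n:(n - h + 1L))
  ci <- c(h:1, 1:m, m:(m - h + 1L))
  x[ri, ci, drop = FALSE]
}

# Separable 2-D convolution with mirror boundary. kr is applied along rows
# (i.e. down columns), kc along columns. Kernels must have odd length.
conv_sep <- function(x, kr, kc = kr) {
  hr <- (length(kr) - 1L) %/% 2L
  hc <- (length(kc) - 1L) %/% 2L
  p <- pad_reflect(x, max(hr, hc))
  n <- nrow(x); m <- ncol(x)
  off <- max(hr, hc)
  # along rows
  acc <- matrix(0, n, ncol(p))
  for (k in seq_along(kr))
    acc <- acc + kr[k] * p[(off + 1L - hr + k - 1L):(off + n - hr + k - 1L), , drop = FALSE]
  out <- matrix(0, n, m)
  for (k in seq_along(kc))
    out <- out + kc[k] * acc[, (off + 1L - hc + k - 1L):(off + m - hc + k - 1L), drop = FALSE]
  out
}

# Gaussian kernel and its derivatives, truncated at 3 sigma (minimum
# radius 1). Derivative kernels are corrected to sum exactly to zero so
# that constant images give an exactly null response despite truncation.
gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(3 * sigma))
  t <- seq(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- switch(as.character(order),
    "0" = g,
    "1" = -t / sigma^2 * g,
    "2" = (t^2 - sigma^2) / sigma^4 * g,
    stop("order must be 0, 1 or 2"))
  if (order > 0L) k <- k - sum(k) * g
  k
}

# Local (box) mean with mirror boundary via summed-area table.
local_mean <- function(x, window_px) {
  h <- (window_px - 1L) %/% 2L
  p <- pad_reflect(x, h + 1L)  # +1 row/col of slack for the SAT offsets
  n <- nrow(x); m <- ncol(x)
  sat <- apply(apply(p, 2L, cumsum), 1L, cumsum)
  sat <- t(sat)
  # box [i-h, i+h] x [j-h, j+h] in original coords; padded coords shift by h+1
  i1 <- (1:n); j1 <- (1:m)
  a <- sat[i1 + 2L * h + 1L, j1 + 2L * h + 1L, drop = FALSE]
  b <- sat[i1, j1 + 2L * h + 1L, drop = FALSE]
  cc <- sat[i1 + 2L * h + 1L, j1, drop = FALSE]
  d <- sat[i1, j1, drop = FALSE]
  (a - b - cc + d) / (window_px^2)
}

# 8-connected component labelling of a logical matrix using igraph.
# Returns an integer matrix, 0 = background, components numbered from 1.
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  id <- integer(n * m)
  id[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% n) + 1L
  cl <- ((fg - 1L) %/% n) + 1L
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + d[1L]; cc <- cl + d[2L]
    ok <- rr >= 1L & rr <= n & cc >= 1L & cc <= m
    nb <- (cc[ok] - 1L) * n + rr[ok]
    hit <- mask[nb]
    if (any(hit))
      edges <- c(edges, rbind(id[fg[ok][hit]], id[nb[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  lab[fg] <- comp$membership
  lab
}

# Validate a scalar field of a config, erroring with the field name.
chk <- function(ok, field, what) {
  if (!isTRUE(ok))
    stop(sprintf("invalid configuration: field '%s' %s", field, what), call. = FALSE)
  invisible(TRUE)
}

# Clamp to [lo, hi]. Argument order keeps x's attributes (dim) intact.
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
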