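#' Vessel density
#'
#' Percentage of vessel pixels in the binary map, an exact integer ratio.
#' An optional region-of-interest mask restricts the computation.
#'
#' @param map a `binary_vessel_map` or logical matrix.
#' @param roi optional logical matrix of the same shape.
#' @return list of class `vessel_density`: `vd_percent`, `n_vessel_px`,
#'   `n_total_px`.
#' @export
vessel_density <- function(map, roi = NULL) {
  mask <- if (inherits(map, "binary_vessel_map")) map$mask else map
  if (!is.logical(mask) || length(mask) == 0L)
    stop("map must be a non-empty logical matrix", call. = FALSE)
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(mask)))
      stop("roi shape differs from map", call. = FALSE)
    if (!any(roi)) stop("roi is empty", call. = FALSE)
    n_tot <- sum(roi)
    n_ves <- sum(mask & roi)
  } else {
    n_tot <- length(mask)
    n_ves <- sum(mask)
  }
  structure(list(vd_percent = 100 * n_ves / n_tot,
                 n_vessel_px = as.integer(n_ves),
                 n_total_px = as.integer(n_tot)),
            class = "vessel_density")
}

#' @export
print.vessel_density <- function(x, ...) {
  cat(sprintf("vessel density: %.3f%% (%d / %d px)\n",
              x$vd_percent, x$n_vessel_px, x$n_total_px))
  invisible(x)
}

# One Guo-Hall subiteration, fully vectorized. Neighbours p1..p8 start at
# north and run clockwise (rows grow downward). A pixel is deleted when its
# boundary crossing number C is 1 (topology preserved), its neighbour count
# N = min(N1, N2) is 2 or 3, and the subiteration's direction test holds.
.gh_pass <- function(mask, odd) {
  n <- nrow(mask); m <- ncol(mask)
  p <- matrix(FALSE, n + 2L, m + 2L)
  p[2:(n + 1L), 2:(m + 1L)] <- mask
  sh <- function(dr, dc) p[(2L + dr):(n + 1L + dr), (2L + dc):(m + 1L + dc)]
  No <- sh(-1L, 0L); NE <- sh(-1L, 1L); Ea <- sh(0L, 1L); SE <- sh(1L, 1L)
  So <- sh(1L, 0L); SW <- sh(1L, -1L); We <- sh(0L, -1L); NW <- sh(-1L, -1L)
  C <- (!No & (NE | Ea)) + (!Ea & (SE | So)) +
       (!So & (SW | We)) + (!We & (NW | No))
  N1 <- (NW | No) + (NE | Ea) + (SE | So) + (SW | We)
  N2 <- (No | NE) + (Ea | SE) + (So | SW) + (We | NW)
  N <- pmin(N1, N2)
  c3 <- if (odd) ((No | NE | !SE) & Ea) else ((So | SW | !NW) & We)
  del <- mask & C == 1L & N >= 2L & N <= 3L & !c3
  mask & !del
}

#' Topology-preserving skeletonization
#'
#' Thins a binary vessel map to one-pixel-wide centerlines using the
#' Guo-Hall two-subiteration parallel thinning algorithm. Connectivity is
#' preserved (the crossing-number condition), so the skeleton has the
#' same number of 8-connected components as the input.
#'
#' @param map a `binary_vessel_map` or logical matrix.
#' @param max_iter safety cap on thinning iterations.
#' @return object of class `skeleton_map` with logical field `mask`.
#' @export
skeletonize_map <- function(map, max_iter = 1000L) {
  mask <- if (inherits(map, "binary_vessel_map")) map$mask else map
  if (!is.logical(mask)) stop("map must be logical", call. = FALSE)
  for (i in seq_len(max_iter)) {
    m1 <- .gh_pass(mask, TRUE)
    m2 <- .gh_pass(m1, FALSE)
    if (identical(m2, mask)) break
    mask <- m2
  }
  structure(list(mask = mask), class = "skeleton_map")
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("skeleton: %d centerline px in %d x %d\n",
              sum(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Multifractal spectrum of a binary vascular pattern
#'
#' Generalized (Renyi) dimensions D(q) by box counting. For each box size
#' eps the image is tiled, the occupancy measure of box i is
#' mu_i = (vessel pixels in box) / (total vessel pixels), and
#' \itemize{
#'   \item for q != 1: D(q) = slope of log(sum mu_i^q) vs log(eps) / (q-1);
#'   \item for q = 1:  D(1) = slope of sum(mu_i log mu_i) vs log(eps).
#' }
#' Slopes are least squares over the box-size range, anchored through the
#' whole-image scale (eps = image side), where the partition function is
#' exactly 1 for every q: a single box holds the entire measure. With the
#' anchored fit each D(q) is a positively weighted average of normalized
#' Renyi entropies, so the spectrum is non-increasing in q by
#' construction, as generalized dimensions must be. `fit_r2` records the
#' per-q goodness of fit (squared uncentered correlation of the anchored
#' regression). Boxes partially overlapping the image edge participate
#' with their true pixel content. D(0) is the capacity (box-counting)
#' dimension and the default summary statistic.
#'
#' For q >= 0 every D(q) lies in \[0, 2\] (up to a small inflation when
#' box sizes do not divide the image side, since partially covered edge
#' boxes still count in full). For q < 0 the standard box-counting
#' moments are dominated by boxes holding only a pixel or two, and the
#' estimate may exceed the embedding dimension 2 on inhomogeneous
#' patterns; this is a known property of the estimator, not an error.
#'
#' @param map a `binary_vessel_map` or logical matrix with >= 1 TRUE pixel.
#' @param q_values moment orders; must include 0 (default -4..4 by 0.5).
#' @param box_sizes_px strictly increasing box sizes; default dyadic from
#'   4 px up to side/4. At least 3 sizes are required.
#' @param summary one of "d0" (capacity dimension, default) or "mean_dq"
#'   (mean of D(q) over the grid).
#' @return object of class `mf_spectrum`: `q_values`, `d_q`, `fit_r2`,
#'   `box_sizes_px`, `summary_fd`.
#' @examples
#' m <- matrix(TRUE, 64, 64)
#' multifractal_spectrum(m)$summary_fd  # filled plane: 2
#' @export
multifractal_spectrum <- function(map, q_values = seq(-4, 4, by = 0.5),
                                  box_sizes_px = NULL, summary = c("d0", "mean_dq")) {
  mask <- if (inherits(map, "binary_vessel_map")) map$mask else map
  if (!is.logical(mask)) stop("map must be logical", call. = FALSE)
  summary <- match.arg(summary)
  n_fg <- sum(mask)
  if (n_fg == 0L) stop("empty pattern: no vessel pixels", call. = FALSE)
  if (!any(q_values == 0)) stop("q_values must contain 0", call. = FALSE)
  side <- min(dim(mask))
  if (is.null(box_sizes_px)) {
    box_sizes_px <- 4L
    while (utils::tail(box_sizes_px, 1L) * 2L <= side %/% 4L)
      box_sizes_px <- c(box_sizes_px, utils::tail(box_sizes_px, 1L) * 2L)
  }
  box_sizes_px <- as.integer(box_sizes_px)
  if (length(box_sizes_px) < 3L)
    stop("at least 3 box sizes are required", call. = FALSE)
  if (any(diff(box_sizes_px) <= 0L) || any(box_sizes_px < 1L))
    stop("box_sizes_px must be strictly increasing positive integers",
         call. = FALSE)
  if (max(box_sizes_px) >= max(dim(mask)))
    stop("box sizes must be smaller than the image side", call. = FALSE)

  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  r <- ((fg - 1L) %% nr) + 1L
  cl <- ((fg - 1L) %/% nr) + 1L
  nq <- length(q_values)
  ns <- length(box_sizes_px)
  logz <- matrix(NA_real_, ns, nq)    # log partition (or entropy for q=1)
  for (si in seq_len(ns)) {
    eps <- box_sizes_px[si]
    nbr <- ceiling(nr / eps)
    bid <- (ceiling(cl / eps) - 1L) * nbr + ceiling(r / eps)
    cntall <- tabulate(bid)
    cnt <- cntall[cntall > 0L]
    mu <- cnt / n_fg
    for (qi in seq_len(nq)) {
      q <- q_values[qi]
      logz[si, qi] <- if (q == 1) sum(mu * log(mu)) else log(sum(mu^q))
    }
  }
  # anchored regression: x = log(eps / L) with L the whole-image scale,
  # through the exactly known point (x = 0, log Z = 0)
  x <- log(box_sizes_px / max(dim(mask)))
  sxx <- sum(x^2)
  d_q <- numeric(nq); r2 <- numeric(nq)
  for (qi in seq_len(nq)) {
    y <- logz[, qi]
    slope <- sum(x * y) / sxx
    syy <- sum(y^2)
    r2[qi] <- if (syy == 0) 1 else
      min(1, max(0, (sum(x * y))^2 / (sxx * syy)))
    q <- q_values[qi]
    d_q[qi] <- if (q == 1) slope else slope / (q - 1)
  }
  fd <- if (summary == "d0") d_q[q_values == 0][1L] else mean(d_q)
  structure(list(q_values = q_values, d_q = unname(d_q), fit_r2 = r2,
                 box_sizes_px = box_sizes_px, summary_fd = unname(fd),
                 summary_mode = summary),
            class = "mf_spectrum")
}

#' @export
print.mf_spectrum <- function(x, ...) {
  cat(sprintf("multifractal spectrum: q in [%g, %g] (%d points), boxes {%s} px\n",
              min(x$q_values), max(x$q_values), length(x$q_values),
              paste(x$box_sizes_px, collapse = ", ")))
  i0 <- which(x$q_values == 0)
  cat(sprintf("  D(0) = %.4f, D(q) range [%.4f, %.4f], summary_fd = %.4f (%s)\n",
              x$d_q[i0], min(x$d_q), max(x$d_q), x$summary_fd, x$summary_mode))
  invisible(x)
}

#' @export
plot.mf_spectrum <- function(x, ...) {
  graphics::plot(x$q_values, x$d_q, type = "b", pch = 16,
                 xlab = "moment order q", ylab = "D(q)",
                 main = "Generalized dimension spectrum", ...)
  invisible(x)
}

#' Per-eye metric table
#'
#' Runs segmentation and morphometrics over a list of enface images and
#' returns one row per eye: identifiers, vessel density, summary fractal
#' dimension, the full D(q) spectrum (JSON-serialized), and the key
#' processing parameters. Unreadable or failing images yield a flagged
#' row (`ok = FALSE`) and processing continues.
#'
#' @param images list of `octa_enface` objects or image file paths.
#' @param q_values,box_sizes_px passed to [multifractal_spectrum()].
#' @param ... segmentation parameters passed to [segment_vessels()].
#' @return data.frame with columns subject_id, eye, vd_percent,
#'   summary_fd, d_q_json, ok, note, and parameter columns.
#' @export
metric_table <- function(images, q_values = seq(-4, 4, by = 0.5),
                         box_sizes_px = NULL, ...) {
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    out <- tryCatch({
      if (is.character(img)) img <- read_enface(img)
      seg <- segment_vessels(img, ...)
      vd <- vessel_density(seg)
      sp <- multifractal_spectrum(seg, q_values = q_values,
                                  box_sizes_px = box_sizes_px)
      data.frame(subject_id = img$subject_id, eye = img$eye,
                 vd_percent = vd$vd_percent, summary_fd = sp$summary_fd,
                 d_q_json = as.character(jsonlite::toJSON(
                   list(q = sp$q_values, d_q = sp$d_q), digits = NA)),
                 ok = TRUE, note = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(subject_id = if (is.character(img)) img else
                   if (!is.null(img$subject_id)) img$subject_id else NA_character_,
                 eye = if (is.list(img) && !is.null(img$eye)) img$eye else NA_character_,
                 vd_percent = NA_real_, summary_fd = NA_real_,
                 d_q_json = NA_character_, ok = FALSE,
                 note = conditionMessage(e), stringsAsFactors = FALSE)
    })
    out
  })
  hdr <- data.frame(subject_id = character(), eye = character(),
                    vd_percent = numeric(), summary_fd = numeric(),
                    d_q_json = character(), ok = logical(),
                    note = character(), stringsAsFactors = FALSE)
  do.call(rbind, c(list(hdr), rows))
}
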