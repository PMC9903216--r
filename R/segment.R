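#' Frangi vesselness enhancement
#'
#' Multiscale Hessian-based ridge filter for bright tubular structures.
#' At each scale sigma the image is convolved with scale-normalized
#' Gaussian second-derivative kernels; from the Hessian eigenvalues
#' ordered |lambda1| <= |lambda2| the response is
#' `exp(-Rb^2/(2*beta^2)) * (1 - exp(-S^2/(2*c^2)))` where
#' `Rb = lambda1/lambda2` (blobness) and `S = sqrt(lambda1^2+lambda2^2)`
#' (second-order structure), zeroed where `lambda2 >= 0` (dark or flat).
#' The per-pixel maximum over scales is rescaled to \[0, 1\].
#'
#' @param img an `octa_enface` object or a numeric matrix of finite,
#'   nonnegative intensities.
#' @param scales Gaussian scales sigma in pixels. The defaults
#'   (1, 1.5, 2, 3) cover vessel calibers of roughly 8-40 um at 6 um/px.
#' @param beta blobness sensitivity (default 0.5).
#' @param c structure sensitivity; `NULL` (default) sets c to half the
#'   maximum Hessian norm of the image at each scale.
#' @return an object of class `vesselness_map` with fields `values`
#'   (matrix in \[0,1\]) and `scales_used`.
#' @export
frangi_enhance <- function(img, scales = c(1, 1.5, 2, 3), beta = 0.5, c = NULL) {
  x <- if (inherits(img, "octa_enface")) img$pixels else img
  if (!is.matrix(x) || length(x) == 0L)
    stop("image must be a non-empty matrix", call. = FALSE)
  if (nrow(x) != ncol(x)) stop("image must be square", call. = FALSE)
  if (!all(is.finite(x))) stop("image contains non-finite pixels", call. = FALSE)
  if (length(scales) == 0L || any(scales <= 0))
    stop("scales must be a non-empty list of positive values", call. = FALSE)
  if (!is.null(c) && c <= 0) stop("c must be positive", call. = FALSE)
  if (beta <= 0) stop("beta must be positive", call. = FALSE)

  best <- matrix(0, nrow(x), ncol(x))
  for (s in scales) {
    g0 <- gauss_kernel(s, 0L); g1 <- gauss_kernel(s, 1L); g2 <- gauss_kernel(s, 2L)
    hrr <- s^2 * conv_sep(x, g2, g0)   # d2/drow2
    hcc <- s^2 * conv_sep(x, g0, g2)   # d2/dcol2
    hrc <- s^2 * conv_sep(x, g1, g1)
    half <- (hrr - hcc) / 2
    disc <- sqrt(half^2 + hrc^2)
    mid <- (hrr + hcc) / 2
    mu1 <- mid + disc; mu2 <- mid - disc
    big <- abs(mu1) >= abs(mu2)
    lam2 <- ifelse(big, mu1, mu2)      # larger magnitude
    lam1 <- ifelse(big, mu2, mu1)
    S2 <- lam1^2 + lam2^2
    cs <- if (is.null(c)) sqrt(max(S2)) / 2 else c
    # flat (or numerically flat) image at this scale: no response
    if (cs < sqrt(.Machine$double.eps) * max(1, max(abs(x)))) next
    rb2 <- ifelse(lam2 == 0, 0, (lam1 / lam2)^2)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cs^2)))
    v[lam2 >= 0] <- 0
    best <- pmax(best, v)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  structure(list(values = best, scales_used = scales),
            class = "vesselness_map")
}

#' @export
print.vesselness_map <- function(x, ...) {
  cat(sprintf("vesselness map: %d x %d, scales {%s}, %.1f%% of pixels > 0.1\n",
              nrow(x$values), ncol(x$values),
              paste(x$scales_used, collapse = ", "),
              100 * mean(x$values > 0.1)))
  invisible(x)
}

#' Otsu global threshold
#'
#' Histogram threshold maximizing between-class variance over `levels`
#' equal-width bins spanning the data range. Ties go to the lowest
#' maximizing bin. The mask marks pixels strictly above the threshold
#' (the upper edge of the background class).
#'
#' @param values numeric matrix (or a `vesselness_map`).
#' @param levels number of histogram bins (default 256).
#' @return list with `threshold` (numeric) and `mask` (logical matrix).
#' @export
otsu_threshold <- function(values, levels = 256L) {
  x <- if (inherits(values, "vesselness_map")) values$values else values
  if (!all(is.finite(x))) stop("values contain non-finite entries", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate histogram: input is constant, no threshold exists",
         call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(idx, nbins = levels)
  p <- cnt / sum(cnt)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[levels]
  w1 <- 1 - w0
  sb2 <- (mt * w0 - m0)^2 / (w0 * w1)
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2[-levels])          # split after bin k
  thr <- breaks[k + 1L]
  list(threshold = thr, mask = x > thr)
}

#' Local adaptive threshold
#'
#' Marks a pixel TRUE iff its value exceeds the mean of its
#' `window_px` x `window_px` neighbourhood minus `offset`. Boundaries are
#' handled by mirror reflection. With a constant image, `offset > 0`
#' yields an all-TRUE mask and `offset < 0` an all-FALSE mask.
#'
#' @param values numeric matrix (or a `vesselness_map`).
#' @param window_px odd window size >= 3.
#' @param offset subtracted from the local mean before comparison.
#' @return logical matrix.
#' @export
adaptive_threshold <- function(values, window_px = 25L, offset = 0) {
  x <- if (inherits(values, "vesselness_map")) values$values else values
  window_px <- as.integer(window_px)
  if (is.na(window_px) || window_px < 3L || window_px %% 2L == 0L)
    stop("window_px must be an odd integer >= 3", call. = FALSE)
  x > (local_mean(x, window_px) - offset)
}

#' Combine global and local threshold maps by agreement
#'
#' The final binary vessel map keeps a pixel only where both the global
#' (Otsu) and local (adaptive) threshold maps agree it is vessel, i.e.
#' the elementwise AND.
#'
#' @param global_mask,local_mask logical matrices of identical shape.
#' @param provenance optional named list of the parameters that produced
#'   the two inputs; stored on the result.
#' @return object of class `binary_vessel_map` with fields `mask` and
#'   `provenance`.
#' @export
combine_agreement <- function(global_mask, local_mask, provenance = list()) {
  if (!is.logical(global_mask) || !is.logical(local_mask))
    stop("masks must be logical", call. = FALSE)
  if (!identical(dim(global_mask), dim(local_mask)))
    stop("mask shapes differ", call. = FALSE)
  structure(list(mask = global_mask & local_mask, provenance = provenance),
            class = "binary_vessel_map")
}

#' @export
print.binary_vessel_map <- function(x, ...) {
  cat(sprintf("binary vessel map: %d x %d, %d vessel px (%.2f%%)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Remove small connected components from a binary map
#'
#' Deletes 8-connected foreground components smaller than `min_object_px`
#' pixels. `min_object_px = 0` is the identity.
#'
#' @param map a `binary_vessel_map` or logical matrix.
#' @param min_object_px minimum surviving component size in pixels.
#' @return same class as the input.
#' @export
clean_binary <- function(map, min_object_px = 10L) {
  is_bvm <- inherits(map, "binary_vessel_map")
  mask <- if (is_bvm) map$mask else map
  min_object_px <- as.integer(min_object_px)
  if (min_object_px > 0L && any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    keep <- sizes >= min_object_px
    mask <- matrix(lab > 0L & keep[pmax(lab, 1L)], nrow(mask), ncol(mask))
  }
  if (is_bvm) {
    map$mask <- mask
    map$provenance$min_object_px <- min_object_px
    map
  } else mask
}

#' 3x3 median filter (optional despeckle prefilter)
#'
#' Median of the 8-neighbourhood plus centre, mirror boundary. Implemented
#' as a 9-input selection network so it stays vectorized.
#'
#' @param x numeric matrix.
#' @return filtered matrix.
#' @export
median_filter3 <- function(x) {
  p <- pad_reflect(x, 1L)
  n <- nrow(x); m <- ncol(x)
  v <- vector("list", 9L)
  k <- 1L
  for (dr in 0:2) for (dc in 0:2) {
    v[[k]] <- p[(1L + dr):(n + dr), (1L + dc):(m + dc), drop = FALSE]
    k <- k + 1L
  }
  sw <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  # 19-comparator median-of-9 network (Paeth); median ends in slot 5
  sw(2,3); sw(5,6); sw(8,9); sw(1,2); sw(4,5); sw(7,8); sw(2,3); sw(5,6)
  sw(8,9); sw(1,4); sw(6,9); sw(5,8); sw(4,7); sw(2,5); sw(3,6); sw(5,8)
  sw(5,3); sw(7,5); sw(5,3)
  v[[5]]
}

#' Segment vessels in an enface image
#'
#' The full enhancement/segmentation chain: optional 3x3 median
#' despeckle, Frangi vesselness enhancement, global Otsu and local
#' adaptive thresholding of the enhanced image, agreement (AND)
#' combination, and small-object cleanup.
#'
#' The thresholded "filtered image" is a convex blend of the raw
#' intensities and the vesselness response,
#' `(1 - vessel_gain) * raw + vessel_gain * vesselness`. The blend keeps
#' the flow-signal contrast across the full vessel lumen (a pure
#' vesselness map decays toward lumen edges and systematically thins the
#' mask) while still suppressing non-tubular background. `vessel_gain = 1`
#' thresholds the vesselness map alone; `use_frangi = FALSE` thresholds
#' the raw image.
#'
#' @param img `octa_enface` or numeric matrix.
#' @param scales,beta,c passed to [frangi_enhance()].
#' @param vessel_gain blend weight of the vesselness response in the
#'   thresholded image, in \[0, 1\] (default 0.5).
#' @param window_px,offset passed to [adaptive_threshold()].
#' @param min_object_px passed to [clean_binary()].
#' @param use_frangi if FALSE both thresholds run on the raw image.
#' @param median_prefilter optional 3x3 median despeckle before
#'   enhancement (default off).
#' @return a `binary_vessel_map` with full parameter provenance.
#' @examples
#' out <- generate_enface(enface_config(side_px = 128, rng_seed = 2))
#' seg <- segment_vessels(out$image)
#' vessel_density(seg)
#' @export
segment_vessels <- function(img, scales = c(1, 1.5, 2, 3), beta = 1,
                            c = NULL, vessel_gain = 0.5, window_px = 25L,
                            offset = 0, min_object_px = 10L,
                            use_frangi = TRUE, median_prefilter = FALSE) {
  x <- if (inherits(img, "octa_enface")) img$pixels else img
  if (vessel_gain < 0 || vessel_gain > 1)
    stop("vessel_gain must lie in [0, 1]", call. = FALSE)
  if (median_prefilter) x <- median_filter3(x)
  feat <- if (use_frangi) {
    v <- frangi_enhance(x, scales = scales, beta = beta, c = c)$values
    (1 - vessel_gain) * x + vessel_gain * v
  } else x
  ot <- otsu_threshold(feat)
  ad <- adaptive_threshold(feat, window_px = window_px, offset = offset)
  bvm <- combine_agreement(ot$mask, ad,
                           provenance = list(otsu_threshold = ot$threshold,
                                             scales = scales, beta = beta,
                                             c = c, vessel_gain = vessel_gain,
                                             window_px = window_px,
                                             offset = offset,
                                             use_frangi = use_frangi,
                                             median_prefilter = median_prefilter))
  clean_binary(bvm, min_object_px)
}
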