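#' Configuration for the synthetic enface image generator
#'
#' Builds and validates the parameter set for [generate_enface()]. Defaults
#' describe a 3 mm x 3 mm superficial-plexus enface acquisition sampled at
#' 6 um per pixel, with vessel calibers spanning the capillary (8 um) to
#' arteriole/venule (40 um) range, a central foveal avascular zone, and
#' speckle noise whose spread is tied to the instrument signal-strength
#' index Q (in decibels).
#'
#' @param side_px image side in pixels.
#' @param pixel_um physical pixel size, micrometres per pixel.
#' @param faz_radius_um radius of the foveal avascular zone disc, um.
#' @param n_seed_vessels number of vessel trees seeded at the image border.
#'   Zero is allowed and yields an empty (avascular) image.
#' @param min_caliber_um,max_caliber_um vessel diameter range, um. Branches
#'   terminate once tapering takes them below `min_caliber_um`.
#' @param branch_prob per-growth-step probability of a bifurcation.
#' @param murray_exponent exponent k of the radius branching rule
#'   r_parent^k = sum(r_child^k); k = 3 is Murray's law of minimal work.
#' @param noise_sigma baseline speckle spread at the reference quality of
#'   30 dB; the effective spread is scaled by `10^((30 - quality_db)/20)`.
#' @param quality_db target signal strength Q in dB (instrument floor 20).
#' @param rng_seed integer seed; all generator randomness derives from it.
#' @return an object of class `enface_config` (a validated list).
#' @export
enface_config <- function(side_px = 500L, pixel_um = 6, faz_radius_um = 250,
                          n_seed_vessels = 14L, min_caliber_um = 8,
                          max_caliber_um = 40, branch_prob = 0.12,
                          murray_exponent = 3, noise_sigma = 0.5,
                          quality_db = 37, rng_seed = 1L) {
  cfg <- list(side_px = as.integer(side_px), pixel_um = pixel_um,
              faz_radius_um = faz_radius_um,
              n_seed_vessels = as.integer(n_seed_vessels),
              min_caliber_um = min_caliber_um, max_caliber_um = max_caliber_um,
              branch_prob = branch_prob, murray_exponent = murray_exponent,
              noise_sigma = noise_sigma, quality_db = quality_db,
              rng_seed = as.integer(rng_seed))
  chk(cfg$side_px >= 16L, "side_px", "must be a positive integer >= 16")
  chk(cfg$pixel_um > 0, "pixel_um", "must be positive")
  chk(cfg$faz_radius_um >= 0, "faz_radius_um", "must be nonnegative")
  chk(cfg$faz_radius_um < cfg$side_px * cfg$pixel_um / 2,
      "faz_radius_um", "must be smaller than half the field of view")
  chk(cfg$n_seed_vessels >= 0L, "n_seed_vessels", "must be nonnegative")
  chk(cfg$min_caliber_um > 0, "min_caliber_um", "must be positive")
  chk(cfg$max_caliber_um >= cfg$min_caliber_um, "max_caliber_um",
      "must be >= min_caliber_um")
  chk(cfg$min_caliber_um / cfg$pixel_um >= 1 || cfg$pixel_um > 8,
      "min_caliber_um", "must resolve to at least one pixel")
  chk(cfg$branch_prob >= 0 && cfg$branch_prob <= 1, "branch_prob",
      "must lie in [0, 1]")
  chk(cfg$murray_exponent > 0, "murray_exponent", "must be positive")
  chk(cfg$noise_sigma >= 0, "noise_sigma", "must be nonnegative")
  chk(is.finite(cfg$quality_db), "quality_db", "must be finite")
  class(cfg) <- "enface_config"
  cfg
}

#' @export
print.enface_config <- function(x, ...) {
  cat(sprintf("enface generator config: %d px @ %.1f um/px (%.2f mm field)\n",
              x$side_px, x$pixel_um, x$side_px * x$pixel_um / 1000))
  cat(sprintf("  %d seed vessels, calibers %.0f-%.0f um, branch prob %.2f, Murray k=%.1f\n",
              x$n_seed_vessels, x$min_caliber_um, x$max_caliber_um,
              x$branch_prob, x$murray_exponent))
  cat(sprintf("  FAZ radius %.0f um, Q = %.1f dB, noise sigma %.2f, seed %d\n",
              x$faz_radius_um, x$quality_db, x$noise_sigma, x$rng_seed))
  invisible(x)
}

# Grow one vessel tree from a border seed. Returns a list of segments,
# each c(x0, y0, x1, y1, r_px). Coordinates in pixels, origin at (1,1).
# Centerlines never enter the FAZ disc: a branch stops just outside it.
grow_tree <- function(side, faz_c, faz_r, r0_px, min_r_px, branch_prob, k,
                      max_segments = 4000L) {
  step <- 6
  # seed on a random border edge, heading inward
  edge <- sample.int(4L, 1L)
  u <- runif(1, 0.05, 0.95) * side
  start <- switch(edge, c(u, 1), c(side, u), c(u, side), c(1, u))
  ang0 <- switch(edge, pi / 2, pi, -pi / 2, 0) + runif(1, -0.6, 0.6)
  queue <- list(list(p = start, ang = ang0, r = r0_px))
  segs <- vector("list", 0L)
  while (length(queue) > 0L && length(segs) < max_segments) {
    br <- queue[[1L]]; queue <- queue[-1L]
    p <- br$p; ang <- br$ang; r <- br$r
    repeat {
      if (r < min_r_px || length(segs) >= max_segments) break
      ang <- ang + rnorm(1, 0, 0.25)
      q <- p + step * c(cos(ang), sin(ang))
      if (sqrt(sum((q - faz_c)^2)) < faz_r) break      # stop at FAZ rim
      segs[[length(segs) + 1L]] <- c(p, q, r)
      p <- q
      if (q[1] < -r || q[1] > side + r || q[2] < -r || q[2] > side + r) break
      r <- r * 0.995                                    # gentle taper
      if (runif(1) < branch_prob && r > 1.3 * min_r_px) {
        f <- runif(1, 0.3, 0.7)
        r1 <- r * f^(1 / k)
        r2 <- r * (1 - f)^(1 / k)
        dth <- runif(1, 0.35, 0.9)
        queue[[length(queue) + 1L]] <- list(p = p, ang = ang + dth, r = r2)
        ang <- ang - dth * runif(1, 0.3, 0.8)
        r <- r1
      }
    }
  }
  segs
}

# Rasterize segments into a logical lumen mask and centerline pixel set.
rasterize_segments <- function(segs, side) {
  mask <- matrix(FALSE, side, side)
  if (length(segs) == 0L)
    return(list(mask = mask, centerlines = matrix(integer(0), 0L, 2L)))
  pts_x <- numeric(0); pts_y <- numeric(0); pts_r <- numeric(0)
  for (s in segs) {
    len <- sqrt((s[3] - s[1])^2 + (s[4] - s[2])^2)
    nsmp <- max(2L, ceiling(len / 0.5))
    t <- seq(0, 1, length.out = nsmp)
    pts_x <- c(pts_x, s[1] + t * (s[3] - s[1]))
    pts_y <- c(pts_y, s[2] + t * (s[4] - s[2]))
    pts_r <- c(pts_r, rep(s[5], nsmp))
  }
  # centerline pixels (unique, inside the field)
  cx <- round(pts_x); cy <- round(pts_y)
  inb <- cx >= 1 & cx <= side & cy >= 1 & cy <= side
  ctr <- unique(cbind(row = as.integer(cy[inb]), col = as.integer(cx[inb])))
  # stamp discs, grouping samples by radius rounded to 0.25 px
  rb <- round(pts_r * 4) / 4
  for (rv in unique(rb)) {
    sel <- rb == rv
    rad <- max(rv, 0.5)
    w <- ceiling(rad)
    off <- expand.grid(dx = -w:w, dy = -w:w)
    off <- off[off$dx^2 + off$dy^2 <= rad^2, , drop = FALSE]
    px <- round(pts_x[sel]); py <- round(pts_y[sel])
    xx <- rep(px, each = nrow(off)) + off$dx
    yy <- rep(py, each = nrow(off)) + off$dy
    ok <- xx >= 1 & xx <= side & yy >= 1 & yy <= side
    mask[cbind(yy[ok], xx[ok])] <- TRUE
  }
  list(mask = mask, centerlines = ctr)
}

#' Generate a synthetic OCTA enface image with ground truth
#'
#' Draws stochastic branching vessel trees (child radii follow the Murray
#' rule r_p^k = r_1^k + r_2^k), rasterizes their lumens onto a pixel grid,
#' and renders an OCTA-like intensity image: vessel flow signal over a weak
#' background, degraded by multiplicative Rayleigh-type speckle plus
#' additive Gaussian noise whose spread grows as the quality index Q drops.
#' Vessel centerlines never enter the foveal avascular zone disc.
#'
#' @param cfg an [enface_config()].
#' @param subject_id,eye identifiers attached to the image.
#' @return a list with components `image` (class `octa_enface`: `pixels`
#'   matrix in \[0,1\], `pixel_um`, `subject_id`, `eye`) and `truth` (class
#'   `octa_truth`: logical `mask` of lumen pixels, `true_vd` percentage,
#'   `centerlines` pixel coordinates).
#' @examples
#' out <- generate_enface(enface_config(side_px = 128, rng_seed = 7))
#' out$truth$true_vd
#' @export
generate_enface <- function(cfg, subject_id = "synthetic", eye = "right") {
  if (!inherits(cfg, "enface_config")) cfg <- do.call(enface_config, cfg)
  eye <- match.arg(eye, c("right", "left"))
  side <- cfg$side_px
  with_seed(cfg$rng_seed, {
    faz_c <- c(side / 2, side / 2)
    faz_r <- cfg$faz_radius_um / cfg$pixel_um
    min_r_px <- cfg$min_caliber_um / 2 / cfg$pixel_um
    segs <- list()
    if (cfg$n_seed_vessels > 0L) {
      for (i in seq_len(cfg$n_seed_vessels)) {
        r0_um <- runif(1, 0.6 * cfg$max_caliber_um, cfg$max_caliber_um)
        segs <- c(segs, grow_tree(side, faz_c, faz_r,
                                  r0_px = r0_um / 2 / cfg$pixel_um,
                                  min_r_px = min_r_px,
                                  branch_prob = cfg$branch_prob,
                                  k = cfg$murray_exponent))
      }
    }
    ras <- rasterize_segments(segs, side)
    true_vd <- 100 * sum(ras$mask) / length(ras$mask)

    clean <- matrix(0.16, side, side)
    clean[ras$mask] <- 0.80
    clean <- conv_sep(clean, gauss_kernel(0.6))     # optical blur
    nscale <- cfg$noise_sigma * 10^((30 - cfg$quality_db) / 20)
    w <- clamp(nscale, 0, 1)
    ray <- sqrt(-2 * log(runif(side * side))) / sqrt(pi / 2)  # unit-mean Rayleigh
    speckle <- matrix((1 - w) + w * ray, side, side)
    img <- clean * speckle + rnorm(side * side, 0, 0.02 + 0.05 * nscale)
    img <- clamp(img)

    image <- structure(list(pixels = img, pixel_um = cfg$pixel_um,
                            subject_id = subject_id, eye = eye),
                       class = "octa_enface")
    truth <- structure(list(mask = ras$mask, true_vd = true_vd,
                            centerlines = ras$centerlines),
                       class = "octa_truth")
    list(image = image, truth = truth)
  })
}

#' @export
print.octa_enface <- function(x, ...) {
  cat(sprintf("OCTA enface image: %d x %d px @ %.1f um/px, subject %s (%s eye)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_um, x$subject_id, x$eye))
  cat(sprintf("  intensity range [%.3f, %.3f]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.octa_truth <- function(x, ...) {
  cat(sprintf("ground truth: %d vessel px (VD %.2f%%), %d centerline px\n",
              sum(x$mask), x$true_vd, nrow(x$centerlines)))
  invisible(x)
}
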