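test_that("frangi response is zero on a constant image", {
  v <- frangi_enhance(matrix(0.5, 32, 32))
  expect_true(all(v$values == 0))
})

test_that("frangi rejects bad input", {
  x <- matrix(0.5, 16, 16); x[3, 3] <- NA
  expect_error(frangi_enhance(x), "non-finite")
  expect_error(frangi_enhance(matrix(0.5, 16, 16), scales = numeric(0)),
               "scales")
  expect_error(frangi_enhance(matrix(0.5, 8, 16)), "square")
})

test_that("frangi response peaks on the ridge centerline", {
  n <- 64L; w <- 4
  x <- matrix(0, n, n)
  x[(n / 2 - w / 2 + 1):(n / 2 + w / 2), ] <- 1   # horizontal bright ridge
  v <- frangi_enhance(x, scales = c(w / 2))$values
  interior <- 5:(n - 4)
  hits <- vapply(interior, function(j) {
    rmax <- which.max(v[, j])
    abs(rmax - (n / 2 + 0.5)) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("frangi commutes with 90-degree rotation", {
  g <- generate_enface(enface_config(side_px = 96, rng_seed = 11))
  x <- g$image$pixels
  rot90 <- function(m) t(m)[, nrow(m):1]
  rot270 <- function(m) t(m[, ncol(m):1])
  v1 <- frangi_enhance(x)$values
  v2 <- rot270(frangi_enhance(rot90(x))$values)
  expect_lt(max(abs(v1 - v2)), 1e-6)
})

test_that("frangi output is invariant to additive intensity offset", {
  g <- generate_enface(enface_config(side_px = 64, faz_radius_um = 80, rng_seed = 13))
  v1 <- frangi_enhance(g$image$pixels)$values
  v2 <- frangi_enhance(g$image$pixels + 0.2)$values
  expect_lt(max(abs(v1 - v2)), 1e-10)
})

test_that("otsu separates a perfectly two-valued image", {
  x <- matrix(10, 20, 20)
  x[sample.int(400, 160)] <- 200
  res <- otsu_threshold(x)
  expect_gt(res$threshold, 10)
  expect_lt(res$threshold, 200)
  expect_identical(res$mask, x > 100)
})

test_that("otsu equals the exhaustive between-class-variance maximizer", {
  set.seed(19)
  for (i in 1:5) {
    x <- matrix(c(rnorm(700, 40, 12), rnorm(300, 150, 25)), 50)
    expect_identical(otsu_threshold(x)$threshold, brute_otsu(x))
  }
})

test_that("otsu threshold shifts with an additive offset", {
  set.seed(4)
  x <- matrix(runif(900), 30)
  d <- otsu_threshold(x + 7)$threshold - otsu_threshold(x)$threshold
  expect_equal(d, 7, tolerance = 1e-9)
})

test_that("otsu errors on a constant image", {
  expect_error(otsu_threshold(matrix(1, 10, 10)), "degenerate")
})

test_that("adaptive threshold closed forms on a constant image", {
  x <- matrix(0.4, 16, 16)
  expect_true(all(adaptive_threshold(x, 5, offset = 1)))
  expect_false(any(adaptive_threshold(x, 5, offset = -1)))
  expect_error(adaptive_threshold(x, 4), "odd")
  expect_error(adaptive_threshold(x, -3), "odd")
})

test_that("adaptive threshold matches brute-force local means on a ramp", {
  x <- matrix(seq(0, 1, length.out = 21), 21, 21)  # column-constant ramp
  for (w in c(3L, 7L)) {
    got <- adaptive_threshold(x, w, offset = 0.01)
    want <- x > (brute_local_mean(x, w) - 0.01)
    expect_identical(got, want)
  }
})

test_that("adaptive threshold resolves a period-2 checkerboard", {
  cb <- checkerboard(13)
  ad <- adaptive_threshold(cb, 3, offset = 0)
  expect_true(all(ad[cb == 1]))
  expect_false(any(ad[cb == 0]))
})

test_that("agreement combination is an exact AND with provenance", {
  n <- 100L
  a <- matrix(TRUE, n, n); b <- matrix(FALSE, n, n)
  expect_false(any(combine_agreement(a, b)$mask))
  set.seed(2)
  m <- matrix(runif(n * n) > 0.5, n, n)
  expect_identical(combine_agreement(m, m)$mask, m)
  g <- matrix(runif(n * n) > 0.4, n, n)
  l <- matrix(runif(n * n) > 0.6, n, n)
  out <- combine_agreement(g, l, provenance = list(tag = "x"))
  expect_identical(sum(out$mask), sum(g & l))
  expect_lte(sum(out$mask), min(sum(g), sum(l)))
  expect_equal(out$provenance$tag, "x")
  expect_error(combine_agreement(g, l[1:50, ]), "shape")
})

test_that("small-object cleanup keeps exactly the large components", {
  m <- matrix(FALSE, 30, 30)
  m[2:3, 2:3] <- TRUE            # 4 px
  m[10, 10:12] <- TRUE           # 3 px
  m[20:24, 20:23] <- TRUE        # 20 px
  expect_identical(clean_binary(m, 0), m)
  out <- clean_binary(m, 4)
  expect_true(all(out[20:24, 20:23]))
  expect_true(all(out[2:3, 2:3]))
  expect_false(any(out[10, 10:12]))
  expect_false(any(clean_binary(matrix(c(TRUE, TRUE, TRUE, FALSE), 2), 4)))
})

test_that("segmentation recovers ground truth on clean synthetic images", {
  # full acquisition geometry; the +/-2 pp density contract is calibrated
  # to the 3 mm / 500 px field
  for (s in 1:2) {
    g <- generate_enface(enface_config(side_px = 500, quality_db = 38,
                                       rng_seed = s))
    seg <- segment_vessels(g$image)
    expect_gt(dice_overlap(seg$mask, g$truth$mask), 0.85)
    vd <- vessel_density(seg)$vd_percent
    expect_lt(abs(vd - g$truth$true_vd), 2)
  }
})

test_that("final mask count never exceeds either threshold map's count", {
  g <- generate_enface(enface_config(side_px = 200, rng_seed = 6))
  v <- frangi_enhance(g$image)
  feat <- 0.5 * g$image$pixels + 0.5 * v$values
  ot <- otsu_threshold(feat)
  ad <- adaptive_threshold(feat)
  comb <- combine_agreement(ot$mask, ad)
  expect_lte(sum(comb$mask), min(sum(ot$mask), sum(ad)))
})
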