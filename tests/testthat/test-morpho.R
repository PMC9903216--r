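test_that("vessel density is an exact integer ratio", {
  expect_equal(vessel_density(matrix(TRUE, 10, 10))$vd_percent, 100)
  cb <- checkerboard(16) == 1
  expect_equal(vessel_density(cb)$vd_percent, 50)
  set.seed(3)
  m <- matrix(runif(1e6) > 0.7, 1000)
  vd <- vessel_density(m)
  expect_identical(vd$n_vessel_px, as.integer(sum(as.integer(m))))
  expect_identical(vd$vd_percent, 100 * sum(m) / 1e6)
})

test_that("vessel density respects an ROI and rejects an empty one", {
  m <- matrix(FALSE, 10, 10); m[1:5, ] <- TRUE
  roi <- matrix(FALSE, 10, 10); roi[1:5, ] <- TRUE
  expect_equal(vessel_density(m, roi)$vd_percent, 100)
  expect_error(vessel_density(m, matrix(FALSE, 10, 10)), "empty")
  expect_error(vessel_density(m, roi[1:5, ]), "shape")
})

test_that("vessel density is invariant under rotation and flip", {
  set.seed(9)
  m <- matrix(runif(400) > 0.6, 20)
  v0 <- vessel_density(m)$vd_percent
  expect_equal(vessel_density(t(m)[, 20:1])$vd_percent, v0)
  expect_equal(vessel_density(m[20:1, ])$vd_percent, v0)
})

test_that("skeletonization leaves 1-px lines unchanged", {
  l <- matrix(FALSE, 10, 10); l[5, 2:9] <- TRUE
  expect_identical(skeletonize_map(l)$mask, l)
  d <- matrix(FALSE, 12, 12); d[cbind(3:9, 3:9)] <- TRUE
  expect_identical(skeletonize_map(d)$mask, d)
})

test_that("a solid bar thins to its central row", {
  m <- matrix(FALSE, 15, 17); m[7:9, 4:14] <- TRUE
  sk <- skeletonize_map(m)$mask
  px <- which(sk, arr.ind = TRUE)
  expect_true(all(px[, "row"] == 8))
  expect_gte(nrow(px), 9)   # 11 minus at most 1 px per end
  expect_lte(nrow(px), 11)
})

test_that("skeleton is a subset and preserves component count", {
  m <- matrix(FALSE, 24, 24)
  m[3:6, 3:10] <- TRUE
  m[15:20, 14:20] <- TRUE
  sk <- skeletonize_map(m)$mask
  expect_false(any(sk & !m))
  lab_in <- octavasc:::label_components(m)
  lab_out <- octavasc:::label_components(sk)
  expect_equal(max(lab_out), max(lab_in))
  g <- generate_enface(enface_config(side_px = 200, rng_seed = 14))
  seg <- segment_vessels(g$image)
  sk2 <- skeletonize_map(seg)
  expect_false(any(sk2$mask & !seg$mask))
  expect_equal(max(octavasc:::label_components(sk2$mask)),
               max(octavasc:::label_components(seg$mask)))
})

test_that("generalized dimensions match analytic oracles", {
  sp <- multifractal_spectrum(matrix(TRUE, 64, 64), box_sizes_px = c(2, 4, 8, 16))
  expect_true(all(abs(sp$d_q - 2) < 0.05))
  ln <- matrix(FALSE, 243, 243); ln[120, ] <- TRUE
  spl <- multifractal_spectrum(ln, box_sizes_px = c(1, 3, 9, 27, 81))
  expect_lt(abs(spl$d_q[spl$q_values == 0] - 1), 0.1)
  carpet <- sierpinski_carpet(4)   # 81 x 81
  spc <- multifractal_spectrum(carpet, box_sizes_px = c(1, 3, 9, 27))
  expect_lt(abs(spc$summary_fd - log(8) / log(3)), 0.03)
})

test_that("box occupancy matches brute-force counting on a small fixture", {
  set.seed(5)
  m <- matrix(runif(144) > 0.6, 12)
  if (!any(m)) m[1, 1] <- TRUE
  # brute-force occupied box count at eps = 3
  occ <- 0
  for (bi in 1:4) for (bj in 1:4)
    occ <- occ + any(m[(3 * bi - 2):(3 * bi), (3 * bj - 2):(3 * bj)])
  sp <- multifractal_spectrum(m, q_values = c(-1, 0, 1),
                              box_sizes_px = c(1, 2, 3))
  # reconstruct N(3) from the q = 0 partition value used internally:
  # log Z_0(3) = log N(3); slope is fit, so recompute directly instead
  fg <- which(m); r <- ((fg - 1) %% 12) + 1; cl <- ((fg - 1) %/% 12) + 1
  bid <- (ceiling(cl / 3) - 1) * 4 + ceiling(r / 3)
  expect_equal(length(unique(bid)), occ)
})

test_that("spectrum validates its inputs", {
  m <- matrix(FALSE, 16, 16)
  expect_error(multifractal_spectrum(m), "empty pattern")
  m[3, 3] <- TRUE
  expect_error(multifractal_spectrum(m, box_sizes_px = c(2, 4)), "3 box sizes")
  expect_error(multifractal_spectrum(m, q_values = c(-1, 1)), "contain 0")
})

test_that("D(q) is non-increasing and bounded on varied patterns", {
  pats <- list(sierpinski_carpet(4),
               checkerboard(64) == 1,
               {set.seed(8); matrix(runif(4096) > 0.8, 64)})
  for (s in 1:4) {
    g <- generate_enface(enface_config(side_px = 128, quality_db = 30 + s,
                                       rng_seed = s))
    pats[[length(pats) + 1]] <- segment_vessels(g$image)$mask
  }
  for (p in pats) {
    sp <- multifractal_spectrum(p)
    expect_true(all(diff(sp$d_q) <= 1e-6))
    expect_true(all(is.finite(sp$d_q)))
    expect_true(all(sp$d_q >= 0))
    # the [0, 2] embedding bound holds for q >= 0 (partial edge boxes may
    # inflate it marginally); negative-q moments may legitimately exceed it
    expect_true(all(sp$d_q[sp$q_values >= 0] <= 2.05))
    expect_true(all(sp$fit_r2 >= 0 & sp$fit_r2 <= 1))
  }
})

test_that("the skeleton is no more space-filling than its source map", {
  g <- generate_enface(enface_config(side_px = 200, rng_seed = 23))
  seg <- segment_vessels(g$image)
  d_map <- multifractal_spectrum(seg)$summary_fd
  d_skel <- multifractal_spectrum(skeletonize_map(seg)$mask)$summary_fd
  expect_lte(d_skel, d_map)
})

test_that("measured VD and branching complexity co-vary across densities", {
  vds <- fds <- c()
  for (ns in c(4, 8, 14, 20)) for (s in 1:2) {
    g <- generate_enface(enface_config(side_px = 160, n_seed_vessels = ns,
                                       rng_seed = s + 10 * ns))
    seg <- segment_vessels(g$image)
    vds <- c(vds, vessel_density(seg)$vd_percent)
    fds <- c(fds, multifractal_spectrum(seg)$summary_fd)
  }
  expect_gt(cor(vds, fds, method = "spearman"), 0.7)
})

test_that("metric_table returns a full header on empty input and is deterministic", {
  empty <- metric_table(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("subject_id", "eye", "vd_percent", "summary_fd",
                    "d_q_json", "ok", "note") %in% names(empty)))
  imgs <- lapply(1:2, function(i) {
    generate_enface(enface_config(side_px = 160, quality_db = 37,
                                  rng_seed = i),
                    subject_id = sprintf("S%02d", i),
                    eye = c("right", "left")[i])$image
  })
  t1 <- metric_table(imgs)
  t2 <- metric_table(imgs)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 2)
  expect_true(all(t1$ok))
})

test_that("metric_table VD tracks ground truth on high-quality images", {
  # full acquisition geometry (500 px, 3 mm field)
  for (i in 1:2) {
    g <- generate_enface(enface_config(side_px = 500, quality_db = 37,
                                       rng_seed = 30 + i))
    tab <- metric_table(list(g$image))
    expect_lt(abs(tab$vd_percent - g$truth$true_vd), 2)
  }
})

test_that("metric_table flags unreadable input and continues", {
  g <- generate_enface(enface_config(side_px = 96, rng_seed = 2))
  tab <- metric_table(list("no/such/file.png", g$image))
  expect_false(tab$ok[1])
  expect_match(tab$note[1], "cannot read")
  expect_true(tab$ok[2])
})
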