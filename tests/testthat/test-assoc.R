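test_that("volume corrections match exact-ratio fixtures", {
  d <- data.frame(wmh_ml = 8.06, icv_ml = 1612,
                  pvs_cso_ml = 11.5, cso_ml = 319.4,
                  pvs_bg_ml = 2.9, bg_ml = 59.2)
  out <- transform_variables(d)
  expect_equal(out$wmh_pct_icv, 0.5, tolerance = 1e-12)
  expect_equal(out$wmh_log, log(0.5), tolerance = 1e-12)
  expect_equal(out$pvs_bg_pct, 4.9, tolerance = 0.01)
  expect_equal(out$pvs_cso_pct, 100 * 11.5 / 319.4, tolerance = 1e-12)
})

test_that("missing or zero denominators leave derived fields missing", {
  d <- data.frame(wmh_ml = c(8, 8, NA), icv_ml = c(NA, 0, 1600),
                  pvs_cso_ml = NA_real_, cso_ml = NA_real_,
                  pvs_bg_ml = NA_real_, bg_ml = NA_real_)
  expect_warning(out <- transform_variables(d), "zero")
  expect_true(all(is.na(out$wmh_pct_icv)))
  expect_equal(nrow(out), 3)   # rows retained
})

test_that("outcome regressed on itself gives beta 1 with a point CI", {
  d <- data.frame(y = rnorm(50))
  d$x <- d$y
  # lm warns about the (intentionally) perfect fit
  f <- suppressWarnings(fit_univariate(d, "y", "x"))
  expect_equal(f$beta_std, 1, tolerance = 1e-10)
  expect_lt(f$ci_high - f$ci_low, 1e-8)
})

test_that("standardized univariate slope equals Pearson correlation", {
  set.seed(33)
  for (i in 1:5) {
    n <- 60 + 40 * i
    x <- rnorm(n); y <- 0.1 * i * x + rnorm(n)
    d <- data.frame(out = y, pred = x)
    f <- fit_univariate(d, "out", "pred")
    expect_equal(f$beta_std, stats::cor(y, x), tolerance = 1e-10)
  }
})

test_that("univariate recovery: simulated slope lands in the CI most of the time", {
  set.seed(55)
  hits <- vapply(1:60, function(i) {
    x <- rnorm(400); y <- 0.3 * x + rnorm(400, 0, sqrt(1 - 0.09))
    f <- fit_univariate(data.frame(y = y, x = x), "y", "x")
    f$ci_low <= 0.3 && 0.3 <= f$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("insufficient and degenerate inputs raise named errors", {
  d <- data.frame(y = rnorm(5), x = rnorm(5))
  expect_error(fit_univariate(d, "y", "x"), "insufficient")
  expect_error(fit_univariate(d, "y", "z"), "missing column")
  coh <- test_cohort(200)
  expect_error(fit_adjusted(coh, "md_nawm", "vd_percent",
                            covariates = c("age", "vd_percent")),
               "rank-deficient")
  coh$vd_copy <- coh$vd_percent
  expect_error(fit_adjusted(coh, "md_nawm", "vd_percent",
                            covariates = c("age", "vd_copy")),
               "collinear|rank-deficient")
})

test_that("without confounding, adjusted and univariate betas agree", {
  set.seed(21)
  n <- 2000
  x <- rnorm(n); z <- rnorm(n)           # covariate independent of x
  y <- 0.25 * x + 0.3 * z + rnorm(n, 0, 0.9)
  d <- data.frame(y = y, x = x, z = z)
  fu <- fit_univariate(d, "y", "x")
  fa <- fit_adjusted(d, "y", "x", covariates = "z")
  se <- (fu$ci_high - fu$ci_low) / (2 * 1.96)
  expect_lt(abs(fa$beta_std - fu$beta_std), 2 * se)
})

test_that("adjustment removes the planted confounding of the generator", {
  coh <- test_cohort(4000, seed = 91)
  r <- coh[coh$eye == "right", ]
  fu <- fit_univariate(r, "md_nawm", "vd_percent")
  fa <- fit_adjusted(r, "md_nawm", "vd_percent")
  bias <- attr(coh, "univariate_bias_vd_md")
  expect_gte(-0.16, fa$ci_low); expect_lte(-0.16, fa$ci_high)
  expect_lt(abs(fu$beta_std - (-0.16 + bias)), 0.06)
  expect_gt(abs(fu$beta_std - fa$beta_std), 0.1)   # confounding was material
})

test_that("adjusted coefficient is invariant to affine covariate rescaling", {
  coh <- test_cohort(800, seed = 13)
  r <- coh[coh$eye == "right", ]
  f1 <- fit_adjusted(r, "md_nawm", "vd_percent")
  r2 <- r
  r2$age <- r2$age * 12 + 1000          # months, shifted
  r2$sbp_mmHg <- r2$sbp_mmHg / 7.5      # arbitrary unit change
  f2 <- fit_adjusted(r2, "md_nawm", "vd_percent")
  expect_equal(f1$beta_std, f2$beta_std, tolerance = 1e-8)
})

test_that("n_used equals the brute-force complete-case count", {
  coh <- test_cohort(500, seed = 17)
  r <- coh[coh$eye == "right", ]
  f <- fit_adjusted(r, "cvr_magnitude", "vd_percent")
  vars <- c("cvr_magnitude", "vd_percent", "age", "eye_disease", "diabetes",
            "sbp_mmHg", "image_quality")
  n_brute <- sum(rowSums(is.na(r[vars])) == 0)
  expect_identical(f$n_used, as.integer(n_brute))
})

test_that("association suite is tidy, deterministic and eye-aware", {
  coh <- test_cohort(300, seed = 3)
  expect_error(run_association_suite(coh, eye = "middle"), "unknown eye")
  empty <- run_association_suite(coh, eye = "right", outcomes = character(0))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("outcome", "predictor", "eye", "adjusted", "beta",
                    "ci_low", "ci_high", "n") %in% names(empty)))
  t1 <- run_association_suite(coh, eye = "right")
  t2 <- run_association_suite(coh, eye = "right")
  expect_identical(t1, t2)
  expect_true(all(t1$eye == "right"))
  expect_true(all(t1$ci_low <= t1$beta & t1$beta <= t1$ci_high))
  # both predictors, both model types present
  expect_setequal(unique(t1$predictor), c("vd_percent", "summary_fd"))
  expect_setequal(unique(t1$adjusted), c(TRUE, FALSE))
})

test_that("planted effects surface as significant in a large suite run", {
  coh <- test_cohort(2000, seed = 19)
  tab <- run_association_suite(coh, eye = "right")
  hit <- tab[tab$outcome == "md_nawm" & tab$predictor == "vd_percent" &
               tab$adjusted, ]
  expect_lt(hit$ci_high, 0)            # significantly negative
  null_hit <- tab[tab$outcome == "arterial_flow" &
                    tab$predictor == "vd_percent" & tab$adjusted, ]
  expect_true(null_hit$ci_low < 0 && null_hit$ci_high > 0)
})
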