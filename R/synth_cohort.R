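#' Configuration for the synthetic cohort generator
#'
#' Parameters for [generate_cohort()]. The generator emulates the tabular
#' structure of a mild-stroke cohort with retinal OCTA metrics, vascular
#' risk covariates and brain imaging outcomes: standardized effects of the
#' latent retinal metrics on selected brain metrics are planted, and the
#' covariates (age, diabetes, blood pressure, eye disease, image quality)
#' load on both sides so that unadjusted associations are confounded.
#'
#' @param n_subjects number of participants (two eye rows each).
#' @param effect_beta_vd_md planted standardized effect of vessel density
#'   on mean diffusivity in normal-appearing white matter.
#' @param effect_beta_vd_cvr planted standardized effect of vessel density
#'   on cerebrovascular reactivity magnitude.
#' @param effect_beta_fd_fa planted standardized effect of branching
#'   complexity (fractal dimension) on fractional anisotropy in NAWM.
#' @param covariate_means,covariate_sds named lists overriding the default
#'   location/scale of the generated variables (see Details).
#' @param missing_rate per-subject probability that one randomly chosen
#'   brain metric is missing; must be < 1.
#' @param eye_dev_sd standard deviation (on the standardized scale) of the
#'   within-subject eye-to-eye deviation of the retinal metrics.
#' @param rng_seed integer seed.
#' @details Default locations and scales: age 68.1 (9.9) years, SBP 149.0
#'   (19.67) mmHg, vessel density 32.1 (5.62) %, fractal complexity 1.81
#'   (0.03), Q 37.3 (2.92) dB, MD in NAWM 0.76 (0.02) 1e-3 mm^2/s, FA in
#'   NAWM 0.42 (0.02), CVR magnitude 0.043 (0.020) %/mmHg, ICV 1612 (160)
#'   ml, WMH volume log-normal with median 8.17 ml, arterial flow 9.44
#'   (1.94) ml/s.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 200L,
                          effect_beta_vd_md = -0.16,
                          effect_beta_vd_cvr = 0.19,
                          effect_beta_fd_fa = 0.17,
                          covariate_means = list(), covariate_sds = list(),
                          missing_rate = 0.05, eye_dev_sd = 0.15,
                          rng_seed = 1L) {
  means <- list(age = 68.1, sbp = 149.0, vd = 32.1, fd = 1.81, q = 37.3,
                md_nawm = 0.76, fa_nawm = 0.42, cvr = 0.043, icv = 1612,
                wmh_meanlog = log(8.17), flow = 9.44, fa_wmh = 0.27,
                md_wmh = 1.09, cso = 319, bg = 59.2,
                pvs_cso_meanlog = log(11.5), pvs_bg_meanlog = log(2.9),
                pvs_count_cso = 890, pvs_count_bg = 170)
  sds <- list(age = 9.9, sbp = 19.67, vd = 5.62, fd = 0.03, q = 2.92,
              md_nawm = 0.02, fa_nawm = 0.02, cvr = 0.020, icv = 160.4,
              wmh_sdlog = 1.245, flow = 1.94, fa_wmh = 0.04, md_wmh = 0.07,
              cso = 30, bg = 6, pvs_cso_sdlog = 0.69, pvs_bg_sdlog = 0.36,
              pvs_count_cso = 302, pvs_count_bg = 41)
  for (nm in names(covariate_means)) {
    chk(nm %in% names(means), paste0("covariate_means$", nm), "is unknown")
    means[[nm]] <- covariate_means[[nm]]
  }
  for (nm in names(covariate_sds)) {
    chk(nm %in% names(sds), paste0("covariate_sds$", nm), "is unknown")
    chk(covariate_sds[[nm]] > 0, paste0("covariate_sds$", nm), "must be > 0")
    sds[[nm]] <- covariate_sds[[nm]]
  }
  chk(all(unlist(sds) > 0), "covariate_sds", "must all be > 0")
  chk(missing_rate >= 0 && missing_rate < 1, "missing_rate",
      "must lie in [0, 1)")
  chk(eye_dev_sd >= 0, "eye_dev_sd", "must be nonnegative")
  cfg <- list(n_subjects = as.integer(n_subjects),
              effect_beta_vd_md = effect_beta_vd_md,
              effect_beta_vd_cvr = effect_beta_vd_cvr,
              effect_beta_fd_fa = effect_beta_fd_fa,
              means = means, sds = sds, missing_rate = missing_rate,
              eye_dev_sd = eye_dev_sd, rng_seed = as.integer(rng_seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("cohort generator config: %d subjects, seed %d\n",
              x$n_subjects, x$rng_seed))
  cat(sprintf("  planted betas: VD->MD %.2f, VD->CVR %.2f, FD->FA %.2f; missing rate %.2f\n",
              x$effect_beta_vd_md, x$effect_beta_vd_cvr,
              x$effect_beta_fd_fa, x$missing_rate))
  invisible(x)
}

# Confounder loadings shared between the retinal metrics and the brain
# outcomes. Order: age, quality, diabetes, eye disease, SBP (all on the
# standardized scale). Sigma is their covariance matrix (age-SBP r = 0.3).
.conf_sigma <- function() {
  s <- diag(5)
  s[1, 5] <- s[5, 1] <- 0.3
  s
}
.vd_loadings <- c(age = -0.35, q = 0.25, d = -0.20, e = -0.15, sbp = -0.10)

# Draw a unit-variance outcome with planted standardized beta on the
# latent predictor zp (itself unit variance with cov(zp, C) = cov_pc),
# confounder loadings b, and independent residual filling to variance 1.
.plant_outcome <- function(beta, zp, C, b, cov_pc, sigma, n) {
  v_sys <- beta^2 + drop(t(b) %*% sigma %*% b) + 2 * beta * sum(cov_pc * b)
  if (v_sys >= 1)
    stop("planted effect and confounder loadings exceed unit variance", call. = FALSE)
  beta * zp + drop(C %*% b) + rnorm(n, 0, sqrt(1 - v_sys))
}

#' Generate a synthetic subject table with planted eye-brain effects
#'
#' Simulates one row per participant and eye: retinal metrics (vessel
#' density, branching complexity, Q index, ordinal quality grade),
#' vascular covariates and brain imaging metrics. Brain outcomes are unit
#' variance linear functions of the latent retinal metrics with the
#' planted standardized betas, plus confounder contributions, so that the
#' covariate-adjusted model is unbiased for the planted effect while the
#' univariate model is biased by a known amount (attribute
#' `univariate_bias_vd_md` of the result).
#'
#' @param cfg a [cohort_config()].
#' @return a data.frame of class `octa_cohort`; one row per eye.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 50, rng_seed = 3))
#' nrow(coh)  # two eyes per subject
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) cfg <- do.call(cohort_config, cfg)
  n <- cfg$n_subjects
  if (n < 10L)
    stop("n_subjects must be at least 10 (degenerate model fits below that)",
         call. = FALSE)
  mu <- cfg$means; sd_ <- cfg$sds
  with_seed(cfg$rng_seed, {
    z_age <- rnorm(n)
    z_q <- rnorm(n)
    p_d <- 0.219; p_e <- 0.12
    diabetes <- rbinom(n, 1, p_d)
    eye_disease <- rbinom(n, 1, p_e)
    z_sbp <- 0.3 * z_age + sqrt(1 - 0.09) * rnorm(n)
    zc_d <- (diabetes - p_d) / sqrt(p_d * (1 - p_d))
    zc_e <- (eye_disease - p_e) / sqrt(p_e * (1 - p_e))
    C <- cbind(z_age, z_q, zc_d, zc_e, z_sbp)
    sigma <- .conf_sigma()
    a <- .vd_loadings
    s_v <- sqrt(1 - drop(t(a) %*% sigma %*% a))
    z_vd <- drop(C %*% a) + s_v * rnorm(n)
    rho <- 0.9
    z_fd <- rho * z_vd + sqrt(1 - rho^2) * rnorm(n)
    cov_vd_c <- drop(sigma %*% a)            # cov(z_vd, C)
    cov_fd_c <- rho * cov_vd_c

    b_md <- c(0.30, -0.15, 0.15, 0.10, 0.10)
    b_cvr <- c(-0.25, 0.10, -0.10, -0.05, -0.10)
    b_fa <- c(-0.25, 0.10, -0.10, -0.05, -0.05)
    z_md <- .plant_outcome(cfg$effect_beta_vd_md, z_vd, C, b_md, cov_vd_c, sigma, n)
    z_cvr <- .plant_outcome(cfg$effect_beta_vd_cvr, z_vd, C, b_cvr, cov_vd_c, sigma, n)
    z_fa <- .plant_outcome(cfg$effect_beta_fd_fa, z_fd, C, b_fa, cov_fd_c, sigma, n)

    # null outcomes carrying confounder structure only
    z_flow <- .plant_outcome(0, z_vd, C, c(-0.15, 0, 0, 0, -0.10), cov_vd_c, sigma, n)
    z_fawmh <- .plant_outcome(0, z_fd, C, c(-0.20, 0.05, -0.05, 0, -0.05), cov_fd_c, sigma, n)
    z_mdwmh <- .plant_outcome(0, z_vd, C, c(0.20, -0.05, 0.10, 0, 0.05), cov_vd_c, sigma, n)

    wmh_ml <- exp(mu$wmh_meanlog + 0.35 * z_age +
                    sqrt(sd_$wmh_sdlog^2 - 0.35^2) * rnorm(n))
    icv_ml <- mu$icv + sd_$icv * rnorm(n)
    cso_ml <- mu$cso + sd_$cso * rnorm(n)
    bg_ml <- mu$bg + sd_$bg * rnorm(n)
    pvs_cso_ml <- exp(mu$pvs_cso_meanlog + 0.30 * z_age +
                        sqrt(sd_$pvs_cso_sdlog^2 - 0.30^2) * rnorm(n))
    pvs_bg_ml <- exp(mu$pvs_bg_meanlog + 0.20 * z_age +
                       sqrt(sd_$pvs_bg_sdlog^2 - 0.20^2) * rnorm(n))
    pvs_count_cso <- pmax(0, round(mu$pvs_count_cso +
                                     sd_$pvs_count_cso * (0.3 * z_age + sqrt(0.91) * rnorm(n))))
    pvs_count_bg <- pmax(0, round(mu$pvs_count_bg +
                                    sd_$pvs_count_bg * (0.3 * z_age + sqrt(0.91) * rnorm(n))))

    q_db <- pmax(20, mu$q + sd_$q * (0.85 * z_q + sqrt(1 - 0.85^2) * rnorm(n)))
    grade_cuts <- qnorm(c(0.115, 0.346, 0.846, 0.904))
    image_quality <- findInterval(z_q, grade_cuts) + 1L

    sex <- ifelse(rbinom(n, 1, 0.65) == 1, "M", "F")
    hypertension <- rbinom(n, 1, clamp(plogis(0.9 + 0.8 * z_sbp), 0.01, 0.99))

    subj <- sprintf("S%04d", seq_len(n))
    two <- function(x) rep(x, each = 2L)
    eye <- rep(c("right", "left"), n)
    z_vd_eye <- two(z_vd) + cfg$eye_dev_sd * rnorm(2L * n)
    z_fd_eye <- two(z_fd) + cfg$eye_dev_sd * rnorm(2L * n)

    df <- data.frame(
      subject_id = two(subj), eye = eye,
      vd_percent = mu$vd + sd_$vd * z_vd_eye,
      summary_fd = mu$fd + sd_$fd * z_fd_eye,
      q_db = two(q_db), image_quality = two(image_quality),
      age = two(mu$age + sd_$age * z_age), sex = two(sex),
      diabetes = two(diabetes), hypertension = two(hypertension),
      sbp_mmHg = two(mu$sbp + sd_$sbp * z_sbp), eye_disease = two(eye_disease),
      wmh_ml = two(wmh_ml), icv_ml = two(icv_ml),
      pvs_cso_ml = two(pvs_cso_ml), cso_ml = two(cso_ml),
      pvs_bg_ml = two(pvs_bg_ml), bg_ml = two(bg_ml),
      pvs_count_cso = two(pvs_count_cso), pvs_count_bg = two(pvs_count_bg),
      cvr_magnitude = two(mu$cvr + sd_$cvr * z_cvr),
      arterial_flow = two(mu$flow + sd_$flow * z_flow),
      fa_nawm = two(mu$fa_nawm + sd_$fa_nawm * z_fa),
      md_nawm = two(mu$md_nawm + sd_$md_nawm * z_md),
      fa_wmh = two(mu$fa_wmh + sd_$fa_wmh * z_fawmh),
      md_wmh = two(mu$md_wmh + sd_$md_wmh * z_mdwmh),
      stringsAsFactors = FALSE)

    if (cfg$missing_rate > 0) {
      brain_cols <- c("wmh_ml", "pvs_cso_ml", "pvs_bg_ml", "cvr_magnitude",
                      "arterial_flow", "fa_nawm", "md_nawm", "fa_wmh", "md_wmh")
      hit <- runif(n) < cfg$missing_rate
      pick <- sample(brain_cols, n, replace = TRUE)
      for (i in which(hit)) df[df$subject_id == subj[i], pick[i]] <- NA
    }

    attr(df, "univariate_bias_vd_md") <- sum(cov_vd_c * b_md)
    attr(df, "univariate_bias_vd_cvr") <- sum(cov_vd_c * b_cvr)
    attr(df, "univariate_bias_fd_fa") <- sum(cov_fd_c * b_fa)
    class(df) <- c("octa_cohort", "data.frame")
    df
  })
}
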