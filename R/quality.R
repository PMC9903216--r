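#' Simulate two ordinal image-quality raters
#'
#' Ordinal-probit stand-in for two human raters grading OCTA image
#' interpretability on a 5-level scale (1 = Inadequate ... 5 = Excellent).
#' Each rater bins `true_quality + N(0, rater_noise_sd)` against four
#' ascending thresholds. Consensus equals the shared grade when the
#' raters agree; otherwise it is the rounded mean, with .5 ties rounded
#' up (to the higher grade) as a deterministic stand-in for resolution
#' by discussion.
#'
#' @param true_quality numeric vector, latent quality on the threshold
#'   scale (e.g. Q in dB).
#' @param rater_noise_sd standard deviation of each rater's independent
#'   perceptual noise.
#' @param thresholds four strictly ascending cut points.
#' @param seed integer seed.
#' @param subject_id,eye optional identifiers recycled to length.
#' @return data.frame of class `quality_records` with columns
#'   subject_id, eye, q_db, grade_r1, grade_r2, consensus.
#' @export
simulate_graders <- function(true_quality, rater_noise_sd,
                             thresholds = c(33, 35.5, 38, 40.5),
                             seed = 1L, subject_id = NULL, eye = "right") {
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0))
    stop("thresholds must be 4 strictly ascending values", call. = FALSE)
  if (rater_noise_sd < 0) stop("rater_noise_sd must be nonnegative", call. = FALSE)
  n <- length(true_quality)
  if (is.null(subject_id)) subject_id <- sprintf("S%04d", seq_len(n))
  with_seed(seed, {
    g1 <- findInterval(true_quality + rnorm(n, 0, rater_noise_sd), thresholds) + 1L
    g2 <- findInterval(true_quality + rnorm(n, 0, rater_noise_sd), thresholds) + 1L
    cons <- ifelse(g1 == g2, g1, as.integer(floor((g1 + g2) / 2 + 0.5)))
    structure(data.frame(subject_id = rep_len(subject_id, n),
                         eye = rep_len(eye, n),
                         q_db = true_quality,
                         grade_r1 = g1, grade_r2 = g2,
                         consensus = as.integer(cons),
                         stringsAsFactors = FALSE),
              class = c("quality_records", "data.frame"))
  })
}

#' Intraclass correlation, two-way random effects
#'
#' ICC(2,1) (absolute agreement, single rater) from the mean squares of
#' the two-way ANOVA decomposition, with the 95% confidence interval from
#' the McGraw-Wong F-distribution bounds. The consistency form ICC(C,1)
#' and the average-measures forms are reported alongside.
#'
#' @param ratings numeric matrix, one row per target (eye), one column
#'   per rater; no missing cells.
#' @param type "agreement" (default, absolute agreement) or
#'   "consistency" for the primary estimate.
#' @param conf_level confidence level, default 0.95.
#' @return object of class `agreement_result`: `icc`, `ci_low`,
#'   `ci_high`, `model`, plus `icc_avg` (average-measures) and the ANOVA
#'   mean squares.
#' @export
icc_two_way <- function(ratings, type = c("agreement", "consistency"),
                        conf_level = 0.95) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("ratings contain missing cells", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("need at least 5 targets", call. = FALSE)
  if (k < 2L) stop("need at least 2 raters", call. = FALSE)
  if (stats::var(rowMeans(ratings)) < .Machine$double.eps * 100)
    stop("zero variance across targets: ICC is undefined for these ratings",
         call. = FALSE)
  alpha <- 1 - conf_level
  gm <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ss_rows <- k * sum((rowm - gm)^2)
  ss_cols <- n * sum((colm - gm)^2)
  ss_tot <- sum((ratings - gm)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  if (type == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    icc_avg <- (msr - mse) / (msr + (msc - mse) / n)
    model <- "ICC(2,1) two-way random effects, absolute agreement, single rater"
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    fl <- f_obs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f_obs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
    icc_avg <- (msr - mse) / msr
    model <- "ICC(C,1) two-way, consistency, single rater"
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi, model = model,
                 icc_avg = icc_avg, msr = msr, msc = msc, mse = mse,
                 n = n, k = k, conf_level = conf_level),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s\n", x$model))
  cat(sprintf("  ICC %.3f [%.0f%%CI %.3f to %.3f], n = %d targets, %d raters\n",
              x$icc, 100 * x$conf_level, x$ci_low, x$ci_high, x$n, x$k))
  cat(sprintf("  average-measures form: %.3f\n", x$icc_avg))
  invisible(x)
}

#' Spearman correlation of consensus grade with the Q index
#'
#' Rank correlation (average ranks for ties) between the consensus visual
#' grade and the instrument signal-strength index.
#'
#' @param consensus integer grades.
#' @param q_db numeric Q values, same length (>= 3).
#' @return Spearman's rho.
#' @export
spearman_vs_q <- function(consensus, q_db) {
  if (length(consensus) != length(q_db))
    stop("consensus and q_db lengths differ", call. = FALSE)
  if (length(consensus) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(consensus)) < 2L || length(unique(q_db)) < 2L)
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  stats::cor(consensus, q_db, method = "spearman")
}
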