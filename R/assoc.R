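#' Variable transformations prior to association modelling
#'
#' Adds the derived analysis variables: WMH volume as a percentage of
#' intracranial volume and its natural log (`wmh_pct_icv`, `wmh_log`),
#' and perivascular-space volumes as percentages of their region of
#' interest (`pvs_cso_pct`, `pvs_bg_pct`). PVS counts pass through
#' uncorrected. Rows with missing inputs keep missing derived fields;
#' zero denominators yield a missing derived field with a warning.
#'
#' @param records data.frame with (any of) wmh_ml, icv_ml, pvs_cso_ml,
#'   cso_ml, pvs_bg_ml, bg_ml.
#' @return the data.frame with derived columns appended.
#' @export
transform_variables <- function(records) {
  stopifnot(is.data.frame(records))
  ratio <- function(num, den, what) {
    if (is.null(records[[num]]) || is.null(records[[den]]))
      return(rep(NA_real_, nrow(records)))
    d <- records[[den]]
    bad <- !is.na(d) & d == 0
    if (any(bad)) {
      warning(sprintf("%d row(s) with zero %s: %s left missing",
                      sum(bad), den, what), call. = FALSE)
      d[bad] <- NA
    }
    100 * records[[num]] / d
  }
  records$wmh_pct_icv <- ratio("wmh_ml", "icv_ml", "wmh_pct_icv")
  records$wmh_log <- log(ifelse(records$wmh_pct_icv > 0,
                                records$wmh_pct_icv, NA))
  records$pvs_cso_pct <- ratio("pvs_cso_ml", "cso_ml", "pvs_cso_pct")
  records$pvs_bg_pct <- ratio("pvs_bg_ml", "bg_ml", "pvs_bg_pct")
  records
}

# TRUE for variables entered untouched (0/1 indicators); everything else
# numeric is z-scored before fitting.
.is_binary <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2L && all(u %in% c(0, 1))
}

.zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant variable", call. = FALSE)
  (x - mean(x)) / s
}

# Shared fitting core: standardized outcome regressed on standardized
# predictor plus covariates (continuous covariates z-scored, binary 0/1
# left as is). Returns an octa_modelfit.
.fit_std <- function(records, outcome, predictor, covariates = character(0),
                     conf_level = 0.95) {
  vars <- c(outcome, predictor, covariates)
  missing_cols <- setdiff(vars, names(records))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (predictor %in% covariates)
    stop("rank-deficient design: predictor '", predictor,
         "' duplicated as covariate", call. = FALSE)
  d <- records[stats::complete.cases(records[vars]), vars, drop = FALSE]
  n <- nrow(d)
  need <- if (length(covariates)) length(covariates) + 3L else 10L
  if (n < need)
    stop(sprintf("insufficient complete cases (%d) for %s ~ %s", n,
                 outcome, predictor), call. = FALSE)
  y <- .zscore(d[[outcome]])
  xs <- lapply(vars[-1L], function(v) {
    x <- d[[v]]
    if (is.character(x) || is.factor(x)) x <- as.numeric(as.factor(x)) - 1
    if (.is_binary(x)) x else .zscore(x)
  })
  X <- do.call(cbind, xs)
  colnames(X) <- vars[-1L]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    drop_idx <- qrX$pivot[(qrX$rank + 1L):(ncol(X) + 1L)] - 1L
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[drop_idx[drop_idx > 0L]], collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm(y ~ X)
  cf <- stats::coef(fit)[2L]                       # predictor is first column
  ci <- stats::confint(fit, level = conf_level)[2L, ]
  structure(list(outcome = outcome, predictor = predictor,
                 beta_std = unname(cf), ci_low = unname(ci[1L]),
                 ci_high = unname(ci[2L]), n_used = n,
                 adjusted = length(covariates) > 0L,
                 covariates = covariates, conf_level = conf_level,
                 lm_fit = fit),
            class = "octa_modelfit")
}

#' Univariate standardized association
#'
#' Ordinary least squares of the standardized outcome on the
#' standardized predictor (binary predictors are left 0/1 with the
#' outcome standardized), reported as the standardized beta with its
#' normal-theory confidence interval. For continuous pairs the
#' standardized slope equals the Pearson correlation.
#'
#' @param records data.frame of subject records.
#' @param outcome,predictor column names.
#' @param conf_level confidence level (default 0.95).
#' @return an `octa_modelfit`.
#' @export
fit_univariate <- function(records, outcome, predictor, conf_level = 0.95) {
  .fit_std(records, outcome, predictor, character(0), conf_level)
}

#' Covariate-adjusted standardized association
#'
#' Multiple linear model of the standardized outcome on the standardized
#' OCTA predictor plus covariates. The default covariate set is age,
#' comorbid eye disease, diabetes, systolic blood pressure and OCTA
#' image quality (the consensus ordinal grade entered as numeric 1-5).
#'
#' @param records data.frame of subject records.
#' @param outcome,predictor column names.
#' @param covariates covariate column names.
#' @param conf_level confidence level (default 0.95).
#' @return an `octa_modelfit`.
#' @export
fit_adjusted <- function(records, outcome, predictor,
                         covariates = c("age", "eye_disease", "diabetes",
                                        "sbp_mmHg", "image_quality"),
                         conf_level = 0.95) {
  if (length(covariates) == 0L)
    stop("covariates must be non-empty; use fit_univariate otherwise",
         call. = FALSE)
  .fit_std(records, outcome, predictor, covariates, conf_level)
}

#' @export
print.octa_modelfit <- function(x, ...) {
  cat(sprintf("%s ~ %s%s\n", x$outcome, x$predictor,
              if (x$adjusted) paste0(" + {", paste(x$covariates, collapse = ", "), "}")
              else " (univariate)"))
  cat(sprintf("  standardized beta %.3f [%.0f%%CI %.3f to %.3f], n = %d\n",
              x$beta_std, 100 * x$conf_level, x$ci_low, x$ci_high, x$n_used))
  invisible(x)
}

#' @export
coef.octa_modelfit <- function(object, ...) {
  stats::setNames(object$beta_std, object$predictor)
}

#' @export
confint.octa_modelfit <- function(object, parm, level, ...) {
  m <- matrix(c(object$ci_low, object$ci_high), 1L, 2L,
              dimnames = list(object$predictor,
                              c(sprintf("%.1f %%", 100 * (1 - object$conf_level) / 2),
                                sprintf("%.1f %%", 100 * (1 + object$conf_level) / 2))))
  m
}

#' @export
summary.octa_modelfit <- function(object, ...) {
  print(object)
  cat("\nunderlying linear model:\n")
  print(summary(object$lm_fit)$coefficients)
  invisible(object)
}

#' Run the full association suite for one eye
#'
#' Fits every (OCTA metric x brain outcome) pair, univariate and
#' covariate-adjusted, on the records of one eye, and returns a tidy
#' table ready for a forest plot.
#'
#' @param records subject records (both eyes); derived variables are
#'   added via [transform_variables()] if absent.
#' @param eye "right" or "left".
#' @param predictors OCTA metric columns (default vessel density and
#'   summary fractal dimension).
#' @param outcomes brain metric columns; pairs whose fit fails (e.g. too
#'   few complete cases) are skipped with a note attribute.
#' @param covariates covariate set for the adjusted models.
#' @param p_adjust optional "BH" to append Benjamini-Hochberg adjusted
#'   p-values across the suite (none by default).
#' @return data.frame (class `octa_assoc_table`) with columns outcome,
#'   predictor, eye, adjusted, beta, ci_low, ci_high, n.
#' @export
run_association_suite <- function(records, eye,
                                  predictors = c("vd_percent", "summary_fd"),
                                  outcomes = c("wmh_log", "pvs_cso_pct",
                                               "pvs_bg_pct", "pvs_count_cso",
                                               "pvs_count_bg", "cvr_magnitude",
                                               "arterial_flow", "fa_nawm",
                                               "md_nawm", "fa_wmh", "md_wmh"),
                                  covariates = c("age", "eye_disease",
                                                 "diabetes", "sbp_mmHg",
                                                 "image_quality"),
                                  p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!eye %in% c("right", "left"))
    stop("unknown eye label: ", eye, call. = FALSE)
  if (!is.null(records$eye)) records <- records[records$eye == eye, , drop = FALSE]
  if (!all(c("wmh_pct_icv") %in% names(records)))
    records <- transform_variables(records)
  rows <- list(); notes <- character(0); pvals <- numeric(0)
  for (pr in predictors) for (oc in outcomes) {
    for (adj in c(FALSE, TRUE)) {
      res <- tryCatch({
        f <- if (adj) fit_adjusted(records, oc, pr, covariates = covariates)
             else fit_univariate(records, oc, pr)
        p <- summary(f$lm_fit)$coefficients[2L, 4L]
        pvals <- c(pvals, p)
        data.frame(outcome = oc, predictor = pr, eye = eye, adjusted = adj,
                   beta = f$beta_std, ci_low = f$ci_low, ci_high = f$ci_high,
                   n = f$n_used, p_value = p, stringsAsFactors = FALSE)
      }, error = function(e) {
        notes <<- c(notes, sprintf("%s ~ %s (adjusted=%s): %s", oc, pr, adj,
                                   conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(outcome = character(), predictor = character(),
               eye = character(), adjusted = logical(), beta = numeric(),
               ci_low = numeric(), ci_high = numeric(), n = integer(),
               p_value = numeric(), stringsAsFactors = FALSE)
  if (p_adjust == "BH" && nrow(out))
    out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "notes") <- notes
  class(out) <- c("octa_assoc_table", "data.frame")
  out
}
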