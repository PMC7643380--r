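#' Ordinary least squares with partial eta squared per predictor
#'
#' Fits `outcome ~ predictors` by OLS and reports, for every predictor,
#' the estimate, SE, 95% CI, p-value and partial eta squared computed from
#' type-III (drop-one) sums of squares:
#' `partial_eta_sq = SS_effect / (SS_effect + SS_residual)`. For the
#' single-degree-of-freedom numeric predictors used here this equals the
#' squared partial correlation between the outcome and that predictor's
#' residualized column.
#'
#' @param data Data frame, one row per subject.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @param alpha Family-wise alpha (default 0.05).
#' @param n_models Number of models in the testing family; significance is
#'   assessed at `alpha / n_models`.
#' @return Data frame: term, estimate, se, ci_lo, ci_hi, p,
#'   partial_eta_sq, significant.
#' @export
metric_regression <- function(data, outcome, predictors,
                              alpha = 0.05, n_models = 1) {
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(data) <= length(predictors) + 1) {
    stop("need n > number of predictors + 1")
  }
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- suppressWarnings(stats::confint(fit))
  rss_full <- sum(stats::residuals(fit)^2)
  eta <- vapply(predictors, function(p) {
    red_form <- if (length(setdiff(predictors, p))) {
      stats::reformulate(setdiff(predictors, p), response = outcome)
    } else {
      stats::reformulate("1", response = outcome)
    }
    reduced <- stats::lm(red_form, data = data)
    ss_eff <- sum(stats::residuals(reduced)^2) - rss_full
    # guard against float dust when the outcome is (near) perfectly fit
    tol <- 1e-12 * max(sum(data[[outcome]]^2), 1)
    if (ss_eff <= tol) 0 else ss_eff / (ss_eff + rss_full)
  }, numeric(1))
  terms <- rownames(co)
  out <- data.frame(
    term = terms,
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    ci_lo = ci[terms, 1],
    ci_hi = ci[terms, 2],
    p = co[, "Pr(>|t|)"],
    partial_eta_sq = NA_real_,
    stringsAsFactors = FALSE
  )
  out$partial_eta_sq[match(predictors, out$term)] <- eta
  # intercept's partial eta^2 from its t statistic (1-df identity)
  t_int <- co["(Intercept)", "t value"]
  out$partial_eta_sq[out$term == "(Intercept)"] <-
    t_int^2 / (t_int^2 + stats::df.residual(fit))
  out$significant <- !is.na(out$p) & out$p < alpha / n_models
  rownames(out) <- NULL
  out
}

#' Age regression for one multilayer metric
#'
#' The standard association model of the pipeline: a multilayer metric
#' (global or network-specific) regressed on grand-mean-centered age at
#' baseline, with gender (1 = female, 0 = male), education (ordinal 1-3,
#' entered as numeric) and mean framewise displacement as nuisance
#' covariates.
#'
#' @param data Data frame with one row per subject holding the metric
#'   column plus `age`, `gender`, `education`, `fd`.
#' @param metric Name of the metric column (outcome).
#' @param n_models Number of models in the family for the Bonferroni-style
#'   `alpha / n` significance level (5 global metrics, or 7 networks).
#' @inheritParams metric_regression
#' @return Data frame as in [metric_regression()].
#' @export
metric_age_regression <- function(data, metric, alpha = 0.05, n_models = 1) {
  needed <- c(metric, "age", "gender", "education", "fd")
  miss <- setdiff(needed, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[, needed]
  d$age <- d$age - mean(d$age)  # grand-mean centering
  metric_regression(d, metric, c("gender", "education", "age", "fd"),
                    alpha = alpha, n_models = n_models)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Optionally a partial correlation controlling for `control` by
#' residual-on-residual correlation (degrees of freedom reduced by one).
#' A degenerate control (zero residual variance in either variable after
#' residualization, e.g. control identical to one of the variables) is
#' flagged with NA rather than reported.
#'
#' @param x,y Numeric vectors.
#' @param control Optional numeric vector to partial out of both.
#' @param conf Confidence level (default 0.95).
#' @return One-row data frame: r, ci_lo, ci_hi, p, n, df.
#' @export
cor_report <- function(x, y, control = NULL, conf = 0.95) {
  ok <- stats::complete.cases(x, y, if (is.null(control)) rep(0, length(x)) else control)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations")
  k <- 0
  if (!is.null(control)) {
    control <- control[ok]
    x <- stats::residuals(stats::lm(x ~ control))
    y <- stats::residuals(stats::lm(y ~ control))
    k <- 1
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
      return(data.frame(r = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        p = NA_real_, n = n, df = n - 2 - k,
                        degenerate = TRUE))
    }
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  df <- n - 2 - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  se_z <- 1 / sqrt(n - 3 - k)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  data.frame(r = r, ci_lo = tanh(z - zcrit * se_z), ci_hi = tanh(z + zcrit * se_z),
             p = p, n = n, df = df, degenerate = FALSE)
}

#' Intercorrelations among modularity, recruitment and flexibility
#'
#' Pairwise Pearson correlations (with Fisher-z CIs) among mean modularity
#' Q, global recruitment and global flexibility across subjects, plus the
#' same correlations partialling out age at baseline.
#'
#' @param data Data frame with per-subject columns `Q`, `recruitment`,
#'   `flexibility` and (for the partial correlations) `age`.
#' @return Data frame: var1, var2, r, ci_lo, ci_hi, p, partial_r,
#'   partial_ci_lo, partial_ci_hi, partial_p.
#' @export
metric_correlations <- function(data) {
  vars <- c("Q", "recruitment", "flexibility")
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  has_age <- "age" %in% names(data)
  pairs <- utils::combn(vars, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    raw <- cor_report(data[[v1]], data[[v2]])
    row <- data.frame(var1 = v1, var2 = v2,
                      r = raw$r, ci_lo = raw$ci_lo, ci_hi = raw$ci_hi,
                      p = raw$p, stringsAsFactors = FALSE)
    if (has_age) {
      pc <- cor_report(data[[v1]], data[[v2]], control = data$age)
      row$partial_r <- pc$r
      row$partial_ci_lo <- pc$ci_lo
      row$partial_ci_hi <- pc$ci_hi
      row$partial_p <- pc$p
    }
    row
  })
  do.call(rbind, out)
}

#' Per-subject cognitive change slopes
#'
#' The individual rate of cognitive change: the subject-specific OLS slope
#' of score on time (years). Because the first follow-up is typically
#' inflated by familiarity with the testing situation, a retest indicator
#' (0 at baseline, 1 at every follow-up) is regressed out of the scores at
#' the cohort level before the slopes are fit (`retest = "partial"`; the
#' bump is estimated jointly with a linear time term so it is not
#' confounded with the trend itself); with
#' `retest = "none"` raw scores are used. An optional empirical-shrinkage
#' mode pulls noisy subject slopes toward the cohort mean slope with weight
#' determined by each subject's sampling variance relative to the
#' between-subject slope variance.
#'
#' @param data Long data frame: one row per subject-occasion with columns
#'   `subject`, `time` (years since baseline, e.g. 0, 1, 2, 4) and the
#'   score column.
#' @param score Name of the score column (a cognitive domain's T-score).
#' @param retest `"partial"` (default) or `"none"`.
#' @param shrink Logical; apply empirical shrinkage toward the cohort mean
#'   slope (default FALSE).
#' @return Named numeric vector of slopes (T-score units per year), one per
#'   subject; NA for subjects with fewer than 3 occasions.
#' @export
change_slopes <- function(data, score, retest = c("partial", "none"),
                          shrink = FALSE) {
  retest <- match.arg(retest)
  needed <- c("subject", "time", score)
  miss <- setdiff(needed, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  y <- data[[score]]
  if (retest == "partial") {
    ind <- as.numeric(data$time > 0)
    if (stats::var(ind) > 0) {
      # estimate the retest bump with time in the model, otherwise the
      # bump estimate absorbs part of the genuine time trend
      fit <- stats::lm(y ~ data$time + ind)
      y <- y - stats::coef(fit)["ind"] * ind
    }
  }
  subj <- split(seq_len(nrow(data)), data$subject)
  slopes <- rep(NA_real_, length(subj))
  svar <- rep(NA_real_, length(subj))
  names(slopes) <- names(subj)
  for (i in seq_along(subj)) {
    idx <- subj[[i]]
    if (length(idx) < 3) next  # too few occasions: flagged missing
    tt <- data$time[idx]
    yy <- y[idx]
    sxx <- sum((tt - mean(tt))^2)
    b <- sum((tt - mean(tt)) * (yy - mean(yy))) / sxx
    slopes[i] <- b
    res <- yy - mean(yy) - b * (tt - mean(tt))
    svar[i] <- sum(res^2) / (length(idx) - 2) / sxx
  }
  if (shrink) {
    ok <- !is.na(slopes)
    mu <- mean(slopes[ok])
    tau2 <- max(0, stats::var(slopes[ok]) - mean(svar[ok]))
    w <- tau2 / (tau2 + svar[ok])
    slopes[ok] <- mu + w * (slopes[ok] - mu)
  }
  slopes
}

#' Change-change brain-cognition correlations
#'
#' Pearson correlations (raw and age-partialled) between per-subject
#' cognitive change slopes and each flexibility measure (global plus the
#' seven predefined networks, or whatever measure columns are supplied).
#'
#' @param measures Data frame, one row per subject: a `subject` column plus
#'   one column per brain measure.
#' @param slopes Named numeric vector of change slopes (names = subjects).
#' @param age Optional named numeric vector of ages for the partial
#'   correlations.
#' @param alpha Family-wise alpha (default 0.05).
#' @param n_comparisons Family size for the `alpha / n` threshold.
#' @return Data frame: measure, r, ci_lo, ci_hi, p, (partial_r, partial_p),
#'   significant.
#' @export
brain_cognition_correlation <- function(measures, slopes, age = NULL,
                                        alpha = 0.05, n_comparisons = 1) {
  if (!"subject" %in% names(measures)) stop("`measures` needs a subject column")
  subj <- as.character(measures$subject)
  sl <- slopes[subj]
  cols <- setdiff(names(measures), "subject")
  out <- lapply(cols, function(m) {
    rep0 <- cor_report(measures[[m]], sl)
    row <- data.frame(measure = m, r = rep0$r, ci_lo = rep0$ci_lo,
                      ci_hi = rep0$ci_hi, p = rep0$p,
                      stringsAsFactors = FALSE)
    if (!is.null(age)) {
      pc <- cor_report(measures[[m]], sl, control = age[subj])
      row$partial_r <- pc$r
      row$partial_p <- pc$p
    }
    row
  })
  out <- do.call(rbind, out)
  out$significant <- !is.na(out$p) & out$p < alpha / n_comparisons
  out
}
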