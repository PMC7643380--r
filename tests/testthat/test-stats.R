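test_that("metric_regression recovers exact fits and degenerate outcomes", {
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  out <- suppressWarnings(metric_regression(d, "y", "x"))  # perfect fit
  expect_equal(out$estimate[out$term == "x"], 2.0, tolerance = 1e-12)
  expect_equal(out$partial_eta_sq[out$term == "x"], 1)

  d$y_const <- 5
  out2 <- suppressWarnings(metric_regression(d, "y_const", "x"))
  expect_equal(out2$estimate[out2$term == "x"], 0)
  expect_equal(out2$partial_eta_sq[out2$term == "x"], 0)

  d$x2 <- d$x * 2  # collinear
  expect_error(metric_regression(d, "y", c("x", "x2")), "x2")
  expect_error(metric_regression(d[1:2, ], "y", "x"), "n >")
})

test_that("partial eta squared equals the squared partial correlation", {
  set.seed(23)
  n <- 60
  d <- data.frame(age = rnorm(n), gender = rbinom(n, 1, 0.5),
                  education = sample(1:3, n, TRUE), fd = runif(n))
  d$y <- 0.3 * d$age - 0.2 * d$fd + rnorm(n)
  out <- metric_age_regression(d, "y")
  for (p in c("age", "fd", "gender", "education")) {
    others <- setdiff(c("age", "gender", "education", "fd"), p)
    ry <- residuals(lm(reformulate(others, "y"), d))
    rx <- residuals(lm(reformulate(others, p), d))
    expect_equal(out$partial_eta_sq[out$term == p], cor(ry, rx)^2,
                 tolerance = 1e-10)
  }
})

test_that("Welch t on equal-variance groups agrees with the OLS dummy t", {
  set.seed(24)
  g <- rep(0:1, each = 25)
  y <- 0.4 * g + rnorm(50)
  # force exactly equal group variances by standardizing within group
  y[g == 0] <- scale(y[g == 0]); y[g == 1] <- scale(y[g == 1]) + 0.4
  welch <- compare_to_null(y[g == 1], y[g == 0])
  ols <- summary(lm(y ~ g))$coefficients["g", ]
  expect_equal(welch$t, unname(ols["t value"]), tolerance = 1e-6)
  expect_equal(welch$p, unname(ols["Pr(>|t|)"]), tolerance = 1e-6)
})

test_that("cor_report matches the covariance formula and flags degeneracy", {
  x <- c(1, 2, 4, 7, 11); y <- c(2, 1, 5, 6, 13)
  rep0 <- cor_report(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rep0$r, r_hand, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(rep0$p, ct$p.value, tolerance = 1e-10)

  expect_equal(cor_report(x, -x)$r, -1)
  # controlling for one of the variables themselves is degenerate
  pc <- cor_report(x, y, control = x)
  expect_true(pc$degenerate)
  expect_true(is.na(pc$r))
  expect_error(cor_report(rep(1, 5), y), "variance")
  expect_error(cor_report(x[1:3], y[1:3]), "at least 4")
})

test_that("correlation p-values agree with a permutation oracle", {
  set.seed(25)
  x <- rnorm(12); y <- 0.8 * x + rnorm(12)
  p_obs <- cor_report(x, y)$p
  r_obs <- abs(cor(x, y))
  perm <- replicate(10000, abs(cor(x, sample(y))))
  p_perm <- mean(perm >= r_obs)
  expect_lt(abs(p_obs - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 10000) + 0.01)
})

test_that("metric_correlations reports raw and age-partialled coefficients", {
  set.seed(26)
  n <- 80
  age <- rnorm(n)
  flex <- 0.4 + 0.05 * age + rnorm(n, sd = 0.05)
  d <- data.frame(age = age,
                  flexibility = flex,
                  Q = 0.5 - 0.6 * flex + rnorm(n, sd = 0.03),
                  recruitment = 0.6 - 0.5 * flex + rnorm(n, sd = 0.03))
  out <- metric_correlations(d)
  expect_equal(nrow(out), 3)
  qf <- out[out$var1 == "Q" & out$var2 == "flexibility", ]
  expect_lt(qf$r, -0.5)
  expect_lt(qf$ci_lo, qf$r); expect_gt(qf$ci_hi, qf$r)
  expect_lt(qf$partial_r, -0.5)
  # partial correlation equals residual-on-residual correlation
  rr <- cor(residuals(lm(Q ~ age, d)), residuals(lm(flexibility ~ age, d)))
  expect_equal(qf$partial_r, rr, tolerance = 1e-12)
})

test_that("change_slopes closed form, retest handling, and missingness", {
  d <- data.frame(subject = "s1", time = c(0, 1, 2, 4),
                  score = c(50, 49, 48, 46))
  expect_equal(unname(change_slopes(d, "score", retest = "none")), -1.0)

  d$score <- 47
  expect_equal(unname(change_slopes(d, "score", retest = "none")), 0)

  # a cohort-level retest bump does not contaminate slopes once partialled
  set.seed(27)
  subj <- sprintf("s%02d", 1:40)
  long <- do.call(rbind, lapply(subj, function(s) {
    data.frame(subject = s, time = c(0, 1, 2, 4),
               score = 50 - 0.8 * c(0, 1, 2, 4) + 2.5 * c(0, 1, 1, 1) +
                 rnorm(4, sd = 0.2))
  }))
  raw <- change_slopes(long, "score", retest = "none")
  adj <- change_slopes(long, "score", retest = "partial")
  expect_gt(mean(raw), -0.8 + 0.2)       # bump biases raw slopes upward
  expect_equal(mean(adj), -0.8, tolerance = 0.1)

  # fewer than 3 occasions flags the subject missing
  short <- rbind(long, data.frame(subject = "s99", time = c(0, 1),
                                  score = c(50, 49)))
  sl <- change_slopes(short, "score")
  expect_true(is.na(sl[["s99"]]))
  expect_false(anyNA(sl[subj]))

  # shrinkage pulls extreme noisy slopes toward the cohort mean
  shr <- change_slopes(long, "score", retest = "partial", shrink = TRUE)
  expect_lte(var(shr), var(adj) + 1e-12)
})

test_that("cohort-level slope recovery at the full cohort sample size", {
  set.seed(28)
  cfg <- sim_config(n_subjects = 150, n_nodes = 28, cognitive_slope_mean = -0.5,
                    seed = 91)
  co <- generate_cohort(cfg)
  d <- co$cognition
  sl <- change_slopes(d, "speed_T", retest = "partial")
  expect_equal(mean(sl), -0.5, tolerance = 0.1)
})

test_that("brain-cognition correlations recover planted sign and stay null under independence", {
  set.seed(29)
  n <- 150
  subj <- sprintf("s%03d", 1:n)
  flex <- rnorm(n, 0.4, 0.05)
  slopes_null <- stats::setNames(rnorm(n, -0.5, 0.3), subj)
  slopes_dep <- stats::setNames(-4 * flex + rnorm(n, sd = 0.1), subj)
  measures <- data.frame(subject = subj, global = flex)
  out_null <- brain_cognition_correlation(measures, slopes_null)
  expect_lt(abs(out_null$r), 0.2)
  out_dep <- brain_cognition_correlation(measures, slopes_dep,
                                         age = stats::setNames(rnorm(n), subj))
  expect_lt(out_dep$r, -0.5)
  expect_lt(out_dep$partial_r, -0.5)
  # n = 4 CI nearly spans [-1, 1]
  tiny <- cor_report(c(1, 2, 3, 5), c(2, 1, 4, 4))
  expect_lt(tiny$ci_lo, -0.5)
  expect_gt(tiny$ci_hi, 0.9)
})
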