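test_that("Welch statistics match brute-force formula evaluation", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6)
  R <- matrix(c(x, y), ncol = 1, dimnames = list(NULL, "p1"))
  grp <- c(rep(TRUE, 4), rep(FALSE, 3))
  res <- welch_case_control(R, grp)
  # independent brute-force evaluation of the two formulas
  se2 <- var(x) / 4 + var(y) / 3
  t_bf <- (mean(x) - mean(y)) / sqrt(se2)
  df_bf <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 3)^2 / 2)
  expect_equal(res$statistic, t_bf, tolerance = 1e-12)
  expect_equal(res$df, df_bf, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_bf), df_bf), tolerance = 1e-12)
  # and against the stock implementation
  tt <- t.test(x, y)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("Welch handles symmetry, degeneracy and affine invariance", {
  v <- c(1.2, 0.7, 2.2, 1.6)
  R <- matrix(c(v, v), ncol = 1, dimnames = list(NULL, "p1"))
  grp <- rep(c(TRUE, FALSE), each = 4)
  res <- welch_case_control(R, grp)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # zero variance in both groups -> degenerate flag, no p
  R0 <- matrix(1, 8, 1, dimnames = list(NULL, "p1"))
  res0 <- welch_case_control(R0, grp)
  expect_equal(res0$flag, "degenerate")
  expect_true(is.na(res0$p_value))
  # affine transform of a probe's residuals leaves t unchanged
  set.seed(2)
  R1 <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  g <- rep(c(TRUE, FALSE), 10)
  r1 <- welch_case_control(R1, g)
  r2 <- welch_case_control(R1 * 3.2 + 7, g)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  expect_error(welch_case_control(R1, rep(TRUE, 20)), "at least 2")
})

test_that("depression adjustment reduces to a pooled t-test when inert and removes mediated effects", {
  set.seed(3)
  n <- 60
  g <- rep(c(1, 0), each = n / 2)
  R <- matrix(rnorm(n * 4) + 0.4 * g, n, 4, dimnames = list(NULL, paste0("p", 1:4)))
  # all-zero depression: group p equals the pooled-variance two-sample t
  res <- posthoc_depression_adjust(R, g, rep(0, n), paste0("p", 1:4), sig = 1e-8)
  for (j in 1:4) {
    tt <- t.test(R[g == 1, j], R[g == 0, j], var.equal = TRUE)
    expect_equal(res$p_value[j], tt$p.value, tolerance = 1e-12)
  }
  # an effect wholly mediated by depression shrinks to ~ 0 after adjustment
  dep <- c(rbinom(n / 2, 1, 0.6), rep(0, n / 2))   # depressed only among patients
  Rm <- matrix(1.5 * dep + rnorm(n, sd = 0.3), ncol = 1,
               dimnames = list(NULL, "med"))
  unadj <- welch_case_control(Rm, g == 1)
  adj <- posthoc_depression_adjust(Rm, g, dep, "med", sig = 1e-8)
  expect_lt(abs(adj$coefficient[1]), 0.25)
  expect_gt(abs(unadj$statistic[1]), 4)
  # group == depression is collinear
  expect_error(posthoc_depression_adjust(R, g, g, "p1", sig = 1e-8), "collinear")
})

test_that("logistic coefficient matches the closed-form 2x2 log odds ratio", {
  counts <- c(a = 12, b = 8, c = 6, d = 14)  # exposed/unexposed x resp/non
  x <- c(rep(1, counts["a"] + counts["b"]), rep(0, counts["c"] + counts["d"]))
  y <- c(rep(1, counts["a"]), rep(0, counts["b"]),
         rep(1, counts["c"]), rep(0, counts["d"]))
  m <- matrix(x, ncol = 1, dimnames = list(NULL, "p1"))
  res <- predict_response_logistic(m, y)
  lor <- log(counts["a"] * counts["d"] / (counts["b"] * counts["c"]))
  expect_equal(res$coefficient, unname(lor), tolerance = 1e-8)
  # sign convention: higher methylation -> higher response odds
  expect_gt(res$coefficient, 0)
  expect_equal(res$statistic, res$coefficient / res$se, tolerance = 1e-12)
})

test_that("null logistic z-scores stay in range and separation is flagged", {
  set.seed(4)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  M <- matrix(rnorm(n * 400), n, 400, dimnames = list(NULL, paste0("p", 1:400)))
  res <- predict_response_logistic(M, y)
  expect_true(all(abs(res$statistic[res$flag == "ok"]) < 5))
  expect_gt(mean(abs(res$statistic) < 4, na.rm = TRUE), 0.995)
  # a perfectly separating probe is flagged, not shrunk
  sep <- matrix(as.numeric(y), ncol = 1, dimnames = list(NULL, "s1")) +
    matrix(seq(0, 1e-3, length.out = n), ncol = 1)
  res2 <- predict_response_logistic(sep, y)
  expect_true(res2$flag %in% c("separation", "nonconverged"))
  expect_true(is.na(res2$p_value))
})

test_that("a planted log-odds slope is recovered across replicates", {
  set.seed(5)
  n <- 300; slope <- 1; s <- 1.0
  hits <- 0
  for (r in 1:100) {
    resp <- rbinom(n, 1, 0.5)
    m <- matrix(resp * slope * s^2 + rnorm(n, 0, s), ncol = 1,
                dimnames = list(NULL, "p1"))
    est <- predict_response_logistic(m, resp)$coefficient
    hits <- hits + (abs(est - slope) <= 0.3)
  }
  expect_gte(hits, 95)
})

test_that("continuous response recovers a planted slope and flags degenerate outcomes", {
  set.seed(6)
  n <- 300
  m <- matrix(rnorm(n, 0, 1), ncol = 1, dimnames = list(NULL, "p1"))
  y <- 5 * m[, 1] + rnorm(n, 0, 10)
  res <- response_continuous(m, y)
  expect_lt(abs(res$coefficient - 5), 2 * res$se)
  # matches lm exactly
  f <- summary(lm(y ~ m))$coefficients[2, ]
  expect_equal(res$coefficient, unname(f[1]), tolerance = 1e-10)
  expect_equal(res$statistic, unname(f[3]), tolerance = 1e-10)
  # with covariates, matches the joint model
  covars <- matrix(rnorm(n * 3), n, 3)
  res2 <- response_continuous(m, y, covars)
  f2 <- summary(lm(y ~ m + covars))$coefficients[2, ]
  expect_equal(res2$statistic, unname(f2[3]), tolerance = 1e-10)
  # constant outcome
  res3 <- response_continuous(m, rep(3, n))
  expect_equal(res3$flag, "zero_variance_outcome")
  expect_true(is.na(res3$p_value))
  expect_error(response_continuous(m[1:2, , drop = FALSE], y[1:2]), "parameters")
})

test_that("paired one-sample t matches its analytic expectation and flags identity input", {
  set.seed(7)
  n <- 100
  d <- matrix(rnorm(n, 0.5, 1), ncol = 1, dimnames = list(NULL, "p1"))
  zero <- matrix(0, n, 1, dimnames = list(NULL, "p1"))
  res <- longitudinal_delta_test(zero, d, rep(TRUE, n))
  expect_null(res$non_responder)
  # analytic expectation sqrt(n) * mu / sigma = 5
  expect_lt(abs(res$responder$statistic - 5), 4)
  expect_equal(res$responder$df, n - 1)
  # cross-check against t.test
  tt <- t.test(d[, 1])
  expect_equal(res$responder$statistic, unname(tt$statistic), tolerance = 1e-12)
  # identical matrices -> degenerate
  res2 <- longitudinal_delta_test(d, d, rep(TRUE, n))
  expect_equal(res2$responder$flag, "degenerate")
  expect_true(is.na(res2$responder$p_value))
  # tiny stratum skipped with a message
  expect_message(res3 <- longitudinal_delta_test(zero, d, c(rep(TRUE, 98), FALSE, FALSE)),
                 "skipped")
  expect_null(res3$non_responder)
})

test_that("robust regression agrees with OLS on clean data and resists contamination", {
  set.seed(8)
  n <- 120
  smoke <- rbinom(n, 1, 0.3)
  while (var(smoke) == 0) smoke <- rbinom(n, 1, 0.3)
  clean <- matrix(0.4 + 0.05 * smoke + rnorm(n, 0, 0.02), ncol = 1,
                  dimnames = list(NULL, "p1"))
  rr <- smoking_ewas_robust(clean, smoke)
  ols <- coef(lm(clean[, 1] ~ smoke))[2]
  expect_lt(abs(rr$coefficient - ols) / abs(ols), 0.05)
  # 5% contamination: robust beats OLS in most replicates
  wins <- 0
  for (r in 1:20) {
    y <- 0.4 + 0.05 * smoke + rnorm(n, 0, 0.02)
    bad <- sample(n, round(0.05 * n))
    y[bad] <- pmin(pmax(y[bad] + sample(c(-0.4, 0.4), length(bad), TRUE), 0), 1)
    ym <- matrix(y, ncol = 1, dimnames = list(NULL, "p1"))
    b_rob <- smoking_ewas_robust(ym, smoke)$coefficient
    b_ols <- coef(lm(y ~ smoke))[2]
    wins <- wins + (abs(b_rob - 0.05) < abs(b_ols - 0.05))
  }
  expect_gte(wins, 13)
  expect_error(smoking_ewas_robust(clean, rep(1, n)), "contrast")
})

test_that("hypergeometric overlap test is exact", {
  expect_equal(overlap_test(paste0("a", 1:5), paste0("b", 1:7), 100)$overlap, 0)
  expect_equal(overlap_test(paste0("a", 1:5), paste0("b", 1:7), 100)$p_value, 1)
  # identical sets of 5 in a universe of 10: p = 1 / choose(10, 5)
  r <- overlap_test(paste0("x", 1:5), paste0("x", 1:5), 10)
  expect_equal(r$overlap, 5)
  expect_equal(r$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  # the study-scale null overlap, checked against log-gamma evaluation
  r2 <- overlap_test(paste0("a", 1:495), paste0("b", 1:88), 780145)
  p_log <- exp(lchoose(780145 - 495, 88) - lchoose(780145, 88))
  expect_equal(r2$p_value, 1, tolerance = 1e-10)   # P(X >= 0) is 1
  p_ge1 <- 1 - p_log                               # P(X >= 1)
  r3 <- stats::phyper(0, 495, 780145 - 495, 88, lower.tail = FALSE)
  expect_equal(r3, p_ge1, tolerance = 1e-10)
  expect_error(overlap_test(paste0("a", 1:5), "b", 3), "universe")
})
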