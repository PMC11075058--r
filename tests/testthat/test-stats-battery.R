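test_that("the normality gate routes tied Likert data to the nonparametric branch", {
  set.seed(1)
  likert <- sample(1:9, 527, replace = TRUE, prob = c(1, 1, 2, 3, 6, 3, 2, 1, 1))
  g <- normality_gate(likert)
  expect_lt(g$p_value, 0.001)
  expect_identical(g$branch, "nonparametric")

  set.seed(2)
  g2 <- normality_gate(rnorm(50))
  expect_identical(g2$branch, "parametric")
  expect_error(normality_gate(rep(1, 10)), "zero variance")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("Friedman statistic hits the perfect-concordance closed form", {
  set.seed(3)
  # all participants rank the k conditions identically, distinct values
  for (k in c(3, 5, 8)) {
    n <- 10
    mat <- matrix(rep(seq_len(k), each = n), n, k) + runif(n * k, 0, 0.1)
    mat <- t(apply(mat, 1, sort))
    fr <- friedman_rank_test(mat)
    expect_equal(fr$statistic, n * (k - 1), tolerance = 1e-12)
    expect_identical(fr$df, k - 1)
  }
  # identical values everywhere: statistic 0
  expect_identical(friedman_rank_test(matrix(5, 10, 4))$statistic, 0)
  expect_error(friedman_rank_test(matrix(1, 5, 2)), "at least 3")
})

test_that("tie-corrected Friedman agrees with stats::friedman.test when untied", {
  set.seed(4)
  for (rep in 1:10) {
    mat <- matrix(rnorm(15 * 4), 15, 4)
    fr <- friedman_rank_test(mat)
    ref <- stats::friedman.test(mat)
    expect_equal(fr$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(fr$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Friedman is invariant to strictly monotone within-row transforms", {
  set.seed(5)
  mat <- matrix(sample(1:9, 20 * 5, replace = TRUE), 20, 5)
  a <- friedman_rank_test(mat)$statistic
  expect_equal(friedman_rank_test(exp(mat))$statistic, a)
  expect_equal(friedman_rank_test(mat^3 + 7)$statistic, a)
  # incomplete participants are dropped with a count
  mat[3, 2] <- NA
  expect_identical(friedman_rank_test(mat)$dropped, 1L)
})

test_that("Durbin-Conover matches a hand-computed block design", {
  # ranks per block: (1,2,3), (1,2,3), (1,3,2)
  mat <- rbind(c(10, 20, 30), c(1, 2, 3), c(5, 9, 7))
  dc <- durbin_conover_posthoc(mat)
  # by hand: R = (3,7,8), A = 42, B = 122/3,
  # denom = sqrt(2*3*(42 - 122/3) / (2*2)) = sqrt(2), df = 4
  expect_equal(dc$statistic[dc$cond1 == "cond1" & dc$cond2 == "cond2"],
               -4 / sqrt(2), tolerance = 1e-6)
  expect_equal(dc$statistic[dc$cond1 == "cond1" & dc$cond2 == "cond3"],
               -5 / sqrt(2), tolerance = 1e-6)
  expect_equal(dc$statistic[dc$cond1 == "cond2" & dc$cond2 == "cond3"],
               -1 / sqrt(2), tolerance = 1e-6)
  expect_true(all(dc$df == 4))
  expect_equal(dc$p_value[1], 2 * pt(4 / sqrt(2), 4, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("Durbin-Conover orders shifted conditions first and handles ties", {
  set.seed(6)
  base <- matrix(rnorm(40 * 4), 40, 4)
  base[, 2] <- base[, 2] + 5  # one condition strongly shifted
  dc <- durbin_conover_posthoc(base)
  involving2 <- dc$cond1 == "cond2" | dc$cond2 == "cond2"
  expect_lt(max(dc$p_adjusted[involving2]), min(dc$p_adjusted[!involving2]))

  flat <- matrix(3, 12, 4)
  dcf <- durbin_conover_posthoc(flat)
  expect_true(all(dcf$p_adjusted == 1))
})

test_that("Spearman correlations hit the monotone extremes with BH adjustment", {
  x <- 1:20
  res <- spearman_with_fdr(list(
    up = list(x = x, y = x^2),
    down = list(x = x, y = -x - 5),
    flat = list(x = x, y = rep(c(1, 2), 10))))
  expect_identical(res$rs[res$name == "up"], 1)
  expect_identical(res$rs[res$name == "down"], -1)
  # BH: adjusted >= raw, and monotone in the raw p-values
  expect_true(all(res$p_adjusted >= res$p_value))
  o <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[o]) >= -1e-15))
  expect_error(spearman_with_fdr(list(list(x = 1:5, y = 1:4))), "mismatch")
  expect_error(spearman_with_fdr(list(list(x = 1:3, y = 1:3))), "fewer than 4")
})

test_that("paired contrasts recover planted shifts and flag degenerate cases", {
  set.seed(7)
  n <- 500
  others <- matrix(rnorm(n * 7), n, 7)
  sdd <- 1
  target <- rowMeans(others) + rnorm(n, 0.2 * sdd, sdd)
  ct <- paired_contrast(target, others)
  expect_lt(abs(ct$cohens_d - 0.2), 0.05)
  expect_lt(ct$p_value, 0.01)

  # noise-free constant shift: infinite effect, flagged
  o2 <- matrix(rep(1:5, each = 7), 5, 7, byrow = TRUE)
  ct2 <- paired_contrast(1:5 + 1, o2)
  expect_true(ct2$degenerate)
  expect_identical(ct2$statistic, Inf)
  expect_identical(ct2$p_value, 0)
  # identical: zero everything
  ct3 <- paired_contrast(1:5, o2)
  expect_identical(ct3$statistic, 0)
  expect_identical(ct3$cohens_d, 0)
  expect_error(paired_contrast(1, matrix(1, 1, 3)), "at least 2")
})

test_that("random-intercept model reports slope, z and variance consistently", {
  set.seed(8)
  n <- 150; k <- 6
  id <- rep(seq_len(n), each = k)
  u <- rep(rnorm(n, 0, 0.4), each = k)
  x <- rnorm(n * k)
  y <- rpois(n * k, exp(0.1 + 0.3 * x + u))
  fit <- fit_random_intercept_model(y, x, id)
  expect_lt(abs(fit$coefficient - 0.3), 0.1)
  expect_identical(fit$ranef_sd, sqrt(fit$ranef_variance))
  expect_identical(fit$family, "poisson")
  expect_true(fit$ci[1] < fit$coefficient & fit$coefficient < fit$ci[2])

  # zero planted heterogeneity: variance estimate collapses
  y0 <- rpois(n * k, exp(0.2 + 0.2 * x))
  fit0 <- fit_random_intercept_model(y0, x, id)
  expect_lte(fit0$ranef_variance, 0.01)

  expect_error(fit_random_intercept_model(c(0.5, 1.2), c(1, 2), c(1, 2)),
               "integer")
  # gaussian identity link is available and recorded
  fitg <- fit_random_intercept_model(y, x, id, family = "gaussian")
  expect_identical(fitg$family, "gaussian")
})

test_that("mediation composes a robust a-path and an OLS b-path", {
  set.seed(9)
  n <- 500
  x <- rep(0:1, each = n / 2)
  m <- 0.5 * x + rnorm(n)
  y <- 0.4 * m + 0.3 * x + rnorm(n)
  med <- mediation(x, m, y, n_boot = 300, seed = 11)
  expect_identical(med$indirect, med$a * med$b)
  expect_lt(abs(med$indirect - 0.2), 0.08)
  expect_gt(med$ci[1], 0)  # planted positive path excluded from 0
  expect_identical(med$direct, med$total - med$indirect)

  # same seed and data: identical CI endpoints
  med2 <- mediation(x, m, y, n_boot = 300, seed = 11)
  expect_identical(med$ci, med2$ci)

  # null b-path: CI covers 0
  y0 <- 0.3 * x + rnorm(n)
  med0 <- mediation(x, m, y0, n_boot = 300, seed = 12)
  expect_true(med0$ci[1] < 0 & med0$ci[2] > 0)

  # noise-free linear truth: indirect + direct(OLS) = total
  mlin <- 0.5 * x + seq(0, 1, length.out = n)
  ylin <- 0.4 * mlin + 0.3 * x
  mednf <- mediation(x, mlin, ylin, n_boot = 1, seed = 1)
  expect_equal(mednf$indirect + mednf$direct_ols, mednf$total,
               tolerance = 1e-9)

  expect_error(mediation(x, m, y, n_boot = 10), "seed")
  expect_error(mediation(x, rep(1, n), y, n_boot = 10, seed = 1),
               "degenerate")
  expect_error(mediation(1:5, 1:5, 1:5, n_boot = 10, seed = 1), "at least 10")
})
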