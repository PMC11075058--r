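#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test and reports which analysis branch it selects:
#' nonparametric when p < alpha (the study's data violated normality
#' throughout), parametric otherwise.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @param alpha gate level, default 0.05.
#' @return list with `statistic` (W), `p_value`, `n` and `branch`
#'   (`"nonparametric"` or `"parametric"`).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("zero variance: constant input")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       n = length(values),
       branch = if (sw$p.value < alpha) "nonparametric" else "parametric")
}

# within-row mid-ranks and the tie-corrected quantities shared by the
# Friedman statistic and the Durbin-Conover post hoc
.friedman_ranks <- function(mat) {
  mat <- as.matrix(mat)
  keep <- stats::complete.cases(mat)
  dropped <- sum(!keep)
  mat <- mat[keep, , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (k < 3L) stop("need at least 3 conditions")
  if (n < 2L) stop("need at least 2 complete participants")
  r <- t(apply(mat, 1L, rank))
  A <- sum(r^2)                       # sum of squared ranks
  C <- n * k * (k + 1)^2 / 4          # its null expectation
  Rj <- colSums(r)
  list(r = r, n = n, k = k, A = A, C = C, Rj = Rj, dropped = dropped)
}

#' Friedman rank test for repeated measures
#'
#' Tie-corrected Friedman statistic on within-participant mid-ranks:
#' \eqn{\chi^2 = (k-1)\sum_j (R_j - n(k+1)/2)^2 / (A - C)} with
#' \eqn{A = \sum r_{ij}^2} and \eqn{C = nk(k+1)^2/4}; reduces to the classic
#' \eqn{12\sum(\cdot)/nk(k+1)} without ties. Participants with missing cells
#' are dropped (count reported).
#'
#' @param mat numeric matrix, participants x conditions (k >= 3).
#' @return list with `statistic` (chi-squared), `df`, `p_value`, `n`, `k`,
#'   `dropped`.
#' @export
friedman_rank_test <- function(mat) {
  f <- .friedman_ranks(mat)
  denom <- f$A - f$C
  stat <- if (denom <= 0) 0 else
    (f$k - 1) * sum((f$Rj - f$n * (f$k + 1) / 2)^2) / denom
  df <- f$k - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       n = f$n, k = f$k, dropped = f$dropped)
}

#' Durbin-Conover post hoc comparisons after a Friedman test
#'
#' Pairwise comparisons of column rank sums,
#' \eqn{t = (R_i - R_j) / \sqrt{2n(A - B)/((n-1)(k-1))}} with
#' \eqn{B = \sum_j R_j^2 / n}, referred to a t distribution on
#' \eqn{(n-1)(k-1)} degrees of freedom; p-values are Benjamini-Hochberg
#' adjusted across the k(k-1)/2 pairs.
#'
#' @param mat numeric matrix, participants x conditions.
#' @return data.frame: `cond1`, `cond2`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`.
#' @export
durbin_conover_posthoc <- function(mat) {
  f <- .friedman_ranks(mat)
  n <- f$n; k <- f$k
  B <- sum(f$Rj^2) / n
  s2 <- 2 * n * (f$A - B) / ((n - 1) * (k - 1))
  df <- (n - 1) * (k - 1)
  cn <- colnames(mat)
  if (is.null(cn)) cn <- paste0("cond", seq_len(k))
  pairs <- utils::combn(k, 2L)
  stat <- (f$Rj[pairs[1L, ]] - f$Rj[pairs[2L, ]]) /
    sqrt(pmax(s2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  if (s2 <= 0) { stat[] <- 0; p[] <- 1 }  # all columns identical
  data.frame(cond1 = cn[pairs[1L, ]], cond2 = cn[pairs[2L, ]],
             statistic = unname(stat), df = df, p_value = unname(p),
             p_adjusted = stats::p.adjust(p, "BH"))
}

#' Spearman correlations with FDR adjustment
#'
#' Rank correlation (mid-rank ties) for each listed pair of vectors, with a
#' single Benjamini-Hochberg adjustment across the family.
#'
#' @param pairs named list; each element `list(x = , y = )` of equal-length
#'   numeric vectors (n >= 4).
#' @return data.frame: `name`, `rs`, `n`, `p_value`, `p_adjusted`.
#' @export
spearman_with_fdr <- function(pairs) {
  if (!length(pairs)) stop("no pairs supplied")
  rows <- lapply(seq_along(pairs), function(i) {
    x <- pairs[[i]]$x; y <- pairs[[i]]$y
    if (length(x) != length(y)) stop("length mismatch in pair ", i)
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 4L) stop("pair ", i, " has fewer than 4 complete cases")
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    nm <- names(pairs)[i]
    data.frame(name = if (is.null(nm) || !nzchar(nm)) paste0("pair", i) else nm,
               rs = unname(ct$estimate), n = length(x), p_value = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' One-versus-rest paired contrast with Cohen's d
#'
#' Paired t test of the target condition against the participant-wise mean of
#' the remaining conditions; Cohen's d is the mean difference over the SD of
#' the differences, with the t-based CI of the mean difference.
#'
#' @param target numeric vector: the target condition, one value per
#'   participant.
#' @param others numeric matrix: participants x remaining conditions.
#' @param conf_level CI level, default 0.95.
#' @return list with `statistic` (T), `df`, `p_value`, `cohens_d`,
#'   `mean_difference`, `ci` (length 2), `n`.
#' @export
paired_contrast <- function(target, others, conf_level = 0.95) {
  others <- as.matrix(others)
  if (length(target) != nrow(others)) stop("participant mismatch")
  d <- target - rowMeans(others)
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 participants")
  sdd <- stats::sd(d)
  if (sdd == 0) {
    # degenerate: a constant shift; effect size is unbounded and flagged
    shifted <- mean(d) != 0
    return(list(statistic = if (shifted) sign(mean(d)) * Inf else 0,
                df = n - 1L, p_value = if (shifted) 0 else 1,
                cohens_d = if (shifted) sign(mean(d)) * Inf else 0,
                mean_difference = mean(d), ci = rep(mean(d), 2L), n = n,
                degenerate = TRUE))
  }
  tt <- stats::t.test(d, conf.level = conf_level)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       cohens_d = mean(d) / sdd,
       mean_difference = mean(d), ci = unname(tt$conf.int), n = n,
       degenerate = FALSE)
}

#' Random-intercept model for click counts
#'
#' Fits `response ~ predictor + (1 | participant)`. The default family is
#' Poisson with log link (the responses are click counts); an identity-link
#' Gaussian fit is available for sensitivity checks. Reports the fixed
#' slope with Wald z and CI plus the random-intercept variance and SD.
#'
#' @param response numeric response (counts under the default family).
#' @param predictor numeric fixed-effect covariate.
#' @param participant participant identifier vector.
#' @param family `"poisson"` (log link) or `"gaussian"` (identity).
#' @return list with `coefficient`, `se`, `z`, `p_value`, `ci`,
#'   `ranef_variance`, `ranef_sd`, `family`, `n_participants`, `fit`.
#' @export
fit_random_intercept_model <- function(response, predictor, participant,
                                       family = c("poisson", "gaussian")) {
  family <- match.arg(family)
  if (length(unique(participant)) < 2L) stop("need >= 2 participants")
  if (family == "poisson" && any(response != round(response) | response < 0))
    stop("count family requires non-negative integer responses")
  dat <- data.frame(y = response, x = predictor,
                    id = factor(participant))
  if (min(table(dat$id)) < 2L)
    stop("every participant needs >= 2 observations")
  fit <- if (family == "poisson") {
    lme4::glmer(y ~ x + (1 | id), data = dat, family = stats::poisson())
  } else {
    lme4::lmer(y ~ x + (1 | id), data = dat, REML = FALSE)
  }
  co <- summary(fit)$coefficients
  est <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  z <- est / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- vc$vcov[vc$grp == "id"][1L]
  list(coefficient = est, se = se, z = z,
       p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       ci = est + c(-1, 1) * stats::qnorm(0.975) * se,
       ranef_variance = v, ranef_sd = sqrt(v),
       family = family, n_participants = nlevels(dat$id), fit = fit)
}

#' Bootstrap mediation with a robust mediator regression
#'
#' Path `a` is the slope of the mediator on the predictor from a Huber
#' M-estimator fit (robust to non-normal residuals); path `b` is the
#' mediator's slope in the OLS fit of the outcome on predictor and mediator.
#' The indirect effect is `a * b`, with a percentile CI from seeded case
#' resampling (both models refitted per resample, 5000 draws by default).
#' The total effect is the OLS slope of `y ~ x`; the direct effect reported
#' is `total - indirect`, alongside the OLS x-coefficient from the full
#' model.
#'
#' @param x predictor (e.g. a 0/1 condition indicator).
#' @param m mediator values.
#' @param y outcome values.
#' @param n_boot bootstrap resamples (>= 1), default 5000.
#' @param seed integer seed (required: CIs are deterministic given it).
#' @param conf_level CI level, default 0.95.
#' @return object of class `mediation_result`: `a`, `b`, `indirect`,
#'   `direct`, `direct_ols`, `total`, `ci`, `n_boot`, `seed`, `n`.
#' @export
mediation <- function(x, m, y, n_boot = 5000L, seed, conf_level = 0.95) {
  if (missing(seed)) stop("'seed' is required")
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("x, m, y must have equal length")
  if (n < 10L) stop("need at least 10 observations")
  if (stats::sd(m) == 0 || stats::sd(y) == 0)
    stop("degenerate input: constant mediator or outcome")
  if (n_boot < 1L) stop("'n_boot' must be >= 1")
  fit_ab <- function(xi, mi, yi) {
    a <- unname(stats::coef(MASS::rlm(mi ~ xi, maxit = 100))["xi"])
    b <- unname(stats::coef(stats::lm(yi ~ xi + mi))["mi"])
    c(a = a, b = b)
  }
  ab <- fit_ab(x, m, y)
  total <- unname(stats::coef(stats::lm(y ~ x))["x"])
  direct_ols <- unname(stats::coef(stats::lm(y ~ x + m))["x"])
  indirect <- ab[["a"]] * ab[["b"]]
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    ix <- sample.int(n, n, replace = TRUE)
    v <- fit_ab(x[ix], m[ix], y[ix])
    v[["a"]] * v[["b"]]
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  structure(
    list(a = ab[["a"]], b = ab[["b"]], indirect = indirect,
         direct = total - indirect, direct_ols = direct_ols, total = total,
         ci = ci, conf_level = conf_level, n_boot = as.integer(n_boot),
         seed = as.integer(seed), n = n),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation: a = %.4f, b = %.4f, indirect = %.4f (%.0f%% CI %.4f to %.4f, %d boots)\n",
              x$a, x$b, x$indirect, 100 * x$conf_level, x$ci[1], x$ci[2],
              x$n_boot))
  cat(sprintf("           total = %.4f, direct = %.4f (OLS x-coef %.4f)\n",
              x$total, x$direct, x$direct_ols))
  invisible(x)
}
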