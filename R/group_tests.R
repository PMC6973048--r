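# Life-form comparisons: data-driven choice between Student's t, Wilcoxon
# rank-sum and the Fligner-Policello robust rank-order test; Holm correction;
# and gamma/Gaussian mixed models with a genus random intercept.

#' Choose a two-sample test from normality and variance diagnostics
#'
#' Implements the decision rule used for the pairwise life-form contrasts:
#' Student's t test when both samples pass a Shapiro-Wilk normality test at
#' `alpha`; otherwise the Wilcoxon rank-sum test when a median-centered
#' Levene test finds no variance difference at `alpha`; otherwise the
#' Fligner-Policello test (non-normal, unequal variances).
#'
#' @param x,y numeric samples, each n >= 3.
#' @param alpha significance level for the diagnostics (default 0.05).
#' @return `"t"`, `"wilcoxon"` or `"fligner_policello"`.
#' @export
select_test <- function(x, y, alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L) stopf("each sample needs n >= 3")
  normal_p <- function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate: clearly non-normal
    stats::shapiro.test(v)$p.value
  }
  both_normal <- normal_p(x) > alpha && normal_p(y) > alpha
  if (both_normal) return("t")
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  lev <- car::leveneTest(c(x, y) ~ g, center = stats::median)
  if (lev[1L, "Pr(>F)"] > alpha) "wilcoxon" else "fligner_policello"
}

#' Fligner-Policello robust rank-order test
#'
#' Two-sample test of location not assuming equal variances or a common
#' distribution shape (Fligner & Policello 1981). For each `x[i]` the
#' placement \eqn{P_i} counts the `y` values below it (ties count one half),
#' and symmetrically \eqn{Q_j} for `y`. The statistic
#' \deqn{U = \frac{\sum P_i - \sum Q_j}{2\sqrt{V_1 + V_2 + \bar P \bar Q}}}
#' with \eqn{V_1 = \sum_i (P_i - \bar P)^2}, \eqn{V_2 = \sum_j (Q_j - \bar
#' Q)^2} is referred to the standard normal distribution (two-sided).
#'
#' @param x,y numeric samples, each n >= 3.
#' @return object of class `htest` with `statistic` (U) and `p.value`.
#' @examples
#' fligner_policello(c(1, 2, 3, 4), c(2.5, 3.5, 9, 10))
#' @export
fligner_policello <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  m <- length(x); n <- length(y)
  if (m < 3L || n < 3L) stopf("each sample needs n >= 3")
  P <- vapply(x, function(xi) sum(y < xi) + 0.5 * sum(y == xi), 0)
  Q <- vapply(y, function(yj) sum(x < yj) + 0.5 * sum(x == yj), 0)
  if (length(unique(c(x, y))) == 1L) {
    stopf("all values tied; Fligner-Policello statistic undefined")
  }
  Pbar <- mean(P); Qbar <- mean(Q)
  V1 <- sum((P - Pbar)^2); V2 <- sum((Q - Qbar)^2)
  denom <- V1 + V2 + Pbar * Qbar
  # complete separation: placement variance vanishes and U diverges
  U <- (sum(P) - sum(Q)) / (2 * sqrt(denom))
  structure(list(
    statistic = c(U = U),
    p.value = 2 * stats::pnorm(-abs(U)),
    method = "Fligner-Policello robust rank-order test",
    alternative = "two.sided",
    data.name = paste(deparse(substitute(x)), "and", deparse(substitute(y)))
  ), class = "htest")
}

#' Holm step-down adjustment of p values
#'
#' Holm-Bonferroni multiple-comparison correction, returned in the input
#' order: sort ascending, multiply the i-th smallest by (m - i + 1), enforce
#' monotonicity by cumulative maximum, cap at 1.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return adjusted p values, same length and order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("p values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}

#' Pairwise group comparisons with data-driven test selection
#'
#' For every pair of groups, chooses a test via [select_test()], runs it
#' (Student's t with pooled variance, Wilcoxon rank-sum, or
#' Fligner-Policello) and Holm-adjusts the p values across the pairs.
#'
#' @param values numeric response (one value per species).
#' @param groups group labels (e.g. life forms), >= 2 levels.
#' @param alpha level for the selection diagnostics.
#' @return data.frame with one row per pair: `group_a`, `group_b`,
#'   `test_used`, `statistic`, `p_raw`, `p_adjusted`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  lev <- levels(groups)
  if (length(lev) < 2L) stopf("need >= 2 groups")
  pairs <- utils::combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    x <- values[groups == a]; y <- values[groups == b]
    test <- select_test(x, y, alpha = alpha)
    ht <- switch(test,
                 t = stats::t.test(x, y, var.equal = TRUE),
                 wilcoxon = suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)),
                 fligner_policello = fligner_policello(x, y))
    data.frame(group_a = a, group_b = b, test_used = test,
               statistic = unname(ht$statistic), p_raw = ht$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_adjust(out$p_raw)
  out
}

#' Gamma or Gaussian mixed model with a genus random intercept
#'
#' Fits `response ~ fixed effects + (1 | genus)`. For positive variables
#' (lengths, variances, the aggregation index) the family is gamma with a
#' log link, fit by Laplace-approximated maximum likelihood
#' ([lme4::glmer()]); for sign-changing variables (skewness) a Gaussian
#' identity-link model is used ([lme4::lmer()], maximum likelihood by
#' default, REML optional). Fixed-effect p values are Wald (normal
#' approximation).
#'
#' @param data data.frame containing the response, predictors and a `genus`
#'   column.
#' @param response name of the response column (must be positive under the
#'   gamma family).
#' @param fixed character vector of predictor column names (may be empty for
#'   an intercept-only model).
#' @param family `"gamma"` (log link) or `"gaussian"` (identity).
#' @param genus name of the random-intercept grouping column.
#' @param REML Gaussian family only: use REML instead of ML? Default
#'   `FALSE`.
#' @return object of class `pheno_mixed`: list with `fit` (the lme4 object),
#'   `coefficients` (estimate, std. error, z, Wald p), `ranef_variance`,
#'   `logLik`, `family`.
#' @export
fit_pheno_glmm <- function(data, response, fixed = character(0),
                           family = c("gamma", "gaussian"), genus = "genus",
                           REML = FALSE) {
  family <- match.arg(family)
  stopifnot(response %in% names(data), genus %in% names(data),
            all(fixed %in% names(data)))
  if (length(unique(data[[genus]])) < 2L) stopf("need >= 2 genera")
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 sprintf("(1 | %s)", genus)), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  if (family == "gamma") {
    if (any(data[[response]] <= 0, na.rm = TRUE)) {
      stopf("gamma family requires a strictly positive response")
    }
    fit <- lme4::glmer(fml, data = data, family = stats::Gamma(link = "log"))
  } else {
    fit <- lme4::lmer(fml, data = data, REML = REML)
  }
  co <- as.data.frame(stats::coef(summary(fit)))
  names(co)[1:2] <- c("estimate", "std_error")
  co$z <- co$estimate / co$std_error
  co$p_wald <- 2 * stats::pnorm(-abs(co$z))
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- vc$vcov[vc$grp == genus][1L]
  if (lme4::isSingular(fit, tol = 1e-5) && rv <= 1e-8) {
    warnf("singular fit: genus random-intercept variance estimated at 0")
  }
  structure(list(fit = fit, coefficients = co, ranef_variance = rv,
                 logLik = as.numeric(stats::logLik(fit)), family = family),
            class = "pheno_mixed")
}

#' @export
print.pheno_mixed <- function(x, ...) {
  cat(sprintf("%s mixed model (genus random intercept), logLik = %.2f\n",
              x$family, x$logLik))
  print(round(x$coefficients, 4))
  cat(sprintf("genus variance: %.4g\n", x$ranef_variance))
  invisible(x)
}

#' Likelihood-ratio comparison of nested genus-random-intercept models
#'
#' Fits, by maximum likelihood on identical data, model 0 (random intercept
#' only), model 1 (adding `year`) and model 2 (adding the number of observed
#' individuals), and tests 0 vs 1 and 0 vs 2 with chi-square
#' likelihood-ratio tests (1 df each). Gaussian identity family, as used for
#' skewness.
#'
#' @param data data.frame with the response, `year`, `n` and `genus`
#'   columns (names configurable).
#' @param response response column name.
#' @param year,n_obs,genus predictor / grouping column names.
#' @return data.frame with one row per comparison: `model`, `df`, `logLik`,
#'   `LRT`, `p_value`.
#' @export
compare_lmm_models <- function(data, response, year = "year", n_obs = "n",
                               genus = "genus") {
  cc <- stats::complete.cases(data[c(response, year, n_obs, genus)])
  data <- data[cc, , drop = FALSE]
  m0 <- fit_pheno_glmm(data, response, character(0), family = "gaussian",
                       genus = genus, REML = FALSE)
  m1 <- fit_pheno_glmm(data, response, year, family = "gaussian",
                       genus = genus, REML = FALSE)
  m2 <- fit_pheno_glmm(data, response, n_obs, family = "gaussian",
                       genus = genus, REML = FALSE)
  lrt <- function(m_big) max(0, 2 * (m_big$logLik - m0$logLik))
  data.frame(
    model = c(sprintf("0 vs 1 (+%s)", year), sprintf("0 vs 2 (+%s)", n_obs)),
    df = 1L,
    logLik = c(m1$logLik, m2$logLik),
    LRT = c(lrt(m1), lrt(m2)),
    p_value = stats::pchisq(c(lrt(m1), lrt(m2)), df = 1L, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}
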