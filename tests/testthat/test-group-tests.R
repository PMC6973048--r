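test_that("test selection follows the normality/variance rule table", {
  # deterministic quantile samples make the diagnostics unambiguous
  zn <- qnorm(ppoints(60))          # exactly normal-shaped
  zl <- qlnorm(ppoints(60))         # exactly lognormal-shaped
  # both normal, same scale -> t
  expect_equal(select_test(zn, 0.3 + zn), "t")
  # non-normal but identical spread -> wilcoxon
  expect_equal(select_test(zl, 1 + zl), "wilcoxon")
  # non-normal with a 10x scale difference -> fligner_policello
  expect_equal(select_test(zl, 10 * zl), "fligner_policello")
  expect_error(select_test(c(1, 2), rnorm(10)), "n >= 3")
  # purity: same inputs, same answer
  x <- rlnorm(30); y <- rlnorm(30)
  expect_identical(select_test(x, y), select_test(x, y))
})

test_that("Fligner-Policello matches exhaustive placement oracles", {
  # identical samples: U = 0, p = 1
  ht <- fligner_policello(c(1, 2, 3, 7), c(1, 2, 3, 7))
  expect_equal(unname(ht$statistic), 0)
  expect_equal(ht$p.value, 1)
  # complete separation maximizes |U| among same-size samples
  sep <- fligner_policello(6:10, 1:5)
  expect_equal(unname(sep$statistic), fp_oracle(6:10, 1:5), tolerance = 1e-12)
  set.seed(55)
  umax <- abs(sep$statistic)
  for (i in 1:200) {
    x <- rnorm(5); y <- rnorm(5)
    expect_lte(abs(fligner_policello(x, y)$statistic), umax + 1e-12)
  }
  # oracle equivalence on random configurations, all sizes 3..6, with ties
  for (i in 1:300) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- sample(1:8, nx, replace = TRUE) + sample(c(0, 0.5), nx, replace = TRUE)
    y <- sample(1:8, ny, replace = TRUE)
    if (all(c(x, y) == c(x, y)[1])) next
    den_ok <- tryCatch({
      u <- fligner_policello(x, y)$statistic
      expect_equal(unname(u), fp_oracle(x, y), tolerance = 1e-12)
      TRUE
    }, error = function(e) grepl("tied", conditionMessage(e)))
    expect_true(den_ok)
  }
  expect_error(fligner_policello(rep(1, 5), rep(1, 5)), "tied")
})

test_that("Fligner-Policello is antisymmetric in its samples", {
  set.seed(77)
  for (i in 1:50) {
    x <- rlnorm(7); y <- rnorm(6, 2)
    a <- fligner_policello(x, y); b <- fligner_policello(y, x)
    expect_equal(unname(a$statistic), -unname(b$statistic), tolerance = 1e-12)
    expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
  }
})

test_that("Holm adjustment matches the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.5, 0.9)), c(1.0, 1.0))
  set.seed(12)
  for (i in 1:200) {
    p <- runif(sample(1:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(holm_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise group comparisons produce Holm-adjusted rows per pair", {
  set.seed(41)
  values <- c(rnorm(12, 10), rnorm(14, 12), rlnorm(13, 2))
  groups <- rep(c("tree", "perennial", "annual"), c(12, 14, 13))
  cmp <- compare_groups(values, groups)
  expect_equal(nrow(cmp), 3)
  expect_true(all(cmp$p_adjusted >= cmp$p_raw))
  expect_equal(cmp$p_adjusted, holm_oracle(cmp$p_raw), tolerance = 1e-12)
  expect_true(all(cmp$test_used %in% c("t", "wilcoxon", "fligner_policello")))
})

test_that("gamma GLMM with zero genus variance collapses to the gamma GLM", {
  # low residual noise pins the genus means, so the variance estimate sits
  # at (or next to) the boundary where the GLMM and GLM coincide
  for (s in 1:3) {
    set.seed(s)
    n <- 600
    d <- data.frame(xv = runif(n, 0, 2),
                    genus = rep(paste0("G", 1:12), length.out = n))
    d$y <- rgamma(n, shape = 200, rate = 200 / exp(1 + 0.5 * d$xv))
    mm <- suppressWarnings(fit_pheno_glmm(d, "y", "xv", family = "gamma"))
    gg <- glm(y ~ xv, data = d, family = Gamma(link = "log"))
    rel <- max(abs(mm$coefficients$estimate - coef(gg)) / abs(coef(gg)))
    expect_lt(rel, 1e-3)
    if (mm$ranef_variance == 0) expect_lt(rel, 1e-6)  # exact at the boundary
    expect_lt(mm$ranef_variance, 1e-3)
  }
  expect_error(fit_pheno_glmm(data.frame(y = c(-1, 1, 2, 3), xv = 1:4,
                                         genus = c("a", "a", "b", "b")),
                              "y", "xv", family = "gamma"), "positive")
})

test_that("Gaussian LMM recovers balanced one-way variance components (REML)", {
  set.seed(15)
  g <- 12; r <- 6
  sig_a <- 2; sig_e <- 1.5
  genus <- rep(paste0("G", seq_len(g)), each = r)
  y <- rep(rnorm(g, 0, sig_a), each = r) + rnorm(g * r, 0, sig_e)
  d <- data.frame(y = y, genus = genus)
  mm <- fit_pheno_glmm(d, "y", family = "gaussian", REML = TRUE)
  # closed-form ANOVA estimators for the balanced design
  gm <- tapply(y, genus, mean)
  MSB <- r * sum((gm - mean(y))^2) / (g - 1)
  MSW <- sum((y - gm[genus])^2) / (g * (r - 1))  # name-indexed per row
  expect_equal(mm$ranef_variance, (MSB - MSW) / r, tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(mm$fit))
  expect_equal(vc$vcov[vc$grp == "Residual"], MSW, tolerance = 1e-4)
})

test_that("mixed models recover a simulated fixed-effect slope", {
  set.seed(90)
  n <- 400; g <- 20
  d <- data.frame(xv = runif(n, 0, 2),
                  genus = rep(paste0("G", seq_len(g)), length.out = n))
  gi <- rnorm(g, 0, 0.3)
  mu <- exp(0.8 + 0.5 * d$xv + gi[as.integer(factor(d$genus))])
  d$y <- rgamma(n, shape = 10, rate = 10 / mu)
  mm <- suppressWarnings(fit_pheno_glmm(d, "y", "xv", family = "gamma"))
  expect_lt(abs(mm$coefficients["xv", "estimate"] - 0.5), 0.1)
  expect_gt(mm$ranef_variance, 0)
})

test_that("likelihood-ratio model comparison is well-formed and powered", {
  set.seed(33)
  g <- 14
  d <- expand.grid(genus = paste0("G", seq_len(g)), rep = 1:3,
                   year = c(0, 1))
  gi <- rnorm(g, 0, 1)
  d$n <- sample(5:30, nrow(d), replace = TRUE)
  d$y <- gi[as.integer(d$genus)] + 1.2 * d$year + rnorm(nrow(d), 0, 0.8)
  out <- compare_lmm_models(d, "y")
  expect_equal(nrow(out), 2)
  expect_true(all(out$LRT >= 0))
  expect_lt(out$p_value[1], 0.01)   # strong year effect detected
  # refitting the null against itself: LRT must be ~0, never negative
  d0 <- d; d0$y <- gi[as.integer(d0$genus)] + rnorm(nrow(d0), 0, 0.8)
  out0 <- compare_lmm_models(d0, "y")
  expect_true(all(out0$LRT >= 0))
})
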