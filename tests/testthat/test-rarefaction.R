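make_recs <- function(onsets, ends, year = 2016L) {
  cal <- weekly_calendar(year)
  list(recs = data.frame(onset = cal$dates[onsets], end = cal$dates[ends]),
       cal = cal)
}

test_that("bootstrap curves are deterministic and flat for degenerate populations", {
  # all individuals of identical 7-day length: curve constant at 7
  recs <- data.frame(onset = as.Date("2016-03-01") + c(0, 7, 14, 21),
                     end = as.Date("2016-03-01") + c(6, 13, 20, 27))
  cu <- bootstrap_curve(recs, "MFL", B = 100, seed = 1)
  expect_equal(cu$mean, rep(7, nrow(cu)))
  expect_equal(cu$j, 1:4)
  expect_equal(cu$B_eff, rep(100L, 4))
  cu2 <- bootstrap_curve(recs, "MFL", B = 100, seed = 1)
  expect_identical(cu, cu2)
  # seed sensitivity needs a non-degenerate population: use mixed lengths
  recs2 <- data.frame(onset = as.Date("2016-03-01") + c(0, 7, 14, 21),
                      end = as.Date("2016-03-01") + c(2, 20, 18, 40))
  cu3a <- bootstrap_curve(recs2, "MFL", B = 100, seed = 1)
  cu3b <- bootstrap_curve(recs2, "MFL", B = 100, seed = 2)
  expect_false(identical(cu3a$mean, cu3b$mean))
})

test_that("TFL bootstrap mean at j = 1 is the average individual length", {
  recs <- data.frame(onset = as.Date("2016-03-01") + c(0, 10, 25, 40),
                     end = as.Date("2016-03-01") + c(3, 30, 27, 60))
  lens <- flowering_length(recs$onset, recs$end)
  cu <- bootstrap_curve(recs, "TFL", B = 4000, seed = 8)
  # single-individual TFL = own length; bootstrap mean ~= mean length
  expect_equal(cu$mean[cu$j == 1], mean(lens), tolerance = 0.05)
  # oracle: direct average over B draws with the same seed path
  direct <- with(list(), {
    set.seed(8)
    idx <- matrix(sample.int(4, 4000, replace = TRUE), 1)
    mean(lens[idx])
  })
  expect_equal(cu$mean[cu$j == 1], direct, tolerance = 1e-12)
})

test_that("monotone statistics give non-decreasing bootstrap means", {
  set.seed(30)
  recs <- data.frame(onset = as.Date("2016-03-01") + sample(0:80, 12),
                     end = as.Date("2016-03-01"))
  recs$end <- recs$onset + sample(3:30, 12, replace = TRUE)
  cu <- bootstrap_curve(recs, "TFL", B = 5000, seed = 5)
  expect_true(all(diff(cu$mean) > -0.5))  # within Monte-Carlo error
})

test_that("statistics undefined at small draws are dropped from the average", {
  recs <- data.frame(onset = as.Date("2016-03-01") + c(0, 0, 0),
                     end = as.Date("2016-03-01") + c(0, 0, 6))
  # skewness needs n >= 3 and non-zero spread; at j = 3 some draws are
  # all-identical (m2 = 0) and must be excluded
  cu <- bootstrap_curve(recs, "skewness", B = 500, seed = 2)
  expect_true(all(cu$B_eff <= 500))
  expect_true(any(cu$B_eff < 500))
  expect_true(all(is.finite(cu$mean)))
  # a variable undefined at every feasible size gives an empty curve
  one <- recs[1, , drop = FALSE]
  expect_warning(cuv <- bootstrap_curve(one, "VFL", B = 10), "undefined")
  expect_equal(nrow(cuv), 0)
})

test_that("model selection recovers generating forms and breaks ties by parsimony", {
  j <- 1:40
  # exact line -> linear wins (quadratic fits equally; fewer parameters win)
  sel <- select_model(data.frame(j = j, y = 0.2 + 0.01 * j))
  expect_equal(sel$form, "linear")
  # constant data: every form interpolates; tie-break by parameter count
  expect_equal(select_model(data.frame(j = j, y = rep(1, 40)))$form, "linear")
  # exact logarithmic curve
  expect_equal(select_model(data.frame(j = j, y = 2 + 3 * log(j)))$form,
               "logarithmic")
  # noisy logistic
  set.seed(77)
  y <- 1 / (1 + exp(-0.5 * (j - 8))) + rnorm(40, 0, 0.01)
  expect_equal(select_model(data.frame(j = j, y = y))$form, "logistic")
})

test_that("standardized values reproduce closed-form fits", {
  j <- 1:30
  curve_df <- structure(data.frame(j = j, mean = 2 + 3 * log(j), B_eff = 100L),
                        class = c("bootstrap_curve", "data.frame"),
                        variable = "MFL", B = 100L, seed = 1L, n = 30L)
  v <- standardized_value(curve_df, "logarithmic", c(5, 22))
  expect_equal(unname(v), 2 + 3 * log(c(5, 22)), tolerance = 1e-6)
  # constant curve: any form must return the constant
  const <- structure(data.frame(j = j, mean = rep(7, 30), B_eff = 100L),
                     class = c("bootstrap_curve", "data.frame"),
                     variable = "MFL", B = 100L, seed = 1L, n = 30L)
  for (form in c("linear", "logarithmic", "quadratic", "logistic")) {
    expect_equal(unname(standardized_value(const, form, 12)), 7,
                 tolerance = 1e-6, label = form)
  }
  # n_std at an observed j on a noiseless linear curve is exact
  lin <- structure(data.frame(j = j, mean = 1 + 2 * j, B_eff = 100L),
                   class = c("bootstrap_curve", "data.frame"),
                   variable = "TFL", B = 100L, seed = 1L, n = 30L)
  expect_equal(unname(standardized_value(lin, "linear", 18)), 1 + 2 * 18,
               tolerance = 1e-9)
})

test_that("max-standardization of curves is invertible", {
  cu <- structure(data.frame(j = 1:10, mean = c(2, 4, 6, 7, 8, 8.5, 9, 9.2, 9.4, 9.5),
                             B_eff = 50L),
                  class = c("bootstrap_curve", "data.frame"))
  pooled <- pool_standardized_curves(list(cu))
  expect_equal(pooled$y * max(cu$mean), cu$mean)
  expect_equal(max(pooled$y), 1)
})

test_that("rarefaction workflow produces one estimate per species, variable and size", {
  sim <- simulate_records(list(
    tree = life_form_params(4, c(8, 10), onset_sd_within = 2, vfl_within = 4),
    annual = life_form_params(4, c(8, 10), onset_sd_within = 12, vfl_within = 80)
  ), toy_calendars(2016L), seed = 5)
  ds <- filter_species(sim$dataset, require_both_years = FALSE)
  std <- standardize_estimates(ds, variables = c("MFL", "VFL"),
                               n_std = c(5, 7), B = 100, seed = 9)
  n_sp <- length(unique(ds$records$species))
  expect_equal(nrow(std), n_sp * 2 * 2)
  expect_true(all(is.finite(std$value)))
  expect_named(attr(std, "forms"), c("MFL", "VFL"))
  std2 <- standardize_estimates(ds, variables = c("MFL", "VFL"),
                                n_std = c(5, 7), B = 100, seed = 9)
  expect_identical(std, std2)
})
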