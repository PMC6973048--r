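# Interspecific (community-wide) synchrony: the census-date x species matrix
# of simultaneously flowering individuals, the Loreau-de Mazancourt synchrony
# index phi, onset-date skewness with the D'Agostino-Pearson omnibus
# normality test, and species-bootstrap confidence intervals.

#' Community matrix of flowering counts
#'
#' Builds the census-date x species matrix whose entry (t, i) is the number
#' of individuals of species i in flower at census date t, over the full
#' season calendar of one year.
#'
#' @param ds a `pheno_dataset`, normally already filtered to species with
#'   enough individuals.
#' @param year calendar year to use.
#' @param life_form optional life-form subset (`"tree"`, `"perennial"`,
#'   `"annual"`); `NULL` keeps all species.
#' @return integer matrix of class `community_matrix` with census dates as
#'   row names and species as column names; attributes `year`, `life_form`.
#' @export
build_community_matrix <- function(ds, year, life_form = NULL) {
  stopifnot(inherits(ds, "pheno_dataset"))
  cal <- ds$calendars[[as.character(year)]]
  if (is.null(cal)) stopf("no calendar for year %s", year)
  r <- ds$records[ds$records$year == as.integer(year), , drop = FALSE]
  if (!is.null(life_form)) {
    life_form <- match.arg(life_form, LIFE_FORMS)
    r <- r[r$life_form == life_form, , drop = FALSE]
  }
  if (!nrow(r)) stopf("no records for year %s%s", year,
                      if (is.null(life_form)) "" else paste0(", life form ", life_form))
  species <- sort(unique(r$species))
  M <- vapply(species, function(sp) {
    g <- r[r$species == sp, ]
    in_flower_counts(g$onset, g$end, cal)
  }, integer(length(cal$dates)))
  dimnames(M) <- list(format(cal$dates), species)
  structure(M, class = c("community_matrix", class(M)),
            year = as.integer(year), life_form = life_form)
}

#' Community-wide synchrony index
#'
#' The Loreau-de Mazancourt (2008) synchrony statistic
#' \deqn{\varphi = \sigma^2_{x_T} / \left(\sum_i \sigma_{x_i}\right)^2}
#' where \eqn{x_T(t) = \sum_i x_i(t)} is the community total and the sums run
#' over species. \eqn{\varphi = 1} when all species' series are perfectly
#' (positively, linearly) synchronous, and \eqn{\varphi \le 1} always by
#' Cauchy-Schwarz; under independence with equal variances its expectation is
#' close to 1/S for S species. Temporal variances use the sample (T-1)
#' denominator consistently; the ratio is invariant to that choice.
#'
#' `denominator = "var_sum"` exposes a literal sum-of-variances denominator
#' \eqn{\sum_i \sigma^2_{x_i}} for sensitivity analysis; it is not bounded by
#' 1 and is not the definition used anywhere else in the package.
#'
#' @param M numeric matrix, time points x species (a `community_matrix`).
#' @param denominator `"sd_sum"` (default, the squared sum of standard
#'   deviations) or `"var_sum"`.
#' @return the synchrony index; `NA` with a warning when every series is
#'   constant through time.
#' @examples
#' x <- rpois(20, 5)
#' synchrony_phi(cbind(x, x, x))  # identical series -> exactly 1
#' @export
synchrony_phi <- function(M, denominator = c("sd_sum", "var_sum")) {
  denominator <- match.arg(denominator)
  M <- as.matrix(M)
  if (nrow(M) < 2L) stopf("need >= 2 time points")
  xT <- rowSums(M)
  sds <- apply(M, 2L, stats::sd)
  den <- if (denominator == "sd_sum") sum(sds)^2 else sum(sds^2)
  if (den == 0) {
    warnf("all species series are constant; synchrony undefined")
    return(NA_real_)
  }
  stats::var(xT) / den
}

#' D'Agostino-Pearson omnibus test of normality (K-squared)
#'
#' Tests departure from normality through skewness and kurtosis jointly:
#' the sample skewness \eqn{\sqrt{b_1}} and kurtosis \eqn{b_2} are each
#' transformed to approximate standard normal deviates (D'Agostino 1970;
#' Anscombe & Glynn 1983) and \eqn{K^2 = Z_1^2 + Z_2^2} is referred to a
#' chi-square distribution with 2 degrees of freedom. Requires n >= 8 for
#' the kurtosis approximation to hold.
#'
#' @param x numeric vector, n >= 8, non-zero variance.
#' @return object of class `htest` with `statistic` (K-squared), `p.value`,
#'   and the sample skewness in `estimate`.
#' @export
dagostino_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stopf("D'Agostino's K-squared test requires n >= 8 (got %d)", n)
  if (stats::var(x) == 0) stopf("zero variance; test undefined")
  g1 <- moment_skewness(x)
  b2 <- moment_kurtosis(x)

  # skewness transform (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(Vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Z1^2 + Z2^2
  structure(list(
    statistic = c(`K-squared` = K2),
    parameter = c(df = 2),
    p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
    estimate = c(skewness = g1, kurtosis = b2),
    method = "D'Agostino-Pearson K-squared omnibus normality test",
    data.name = deparse(substitute(x))
  ), class = "htest")
}

#' Skewness of species-level onset dates with significance test
#'
#' Computes the moment skewness of the species-level onset days of one group
#' (one life form in one year; species-level onset = the earliest individual
#' onset) and tests its significance via [dagostino_test()]. Skewness is
#' shift-invariant, so day-of-year and days-since-first-onset give identical
#' values.
#'
#' @param onsets numeric or `Date` vector of species-level onsets, n >= 8.
#' @return list with `skewness`, `statistic` (K-squared), `p.value`.
#' @export
onset_skewness_test <- function(onsets) {
  x <- as.numeric(onsets)
  ht <- dagostino_test(x)
  list(skewness = unname(ht$estimate["skewness"]),
       statistic = unname(ht$statistic),
       p.value = ht$p.value)
}

#' Species-level onset dates for a group
#'
#' Earliest individual onset per species, for one life form and year.
#'
#' @param ds a `pheno_dataset`.
#' @param year calendar year.
#' @param life_form optional life-form subset.
#' @return named `Date` vector, one element per species.
#' @export
species_onsets <- function(ds, year, life_form = NULL) {
  r <- ds$records[ds$records$year == as.integer(year), , drop = FALSE]
  if (!is.null(life_form)) r <- r[r$life_form == life_form, , drop = FALSE]
  if (!nrow(r)) stopf("no records for the requested group")
  out <- vapply(split(r$onset, r$species), min, as.numeric(Sys.Date()))
  ret <- as.Date(out, origin = "1970-01-01")
  names(ret) <- names(out)
  ret
}

#' Species-bootstrap confidence interval for a group statistic
#'
#' Resamples species (columns of a community matrix for `statistic = "phi"`,
#' elements of the onset vector for `statistic = "skewness"`) with
#' replacement at the group's own size, `B` times, and returns the 2.5% and
#' 97.5% percentiles of the replicate statistics. Replicates in which the
#' statistic is undefined are dropped and the effective replicate count
#' reported.
#'
#' @param x a `community_matrix` (for `"phi"`) or numeric/`Date` vector of
#'   species-level onsets (for `"skewness"`), >= 2 species.
#' @param statistic `"phi"` or `"skewness"`.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed or `NULL`.
#' @param conf confidence level (default 0.95, percentile method).
#' @return object of class `synchrony_ci`: list with `estimate`, `ci_low`,
#'   `ci_high`, `B`, `B_eff`, `statistic`, `seed`.
#' @export
bootstrap_group_ci <- function(x, statistic = c("phi", "skewness"),
                               B = 1000L, seed = NULL, conf = 0.95) {
  statistic <- match.arg(statistic)
  if (statistic == "phi") {
    M <- as.matrix(x)
    S <- ncol(M)
    if (S < 2L) stopf("need >= 2 species")
    est <- suppressWarnings(synchrony_phi(M))
    reps <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        cols <- sample.int(S, S, replace = TRUE)
        suppressWarnings(synchrony_phi(M[, cols, drop = FALSE]))
      }, 0)
    })
  } else {
    v <- as.numeric(x)
    S <- length(v)
    if (S < 2L) stopf("need >= 2 species")
    est <- moment_skewness(v)
    reps <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        moment_skewness(sample(v, S, replace = TRUE))
      }, 0)
    })
  }
  ok <- is.finite(reps)
  if (!any(ok)) stopf("statistic undefined in every bootstrap replicate")
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(reps[ok], c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(estimate = est, ci_low = qs[1L], ci_high = qs[2L],
                 B = B, B_eff = sum(ok), statistic = statistic, seed = seed),
            class = "synchrony_ci")
}

#' @export
print.synchrony_ci <- function(x, ...) {
  cat(sprintf("%s = %.4g, %d bootstrap replicates (%d defined): [%.4g, %.4g]\n",
              x$statistic, x$estimate, x$B, x$B_eff, x$ci_low, x$ci_high))
  invisible(x)
}
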