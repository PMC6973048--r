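# Bootstrap rarefaction-extrapolation: expected value of each phenological
# variable as a function of the number of observed individuals, a four-model
# least-squares fit with BIC selection on pooled max-standardized curves, and
# evaluation of per-species fits at standardized sample sizes.

PHENO_VARIABLES <- c("TFL", "MFL", "VFL", "skewness", "kurtosis",
                     "onset_variance", "morisita")

# smallest sample size at which each statistic is defined
variable_min_n <- function(variable) {
  switch(variable,
         TFL = 1L, MFL = 1L,
         VFL = 2L, onset_variance = 2L, morisita = 2L,
         skewness = 3L, kurtosis = 4L,
         stopf("unknown phenological variable '%s'", variable))
}

#' Evaluate one phenological variable on a set of individuals
#'
#' The statistic computed by the bootstrap machinery for a single draw.
#' Returns `NA` when undefined at the given sample (e.g. zero second moment
#' for skewness).
#'
#' @param variable one of `"TFL"`, `"MFL"`, `"VFL"`, `"skewness"`,
#'   `"kurtosis"`, `"onset_variance"`, `"morisita"`.
#' @param onset,end `Date` vectors.
#' @param calendar [census_calendar()]; required for `"morisita"` only.
#' @param morisita_bins bin set for the aggregation index, see
#'   [morisita_index()].
#' @return numeric scalar.
#' @export
pheno_statistic <- function(variable, onset, end, calendar = NULL,
                            morisita_bins = "season") {
  len <- flowering_length(onset, end)
  switch(variable,
         TFL = as.numeric(total_flowering_length(onset, end)),
         MFL = mean(len),
         VFL = if (length(len) >= 2L) stats::var(len) else NA_real_,
         skewness = moment_skewness(len),
         kurtosis = moment_kurtosis(len),
         onset_variance = if (length(onset) >= 2L) {
           stats::var(as.numeric(onset))
         } else NA_real_,
         morisita = {
           if (is.null(calendar)) stopf("morisita needs a census calendar")
           suppressWarnings(morisita_index(onset, end, calendar,
                                           bins = morisita_bins))
         },
         stopf("unknown phenological variable '%s'", variable))
}

#' Bootstrap rarefaction curve for one species
#'
#' For every sample size `j` from the statistic's minimum up to `n_max`,
#' draws `j` individuals with replacement `B` times, evaluates `variable` on
#' each draw and averages over the replicates in which it is defined (the
#' effective replicate count is recorded per point). Reproducible given
#' `seed`.
#'
#' @param recs data.frame of one species-year (or species, years pooled)
#'   with `onset`, `end` columns.
#' @param variable phenological variable name (see [pheno_statistic()]).
#' @param calendar [census_calendar()] for `"morisita"`.
#' @param n_max largest sample size; defaults to the number of observed
#'   individuals. Values beyond `nrow(recs)` are permitted (sampling is with
#'   replacement) but extrapolation is normally done through the fitted
#'   model instead.
#' @param B bootstrap replicates per sample size (default 1000).
#' @param seed integer seed or `NULL`.
#' @param morisita_bins bin set for the aggregation index, see
#'   [morisita_index()].
#' @return object of class `bootstrap_curve`: data.frame with columns `j`,
#'   `mean`, `B_eff`, and attributes `variable`, `B`, `seed`, `n`.
#' @export
bootstrap_curve <- function(recs, variable, calendar = NULL, n_max = NULL,
                            B = 1000L, seed = NULL, morisita_bins = "season") {
  stopifnot(is.data.frame(recs), nrow(recs) >= 1L, B >= 1L)
  n <- nrow(recs)
  if (is.null(n_max)) n_max <- n
  j_min <- variable_min_n(variable)
  if (n_max < j_min) {
    warnf("'%s' is undefined at every sample size <= %d; empty curve", variable, n_max)
    out <- data.frame(j = integer(), mean = numeric(), B_eff = integer())
    return(structure(out, class = c("bootstrap_curve", "data.frame"),
                     variable = variable, B = B, seed = seed, n = n))
  }
  onset_num <- as.numeric(recs$onset)
  end_num <- as.numeric(recs$end)
  len <- flowering_length(recs$onset, recs$end)

  if (variable == "morisita") {
    dates <- calendar$dates
    q_all <- length(dates)
    C <- matrix(0L, n, q_all)
    for (i in seq_len(n)) {
      C[i, ] <- as.integer(onset_num[i] <= as.numeric(dates) &
                             as.numeric(dates) <= end_num[i])
    }
    first_idx <- apply(C, 1L, function(z) which(z == 1L)[1L])
    last_idx <- apply(C, 1L, function(z) max(which(z == 1L)))
    if (anyNA(first_idx)) stopf("record(s) cover no census date")
  }

  js <- seq.int(j_min, n_max)
  means <- numeric(length(js))
  B_eff <- integer(length(js))
  with_seed(seed, {
    for (k in seq_along(js)) {
      j <- js[k]
      idx <- matrix(sample.int(n, j * B, replace = TRUE), j, B)
      vals <- switch(variable,
        MFL = .colMeans(matrix(len[idx], j, B), j, B),
        VFL = boot_col_var(matrix(len[idx], j, B)),
        onset_variance = boot_col_var(matrix(onset_num[idx], j, B)),
        skewness = boot_col_shape(matrix(len[idx], j, B), moment = 3L),
        kurtosis = boot_col_shape(matrix(len[idx], j, B), moment = 4L),
        TFL = {
          E <- matrix(end_num[idx], j, B)
          O <- matrix(onset_num[idx], j, B)
          Reduce(pmax, asplit(E, 1L)) - Reduce(pmin, asplit(O, 1L)) + 1
        },
        morisita = {
          v <- numeric(B)
          window <- morisita_bins == "flowering"
          for (b in seq_len(B)) {
            rows <- idx[, b]
            if (window) {
              lo <- min(first_idx[rows]); hi <- max(last_idx[rows])
            } else {
              lo <- 1L; hi <- q_all
            }
            cnt <- .colSums(C[rows, lo:hi, drop = FALSE], length(rows), hi - lo + 1L)
            N <- sum(cnt)
            v[b] <- if (N < 2) NA_real_ else {
              (hi - lo + 1L) * sum(cnt * (cnt - 1)) / (N * (N - 1))
            }
          }
          v
        })
      ok <- is.finite(vals)
      means[k] <- if (any(ok)) mean(vals[ok]) else NA_real_
      B_eff[k] <- sum(ok)
    }
  })
  out <- data.frame(j = js, mean = means, B_eff = B_eff)
  keep <- is.finite(out$mean)
  if (!all(keep)) {
    warnf("'%s' undefined in all replicates at %d sample size(s); dropped",
          variable, sum(!keep))
    out <- out[keep, , drop = FALSE]
  }
  structure(out, class = c("bootstrap_curve", "data.frame"),
            variable = variable, B = B, seed = seed, n = n)
}

# sample variance (n-1) of each column of a j x B matrix
boot_col_var <- function(M) {
  j <- nrow(M)
  if (j < 2L) return(rep(NA_real_, ncol(M)))
  cm <- .colMeans(M, j, ncol(M))
  (.colSums(M^2, j, ncol(M)) - j * cm^2) / (j - 1)
}

# columnwise moment skewness (moment = 3) or raw kurtosis (moment = 4)
boot_col_shape <- function(M, moment) {
  j <- nrow(M); B <- ncol(M)
  cm <- .colMeans(M, j, B)
  Mc <- M - matrix(cm, j, B, byrow = TRUE)
  m2 <- .colSums(Mc^2, j, B) / j
  out <- if (moment == 3L) {
    (.colSums(Mc^3, j, B) / j) / m2^1.5
  } else {
    (.colSums(Mc^4, j, B) / j) / m2^2
  }
  out[m2 <= 0] <- NA_real_
  out
}

CURVE_FORMS <- c("linear", "logarithmic", "quadratic", "logistic")

# least-squares fit of one candidate mean function; returns NULL when the
# optimizer fails (logistic only -- the linear-in-parameters forms cannot)
fit_curve_form <- function(j, y, form) {
  fit <- switch(form,
    linear = {
      co <- stats::coef(stats::lm(y ~ j))
      list(coef = c(a = unname(co[1L]), b = unname(co[2L])),
           predict = function(x) co[1L] + co[2L] * x, k = 2L)
    },
    quadratic = {
      co <- stats::coef(stats::lm(y ~ j + I(j^2)))
      list(coef = c(a = unname(co[1L]), b = unname(co[2L]), c = unname(co[3L])),
           predict = function(x) co[1L] + co[2L] * x + co[3L] * x^2, k = 3L)
    },
    logarithmic = {
      co <- stats::coef(stats::lm(y ~ log(j)))
      list(coef = c(a = unname(co[1L]), b = unname(co[2L])),
           predict = function(x) co[1L] + co[2L] * log(x), k = 2L)
    },
    logistic = {
      a0 <- max(y)
      if (a0 <= 0) a0 <- max(abs(y)) + 1e-6
      c0 <- j[which.min(abs(y - a0 / 2))]
      dat <- data.frame(j = j, y = y)
      m <- tryCatch(
        minpack.lm::nlsLM(y ~ a / (1 + exp(-b * (j - c))), data = dat,
                          start = list(a = a0, b = 1, c = c0),
                          lower = c(a = 1e-10, b = -50, c = min(j) - diff(range(j)) - 1),
                          upper = c(a = Inf, b = 50, c = max(j) + diff(range(j)) + 1),
                          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (is.null(m)) return(NULL)
      co <- stats::coef(m)
      list(coef = co,
           predict = function(x) co[["a"]] / (1 + exp(-co[["b"]] * (x - co[["c"]]))),
           k = 3L)
    },
    stopf("unknown curve form '%s'", form))
  if (is.null(fit)) return(NULL)
  rss <- sum((y - fit$predict(j))^2)
  c(fit, list(form = form, rss = rss, m = length(j)))
}

# BIC with a Gaussian error model on the curve points:
#   BIC = m log(RSS/m) + k log(m),  k = mean-function parameters + 1.
# RSS/m is floored at 1e-12 so that interpolating fits compare by k alone.
curve_bic <- function(fit) {
  m <- fit$m
  m * log(max(fit$rss / m, 1e-12)) + (fit$k + 1L) * log(m)
}

#' Select a rarefaction-curve model by BIC
#'
#' Fits linear, logarithmic, quadratic and three-parameter logistic mean
#' functions by least squares to pooled curve points and returns the form
#' with the smallest BIC (`m log(RSS/m) + k log m`, `k` counting the error
#' variance). The intended input pools every species' bootstrap curve for
#' one variable after rescaling each curve by its own maximum (see
#' [pool_standardized_curves()]). Ties are broken towards fewer parameters,
#' then by the fixed order linear, logarithmic, quadratic, logistic. A
#' non-convergent logistic fit is excluded with a warning.
#'
#' @param pooled data.frame with columns `j`, `y`.
#' @param forms candidate forms (default all four).
#' @return object of class `curve_model_selection`: list with `form` (the
#'   winner), `table` (per-form k, RSS, BIC, converged flag).
#' @export
select_model <- function(pooled, forms = CURVE_FORMS) {
  stopifnot(all(c("j", "y") %in% names(pooled)), nrow(pooled) >= 5L)
  forms <- match.arg(forms, CURVE_FORMS, several.ok = TRUE)
  fits <- lapply(forms, function(f) fit_curve_form(pooled$j, pooled$y, f))
  names(fits) <- forms
  failed <- vapply(fits, is.null, TRUE)
  if (any(failed)) {
    warnf("curve fit did not converge and was excluded: %s",
          paste(forms[failed], collapse = ", "))
  }
  tab <- data.frame(
    form = forms,
    k = vapply(fits, function(f) if (is.null(f)) NA_integer_ else f$k, 0L),
    RSS = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$rss, 0),
    BIC = vapply(fits, function(f) if (is.null(f)) NA_real_ else curve_bic(f), 0),
    converged = !failed,
    stringsAsFactors = FALSE
  )
  ok <- tab[tab$converged, , drop = FALSE]
  if (!nrow(ok)) stopf("no candidate model converged")
  # stable order: BIC, then parameter count, then the fixed form order
  ok <- ok[order(round(ok$BIC, 9), ok$k, match(ok$form, CURVE_FORMS)), , drop = FALSE]
  structure(list(form = ok$form[1L], table = tab),
            class = "curve_model_selection")
}

#' @export
print.curve_model_selection <- function(x, ...) {
  cat("Rarefaction-curve model selection (BIC):\n")
  print(x$table, row.names = FALSE)
  cat("selected:", x$form, "\n")
  invisible(x)
}

#' Pool max-standardized bootstrap curves
#'
#' Rescales each species' curve by its own maximum mean value and stacks the
#' points, the input expected by [select_model()].
#'
#' @param curves list of [bootstrap_curve()] objects for one variable.
#' @return data.frame with columns `j`, `y`.
#' @export
pool_standardized_curves <- function(curves) {
  pieces <- lapply(curves, function(cu) {
    if (!nrow(cu)) return(NULL)
    mx <- max(abs(cu$mean))
    if (mx == 0) mx <- 1
    data.frame(j = cu$j, y = cu$mean / mx)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Evaluate a fitted rarefaction curve at a standardized sample size
#'
#' Fits `form` (selected globally for the variable) to the species' own raw
#' curve and returns the fitted value at each `n_std`, interpolating or
#' extrapolating as needed. If the fit does not converge, falls back to the
#' bootstrap mean at the nearest available sample size, with a warning.
#'
#' @param curve a [bootstrap_curve()].
#' @param form one of the candidate forms.
#' @param n_std integer sample size(s), e.g. `c(5, 7, 12, 18, 22)`.
#' @return named numeric vector of fitted values along `n_std`.
#' @export
standardized_value <- function(curve, form, n_std) {
  stopifnot(inherits(curve, "bootstrap_curve"), nrow(curve) >= 1L)
  fit <- if (nrow(curve) >= variable_min_n_form(form)) {
    fit_curve_form(curve$j, curve$mean, form)
  } else {
    NULL
  }
  vals <- if (is.null(fit)) {
    warnf("per-species '%s' fit unavailable; using nearest-sample-size bootstrap mean",
          form)
    vapply(n_std, function(ns) curve$mean[which.min(abs(curve$j - ns))], 0)
  } else {
    fit$predict(n_std)
  }
  names(vals) <- n_std
  vals
}

# points needed to identify the mean function (parameters count)
variable_min_n_form <- function(form) {
  switch(form, linear = 2L, logarithmic = 2L, quadratic = 3L, logistic = 3L)
}

#' Standardized estimates of phenological variables for all species
#'
#' The full rarefaction-extrapolation workflow: per species, bootstrap
#' curves for each variable (years pooled into a single individual pool by
#' default, onset-based statistics computed within-year would require
#' `pool_years = FALSE`); model selection by BIC on the pooled
#' max-standardized curves; per-species fits of the selected form evaluated
#' at the standardized sample sizes.
#'
#' @param ds a `pheno_dataset` (already filtered).
#' @param variables subset of [PHENO_VARIABLES].
#' @param n_std standardized sample sizes (default `c(5, 7, 12, 18, 22)`).
#' @param B bootstrap replicates (default 1000).
#' @param n_max per-species maximum sample size (default: own n).
#' @param seed master seed; per-(species, variable) sub-seeds are derived.
#' @param pool_years average the two years' standardized values per species
#'   (default `TRUE`); curves themselves are computed per species-year.
#' @param morisita_bins bin set for the aggregation index, see
#'   [morisita_index()].
#' @return data.frame with columns `species`, `life_form`, `variable`,
#'   `n_std`, `value`; attribute `"forms"` holds the selected model per
#'   variable.
#' @export
standardize_estimates <- function(ds, variables = c("TFL", "MFL", "VFL", "morisita"),
                                  n_std = c(5L, 7L, 12L, 18L, 22L),
                                  B = 1000L, n_max = NULL, seed = NULL,
                                  pool_years = TRUE, morisita_bins = "season") {
  stopifnot(inherits(ds, "pheno_dataset"))
  variables <- match.arg(variables, PHENO_VARIABLES, several.ok = TRUE)
  r <- ds$records
  key <- interaction(r$species, r$year, drop = TRUE)
  groups <- split(r, key)

  out <- list()
  forms <- character(0)
  for (v in variables) {
    curves <- lapply(groups, function(g) {
      cal <- ds$calendars[[as.character(g$year[1L])]]
      bootstrap_curve(g, v, calendar = cal, n_max = n_max, B = B,
                      seed = derive_seed(seed, c(g$species[1L], g$year[1L], v)),
                      morisita_bins = morisita_bins)
    })
    nonempty <- vapply(curves, nrow, 0L) > 0L
    if (!any(nonempty)) {
      warnf("no species-year has a defined '%s' curve; variable skipped", v)
      next
    }
    sel <- select_model(pool_standardized_curves(curves[nonempty]))
    forms[v] <- sel$form
    vals <- lapply(which(nonempty), function(i) {
      g <- groups[[i]]
      sv <- standardized_value(curves[[i]], sel$form, n_std)
      data.frame(species = g$species[1L], year = g$year[1L],
                 life_form = g$life_form[1L], variable = v,
                 n_std = n_std, value = unname(sv), stringsAsFactors = FALSE)
    })
    out[[v]] <- do.call(rbind, vals)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (pool_years) {
    agg <- stats::aggregate(value ~ species + life_form + variable + n_std,
                            data = res, FUN = mean)
    res <- agg[order(agg$variable, agg$species, agg$n_std), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "forms") <- forms
  res
}
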