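# Species-level phenological variables computed from individual onset/end
# records: flowering lengths (total, mean, variance, shape), onset variance,
# and Morisita's temporal aggregation index.

#' Flowering length of individuals
#'
#' Length of the flowering interval in inclusive days: `(end - onset) + 1`,
#' so an individual seen flowering on a single census date has length 1.
#'
#' @param onset,end `Date` vectors (recycled like arithmetic).
#' @return integer days.
#' @examples
#' flowering_length(as.Date("2016-03-01"), as.Date("2016-03-15"))  # 15
#' @export
flowering_length <- function(onset, end) {
  len <- as.integer(as.numeric(end) - as.numeric(onset)) + 1L
  if (any(len < 1L)) stopf("end date before onset date")
  len
}

#' Total flowering length of a species
#'
#' Days from the onset of the first-flowering individual to the end of the
#' last-flowering individual, inclusive. Gaps between disjoint individual
#' intervals count: the value is `max(end) - min(onset) + 1`.
#'
#' @param onset,end `Date` (or numeric day) vectors for the individuals of
#'   one species in one year.
#' @return integer days.
#' @export
total_flowering_length <- function(onset, end) {
  if (!length(onset)) stopf("total_flowering_length needs >= 1 individual")
  as.integer(max(as.numeric(end)) - min(as.numeric(onset))) + 1L
}

#' Morisita aggregation index from time-bin counts
#'
#' The dispersion index \eqn{I_\delta = q \sum n_i (n_i - 1) / (N (N - 1))}
#' over `q` time bins with counts `n_i` and \eqn{N = \sum n_i}. Values near 1
#' indicate random (Poisson-like) spread over bins; the maximum `q` is
#' reached when all N observations fall in a single bin (maximal temporal
#' aggregation, i.e. maximal flowering synchrony).
#'
#' @param counts non-negative integer vector of per-bin counts.
#' @return the index, or `NA` (with a warning) when `N < 2`.
#' @examples
#' morisita_idelta(rep(2, 5))      # q(n-1)/(qn-1) = 5/9
#' morisita_idelta(c(7, 0, 0))     # = q = 3, all co-occur
#' @export
morisita_idelta <- function(counts) {
  if (any(counts < 0)) stopf("negative bin counts")
  q <- length(counts)
  N <- sum(counts)
  if (N < 2) {
    warnf("Morisita index undefined for N < 2 individuals-in-flower")
    return(NA_real_)
  }
  q * sum(counts * (counts - 1)) / (N * (N - 1))
}

#' Counts of simultaneously flowering individuals per census date
#'
#' For each census date, the number of individuals whose `[onset, end]`
#' interval covers it.
#'
#' @param onset,end `Date` vectors.
#' @param calendar a [census_calendar()].
#' @return integer vector along `calendar$dates`.
#' @export
in_flower_counts <- function(onset, end, calendar) {
  vapply(calendar$dates, function(d) sum(onset <= d & d <= end), 0L)
}

#' Morisita aggregation index for a species' records
#'
#' Computes per-census-date counts of individuals in flower (each individual
#' contributes to every census inside its interval) and applies
#' [morisita_idelta()]. By default the bins are the full season calendar,
#' common to every species, so that concentrating all flowering into a few
#' census dates yields a large index (high intraspecific synchrony) and
#' spreading it through the season yields a small one. `bins = "flowering"`
#' restricts the bins to the species' own window (first onset census to last
#' end census), which instead measures count aggregation *within* the
#' flowering period. `counts = "onset"` bins onset events rather than
#' in-flower status.
#'
#' @param onset,end `Date` vectors for one species-year (>= 2 individuals).
#' @param calendar a [census_calendar()].
#' @param bins `"season"` (default) or `"flowering"`.
#' @param counts `"in_flower"` (default) or `"onset"`.
#' @return the index (`NA` with a warning when undefined).
#' @export
morisita_index <- function(onset, end, calendar,
                           bins = c("season", "flowering"),
                           counts = c("in_flower", "onset")) {
  bins <- match.arg(bins)
  counts <- match.arg(counts)
  dates <- calendar$dates
  if (bins == "flowering") {
    lo <- which(dates >= min(onset))[1L]
    hi <- max(which(dates <= max(end)))
    if (is.na(lo) || !is.finite(hi) || hi < lo) {
      warnf("no census dates inside the species' flowering window")
      return(NA_real_)
    }
    dates <- dates[lo:hi]
  }
  n_i <- if (counts == "in_flower") {
    vapply(dates, function(d) sum(onset <= d & d <= end), 0L)
  } else {
    vapply(dates, function(d) sum(onset == d), 0L)
  }
  morisita_idelta(n_i)
}

#' Species-year phenology summaries
#'
#' Computes, for every species-year with at least one record, the variables
#' used throughout the pipeline:
#' \describe{
#'   \item{TFL}{total flowering length (days)}
#'   \item{MFL}{mean flowering length of individuals (days)}
#'   \item{VFL}{sample variance (n-1 denominator) of individual lengths}
#'   \item{skewness, kurtosis}{moment estimators of the flowering-length
#'     distribution shape (kurtosis is raw, normal = 3); `NA` below n = 3 / 4}
#'   \item{onset_variance}{sample variance of onset offsets, i.e. days since
#'     the species' earliest onset that year (shift-invariant)}
#'   \item{morisita}{[morisita_index()] on in-flower counts over the season
#'     calendar}
#' }
#'
#' @param ds a `pheno_dataset`.
#' @param excess_kurtosis subtract 3 from kurtosis? Default `FALSE`.
#' @param morisita_bins passed to [morisita_index()].
#' @return data.frame, one row per species-year, ordered by species then
#'   year, with columns `species, year, life_form, genus, n, TFL, MFL, VFL,
#'   skewness, kurtosis, onset_variance, morisita`.
#' @export
summarize_species <- function(ds, excess_kurtosis = FALSE,
                              morisita_bins = "season") {
  stopifnot(inherits(ds, "pheno_dataset"))
  r <- ds$records
  if (!nrow(r)) stopf("dataset has no records")
  key <- interaction(r$species, r$year, drop = TRUE)
  rows <- lapply(split(r, key), function(g) {
    cal <- ds$calendars[[as.character(g$year[1L])]]
    len <- flowering_length(g$onset, g$end)
    onset_off <- as.numeric(g$onset) - min(as.numeric(g$onset))
    n <- nrow(g)
    data.frame(
      species = g$species[1L],
      year = g$year[1L],
      life_form = g$life_form[1L],
      genus = g$genus[1L],
      n = n,
      TFL = total_flowering_length(g$onset, g$end),
      MFL = mean(len),
      VFL = if (n >= 2L) stats::var(len) else NA_real_,
      skewness = moment_skewness(len),
      kurtosis = moment_kurtosis(len, excess = excess_kurtosis),
      onset_variance = if (n >= 2L) stats::var(onset_off) else NA_real_,
      morisita = if (n >= 2L) {
        morisita_index(g$onset, g$end, cal, bins = morisita_bins)
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}
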