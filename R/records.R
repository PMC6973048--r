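# Data model and I/O for individual-level flowering records observed on a
# weekly census calendar, plus the species-inclusion filters applied before
# any statistics are computed.

LIFE_FORMS <- c("tree", "perennial", "annual")

#' Census calendar
#'
#' An ordered set of observation dates for one year. The field protocol this
#' package targets is a weekly census through the flowering season, so all
#' record dates must be members of the calendar: individuals are only ever
#' seen (and their onset/end recorded) on census dates.
#'
#' @param year integer year.
#' @param dates `Date` vector (or ISO-8601 strings), strictly increasing,
#'   all within `year`, at least two dates.
#' @return an object of class `census_calendar` with fields `year`, `dates`.
#' @seealso [weekly_calendar()] for the standard weekly season.
#' @export
census_calendar <- function(year, dates) {
  year <- as.integer(year)
  dates <- as.Date(dates)
  if (anyNA(dates)) stopf("census calendar for %d contains unparseable dates", year)
  if (length(dates) < 2L) stopf("census calendar needs >= 2 dates, got %d", length(dates))
  if (any(as.integer(format(dates, "%Y")) != year)) {
    stopf("census calendar for %d contains dates outside that year", year)
  }
  if (any(diff(dates) <= 0)) stopf("census dates must be strictly increasing")
  structure(list(year = year, dates = dates), class = "census_calendar")
}

#' Weekly census calendar over a flowering season
#'
#' Builds the weekly observation calendar used throughout: censuses every
#' `by` days from `start` to no later than `end` within one year. Defaults
#' reproduce a 1 March - 31 July weekly season.
#'
#' @param year integer year.
#' @param start,end month-day strings (`"mm-dd"`) bounding the season.
#' @param by census interval in days (default 7).
#' @return a [census_calendar()].
#' @examples
#' cal <- weekly_calendar(2016)
#' length(cal$dates)  # 22 weekly censuses
#' @export
weekly_calendar <- function(year, start = "03-01", end = "07-31", by = 7L) {
  d0 <- as.Date(sprintf("%d-%s", year, start))
  d1 <- as.Date(sprintf("%d-%s", year, end))
  census_calendar(year, seq(d0, d1, by = by))
}

#' @export
print.census_calendar <- function(x, ...) {
  cat(sprintf("Census calendar %d: %d dates, %s .. %s\n",
              x$year, length(x$dates), format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

#' Assemble a validated phenology dataset
#'
#' Bundles flowering records, per-year census calendars and species metadata,
#' enforcing the referential invariants the analyses rely on: every record's
#' species appears in the metadata, its life form is one of tree / perennial /
#' annual, onset <= end, and both dates are members of that year's census
#' calendar (records are census-resolution by construction).
#'
#' @param records data.frame with columns `species`, `genus`, `family`,
#'   `life_form`, `year`, `individual_id`, `onset`, `end` (dates as `Date`
#'   or ISO-8601 strings).
#' @param calendars a single [census_calendar()] or a list of them covering
#'   every year present in `records`.
#' @param meta data.frame with columns `species`, `genus`, `family`,
#'   `life_form` (one row per species); optional extra columns kept as-is.
#'   If `NULL`, metadata is derived from the records.
#' @return an object of class `pheno_dataset` with fields `records`,
#'   `calendars` (named by year), `meta`.
#' @export
pheno_dataset <- function(records, calendars, meta = NULL) {
  req <- c("species", "genus", "family", "life_form", "year",
           "individual_id", "onset", "end")
  miss <- setdiff(req, names(records))
  if (length(miss)) stopf("records are missing columns: %s", paste(miss, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$year <- as.integer(records$year)
  records$onset <- parse_iso_dates(records$onset, "onset")
  records$end <- parse_iso_dates(records$end, "end")
  bad <- which(records$end < records$onset)
  if (length(bad)) {
    stopf("end date before onset date in record row(s) %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad_lf <- setdiff(unique(records$life_form), LIFE_FORMS)
  if (length(bad_lf)) {
    stopf("unknown life_form value(s): %s (expected %s)",
          paste(bad_lf, collapse = ", "), paste(LIFE_FORMS, collapse = ", "))
  }

  if (inherits(calendars, "census_calendar")) calendars <- list(calendars)
  if (!length(calendars) || !all(vapply(calendars, inherits, TRUE, "census_calendar"))) {
    stopf("calendars must be census_calendar objects")
  }
  names(calendars) <- vapply(calendars, function(c) as.character(c$year), "")

  if (is.null(meta)) {
    meta <- unique(records[c("species", "genus", "family", "life_form")])
    rownames(meta) <- NULL
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (anyDuplicated(meta$species)) stopf("species names in meta are not unique")
  if (any(!nzchar(meta$genus)) || any(!nzchar(meta$family))) {
    stopf("meta genus/family must be non-empty")
  }

  orphan <- setdiff(unique(records$species), meta$species)
  if (length(orphan)) {
    stopf("record species absent from meta: %s", paste(orphan, collapse = ", "))
  }
  no_cal <- setdiff(unique(records$year), as.integer(names(calendars)))
  if (length(no_cal)) {
    stopf("no census calendar supplied for year(s): %s", paste(no_cal, collapse = ", "))
  }
  for (yr in unique(records$year)) {
    cal <- calendars[[as.character(yr)]]
    r <- records[records$year == yr, ]
    off <- !(r$onset %in% cal$dates) | !(r$end %in% cal$dates)
    if (any(off)) {
      stopf("year %d: %d record(s) have onset/end not on a census date (first species: %s)",
            yr, sum(off), r$species[which(off)[1L]])
    }
  }
  structure(list(records = records, calendars = calendars, meta = meta),
            class = "pheno_dataset")
}

parse_iso_dates <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    stopf("malformed %s date in row(s) %s", what,
          paste(utils::head(which(is.na(d)), 5L), collapse = ", "))
  }
  d
}

#' @export
print.pheno_dataset <- function(x, ...) {
  cat(sprintf("Flowering phenology dataset: %d records, %d species, years %s\n",
              nrow(x$records), length(unique(x$records$species)),
              paste(names(x$calendars), collapse = ", ")))
  tb <- table(x$meta$life_form)
  cat("  life forms:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Read a phenology dataset from delimited text
#'
#' Reads the three CSV inputs (records, census calendar, species metadata),
#' parses dates as ISO-8601 and returns a validated [pheno_dataset()]. Row
#' order of the records file is preserved.
#'
#' @param records_path CSV with header
#'   `species,genus,family,life_form,year,individual_id,onset,end`.
#' @param calendar_path CSV with header `year,date`, one row per census date.
#' @param meta_path optional CSV with header
#'   `species,genus,family,life_form,...`; derived from records when `NULL`.
#' @return a `pheno_dataset`.
#' @export
read_pheno_dataset <- function(records_path, calendar_path, meta_path = NULL) {
  records <- utils::read.csv(records_path, stringsAsFactors = FALSE)
  cal_df <- utils::read.csv(calendar_path, stringsAsFactors = FALSE)
  if (!all(c("year", "date") %in% names(cal_df))) {
    stopf("calendar file must have columns year,date")
  }
  calendars <- lapply(split(cal_df, cal_df$year), function(d) {
    census_calendar(d$year[1L], sort(as.Date(d$date)))
  })
  meta <- if (is.null(meta_path)) NULL else utils::read.csv(meta_path, stringsAsFactors = FALSE)
  pheno_dataset(records, calendars, meta)
}

#' Write phenology records, calendars and metadata back to CSV
#'
#' Inverse of [read_pheno_dataset()]; writing then reading reproduces the
#' dataset.
#'
#' @param ds a `pheno_dataset`.
#' @param records_path,calendar_path,meta_path output file paths.
#' @return `ds`, invisibly.
#' @export
write_pheno_dataset <- function(ds, records_path, calendar_path, meta_path) {
  stopifnot(inherits(ds, "pheno_dataset"))
  utils::write.csv(ds$records, records_path, row.names = FALSE)
  cal_df <- do.call(rbind, lapply(ds$calendars, function(c) {
    data.frame(year = c$year, date = format(c$dates), stringsAsFactors = FALSE)
  }))
  utils::write.csv(cal_df, calendar_path, row.names = FALSE)
  utils::write.csv(ds$meta, meta_path, row.names = FALSE)
  invisible(ds)
}

#' Species-inclusion filters
#'
#' Applies the two inclusion rules used before computing species-level
#' statistics: a species must have flowered on strictly more than
#' `min_flowering_days` census dates (distinct year-date pairs with at least
#' one individual in flower), and must have at least `min_individuals`
#' observed individuals -- per year in every calendar year when
#' `require_both_years = TRUE`, else pooled over years. Dropped species are
#' reported in the `"dropped"` attribute of the result.
#'
#' The filter is idempotent and monotone: raising thresholds never adds
#' species back.
#'
#' @param ds a `pheno_dataset`.
#' @param min_flowering_days keep species flowering on more than this many
#'   census dates (default 2, i.e. "> 2 observation days").
#' @param min_individuals minimum individual count (default 5).
#' @param require_both_years apply the individual threshold within every
#'   calendar year rather than to the pooled count? Default `TRUE`.
#' @return a filtered `pheno_dataset`; attribute `"dropped"` is a data.frame
#'   with columns `species`, `reason`.
#' @export
filter_species <- function(ds, min_flowering_days = 2L, min_individuals = 5L,
                           require_both_years = TRUE) {
  stopifnot(inherits(ds, "pheno_dataset"))
  r <- ds$records
  sp <- unique(r$species)
  years <- as.integer(names(ds$calendars))

  keep <- logical(length(sp))
  reason <- character(length(sp))
  for (i in seq_along(sp)) {
    ri <- r[r$species == sp[i], ]
    # distinct (year, census date) pairs with >= 1 individual in flower
    fdays <- 0L
    for (yr in unique(ri$year)) {
      cal <- ds$calendars[[as.character(yr)]]
      ry <- ri[ri$year == yr, ]
      infl <- vapply(cal$dates,
                     function(d) any(ry$onset <= d & d <= ry$end), TRUE)
      fdays <- fdays + sum(infl)
    }
    if (fdays <= min_flowering_days) {
      reason[i] <- sprintf("flowering days %d <= %d", fdays, min_flowering_days)
      next
    }
    if (require_both_years) {
      counts <- vapply(years, function(yr) sum(ri$year == yr), 0L)
      if (any(counts < min_individuals)) {
        reason[i] <- sprintf("individuals per year (%s) below %d",
                             paste(counts, collapse = "/"), min_individuals)
        next
      }
    } else if (nrow(ri) < min_individuals) {
      reason[i] <- sprintf("individuals %d < %d", nrow(ri), min_individuals)
      next
    }
    keep[i] <- TRUE
  }

  dropped <- data.frame(species = sp[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- ds
  out$records <- r[r$species %in% sp[keep], , drop = FALSE]
  rownames(out$records) <- NULL
  out$meta <- ds$meta[!(ds$meta$species %in% dropped$species), , drop = FALSE]
  rownames(out$meta) <- NULL
  if (!nrow(out$records)) warnf("all species were dropped by the filters")
  attr(out, "dropped") <- dropped
  out
}

#' Write a species-year summary table
#'
#' Writes one row per species-year in a fixed column order; reading the file
#' back with [read_summary_table()] reproduces the values.
#'
#' @param summaries data.frame as produced by [summarize_species()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  cols <- c("species", "year", "life_form", "genus", "n", "TFL", "MFL", "VFL",
            "skewness", "kurtosis", "onset_variance", "morisita")
  cols <- cols[cols %in% names(summaries)]
  extra <- setdiff(names(summaries), cols)
  utils::write.csv(summaries[c(cols, extra)], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_table
#' @export
read_summary_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
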