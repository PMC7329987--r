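#' Daily mean soil temperatures per plot
#'
#' Arithmetic mean of all hourly readings grouped by Julian day; partial
#' first/last days are averaged over whatever readings exist.
#'
#' @param temperature Tibble with `plot_id`, `julian_day`, `hour`, `temp_c`.
#' @return Tibble `plot_id`, `julian_day`, `mean_c`, ordered by plot and day.
#' @export
daily_means <- function(temperature) {
  if (nrow(temperature) == 0) abort("Empty temperature series.")
  temperature %>%
    group_by(.data$plot_id, .data$julian_day) %>%
    summarise(mean_c = mean(.data$temp_c), .groups = "drop") %>%
    arrange(.data$plot_id, .data$julian_day)
}

#' Seasonal thaw degree days (TDD) per plot
#'
#' TDD measures the magnitude of warming above 0 degC: the sum of daily mean
#' temperatures over all days strictly greater than 0 degC within the logged
#' window. Days at or below 0 degC contribute nothing. Over a fixed logging
#' window this is a relative measure of warmth between microtopographies,
#' not an absolute seasonal total.
#'
#' @param daily Tibble from [daily_means()].
#' @return Tibble `plot_id`, `tdd`.
#' @export
thaw_degree_days <- function(daily) {
  daily %>%
    group_by(.data$plot_id) %>%
    summarise(tdd = sum(.data$mean_c[.data$mean_c > 0]), .groups = "drop")
}

#' Cumulative TDD up to a (community-weighted) phenophase date
#'
#' For a real-valued community-weighted mean date, the cutoff is the date
#' rounded down to a whole Julian day; the cumulative TDD is the sum of
#' positive daily means for all logged days up to and including the cutoff.
#' A cutoff before the first logged day yields 0 with a warning.
#'
#' @param daily Named numeric vector of daily means for one plot, names =
#'   Julian days (as from `setNames(x$mean_c, x$julian_day)`).
#' @param cwm_date Real-valued Julian date(s).
#' @return Numeric vector of degree-day values, one per `cwm_date`.
#' @seealso [phenophase_tdd()] for the table-based version over all plots.
#' @export
cumulative_tdd <- function(daily, cwm_date) {
  days <- as.integer(names(daily))
  if (is.unsorted(days)) {
    daily <- daily[order(days)]
    days <- sort(days)
  }
  cutoff <- floor(cwm_date)
  if (any(cutoff < days[1])) {
    warn(sprintf("%d cutoff date(s) precede the first logged day (%d); returning 0.",
                 sum(cutoff < days[1]), days[1]))
  }
  cum_pos <- cumsum(pmax(daily, 0) * (daily > 0))
  idx <- findInterval(cutoff, days)
  out <- numeric(length(cutoff))
  out[idx > 0] <- cum_pos[idx[idx > 0]]
  unname(out)
}

#' Cumulative TDD for every (plot, phenophase) date
#'
#' Table version of [cumulative_tdd()]: joins each plot's daily-mean series
#' to its phenophase dates and returns one degree-day value per row of
#' `dates`.
#'
#' @param daily Tibble from [daily_means()].
#' @param dates Tibble with `plot_id`, `phenophase`, and a real-valued date
#'   column named by `date_col`.
#' @param date_col Name of the date column in `dates`.
#' @return `dates` with an added `cum_tdd` column.
#' @export
phenophase_tdd <- function(daily, dates, date_col = "cwm_date") {
  split_daily <- split(setNames(daily$mean_c, daily$julian_day), daily$plot_id)
  first_day <- min(daily$julian_day)
  cutoffs <- floor(dates[[date_col]])
  n_early <- sum(cutoffs < first_day, na.rm = TRUE)
  if (n_early > 0) {
    warn(sprintf("%d cutoff date(s) precede the first logged day (%d); returning 0.",
                 n_early, first_day))
  }
  dates$cum_tdd <- vapply(seq_len(nrow(dates)), function(i) {
    d <- split_daily[[dates$plot_id[i]]]
    if (is.null(d)) return(NA_real_)
    suppressWarnings(cumulative_tdd(d, dates[[date_col]][i]))
  }, numeric(1))
  dates
}

#' Per-plot thermal summary table
#'
#' Seasonal TDD per plot plus, when community-weighted dates are supplied,
#' one cumulative-TDD column per phenophase (`ctdd_<phenophase>`).
#'
#' @param temperature Hourly series tibble.
#' @param cwm_dates Optional tibble `plot_id`, `phenophase`, `cwm_date`.
#' @return Tibble `plot_id`, `tdd`, and optional `ctdd_*` columns.
#' @export
thermal_summary <- function(temperature, cwm_dates = NULL) {
  daily <- daily_means(temperature)
  out <- thaw_degree_days(daily)
  if (!is.null(cwm_dates) && nrow(cwm_dates) > 0) {
    ctdd <- phenophase_tdd(daily, cwm_dates) %>%
      mutate(phenophase = paste0("ctdd_", .data$phenophase)) %>%
      select("plot_id", "phenophase", "cum_tdd") %>%
      tidyr::pivot_wider(names_from = "phenophase", values_from = "cum_tdd")
    out <- left_join(out, ctdd, by = "plot_id")
  }
  out
}
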