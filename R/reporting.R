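#' Report configuration
#'
#' @param rounding decimal places for displayed values (default 1).
#' @param days_in_period days used for daily rates (default 365).
#' @param station_count stations in the market, for per-station averages.
#' @return List of class `report_config`.
#' @export
report_config <- function(rounding = 1L, days_in_period = 365L,
                          station_count = 36L) {
  if (rounding < 0 || days_in_period <= 0 || station_count <= 0)
    stop("report_config values must be positive")
  structure(list(rounding = as.integer(rounding),
                 days_in_period = days_in_period,
                 station_count = station_count),
            class = "report_config")
}

#' Round half away from zero
#'
#' Commercial rounding used for displayed exposures (base R's `round()`
#' rounds half to even). Applied once, after all aggregation.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Child-versus-adolescent difference statistics
#'
#' Absolute difference is adolescent minus child exposure; relative
#' difference divides that by the CHILD exposure (x 100). Differences are
#' computed on unrounded exposures and rounded last. A zero child exposure
#' leaves the relative difference `NA` (flagged, not infinite).
#'
#' @param child,adolescent per-capita exposures (ads/person/period), same
#'   length.
#' @param config [report_config()] controlling rounding.
#' @return `data.table`: `child_exposure`, `adolescent_exposure`,
#'   `absolute_diff`, `relative_diff_pct`, `relative_undefined`.
#' @examples
#' difference_row(2234.4, 1631.7)  # -602.7, -27.0%
#' @export
difference_row <- function(child, adolescent, config = report_config()) {
  if (any(child < 0) || any(adolescent < 0)) stop("exposures must be >= 0")
  abs_d <- adolescent - child
  rel_d <- ifelse(child > 0, abs_d / child * 100, NA_real_)
  d <- config$rounding
  data.table(
    child_exposure      = round_half_up(child, d),
    adolescent_exposure = round_half_up(adolescent, d),
    absolute_diff       = round_half_up(abs_d, d),
    relative_diff_pct   = round_half_up(rel_d, d),
    relative_undefined  = child == 0
  )
}

#' Average daily advertising exposure
#'
#' @param annual_exposure ads/person/period (>= 0).
#' @param config [report_config()]; supplies period length and rounding.
#' @return ads/person/day, rounded.
#' @examples
#' daily_rate(2234.4)  # 6.1
#' @export
daily_rate <- function(annual_exposure, config = report_config()) {
  if (any(annual_exposure < 0)) stop("annual_exposure must be >= 0")
  round_half_up(annual_exposure / config$days_in_period, config$rounding)
}

#' Share of advertising frequency covered by content coding
#'
#' @param coded_frequency weighted frequency of coded ads.
#' @param total_frequency total weighted frequency (> 0, >= coded).
#' @param config [report_config()].
#' @return Percent, rounded.
#' @examples
#' coverage_share(1670912, 1720673)  # 97.1
#' @export
coverage_share <- function(coded_frequency, total_frequency,
                           config = report_config()) {
  if (total_frequency <= 0) stop("total_frequency must be > 0")
  if (coded_frequency > total_frequency)
    stop("coded_frequency exceeds total_frequency")
  round_half_up(coded_frequency / total_frequency * 100, config$rounding)
}

#' Slice-level difference table
#'
#' Casts exposure estimates for two age groups into one row per slice with
#' the child/adolescent exposures and their absolute/relative differences.
#' The shared shape of the station, category, technique and healthfulness
#' reports.
#'
#' @param estimates output of [estimate_exposure()] containing both groups.
#' @param freq optional data.frame `slice`, `weighted_freq` to prepend
#'   frequency and percent-of-total columns.
#' @param child_group,adol_group age-group codes in `estimates`.
#' @param config [report_config()].
#' @return `data.table`, one row per slice.
#' @export
difference_table <- function(estimates, freq = NULL,
                             child_group = "child_2_11",
                             adol_group = "adolescent_12_17",
                             config = report_config()) {
  est <- as.data.table(estimates)
  miss <- setdiff(c(child_group, adol_group), unique(est$group))
  if (length(miss))
    stop("estimates lack groups: ", paste(miss, collapse = ", "))
  ch <- est[group == child_group, .(slice, child = exposure)]
  ad <- est[group == adol_group, .(slice, adol = exposure)]
  x <- merge(ch, ad, by = "slice")
  out <- cbind(x[, .(slice)], difference_row(x$child, x$adol, config))
  if (!is.null(freq)) {
    fq <- as.data.table(freq)
    out <- merge(fq[, .(slice, weighted_freq)], out, by = "slice",
                 all.y = TRUE)
    total <- fq[slice == "total", weighted_freq]
    if (!length(total)) total <- sum(fq$weighted_freq)
    out[, pct := round_half_up(weighted_freq / total * 100, config$rounding)]
    setcolorder(out, c("slice", "weighted_freq", "pct"))
  }
  out[]
}

#' Station exposure report with totals and per-station average
#'
#' One row per station (frequency, share, exposures, differences), a
#' `total` row from the total-slice estimates, and an `average_by_station`
#' row dividing the totals by the station count. Station rows partition the
#' total exposure.
#'
#' @param station_estimates [estimate_exposure()] output, `slice_by =
#'   "station"`; must cover every market station for both groups.
#' @param total_estimates [estimate_exposure()] output, `slice_by = "total"`.
#' @param freq optional data.frame `slice`, `weighted_freq` per station.
#' @param stations character vector of all market stations (defaults to
#'   stations present in the estimates).
#' @param child_group,adol_group age-group codes.
#' @param config [report_config()]; `station_count` sets the average's
#'   denominator.
#' @return `data.table` shaped like the published station table.
#' @export
station_table <- function(station_estimates, total_estimates, freq = NULL,
                          stations = NULL,
                          child_group = "child_2_11",
                          adol_group = "adolescent_12_17",
                          config = report_config()) {
  est <- as.data.table(station_estimates)
  if (is.null(stations)) stations <- sort(unique(est$slice))
  miss <- setdiff(stations, unique(est$slice))
  if (length(miss))
    stop("estimates missing stations: ", paste(miss, collapse = ", "))
  rows <- difference_table(est[slice %in% stations], freq,
                           child_group, adol_group, config)
  tot <- as.data.table(total_estimates)
  ch_t <- tot[group == child_group & slice == "total", exposure]
  ad_t <- tot[group == adol_group & slice == "total", exposure]
  total_row <- cbind(data.table(slice = "total"),
                     difference_row(ch_t, ad_t, config))
  avg_row <- cbind(data.table(slice = "average_by_station"),
                   difference_row(ch_t / config$station_count,
                                  ad_t / config$station_count, config))
  if (!is.null(freq)) {
    fq <- as.data.table(freq)
    total_wf <- sum(fq[slice %in% stations, weighted_freq])
    total_row[, `:=`(weighted_freq = total_wf, pct = 100)]
    avg_row[, `:=`(weighted_freq =
                     round_half_up(total_wf / config$station_count, 0),
                   pct = NA_real_)]
    setcolorder(total_row, names(rows))
    setcolorder(avg_row, names(rows))
  }
  rbind(rows, total_row, avg_row, fill = TRUE)
}

#' Write a report table to CSV or JSON
#'
#' CSV via `data.table::fwrite`, JSON via `jsonlite` with unboxed scalars;
#' both round-trip exactly through [read_report()] at the written
#' precision.
#'
#' @param x report `data.table`.
#' @param path output file; format inferred from extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") fwrite(x, path)
  else jsonlite::write_json(x, path, digits = NA, na = "null")
  invisible(path)
}

#' Read back a report table
#'
#' @param path file written by [write_report()].
#' @return `data.table`.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.table(jsonlite::read_json(path, simplifyVector = TRUE))
  else fread(path)
}
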