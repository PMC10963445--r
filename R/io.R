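#' Read a Tucson-format (RWL) ring-width file
#'
#' Parses the decadal Tucson format used for ring-width depositions: an
#' 8-character series id, a row-start year, and up to ten width values per
#' row, with a `999` (hundredths of mm) or `-9999` (thousandths of mm)
#' terminator after the final ring. Widths are returned in millimetres.
#'
#' @param path Path to an RWL file.
#' @return A tibble with columns `series_id`, `year`, `width` (mm), one row
#'   per measured ring, years strictly increasing within each series.
#' @export
#' @examples
#' f <- tempfile(fileext = ".rwl")
#' rings <- tibble::tibble(series_id = "TREE01A",
#'                         year = 1950:1959, width = seq(1, 0.1, by = -0.1))
#' write_rwl(rings, f)
#' read_rwl(f)
read_rwl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(series_id = character(), year = integer(), width = double()))
  }
  out <- vector("list", length(lines))
  scale_map <- list()
  prev_id <- ""
  expect_year <- NA_integer_
  closed_ids <- character()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    id <- trimws(substr(ln, 1, 8))
    rest <- strsplit(trimws(substr(ln, 9, nchar(ln))), "\\s+")[[1]]
    if (id == "" || length(rest) < 2) {
      abort(sprintf("malformed RWL row at line %d: '%s'", i, ln))
    }
    yr <- suppressWarnings(as.integer(rest[[1]]))
    vals <- suppressWarnings(as.numeric(rest[-1]))
    if (is.na(yr) || anyNA(vals)) {
      abort(sprintf("malformed RWL row at line %d: non-numeric field", i))
    }
    if (id != prev_id) {
      if (id %in% closed_ids) {
        abort(sprintf("duplicate series id '%s' at line %d", id, i))
      }
      if (prev_id != "") closed_ids <- c(closed_ids, prev_id)
      prev_id <- id
      expect_year <- yr
    }
    if (yr != expect_year) {
      abort(sprintf(
        "decade row at line %d starts at %d but %d was expected for series '%s'",
        i, yr, expect_year, id))
    }
    term <- length(vals) > 0 && vals[[length(vals)]] %in% c(999, -9999)
    if (term) {
      scale_map[[id]] <- if (vals[[length(vals)]] == -9999) 1000 else 100
      vals <- vals[-length(vals)]
    }
    n_slots <- 10 - (yr %% 10)
    if (!term && length(vals) != n_slots) {
      abort(sprintf(
        "decade row at line %d for series '%s' has %d values where %d fit the decade",
        i, id, length(vals), n_slots))
    }
    if (length(vals) > 0) {
      out[[i]] <- tibble(series_id = id,
                         year = yr + seq_along(vals) - 1L,
                         width = vals)
    }
    expect_year <- yr + length(vals)
    if (term) {
      closed_ids <- c(closed_ids, id)
      prev_id <- ""
      expect_year <- NA_integer_
    }
  }
  res <- bind_rows(out)
  # the terminator type fixes the units for the whole series (100ths of a
  # mm for 999, 1000ths for -9999); unterminated series default to 100ths
  scales <- vapply(res$series_id,
                   function(id) scale_map[[id]] %||% 100, numeric(1))
  res$width <- res$width / unname(scales)
  if (any(res$width < 0)) abort("negative ring width in RWL input")
  res
}

#' Write ring-width series to a Tucson (RWL) file
#'
#' Widths are written as integer thousandths of a millimetre with the
#' `-9999` terminator. Inputs finer than 0.001 mm are rounded with a warning.
#' Output is bit-stable: identical input produces identical bytes.
#'
#' @param rings Tibble with columns `series_id`, `year`, `width` (mm).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rings, path) {
  stopifnot_cols(rings, c("series_id", "year", "width"), "rings")
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(rings) == 0) {
    return(invisible(path))
  }
  if (any(nchar(rings$series_id) > 8)) {
    abort("series_id longer than 8 characters cannot be written to RWL")
  }
  if (any(rings$width < 0)) abort("ring widths must be non-negative")
  thous <- rings$width * 1000
  if (any(abs(thous - round(thous)) > 1e-6)) {
    warn("ring widths finer than 0.001 mm rounded to integer thousandths")
  }
  lines <- character()
  for (id in unique(rings$series_id)) {
    s <- rings[rings$series_id == id, ]
    s <- s[order(s$year), ]
    if (any(diff(s$year) != 1)) {
      abort(sprintf("series '%s' has non-contiguous years", id))
    }
    vals <- c(as.integer(round(s$width * 1000)), -9999L)
    yrs <- c(s$year, s$year[length(s$year)] + 1L)
    row_start <- 1L
    while (row_start <= length(vals)) {
      y0 <- yrs[row_start]
      n_fit <- 10L - (y0 %% 10L)
      idx <- row_start:min(row_start + n_fit - 1L, length(vals))
      lines <- c(lines, paste0(sprintf("%-8s", id), sprintf("%4d", y0),
                               paste0(sprintf("%6d", vals[idx]), collapse = "")))
      row_start <- row_start + length(idx)
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Seasonal mean of a daily or monthly temperature series
#'
#' Collapses a daily series (columns `date`, `value`) or a monthly series
#' (columns `year`, `month`, `value`) to one value per calendar year over the
#' given months — e.g. `months = 3:5` for the spring (MAM) season. For daily
#' input the mean is day-weighted over all days of the listed months and a
#' year is kept only if at least `min_coverage` of those days are observed;
#' for monthly input it is the unweighted mean of the monthly values, subject
#' to the same coverage fraction on months.
#'
#' @param data Daily or monthly tibble; an optional `site_id` column is
#'   carried through.
#' @param months Integer months in 1..12, non-empty.
#' @param min_coverage Minimum fraction of days (or months) that must be
#'   non-missing; years below it get `NA`.
#' @return Tibble with columns (`site_id`,) `year`, `value`, plus a
#'   `"season"` attribute naming the months used.
#' @export
seasonal_mean <- function(data, months = 3:5, min_coverage = 0.9) {
  if (length(months) == 0 || !all(months %in% 1:12)) {
    abort("`months` must be a non-empty subset of 1..12")
  }
  months <- sort(unique(as.integer(months)))
  has_site <- "site_id" %in% names(data)
  if ("date" %in% names(data)) {
    stopifnot_cols(data, c("date", "value"), "daily series")
    if (nrow(data) == 0) {
      out <- tibble(year = integer(), value = double())
    } else {
      d <- as.Date(data$date)
      if (anyDuplicated(paste(if (has_site) data$site_id else "", d))) {
        abort("duplicate dates in daily series")
      }
      df <- tibble(site_id = if (has_site) data$site_id else "series",
                   year = as.integer(format(d, "%Y")),
                   month = as.integer(format(d, "%m")),
                   value = data$value) %>%
        filter(.data$month %in% months)
      ndays <- function(y) {
        sum(vapply(months, function(m) {
          as.integer(as.Date(sprintf("%d-%02d-01", y + (m == 12), (m %% 12) + 1)) -
                       as.Date(sprintf("%d-%02d-01", y, m)))
        }, integer(1)))
      }
      out <- df %>%
        group_by(.data$site_id, .data$year) %>%
        summarise(n_obs = sum(!is.na(.data$value)),
                  value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
        mutate(total = vapply(.data$year, ndays, integer(1)),
               value = ifelse(.data$n_obs / .data$total >= min_coverage,
                              .data$value, NA_real_)) %>%
        select(dplyr::any_of("site_id"), "year", "value")
      if (!has_site) out$site_id <- NULL
    }
  } else {
    stopifnot_cols(data, c("year", "month", "value"), "monthly series")
    if (nrow(data) == 0) {
      out <- tibble(year = integer(), value = double())
    } else {
      out <- data %>%
        filter(.data$month %in% months) %>%
        group_by(dplyr::across(dplyr::any_of("site_id")), .data$year) %>%
        summarise(n_obs = sum(!is.na(.data$value)),
                  value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
        mutate(value = ifelse(.data$n_obs / length(months) >= min_coverage,
                              .data$value, NA_real_)) %>%
        select(dplyr::any_of("site_id"), "year", "value") %>%
        arrange(.data$year)
    }
  }
  attr(out, "season") <- paste(month.abb[months], collapse = "-")
  out
}

#' Winter (December-March) mean of a monthly circulation index
#'
#' Averages December of the preceding year with January-March of the labelled
#' year, the convention used for winter circulation indices such as the PNA
#' and NAM. Winter 1976/77 is labelled 1977, aligning the circulation state
#' with the following spring. Years whose preceding December (or any of the
#' four months) is absent are `NA`.
#'
#' @param index Monthly tibble with columns `year`, `month`, `value`; an
#'   optional `name` column is carried through.
#' @return Tibble with columns (`name`,) `year`, `value`.
#' @export
winter_mean_index <- function(index) {
  stopifnot_cols(index, c("year", "month", "value"), "index")
  if (anyDuplicated(index[c(intersect("name", names(index)), "year", "month")])) {
    abort("duplicate (year, month) in index")
  }
  has_name <- "name" %in% names(index)
  idx <- index %>%
    mutate(wyear = ifelse(.data$month == 12, .data$year + 1L,
                          ifelse(.data$month %in% 1:3, .data$year, NA_integer_))) %>%
    filter(!is.na(.data$wyear))
  out <- idx %>%
    group_by(dplyr::across(dplyr::any_of("name")), year = .data$wyear) %>%
    summarise(n_m = sum(!is.na(.data$value)),
              value = mean(.data$value), .groups = "drop") %>%
    mutate(value = ifelse(.data$n_m == 4L, .data$value, NA_real_)) %>%
    select(dplyr::any_of("name"), "year", "value") %>%
    arrange(.data$year)
  out
}

#' Daily station record to daily mean temperature
#'
#' Station CSVs carry `tmax`/`tmin` and sometimes a pre-computed `tmean`.
#' Both reductions are exposed: the archive's own daily mean where present,
#' or the midrange (tmax + tmin)/2.
#'
#' @param station Tibble with columns `date` and `tmax`,`tmin` and/or `tmean`.
#' @param method `"tmean"` to use the stored daily mean, `"minmax"` for
#'   (tmax + tmin)/2.
#' @return Tibble with columns (`site_id`,) `date`, `value` (degC).
#' @export
station_daily_mean <- function(station, method = c("tmean", "minmax")) {
  method <- match.arg(method)
  if (method == "tmean" && !"tmean" %in% names(station)) method <- "minmax"
  if (method == "tmean") {
    value <- station$tmean
  } else {
    stopifnot_cols(station, c("tmax", "tmin"), "station")
    value <- (station$tmax + station$tmin) / 2
  }
  out <- tibble(date = as.Date(station$date), value = value)
  if ("site_id" %in% names(station)) out <- tibble(site_id = station$site_id, out)
  out
}

#' Read or write an annual series CSV
#'
#' Annual series (one value per calendar year: a seasonal temperature, a
#' ring-width index, a green-up day of year) are the exchange format between
#' every analysis stage. Missing values are written as `NA`.
#'
#' @param path CSV path.
#' @return `read_annual_csv`: a tibble with at least `year` and `value`.
#' @export
read_annual_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, na = "NA")
  stopifnot_cols(out, c("year", "value"), "annual CSV")
  out
}

#' @rdname read_annual_csv
#' @param data Tibble with columns `year`, `value` (and optionally others).
#' @export
write_annual_csv <- function(data, path) {
  stopifnot_cols(data, c("year", "value"), "annual series")
  readr::write_csv(data, path, na = "NA")
  invisible(path)
}

#' Read a monthly index table
#'
#' Accepts comma- or whitespace-separated tables with columns
#' `year`, `month`, `value` (header optional for the whitespace form).
#'
#' @param path File path.
#' @param name Index name to attach (e.g. `"PNA"`).
#' @return Tibble with columns `name`, `year`, `month`, `value`.
#' @export
read_index_table <- function(path, name = "index") {
  first <- readLines(path, n = 1)
  if (grepl(",", first)) {
    raw <- readr::read_csv(path, show_col_types = FALSE, na = "NA")
  } else {
    raw <- readr::read_table(path, show_col_types = FALSE, na = "NA",
                             col_names = grepl("[A-Za-z]", first))
    if (!"year" %in% names(raw)) names(raw)[1:3] <- c("year", "month", "value")
  }
  stopifnot_cols(raw, c("year", "month", "value"), "index table")
  tibble(name = name, year = as.integer(raw$year),
         month = as.integer(raw$month), value = as.numeric(raw$value))
}
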