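#' Read daily acoustic monitoring records
#'
#' Combines an effort table (one row per site-day on which a logger was
#' deployed and recording) with a detections table (one row per site-day with
#' at least the click count) into a single validated daily record set. A
#' site-day listed in the effort file but absent from the detections file is
#' a sampled day with zero detections, not a missing day; a site-day absent
#' from the effort file contributed no effort and carries no counts.
#'
#' The canonical column schema is `site_id, date` for the effort file and
#' `site_id, date, clicks, dpm` for the detections file (`dpm` =
#' detection-positive minutes, optional). Files with other headers can be
#' adapted through `col_map` without editing them.
#'
#' @param detections_path path to a delimited text file of daily detections.
#' @param effort_path path to a delimited text file of sampled site-days.
#' @param col_map optional named list (or path to a YAML file holding one)
#'   mapping canonical names (`site_id`, `date`, `clicks`, `dpm`) to the
#'   column names actually present in the files.
#' @param grid optional [site_grid()]; if given, any record whose site id is
#'   not on the grid is a hard error naming the offending row.
#' @param sep field separator, default comma.
#' @return data frame of class `daily_records` with columns `site_id`,
#'   `date` (Date), `clicks`, `dpm`, `sampled`.
#' @export
load_daily_records <- function(detections_path, effort_path, col_map = NULL,
                               grid = NULL, sep = ",") {
  map <- resolve_col_map(col_map)
  eff <- utils::read.table(effort_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  det <- utils::read.table(detections_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  eff <- rename_canonical(eff, map, c("site_id", "date"), effort_path)
  det <- rename_canonical(det, map, c("site_id", "date", "clicks"),
                          detections_path)
  if (is.null(det$dpm)) det$dpm <- NA_real_

  eff$site_id <- as.character(eff$site_id)
  det$site_id <- as.character(det$site_id)
  eff$date <- as.Date(eff$date)
  det$date <- as.Date(det$date)
  if (anyNA(eff$date) || anyNA(det$date))
    stop("unparseable dates in input files (expected ISO yyyy-mm-dd)",
         call. = FALSE)

  key_e <- paste(eff$site_id, eff$date)
  key_d <- paste(det$site_id, det$date)
  if (anyDuplicated(key_e))
    stop("duplicate (site, date) rows in effort file: ",
         key_e[anyDuplicated(key_e)], call. = FALSE)
  if (anyDuplicated(key_d))
    stop("duplicate (site, date) rows in detections file: ",
         key_d[anyDuplicated(key_d)], call. = FALSE)
  if (!is.null(grid)) {
    bad <- setdiff(unique(c(eff$site_id, det$site_id)), grid$site_id)
    if (length(bad))
      stop("unknown site id(s) not on the grid: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(det$clicks < 0, na.rm = TRUE))
    stop("negative click counts in row(s) ",
         paste(which(det$clicks < 0), collapse = ", "),
         " of detections file", call. = FALSE)
  if (any(det$dpm < 0 | det$dpm > 1440, na.rm = TRUE))
    stop("detection-positive minutes outside [0, 1440]", call. = FALSE)
  orphan <- !(key_d %in% key_e) & det$clicks > 0
  if (any(orphan))
    stop("detections on site-days with no recorded effort: ",
         paste(utils::head(key_d[orphan], 5), collapse = "; "), call. = FALSE)

  idx <- match(key_e, key_d)
  rec <- data.frame(
    site_id = eff$site_id,
    date = eff$date,
    clicks = ifelse(is.na(idx), 0, det$clicks[idx]),
    dpm = ifelse(is.na(idx), 0, ifelse(is.na(det$dpm[idx]), 0, det$dpm[idx])),
    sampled = TRUE,
    stringsAsFactors = FALSE
  )
  if (any(rec$dpm > 0 & rec$clicks == 0))
    stop("records with positive detection-positive minutes but zero clicks",
         call. = FALSE)
  rec <- rec[order(rec$site_id, rec$date), ]
  rownames(rec) <- NULL
  class(rec) <- c("daily_records", "data.frame")
  rec
}

resolve_col_map <- function(col_map) {
  defaults <- list(site_id = "site_id", date = "date",
                   clicks = "clicks", dpm = "dpm")
  if (is.null(col_map)) return(defaults)
  if (is.character(col_map) && length(col_map) == 1)
    col_map <- yaml::read_yaml(col_map)
  utils::modifyList(defaults, as.list(col_map))
}

rename_canonical <- function(df, map, required, path) {
  for (canon in names(map)) {
    src <- map[[canon]]
    if (src %in% names(df)) names(df)[names(df) == src] <- canon
  }
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Julian day of year
#'
#' Day-of-year number (1 = 1 January). The analysis window is anchored on
#' Julian day numbers (170-231, i.e. 19 June - 19 August in non-leap years);
#' in leap years the same day numbers fall one calendar day earlier.
#'
#' @param date a Date vector.
#' @return integer day-of-year.
#' @export
julian_day <- function(date) {
  as.POSIXlt(date)$yday + 1L
}

#' Aggregate daily records into site-by-year summaries
#'
#' For every site and year, computes the mean number of clicks per sampled
#' day, W_ti, averaged over the n_ti days sampled inside the core window, and
#' the effort count n_ti itself. Site-years with no sampled days inside the
#' window are missing, never zero: the model distinguishes "no effort" from
#' "effort but silence".
#'
#' @param records a `daily_records` frame from [load_daily_records()].
#' @param grid a [site_grid()] listing all monitoring sites (sites with no
#'   data in some year still occupy a position in the spatial model).
#' @param core_window integer length-2 vector of Julian day bounds,
#'   inclusive; default `c(170, 231)`, the 62-day summer window.
#' @return object of class `monitoring_dataset`: list with elements `grid`,
#'   `summaries` (data frame `year`, `site_id`, `W`, `n`), `core_window`.
#' @export
annualize <- function(records, grid, core_window = c(170L, 231L)) {
  if (nrow(records) == 0) stop("empty record set", call. = FALSE)
  stopifnot(length(core_window) == 2, core_window[1] <= core_window[2])
  jd <- julian_day(records$date)
  keep <- records$sampled & jd >= core_window[1] & jd <= core_window[2]
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0)
    stop("no sampled days fall inside the core window", call. = FALSE)
  year <- as.integer(format(rec$date, "%Y"))
  key <- interaction(year, rec$site_id, drop = TRUE)
  W <- tapply(rec$clicks, key, mean)
  n <- tapply(rec$clicks, key, length)
  parts <- strsplit(names(W), ".", fixed = TRUE)
  summaries <- data.frame(
    year = as.integer(vapply(parts, `[[`, "", 1)),
    site_id = vapply(parts, function(p) paste(p[-1], collapse = "."), ""),
    W = as.numeric(W),
    n = as.integer(n),
    stringsAsFactors = FALSE
  )
  summaries <- summaries[order(summaries$year, summaries$site_id), ]
  rownames(summaries) <- NULL
  monitoring_dataset(grid, summaries, core_window)
}

#' Assemble a monitoring dataset from pre-aggregated summaries
#'
#' @param grid a [site_grid()].
#' @param summaries data frame with columns `year`, `site_id`, `W`, `n`.
#' @param core_window Julian-day window the summaries were computed over.
#' @return object of class `monitoring_dataset`.
#' @export
monitoring_dataset <- function(grid, summaries, core_window = c(170L, 231L)) {
  stopifnot(inherits(grid, "site_grid"))
  req <- c("year", "site_id", "W", "n")
  if (!all(req %in% names(summaries)))
    stop("summaries must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  summaries$site_id <- as.character(summaries$site_id)
  if (anyDuplicated(summaries[c("year", "site_id")]))
    stop("more than one summary for some (year, site) pair", call. = FALSE)
  if (!all(summaries$site_id %in% grid$site_id))
    stop("summaries reference sites absent from the grid", call. = FALSE)
  window_len <- core_window[2] - core_window[1] + 1L
  if (any(summaries$n < 1) || any(summaries$n > window_len))
    stop("effort counts must be in [1, ", window_len, "]", call. = FALSE)
  if (any(summaries$W < 0)) stop("W must be nonnegative", call. = FALSE)
  structure(list(grid = grid, summaries = summaries,
                 core_window = as.integer(core_window)),
            class = "monitoring_dataset")
}

#' @export
print.monitoring_dataset <- function(x, ...) {
  yrs <- sort(unique(x$summaries$year))
  cat(sprintf(paste0("Monitoring dataset: %d sites, years %d-%d, ",
                     "core window Julian %d-%d\n"),
              nrow(x$grid), min(yrs), max(yrs),
              x$core_window[1], x$core_window[2]))
  tab <- table(x$summaries$year)
  cat("Site-years with data per year:\n")
  print(tab)
  invisible(x)
}

#' Raw (effort-unadjusted) between-year change
#'
#' Ratio of the cross-site mean of W between two years, each mean taken over
#' the sites with data in that year. This descriptive ratio ignores the
#' imbalance of effort across sites and years that the geostatistical model
#' corrects for; it is reported for comparison only.
#'
#' @param dataset a `monitoring_dataset`.
#' @param year_a,year_b earlier and later year.
#' @return list with `ratio` (mean_b / mean_a; `NA` when the year-a mean is
#'   zero), `percent_decline` = (1 - ratio) * 100, `mean_a`, `mean_b`, and
#'   the per-year site counts used.
#' @export
raw_change <- function(dataset, year_a, year_b) {
  s <- dataset$summaries
  wa <- s$W[s$year == year_a]
  wb <- s$W[s$year == year_b]
  if (length(wa) == 0 || length(wb) == 0)
    stop("both years must have at least one site with data", call. = FALSE)
  ma <- mean(wa)
  mb <- mean(wb)
  if (ma == 0) {
    warning("cross-site mean in year ", year_a,
            " is zero; ratio undefined", call. = FALSE)
    ratio <- NA_real_
  } else {
    ratio <- mb / ma
  }
  list(ratio = ratio, percent_decline = (1 - ratio) * 100,
       mean_a = ma, mean_b = mb,
       n_sites = c(length(wa), length(wb)))
}

#' Daily effort series
#'
#' Number of sites actively sampling on each (year, Julian day), the standard
#' effort diagnostic plot for a fixed monitoring grid.
#'
#' @param records a `daily_records` frame.
#' @return data frame `year`, `julian_day`, `n_active`.
#' @export
effort_series <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(year = integer(), julian_day = integer(),
                      n_active = integer()))
  rec <- records[records$sampled, , drop = FALSE]
  year <- as.integer(format(rec$date, "%Y"))
  jd <- julian_day(rec$date)
  agg <- stats::aggregate(list(n_active = rec$site_id),
                          by = list(year = year, julian_day = jd),
                          FUN = length)
  agg <- agg[order(agg$year, agg$julian_day), ]
  rownames(agg) <- NULL
  agg
}

#' Write / read annualized summaries as headered CSV
#'
#' Round-trip serialization of a `monitoring_dataset`: `<stem>_summaries.csv`
#' (year, site_id, W, n) and `<stem>_sites.csv` (site_id, easting_km,
#' northing_km).
#'
#' @param dataset a `monitoring_dataset`.
#' @param stem path stem for the two CSV files.
#' @return `write_dataset` the two paths invisibly; `read_dataset` the
#'   reconstructed `monitoring_dataset`.
#' @export
write_dataset <- function(dataset, stem) {
  ps <- paste0(stem, "_summaries.csv")
  pg <- paste0(stem, "_sites.csv")
  utils::write.csv(dataset$summaries, ps, row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$grid), pg, row.names = FALSE)
  invisible(c(summaries = ps, sites = pg))
}

#' @rdname write_dataset
#' @param core_window Julian-day window recorded with the summaries.
#' @export
read_dataset <- function(stem, core_window = c(170L, 231L)) {
  s <- utils::read.csv(paste0(stem, "_summaries.csv"),
                       stringsAsFactors = FALSE)
  g <- utils::read.csv(paste0(stem, "_sites.csv"), stringsAsFactors = FALSE)
  monitoring_dataset(site_grid(g$site_id, g$easting_km, g$northing_km),
                     s, core_window)
}
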