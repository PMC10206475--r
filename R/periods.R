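#' Assign 30-day sampling periods to observation records
#'
#' Within each (troop, field season), consecutive non-overlapping 30-day
#' windows are generated starting from the first day on which data were
#' collected in that season *for the record stream at hand* — proximity and
#' grooming streams processed separately therefore get different window
#' boundaries. A trailing partial window is generated like any other and left
#' to the observation-count filter.
#'
#' @param records Record data frame with `datetime` and `troop` columns (scan
#'   or grooming/dominance schema).
#' @param seasons Season table (`troop`, `year`, `start_date`, `end_date`).
#' @return The records with added columns `year`, `period` (1-based index
#'   within the season), `period_start`, `period_end`. A record dated outside
#'   every declared season for its troop is an error.
#' @export
assign_periods <- function(records, seasons) {
  if (nrow(records) == 0) {
    records$year <- integer(0); records$period <- integer(0)
    records$period_start <- as.Date(character())
    records$period_end <- as.Date(character())
    return(records)
  }
  date <- as.Date(records$datetime)
  records$year <- NA_integer_
  for (s in seq_len(nrow(seasons))) {
    hit <- records$troop == seasons$troop[s] &
      date >= seasons$start_date[s] & date <= seasons$end_date[s]
    records$year[hit] <- seasons$year[s]
  }
  if (anyNA(records$year)) {
    bad <- which(is.na(records$year))
    stop(sprintf("%d record(s) fall outside every declared season (first: %s, troop %s)",
                 length(bad), format(date[bad[1]]), records$troop[bad[1]]),
         call. = FALSE)
  }
  key <- paste(records$troop, records$year)
  anchor <- stats::ave(as.numeric(date), key, FUN = min)
  offset <- as.numeric(date) - anchor
  records$period <- as.integer(offset %/% 30 + 1)
  records$period_start <- as.Date(anchor + (records$period - 1) * 30,
                                  origin = "1970-01-01")
  records$period_end <- records$period_start + 29
  records
}

#' Summarize sampling periods
#'
#' @param records Period-tagged records (see [assign_periods()]).
#' @return One row per (troop, year, period) with window dates and
#'   `n_observations`.
#' @export
periods_table <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(troop = character(), year = integer(),
                      period = integer(), period_start = as.Date(character()),
                      period_end = as.Date(character()),
                      n_observations = integer()))
  }
  agg <- stats::aggregate(
    list(n_observations = records$period),
    by = list(troop = records$troop, year = records$year,
              period = records$period,
              period_start = records$period_start,
              period_end = records$period_end),
    FUN = length)
  agg[order(agg$troop, agg$year, agg$period), ]
}

#' Drop sparsely sampled periods
#'
#' Removes every (troop, year, period) with fewer than `min_obs` observation
#' records, the robustness filter applied before building networks.
#'
#' @param records Period-tagged records.
#' @param min_obs Minimum observations per period (default 95).
#' @return Filtered records; removed periods are reported via [message()] and
#'   attached as attribute `"removed_periods"`.
#' @export
filter_periods <- function(records, min_obs = 95) {
  pt <- periods_table(records)
  drop <- pt[pt$n_observations < min_obs, ]
  if (nrow(drop) > 0) {
    message(sprintf("filter_periods: removing %d period(s) with < %d observations",
                    nrow(drop), min_obs))
    key <- paste(records$troop, records$year, records$period)
    records <- records[!(key %in% paste(drop$troop, drop$year, drop$period)), ]
  }
  attr(records, "removed_periods") <- drop
  records
}

#' Drop rarely seen individuals
#'
#' Excludes, within each (troop, season), individuals seen fewer than
#' `min_sightings` times in the record stream (e.g. individuals who died or
#' emigrated mid-season). For scans, a sighting is any subgroup membership;
#' excluded ids are scrubbed from subgroup memberships and scans whose focal
#' is excluded are dropped. For grooming, a sighting is participation in an
#' event; events involving an excluded individual are dropped.
#'
#' @param records Scan or grooming records (period tagging not required).
#' @param seasons Season table, used to attribute records to seasons.
#' @param kind `"scan"` or `"grooming"`.
#' @param min_sightings Minimum sightings per season (default 5).
#' @return Filtered records with attribute `"excluded"` (data frame of
#'   troop, year, id).
#' @export
filter_individuals <- function(records, seasons, kind = c("scan", "grooming"),
                               min_sightings = 5) {
  kind <- match.arg(kind)
  if (nrow(records) == 0) return(records)
  date <- as.Date(records$datetime)
  year <- rep(NA_integer_, nrow(records))
  for (s in seq_len(nrow(seasons))) {
    hit <- records$troop == seasons$troop[s] &
      date >= seasons$start_date[s] & date <= seasons$end_date[s]
    year[hit] <- seasons$year[s]
  }
  if (anyNA(year)) stop("record outside every declared season", call. = FALSE)

  if (kind == "scan") {
    members <- subgroup_members(records)
    long <- data.frame(
      id = unlist(members),
      key = rep(paste(records$troop, year), lengths(members)))
  } else {
    long <- data.frame(
      id = c(records$giver_id, records$recipient_id),
      key = rep(paste(records$troop, year), 2))
  }
  counts <- stats::aggregate(list(n = long$id),
                             by = list(key = long$key, id = long$id),
                             FUN = length)
  excl <- counts[counts$n < min_sightings, ]
  excluded <- data.frame(
    troop = sub(" .*$", "", excl$key),
    year = as.integer(sub("^.* ", "", excl$key)),
    id = excl$id)
  if (nrow(excluded) > 0) {
    message(sprintf("filter_individuals: excluding %d individual-season(s) seen < %d times",
                    nrow(excluded), min_sightings))
    key <- paste(records$troop, year)
    if (kind == "scan") {
      members <- subgroup_members(records)
      keep <- rep(TRUE, nrow(records))
      for (r in seq_len(nrow(records))) {
        out_ids <- excluded$id[paste(excluded$troop, excluded$year) == key[r]]
        if (length(out_ids) == 0) next
        if (records$focal_id[r] %in% out_ids) { keep[r] <- FALSE; next }
        members[[r]] <- setdiff(members[[r]], out_ids)
      }
      records$subgroup_ids <- vapply(members, paste, character(1),
                                     collapse = ";")
      records <- records[keep, ]
    } else {
      ex_key <- paste(excluded$troop, excluded$year, excluded$id)
      keep <- !(paste(key, records$giver_id) %in% ex_key |
                  paste(key, records$recipient_id) %in% ex_key)
      records <- records[keep, ]
    }
  }
  rownames(records) <- NULL
  attr(records, "excluded") <- excluded
  records
}
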