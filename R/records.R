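#' Read observation records from CSV
#'
#' Parses the standard record schemas used throughout the package:
#'
#' * `scan`: `datetime, troop, focal_id, subgroup_ids` (semicolon-joined,
#'   including the focal; a subgroup of size 1 is an individual recorded
#'   alone);
#' * `grooming` / `dominance`: `datetime, troop, giver_id, recipient_id`;
#' * `individual`: `id, sex, birth_date, mother_id, troop`;
#' * `season`: `troop, year, start_date, end_date`.
#'
#' Structural problems (missing columns, unparsable timestamps or dates) are
#' errors naming the offending lines. Row-level invariant violations
#' (grooming giver equal to recipient, a focal missing from its own subgroup)
#' are dropped with a warning listing line numbers; duplicate ids within a
#' subgroup are collapsed (set semantics). An empty file with a valid header
#' yields an empty frame with a warning.
#'
#' @param path CSV file path.
#' @param kind One of `"scan"`, `"grooming"`, `"dominance"`, `"individual"`,
#'   `"season"`.
#' @return A typed data frame of records.
#' @export
read_records <- function(path, kind = c("scan", "grooming", "dominance",
                                        "individual", "season")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- switch(kind,
    scan = c("datetime", "troop", "focal_id", "subgroup_ids"),
    grooming = ,
    dominance = c("datetime", "troop", "giver_id", "recipient_id"),
    individual = c("id", "sex", "birth_date", "mother_id", "troop"),
    season = c("troop", "year", "start_date", "end_date"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning(sprintf("%s: no data rows", path), call. = FALSE)
  }
  # data line numbers (header is line 1)
  line <- seq_len(nrow(df)) + 1L

  parse_time <- function(x, what) {
    # per-format strptime: unparsable strings become NA (and then a
    # line-numbered error) instead of aborting the whole read
    out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                      tz = "UTC")
    for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                  "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
      idx <- which(is.na(out))
      if (length(idx) == 0) break
      out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"), tz = "UTC")
    }
    bad <- which(is.na(out) & !is.na(x) & nzchar(x))
    if (length(bad) > 0) {
      stop(sprintf("%s: unparsable %s at line(s) %s", path, what,
                   paste(line[bad], collapse = ", ")), call. = FALSE)
    }
    out
  }
  parse_date <- function(x, what) {
    out <- as.Date(x)
    bad <- which(is.na(out) & !is.na(x) & nzchar(x))
    if (length(bad) > 0) {
      stop(sprintf("%s: unparsable %s at line(s) %s", path, what,
                   paste(line[bad], collapse = ", ")), call. = FALSE)
    }
    out
  }

  if (kind %in% c("grooming", "dominance")) {
    df$datetime <- parse_time(df$datetime, "timestamp")
    bad <- which(df$giver_id == df$recipient_id)
    if (length(bad) > 0) {
      warning(sprintf("%s: dropped %d row(s) with giver == recipient (line(s) %s)",
                      path, length(bad), paste(line[bad], collapse = ", ")),
              call. = FALSE)
      df <- df[-bad, ]
    }
  } else if (kind == "scan") {
    df$datetime <- parse_time(df$datetime, "timestamp")
    members <- strsplit(df$subgroup_ids, ";", fixed = TRUE)
    members <- lapply(members, function(m) unique(trimws(m)))
    bad <- which(!mapply(function(f, m) f %in% m, df$focal_id, members))
    if (length(bad) > 0) {
      warning(sprintf("%s: dropped %d scan(s) whose focal is missing from the subgroup (line(s) %s)",
                      path, length(bad), paste(line[bad], collapse = ", ")),
              call. = FALSE)
      df <- df[-bad, ]
      members <- members[-bad]
    }
    df$subgroup_ids <- vapply(members, paste, character(1), collapse = ";")
  } else if (kind == "individual") {
    df$birth_date <- parse_date(df$birth_date, "birth_date")
    df$mother_id[!nzchar(df$mother_id)] <- NA_character_
  } else if (kind == "season") {
    df$start_date <- parse_date(df$start_date, "start_date")
    df$end_date <- parse_date(df$end_date, "end_date")
    df$year <- as.integer(df$year)
  }
  rownames(df) <- NULL
  df
}

# Split semicolon-joined subgroup strings into a list of id vectors.
subgroup_members <- function(records) {
  lapply(strsplit(records$subgroup_ids, ";", fixed = TRUE),
         function(m) unique(trimws(m)))
}
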