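#' Simulate proximity scan records for one 30-day period
#'
#' Emulates the field protocol: focal individuals are drawn from a randomized
#' list of all troop members; every troop member within 10 m of the focal is
#' recorded as a proximity subgroup (size 1 = recorded alone). Each individual
#' receives `scans_per_individual_per_month` focal scans at distinct
#' (day, hour) slots, so no individual is re-sampled as a focal within one
#' simulated hour. Each potential neighbour `j` joins focal `i`'s subgroup
#' independently with probability `propensities$assoc[i, j]`.
#'
#' @param population Data frame from [make_population()] (one or more troops).
#' @param propensities Result of [latent_propensities()].
#' @param config A [sim_config()].
#' @param period_start Date of the first day of the 30-day window.
#' @param seed Integer seed for this period (derived from the config seed by
#'   [simulate_troop()]).
#' @return Data frame of scan records: `datetime`, `troop`, `focal_id`,
#'   `subgroup_ids` (semicolon-joined, includes the focal).
#' @export
simulate_scans <- function(population, propensities, config,
                           period_start = season_starts(config)[1],
                           seed = config$rng_seed) {
  set.seed(seed)
  P <- propensities$assoc
  m <- config$scans_per_individual_per_month
  out <- vector("list", nrow(population))
  slot_hours <- 7:17
  n_slots <- 30 * length(slot_hours)
  if (m > n_slots) stop("more scans than hourly slots in a period")
  k <- 0
  for (tr in unique(population$troop)) {
    t_ids <- population$id[population$troop == tr]
    for (focal in sample(t_ids)) {
      slots <- sample.int(n_slots, m)
      day <- (slots - 1) %/% length(slot_hours) + 1
      hour <- slot_hours[(slots - 1) %% length(slot_hours) + 1]
      # one within-hour offset per focal keeps successive focal scans a full
      # hour apart (the protocol's no-resampling-within-an-hour rule)
      offset <- round(stats::runif(1, 0, 3599))
      others <- setdiff(t_ids, focal)
      p <- P[focal, others]
      members <- lapply(seq_len(m), function(s) {
        c(focal, others[stats::runif(length(others)) < p])
      })
      k <- k + 1
      out[[k]] <- data.frame(
        datetime = as.POSIXct(period_start, tz = "UTC") +
          (day - 1) * 86400 + hour * 3600 + offset,
        troop = tr,
        focal_id = focal,
        subgroup_ids = vapply(members, paste, character(1), collapse = ";")
      )
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$datetime), ]
  rownames(res) <- NULL
  res
}

#' Simulate directed grooming events for one 30-day period
#'
#' Directed events are sampled with probability proportional to the grooming
#' propensity of each ordered dyad; a grooming dyad (either direction) is not
#' recorded more than once within the same half-hour, mirroring the field
#' deduplication rule.
#'
#' @inheritParams simulate_scans
#' @return Data frame of grooming records: `datetime`, `troop`, `giver_id`,
#'   `recipient_id`.
#' @export
simulate_grooming <- function(population, propensities, config,
                              period_start = season_starts(config)[1],
                              seed = config$rng_seed) {
  set.seed(seed)
  G <- propensities$groom
  out <- list()
  for (tr in unique(population$troop)) {
    t_ids <- population$id[population$troop == tr]
    n <- length(t_ids)
    if (n < 2) next
    n_events <- round(n * config$grooming_events_per_individual_per_month / 2)
    Gt <- G[t_ids, t_ids, drop = FALSE]
    probs <- as.vector(Gt)
    if (sum(probs) == 0) next
    pick <- sample.int(n * n, n_events, replace = TRUE, prob = probs)
    gi <- (pick - 1) %% n + 1
    ri <- (pick - 1) %/% n + 1   # column-major: entry [gi, ri] = giver -> recipient
    times <- as.POSIXct(period_start, tz = "UTC") +
      sample.int(30, n_events, replace = TRUE) * 86400 - 86400 +
      round(stats::runif(n_events, 7 * 3600, 18 * 3600))
    ev <- data.frame(datetime = times, troop = tr,
                     giver_id = t_ids[gi], recipient_id = t_ids[ri])
    ev <- ev[ev$giver_id != ev$recipient_id, ]
    out[[tr]] <- dedupe_grooming(ev)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(datetime = as.POSIXct(character(), tz = "UTC"),
                      troop = character(), giver_id = character(),
                      recipient_id = character())
  }
  res <- res[order(res$datetime), ]
  rownames(res) <- NULL
  res
}

# Keep at most one record per unordered dyad per half-hour: events are walked
# in time order and dropped while within 30 min of the last kept record of
# the same dyad.
dedupe_grooming <- function(events) {
  if (nrow(events) == 0) return(events)
  key <- paste(pmin(events$giver_id, events$recipient_id),
               pmax(events$giver_id, events$recipient_id))
  keep <- rep(TRUE, nrow(events))
  ord <- order(key, events$datetime)
  last_key <- ""
  last_time <- -Inf
  for (r in ord) {
    if (key[r] == last_key &&
        as.numeric(difftime(events$datetime[r], last_time, units = "mins")) <= 30) {
      keep[r] <- FALSE
    } else {
      last_key <- key[r]
      last_time <- events$datetime[r]
    }
  }
  events[keep, ]
}

#' Simulate ad libitum dominance interactions for one field season
#'
#' Adult females interact at random; the higher-ranked female of a dyad (by
#' the troop's latent order) wins with probability
#' `plogis(steepness * gap)` where `gap` is the difference in latent relative
#' rank. Infinite steepness gives a fully deterministic hierarchy; zero
#' steepness makes wins coin flips.
#'
#' @inheritParams simulate_scans
#' @param latent_ranks Named list: for each troop, a character vector of adult
#'   female ids in latent rank order (highest first), as produced by
#'   [simulate_troop()].
#' @param season_start First day of the season.
#' @param n_days Days covered by the season's interactions.
#' @return Data frame of interactions: `datetime`, `troop`, `giver_id`
#'   (winner), `recipient_id` (loser).
#' @export
simulate_dominance <- function(population, config, latent_ranks,
                               season_start = season_starts(config)[1],
                               n_days = 60, seed = config$rng_seed) {
  set.seed(seed)
  out <- list()
  for (tr in unique(population$troop)) {
    order_ids <- latent_ranks[[tr]]
    n <- length(order_ids)
    if (n < 2) stop("simulate_dominance needs at least two adult females")
    rel <- standardize_rank(seq_len(n), n)  # 1 = highest -> rel 1
    n_int <- round(config$dominance_interactions_per_dyad * choose(n, 2))
    a <- sample.int(n, n_int, replace = TRUE)
    b <- sample.int(n - 1, n_int, replace = TRUE)
    b <- ifelse(b >= a, b + 1, b)
    gap <- rel[a] - rel[b]
    p_a_wins <- if (is.infinite(config$dominance_steepness)) {
      as.numeric(gap > 0) + 0.5 * (gap == 0)
    } else {
      stats::plogis(config$dominance_steepness * gap)
    }
    a_wins <- stats::runif(n_int) < p_a_wins
    win <- ifelse(a_wins, a, b)
    lose <- ifelse(a_wins, b, a)
    out[[tr]] <- data.frame(
      datetime = as.POSIXct(season_start, tz = "UTC") +
        sample.int(n_days, n_int, replace = TRUE) * 86400 - 86400 +
        round(stats::runif(n_int, 7 * 3600, 18 * 3600)),
      troop = tr,
      giver_id = order_ids[win],
      recipient_id = order_ids[lose]
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$datetime), ]
  rownames(res) <- NULL
  res
}
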