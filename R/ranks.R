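#' Win matrix from dominance interactions
#'
#' @param records Dominance records (`giver_id` won over `recipient_id`).
#' @param ids Optional id order; defaults to the sorted union of participants.
#' @return Square count matrix: `wins[i, j]` = interactions `i` won over `j`.
#' @export
dominance_matrix <- function(records, ids = NULL) {
  if (is.null(ids)) {
    ids <- sort(unique(c(records$giver_id, records$recipient_id)))
  }
  wins <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(records) > 0) {
    tab <- table(factor(records$giver_id, levels = ids),
                 factor(records$recipient_id, levels = ids))
    wins <- wins + unclass(tab)
  }
  diag(wins) <- 0
  wins
}

# Lexicographic (I, SI) objective of an ordering. A dyad is inconsistent when
# the individual ranked lower won more interactions than the one ranked
# higher; ties in win counts and unknown (0-0) dyads contribute nothing. SI
# sums the rank distances of inconsistent dyads.
isi_objective <- function(wins, order_idx) {
  n <- length(order_idx)
  w <- wins[order_idx, order_idx, drop = FALSE]
  upper <- upper.tri(w)
  inc <- upper & (t(w) > w)      # lower-ranked (col) beat higher-ranked (row)
  I <- sum(inc)
  SI <- sum((col(w)[inc] - row(w)[inc]))
  c(I = I, SI = SI)
}

better <- function(a, b) a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])

#' I&SI dominance ordering
#'
#' Finds a linear hierarchy minimizing first the number of inconsistencies I
#' (dyads in which the lower-ranked individual won more interactions), then
#' the total strength of inconsistencies SI (the summed rank distances of
#' inconsistent dyads). The optimum is searched by repeated pairwise-swap
#' improvement passes from random restarts; exhaustive-search tests pin
#' correctness at small group sizes.
#'
#' @param wins Win count matrix from [dominance_matrix()].
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Seed controlling the restarts.
#' @return List: `order` (ids, highest rank first), `I`, `SI`.
#' @export
isi_order <- function(wins, n_restarts = 100, seed = 1L) {
  n <- nrow(wins)
  if (n < 2) stop("isi_order: need at least two individuals", call. = FALSE)
  if (all(wins == 0)) {
    stop("isi_order: all-zero win matrix, ordering undefined", call. = FALSE)
  }
  set.seed(seed)
  # seed ordering: win proportion (David's-score-like start)
  totals <- rowSums(wins) / pmax(1, rowSums(wins) + colSums(wins))
  best_ord <- order(totals, decreasing = TRUE)
  best_obj <- isi_objective(wins, best_ord)

  improve <- function(ord) {
    obj <- isi_objective(wins, ord)
    repeat {
      improved <- FALSE
      for (a in seq_len(n - 1)) {
        for (b in (a + 1):n) {
          cand <- ord
          cand[c(a, b)] <- cand[c(b, a)]
          cobj <- isi_objective(wins, cand)
          if (better(cobj, obj)) {
            ord <- cand; obj <- cobj; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    list(ord = ord, obj = obj)
  }

  res <- improve(best_ord)
  best_ord <- res$ord; best_obj <- res$obj
  for (r in seq_len(n_restarts)) {
    res <- improve(sample.int(n))
    if (better(res$obj, best_obj)) {
      best_ord <- res$ord; best_obj <- res$obj
    }
  }
  list(order = rownames(wins)[best_ord],
       I = unname(best_obj[1]), SI = unname(best_obj[2]))
}

#' Standardize an ordinal rank by group size
#'
#' `1 - (1 - r) / (1 - n)`: maps ordinal rank `r` (1 = highest) in a group of
#' `n` to a relative rank between 0 (lowest) and 1 (highest), evenly spaced.
#'
#' @param r Ordinal rank(s), 1-based.
#' @param n Group size (>= 2).
#' @return Relative rank(s) in \[0, 1\].
#' @export
standardize_rank <- function(r, n) {
  if (n < 2) stop("standardize_rank: n must be >= 2", call. = FALSE)
  if (any(r < 1 | r > n)) {
    stop("standardize_rank: r out of range 1..n", call. = FALSE)
  }
  1 - (1 - r) / (1 - n)
}

#' Seasonal adult-female rank table
#'
#' Computes I&SI ordinal ranks per (troop, season) from dominance
#' interactions and standardizes them to relative ranks.
#'
#' @param dominance Dominance records.
#' @param seasons Season table.
#' @param n_restarts,seed Passed to [isi_order()].
#' @return Data frame: `troop`, `year`, `id`, `ordinal_rank`,
#'   `relative_rank`.
#' @export
rank_table <- function(dominance, seasons, n_restarts = 100, seed = 1L) {
  date <- as.Date(dominance$datetime)
  out <- list()
  for (s in seq_len(nrow(seasons))) {
    recs <- dominance[dominance$troop == seasons$troop[s] &
                        date >= seasons$start_date[s] &
                        date <= seasons$end_date[s], ]
    if (nrow(recs) == 0) next
    wins <- dominance_matrix(recs)
    ord <- isi_order(wins, n_restarts = n_restarts, seed = seed)
    n <- length(ord$order)
    out[[length(out) + 1]] <- data.frame(
      troop = seasons$troop[s], year = seasons$year[s], id = ord$order,
      ordinal_rank = seq_len(n),
      relative_rank = standardize_rank(seq_len(n), n))
  }
  do.call(rbind, out)
}
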