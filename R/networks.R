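#' Group-by-individual matrix for one troop-period
#'
#' One row per recorded subgroup (including "alone" rows of size 1), one
#' column per individual; entry 1 iff the individual was in the subgroup.
#'
#' @param records Scan records of a single troop-period.
#' @param ids Optional fixed column order; defaults to the sorted union of
#'   observed members.
#' @return Binary matrix with individuals as named columns.
#' @export
gbi_matrix <- function(records, ids = NULL) {
  if (nrow(records) == 0) stop("gbi_matrix: empty period", call. = FALSE)
  members <- subgroup_members(records)
  if (is.null(ids)) ids <- sort(unique(unlist(members)))
  gbi <- matrix(0L, nrow = length(members), ncol = length(ids),
                dimnames = list(NULL, ids))
  for (r in seq_along(members)) {
    gbi[r, intersect(members[[r]], ids)] <- 1L
  }
  gbi
}

#' Simple ratio index association matrix
#'
#' For every pair (A, B), `SRI = x / (x + yA + yB)` where `x` is the number of
#' subgroups containing both and `yA`, `yB` the numbers containing only one of
#' them: the proportion of sampled subgroups involving either individual in
#' which the two were associated (0 = never associated, 1 = always
#' associated). Joint absences do not enter the denominator. A pair whose
#' denominator is zero (neither individual ever observed) is undefined: the
#' value is stored as 0 and flagged in the `"mask"` attribute.
#'
#' @param gbi Group-by-individual matrix from [gbi_matrix()].
#' @return Symmetric matrix of SRI values in \[0, 1\] with zero diagonal and
#'   a logical `"mask"` attribute marking undefined pairs.
#' @export
sri_matrix <- function(gbi) {
  x <- crossprod(gbi)                      # joint appearances
  n <- diag(x)                             # total appearances
  denom <- outer(n, n, "+") - x            # x + yA + yB
  mask <- denom == 0
  sri <- ifelse(mask, 0, x / ifelse(mask, 1, denom))
  diag(sri) <- 0
  diag(mask) <- FALSE
  dimnames(sri) <- dimnames(x)
  dimnames(mask) <- dimnames(x)
  attr(sri, "mask") <- mask
  sri
}

#' Grooming matrix for one troop-period
#'
#' Counts of directed grooming events aggregated per dyad. `given` is the
#' giver-to-recipient count matrix, `received` its transpose, and `total` the
#' symmetrized sum (given + received per unordered dyad). With
#' `proportion = TRUE` rows of the requested mode are normalized to sum to 1
#' (an individual with no events keeps an all-zero row).
#'
#' @param records Grooming records of a single troop-period.
#' @param ids Optional fixed id order; defaults to the sorted union of
#'   participants.
#' @param mode One of `"given"`, `"received"`, `"total"`.
#' @param proportion Normalize rows to proportions?
#' @return Square matrix with named dimensions.
#' @export
grooming_matrix <- function(records, ids = NULL,
                            mode = c("given", "received", "total"),
                            proportion = FALSE) {
  mode <- match.arg(mode)
  if (is.null(ids)) {
    ids <- sort(unique(c(records$giver_id, records$recipient_id)))
  }
  given <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(records) > 0) {
    tab <- table(factor(records$giver_id, levels = ids),
                 factor(records$recipient_id, levels = ids))
    given <- given + unclass(tab)
  }
  out <- switch(mode,
                given = given,
                received = t(given),
                total = given + t(given))
  if (proportion) {
    rs <- rowSums(out)
    out <- out / ifelse(rs == 0, 1, rs)
  }
  out
}

#' Extract an ego-network vector
#'
#' Returns the matrix row of `id` with the columns in `drop_ids` removed, in
#' a recorded column order so that two ego vectors extracted with the same
#' `drop_ids` are aligned and comparable (as needed for mother-offspring
#' similarity).
#'
#' @param matrix Square weighted matrix with id dimnames.
#' @param id Ego id (must be present).
#' @param drop_ids Ids whose columns are removed (typically both members of
#'   the focal dyad).
#' @return Named numeric vector.
#' @export
ego_vector <- function(matrix, id, drop_ids = id) {
  if (!(id %in% rownames(matrix))) {
    stop(sprintf("ego_vector: id '%s' not in matrix", id), call. = FALSE)
  }
  keep <- setdiff(colnames(matrix), drop_ids)
  matrix[id, keep]
}

#' Build per troop-period networks from record streams
#'
#' Applies the full aggregation protocol: 30-day period assignment anchored
#' at each season's first observation date (separately per stream), the
#' minimum-sightings individual filter, the minimum-observations period
#' filter, then builds a group-by-individual matrix and SRI association
#' matrix per proximity troop-period and a directed count matrix per grooming
#' troop-period.
#'
#' @param scans Scan records (raw schema).
#' @param grooming Grooming records (raw schema).
#' @param seasons Season table.
#' @param min_obs Minimum observations per retained period (default 95).
#' @param min_sightings Minimum sightings per individual-season (default 5).
#' @return Object of class `troop_networks`: a list with elements `proximity`
#'   and `grooming`, each a named list (key `troop|year|period`) of
#'   per-period entries carrying `troop`, `year`, `period`, window dates,
#'   `ids`, `n_obs`, and `gbi` + `sri` (proximity) or `counts` (grooming,
#'   directed given matrix).
#' @export
build_networks <- function(scans, grooming, seasons, min_obs = 95,
                           min_sightings = 5) {
  prox <- assign_periods(scans, seasons)
  prox <- suppressMessages(filter_individuals(prox, seasons, "scan",
                                              min_sightings))
  prox <- suppressMessages(filter_periods(prox, min_obs))
  gr <- assign_periods(grooming, seasons)
  gr <- suppressMessages(filter_individuals(gr, seasons, "grooming",
                                            min_sightings))
  gr <- suppressMessages(filter_periods(gr, min_obs))

  split_key <- function(df) split(df, paste(df$troop, df$year, df$period,
                                            sep = "|"), drop = TRUE)
  prox_nets <- lapply(split_key(prox), function(recs) {
    gbi <- gbi_matrix(recs)
    list(troop = recs$troop[1], year = recs$year[1], period = recs$period[1],
         period_start = recs$period_start[1], period_end = recs$period_end[1],
         ids = colnames(gbi), n_obs = nrow(recs),
         gbi = gbi, sri = sri_matrix(gbi), records = recs)
  })
  groom_nets <- lapply(split_key(gr), function(recs) {
    ids <- sort(unique(c(recs$giver_id, recs$recipient_id)))
    list(troop = recs$troop[1], year = recs$year[1], period = recs$period[1],
         period_start = recs$period_start[1], period_end = recs$period_end[1],
         ids = ids, n_obs = nrow(recs),
         counts = grooming_matrix(recs, ids, "given"), records = recs)
  })
  structure(list(proximity = prox_nets, grooming = groom_nets),
            class = "troop_networks")
}

#' @export
print.troop_networks <- function(x, ...) {
  cat("<troop_networks>\n")
  cat(sprintf("  proximity: %d troop-period network(s)\n", length(x$proximity)))
  cat(sprintf("  grooming:  %d troop-period network(s)\n", length(x$grooming)))
  invisible(x)
}

#' Export networks as edge lists and GraphML
#'
#' Writes one edge-list CSV (`id_a, id_b, weight, kind, mode`) covering every
#' troop-period network, and one GraphML file per network.
#'
#' @param networks A `troop_networks` object.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
export_networks <- function(networks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); files <- c()
  emit <- function(mat, net, kind, mode, directed) {
    g <- igraph::graph_from_adjacency_matrix(mat, weighted = TRUE,
                                             mode = if (directed) "directed" else "undirected",
                                             diag = FALSE)
    el <- igraph::as_data_frame(g, "edges")
    if (nrow(el) > 0) {
      rows[[length(rows) + 1]] <<- data.frame(
        troop = net$troop, year = net$year, period = net$period,
        id_a = el$from, id_b = el$to, weight = el$weight,
        kind = kind, mode = mode)
    }
    gml <- file.path(dir, sprintf("%s_%s_%s_%d_p%d.graphml", kind, mode,
                                  net$troop, net$year, net$period))
    igraph::write_graph(g, gml, format = "graphml")
    files <<- c(files, gml)
  }
  for (net in networks$proximity) emit(net$sri, net, "proximity", "sri", FALSE)
  for (net in networks$grooming) emit(net$counts, net, "grooming", "given", TRUE)
  edge_path <- file.path(dir, "edges.csv")
  utils::write.csv(do.call(rbind, rows), edge_path, row.names = FALSE)
  invisible(c(edge_path, files))
}
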