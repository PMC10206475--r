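#' Node strength
#'
#' Sum of the edge weights incident to each node: `out` sums rows, `in` sums
#' columns, `total` their sum; `undirected` equals the row sums of a
#' symmetric matrix.
#'
#' @param mat Weighted square matrix with id dimnames.
#' @param mode One of `"undirected"`, `"out"`, `"in"`, `"total"`.
#' @return Named numeric vector.
#' @export
node_strength <- function(mat, mode = c("undirected", "out", "in", "total")) {
  mode <- match.arg(mode)
  switch(mode,
         undirected = rowSums(mat),
         out = rowSums(mat),
         "in" = colSums(mat),
         total = rowSums(mat) + colSums(mat))
}

#' Weighted eigenvector centrality
#'
#' Leading-eigenvector score of the (symmetric) weight matrix, rescaled so
#' the maximum is 1, via igraph. Directed grooming networks must be collapsed
#' to the symmetrized total first (the given/received components cannot be
#' separated for centrality). On disconnected graphs the score concentrates
#' on the dominant component and other components fall to ~0, which is
#' reported via a message.
#'
#' @param mat Symmetric non-negative weight matrix.
#' @return Named numeric vector with maximum 1.
#' @export
eigencentrality <- function(mat) {
  if (all(mat == 0)) {
    stop("eigencentrality: all-zero matrix", call. = FALSE)
  }
  if (max(abs(mat - t(mat))) > 1e-8) {
    stop("eigencentrality: matrix must be symmetric (use the total network)",
         call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(mat, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::count_components(g) > 1) {
    message("eigencentrality: graph is disconnected; scores outside the ",
            "dominant component are ~0")
  }
  # eigen_centrality max-scales its result (scale argument retired in
  # igraph >= 2.1)
  res <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  res[colnames(mat)]
}

#' Weighted betweenness centrality
#'
#' Fractional count of shortest paths through each node (Brandes), with edge
#' length equal to the raw weight (`"weights_as_costs"`, the convention of
#' the graph library the analysis replicates — larger association weight
#' means a *longer* path) or its reciprocal (`"inverse_weights"`, the
#' biologically intuitive reading where strong associations are short paths).
#' Zero-weight pairs are non-edges.
#'
#' @param mat Weighted square matrix; treated as undirected if symmetric.
#' @param weight_handling `"weights_as_costs"` or `"inverse_weights"`.
#' @return Named numeric vector.
#' @export
betweenness_w <- function(mat,
                          weight_handling = c("weights_as_costs",
                                              "inverse_weights")) {
  weight_handling <- match.arg(weight_handling)
  directed <- max(abs(mat - t(mat))) > 1e-8
  g <- igraph::graph_from_adjacency_matrix(
    mat, mode = if (directed) "directed" else "undirected",
    weighted = TRUE, diag = FALSE)
  w <- igraph::E(g)$weight
  if (weight_handling == "inverse_weights") w <- 1 / w
  res <- igraph::betweenness(g, weights = w)
  res[colnames(mat)]
}

# metric name -> transform, mirroring the transforms used to normalize each
# metric's distribution before standardization
metric_transforms <- c(
  strength_prox = "identity",
  strength_groom_given = "log1p",
  strength_groom_received = "identity",
  strength_groom_total = "identity",
  eigencent_prox = "identity",
  eigencent_groom_total = "sqrt",
  betweenness_prox = "log1p",
  betweenness_groom_total = "sqrt"
)

#' Transform metric values
#'
#' Applies the metric-specific variance-stabilizing transform: `log1p` for
#' proximity betweenness and grooming strength given, `sqrt` for grooming
#' centrality and betweenness, identity otherwise.
#'
#' @param values Numeric vector (non-negative for `sqrt`).
#' @param kind A metric name (see [metric_table()]) or one of `"identity"`,
#'   `"log1p"`, `"sqrt"`.
#' @return Transformed values.
#' @export
metric_transform <- function(values, kind) {
  if (kind %in% names(metric_transforms)) kind <- metric_transforms[[kind]]
  switch(kind,
         identity = values,
         log1p = log1p(values),
         sqrt = {
           if (any(values < 0)) {
             stop("metric_transform: negative input to sqrt", call. = FALSE)
           }
           sqrt(values)
         },
         stop("metric_transform: unknown transform ", kind, call. = FALSE))
}

#' Standardize values within groups
#'
#' Z-scores (`mean 0, sample sd 1`) computed independently within each
#' period, making node metrics comparable across networks of different
#' sizes. A zero-variance group is returned as all zeros with a warning.
#'
#' @param values Numeric vector.
#' @param period Grouping factor (one level per sampling period).
#' @return Standardized values.
#' @export
standardize_within_period <- function(values, period = rep(1, length(values))) {
  out <- numeric(length(values))
  for (g in unique(period)) {
    idx <- period == g
    v <- values[idx]
    s <- stats::sd(v)
    if (length(v) < 2 || is.na(s) || s == 0) {
      warning("standardize_within_period: zero variance in a period; ",
              "returning zeros", call. = FALSE)
      out[idx] <- 0
    } else {
      out[idx] <- (v - mean(v)) / s
    }
  }
  out
}

#' Node-level metric table across troop-periods
#'
#' Computes, for every troop-period network, the metric roster of the
#' analysis — proximity strength/eigenvector centrality/betweenness on the
#' SRI network, grooming strength given/received/total on counts, and
#' grooming eigenvector centrality/betweenness on the symmetrized total
#' count network — then applies each metric's transform and standardizes
#' within period.
#'
#' @param networks A `troop_networks` object from [build_networks()].
#' @param metrics Optional subset of metric names to compute (default: all).
#' @return Long data frame: `troop`, `year`, `period`, `kind`, `metric`,
#'   `id`, `raw`, `transformed`, `standardized`.
#' @export
metric_table <- function(networks, metrics = NULL) {
  want <- function(m) is.null(metrics) || m %in% metrics
  rows <- list()
  add <- function(net, kind, metric, vals) {
    if (!want(metric)) return(invisible())
    tr <- metric_transform(vals, metric)
    rows[[length(rows) + 1]] <<- data.frame(
      troop = net$troop, year = net$year, period = net$period,
      period_start = net$period_start, kind = kind,
      metric = metric, id = names(vals), raw = unname(vals),
      transformed = unname(tr),
      standardized = suppressWarnings(standardize_within_period(unname(tr))))
  }
  for (net in networks$proximity) {
    if (want("strength_prox")) {
      add(net, "proximity", "strength_prox", node_strength(net$sri))
    }
    if (want("eigencent_prox")) {
      ec <- tryCatch(suppressMessages(eigencentrality(net$sri)),
                     error = function(e) NULL)
      if (!is.null(ec)) add(net, "proximity", "eigencent_prox", ec)
    }
    if (want("betweenness_prox")) {
      add(net, "proximity", "betweenness_prox", betweenness_w(net$sri))
    }
  }
  for (net in networks$grooming) {
    counts <- net$counts
    total <- counts + t(counts)
    if (want("strength_groom_given")) {
      add(net, "grooming", "strength_groom_given",
          node_strength(counts, "out"))
    }
    if (want("strength_groom_received")) {
      add(net, "grooming", "strength_groom_received",
          node_strength(counts, "in"))
    }
    if (want("strength_groom_total")) {
      add(net, "grooming", "strength_groom_total", node_strength(total))
    }
    if (want("eigencent_groom_total")) {
      ec <- tryCatch(suppressMessages(eigencentrality(total)),
                     error = function(e) NULL)
      if (!is.null(ec)) add(net, "grooming", "eigencent_groom_total", ec)
    }
    if (want("betweenness_groom_total")) {
      add(net, "grooming", "betweenness_groom_total", betweenness_w(total))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
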